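#' Default task names for the four-condition tiling MPRA design
#'
#' Two cell lines (K562, HepG2) crossed with two promoters (minimal promoter
#' minP, strong promoter SV40P).
#' @export
mpra_tasks <- function() c("K562_minP", "K562_SV40P", "HepG2_minP", "HepG2_SV40P")

#' Construct an MPRA dataset
#'
#' Bundles fragment metadata, per-task activity labels, and optional
#' per-replicate measurements into a single object used by the fitting,
#' attribution and evaluation functions.
#'
#' @param fragments Data frame with columns `fragment_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `sequence`, and optionally
#'   `region_id`, `tile_offset`, `state`.
#' @param labels N x T numeric matrix of per-task activities
#'   (replicate-averaged).  Column names are the task names.
#' @param replicates Optional list of N x T matrices, one per replicate.
#' @param fragment_length Expected fragment length (default 145).
#' @return An object of class `mpra_dataset`.
#' @export
mpra_dataset <- function(fragments, labels, replicates = NULL,
                         fragment_length = 145L) {
  stopifnot(is.data.frame(fragments), is.matrix(labels),
            nrow(fragments) == nrow(labels))
  need <- c("fragment_id", "chrom", "start", "end", "strand", "sequence")
  miss <- setdiff(need, names(fragments))
  if (length(miss)) stop("fragments missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(fragments$fragment_id))
    stop("duplicate fragment_id values")
  if (!all(fragments$end - fragments$start == nchar(fragments$sequence)))
    stop("end - start must equal sequence length")
  if (!all(nchar(fragments$sequence) == fragment_length))
    stop("all sequences must have length ", fragment_length)
  if (is.null(colnames(labels)))
    colnames(labels) <- if (ncol(labels) == 4) mpra_tasks() else
      paste0("task", seq_len(ncol(labels)))
  if (!is.null(replicates)) {
    stopifnot(is.list(replicates),
              all(vapply(replicates, function(r)
                all(dim(r) == dim(labels)), logical(1))))
  }
  structure(list(
    fragments = fragments,
    labels = labels,
    replicates = replicates,
    tasks = colnames(labels),
    partition = NULL,
    normalization = NULL,
    augmented = FALSE,
    fragment_length = as.integer(fragment_length)
  ), class = "mpra_dataset")
}

#' @export
print.mpra_dataset <- function(x, ...) {
  cat("MPRA dataset:", nrow(x$fragments), "fragments x", length(x$tasks),
      "tasks (", paste(x$tasks, collapse = ", "), ")\n")
  if (!is.null(x$partition))
    print(table(partition = x$partition))
  if (!is.null(x$normalization)) cat("labels z-score normalized\n")
  if (!is.null(x$replicates))
    cat(length(x$replicates), "replicates retained (raw scale)\n")
  invisible(x)
}

#' Partition fragments by chromosome
#'
#' Assigns every fragment to train, validation or test purely as a function
#' of its chromosome, so that no tiled region contributes near-duplicate
#' sequences to two partitions.  Defaults follow the held-out-chromosome
#' scheme: chr8 for validation and chr18 for testing; everything else trains.
#'
#' @param x An `mpra_dataset`.
#' @param val_chroms,test_chroms Character vectors of chromosome names;
#'   must be disjoint.
#' @return The dataset with `$partition` set (a factor named by fragment_id
#'   with levels train/val/test).
#' @export
split_by_chromosome <- function(x, val_chroms = "chr8", test_chroms = "chr18") {
  stopifnot(inherits(x, "mpra_dataset"))
  if (length(intersect(val_chroms, test_chroms)))
    stop("val_chroms and test_chroms must be disjoint")
  p <- rep("train", nrow(x$fragments))
  p[x$fragments$chrom %in% val_chroms] <- "val"
  p[x$fragments$chrom %in% test_chroms] <- "test"
  x$partition <- factor(stats::setNames(p, x$fragments$fragment_id),
                        levels = c("train", "val", "test"))
  names(x$partition) <- x$fragments$fragment_id
  x
}

#' Z-score normalize activity labels per task
#'
#' Centers and scales each task's labels using mean and standard deviation
#' estimated on the training partition only, then applies those parameters
#' to all partitions; the parameters are stored for inverse transforms.
#' For a plain matrix, pass the row indices to fit on.
#'
#' @param x An `mpra_dataset` (with a partition set) or an N x T matrix.
#' @param fit_idx For the matrix method: integer/logical row index of the
#'   fitting subset (default all rows).
#' @return For a dataset: the dataset with normalized `$labels` and
#'   `$normalization = list(mean, sd)`.  For a matrix: a list with elements
#'   `labels`, `mean`, `sd`.
#' @export
zscore_normalize <- function(x, fit_idx = NULL) UseMethod("zscore_normalize")

#' @rdname zscore_normalize
#' @export
zscore_normalize.matrix <- function(x, fit_idx = NULL) {
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(x))
  fit <- x[fit_idx, , drop = FALSE]
  if (nrow(fit) < 2) stop("need at least 2 observations per task to normalize")
  mu <- colMeans(fit)
  ## population sd, so a normalized column has mean exactly 0 and variance 1
  sd <- sqrt(colMeans(sweep(fit, 2, mu)^2))
  if (any(sd <= 0)) stop("zero-variance task: cannot z-score normalize")
  list(labels = sweep(sweep(x, 2, mu), 2, sd, "/"), mean = mu, sd = sd)
}

#' @rdname zscore_normalize
#' @export
zscore_normalize.mpra_dataset <- function(x, fit_idx = NULL) {
  if (!is.null(x$normalization)) stop("labels are already normalized")
  if (is.null(fit_idx)) {
    if (is.null(x$partition)) stop("set a partition first (split_by_chromosome)")
    fit_idx <- which(x$partition == "train")
  }
  z <- zscore_normalize(x$labels, fit_idx)
  x$labels <- z$labels
  x$normalization <- list(mean = z$mean, sd = z$sd)
  x
}

#' Augment the training partition with reverse-complement copies
#'
#' Each training fragment gains a reverse-complement twin carrying an
#' identical label vector, doubling the number of training examples.  The
#' copies are flagged (`augmented` column, id suffix `::rc`) and are used
#' for fitting only; evaluation functions operate on original orientations.
#'
#' @param x An `mpra_dataset` with a partition.
#' @return The augmented dataset (`$augmented` set to `TRUE`).
#' @export
augment_with_revcomp <- function(x) {
  stopifnot(inherits(x, "mpra_dataset"))
  if (isTRUE(x$augmented)) stop("dataset is already augmented")
  if (is.null(x$partition)) stop("set a partition first (split_by_chromosome)")
  tr <- which(x$partition == "train")
  fr <- x$fragments
  fr$augmented <- FALSE
  if (length(tr)) {
    add <- fr[tr, , drop = FALSE]
    add$fragment_id <- paste0(add$fragment_id, "::rc")
    add$sequence <- vapply(add$sequence, revcomp_seq, character(1), USE.NAMES = FALSE)
    add$strand <- ifelse(add$strand == "+", "-", "+")
    add$augmented <- TRUE
    x$fragments <- rbind(fr, add)
    x$labels <- rbind(x$labels, x$labels[tr, , drop = FALSE])
    if (!is.null(x$replicates))
      x$replicates <- lapply(x$replicates, function(r)
        rbind(r, r[tr, , drop = FALSE]))
    newp <- factor(c(as.character(x$partition), rep("train", length(tr))),
                   levels = levels(x$partition))
    names(newp) <- x$fragments$fragment_id
    x$partition <- newp
  } else {
    x$fragments <- fr
  }
  x$augmented <- TRUE
  x
}

#' Collapse 25-state ChromHMM labels to promoter/enhancer/repressed/other
#'
#' Groups chromatin-state names: Tss and PromF become `promoter`; Enh, EnhF,
#' DnaseD, DnaseU and FaireW become `enhancer`; Repr, ReprW, ReprD and Quies
#' become `repressed`; anything else (including unknown strings) maps to
#' `other`.  A leading numeric prefix such as `"10_Tss"` is tolerated.
#'
#' @param states Character vector of state names.
#' @return Factor with levels promoter, enhancer, repressed, other.
#' @export
map_chromhmm_states <- function(states) {
  s <- sub("^[0-9]+_", "", as.character(states))
  grp <- rep("other", length(s))
  grp[s %in% c("Tss", "PromF")] <- "promoter"
  grp[s %in% c("Enh", "EnhF", "DnaseD", "DnaseU", "FaireW")] <- "enhancer"
  grp[s %in% c("Repr", "ReprW", "ReprD", "Quies")] <- "repressed"
  factor(grp, levels = c("promoter", "enhancer", "repressed", "other"))
}

## Convenience accessors -----------------------------------------------------

#' Subset an MPRA dataset to one partition
#' @param x An `mpra_dataset`.
#' @param which One of "train", "val", "test".
#' @param drop_augmented Drop reverse-complement copies (default FALSE).
#' @return List with `fragments`, `labels`, `replicates` for that partition.
#' @export
dataset_partition <- function(x, which = c("train", "val", "test"),
                              drop_augmented = FALSE) {
  which <- match.arg(which)
  if (is.null(x$partition)) stop("dataset has no partition")
  idx <- which(x$partition == which)
  if (drop_augmented && "augmented" %in% names(x$fragments))
    idx <- idx[!x$fragments$augmented[idx]]
  list(fragments = x$fragments[idx, , drop = FALSE],
       labels = x$labels[idx, , drop = FALSE],
       replicates = lapply(x$replicates, function(r) r[idx, , drop = FALSE]))
}
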