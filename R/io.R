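#' Read fragment or genome sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an activity table
#'
#' Tab-separated with header columns `fragment_id`, `chrom`, `start`,
#' `end`, `strand`, optionally `sequence`, then one column per task and
#' optionally `<task>_rep1` / `<task>_rep2` replicate columns.  Extra
#' metadata columns (`region_id`, `tile_offset`, `state`) are carried
#' through.  When `sequence` is absent a `fasta` file keyed by fragment_id
#' must be supplied.
#'
#' @param path TSV file.
#' @param tasks Task column names (default [mpra_tasks()]).
#' @param fasta Optional FASTA path providing sequences.
#' @return An [mpra_dataset()].
#' @export
read_activity_table <- function(path, tasks = mpra_tasks(), fasta = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(tasks, names(df))
  if (length(miss)) stop("missing task columns: ", paste(miss, collapse = ", "))
  if (!"sequence" %in% names(df)) {
    if (is.null(fasta)) stop("no sequence column and no FASTA supplied")
    seqs <- read_fasta(fasta)
    df$sequence <- unname(seqs[df$fragment_id])
    if (anyNA(df$sequence)) stop("FASTA does not cover all fragment ids")
  }
  labels <- as.matrix(df[, tasks, drop = FALSE])
  rep_cols1 <- paste0(tasks, "_rep1")
  rep_cols2 <- paste0(tasks, "_rep2")
  replicates <- NULL
  if (all(c(rep_cols1, rep_cols2) %in% names(df)))
    replicates <- list(as.matrix(stats::setNames(df[, rep_cols1], tasks)),
                       as.matrix(stats::setNames(df[, rep_cols2], tasks)))
  meta <- intersect(c("fragment_id", "chrom", "start", "end", "strand",
                      "sequence", "region_id", "tile_offset", "state"),
                    names(df))
  mpra_dataset(df[, meta, drop = FALSE], labels, replicates,
               fragment_length = nchar(df$sequence[1]))
}

#' Write an activity table
#' @param dataset An [mpra_dataset()].
#' @param path Output TSV.
#' @export
write_activity_table <- function(dataset, path) {
  df <- dataset$fragments
  lab <- as.data.frame(dataset$labels)
  names(lab) <- dataset$tasks
  out <- cbind(df, lab)
  if (!is.null(dataset$replicates)) {
    for (r in seq_along(dataset$replicates)) {
      rp <- as.data.frame(dataset$replicates[[r]])
      names(rp) <- paste0(dataset$tasks, "_rep", r)
      out <- cbind(out, rp)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mpracnn activity table; one-hot column order A,C,G,T; ",
                    "coordinates 0-based half-open"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses the letter-probability matrices of a MEME minimal motif file
#' (alphabet ACGT).
#'
#' @param path MEME file.
#' @return List of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s", lines[i])) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) && !grepl("letter-probability", lines[j]))
        j <- j + 1L
      if (j > length(lines)) stop("MOTIF ", id, " has no probability matrix")
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      m <- do.call(rbind, lapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
      ## guard against rounding in the file
      m <- m / rowSums(m)
      out[[length(out) + 1L]] <- pwm(id, m, "prob")
      i <- j + w + 1L
    } else i <- i + 1L
  }
  out
}

#' Write motifs in MEME minimal format
#' @param pwms List of probability [pwm()]s.
#' @param path Output file.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (p in pwms) {
    stopifnot(p$type == "prob")
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       p$width), con)
    for (i in seq_len(p$width))
      writeLines(paste(sprintf("%.6f", p$matrix[i, ]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read BED intervals
#'
#' @param path BED file (>= 3 columns).
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$name)) gr$name else NA_character_,
                   score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  df
}

#' Write BED6 intervals
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand` (0-based half-open).
#' @param path Output file.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(intervals$start < intervals$end))
  df <- data.frame(
    chrom = intervals$chrom, start = intervals$start, end = intervals$end,
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0,
    strand = if ("strand" %in% names(intervals)) intervals$strand else "+")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read biallelic SNPs from a VCF
#'
#' Multi-allelic records are split into one biallelic evaluation per
#' alternate allele; indels are skipped with a count.
#'
#' @param path VCF file.
#' @return Data frame with `variant_id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`; attribute `n_skipped_indels`.
#' @export
read_vcf_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (a in alts) {
      if (nchar(fix$REF[i]) != 1L || nchar(a) != 1L) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = if (is.na(fix$ID[i]) || fix$ID[i] == ".")
          sprintf("%s:%s", fix$CHROM[i], fix$POS[i]) else fix$ID[i],
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = a)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_skipped_indels") <- skipped
  out
}

#' Write SNPs to a minimal VCF 4.2 file
#' @param variants Data frame with `variant_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param path Output file.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                     v$chrom, v$pos, v$variant_id, v$ref, v$alt), con)
  invisible(path)
}

#' Write a complete simulation to disk
#'
#' Emits the formats the package reads back: regions FASTA, activity TSV
#' (with replicate columns), planted-motif BED, MEME motif file, and, when
#' variants were simulated, VCF, LD TSV (`tag_id`, `proxy_id`, `r2`) and
#' GWAS TSV (`variant_id`, `p`).
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param variants Optional result of [simulate_variants()].
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir, variants = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$truth$region_seq, file.path(dir, "regions.fa"))
  write_activity_table(sim$dataset, file.path(dir, "activity.tsv"))
  inst <- sim$truth$instances
  if (nrow(inst))
    write_bed(data.frame(chrom = inst$region_id, start = inst$start,
                         end = inst$end, name = inst$motif_id,
                         score = round(inst$match_frac, 4),
                         strand = inst$strand),
              file.path(dir, "planted_motifs.bed"))
  write_meme(lapply(sim$truth$motif_library, `[[`, "pwm"),
             file.path(dir, "motifs.meme"))
  if (!is.null(variants)) {
    write_vcf(variants$variants, file.path(dir, "variants.vcf"))
    utils::write.table(variants$ld, file.path(dir, "ld.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(variants$gwas, file.path(dir, "gwas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Save a fitted model to a checkpoint directory
#'
#' Writes the parameters (plain text RDS-free: one `dput` file), the
#' architecture and training configuration as YAML, the normalization
#' parameters and the training history.
#'
#' @param model A fitted [mpra_cnn()].
#' @param dir Checkpoint directory.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(
    spec = unclass(model$spec),
    control = if (!is.null(model$control)) unclass(model$control),
    tasks = model$tasks),
    file.path(dir, "model.yaml"))
  ## parameters and normalization go through dput (hex floats), which is
  ## lossless; YAML holds only the human-readable metadata
  dput(list(layers = model$layers, normalization = model$normalization),
       file.path(dir, "parameters.R"),
       control = c("keepNA", "keepInteger", "showAttributes", "hexNumeric"))
  if (!is.null(model$history))
    utils::write.table(model$history, file.path(dir, "history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a fitted model from a checkpoint directory
#' @param dir Directory written by [save_model()].
#' @return An `mpra_cnn` object.
#' @export
load_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  spec <- do.call(mpra_model_spec, meta$spec[c(
    "n_conv_layers", "filters_per_layer", "filter_length", "p_dropout",
    "batchnorm", "n_tasks", "fragment_length")])
  stored <- dget(file.path(dir, "parameters.R"))
  layers <- stored$layers
  hist_path <- file.path(dir, "history.tsv")
  norm <- stored$normalization
  structure(list(spec = spec, layers = layers, tasks = meta$tasks,
                 trained = TRUE,
                 history = if (file.exists(hist_path))
                   utils::read.delim(hist_path) else NULL,
                 normalization = norm, control = NULL),
            class = "mpra_cnn")
}
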