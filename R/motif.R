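#' Position weight matrix
#'
#' @param motif_id Motif identifier.
#' @param matrix W x 4 numeric matrix (columns A, C, G, T), either base
#'   probabilities (rows summing to 1) or log-odds.
#' @param type `"prob"` or `"logodds"`.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, matrix, type = c("prob", "logodds")) {
  type <- match.arg(type)
  stopifnot(is.matrix(matrix), ncol(matrix) == 4L)
  if (nrow(matrix) < 4L) stop("PWM width must be at least 4")
  if (type == "prob" && any(abs(rowSums(matrix) - 1) > 1e-6))
    stop("probability PWM rows must sum to 1")
  colnames(matrix) <- DNA_BASES
  structure(list(motif_id = motif_id, matrix = matrix, type = type,
                 width = nrow(matrix)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s), width %d; consensus %s\n", x$motif_id, x$type,
              x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x A [pwm()].
#' @return The string of per-position majority bases.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[max.col(x$matrix, ties.method = "first")], collapse = "")
}

#' Reverse-complement a PWM
#' @param x A [pwm()].
#' @return The PWM of the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  m <- x$matrix[rev(seq_len(x$width)), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(m) <- DNA_BASES
  pwm(x$motif_id, m, x$type)
}

#' Column-shuffle a PWM (negative control)
#'
#' Permutes the positions (rows) of the matrix, preserving its information
#' content while destroying the motif; used to build shuffled-control
#' matches.  Deterministic given `seed`.
#'
#' @param x A [pwm()].
#' @param seed Optional seed.
#' @return A shuffled `pwm` with id suffixed `::shuf`.
#' @export
shuffle_pwm <- function(x, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  pwm(paste0(x$motif_id, "::shuf"),
      x$matrix[sample.int(x$width), , drop = FALSE], x$type)
}

#' Scan sequences for PWM matches
#'
#' Simple log-odds scanner against a uniform background: reports, per
#' sequence and strand, every window whose log-odds score reaches
#' `threshold` times the maximum attainable score of the motif.
#'
#' @param seqs Named character vector of sequences.
#' @param x A [pwm()] (probabilities are converted to log-odds with a 0.001
#'   pseudo-probability floor).
#' @param threshold Fraction of the maximum score required (default 0.8).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return Data frame with columns `fragment_id`, `start`, `end` (0-based
#'   half-open, forward-strand coordinates), `strand`, `motif_id`, `score`.
#' @export
scan_pwm <- function(seqs, x, threshold = 0.8, both_strands = TRUE) {
  lo <- pwm_logodds(x)
  strands <- if (both_strands) c("+", "-") else "+"
  max_score <- sum(apply(lo, 1, max))
  out <- list()
  for (id in names(seqs)) {
    oh <- encode_one_hot(seqs[[id]])
    L <- nrow(oh)
    if (L < x$width) next
    for (st in strands) {
      m <- if (st == "+") lo else pwm_logodds_rc(lo)
      sc <- slide_scores(oh, m)
      hit <- which(sc >= threshold * max_score)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          fragment_id = id, start = hit - 1L, end = hit - 1L + x$width,
          strand = st, motif_id = x$motif_id, score = sc[hit])
    }
  }
  if (!length(out))
    return(data.frame(fragment_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      motif_id = character(0), score = numeric(0)))
  do.call(rbind, out)
}

pwm_logodds <- function(x) {
  if (x$type == "logodds") return(x$matrix)
  p <- pmax(x$matrix, 1e-3)
  log2(p / 0.25)
}

pwm_logodds_rc <- function(lo) {
  lo[rev(seq_len(nrow(lo))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

## Inner products of a W x 4 weight matrix with every window of an L x 4
## track, via one matrix-vector product over stacked windows.
slide_scores <- function(track, w) {
  W <- nrow(w); L <- nrow(track)
  P <- L - W + 1L
  sl <- matrix(0, nrow = P, ncol = W * 4L)
  for (j in seq_len(W))
    sl[, ((j - 1L) * 4L + 1L):(j * 4L)] <- track[j:(j + P - 1L), , drop = FALSE]
  as.vector(sl %*% as.vector(t(w)))
}

#' Mean attribution score over a motif match
#'
#' @param track An `attribution_track` or numeric per-position score vector.
#' @param start,end Match span within the fragment, 0-based half-open.
#' @return Arithmetic mean of the per-position scores over the span.
#' @export
score_motif_match <- function(track, start, end) {
  s <- if (inherits(track, "attribution_track")) track$scores else track
  stopifnot(end > start)
  if (start < 0 || end > length(s))
    stop(sprintf("match [%d, %d) outside track of length %d",
                 start, end, length(s)))
  mean(s[(start + 1L):end])
}

#' One-sided z-test of motif match scores against shuffled controls
#'
#' Tests whether the mean attribution score of a motif's matches exceeds the
#' control distribution: the control sample's mean and standard deviation
#' are used as plug-in population values, the observed mean's standard error
#' is `sd_control / sqrt(n_matches)`, and the p-value is the standard normal
#' upper tail.
#'
#' @param match_scores Numeric vector of per-match mean scores.
#' @param control_scores Numeric vector of control match scores (>= 20).
#' @return List with `n_matches`, `mean_score`, `z`, `p`.
#' @export
motif_significance <- function(match_scores, control_scores) {
  if (length(control_scores) < 20)
    stop("need at least 20 control scores")
  sd0 <- stats::sd(control_scores)
  if (sd0 == 0) stop("control scores have zero variance")
  n <- length(match_scores)
  z <- (mean(match_scores) - mean(control_scores)) / (sd0 / sqrt(n))
  list(n_matches = n, mean_score = mean(match_scores), z = z,
       p = stats::pnorm(z, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR threshold (default 0.1).
#' @return List with `q` (BH-adjusted values) and `significant` (logical,
#'   `q < alpha`).
#' @export
bh_fdr <- function(p_values, alpha = 0.1) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, significant = q < alpha)
}

#' Per-motif significance table with FDR correction
#'
#' Applies [motif_significance()] to each motif and corrects across motifs
#' with [bh_fdr()].
#'
#' @param match_scores_by_motif Named list of per-match score vectors.
#' @param control_scores_by_motif Named list (same names) of control score
#'   vectors.
#' @param alpha FDR threshold (default 0.1).
#' @return Data frame with columns `motif_id`, `n_matches`, `mean_score`,
#'   `z`, `p`, `q`, `significant`.
#' @export
motif_stats <- function(match_scores_by_motif, control_scores_by_motif,
                        alpha = 0.1) {
  ids <- names(match_scores_by_motif)
  stopifnot(!is.null(ids), all(ids %in% names(control_scores_by_motif)))
  rows <- lapply(ids, function(id) {
    st <- motif_significance(match_scores_by_motif[[id]],
                             control_scores_by_motif[[id]])
    data.frame(motif_id = id, n_matches = st$n_matches,
               mean_score = st$mean_score, z = st$z, p = st$p)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, alpha)
  out$q <- fdr$q
  out$significant <- fdr$significant
  out
}

#' PWM usage score of an attribution track
#'
#' The maximum Frobenius inner product between the W x 4 PWM matrix and the
#' W x 4 slice of the per-channel attribution track, over all alignments
#' (both strands by default, taking the larger).  Combines motif presence
#' with motif importance: a strong match over near-zero attributions, or a
#' strong attribution without the motif, both score low.
#'
#' @param track L x 4 per-channel attribution matrix (e.g. the
#'   `base_matrix` of a [deeplift_track()]), or an `attribution_track`
#'   carrying one.
#' @param x A [pwm()] (probability matrix recommended).
#' @param both_strands Also score the reverse-complement PWM (default TRUE).
#' @return Scalar usage score.
#' @export
usage_score <- function(track, x, both_strands = TRUE) {
  m <- if (inherits(track, "attribution_track")) track$base_matrix else track
  stopifnot(is.matrix(m), ncol(m) == 4L)
  if (x$width > nrow(m)) stop("PWM wider than the track")
  best <- max(slide_scores(m, x$matrix))
  if (both_strands)
    best <- max(best, max(slide_scores(m, pwm_revcomp(x)$matrix)))
  best
}

#' Usage matrix of motifs across fragments
#'
#' @param tracks List of L x 4 per-channel attribution matrices (one per
#'   fragment; names become row names).
#' @param pwms List of [pwm()] objects.
#' @param both_strands Passed to [usage_score()].
#' @return S x M numeric matrix; entry (i, j) is motif j's usage score on
#'   fragment i.
#' @export
usage_matrix <- function(tracks, pwms, both_strands = TRUE) {
  M <- vapply(pwms, function(p)
    vapply(tracks, usage_score, numeric(1), x = p,
           both_strands = both_strands),
    numeric(length(tracks)))
  if (length(tracks) == 1L) M <- matrix(M, nrow = 1L)
  rownames(M) <- names(tracks)
  colnames(M) <- vapply(pwms, function(p) p$motif_id, character(1))
  M
}

#' Promoter-to-enhancer usage specificity per motif
#'
#' For each motif, the ratio of its mean usage score over promoter fragments
#' to its mean over enhancer fragments, z-scored across motifs.  When any
#' enhancer mean is not positive the ratio cannot be formed directly; all
#' usage scores are then shifted by a common offset to make group means
#' positive, and the result is flagged.
#'
#' @param usage S x M usage matrix from [usage_matrix()].
#' @param state_label Factor/character of length S with levels including
#'   `promoter` and `enhancer`.
#' @return Data frame with columns `motif_id`, `promoter_mean`,
#'   `enhancer_mean`, `ratio`, `z`, plus an attribute `shifted`.
#' @export
promoter_enhancer_ratio <- function(usage, state_label) {
  stopifnot(nrow(usage) == length(state_label))
  pr <- which(state_label == "promoter")
  en <- which(state_label == "enhancer")
  if (!length(pr) || !length(en))
    stop("need both promoter and enhancer fragments")
  pm <- colMeans(usage[pr, , drop = FALSE])
  em <- colMeans(usage[en, , drop = FALSE])
  shifted <- FALSE
  if (any(em <= 0) || any(pm <= 0)) {
    off <- -min(c(pm, em)) + stats::sd(as.vector(usage)) + 1e-12
    pm <- pm + off; em <- em + off
    shifted <- TRUE
    warning("non-positive group means: ratios computed on shifted scores")
  }
  ratio <- pm / em
  z <- (ratio - mean(ratio)) / stats::sd(ratio)
  out <- data.frame(motif_id = colnames(usage), promoter_mean = pm,
                    enhancer_mean = em, ratio = ratio, z = z,
                    row.names = NULL)
  attr(out, "shifted") <- shifted
  out
}

#' Between-motif usage correlation with clustering order
#'
#' Spearman correlation matrix of the usage-score columns, with a
#' hierarchical clustering (average linkage on 1 - rho) ordering for
#' display.
#'
#' @param usage S x M usage matrix (S >= 3).
#' @return List with `cor` (M x M Spearman matrix) and `order` (integer
#'   permutation from clustering).
#' @export
usage_correlation <- function(usage) {
  if (nrow(usage) < 3) stop("need at least 3 fragments")
  rho <- stats::cor(usage, method = "spearman")
  ord <- if (ncol(usage) > 2)
    stats::hclust(stats::as.dist(1 - rho), method = "average")$order
  else seq_len(ncol(usage))
  list(cor = rho, order = ord)
}

#' Mean attribution profile around motif match centers
#'
#' Aligns per-position attribution tracks on the centers of motif matches
#' (strand-oriented: minus-strand matches are flipped) and averages the
#' scores at each relative offset.  Matches near a fragment edge contribute
#' partial windows; counts are reported per offset.
#'
#' @param tracks Named list of per-position score vectors (or
#'   `attribution_track`s), indexed by fragment id.
#' @param matches Data frame with `fragment_id`, `start`, `end` (0-based
#'   half-open, within-fragment) and `strand`.
#' @param halfwidth Window half-width in bp (default 50).
#' @return Data frame with columns `offset` (-halfwidth..halfwidth), `mean`,
#'   `n`.
#' @export
positional_profile <- function(tracks, matches, halfwidth = 50L) {
  stopifnot(all(c("fragment_id", "start", "end", "strand") %in% names(matches)))
  width <- 2L * halfwidth + 1L
  acc <- numeric(width)
  cnt <- integer(width)
  for (i in seq_len(nrow(matches))) {
    tr <- tracks[[matches$fragment_id[i]]]
    if (is.null(tr)) stop("no track for fragment ", matches$fragment_id[i])
    if (inherits(tr, "attribution_track")) tr <- tr$scores
    center <- (matches$start[i] + matches$end[i] - 1L) %/% 2L + 1L  # 1-based
    pos <- center + (-halfwidth:halfwidth)
    ok <- pos >= 1L & pos <= length(tr)
    vals <- tr[pos[ok]]
    slots <- which(ok)
    if (matches$strand[i] == "-") {
      vals <- rev(vals)
      slots <- rev(width - slots + 1L)
    }
    acc[slots] <- acc[slots] + vals
    cnt[slots] <- cnt[slots] + 1L
  }
  data.frame(offset = -halfwidth:halfwidth,
             mean = ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_),
             n = cnt)
}

#' Annotation overlap across attribution-score quantiles
#'
#' Sorts genome-positioned per-base scores, bins them into `n_quantiles`
#' near-equal bins (ties broken by a stable sort on genomic coordinate), and
#' reports the fraction of bases in each bin that fall inside any annotation
#' interval.  The linear correlation between bin mean score and overlap
#' fraction is reported separately for bins with mean score above
#' `fit_threshold` and below `-fit_threshold`.
#'
#' @param scores Data frame with columns `chrom`, `pos` (0-based base
#'   coordinate) and `score`.
#' @param annotations Data frame with `chrom`, `start`, `end` (0-based
#'   half-open intervals).
#' @param n_quantiles Number of bins (>= 2, <= number of bases).
#' @param fit_threshold Score magnitude defining the positive/negative
#'   fitting regimes (default 0.2).
#' @return List with `bins` (data frame: `quantile`, `n`, `mean_score`,
#'   `overlap_fraction`), `r_positive`, `r_negative`.
#' @export
quantile_overlap <- function(scores, annotations, n_quantiles,
                             fit_threshold = 0.2) {
  stopifnot(all(c("chrom", "pos", "score") %in% names(scores)),
            n_quantiles >= 2)
  n <- nrow(scores)
  if (n < n_quantiles) stop("fewer bases than quantiles")
  ord <- order(scores$score, scores$chrom, scores$pos, method = "radix")
  s <- scores[ord, , drop = FALSE]
  bin <- rep(seq_len(n_quantiles), times = tabulate_even(n, n_quantiles))
  inside <- overlaps_any(s, annotations)
  bins <- data.frame(
    quantile = seq_len(n_quantiles),
    n = as.integer(table(bin)),
    mean_score = as.vector(tapply(s$score, bin, mean)),
    overlap_fraction = as.vector(tapply(inside, bin, mean)))
  fit_r <- function(idx) {
    if (length(idx) < 3 || stats::sd(bins$overlap_fraction[idx]) == 0 ||
        stats::sd(bins$mean_score[idx]) == 0) return(NA_real_)
    stats::cor(bins$mean_score[idx], bins$overlap_fraction[idx])
  }
  list(bins = bins,
       r_positive = fit_r(which(bins$mean_score > fit_threshold)),
       r_negative = fit_r(which(bins$mean_score < -fit_threshold)))
}

## n items into k near-equal consecutive groups (first n %% k groups larger)
tabulate_even <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- base + 1L
  sizes
}

## logical: is each (chrom, pos) base inside any [start, end) interval
overlaps_any <- function(scores, annotations) {
  out <- logical(nrow(scores))
  for (ch in unique(scores$chrom)) {
    si <- which(scores$chrom == ch)
    ai <- which(annotations$chrom == ch)
    if (!length(ai)) next
    iv <- annotations[ai, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    ## merge overlapping intervals so findInterval logic is valid
    merged_s <- numeric(0); merged_e <- numeric(0)
    for (j in seq_len(nrow(iv))) {
      if (length(merged_s) && iv$start[j] <= merged_e[length(merged_e)]) {
        merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], iv$end[j])
      } else {
        merged_s <- c(merged_s, iv$start[j])
        merged_e <- c(merged_e, iv$end[j])
      }
    }
    k <- findInterval(scores$pos[si], merged_s)
    out[si] <- k >= 1 & scores$pos[si] < merged_e[pmax(k, 1L)]
  }
  out
}
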