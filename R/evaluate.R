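#' Per-task Spearman correlation between predictions and labels
#'
#' Rank correlation (ties mid-ranked) computed independently for each task
#' column.  Constant predictions or labels give `NA` with a warning.
#'
#' @param predictions,labels N x T matrices with matching dimensions.
#' @return Named numeric vector of length T.
#' @export
evaluate_spearman <- function(predictions, labels) {
  predictions <- as.matrix(predictions); labels <- as.matrix(labels)
  stopifnot(all(dim(predictions) == dim(labels)))
  if (nrow(labels) < 3) stop("need at least 3 observations")
  out <- vapply(seq_len(ncol(labels)), function(j) {
    p <- predictions[, j]; y <- labels[, j]
    if (stats::sd(p) == 0 || stats::sd(y) == 0) {
      warning("constant column: Spearman undefined, returning NA")
      return(NA_real_)
    }
    stats::cor(p, y, method = "spearman")
  }, numeric(1))
  names(out) <- colnames(labels)
  out
}

#' Spearman performance stratified by chromatin-state group
#'
#' Splits the fragments by their promoter/enhancer/repressed/other label and
#' reports the per-task Spearman correlation within each group, together
#' with group sizes.  Groups with fewer than 3 members are skipped with a
#' warning.
#'
#' @param predictions,labels N x T matrices.
#' @param state_label Factor or character vector of length N (see
#'   [map_chromhmm_states()]).
#' @return Data frame with columns `state`, `n`, then one Spearman column
#'   per task.
#' @export
evaluate_by_state <- function(predictions, labels, state_label) {
  predictions <- as.matrix(predictions); labels <- as.matrix(labels)
  stopifnot(nrow(predictions) == length(state_label))
  groups <- split(seq_along(state_label), state_label, drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) < 3) {
      warning(sprintf("state group '%s' has < 3 members; skipped", g))
      return(NULL)
    }
    rho <- evaluate_spearman(predictions[idx, , drop = FALSE],
                             labels[idx, , drop = FALSE])
    cbind(data.frame(state = g, n = length(idx)), as.data.frame(as.list(rho)))
  })
  do.call(rbind, rows)
}

#' Correlation between prediction error and replicate disagreement
#'
#' Tests whether fragments with noisier measurements (larger gap between
#' their two replicate activities) are also predicted less accurately:
#' the Spearman correlation between |prediction - replicate mean| and
#' |replicate1 - replicate2|, per task.
#'
#' @param predictions N x T matrix of predictions.
#' @param replicate_labels List of two N x T replicate matrices on the same
#'   scale as the predictions.
#' @return Named numeric vector of per-task Spearman correlations (NA with a
#'   warning when the gap vector is constant, e.g. identical replicates).
#' @export
error_vs_replicate_gap <- function(predictions, replicate_labels) {
  if (!is.list(replicate_labels) || length(replicate_labels) != 2)
    stop("need exactly two replicate matrices")
  r1 <- as.matrix(replicate_labels[[1]]); r2 <- as.matrix(replicate_labels[[2]])
  predictions <- as.matrix(predictions)
  stopifnot(all(dim(r1) == dim(predictions)), all(dim(r2) == dim(predictions)))
  err <- abs(predictions - (r1 + r2) / 2)
  gap <- abs(r1 - r2)
  out <- vapply(seq_len(ncol(predictions)), function(j) {
    if (stats::sd(gap[, j]) == 0) {
      warning("replicate gap is constant: correlation undefined, returning NA")
      return(NA_real_)
    }
    stats::cor(err[, j], gap[, j], method = "spearman")
  }, numeric(1))
  names(out) <- colnames(predictions)
  out
}
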