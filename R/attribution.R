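#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles a sequence while exactly preserving all dinucleotide counts and
#' the first and last base, via the Altschul-Erickson Eulerian-walk
#' construction: the sequence is viewed as an Eulerian path on the graph
#' whose vertices are the symbols and whose edges are the observed adjacent
#' pairs; a random "last edge" arborescence into the terminal symbol is
#' drawn, remaining edges are permuted, and the path is re-walked.  `N` is
#' treated as a fifth symbol, so runs of ambiguous bases are preserved in
#' count.  Deterministic given `seed`.
#'
#' @param seq A DNA string of length >= 3.
#' @param seed Optional integer seed (the global RNG state is restored).
#' @return A shuffled string with identical dinucleotide count table.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 3) stop("sequence must have length >= 3")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  verts <- unique(chars)
  if (length(verts) == 1L) return(seq)
  vi <- match(chars, verts)
  nv <- length(verts)
  from <- vi[-n]; to <- vi[-1]
  adj <- split(to, factor(from, levels = seq_len(nv)))
  last_v <- vi[n]

  ## draw random last-edges until they form an arborescence into last_v
  repeat {
    last_edge <- rep(NA_integer_, nv)
    for (v in seq_len(nv)) {
      if (v == last_v || !length(adj[[v]])) next
      es <- adj[[v]]
      last_edge[v] <- es[sample.int(length(es), 1L)]
    }
    ok <- TRUE
    for (v in seq_len(nv)) {
      if (v == last_v || is.na(last_edge[v])) next
      cur <- v
      for (s in seq_len(nv + 1L)) {
        cur <- last_edge[cur]
        if (is.na(cur) || cur == last_v) break
      }
      if (is.na(cur) || cur != last_v) { ok <- FALSE; break }
    }
    if (ok) break
  }

  ## permute remaining edges, appending each vertex's last edge
  order_out <- vector("list", nv)
  for (v in seq_len(nv)) {
    es <- adj[[v]]
    if (!length(es)) next
    if (!is.na(last_edge[v])) {
      drop1 <- match(last_edge[v], es)
      rest <- es[-drop1]
      order_out[[v]] <- c(if (length(rest)) rest[sample.int(length(rest))],
                          last_edge[v])
    } else {
      order_out[[v]] <- es[sample.int(length(es))]
    }
  }

  ## walk the Eulerian path
  out <- integer(n)
  out[1] <- vi[1]
  ptr <- integer(nv)
  cur <- vi[1]
  for (i in 2:n) {
    ptr[cur] <- ptr[cur] + 1L
    nxt <- order_out[[cur]][ptr[cur]]
    out[i] <- nxt
    cur <- nxt
  }
  paste(verts[out], collapse = "")
}

#' Count dinucleotides in a sequence
#' @param seq A DNA string.
#' @return Named table of adjacent-pair counts.
#' @export
dinucleotide_counts <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  table(paste0(chars[-n], chars[-1]))
}

## Fold batch normalization (running statistics) into the preceding
## convolution and drop dropout, leaving an affine inference network of
## conv / relu / flatten / dense layers only.
fold_inference_net <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (ly$type == "batchnorm") {
      prev <- out[[length(out)]]
      if (is.null(prev) || prev$type != "conv")
        stop("batchnorm not preceded by a convolution; cannot fold")
      s <- ly$gamma / sqrt(ly$run_var + ly$eps)
      prev$W <- prev$W * s
      prev$b <- (prev$b - ly$run_mean) * s + ly$beta
      out[[length(out)]] <- prev
    } else if (ly$type == "dropout") {
      ## inference identity
    } else if (ly$type %in% c("conv", "relu", "flatten", "dense")) {
      out[[length(out) + 1L]] <- ly
    } else {
      stop("unsupported layer type for attribution: ", ly$type)
    }
  }
  out
}

## Forward through a folded net caching ReLU inputs.  X: (4, L, N).
dl_forward <- function(folded, X) {
  Z <- X
  pre <- list()
  for (i in seq_along(folded)) {
    ly <- folded[[i]]
    if (ly$type == "conv") {
      ic <- nn_im2col(Z, ly$k)
      O <- ly$W %*% ic$mat + ly$b
      dim(O) <- c(ly$filters, ic$P, ic$N)
      Z <- O
    } else if (ly$type == "relu") {
      pre[[as.character(i)]] <- Z
      Z <- pmax(Z, 0)
    } else if (ly$type == "flatten") {
      d <- dim(Z); dim(Z) <- c(d[1] * d[2], d[3])
    } else if (ly$type == "dense") {
      Z <- ly$W %*% Z + ly$b
    }
  }
  list(out = Z, pre = pre)
}

## Propagate contribution multipliers for all T outputs at once, for a
## single fragment against a single reference.  pre_x / pre_ref hold ReLU
## inputs with a trailing singleton batch dim.  Returns (4, L, T) input
## multipliers.
dl_backward <- function(folded, pre_x, pre_ref, L_in, n_out) {
  M <- diag(n_out)                        # n_out x T(=n_out)
  shape <- NULL                           # (C, P) once conv stage reached
  for (i in rev(seq_along(folded))) {
    ly <- folded[[i]]
    if (ly$type == "dense") {
      M <- crossprod(ly$W, M)
    } else if (ly$type == "flatten") {
      shape <- c(ly$C, ly$L)
      if (is.null(ly$C)) stop("flatten layer lacks shape info")
      dim(M) <- c(ly$C, ly$L, ncol(M))
    } else if (ly$type == "relu") {
      ax <- pre_x[[as.character(i)]]
      ar <- pre_ref[[as.character(i)]]
      dim(ax) <- dim(ax)[1:2]; dim(ar) <- dim(ar)[1:2]
      delta <- ax - ar
      ratio <- ifelse(abs(delta) > 1e-10,
                      (pmax(ax, 0) - pmax(ar, 0)) / delta,
                      (ax > 0) * 1)
      M <- M * as.vector(ratio)           # broadcast over task dim
    } else if (ly$type == "conv") {
      d <- dim(M); C_out <- d[1]; P <- d[2]; Tt <- d[3]
      dim(M) <- c(C_out, P * Tt)
      Mcol <- crossprod(ly$W, M)
      L_prev <- P + ly$k - 1L
      M <- nn_col2im(Mcol, ly$C_in, ly$k, L_prev, Tt)
    }
  }
  M
}

#' DeepLIFT-style contribution track for one fragment
#'
#' Computes per-nucleotide contributions of a fragment to the model's
#' predicted activity, relative to dinucleotide-shuffled references.
#' Batch normalization is folded into the preceding convolution (affine at
#' inference) and contributions are propagated by the rescale rule through
#' ReLU units and the linear rule through convolutions and the dense output
#' layer.  For each reference the contributions satisfy summation-to-delta:
#' they sum to `f(x) - f(reference)` for every task.  Scores are averaged
#' over `n_shuffles` references; positive scores mark activating
#' nucleotides (they increase predicted activity).
#'
#' @param model A fitted [mpra_cnn()].
#' @param fragment A DNA string of the model's fragment length (or an L x 4
#'   one-hot matrix, which is decoded first).
#' @param task Task name or index (default 1).
#' @param n_shuffles Number of shuffled references to average (default 10).
#' @param seed Seed for the reference shuffles (default 1).
#' @param references Optional explicit reference sequences (overrides the
#'   shuffles); used mainly for testing.
#' @return An object of class `attribution_track` with per-position `scores`
#'   (length L, summed over the four base channels), the per-channel L x 4
#'   `base_matrix`, `f_x`, `f_ref` (per-reference predictions), and
#'   `reference_meta`.
#' @export
deeplift_track <- function(model, fragment, task = 1L, n_shuffles = 10L,
                           seed = 1L, references = NULL) {
  all <- deeplift_all_tasks(model, fragment, n_shuffles, seed, references)
  ti <- task_index(model, task)
  structure(list(
    method = "deeplift",
    task = model$tasks[ti],
    scores = colSums(all$contrib[, , ti]),
    base_matrix = build_base_matrix(all$contrib[, , ti]),
    f_x = all$f_x[ti],
    f_ref = all$f_ref[, ti],
    reference_meta = list(n_shuffles = all$n_refs, seed = seed),
    sequence = all$sequence
  ), class = "attribution_track")
}

build_base_matrix <- function(contrib_cl) {
  m <- t(contrib_cl)
  colnames(m) <- DNA_BASES
  m
}

task_index <- function(model, task) {
  if (is.character(task)) {
    ti <- match(task, model$tasks)
    if (is.na(ti)) stop("unknown task: ", task)
    return(ti)
  }
  ti <- as.integer(task)
  stopifnot(ti >= 1, ti <= length(model$tasks))
  ti
}

## Contributions for every task at once: returns contrib (4, L, T) averaged
## over references, per-reference outputs, and per-reference contribution
## sums for the summation-to-delta check.
deeplift_all_tasks <- function(model, fragment, n_shuffles = 10L, seed = 1L,
                               references = NULL) {
  L <- model$spec$fragment_length
  if (is.matrix(fragment)) fragment <- decode_one_hot(fragment)
  stopifnot(is.character(fragment), nchar(fragment) == L)
  folded <- fold_inference_net(model$layers)
  if (is.null(references))
    references <- vapply(seq_len(n_shuffles), function(i)
      dinucleotide_shuffle(fragment, seed = seed + i - 1L), character(1))
  R <- length(references)
  Tn <- length(model$tasks)

  x_arr <- encode_batch(fragment)
  fx <- dl_forward(folded, x_arr)
  f_x <- as.vector(fx$out)
  contrib <- array(0, dim = c(4L, L, Tn))
  f_ref <- matrix(0, R, Tn)
  per_ref_sum <- matrix(0, R, Tn)
  for (r in seq_len(R)) {
    r_arr <- encode_batch(references[r])
    fr <- dl_forward(folded, r_arr)
    f_ref[r, ] <- as.vector(fr$out)
    M <- dl_backward(folded, fx$pre, fr$pre, L, Tn)
    dx <- x_arr[, , 1] - r_arr[, , 1]
    cr <- M * as.vector(dx)
    per_ref_sum[r, ] <- apply(cr, 3, sum)
    contrib <- contrib + cr
  }
  list(contrib = contrib / R, f_x = f_x, f_ref = f_ref,
       per_ref_sum = per_ref_sum, n_refs = R, sequence = fragment,
       references = references)
}

#' In-silico mutagenesis track for one fragment
#'
#' Evaluates all three single-base substitutions at every position (3L
#' forward passes, batched) and scores each position as the maximum of
#' `f(reference) - f(mutant)` over its three mutants, so that positions
#' whose disruption lowers predicted activity score positively.  The full
#' signed delta matrix `f(mutant) - f(reference)` is retained (L x 4, zero
#' at the reference base).  Positions holding `N` get score 0 and are
#' flagged.
#'
#' @param model A fitted [mpra_cnn()].
#' @param fragment DNA string (or L x 4 one-hot matrix).
#' @param task Task name or index (default 1).
#' @return An `attribution_track` (method `"ism"`) with `scores`, the signed
#'   `delta` matrix, `f_x`, and `n_flagged` counting N positions.
#' @export
ism_track <- function(model, fragment, task = 1L) {
  L <- model$spec$fragment_length
  if (is.matrix(fragment)) fragment <- decode_one_hot(fragment)
  stopifnot(is.character(fragment), nchar(fragment) == L)
  ti <- task_index(model, task)
  chars <- strsplit(toupper(fragment), "", fixed = TRUE)[[1]]
  ref_idx <- match(chars, DNA_BASES)        # NA for N

  muts <- character(0)
  map <- matrix(0L, nrow = 0, ncol = 2)     # position, base index
  for (i in seq_len(L)) {
    if (is.na(ref_idx[i])) next
    for (b in seq_len(4L)) {
      if (b == ref_idx[i]) next
      s <- chars; s[i] <- DNA_BASES[b]
      muts <- c(muts, paste(s, collapse = ""))
      map <- rbind(map, c(i, b))
    }
  }
  preds <- predict(model, c(fragment, muts))
  f_ref <- preds[1, ti]
  delta <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  if (length(muts))
    delta[map] <- preds[-1, ti] - f_ref
  scores <- numeric(L)
  for (i in seq_len(L)) {
    if (is.na(ref_idx[i])) next
    scores[i] <- max(-delta[i, -ref_idx[i]])
  }
  structure(list(method = "ism", task = model$tasks[ti], scores = scores,
                 delta = delta, f_x = f_ref,
                 n_flagged = sum(is.na(ref_idx)),
                 flagged = which(is.na(ref_idx)),
                 reference_meta = NULL, sequence = fragment),
            class = "attribution_track")
}

#' @export
print.attribution_track <- function(x, ...) {
  cat(sprintf("%s attribution track: %d positions, task %s\n",
              x$method, length(x$scores), x$task))
  cat(sprintf("score range [%.4f, %.4f], f(x) = %.4f\n",
              min(x$scores), max(x$scores), x$f_x))
  invisible(x)
}

#' Agreement between two attribution tracks
#'
#' @param track_a,track_b `attribution_track` objects or plain numeric
#'   vectors of equal length.
#' @return List with `pearson` and `spearman` correlations (NA with a
#'   warning for constant tracks).
#' @export
attribution_concordance <- function(track_a, track_b) {
  a <- if (inherits(track_a, "attribution_track")) track_a$scores else track_a
  b <- if (inherits(track_b, "attribution_track")) track_b$scores else track_b
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant track: correlation undefined")
    return(list(pearson = NA_real_, spearman = NA_real_))
  }
  list(pearson = stats::cor(a, b),
       spearman = stats::cor(a, b, method = "spearman"))
}

## A bare linear model (flatten + dense) over one-hot input, as an mpra_cnn
## object; used to validate the attribution rules against the closed form
## w * (x - x_ref).
linear_mpra_model <- function(W, b, fragment_length, tasks = NULL) {
  n_out <- nrow(W)
  stopifnot(ncol(W) == 4L * fragment_length, length(b) == n_out)
  if (is.null(tasks)) tasks <- paste0("task", seq_len(n_out))
  spec <- mpra_model_spec(n_conv_layers = 1L, filters_per_layer = 1L,
                          filter_length = 1L, p_dropout = 0, batchnorm = FALSE,
                          n_tasks = n_out, fragment_length = fragment_length)
  layers <- list(list(type = "flatten", C = 4L, L = fragment_length),
                 list(type = "dense", W = W, b = b, n_in = ncol(W),
                      n_out = n_out))
  structure(list(spec = spec, layers = layers, tasks = tasks, trained = TRUE,
                 history = NULL, normalization = NULL, control = NULL),
            class = "mpra_cnn")
}
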