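## Internal convolutional-network engine.
##
## Layers operate on channel-fastest arrays: activations have dim (C, L, N)
## for convolutional stages and (features, N) after flattening.  Convolutions
## are "valid" (no padding), stride 1, no pooling; they are computed as
## im2col gathers followed by a single BLAS dgemm, which is where almost all
## of the training time goes.

nn_im2col <- function(Z, k) {
  d <- dim(Z); C <- d[1]; L <- d[2]; N <- d[3]
  P <- L - k + 1L
  list(mat = conv_im2col(Z, C, L, N, k), P = P, N = N)
}

nn_col2im <- function(dXcol, C, k, L, N) {
  if (!is.matrix(dXcol)) dim(dXcol) <- c(C * k, length(dXcol) %/% (C * k))
  conv_col2im(dXcol, C, L, N, k)
}

## Layer constructors --------------------------------------------------------

nn_init_conv <- function(C_in, filters, k) {
  fan_in <- C_in * k
  list(type = "conv",
       W = matrix(stats::rnorm(filters * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = filters),
       b = numeric(filters), k = k, C_in = C_in, filters = filters)
}

nn_init_batchnorm <- function(filters, eps = 1e-5, momentum = 0.9) {
  list(type = "batchnorm", gamma = rep(1, filters), beta = numeric(filters),
       run_mean = numeric(filters), run_var = rep(1, filters),
       eps = eps, momentum = momentum, filters = filters)
}

nn_init_dense <- function(n_in, n_out) {
  ## near-zero output head: initial predictions sit at the label mean, so
  ## early training fits signal rather than unwinding random projections
  list(type = "dense",
       W = matrix(stats::rnorm(n_out * n_in, sd = 0.01), nrow = n_out),
       b = numeric(n_out), n_in = n_in, n_out = n_out)
}

## Build the full layer stack from a model spec.  Consumes RNG for the
## weight initialization.
nn_build <- function(spec) {
  C <- 4L; L <- spec$fragment_length
  layers <- list()
  for (i in seq_len(spec$n_conv_layers)) {
    layers[[length(layers) + 1L]] <- nn_init_conv(C, spec$filters_per_layer,
                                                  spec$filter_length)
    if (spec$batchnorm)
      layers[[length(layers) + 1L]] <- nn_init_batchnorm(spec$filters_per_layer)
    layers[[length(layers) + 1L]] <- list(type = "relu")
    if (spec$p_dropout > 0)
      layers[[length(layers) + 1L]] <- list(type = "dropout", p = spec$p_dropout)
    L <- L - spec$filter_length + 1L
    C <- spec$filters_per_layer
  }
  layers[[length(layers) + 1L]] <- list(type = "flatten", C = C, L = L)
  layers[[length(layers) + 1L]] <- nn_init_dense(C * L, spec$n_tasks)
  layers
}

## Forward pass.  X: (4, L, N) array.  Returns list(out = T x N matrix,
## cache = per-layer intermediates when requested).  `training` switches
## batchnorm to batch statistics and enables dropout (consumes RNG); the
## possibly-updated layer list is returned so running statistics persist.
nn_forward <- function(layers, X, training = FALSE, keep_cache = FALSE) {
  Z <- X
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  skip <- FALSE
  for (i in seq_along(layers)) {
    if (skip) { skip <- FALSE; next }
    ly <- layers[[i]]
    if (ly$type == "conv") {
      ic <- nn_im2col(Z, ly$k)
      O <- ly$W %*% ic$mat + ly$b
      d_in <- dim(Z)
      dim(O) <- c(ly$filters, ic$P, ic$N)
      if (keep_cache) cache[[i]] <- list(Xcol = ic$mat, d_in = d_in)
      Z <- O
    } else if (ly$type == "batchnorm") {
      d <- dim(Z)
      bn <- bn_forward(Z, d[1], ly$gamma, ly$beta, ly$run_mean, ly$run_var,
                       ly$eps, ly$momentum, training)
      if (training) {
        layers[[i]]$run_mean <- bn$run_mean
        layers[[i]]$run_var <- bn$run_var
      }
      Z <- bn$y
      dim(Z) <- d
      if (keep_cache) cache[[i]] <- list(Y = Z, istd = bn$istd, d = d)
    } else if (ly$type == "relu") {
      if (training) {
        ## fuse with a following dropout layer (dropout draws from R's RNG)
        p <- 0
        if (i < length(layers) && layers[[i + 1L]]$type == "dropout") {
          p <- layers[[i + 1L]]$p
          skip <- TRUE
        }
        d <- dim(Z)
        rd <- relu_dropout_forward(Z, p)
        Z <- rd$y
        dim(Z) <- d
        if (keep_cache) cache[[i]] <- list(g = rd$g)
      } else {
        Z <- pmax(Z, 0)
        if (keep_cache) cache[[i]] <- list(pos = Z > 0)
      }
    } else if (ly$type == "dropout") {
      ## reached only at inference (identity) or when not fused
    } else if (ly$type == "flatten") {
      d <- dim(Z)
      dim(Z) <- c(d[1] * d[2], d[3])
      if (keep_cache) cache[[i]] <- list(d = d)
    } else if (ly$type == "dense") {
      if (keep_cache) cache[[i]] <- list(Zin = Z)
      Z <- ly$W %*% Z + ly$b
    }
  }
  list(out = Z, cache = cache, layers = layers)
}

## Backward pass from dOut (T x N).  Returns list of per-layer gradients
## (NULL for parameterless layers).
nn_backward <- function(layers, cache, dOut) {
  grads <- vector("list", length(layers))
  dZ <- dOut
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "dense") {
      Zin <- cache[[i]]$Zin
      grads[[i]] <- list(W = tcrossprod(dZ, Zin), b = rowSums(dZ))
      dZ <- crossprod(ly$W, dZ)
    } else if (ly$type == "flatten") {
      dim(dZ) <- cache[[i]]$d
    } else if (ly$type == "dropout") {
      ## handled by the fused relu gradient
    } else if (ly$type == "relu") {
      cc <- cache[[i]]
      d <- dim(dZ)
      dZ <- if (!is.null(cc$g)) ew_mul(dZ, cc$g) else dZ * cc$pos
      dim(dZ) <- d
    } else if (ly$type == "batchnorm") {
      cc <- cache[[i]]
      bb <- bn_backward(dZ, cc$Y, cc$d[1], ly$gamma, ly$beta, cc$istd)
      grads[[i]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      dZ <- bb$dX
      dim(dZ) <- cc$d
    } else if (ly$type == "conv") {
      cc <- cache[[i]]
      d_out_len <- prod(dim(dZ)[-1])
      dim(dZ) <- c(ly$filters, d_out_len)
      grads[[i]] <- list(W = tcrossprod(dZ, cc$Xcol), b = rowSums(dZ))
      dXcol <- crossprod(ly$W, dZ)
      dZ <- nn_col2im(dXcol, cc$d_in[1], ly$k, cc$d_in[2], cc$d_in[3])
    }
  }
  grads
}

nn_param_names <- function(ly) {
  switch(ly$type, conv = c("W", "b"), dense = c("W", "b"),
         batchnorm = c("gamma", "beta"), character(0))
}

## Scale all gradients so their global L2 norm does not exceed `max_norm`.
nn_clip_grads <- function(grads, max_norm) {
  gss <- 0
  for (g in grads) if (!is.null(g))
    for (p in g) gss <- gss + sum(p * p)
  gnorm <- sqrt(gss)
  if (gnorm <= max_norm) return(grads)
  sc <- max_norm / gnorm
  lapply(grads, function(g) {
    if (is.null(g)) return(NULL)
    lapply(g, function(p) p * sc)
  })
}

nn_adam_init <- function(layers) {
  lapply(layers, function(ly) {
    nm <- nn_param_names(ly)
    if (!length(nm)) return(NULL)
    st <- lapply(nm, function(p) list(m = ly[[p]] * 0, v = ly[[p]] * 0))
    names(st) <- nm
    st
  })
}

nn_adam_step <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    nm <- nn_param_names(layers[[i]])
    for (p in nm) {
      g <- grads[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * (st$m / c1) / (sqrt(st$v / c2) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

## Reset batchnorm running statistics to the exact moments of one large
## calibration batch, with dropout disabled so the statistics match the
## inference-time input distribution of each layer.
nn_recalibrate_bn <- function(layers, X) {
  Z <- X
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      ic <- nn_im2col(Z, ly$k)
      O <- ly$W %*% ic$mat + ly$b
      dim(O) <- c(ly$filters, ic$P, ic$N)
      Z <- O
    } else if (ly$type == "batchnorm") {
      d <- dim(Z); F <- d[1]; m <- prod(d[-1])
      Zm <- Z; dim(Zm) <- c(F, m)
      mu <- rowMeans(Zm)
      v <- rowMeans(Zm * Zm) - mu * mu
      layers[[i]]$run_mean <- mu
      layers[[i]]$run_var <- v
      istd <- 1 / sqrt(v + ly$eps)
      Zm <- ly$gamma * ((Zm - mu) * istd) + ly$beta
      dim(Zm) <- d
      Z <- Zm
    } else if (ly$type == "relu") {
      Z <- pmax(Z, 0)
    } else if (ly$type == "flatten") {
      break                              # no batchnorm beyond this point
    }
  }
  layers
}

## Sequences -> base-code raw vector (0=A,1=C,2=G,3=T,4=N), sample-major.
seq_to_codes <- function(seqs) {
  flat <- strsplit(toupper(paste(seqs, collapse = "")), "", fixed = TRUE)[[1]]
  idx <- match(flat, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) stop("non-IUPAC character in training sequences")
  as.raw(idx - 1L)
}

## Split an R layer list into the argument lists the C++ engine expects.
layers_to_engine_args <- function(layers) {
  conv_W <- list(); conv_b <- list(); bn <- list()
  dense_W <- NULL; dense_b <- NULL
  for (ly in layers) {
    if (ly$type == "conv") {
      conv_W[[length(conv_W) + 1L]] <- ly$W
      conv_b[[length(conv_b) + 1L]] <- ly$b
    } else if (ly$type == "batchnorm") {
      bn[[length(bn) + 1L]] <- ly[c("gamma", "beta", "run_mean", "run_var",
                                    "eps", "momentum")]
    } else if (ly$type == "dense") {
      dense_W <- ly$W; dense_b <- ly$b
    }
  }
  if (!length(bn)) bn <- vector("list", length(conv_W))
  list(conv_W = conv_W, conv_b = conv_b, bn_par = bn,
       dense_W = dense_W, dense_b = dense_b)
}

## Write engine parameters back into an R layer list.
set_layer_params <- function(layers, par) {
  ci <- 0L; bi <- 0L
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      ci <- ci + 1L
      layers[[i]]$W <- par$conv_W[[ci]]
      layers[[i]]$b <- as.numeric(par$conv_b[[ci]])
    } else if (ly$type == "batchnorm") {
      bi <- bi + 1L
      layers[[i]]$gamma <- as.numeric(par$bn[[bi]]$gamma)
      layers[[i]]$beta <- as.numeric(par$bn[[bi]]$beta)
      layers[[i]]$run_mean <- as.numeric(par$bn[[bi]]$run_mean)
      layers[[i]]$run_var <- as.numeric(par$bn[[bi]]$run_var)
    } else if (ly$type == "dense") {
      layers[[i]]$W <- par$dense_W
      layers[[i]]$b <- as.numeric(par$dense_b)
    }
  }
  layers
}

## Batched inference on an arbitrary number of fragments.
nn_predict <- function(layers, X, batch_size = 512L) {
  N <- dim(X)[3]
  if (N == 0) return(matrix(numeric(0), nrow = 0,
                            ncol = nrow(layers[[length(layers)]]$W)))
  outs <- vector("list", ceiling(N / batch_size))
  bi <- 0L
  for (s in seq(1L, N, by = batch_size)) {
    e <- min(s + batch_size - 1L, N)
    bi <- bi + 1L
    outs[[bi]] <- nn_forward(layers, X[, , s:e, drop = FALSE],
                             training = FALSE)$out
  }
  t(do.call(cbind, outs))
}
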