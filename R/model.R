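#' Architecture description for the convolutional MPRA regressor
#'
#' The default mirrors the reference architecture for 145 bp reporter
#' fragments: three convolutional layers of 120 filters of length 5, each
#' followed by batch normalization, ReLU and dropout (p = 0.1), then a single
#' linear layer mapping the flattened feature map to the task outputs.  No
#' pooling and no intermediate fully connected layers are used; convolutions
#' are "valid" with stride 1, so the receptive field of the output is
#' `1 + n_conv_layers * (filter_length - 1)` bp.
#'
#' @param n_conv_layers Number of convolutional layers (default 3).
#' @param filters_per_layer Filters per convolutional layer (default 120).
#' @param filter_length Convolution filter width in bp (default 5).
#' @param p_dropout Dropout probability in `[0, 1)` (default 0.1).
#' @param batchnorm Use batch normalization after each convolution (default TRUE).
#' @param n_tasks Number of regression outputs (default 4).
#' @param fragment_length Input fragment length in bp (default 145).
#' @return An object of class `mpra_model_spec`.
#' @export
mpra_model_spec <- function(n_conv_layers = 3L, filters_per_layer = 120L,
                            filter_length = 5L, p_dropout = 0.1,
                            batchnorm = TRUE, n_tasks = 4L,
                            fragment_length = 145L) {
  stopifnot(n_conv_layers >= 1, filters_per_layer >= 1, filter_length >= 1,
            p_dropout >= 0, p_dropout < 1, n_tasks >= 1)
  rf <- 1L + n_conv_layers * (filter_length - 1L)
  if (fragment_length < rf)
    stop(sprintf("fragment_length %d is shorter than the receptive field %d",
                 fragment_length, rf))
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 filters_per_layer = as.integer(filters_per_layer),
                 filter_length = as.integer(filter_length),
                 p_dropout = p_dropout, batchnorm = isTRUE(batchnorm),
                 n_tasks = as.integer(n_tasks),
                 fragment_length = as.integer(fragment_length),
                 receptive_field = rf),
            class = "mpra_model_spec")
}

#' @export
print.mpra_model_spec <- function(x, ...) {
  cat(sprintf(
    "CNN spec: %d x [conv(%d filters, length %d)%s -> ReLU%s] -> dense(%d)\n",
    x$n_conv_layers, x$filters_per_layer, x$filter_length,
    if (x$batchnorm) " -> BN" else "",
    if (x$p_dropout > 0) sprintf(" -> dropout(%.2g)", x$p_dropout) else "",
    x$n_tasks))
  cat(sprintf("input %d bp; receptive field %d bp\n",
              x$fragment_length, x$receptive_field))
  invisible(x)
}

#' Training configuration
#'
#' Optimization settings for [mpra_cnn()].  The loss is the unweighted mean
#' of per-task mean squared errors; Adam with learning rate 1e-3, batch size
#' 128 and early stopping (patience 5 epochs on validation MSE) are the
#' defaults.
#'
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 128).
#' @param epochs Maximum epochs (default 20).  Zero epochs returns the
#'   freshly initialized model unchanged.
#' @param patience Early-stopping patience on validation MSE (default 5).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param engine `"float"` (default) runs the minibatch loop in a
#'   single-precision C++ engine, about twice as fast on one core;
#'   `"reference"` runs the pure-R double-precision loop.  Both produce a
#'   model whose inference path is the same double-precision code.
#' @param lr_schedule `"constant"` or `"cosine"` (annealing from
#'   `learning_rate` to ~0 across the epoch budget).
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to the
#'   dense output weights (default 0); convolution weights are not decayed
#'   because batch normalization cancels their scale.
#' @param clip_norm Global gradient-norm clipping threshold (default 5;
#'   0 disables), guarding against early-training instability.
#' @param verbose Print a line per epoch.
#' @return An object of class `mpra_train_control`.
#' @export
mpra_train_control <- function(learning_rate = 1e-3, batch_size = 128L,
                               epochs = 20L, patience = 5L, seed = 1L,
                               engine = c("float", "reference"),
                               lr_schedule = c("constant", "cosine"),
                               weight_decay = 0, clip_norm = 5,
                               verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0, patience >= 1,
            weight_decay >= 0, clip_norm >= 0)
  engine <- match.arg(engine)
  lr_schedule <- match.arg(lr_schedule)
  structure(list(loss = "mse", optimizer = "adam",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed), engine = engine,
                 lr_schedule = lr_schedule, weight_decay = weight_decay,
                 clip_norm = clip_norm, verbose = isTRUE(verbose)),
            class = "mpra_train_control")
}

## Per-epoch learning rate under the configured schedule.  The cosine decay
## uses a reduced-rate first epoch (warm-up, stabilizing Adam and the batch
## statistics) and then anneals from the base rate to ~0.
epoch_lr <- function(control, epoch) {
  if (identical(control$lr_schedule, "cosine")) {
    if (epoch == 1 && control$epochs > 1) return(control$learning_rate * 0.3)
    control$learning_rate * 0.5 *
      (1 + cos(pi * (epoch - 2) / max(control$epochs - 1, 1)))
  } else control$learning_rate
}

#' Build an untrained convolutional MPRA model
#'
#' Initializes the network parameters for a given architecture without
#' training.  Useful for zero-epoch baselines and for attribution tests
#' against hand-constructed parameter values.
#'
#' @param spec An [mpra_model_spec()].
#' @param seed RNG seed for weight initialization.
#' @param tasks Optional task names (length `spec$n_tasks`).
#' @return An object of class `mpra_cnn` with `trained = FALSE`.
#' @export
build_model <- function(spec = mpra_model_spec(), seed = 1L, tasks = NULL) {
  stopifnot(inherits(spec, "mpra_model_spec"))
  if (is.null(tasks))
    tasks <- if (spec$n_tasks == 4) mpra_tasks() else
      paste0("task", seq_len(spec$n_tasks))
  stopifnot(length(tasks) == spec$n_tasks)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(seed)
  structure(list(spec = spec, layers = nn_build(spec), tasks = tasks,
                 trained = FALSE, history = NULL, normalization = NULL,
                 control = NULL, call = match.call()),
            class = "mpra_cnn")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Fit a multi-task convolutional regression model of MPRA activity
#'
#' Trains a convolutional network mapping one-hot encoded DNA fragments to
#' per-task regulatory activities by minimizing mean squared error with Adam.
#' Training uses the dataset's train partition (reverse-complement augmented
#' copies included when present); the model with the best validation MSE is
#' returned, with early stopping after `control$patience` epochs without
#' improvement.  Labels are expected to be z-score normalized; the dataset's
#' normalization parameters are carried on the fitted object.
#'
#' @param dataset An [mpra_dataset()] with a partition (see
#'   [split_by_chromosome()]), normally normalized with [zscore_normalize()]
#'   and augmented with [augment_with_revcomp()].
#' @param spec An [mpra_model_spec()]; its `n_tasks` and `fragment_length`
#'   must match the dataset.
#' @param control An [mpra_train_control()].
#' @return An object of class `mpra_cnn` with components `spec`, `layers`
#'   (opaque parameters), `history` (per-epoch train/val MSE), `tasks`,
#'   `normalization`, and `control`.
#' @seealso [predict.mpra_cnn()], [evaluate_spearman()], [deeplift_track()],
#'   [ism_track()]
#' @export
mpra_cnn <- function(dataset, spec = mpra_model_spec(), control = mpra_train_control()) {
  stopifnot(inherits(dataset, "mpra_dataset"),
            inherits(spec, "mpra_model_spec"),
            inherits(control, "mpra_train_control"))
  if (spec$n_tasks != length(dataset$tasks))
    stop("spec$n_tasks does not match the dataset")
  if (spec$fragment_length != dataset$fragment_length)
    stop("spec$fragment_length does not match the dataset")
  if (is.null(dataset$partition)) stop("dataset has no partition")

  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(control$seed)

  layers <- nn_build(spec)
  tr <- which(dataset$partition == "train")
  va <- which(dataset$partition == "val")
  if (!length(tr)) stop("empty training partition")
  if (!length(va) && control$epochs > 0) stop("empty validation partition")

  Ytr <- t(dataset$labels[tr, , drop = FALSE])        # T x N
  Xva <- encode_batch(dataset$fragments$sequence[va])
  Yva <- dataset$labels[va, , drop = FALSE]

  ntr <- length(tr)
  use_float <- control$engine == "float" && control$epochs > 0
  if (use_float) {
    codes <- seq_to_codes(dataset$fragments$sequence[tr])
    eng <- do.call(engine_create, c(list(unclass(spec)),
                                    layers_to_engine_args(layers)))
  } else {
    Xtr <- encode_batch(dataset$fragments$sequence[tr])
    state <- nn_adam_init(layers)
  }
  best <- list(layers = layers, val = Inf, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_mse = numeric(0),
                     val_mse = numeric(0))
  step <- 0L
  bad <- 0L
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(ntr)
    cal <- ord[seq_len(min(2048L, ntr))]
    lr_ep <- epoch_lr(control, ep)
    if (use_float) {
      tl <- ntr * engine_train_epoch(eng, codes, Ytr, as.integer(ord - 1L),
                                     control$batch_size, lr_ep,
                                     control$weight_decay, control$clip_norm)
      ## validate the Polyak-averaged weights; batchnorm statistics are
      ## recalibrated against them on a large batch (dropout off)
      layers <- set_layer_params(layers, engine_params(eng, TRUE))
      layers <- nn_recalibrate_bn(
        layers, encode_batch(dataset$fragments$sequence[tr][cal]))
    } else {
      tl <- 0
      for (s in seq(1L, ntr, by = control$batch_size)) {
        e <- min(s + control$batch_size - 1L, ntr)
        ix <- ord[s:e]
        fw <- nn_forward(layers, Xtr[, , ix, drop = FALSE], training = TRUE,
                         keep_cache = TRUE)
        layers <- fw$layers
        resid <- fw$out - Ytr[, ix, drop = FALSE]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d (batch %d); ",
                       ep, s %/% control$batch_size + 1L),
               "try a lower learning rate")
        tl <- tl + loss * length(ix)
        dOut <- 2 * resid / length(resid)
        grads <- nn_backward(layers, fw$cache, dOut)
        if (control$clip_norm > 0) grads <- nn_clip_grads(grads, control$clip_norm)
        step <- step + 1L
        up <- nn_adam_step(layers, grads, state, lr_ep, step)
        layers <- up$layers
        state <- up$state
        if (control$weight_decay > 0) {
          ## decay the dense head only; batchnorm cancels conv weight scale
          for (li in seq_along(layers)) {
            if (layers[[li]]$type == "dense")
              layers[[li]]$W <- layers[[li]]$W *
                (1 - lr_ep * control$weight_decay)
          }
        }
      }
      ## pin batchnorm running statistics to the current weights before
      ## validating (large calibration batch, dropout off)
      layers <- nn_recalibrate_bn(layers, Xtr[, , cal, drop = FALSE])
    }
    pv <- nn_predict(layers, Xva)
    vmse <- mean((pv - Yva)^2)
    hist <- rbind(hist, data.frame(epoch = ep, train_mse = tl / ntr,
                                   val_mse = vmse))
    if (control$verbose)
      message(sprintf("epoch %d: train MSE %.4f, val MSE %.4f",
                      ep, tl / ntr, vmse))
    if (vmse < best$val) {
      best <- list(layers = layers, val = vmse, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= control$patience) break
    }
  }
  if (control$epochs > 0) layers <- best$layers

  structure(list(spec = spec, layers = layers, tasks = dataset$tasks,
                 trained = control$epochs > 0, history = hist,
                 best_epoch = best$epoch,
                 val_mse = if (is.finite(best$val)) best$val else NA_real_,
                 normalization = dataset$normalization, control = control,
                 call = match.call()),
            class = "mpra_cnn")
}

## Accept sequences in several forms and return the engine array (4, L, N).
as_engine_array <- function(x, fragment_length) {
  if (is.character(x)) {
    if (length(x) && any(nchar(x) != fragment_length))
      stop("all fragments must have length ", fragment_length)
    if (!length(x)) return(array(0, dim = c(4L, fragment_length, 0L)))
    return(encode_batch(x))
  }
  if (is.matrix(x)) x <- list(x)
  if (is.list(x)) {
    if (!length(x)) return(array(0, dim = c(4L, fragment_length, 0L)))
    stopifnot(all(vapply(x, function(m)
      is.matrix(m) && ncol(m) == 4L && nrow(m) == fragment_length, logical(1))))
    arr <- array(0, dim = c(4L, fragment_length, length(x)))
    for (i in seq_along(x)) arr[, , i] <- t(x[[i]])
    return(arr)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(dim(x)[1] == 4L, dim(x)[2] == fragment_length)
    return(x)
  }
  stop("cannot interpret fragment input")
}

#' Predict MPRA activity for DNA fragments
#'
#' Deterministic batch prediction: batch normalization uses running
#' statistics and dropout is disabled, so repeated calls give identical
#' results and batching does not change the output.
#'
#' @param object A fitted [mpra_cnn()] model.
#' @param newdata Fragments as a character vector of sequences, an L x 4
#'   one-hot matrix, a list of such matrices, or an `mpra_dataset`.
#' @param partition When `newdata` is a dataset: which partition to predict
#'   (`NULL` = all fragments).
#' @param batch_size Internal batch size (does not affect results).
#' @param ... Unused.
#' @return N x T matrix of predicted activities (z-score units), with task
#'   column names and fragment ids as row names when available.
#' @export
predict.mpra_cnn <- function(object, newdata, partition = NULL,
                             batch_size = 512L, ...) {
  ids <- NULL
  if (inherits(newdata, "mpra_dataset")) {
    fr <- newdata$fragments
    if (!is.null(partition)) {
      idx <- which(newdata$partition == partition)
      fr <- fr[idx, , drop = FALSE]
    }
    ids <- fr$fragment_id
    newdata <- fr$sequence
  }
  X <- as_engine_array(newdata, object$spec$fragment_length)
  out <- nn_predict(object$layers, X, batch_size = batch_size)
  colnames(out) <- object$tasks
  if (!is.null(ids)) rownames(out) <- ids
  out
}

#' @export
print.mpra_cnn <- function(x, ...) {
  cat("Multi-task convolutional MPRA activity model\n")
  print(x$spec)
  if (x$trained) {
    cat(sprintf("trained %d epoch(s); best validation MSE %.4f at epoch %d\n",
                nrow(x$history), x$val_mse, x$best_epoch))
  } else cat("untrained (initialized parameters)\n")
  cat("tasks:", paste(x$tasks, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mpra_cnn <- function(object, ...) {
  np <- sum(vapply(object$layers, function(ly)
    sum(vapply(nn_param_names(ly), function(p) length(ly[[p]]), numeric(1)),
        0), numeric(1)))
  cat("Multi-task convolutional MPRA activity model\n")
  print(object$spec)
  cat(sprintf("%d trainable parameters\n", as.integer(np)))
  if (!is.null(object$history) && nrow(object$history)) {
    cat("training history (MSE):\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' Extract model parameters
#'
#' @param object A fitted `mpra_cnn`.
#' @param ... Unused.
#' @return Named list of parameter arrays per layer (convolution filter
#'   weights `W` are filters x (filter_length * 4) matrices).
#' @export
coef.mpra_cnn <- function(object, ...) {
  out <- list()
  ci <- 0L
  for (ly in object$layers) {
    nm <- nn_param_names(ly)
    if (!length(nm)) next
    ci <- ci + 1L
    out[[paste0(ly$type, ci)]] <- ly[nm]
  }
  out
}

#' Plot the training history
#' @param x A fitted `mpra_cnn`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mpra_cnn <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("no training history to plot")
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "b",
                    pch = c(1, 2), lty = 1, xlab = "epoch", ylab = "MSE", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = 1:2, lty = 1, bty = "n")
  invisible(x)
}

#' Residuals of a fitted MPRA model on a dataset partition
#'
#' @param object A fitted `mpra_cnn`.
#' @param dataset The `mpra_dataset` to evaluate on.
#' @param partition Partition to use (default "test"); augmented copies are
#'   excluded.
#' @param ... Unused.
#' @return N x T matrix of observed minus predicted activities.
#' @export
residuals.mpra_cnn <- function(object, dataset, partition = "test", ...) {
  part <- dataset_partition(dataset, partition, drop_augmented = TRUE)
  pred <- predict(object, part$fragments$sequence)
  res <- part$labels - pred
  rownames(res) <- part$fragments$fragment_id
  res
}
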