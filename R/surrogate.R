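# Feed-forward surrogate: architecture, training (Adam + early stopping),
# prediction, and a portable text serialization.  The network is small
# (two hidden layers of 16 rectifier units) so plain R matrix algebra is
# the right tool; training is fully seeded and bit-reproducible.

#' Surrogate network architecture specification
#'
#' @param n_in,n_out input / output dimensions
#' @param hidden sizes of the hidden layers (rectifier activations)
#' @param dropout_rate dropout probability on hidden activations during
#'   training (inverted scaling; inference is deterministic)
#' @return `mlp_spec` object
#' @export
mlp_spec <- function(n_in = 4, hidden = c(16, 16), n_out = 4,
                     dropout_rate = 0.1) {
  stopifnot(length(hidden) >= 1, dropout_rate >= 0, dropout_rate < 1)
  structure(list(layer_sizes = c(n_in, hidden, n_out),
                 dropout_rate = dropout_rate),
            class = "mlp_spec")
}

#' Training configuration for the surrogate
#'
#' @param split_fraction train fraction of the 80:20 train-test split
#' @param learning_rate Adam step size
#' @param batch_size minibatch size
#' @param max_epochs maximum training epochs
#' @param patience early-stopping patience (epochs without test-loss
#'   improvement); best-test-loss weights are restored
#' @param lr_decay_every,lr_decay_factor step learning-rate schedule: the
#'   rate is multiplied by `lr_decay_factor` every `lr_decay_every` epochs.
#'   The decay damps the weight jitter that dropout and minibatching cause
#'   on the late-training plateau, which matters when some targets are much
#'   harder than others (their loss dominates epoch-to-epoch noise).
#' @param polish_epochs length of the final polish phase: training resumes
#'   from the best early-stopping weights with dropout annealed off and the
#'   decayed learning rate, which settles the stochastic weight jitter that
#'   dropout leaves on the late-training plateau.  Set 0 to disable.
#' @param seed RNG seed governing split, initialization, shuffling and
#'   dropout (same seed, same data: bit-identical weights)
#' @return `train_config` object
#' @export
train_config <- function(split_fraction = 0.8, learning_rate = 1e-3,
                         batch_size = 64, max_epochs = 2000,
                         patience = 100, lr_decay_every = 250,
                         lr_decay_factor = 0.5, polish_epochs = 200,
                         seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1, learning_rate > 0,
            batch_size >= 1, max_epochs >= 1, patience >= 1,
            lr_decay_every >= 1, lr_decay_factor > 0, lr_decay_factor <= 1)
  structure(list(split_fraction = split_fraction,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor,
                 polish_epochs = as.integer(polish_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  if (any(sd <= 0) || any(!is.finite(sd))) {
    stop("scaler: a column has zero or non-finite standard deviation")
  }
  list(mean = mu, sd = sd)
}
.scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mean), 2, sc$sd, "/")
.scale_invert <- function(X, sc) sweep(sweep(X, 2, sc$sd, "*"), 2, sc$mean, "+")

.init_weights <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization for rectifier layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

# Forward pass on standardized inputs; returns activations for backprop.
.net_forward <- function(W, b, X, dropout_rate = 0, training = FALSE) {
  L <- length(W)
  A <- vector("list", L + 1L)
  masks <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% W[[l]]
    Z <- sweep(Z, 2, b[[l]], "+")
    if (l < L) {
      Z <- pmax(Z, 0)
      if (training && dropout_rate > 0) {
        keep <- 1 - dropout_rate
        m <- matrix(stats::runif(length(Z)) < keep, nrow(Z), ncol(Z)) / keep
        Z <- Z * m
        masks[[l]] <- m
      }
    }
    A[[l + 1L]] <- Z
  }
  list(A = A, masks = masks)
}

#' Evaluate the surrogate network on raw-scale inputs
#'
#' Applies the input scaler, the affine-rectifier stack, and the inverse
#' output scaler.  Dropout masks are applied to hidden activations only when
#' `training_mode` is TRUE (with inverted scaling); inference is
#' deterministic.
#'
#' @param surrogate a `trained_surrogate`
#' @param x numeric matrix (rows = samples) or vector of features, raw scale
#' @param training_mode apply dropout (training semantics)?
#' @param dropout_seed optional seed for the dropout masks
#' @return matrix of raw-scale predictions, columns named by target
#' @export
mlp_forward <- function(surrogate, x, training_mode = FALSE,
                        dropout_seed = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != surrogate$spec$layer_sizes[1]) {
    stop("feature dimension mismatch: expected ",
         surrogate$spec$layer_sizes[1], ", got ", ncol(x))
  }
  Xs <- .scale_apply(x, surrogate$input_scaler)
  run <- function() {
    .net_forward(surrogate$W, surrogate$b, Xs,
                 dropout_rate = surrogate$spec$dropout_rate,
                 training = training_mode)
  }
  fw <- if (!is.null(dropout_seed)) .with_seed(dropout_seed, run()) else run()
  Y <- .scale_invert(fw$A[[length(fw$A)]], surrogate$output_scaler)
  colnames(Y) <- surrogate$targets
  Y
}

.default_columns <- function(direction, params) {
  param_cols <- paste0("f_", params)
  obs_cols <- c("Na_cell", "K_cell", "J_Na", "J_K")
  state_cols <- c("Na_cell", "K_cell", "Va", "Vb")
  if (direction == "forward") {
    list(features = param_cols, targets = state_cols)
  } else {
    list(features = obs_cols, targets = param_cols)
  }
}

#' Train a surrogate network on a dataset
#'
#' Forward direction: features are the four transport-parameter fractions,
#' targets the cytosolic Na+ and K+ concentrations and the apical and
#' basolateral membrane potentials.  Inverse direction: features are the
#' observables (cytosolic Na+ and K+ and transcellular Na+ and K+ fluxes),
#' targets the four transport parameters.
#'
#' The dataset is split (seeded) into training and test parts; input and
#' output scalers are fitted on the training split only; the mean squared
#' error on standardized targets is minimized by Adam with minibatches;
#' early stopping restores the best-test-loss weights.
#'
#' @param ds a `transport_dataset` (or merged datasets)
#' @param direction "forward" or "inverse"
#' @param config a [train_config()]
#' @param spec a [mlp_spec()]; default 4-16-16-4 with dropout 0.1
#' @return `trained_surrogate` with weights, scalers, column names, and the
#'   per-epoch loss history
#' @export
train_surrogate <- function(ds, direction = c("forward", "inverse"),
                            config = train_config(), spec = NULL) {
  direction <- match.arg(direction)
  tab <- ds$table
  if (nrow(tab) < 50) stop("refusing to train on fewer than 50 rows")
  cols <- .default_columns(direction, ds$meta$params)
  missing <- setdiff(c(cols$features, cols$targets), names(tab))
  if (length(missing) > 0) {
    stop("dataset lacks required column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(tab[, cols$features])
  Y <- as.matrix(tab[, cols$targets])
  if (is.null(spec)) {
    spec <- mlp_spec(n_in = ncol(X), n_out = ncol(Y))
  }

  .with_seed(config$seed, {
    n <- nrow(X)
    n_train <- floor(config$split_fraction * n)
    idx <- sample.int(n)
    tr <- idx[seq_len(n_train)]
    te <- idx[-seq_len(n_train)]

    in_sc <- .fit_scaler(X[tr, , drop = FALSE])
    out_sc <- .fit_scaler(Y[tr, , drop = FALSE])
    Xtr <- .scale_apply(X[tr, , drop = FALSE], in_sc)
    Ytr <- .scale_apply(Y[tr, , drop = FALSE], out_sc)
    Xte <- .scale_apply(X[te, , drop = FALSE], in_sc)
    Yte <- .scale_apply(Y[te, , drop = FALSE], out_sc)

    net <- .init_weights(spec$layer_sizes)
    W <- net$W; b <- net$b
    L <- length(W)
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    tstep <- 0L

    test_loss <- function(W, b) {
      P <- .net_forward(W, b, Xte)$A[[L + 1L]]
      mean((P - Yte)^2)
    }
    train_loss_full <- function(W, b) {
      P <- .net_forward(W, b, Xtr)$A[[L + 1L]]
      mean((P - Ytr)^2)
    }

    history <- data.frame(epoch = 0L,
                          train = train_loss_full(W, b),
                          test = test_loss(W, b))
    best <- list(W = W, b = b, loss = history$test[1], epoch = 0L)
    nb <- ceiling(n_train / config$batch_size)

    epoch_offset <- 0L
    run_epochs <- function(n_epochs, dropout_rate, lr_base) for (ep in seq_len(n_epochs)) {
      epoch <- epoch_offset + ep
      lr <- lr_base(ep)
      ord <- sample.int(n_train)
      for (ib in seq_len(nb)) {
        rows <- ord[((ib - 1L) * config$batch_size + 1L):
                      min(ib * config$batch_size, n_train)]
        Xb <- Xtr[rows, , drop = FALSE]
        Yb <- Ytr[rows, , drop = FALSE]
        fw <- .net_forward(W, b, Xb, dropout_rate, training = TRUE)
        A <- fw$A
        m <- nrow(Xb)
        delta <- 2 * (A[[L + 1L]] - Yb) / (m * ncol(Yb))
        for (l in L:1) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- tcrossprod(delta, W[[l]])
            act <- A[[l]]
            delta <- delta * (act > 0)
            if (!is.null(fw$masks[[l - 1L]])) {
              delta <- delta * fw$masks[[l - 1L]]
            }
          }
          tstep_l <- tstep + 1L
          mW[[l]] <<- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <<- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <<- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <<- beta2 * vb[[l]] + (1 - beta2) * gb^2
          bc1 <- 1 - beta1^tstep_l; bc2 <- 1 - beta2^tstep_l
          W[[l]] <<- W[[l]] - lr * (mW[[l]] / bc1) / (sqrt(vW[[l]] / bc2) + eps)
          b[[l]] <<- b[[l]] - lr * (mb[[l]] / bc1) / (sqrt(vb[[l]] / bc2) + eps)
        }
        tstep <<- tstep + 1L
      }
      tl <- test_loss(W, b)
      trl <- train_loss_full(W, b)
      if (!is.finite(tl) || !is.finite(trl)) {
        stop("non-finite loss at epoch ", epoch,
             " (learning rate too high or degenerate data)")
      }
      history <<- rbind(history, data.frame(epoch = epoch, train = trl, test = tl))
      if (tl < best$loss) {
        best <<- list(W = W, b = b, loss = tl, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }

    # main phase: dropout on, step-decayed learning rate, early stopping
    run_epochs(config$max_epochs, spec$dropout_rate, function(ep) {
      config$learning_rate *
        config$lr_decay_factor^((ep - 1L) %/% config$lr_decay_every)
    })

    # polish phase: resume from the best weights with dropout annealed off
    # at the final decayed rate, settling the stochastic weight jitter
    if (config$polish_epochs > 0L) {
      W <- best$W; b <- best$b
      mW <- lapply(W, function(w) w * 0); vW <- mW
      mb <- lapply(b, function(x) x * 0); vb <- mb
      tstep <- 0L
      epoch_offset <- max(history$epoch)
      lr_polish <- config$learning_rate *
        config$lr_decay_factor^(epoch_offset %/% config$lr_decay_every)
      run_epochs(config$polish_epochs, 0, function(ep) lr_polish)
    }

    structure(list(
      spec = spec,
      W = best$W, b = best$b,
      input_scaler = in_sc, output_scaler = out_sc,
      direction = direction,
      features = cols$features, targets = cols$targets,
      feature_range = list(lo = apply(X[tr, , drop = FALSE], 2, min),
                           hi = apply(X[tr, , drop = FALSE], 2, max)),
      loss_history = history,
      best_epoch = best$epoch,
      config = config,
      meta = ds$meta
    ), class = "trained_surrogate")
  })
}

#' @export
print.trained_surrogate <- function(x, ...) {
  cat(sprintf("<trained_surrogate> %s: [%s] -> [%s]\n", x$direction,
              paste(x$features, collapse = ", "),
              paste(x$targets, collapse = ", ")))
  cat(sprintf("  layers %s, dropout %.2f; best epoch %d, test loss %.3g (from %.3g)\n",
              paste(x$spec$layer_sizes, collapse = "-"),
              x$spec$dropout_rate, x$best_epoch,
              min(x$loss_history$test), x$loss_history$test[1]))
  invisible(x)
}

#' Predict with a trained surrogate
#'
#' @param object a `trained_surrogate`
#' @param newdata data.frame (or named matrix) containing the surrogate's
#'   feature columns; rows outside the training feature range produce a
#'   warning (extrapolation is supported but less accurate), not an error
#' @param ... unused
#' @return data.frame of predictions, columns named by target
#' @export
predict.trained_surrogate <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    stop("newdata must be a data.frame or matrix with named columns")
  }
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing) > 0) {
    stop("newdata lacks feature column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  lo <- object$feature_range$lo; hi <- object$feature_range$hi
  outside <- sweep(X, 2, lo, "<") | sweep(X, 2, hi, ">")
  if (any(outside)) {
    .nn_log(sprintf("%d of %d rows outside the training feature range (extrapolating)",
                    sum(rowSums(outside) > 0), nrow(X)))
  }
  as.data.frame(mlp_forward(object, X))
}

#' Save / load a trained surrogate as a portable text bundle
#'
#' Writes a directory with `manifest.json` (architecture, scalers, column
#' names, loss history, provenance) and `weights.csv` (flat layer/row/col/
#' value table at full double precision).  Loading reproduces predictions
#' to better than 1e-12 relative.
#'
#' @param surrogate a `trained_surrogate`
#' @param path bundle directory
#' @export
save_surrogate <- function(surrogate, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    layer_sizes = surrogate$spec$layer_sizes,
    dropout_rate = surrogate$spec$dropout_rate,
    direction = surrogate$direction,
    features = surrogate$features,
    targets = surrogate$targets,
    input_scaler = surrogate$input_scaler,
    output_scaler = surrogate$output_scaler,
    feature_range = surrogate$feature_range,
    loss_history = surrogate$loss_history,
    best_epoch = surrogate$best_epoch,
    config = unclass(surrogate$config),
    meta = surrogate$meta,
    version = as.character(utils::packageVersion("nephroNN"))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  rows <- do.call(rbind, lapply(seq_along(surrogate$W), function(l) {
    W <- surrogate$W[[l]]; b <- surrogate$b[[l]]
    rbind(
      data.frame(layer = l, kind = "W",
                 i = rep(seq_len(nrow(W)), ncol(W)),
                 j = rep(seq_len(ncol(W)), each = nrow(W)),
                 value = sprintf("%.17g", as.vector(W))),
      data.frame(layer = l, kind = "b", i = 0L, j = seq_along(b),
                 value = sprintf("%.17g", b))
    )
  }))
  utils::write.csv(rows, file.path(path, "weights.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  wt <- utils::read.csv(file.path(path, "weights.csv"))
  wt$value <- as.numeric(wt$value)
  sizes <- manifest$layer_sizes
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    wl <- wt[wt$layer == l & wt$kind == "W", ]
    bl <- wt[wt$layer == l & wt$kind == "b", ]
    if (nrow(wl) != sizes[l] * sizes[l + 1L] || nrow(bl) != sizes[l + 1L]) {
      stop(sprintf(
        "weights.csv layer %d shape mismatch: manifest declares %dx%d (+%d bias), found %d weight and %d bias entries",
        l, sizes[l], sizes[l + 1L], sizes[l + 1L], nrow(wl), nrow(bl)))
    }
    W[[l]] <- matrix(0, sizes[l], sizes[l + 1L])
    W[[l]][cbind(wl$i, wl$j)] <- wl$value
    b[[l]] <- bl$value[order(bl$j)]
  }
  as_scaler <- function(s) list(mean = unlist(s$mean), sd = unlist(s$sd))
  structure(list(
    spec = mlp_spec(n_in = sizes[1], hidden = sizes[-c(1, length(sizes))],
                    n_out = sizes[length(sizes)],
                    dropout_rate = manifest$dropout_rate),
    W = W, b = b,
    input_scaler = as_scaler(manifest$input_scaler),
    output_scaler = as_scaler(manifest$output_scaler),
    direction = manifest$direction,
    features = manifest$features, targets = manifest$targets,
    feature_range = list(lo = unlist(manifest$feature_range$lo),
                         hi = unlist(manifest$feature_range$hi)),
    loss_history = as.data.frame(manifest$loss_history),
    best_epoch = manifest$best_epoch,
    config = do.call(train_config, manifest$config[
      c("split_fraction", "learning_rate", "batch_size", "max_epochs",
        "patience", "seed")]),
    meta = manifest$meta
  ), class = "trained_surrogate")
}
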