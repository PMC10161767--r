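#' Training configuration for the fully connected network
#'
#' @param hidden integer vector of hidden-layer widths; `integer(0)` gives a
#'   purely linear model. The default 512-256-128 funnel is sized for
#'   CPU-scale training on tens of thousands of curves.
#' @param lr Adam learning rate.
#' @param lr_decay multiplicative learning-rate decay per epoch (default 1,
#'   no decay); with mean-absolute-error loss the gradient magnitude does
#'   not vanish near the optimum, so a mild decay sharpens convergence.
#' @param batch_size mini-batch size.
#' @param epochs maximum training epochs (>= 1).
#' @param patience early-stopping patience on validation MAE, in epochs.
#' @param restore_best return the weights of the best validation epoch
#'   (default) rather than the final epoch; disable for capacity checks
#'   that deliberately overfit.
#' @param seed integer seed for initialization and batch shuffling.
#' @param n_repetitions repetitions used by [repeat_phase1()] (default 5).
#' @return an object of class `fcnn_config`.
#' @export
fcnn_config <- function(hidden = c(512L, 256L, 128L), lr = 1e-3,
                        lr_decay = 1, batch_size = 256L, epochs = 200L,
                        patience = 20L, restore_best = TRUE, seed = 1L,
                        n_repetitions = 5L) {
  stopifnot(
    epochs >= 1, n_repetitions >= 1, lr > 0, batch_size >= 1,
    lr_decay > 0, lr_decay <= 1
  )
  structure(
    list(
      hidden = as.integer(hidden), lr = lr, lr_decay = lr_decay,
      batch_size = as.integer(batch_size), epochs = as.integer(epochs),
      patience = as.integer(patience), restore_best = isTRUE(restore_best),
      seed = as.integer(seed),
      n_repetitions = as.integer(n_repetitions)
    ),
    class = "fcnn_config"
  )
}

#' Train the fully connected network regressor
#'
#' Learns the mapping from corrupted `[intensity; mask]` features to the
#' 17-value encoded label vector by minimizing mean absolute error with
#' Adam. Training runs over mini-batches with per-epoch reshuffling,
#' monitors validation MAE, stops early after `patience` epochs without
#' improvement, and restores the best weights.
#'
#' @param dataset a `fiber_dataset` with non-empty train and val splits.
#' @param config an [fcnn_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `c("fcnn_model", "fib_model")` with the
#'   fitted weights, config snapshot, and per-epoch loss `history`.
#' @export
train_fcnn <- function(dataset, config = fcnn_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "fiber_dataset"), inherits(config, "fcnn_config"))
  tr <- dataset_rows(dataset, "train")
  va <- dataset_rows(dataset, "val")
  if (!length(tr) || !length(va)) {
    abort("dataset needs non-empty train and val splits.")
  }
  X <- dataset_features(dataset, tr)
  Y <- dataset$labels[tr, , drop = FALSE]
  Xv <- dataset_features(dataset, va)
  Yv <- dataset$labels[va, , drop = FALSE]

  sizes <- c(ncol(X), config$hidden, ncol(Y))
  net <- mlp_init(sizes, seed = config$seed)
  state <- adam_init(net)
  best <- list(net = net, val = mlp_mae(net, Xv, Yv), epoch = 0L)
  init_val <- best$val
  history <- tibble::tibble(
    epoch = integer(0), train_mae = double(0), val_mae = double(0)
  )
  n <- nrow(X)
  bad_epochs <- 0L
  lr <- config$lr
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, epoch), sample.int(n))
    tr_loss <- 0
    nb <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      rows <- ord[s:min(n, s + config$batch_size - 1L)]
      fwd <- mlp_forward(net, X[rows, , drop = FALSE], keep = TRUE)
      tr_loss <- tr_loss + mean(abs(fwd$out - Y[rows, , drop = FALSE]))
      nb <- nb + 1L
      grads <- mlp_grad(net, fwd, Y[rows, , drop = FALSE])
      upd <- adam_step(net, grads, state, lr = lr)
      net <- upd$net
      state <- upd$state
    }
    tr_loss <- tr_loss / nb
    if (!is.finite(tr_loss)) {
      abort(sprintf("training diverged (non-finite loss) at epoch %d.", epoch))
    }
    val_loss <- mlp_mae(net, Xv, Yv)
    history <- tibble::add_row(
      history, epoch = epoch, train_mae = tr_loss, val_mae = val_loss
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  train %.5f  val %.5f", epoch, tr_loss, val_loss
      ))
    }
    lr <- lr * config$lr_decay
    if (val_loss < best$val) {
      best <- list(net = net, val = val_loss, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }
  final <- if (config$restore_best) best$net else net
  structure(
    list(
      algo = "fcnn", net = final, config = config,
      input_len = ncol(X), n_bins = dataset$grid$n_bins,
      history = history, best_epoch = best$epoch,
      init_val_mae = init_val, best_val_mae = best$val,
      train_fingerprint = c(n_train = length(tr), seed = dataset$seed)
    ),
    class = c("fcnn_model", "fib_model")
  )
}

#' Train a classical baseline regressor
#'
#' Multi-output regression on flattened `[intensity; mask]` features.
#' `"knn"` is a K-nearest-neighbors regressor (label average over the k
#' nearest training curves by Euclidean distance, computed with BLAS);
#' `"rf"` and `"svr"` fit one randomForest / e1071 SVR model per output.
#' When `tune = TRUE` the KNN `k` is selected on the validation split from
#' a small documented grid.
#'
#' @param dataset a `fiber_dataset`.
#' @param algo `"knn"`, `"rf"` or `"svr"`.
#' @param hyperparams named list, e.g. `list(k = 5)`, `list(ntree = 100)`,
#'   `list(cost = 1)`.
#' @param tune logical; small validation-grid search (KNN only).
#' @return an object of class `c("<algo>_model", "fib_model")`.
#' @export
train_baseline <- function(dataset, algo = c("knn", "rf", "svr"),
                           hyperparams = list(), tune = FALSE) {
  algo <- match.arg(algo)
  stopifnot(inherits(dataset, "fiber_dataset"))
  tr <- dataset_rows(dataset, "train")
  X <- dataset_features(dataset, tr)
  Y <- dataset$labels[tr, , drop = FALSE]
  fit <- switch(algo,
    knn = {
      k <- hyperparams$k %||% 5L
      if (tune) {
        va <- dataset_rows(dataset, "val")
        Xv <- dataset_features(dataset, va)
        Yv <- dataset$labels[va, , drop = FALSE]
        grid <- c(1L, 3L, 5L, 10L, 20L)
        grid <- grid[grid <= nrow(X)]
        val_mae <- vapply(grid, function(kk) {
          mean(abs(knn_predict(X, Y, Xv, kk) - Yv))
        }, double(1))
        k <- grid[which.min(val_mae)]
      }
      list(X = X, Y = Y, k = as.integer(k))
    },
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        abort("the randomForest package is required for algo = 'rf'.")
      }
      ntree <- hyperparams$ntree %||% 100L
      seed <- hyperparams$seed %||% 1L
      with_seed(seed, {
        lapply(seq_len(ncol(Y)), function(j) {
          randomForest::randomForest(x = X, y = Y[, j], ntree = ntree)
        })
      })
    },
    svr = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        abort("the e1071 package is required for algo = 'svr'.")
      }
      cost <- hyperparams$cost %||% 1
      # scale = FALSE: features are already on [0, 1] and the constant
      # mask-channel columns of clean datasets break e1071's scaling.
      # Near-constant targets can leave epsilon-SVR with zero support
      # vectors (an "empty" model); fall back to the target mean then.
      lapply(seq_len(ncol(Y)), function(j) {
        fit <- e1071::svm(x = X, y = Y[, j], cost = cost, fitted = FALSE,
          scale = FALSE
        )
        list(fit = fit, fallback = mean(Y[, j]), empty = fit$tot.nSV == 0)
      })
    }
  )
  structure(
    list(
      algo = algo, fit = fit, hyperparams = hyperparams,
      input_len = ncol(X), n_bins = dataset$grid$n_bins,
      train_fingerprint = c(n_train = length(tr), seed = dataset$seed)
    ),
    class = c(paste0(algo, "_model"), "fib_model")
  )
}

# Chunked KNN label-average prediction (Euclidean distance via dgemm).
knn_predict <- function(X, Y, Xnew, k, chunk = 512L) {
  xn2 <- rowSums(X^2)
  out <- matrix(0, nrow(Xnew), ncol(Y))
  for (s in seq(1L, nrow(Xnew), by = chunk)) {
    e <- min(nrow(Xnew), s + chunk - 1L)
    B <- Xnew[s:e, , drop = FALSE]
    d2 <- outer(rowSums(B^2), xn2, `+`) - 2 * tcrossprod(B, X)
    for (i in seq_len(nrow(B))) {
      nn <- order(d2[i, ])[seq_len(k)]
      out[s + i - 1L, ] <- colMeans(Y[nn, , drop = FALSE])
    }
  }
  out
}

# Raw 17-column prediction from [intensity; mask] features.
predict_raw <- function(model, features) {
  stopifnot(inherits(model, "fib_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$input_len) {
    abort(sprintf(
      "feature length %d does not match the model input length %d.",
      ncol(features), model$input_len
    ))
  }
  switch(model$algo,
    fcnn = mlp_forward(model$net, features),
    knn = knn_predict(model$fit$X, model$fit$Y, features, model$fit$k),
    rf = vapply(
      model$fit, function(f) unname(stats::predict(f, features)),
      double(nrow(features))
    ) |> matrix(nrow = nrow(features)),
    svr = vapply(
      model$fit, function(f) {
        if (f$empty) {
          rep(f$fallback, nrow(features))
        } else {
          unname(stats::predict(f$fit, features))
        }
      },
      double(nrow(features))
    ) |> matrix(nrow = nrow(features)),
    abort(sprintf("unsupported model algo '%s'.", model$algo))
  )
}

#' Predict orientation parameters from curves
#'
#' Runs the fitted regressor on `[intensity; mask]` features and decodes the
#' raw 17-value outputs into the nine orientation parameters.
#'
#' @param model a fitted model from [train_fcnn()] or [train_baseline()].
#' @param curves intensity matrix (n x n_bins), a single [ichi_curve()], or
#'   a list of them; masked bins are taken from `masks` / the curve masks.
#' @param masks optional logical matrix matching `curves`.
#' @return a canonical parameter tibble with one row per curve.
#' @export
predict_orientation <- function(model, curves, masks = NULL) {
  feats <- curves_to_features(curves, masks, model$n_bins)
  if (nrow(feats) == 0L) {
    return(validate_params(tibble::as_tibble(
      matrix(numeric(0), 0, 9, dimnames = list(NULL, PARAM_NAMES))
    )))
  }
  decode_labels(predict_raw(model, feats))
}

curves_to_features <- function(curves, masks = NULL, n_bins = NULL) {
  if (inherits(curves, "ichi_curve")) curves <- list(curves)
  if (is.list(curves) && !is.data.frame(curves)) {
    if (!length(curves)) {
      return(matrix(numeric(0), 0L, 2L * (n_bins %||% 0L)))
    }
    stopifnot(all(vapply(curves, inherits, logical(1), "ichi_curve")))
    inten <- do.call(rbind, lapply(curves, function(cu) cu$intensity))
    masks <- do.call(rbind, lapply(curves, function(cu) cu$valid_mask))
    curves <- inten
  }
  curves <- as.matrix(curves)
  if (!is.null(n_bins) && ncol(curves) != n_bins) {
    abort(sprintf(
      "curve grid length %d does not match the model grid %d.",
      ncol(curves), n_bins
    ))
  }
  if (is.null(masks)) masks <- matrix(TRUE, nrow(curves), ncol(curves))
  cbind(curves, masks * 1)
}

#' @export
print.fib_model <- function(x, ...) {
  cat(sprintf(
    "<%s model> input %d, trained on %d curves\n",
    x$algo, x$input_len, x$train_fingerprint[["n_train"]]
  ))
  invisible(x)
}

#' Glance at a fitted FCNN
#'
#' @param x an `fcnn_model`.
#' @param ... unused.
#' @return one-row tibble with epochs run, best epoch and MAE values.
#' @importFrom generics glance
#' @export
glance.fcnn_model <- function(x, ...) {
  tibble::tibble(
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    init_val_mae = x$init_val_mae,
    best_val_mae = x$best_val_mae
  )
}

#' @export
tidy.fcnn_model <- function(x, ...) x$history
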