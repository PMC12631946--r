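# Regression heads and cross-validation.

#' Model configuration constructors
#'
#' `mlp_config()` describes a feed-forward network: `depth` hidden layers of
#' `width` ReLU units, dropout regularisation, Adam optimisation with early
#' stopping on an internal validation split. `gbdt_config()` describes the
#' gradient-boosted tree baseline.
#'
#' @param depth hidden layers (default 6).
#' @param width units per hidden layer (default 400).
#' @param dropout dropout rate on hidden activations.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience, epochs.
#' @param val_fraction internal validation fraction for early stopping.
#' @param weight_decay decoupled (AdamW-style) weight decay.
#' @param ema_decay exponential-moving-average decay for the weight average
#'   used at validation and prediction time (0 disables averaging).
#' @param snapshots number of snapshot-ensemble members: the cosine schedule
#'   restarts `snapshots` times over `max_epochs` and the averaged weights
#'   at each cycle end become one ensemble member; predictions average the
#'   members. 1 gives a single anneal with early stopping.
#' @param seed integer seed controlling initialisation, shuffling, dropout.
#' @return A list of class `plaff_model_config`.
#' @details The Adam step size follows a cyclic cosine anneal from
#'   `learning_rate` to 0; with `snapshots = 1` training stops early after
#'   `patience` epochs without validation improvement, restoring the best
#'   (averaged) weights.
#' @export
mlp_config <- function(depth = 6L, width = 400L, dropout = 0.1,
                       learning_rate = 1e-3, batch_size = 64L,
                       max_epochs = 60L, patience = 20L,
                       val_fraction = 0.1, weight_decay = 1e-4,
                       ema_decay = 0.999, snapshots = 1L, seed = 1L) {
  stopifnot(depth >= 1L, width >= 1L, patience >= 1L,
            dropout >= 0, dropout < 1, ema_decay >= 0, ema_decay < 1,
            snapshots >= 1L)
  structure(list(kind = "mlp", depth = depth, width = width,
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, val_fraction = val_fraction,
                 weight_decay = weight_decay, ema_decay = ema_decay,
                 snapshots = snapshots, seed = seed),
            class = "plaff_model_config")
}

#' @rdname mlp_config
#' @param trees boosting rounds (default 500).
#' @param tree_depth maximum tree depth.
#' @param subsample row subsampling rate.
#' @export
gbdt_config <- function(trees = 500L, tree_depth = 6L, learning_rate = 0.05,
                        subsample = 0.8, seed = 1L) {
  structure(list(kind = "gbdt", trees = trees, tree_depth = tree_depth,
                 learning_rate = learning_rate, subsample = subsample,
                 seed = seed),
            class = "plaff_model_config")
}

#' Regression metrics: Pearson correlation, MAE, RMSE
#'
#' The correlation is computed from its definition,
#' `sum((y - ybar)(yhat - yhatbar)) / sqrt(sum((y - ybar)^2)
#' sum((yhat - yhatbar)^2))`. Zero variance in either vector makes the
#' correlation undefined; it is reported as `NaN` with
#' `degenerate = TRUE`.
#'
#' @param y observed labels (kcal/mol).
#' @param yhat predictions.
#' @return Object of class `plaff_metrics`: `rp`, `mae`, `rmse`, `n`,
#'   `degenerate`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L,
            all(is.finite(y)), all(is.finite(yhat)))
  dy <- y - mean(y); dp <- yhat - mean(yhat)
  den <- sqrt(sum(dy^2) * sum(dp^2))
  degenerate <- den == 0
  rp <- if (degenerate) NaN else sum(dy * dp) / den
  structure(list(rp = rp, mae = mean(abs(y - yhat)),
                 rmse = sqrt(mean((y - yhat)^2)), n = length(y),
                 degenerate = degenerate),
            class = "plaff_metrics")
}

#' @export
print.plaff_metrics <- function(x, ...) {
  cat(sprintf("n = %d  Rp = %.4f  MAE = %.3f  RMSE = %.3f kcal/mol\n",
              x$n, x$rp, x$mae, x$rmse))
  invisible(x)
}

## ---- MLP internals ---------------------------------------------------------

.mlp_init <- function(d_in, cfg) {
  dims <- c(d_in, rep(cfg$width, cfg$depth), 1L)
  lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = matrix(stats::rnorm(dims[l] * dims[l + 1L], 0,
                                 sqrt(2 / dims[l])),
                    dims[l], dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
}

.mlp_ens_forward <- function(members, X) {
  Reduce(`+`, lapply(members, function(m) .mlp_forward(m, X))) /
    length(members)
}

.mlp_forward <- function(layers, X) {
  a <- X
  nl <- length(layers)
  for (l in seq_len(nl - 1L)) {
    a <- a %*% layers[[l]]$W
    a <- sweep(a, 2L, layers[[l]]$b, "+")
    a[a < 0] <- 0
  }
  drop(sweep(a %*% layers[[nl]]$W, 2L, layers[[nl]]$b, "+"))
}

# one Adam minibatch step; returns updated layers and optimiser state
.mlp_step <- function(layers, opt, X, y, cfg, t, lr) {
  nl <- length(layers)
  acts <- vector("list", nl + 1L)
  masks <- vector("list", nl)
  acts[[1L]] <- X
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    if (l < nl) {
      z[z < 0] <- 0
      if (cfg$dropout > 0) {
        m <- matrix(stats::runif(length(z)) >= cfg$dropout,
                    nrow(z), ncol(z)) / (1 - cfg$dropout)
        z <- z * m
        masks[[l]] <- m
      }
    }
    acts[[l + 1L]] <- z
  }
  nb <- nrow(X)
  delta <- 2 * (acts[[nl + 1L]] - y) / nb     # d loss / d output
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (l in rev(seq_len(nl))) {
    gW <- crossprod(acts[[l]], delta)
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, layers[[l]]$W)
      if (cfg$dropout > 0 && !is.null(masks[[l - 1L]])) {
        delta <- delta * masks[[l - 1L]]
      }
      delta[acts[[l]] <= 0] <- 0             # ReLU gate
    }
    o <- opt[[l]]
    o$mW <- b1 * o$mW + (1 - b1) * gW
    o$vW <- b2 * o$vW + (1 - b2) * gW^2
    o$mb <- b1 * o$mb + (1 - b1) * gb
    o$vb <- b2 * o$vb + (1 - b2) * gb^2
    corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
    wd <- cfg$weight_decay %||% 0
    layers[[l]]$W <- layers[[l]]$W * (1 - lr * wd) -
      lr * (o$mW / corr1) / (sqrt(o$vW / corr2) + eps)
    layers[[l]]$b <- layers[[l]]$b -
      lr * (o$mb / corr1) / (sqrt(o$vb / corr2) + eps)
    opt[[l]] <- o
  }
  list(layers = layers, opt = opt)
}

.mlp_train <- function(X, y, cfg, groups = NULL) {
  n <- nrow(X)
  n_val <- max(1L, round(cfg$val_fraction * n))
  if (is.null(groups)) {
    val_idx <- sample.int(n, n_val)
  } else {
    # grouped validation split: whole groups held out, so early stopping
    # measures cross-group generalisation
    gids <- sample(unique(groups))
    cum <- cumsum(vapply(gids, function(g) sum(groups == g), integer(1)))
    take <- gids[seq_len(max(1L, which(cum >= n_val)[1L]))]
    val_idx <- which(groups %in% take)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]

  layers <- .mlp_init(ncol(X), cfg)
  opt <- lapply(layers, function(l) list(mW = 0 * l$W, vW = 0 * l$W,
                                         mb = 0 * l$b, vb = 0 * l$b))
  best <- list(val = Inf, layers = layers, epoch = 0L)
  stall <- 0L; t <- 0L
  ema <- if ((cfg$ema_decay %||% 0) > 0) layers else NULL
  ed <- cfg$ema_decay %||% 0
  n_snap <- cfg$snapshots %||% 1L
  cycle <- max(1L, ceiling(cfg$max_epochs / n_snap))
  members <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    # cyclic cosine-annealed step size (one cycle per snapshot member)
    phase <- ((epoch - 1L) %% cycle) / cycle
    lr <- cfg$learning_rate * 0.5 * (1 + cos(pi * phase))
    perm <- sample.int(length(tr_idx))
    starts <- seq(1L, length(perm), by = cfg$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, length(perm))]
      t <- t + 1L
      st <- .mlp_step(layers, opt, Xtr[idx, , drop = FALSE], ytr[idx],
                      cfg, t, lr)
      layers <- st$layers; opt <- st$opt
      if (!is.null(ema)) {
        w <- min(ed, (t - 1) / (t + 1))  # warmup-adjusted averaging
        for (l in seq_along(ema)) {
          ema[[l]]$W <- w * ema[[l]]$W + (1 - w) * layers[[l]]$W
          ema[[l]]$b <- w * ema[[l]]$b + (1 - w) * layers[[l]]$b
        }
      }
    }
    eval_layers <- if (!is.null(ema)) ema else layers
    if (n_snap > 1L) {
      if (epoch %% cycle == 0L || epoch == cfg$max_epochs) {
        members[[length(members) + 1L]] <- eval_layers
      }
      next
    }
    val_mse <- mean((.mlp_forward(eval_layers, Xva) - yva)^2)
    if (val_mse < best$val - 1e-9) {
      best <- list(val = val_mse, layers = eval_layers, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  if (n_snap > 1L) {
    ens <- unique(members)
    val_mse <- mean((.mlp_ens_forward(ens, Xva) - yva)^2)
    return(list(ensemble = ens, best_val_mse = val_mse,
                epochs_run = epoch, best_epoch = epoch))
  }
  list(layers = best$layers, best_val_mse = best$val,
       epochs_run = epoch, best_epoch = best$epoch)
}

## ---- training interface ----------------------------------------------------

#' Train a regression model on a feature matrix
#'
#' Standardises features and labels with the training statistics (stored on
#' the model, reapplied at prediction time), then fits either the MLP (Adam,
#' dropout, early stopping on an internal validation split) or the xgboost
#' GBDT baseline. All randomness derives from `config$seed`; the global RNG
#' state is left untouched.
#'
#' @param config from [mlp_config()] or [gbdt_config()].
#' @param X numeric feature matrix (rows = complexes). Columns with zero
#'   training variance are dropped from standardisation (scale 1).
#' @param y labels, kcal/mol.
#' @param manifest optional feature manifest stored for prediction-time
#'   layout checks.
#' @param groups optional per-row group labels; when given, the MLP's
#'   internal early-stopping validation split holds out whole groups.
#' @return Object of class `plaff_model`.
#' @export
train_model <- function(config, X, y, manifest = NULL, groups = NULL) {
  stopifnot(inherits(config, "plaff_model_config"),
            is.matrix(X) || is.data.frame(X))
  X <- as.matrix(X)
  if (!all(is.finite(X))) {
    bad <- which(!apply(is.finite(X), 2L, all))
    nm <- if (!is.null(colnames(X))) colnames(X)[bad[1L]] else bad[1L]
    stop("non-finite feature values in column ", nm)
  }
  stopifnot(all(is.finite(y)), nrow(X) == length(y))

  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  y_ctr <- mean(y); y_scl <- stats::sd(y)
  if (y_scl == 0) y_scl <- 1
  ys <- (y - y_ctr) / y_scl

  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  fit <- if (config$kind == "mlp") {
    .mlp_train(Xs, ys, config, groups = groups)
  } else {
    xgboost::xgb.train(
      params = list(max_depth = config$tree_depth,
                    eta = config$learning_rate,
                    subsample = config$subsample,
                    objective = "reg:squarederror",
                    nthread = 1L, seed = config$seed),
      data = xgboost::xgb.DMatrix(Xs, label = ys),
      nrounds = config$trees, verbose = 0)
  }
  structure(list(kind = config$kind, config = config, fit = fit,
                 x_center = ctr, x_scale = scl,
                 y_center = y_ctr, y_scale = y_scl,
                 manifest = manifest, n_train = nrow(X)),
            class = "plaff_model")
}

#' @export
print.plaff_model <- function(x, ...) {
  cat("plaff ", toupper(x$kind), " model: ", length(x$x_center),
      " features, ", x$n_train, " training rows\n", sep = "")
  if (x$kind == "mlp") {
    cat(sprintf("  depth %d x width %d; stopped after %d epochs (best %d)\n",
                x$config$depth, x$config$width, x$fit$epochs_run,
                x$fit$best_epoch))
  } else {
    cat(sprintf("  %d trees, depth %d, eta %g\n", x$config$trees,
                x$config$tree_depth, x$config$learning_rate))
  }
  invisible(x)
}

#' Predict binding free energy for new feature rows
#'
#' Applies the stored standardisation, then the fitted model; output is on
#' the original kcal/mol scale. When both the model and `newdata` carry a
#' manifest, block layouts are compared and the first differing block is
#' named on error.
#'
#' @param object a `plaff_model`.
#' @param newdata numeric matrix, or a `plaff_feature_vector`.
#' @param manifest optional manifest of `newdata` for the layout check.
#' @param ... unused.
#' @export
predict.plaff_model <- function(object, newdata, manifest = NULL, ...) {
  if (inherits(newdata, "plaff_feature_vector")) {
    manifest <- newdata$manifest
    newdata <- matrix(newdata$values, nrow = 1L)
  }
  newdata <- as.matrix(newdata)
  if (!is.null(manifest) && !is.null(object$manifest)) {
    ok <- identical(manifest$block, object$manifest$block) &&
      identical(manifest$start, object$manifest$start) &&
      identical(manifest$end, object$manifest$end)
    if (!ok) {
      diff <- which(!(manifest$block == object$manifest$block[
        seq_len(min(nrow(manifest), nrow(object$manifest)))]))[1L]
      stop("feature manifest mismatch at block '",
           manifest$block[min(diff, nrow(manifest), na.rm = TRUE)], "'")
    }
  }
  if (ncol(newdata) != length(object$x_center)) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object$x_center))
  }
  Xs <- sweep(sweep(newdata, 2L, object$x_center), 2L, object$x_scale, "/")
  ys <- if (object$kind == "mlp") {
    if (!is.null(object$fit$ensemble)) {
      .mlp_ens_forward(object$fit$ensemble, Xs)
    } else .mlp_forward(object$fit$layers, Xs)
  } else {
    stats::predict(object$fit, xgboost::xgb.DMatrix(Xs))
  }
  as.numeric(ys) * object$y_scale + object$y_center
}

#' Cross-validated evaluation of a model configuration
#'
#' For each fold of the plan, fits on the complement (standardisation refit
#' per fold, so no information leaks from the test rows) and predicts the
#' held-out rows. Metrics are reported pooled over the concatenated
#' out-of-fold predictions (the headline convention) and per fold.
#'
#' @param config a `plaff_model_config`.
#' @param X feature matrix.
#' @param y labels, kcal/mol.
#' @param plan a `plaff_split_plan` whose folds partition the rows of `X`.
#' @return Object of class `plaff_cv`: `pooled` (a `plaff_metrics`),
#'   `per_fold` data.frame, `predictions` (one out-of-fold prediction per
#'   row), `plan`.
#' @export
cross_validate <- function(config, X, y, plan) {
  stopifnot(inherits(plan, "plaff_split_plan"))
  X <- as.matrix(X)
  n <- nrow(X)
  all_idx <- sort(unlist(plan$folds, use.names = FALSE))
  if (!identical(all_idx, seq_len(n))) {
    stop("split plan does not partition the ", n, " rows")
  }
  preds <- rep(NA_real_, n)
  per_fold <- list()
  for (fi in seq_along(plan$folds)) {
    test <- plan$folds[[fi]]
    if (length(test) < 1L) {
      warning("fold ", fi, " has no test rows; skipped")
      next
    }
    train <- setdiff(seq_len(n), test)
    fit <- train_model(config, X[train, , drop = FALSE], y[train],
                       groups = plan$groups[train])
    p <- predict(fit, X[test, , drop = FALSE])
    preds[test] <- p
    per_fold[[length(per_fold) + 1L]] <- data.frame(
      fold = fi, n = length(test),
      rp = if (length(test) >= 2L && stats::sd(y[test]) > 0 &&
               stats::sd(p) > 0) stats::cor(y[test], p) else NA_real_,
      mae = mean(abs(y[test] - p)),
      rmse = sqrt(mean((y[test] - p)^2)))
  }
  structure(list(pooled = regression_metrics(y, preds),
                 per_fold = do.call(rbind, per_fold),
                 predictions = preds, plan = plan, config = config),
            class = "plaff_cv")
}

#' @export
print.plaff_cv <- function(x, ...) {
  cat("Cross-validation (", x$plan$mode, ", ", length(x$plan$folds),
      " folds), pooled out-of-fold:\n", sep = "")
  print(x$pooled)
  invisible(x)
}
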