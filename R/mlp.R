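#' Training configuration for the perceptron
#'
#' The study design fixes the architecture and training protocol: one hidden
#' layer of 10 logistic units and a logistic output, full-batch BFGS on the
#' sum-of-squares (SOS) loss capped at 300 epochs (one quasi-Newton iteration
#' = one epoch), Gaussian weight initialization, and 5 random restarts with
#' the most accurate model kept.
#'
#' @param hidden_units hidden-layer width (default 10).
#' @param max_epochs BFGS iteration cap (default 300).
#' @param restarts number of random restarts (default 5).
#' @param init_sigma standard deviation of the zero-mean Gaussian weight
#'   initialization (default 0.5; the original software does not document its
#'   scale).
#' @param seed master seed; restart and split seeds are derived from it.
#' @param tol relative convergence tolerance handed to the optimizer.
#' @param squash_range the (lo, hi) interval inside (0, 1) the target is
#'   scaled to, keeping the logistic output away from saturation.
#' @return a `train_config` list.
#' @export
train_config <- function(hidden_units = 10, max_epochs = 300, restarts = 5,
                         init_sigma = 0.5, seed = 1, tol = 1e-8,
                         squash_range = c(0.1, 0.9)) {
  stopifnot(hidden_units >= 1, max_epochs >= 1, restarts >= 1,
            init_sigma > 0, squash_range[1] > 0, squash_range[2] < 1,
            squash_range[1] < squash_range[2])
  structure(list(hidden_units = as.integer(hidden_units),
                 max_epochs = as.integer(max_epochs),
                 restarts = as.integer(restarts),
                 init_sigma = init_sigma, seed = as.integer(seed),
                 tol = tol, squash_range = squash_range),
            class = "train_config")
}

logistic <- function(z) 1 / (1 + exp(-z))

# Min-max scaling parameters fitted on the training split only. Constant
# columns get span 1 so they map to 0 and carry no information.
fit_scaling <- function(X, y, squash_range) {
  xmin <- apply(X, 2, min)
  xmax <- apply(X, 2, max)
  span <- xmax - xmin
  span[span == 0] <- 1
  list(xmin = xmin, xspan = span, ymin = min(y), yspan = max(y) - min(y),
       lo = squash_range[1], hi = squash_range[2])
}

scale_X <- function(X, sc) sweep(sweep(X, 2, sc$xmin), 2, sc$xspan, "/")
scale_y <- function(y, sc) sc$lo + (y - sc$ymin) / sc$yspan * (sc$hi - sc$lo)
unscale_y <- function(ys, sc) sc$ymin + (ys - sc$lo) / (sc$hi - sc$lo) * sc$yspan

pack_params <- function(W1, b1, w2, b2) c(as.vector(W1), b1, w2, b2)

unpack_params <- function(par, p, h) {
  W1 <- matrix(par[seq_len(h * p)], nrow = h, ncol = p)
  b1 <- par[h * p + seq_len(h)]
  w2 <- par[h * p + h + seq_len(h)]
  b2 <- par[h * p + 2 * h + 1]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

# Forward pass on scaled inputs; returns hidden activations and scaled output.
mlp_forward <- function(par, Xs, p, h) {
  w <- unpack_params(par, p, h)
  A1 <- logistic(sweep(Xs %*% t(w$W1), 2, w$b1, "+"))
  yhat <- logistic(drop(A1 %*% w$w2) + w$b2)
  list(A1 = A1, yhat = yhat, w = w)
}

# SOS = sum((yhat - ys)^2) on the scaled target.
mlp_sos <- function(par, Xs, ys, p, h) {
  fw <- mlp_forward(par, Xs, p, h)
  sum((fw$yhat - ys)^2)
}

# Analytic gradient of the SOS loss (backpropagation).
mlp_sos_grad <- function(par, Xs, ys, p, h) {
  fw <- mlp_forward(par, Xs, p, h)
  d2 <- 2 * (fw$yhat - ys) * fw$yhat * (1 - fw$yhat)         # n
  gw2 <- drop(crossprod(fw$A1, d2))                          # h
  gb2 <- sum(d2)
  D1 <- (d2 %o% fw$w$w2) * fw$A1 * (1 - fw$A1)               # n x h
  gW1 <- crossprod(D1, Xs)                                   # h x p
  gb1 <- colSums(D1)
  pack_params(gW1, gb1, gw2, gb2)
}

#' Fit a single multilayer perceptron
#'
#' Trains the fixed architecture (inputs -> `hidden_units` logistic units ->
#' 1 logistic output) by full-batch BFGS minimization of the sum-of-squares
#' loss on the training split, for at most `max_epochs` iterations. Inputs are
#' min-max scaled to \[0, 1\] and the target affinely mapped into the squash
#' range, both using training-split statistics only. Weights start from a
#' zero-mean Gaussian drawn at `restart_seed` (the output bias starts at the
#' logit of the scaled-target mean, so the first forward pass predicts the
#' mean rather than a saturated extreme); the fit is deterministic given its
#' arguments.
#'
#' @param table a `case_table` (target in the last column, per `target` attr).
#' @param split a `split_assignment` for the rows of `table`.
#' @param cfg a [train_config()].
#' @param restart_seed integer seed for the weight initialization.
#' @return an `mlp_model` with weights, scaling parameters and training
#'   metadata (`sos_train`, `sos_valid`, `epochs`, `restart_seed`).
#' @export
fit_mlp <- function(table, split, cfg = train_config(), restart_seed = cfg$seed) {
  target <- attr(table, "target")
  X <- as.matrix(as.data.frame(table)[, setdiff(names(table), target), drop = FALSE])
  y <- table[[target]]
  tr <- split == "train"
  va <- split == "valid"
  if (stats::var(y[tr]) == 0) {
    stop(degenerate_segment_error(target, y[tr][1], sum(tr)))
  }
  sc <- fit_scaling(X[tr, , drop = FALSE], y[tr], cfg$squash_range)
  Xs_tr <- scale_X(X[tr, , drop = FALSE], sc)
  ys_tr <- scale_y(y[tr], sc)
  p <- ncol(X)
  h <- cfg$hidden_units
  npar <- h * p + 2 * h + 1
  par0 <- with_seed(restart_seed, stats::rnorm(npar, 0, cfg$init_sigma))
  # start the output at the scaled-target mean: a randomly saturated logistic
  # output is a flat plateau on which full-batch BFGS stalls immediately
  par0[npar] <- stats::qlogis(mean(ys_tr))
  sos0 <- mlp_sos(par0, Xs_tr, ys_tr, p, h)
  res <- stats::optim(par0,
                      fn = function(par) mlp_sos(par, Xs_tr, ys_tr, p, h),
                      gr = function(par) mlp_sos_grad(par, Xs_tr, ys_tr, p, h),
                      method = "BFGS",
                      control = list(maxit = cfg$max_epochs, reltol = cfg$tol))
  if (!is.finite(res$value)) stop("non-finite SOS after optimization")
  # one gradient evaluation per quasi-Newton iteration, plus the initial one
  epochs <- max(0L, unname(res$counts["gradient"]) - 1L)
  sos_valid <- NA_real_
  if (any(va)) {
    sos_valid <- mlp_sos(res$par, scale_X(X[va, , drop = FALSE], sc),
                         scale_y(y[va], sc), p, h)
  }
  structure(list(
    par = res$par, p = p, h = h, scaling = sc,
    columns = colnames(X), target = target,
    sos_train = res$value, sos_train_init = sos0, sos_valid = sos_valid,
    epochs = epochs, restart_seed = as.integer(restart_seed), cfg = cfg
  ), class = "mlp_model")
}

degenerate_segment_error <- function(target, value, n) {
  structure(class = c("degenerate_segment", "error", "condition"),
            list(message = sprintf(
              "cannot train on %s: zero target variability (constant %.4g over %d training cases)",
              target, value, n), call = NULL, constant = value))
}

#' Fit with random restarts, keeping the most accurate model
#'
#' Runs [fit_mlp()] `cfg$restarts` times with distinct derived initialization
#' seeds and returns the model with the lowest validation SOS (ties broken by
#' lower restart index). The test split stays untouched.
#'
#' @inheritParams fit_mlp
#' @return the selected `mlp_model`, with `restart_sos` (all validation SOS
#'   values) attached.
#' @export
fit_best_of_restarts <- function(table, split, cfg = train_config()) {
  fits <- vector("list", cfg$restarts)
  errs <- character(0)
  for (r in seq_len(cfg$restarts)) {
    seed_r <- derive_seed(cfg$seed, 101, r)
    res <- tryCatch(fit_mlp(table, split, cfg, restart_seed = seed_r),
                    error = function(e) e)
    if (inherits(res, "degenerate_segment")) {
      stop(res) # a property of the data, not of the restart: fail immediately
    }
    if (inherits(res, "error")) {
      errs <- c(errs, conditionMessage(res))
    } else {
      fits[[r]] <- res
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("all ", cfg$restarts, " restarts failed: ",
         paste(unique(errs), collapse = "; "))
  }
  crit <- vapply(fits, function(f) {
    if (is.null(f)) Inf else if (is.na(f$sos_valid)) f$sos_train else f$sos_valid
  }, numeric(1))
  best <- which.min(crit) # which.min returns the first (lowest index) minimum
  model <- fits[[best]]
  model$restart_sos <- crit
  model$restart_index <- best
  model
}

#' Predict with a fitted perceptron
#'
#' Forward pass through the logistic network on min-max-scaled inputs, mapped
#' back to concentration units. Values outside the training range pass through
#' the same affine scaling (extrapolation); the logistic output itself bounds
#' predictions to the unscaled image of (0, 1).
#'
#' @param object an `mlp_model`.
#' @param newdata a `case_table` or data frame containing the model's columns.
#' @param ... unused.
#' @return numeric vector of predicted concentrations.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  miss <- setdiff(object$columns, names(newdata))
  if (length(miss) > 0) {
    stop("newdata lacks column(s): ", paste(miss, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(newdata)[, object$columns, drop = FALSE])
  fw <- mlp_forward(object$par, scale_X(X, object$scaling), object$p, object$h)
  unscale_y(fw$yhat, object$scaling)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s ~ %d inputs -> %d logistic hidden -> 1 logistic\n",
              x$target, x$p, x$h))
  cat(sprintf(" SOS train %.4g (from %.4g), valid %.4g, epochs %d, seed %d\n",
              x$sos_train, x$sos_train_init, x$sos_valid, x$epochs,
              x$restart_seed))
  invisible(x)
}

#' Serialize / load a perceptron as JSON
#'
#' Stores shapes, flattened weights, scaling parameters and metadata so a
#' model can be reloaded for prediction without retraining.
#'
#' @param model an `mlp_model`.
#' @param path file path.
#' @return `path` invisibly; `read_mlp_json` returns the `mlp_model`.
#' @export
write_mlp_json <- function(model, path) {
  jsonlite::write_json(mlp_to_list(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  mlp_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

mlp_to_list <- function(model) {
  list(kind = "mlp_model", par = model$par, p = model$p, h = model$h,
       scaling = model$scaling, columns = model$columns, target = model$target,
       sos_train = model$sos_train, sos_valid = model$sos_valid,
       epochs = model$epochs, restart_seed = model$restart_seed)
}

mlp_from_list <- function(x) {
  x$scaling$xmin <- stats::setNames(as.numeric(x$scaling$xmin), x$columns)
  x$scaling$xspan <- stats::setNames(as.numeric(x$scaling$xspan), x$columns)
  structure(x[setdiff(names(x), "kind")], class = "mlp_model")
}
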