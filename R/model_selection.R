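#' Stratified calibration/validation split
#'
#' Randomly partitions samples into a calibration set (about
#' `calibration_fraction`, default two-thirds) and a validation set, drawing
#' evenly from all quartiles of the stratifying reference values: within
#' each quartile, the number of calibration samples is the rounded target
#' fraction, so the realized per-quartile fraction deviates from the target
#' by less than one sample. One plan is typically reused for all chemicals,
#' stratified on the total wax amount.
#'
#' @param reference_values Numeric vector (named, ideally) used for
#'   quartile stratification.
#' @param calibration_fraction Target calibration fraction in (0, 1);
#'   default 2/3.
#' @param seed Optional integer seed; equal seeds give identical plans.
#' @return Object of class `split_plan`: `calibration` and `validation`
#'   (ids when `reference_values` is named, indices otherwise), `quartile`
#'   (per sample), `calibration_fraction`, `seed`.
#' @export
stratified_split <- function(reference_values, calibration_fraction = 2 / 3,
                             seed = NULL) {
  if (calibration_fraction <= 0 || calibration_fraction >= 1) {
    stop("`calibration_fraction` must lie in (0, 1)", call. = FALSE)
  }
  n <- length(reference_values)
  if (n < 8L) stop("need at least 8 samples (2 per quartile)", call. = FALSE)
  ids <- names(reference_values) %||% seq_len(n)
  rk <- rank(reference_values, ties.method = "first")
  quart <- ceiling(4 * rk / n)
  cal <- with_seed(seed, {
    unlist(lapply(1:4, function(qq) {
      members <- which(quart == qq)
      k <- round(calibration_fraction * length(members))
      k <- max(1L, min(k, length(members) - 1L))
      sample(members, k)
    }))
  })
  cal <- sort(cal)
  structure(list(
    calibration = ids[cal],
    validation = ids[setdiff(seq_len(n), cal)],
    quartile = setNames(quart, ids),
    calibration_fraction = calibration_fraction,
    seed = seed
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d calibration / %d validation (target %.1f%%)\n",
              length(x$calibration), length(x$validation),
              100 * x$calibration_fraction))
  invisible(x)
}

#' Select the number of latent vectors by PRESS
#'
#' Repeatedly splits the calibration data at random into an inner training
#' part (fraction `inner_fraction`, default 90%) and a held-out part,
#' refits the PLSR on the training part, and accumulates squared prediction
#' error on the held-out part for every candidate component count. The
#' chosen count minimizes the mean predicted residual sum of squares
#' (PRESS) over permutations; ties break toward fewer components. Inner
#' splits are independent uniform draws, not a partition.
#'
#' @param X Calibration predictors (matrix samples x predictors or
#'   [spectra]).
#' @param y Calibration response.
#' @param max_ncomp Largest candidate component count; default 15, capped
#'   at half the calibration size (and at the fit's algebraic limit).
#' @param n_perm Number of random inner splits; default 500.
#' @param inner_fraction Inner training fraction in (0, 1); default 0.9.
#' @param scale Autoscale predictors (passed to [fit_plsr()])?
#' @param seed Optional integer seed.
#' @return Object of class `press_curve`: `press` (mean PRESS per candidate
#'   count), `ncomp` (the argmin), `n_perm`, `inner_fraction`, `seed`, and
#'   `held_out` (data frame of pooled held-out predictions at the chosen
#'   count: `index`, `observed`, `predicted`), from which a cross-validation
#'   R2 can be computed.
#' @export
select_components_press <- function(X, y, max_ncomp = 15L, n_perm = 500L,
                                    inner_fraction = 0.9, seed = NULL,
                                    scale = FALSE) {
  X <- as_predictor_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (max_ncomp < 1L) stop("`max_ncomp` must be at least 1", call. = FALSE)
  if (inner_fraction <= 0 || inner_fraction >= 1) {
    stop("`inner_fraction` must lie in (0, 1)", call. = FALSE)
  }
  n_in <- round(inner_fraction * n)
  if (n_in < 3L || n_in >= n) {
    stop("calibration set too small for the inner split", call. = FALSE)
  }
  A <- min(max_ncomp, floor(n / 2), n_in - 1L, ncol(X))
  if (A < 1L) stop("calibration set too small for any component", call. = FALSE)
  with_seed(seed, {
    sse <- matrix(0, n_perm, A)
    m <- 0L
    held <- vector("list", n_perm)
    for (perm in seq_len(n_perm)) {
      tr <- sample(n, n_in)
      te <- setdiff(seq_len(n), tr)
      fit <- suppressWarnings(fit_plsr(X[tr, , drop = FALSE], y[tr],
                                       ncomp = A, scale = scale))
      pred <- predict_components(fit, X[te, , drop = FALSE])  # n_te x ncomp
  if (fit$ncomp < A) {  # degenerate refit: reuse the last column
        pred <- cbind(pred, matrix(pred[, fit$ncomp], nrow(pred),
                                   A - fit$ncomp))
      }
      err <- (pred - y[te])^2
      sse[perm, ] <- colSums(err)
      m <- m + length(te)
      held[[perm]] <- data.frame(index = te, observed = y[te],
                                 predicted = pred)
    }
    press <- colMeans(sse)
    ncomp <- which.min(press)
    held_df <- do.call(rbind, held)
    held_out <- data.frame(index = held_df$index, observed = held_df$observed,
                           predicted = held_df[[2L + ncomp]])
    structure(list(press = press, ncomp = ncomp, n_perm = n_perm,
                   inner_fraction = inner_fraction, seed = seed,
                   held_out = held_out),
              class = "press_curve")
  })
}

# Per-component predictions for new data: column a holds the prediction
# using the first a latent vectors (computed by deflating the new data with
# the training loadings, avoiding repeated coefficient solves).
predict_components <- function(model, newX) {
  Md <- sweep(sweep(as.matrix(newX), 2L, model$xmean), 2L, model$xscale, "/")
  out <- matrix(0, nrow(Md), model$ncomp)
  acc <- rep(model$ymean, nrow(Md))
  for (a in seq_len(model$ncomp)) {
    tt <- Md %*% model$W[, a]
    Md <- Md - tcrossprod(tt, model$P[, a])
    acc <- acc + tt[, 1L] * model$q[a]
    out[, a] <- acc
  }
  out
}

#' @export
print.press_curve <- function(x, ...) {
  cat(sprintf("<press_curve> chose %d latent vector(s) over %d candidates (%d splits)\n",
              x$ncomp, length(x$press), x$n_perm))
  invisible(x)
}

#' Plot a PRESS curve
#' @param x A `press_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.press_curve <- function(x, ...) {
  graphics::plot(seq_along(x$press), x$press, type = "b",
                 xlab = "latent vectors", ylab = "mean PRESS", ...)
  graphics::abline(v = x$ncomp, lty = 2)
  invisible(x)
}

#' Evaluate predictions against observed values
#'
#' R2 is the squared Pearson correlation between predicted and observed
#' (the scatter-plot definition); RMSE is the root-mean-square error; the
#' relative RMSE is `100 * RMSE / (max(observed) - min(observed))`.
#'
#' @param predicted Numeric vector.
#' @param observed Numeric vector of the same length (>= 2) with nonzero
#'   range.
#' @return Data frame with one row: `r2`, `rmse`, `rel_rmse_pct`,
#'   `range_min`, `range_max`, `n`.
#' @export
evaluate_predictions <- function(predicted, observed) {
  predicted <- as.numeric(predicted); observed <- as.numeric(observed)
  if (length(predicted) != length(observed) || length(observed) < 2L) {
    stop("`predicted` and `observed` must be equal-length vectors (>= 2)",
         call. = FALSE)
  }
  rng <- range(observed)
  if (diff(rng) == 0) stop("observed values have zero range", call. = FALSE)
  rmse <- sqrt(mean((predicted - observed)^2))
  data.frame(
    r2 = if (sd(predicted) == 0) 0 else cor(predicted, observed)^2,
    rmse = rmse,
    rel_rmse_pct = 100 * rmse / diff(rng),
    range_min = rng[1L], range_max = rng[2L],
    n = length(observed)
  )
}

#' @importFrom stats cor
NULL
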