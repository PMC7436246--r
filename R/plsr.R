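#' Fit a partial least-squares regression (PLS1, NIPALS)
#'
#' NIPALS PLS with a single response: latent vectors are extracted
#' iteratively to maximize covariance between predictors and response,
#' deflating the predictor matrix only. Predictors are mean-centered (and
#' optionally autoscaled); the response is mean-centered. For determinism
#' across platforms, each weight vector is sign-fixed so its
#' largest-magnitude element is positive. Extraction stops early (with a
#' warning) if the deflated predictors carry no remaining covariance.
#'
#' @param X Numeric matrix, samples x predictors (e.g. wavelengths), or a
#'   [spectra] object (samples taken from columns).
#' @param y Numeric response vector, one value per sample.
#' @param ncomp Number of latent vectors; must satisfy
#'   `1 <= ncomp <= min(nrow(X) - 1, ncol(X))`.
#' @param scale Autoscale predictors to unit variance? Default `FALSE`
#'   (centering only).
#' @return Object of class `plsr_model`: weights `W` (unit columns),
#'   predictor loadings `P`, response loadings `q`, scores `scores`,
#'   coefficient vector `coefficients` (per predictor, on the centered/
#'   scaled scale), per-component explained response sum of squares `SSY`,
#'   centering/scaling vectors, and the training column names.
#' @export
fit_plsr <- function(X, y, ncomp, scale = FALSE) {
  X <- as_predictor_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("`y` must have one value per row of X", call. = FALSE)
  if (ncomp < 1L) stop("`ncomp` must be at least 1", call. = FALSE)
  if (ncomp > min(n - 1L, p)) {
    stop("`ncomp` may not exceed min(n - 1, p)", call. = FALSE)
  }
  if (var(y) == 0) stop("response has zero variance", call. = FALSE)
  xmean <- colMeans(X)
  xscale <- if (scale) {
    s <- apply(X, 2L, sd)
    s[s == 0] <- 1
    s
  } else rep(1, p)
  ymean <- mean(y)
  Xd <- sweep(sweep(X, 2L, xmean), 2L, xscale, "/")
  Xc <- Xd  # retained (undeflated) centered predictors
  yc <- y - ymean
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yc)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning(sprintf("no covariance left after %d component(s); ncomp reduced",
                      a - 1L))
      break
    }
    w <- w / nw
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w
    tt <- Xd %*% w
    t2 <- sum(tt^2)
    if (t2 < 1e-12) {
      warning(sprintf("degenerate score at component %d; ncomp reduced", a))
      break
    }
    pa <- crossprod(Xd, tt)[, 1L] / t2
    qa <- sum(yc * tt) / t2
    Xd <- Xd - tcrossprod(tt, pa)
    W[, a] <- w; P[, a] <- pa; q[a] <- qa; Tm[, a] <- tt
    ssy[a] <- qa^2 * t2
    a_done <- a
  }
  if (a_done == 0L) stop("no PLS component could be extracted", call. = FALSE)
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  q <- q[seq_len(a_done)]
  Tm <- Tm[, seq_len(a_done), drop = FALSE]
  ssy <- ssy[seq_len(a_done)]
  b <- W %*% solve(crossprod(P, W), q)
  structure(list(
    W = W, P = P, q = q, scores = Tm, SSY = ssy,
    coefficients = b[, 1L], ncomp = a_done,
    xmean = xmean, xscale = xscale, ymean = ymean,
    ysd = sd(y), xsd = apply(Xc, 2L, sd) * xscale,
    scaled = scale, predictors = colnames(X)
  ), class = "plsr_model")
}

as_predictor_matrix <- function(X) {
  if (inherits(X, "spectra")) {
    M <- t(X$values)
    colnames(M) <- as.character(X$wavelength)
    return(M)
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent vector(s), %d predictors%s\n",
              x$ncomp, length(x$coefficients),
              if (x$scaled) ", autoscaled" else ", centered"))
  invisible(x)
}

#' Predict wax amounts from a fitted PLSR model
#'
#' Applies the centered-and-scaled linear map plus the response mean. New
#' predictors must be on the training wavelength grid.
#'
#' @param object A `plsr_model`.
#' @param newdata Matrix (samples x predictors) or [spectra] object on the
#'   training grid.
#' @param ncomp Number of components to use (<= fitted); default all.
#' @param truncate Truncate negative predictions to zero? Default `FALSE`.
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ncomp = object$ncomp,
                               truncate = FALSE, ...) {
  M <- as_predictor_matrix(newdata)
  if (ncol(M) != length(object$coefficients) ||
      (!is.null(object$predictors) && !is.null(colnames(M)) &&
       !identical(colnames(M), object$predictors))) {
    stop("new data grid does not match the training grid", call. = FALSE)
  }
  if (ncomp < 1L || ncomp > object$ncomp) {
    stop("`ncomp` outside the fitted range", call. = FALSE)
  }
  b <- if (ncomp == object$ncomp) {
    object$coefficients
  } else {
    W <- object$W[, seq_len(ncomp), drop = FALSE]
    P <- object$P[, seq_len(ncomp), drop = FALSE]
    (W %*% solve(crossprod(P, W), object$q[seq_len(ncomp)]))[, 1L]
  }
  Md <- sweep(sweep(M, 2L, object$xmean), 2L, object$xscale, "/")
  out <- drop(Md %*% b) + object$ymean
  if (truncate) out <- pmax(out, 0)
  unname(out)
}

#' Variable importance in projection (VIP) scores
#'
#' Wold's VIP: `VIP_j = sqrt(p * sum_a SSY_a * w_ja^2 / sum_a SSY_a)` with
#' unit-norm weight vectors over `p` predictors, so the squared scores
#' average to exactly 1. Wavelengths with VIP > 1 are flagged as the most
#' important contributors to the model.
#'
#' @param model A `plsr_model`.
#' @return Data frame with columns `predictor`, `wavelength` (NA when the
#'   predictors are not wavelengths), `vip`, `important` (VIP > 1).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  if (sum(model$SSY) <= 0) stop("zero explained response variance", call. = FALSE)
  wgt <- model$SSY / sum(model$SSY)
  p <- nrow(model$W)
  v <- sqrt(p * as.vector(model$W^2 %*% wgt))
  wl <- suppressWarnings(as.numeric(model$predictors))
  data.frame(predictor = model$predictors, wavelength = wl, vip = v,
             important = v > 1, stringsAsFactors = FALSE)
}

#' Standardized PLSR coefficients
#'
#' Coefficients rescaled to `b_j * sd(X_j) / sd(y)` using training-set
#' standard deviations, making magnitudes comparable across spectral
#' regions with different reflectance scales. Invariant to per-predictor
#' affine rescaling of the input units.
#'
#' @param model A `plsr_model`.
#' @return Data frame with columns `predictor`, `wavelength`,
#'   `coefficient` (raw, original units), `standardized`.
#' @export
standardized_coefficients <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  if (model$ysd == 0) stop("zero-variance response", call. = FALSE)
  b_raw <- model$coefficients / model$xscale
  std <- b_raw * model$xsd / model$ysd
  wl <- suppressWarnings(as.numeric(model$predictors))
  data.frame(predictor = model$predictors, wavelength = wl,
             coefficient = b_raw, standardized = std,
             stringsAsFactors = FALSE)
}

#' Serialize a PLSR model to JSON
#'
#' Writes all model vectors (weights, loadings, coefficients, centering and
#' scaling) to a documented JSON file that [read_plsr_model()] restores.
#'
#' @param model A `plsr_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plsr_model <- function(model, path) {
  stopifnot(inherits(model, "plsr_model"))
  obj <- unclass(model)
  obj$W <- unname(as.matrix(obj$W)); obj$P <- unname(as.matrix(obj$P))
  obj$scores <- unname(as.matrix(obj$scores))
  obj$xmean <- unname(obj$xmean); obj$xsd <- unname(obj$xsd)
  obj$xscale <- unname(obj$xscale); obj$coefficients <- unname(obj$coefficients)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a PLSR model written by [write_plsr_model()]
#' @param path Path to the JSON file.
#' @return A `plsr_model`.
#' @export
read_plsr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("W", "P", "scores")) obj[[nm]] <- as.matrix(obj[[nm]])
  structure(obj, class = "plsr_model")
}
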