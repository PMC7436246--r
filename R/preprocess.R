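#' Resample spectra onto the 5 nm analysis grid
#'
#' Linear interpolation of each spectrum onto 350, 355, ..., 2500 nm, the
#' resolution at which the prediction models operate. Input wavelengths must
#' cover the full grid (no extrapolation) with no internal gap wider than
#' `max_gap`.
#'
#' @param x A [spectra] object covering at least 350--2500 nm.
#' @param max_gap Largest tolerated spacing (nm) between consecutive input
#'   wavelengths; default 25.
#' @return A [spectra] object on the grid of [analysis_grid()].
#' @export
resample_5nm <- function(x, max_gap = 25) {
  stopifnot(inherits(x, "spectra"))
  grid <- analysis_grid()
  if (min(x$wavelength) > grid[1L] || max(x$wavelength) < grid[length(grid)]) {
    stop("input spectra must cover 350-2500 nm", call. = FALSE)
  }
  if (length(x$wavelength) >= 2L && max(diff(x$wavelength)) > max_gap) {
    stop(sprintf("input grid has a coverage gap wider than %g nm", max_gap),
         call. = FALSE)
  }
  vals <- apply(x$values, 2L, function(v) {
    approx(x$wavelength, v, xout = grid, method = "linear")$y
  })
  vals <- matrix(vals, nrow = length(grid),
                 dimnames = list(NULL, colnames(x$values)))
  spectra(grid, vals, kind = x$kind, meta = x$meta)
}

#' Average replicate spectra within groups
#'
#' Point-wise arithmetic mean of all spectra sharing a value of the grouping
#' key (e.g. the four consecutive readings of one leaf). The result has one
#' spectrum per group; its metadata records the member count in `n_averaged`.
#'
#' @param x A [spectra] object.
#' @param group_key Name of a metadata column, or a vector with one group
#'   label per sample.
#' @return A [spectra] object with one sample per group, ordered by first
#'   appearance of the group.
#' @export
average_replicates <- function(x, group_key) {
  stopifnot(inherits(x, "spectra"))
  if (is.character(group_key) && length(group_key) == 1L) {
    if (!group_key %in% names(x$meta)) {
      stop(sprintf("metadata column '%s' not found", group_key), call. = FALSE)
    }
    g <- as.character(x$meta[[group_key]])
  } else {
    if (length(group_key) != ncol(x$values)) {
      stop("`group_key` must have one entry per sample", call. = FALSE)
    }
    g <- as.character(group_key)
  }
  if (anyNA(g)) stop("grouping key contains NA", call. = FALSE)
  groups <- unique(g)
  vals <- vapply(groups, function(gg) {
    rowMeans(x$values[, g == gg, drop = FALSE])
  }, numeric(length(x$wavelength)))
  vals <- matrix(vals, nrow = length(x$wavelength),
                 dimnames = list(NULL, groups))
  meta <- data.frame(sample_id = groups,
                     n_averaged = as.integer(table(g)[groups]),
                     stringsAsFactors = FALSE)
  spectra(x$wavelength, vals, kind = x$kind, meta = meta)
}

#' First derivative of reflectance spectra
#'
#' Derivative of reflectance with respect to wavelength (per nm).
#' `method = "sg"` (default) uses a Savitzky-Golay smoothing derivative,
#' standard chemometric practice for noisy reflectance; `method = "diff"`
#' uses plain central differences (one-sided at the ends). Savitzky-Golay
#' edge points are handled with the filter's off-center polynomial fits.
#'
#' @param x A [spectra] object of kind `"reflectance"` on a uniform grid.
#' @param method `"sg"` or `"diff"`.
#' @param window Savitzky-Golay window length in points (odd); default 11
#'   points, i.e. 50 nm on the 5 nm grid.
#' @param polyorder Savitzky-Golay polynomial order; default 2. Must satisfy
#'   `window >= polyorder + 1`.
#' @return A [spectra] object of kind `"first_derivative"` on the same grid.
#' @export
first_derivative <- function(x, method = c("sg", "diff"), window = 11L,
                             polyorder = 2L) {
  stopifnot(inherits(x, "spectra"))
  method <- match.arg(method)
  if (x$kind != "reflectance") {
    stop("`first_derivative()` expects reflectance-kind spectra", call. = FALSE)
  }
  wl <- x$wavelength
  h <- diff(wl)
  if (length(h) < 2L) stop("spectrum too short to differentiate", call. = FALSE)
  if (method == "sg") {
    if (max(abs(h - h[1L])) > 1e-8) {
      stop("Savitzky-Golay differentiation requires a uniform grid", call. = FALSE)
    }
    window <- as.integer(window)
    polyorder <- as.integer(polyorder)
    if (window %% 2L == 0L || window < polyorder + 1L) {
      stop("`window` must be odd and >= polyorder + 1", call. = FALSE)
    }
    if (window > length(wl)) {
      stop("`window` exceeds the spectrum length", call. = FALSE)
    }
    vals <- apply(x$values, 2L, function(v) {
      signal::sgolayfilt(v, p = polyorder, n = window, m = 1L, ts = h[1L])
    })
  } else {
    vals <- apply(x$values, 2L, function(v) {
      n <- length(v)
      d <- numeric(n)
      d[1L] <- (v[2L] - v[1L]) / h[1L]
      d[n] <- (v[n] - v[n - 1L]) / h[n - 1L]
      idx <- 2L:(n - 1L)
      d[idx] <- (v[idx + 1L] - v[idx - 1L]) / (wl[idx + 1L] - wl[idx - 1L])
      d
    })
  }
  vals <- matrix(vals, nrow = length(wl),
                 dimnames = list(NULL, colnames(x$values)))
  meta <- x$meta
  meta$derivative_method <- method
  spectra(wl, vals, kind = "first_derivative", meta = meta)
}

#' Quality-control filter for reflectance spectra
#'
#' Flags spectra with measurement abnormalities, emulating the visual
#' screening of raw field spectra: any non-finite value
#' (`non_finite`), any reflectance below `min_value` (`negative_reflectance`),
#' any reflectance above `max_value` (`out_of_range`), or mean near-infrared
#' reflectance over `nir_range` below `min_nir` (`low_reflectance`, a dark or
#' badly aimed reading). Thresholds are configurable; the defaults are
#' deliberately permissive so healthy leaf spectra always pass.
#'
#' @param x A [spectra] object of kind `"reflectance"`.
#' @param min_value Lower tolerated reflectance; default -0.01.
#' @param max_value Upper tolerated reflectance; default 1.5.
#' @param nir_range Wavelength window (nm) used for the low-reflectance rule;
#'   default `c(760, 900)`.
#' @param min_nir Minimum mean reflectance over `nir_range`; default 0.10.
#' @return A list with `kept` (a [spectra] object, possibly with zero
#'   samples) and `report`, a data frame with columns `sample_id`, `kept`,
#'   `reason` (NA when kept).
#' @export
qc_filter <- function(x, min_value = -0.01, max_value = 1.5,
                      nir_range = c(760, 900), min_nir = 0.10) {
  stopifnot(inherits(x, "spectra"))
  if (x$kind != "reflectance") {
    stop("`qc_filter()` expects reflectance-kind spectra", call. = FALSE)
  }
  in_nir <- x$wavelength >= nir_range[1L] & x$wavelength <= nir_range[2L]
  reason <- vapply(seq_len(ncol(x$values)), function(j) {
    v <- x$values[, j]
    if (any(!is.finite(v))) return("non_finite")
    if (any(v < min_value)) return("negative_reflectance")
    if (any(v > max_value)) return("out_of_range")
    if (any(in_nir) && mean(v[in_nir]) < min_nir) return("low_reflectance")
    NA_character_
  }, character(1L))
  keep <- is.na(reason)
  report <- data.frame(sample_id = colnames(x$values), kept = keep,
                       reason = reason, stringsAsFactors = FALSE)
  kept <- if (any(keep)) x[keep] else NULL
  list(kept = kept, report = report)
}
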