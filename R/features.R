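#' Detect features in a first-derivative spectrum
#'
#' Finds local extrema of both signs (positive maxima and negative minima)
#' whose absolute derivative value reaches `min_prominence`, then enforces a
#' minimum wavelength separation by keeping the strongest extrema first.
#'
#' @param x A single-sample [spectra] object of kind `"first_derivative"`.
#' @param min_prominence Minimum |derivative| for a feature; default 10% of
#'   the spectrum's maximum |derivative|.
#' @param min_separation Minimum wavelength spacing (nm) between reported
#'   features; default 10.
#' @return Data frame of class `feature_set` with attributes `wax_id`;
#'   columns `wavelength`, `value` (signed derivative), `prominence`
#'   (absolute value), sorted by wavelength.
#' @export
detect_features <- function(x, min_prominence = NULL, min_separation = 10) {
  stopifnot(inherits(x, "spectra"))
  if (x$kind != "first_derivative") {
    stop("`detect_features()` expects a first-derivative spectrum", call. = FALSE)
  }
  if (ncol(x$values) != 1L) {
    stop("supply one spectrum at a time", call. = FALSE)
  }
  wl <- x$wavelength
  v <- x$values[, 1L]
  if (is.null(min_prominence)) min_prominence <- 0.10 * max(abs(v))
  n <- length(v)
  is_ext <- logical(n)
  if (n >= 3L) {
    i <- 2L:(n - 1L)
    is_ext[i] <- (v[i] > 0 & v[i] >= v[i - 1L] & v[i] >= v[i + 1L]) |
      (v[i] < 0 & v[i] <= v[i - 1L] & v[i] <= v[i + 1L])
  }
  cand <- which(is_ext & abs(v) >= min_prominence)
  keep <- integer(0)
  for (i in cand[order(-abs(v[cand]))]) {
    if (!length(keep) || all(abs(wl[i] - wl[keep]) >= min_separation)) {
      keep <- c(keep, i)
    }
  }
  keep <- sort(keep)
  out <- data.frame(wavelength = wl[keep], value = v[keep],
                    prominence = abs(v[keep]))
  wax <- if ("wax" %in% names(x$meta)) x$meta$wax[1L] else x$meta$sample_id[1L]
  attr(out, "wax_id") <- wax
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Classify features as unique or shared across waxes
#'
#' Pools the detected feature wavelengths of several waxes and clusters them
#' by single linkage: consecutive wavelengths (in sorted order) closer than
#' `match_tolerance_nm` join one cluster. Each cluster is classified by its
#' member waxes: `unique` (one wax), `all_shared` (every input wax), or
#' `pairwise_shared` otherwise. A `unique` cluster is a single spectral
#' variation (SSV): a presence/absence fingerprint for that wax.
#'
#' @param feature_sets Named list (>= 2) of [detect_features()] outputs, or
#'   of data frames with a `wavelength` column; names are the wax ids.
#' @param match_tolerance_nm Positive linkage tolerance in nm; default 10.
#' @return Data frame of class `ssv_table` with columns `center` (mean
#'   member wavelength), `n_waxes`, `waxes` (comma-separated), `class`.
#' @export
classify_unique_shared <- function(feature_sets, match_tolerance_nm = 10) {
  if (length(feature_sets) < 2L) {
    stop("need at least two feature sets", call. = FALSE)
  }
  if (match_tolerance_nm <= 0) {
    stop("`match_tolerance_nm` must be positive", call. = FALSE)
  }
  if (is.null(names(feature_sets))) {
    names(feature_sets) <- vapply(feature_sets, function(f) {
      attr(f, "wax_id") %||% stop("unnamed feature set without wax_id",
                                  call. = FALSE)
    }, character(1L))
  }
  pool <- do.call(rbind, lapply(names(feature_sets), function(w) {
    data.frame(wax = w, wavelength = feature_sets[[w]]$wavelength,
               stringsAsFactors = FALSE)
  }))
  if (!nrow(pool)) {
    out <- data.frame(center = numeric(0), n_waxes = integer(0),
                      waxes = character(0), class = character(0))
    class(out) <- c("ssv_table", "data.frame")
    return(out)
  }
  pool <- pool[order(pool$wavelength), ]
  gap <- c(Inf, diff(pool$wavelength))
  cluster <- cumsum(gap > match_tolerance_nm)
  n_total <- length(feature_sets)
  rows <- lapply(split(pool, cluster), function(d) {
    waxes <- sort(unique(d$wax))
    data.frame(
      center = mean(d$wavelength),
      n_waxes = length(waxes),
      waxes = paste(waxes, collapse = ","),
      class = if (length(waxes) == 1L) "unique"
              else if (length(waxes) == n_total) "all_shared"
              else "pairwise_shared",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$center), ]
  rownames(out) <- NULL
  class(out) <- c("ssv_table", "data.frame")
  out
}
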