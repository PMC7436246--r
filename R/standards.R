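#' Default first-derivative feature tables for the three wax standards
#'
#' Wavelength positions of the absorption/reflectance features seen in
#' first-derivative spectra of pure hentriacontanone-16 (`H16`),
#' octacosanol-1 (`Oct`), and triacontanol-1 (`Tri`). Each wax carries one
#' unique fingerprint wavelength (H16: 2259 nm, Oct: 645 nm, Tri: 730 nm);
#' the 1714-1757 and 2302-2348 nm bands are common to all three waxes, and
#' 915, 1500, 1890, and 2175 nm are shared by the two fatty alcohols only.
#'
#' Feature shape parameters (Gaussian amplitude and width in
#' first-derivative units and nm) are not physically constrained; the
#' defaults use width 10 nm, amplitude 1.0 for the unique fingerprints and
#' 0.6 for shared features, with signs alternating along the wavelength
#' axis as in derivative spectra.
#'
#' @return Named list of data frames (one per wax) with columns `center`,
#'   `amplitude`, `width`, `unique_to_wax`.
#' @export
wax_feature_tables <- function() {
  h16 <- c(365, 437, 1233, 1372, 1440, 1610, 1714, 1757, 1850, 2031, 2082,
           2222, 2259, 2302, 2348, 2445, 2499)
  oct <- c(365, 437, 645, 915, 1233, 1372, 1440, 1500, 1610, 1714, 1757,
           1850, 1890, 2082, 2175, 2222, 2302, 2348, 2445, 2499)
  tri <- c(365, 730, 915, 1233, 1372, 1440, 1500, 1610, 1714, 1757, 1850,
           1890, 2031, 2175, 2302, 2348, 2445)
  uniq <- c(H16 = 2259, Oct = 645, Tri = 730)
  build <- function(centers, wax) {
    centers <- sort(centers)
    is_unique <- centers == uniq[[wax]]
    data.frame(
      center = centers,
      amplitude = ifelse(is_unique, 1.0, 0.6) *
        rep_len(c(1, -1), length(centers)),
      width = 10,
      unique_to_wax = is_unique
    )
  }
  list(H16 = build(h16, "H16"), Oct = build(oct, "Oct"), Tri = build(tri, "Tri"))
}

#' Unique fingerprint wavelengths of the three waxes
#' @return Named numeric vector (nm).
#' @export
unique_wavelengths <- function() c(H16 = 2259, Oct = 645, Tri = 730)

validate_feature_table <- function(ft, wax_id) {
  ft <- as.data.frame(ft)
  need <- c("center", "amplitude", "width")
  if (!all(need %in% names(ft))) {
    stop("feature table needs columns center, amplitude, width", call. = FALSE)
  }
  if (nrow(ft) > 0L) {
    if (any(ft$center < 350 | ft$center > 2500)) {
      stop("feature centers must lie within 350-2500 nm", call. = FALSE)
    }
    if (any(ft$width <= 0)) stop("feature widths must be positive", call. = FALSE)
  }
  uniq <- unique_wavelengths()
  others <- uniq[setdiff(names(uniq), wax_id)]
  if (any(ft$center %in% others)) {
    stop(sprintf("feature table for %s contains another wax's unique wavelength",
                 wax_id), call. = FALSE)
  }
  ft
}

#' Build a pure-standard first-derivative signature
#'
#' Evaluates the sum of Gaussian-shaped first-derivative features of one wax
#' standard on a wavelength grid. Deterministic; the default tables
#' reproduce the unique/shared structure of the three wax standards.
#'
#' @param wax_id One of `"H16"`, `"Oct"`, `"Tri"` (used for labelling and
#'   for the unique-wavelength invariant check).
#' @param feature_table Data frame with columns `center` (nm), `amplitude`
#'   (signed first-derivative units), `width` (Gaussian sd, nm); defaults to
#'   the packaged table for `wax_id`.
#' @param grid Wavelength grid (nm), monotone increasing within 350--2500;
#'   default [analysis_grid()].
#' @return A single-sample [spectra] object of kind `"first_derivative"`.
#' @export
build_standard_signature <- function(wax_id, feature_table = NULL,
                                     grid = analysis_grid()) {
  if (!wax_id %in% c("H16", "Oct", "Tri")) {
    stop(sprintf("unknown wax id '%s'", wax_id), call. = FALSE)
  }
  if (is.null(feature_table)) feature_table <- wax_feature_tables()[[wax_id]]
  feature_table <- validate_feature_table(feature_table, wax_id)
  grid <- as.numeric(grid)
  if (length(grid) >= 2L && any(diff(grid) <= 0)) {
    stop("`grid` must be monotone increasing", call. = FALSE)
  }
  if (any(grid < 350 | grid > 2500)) {
    stop("`grid` must lie within 350-2500 nm", call. = FALSE)
  }
  if (nrow(feature_table) > 0L &&
      (any(feature_table$center < min(grid)) ||
       any(feature_table$center > max(grid)))) {
    stop("feature centers fall outside the grid coverage", call. = FALSE)
  }
  v <- numeric(length(grid))
  for (k in seq_len(nrow(feature_table))) {
    v <- v + feature_table$amplitude[k] *
      exp(-(grid - feature_table$center[k])^2 / (2 * feature_table$width[k]^2))
  }
  vals <- matrix(v, ncol = 1L, dimnames = list(NULL, wax_id))
  spectra(grid, vals, kind = "first_derivative",
          meta = data.frame(sample_id = wax_id, wax = wax_id,
                            stringsAsFactors = FALSE))
}

# Cumulative (trapezoid) integral of a first-derivative signature over its
# grid: the reflectance-scale form a leaf spectrum carries, so that
# differentiating the leaf spectrum recovers the signature at zero noise.
integrate_signature <- function(sig) {
  stopifnot(inherits(sig, "spectra"))
  wl <- sig$wavelength
  v <- sig$values[, 1L]
  c(0, cumsum(diff(wl) * (head(v, -1L) + tail(v, -1L)) / 2))
}
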