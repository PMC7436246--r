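#' Spectra collection
#'
#' A `spectra` object holds one or more spectra measured on a shared
#' wavelength grid: a strictly increasing wavelength vector (nm), a values
#' matrix with one row per wavelength and one column per sample, a kind flag
#' (`"reflectance"` or `"first_derivative"`), and a metadata data frame with
#' one row per sample (`sample_id` plus free columns such as `accession`,
#' `leaf`, `replicate`).
#'
#' Reflectance values are relative to a white reference and are unitless;
#' first-derivative values are per-nm.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param values Numeric matrix (`length(wavelength)` rows) or vector for a
#'   single spectrum. Column names, if present, become sample ids.
#' @param kind `"reflectance"` or `"first_derivative"`.
#' @param meta Optional data frame of per-sample metadata with a `sample_id`
#'   column; created from column names when omitted.
#' @return An object of class `spectra`.
#' @examples
#' s <- spectra(seq(350, 2500, by = 5),
#'              matrix(0.3, 431, 2, dimnames = list(NULL, c("a", "b"))))
#' s
#' @export
spectra <- function(wavelength, values, kind = c("reflectance", "first_derivative"),
                    meta = NULL) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  if (length(wavelength) != nrow(values)) {
    stop("`values` must have one row per wavelength", call. = FALSE)
  }
  if (length(wavelength) >= 2L && any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  if (is.null(meta)) {
    meta <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta)
    if (!"sample_id" %in% names(meta)) {
      stop("`meta` must contain a `sample_id` column", call. = FALSE)
    }
    if (nrow(meta) != ncol(values) ||
        !identical(as.character(meta$sample_id), colnames(values))) {
      stop("`meta$sample_id` must match the value columns in order", call. = FALSE)
    }
  }
  if (kind == "reflectance" && any(!is.finite(values))) {
    stop("reflectance values must be finite", call. = FALSE)
  }
  structure(list(wavelength = wavelength, values = values, kind = kind,
                 meta = meta),
            class = "spectra")
}

#' @export
print.spectra <- function(x, ...) {
  cat(sprintf("<spectra> %d sample(s) x %d wavelengths [%g-%g nm], kind = %s\n",
              ncol(x$values), length(x$wavelength),
              min(x$wavelength), max(x$wavelength), x$kind))
  extra <- setdiff(names(x$meta), "sample_id")
  if (length(extra)) cat("metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Subset samples of a spectra object
#'
#' @param x A `spectra` object.
#' @param i Sample index, logical mask, or sample ids.
#' @param ... Ignored.
#' @return A `spectra` object with the selected samples.
#' @export
`[.spectra` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, colnames(x$values))
  if (anyNA(i)) stop("unknown sample id(s)", call. = FALSE)
  spectra(x$wavelength, x$values[, i, drop = FALSE], kind = x$kind,
          meta = x$meta[seq_len(ncol(x$values))[i], , drop = FALSE])
}

#' Number of samples in a spectra object
#' @param x A `spectra` object.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "spectra"))
  ncol(x$values)
}

#' Sample ids of a spectra object
#' @param x A `spectra` object.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "spectra"))
  colnames(x$values)
}

#' Combine spectra objects sharing a grid
#' @param ... `spectra` objects on identical grids and of identical kind.
#' @return A single `spectra` object.
#' @export
cbind_spectra <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "spectra")))
  wl <- xs[[1L]]$wavelength
  kind <- xs[[1L]]$kind
  for (x in xs[-1L]) {
    if (!isTRUE(all.equal(x$wavelength, wl)) || !identical(x$kind, kind)) {
      stop("all spectra must share one grid and kind", call. = FALSE)
    }
  }
  vals <- do.call(cbind, lapply(xs, function(x) x$values))
  metas <- lapply(xs, function(x) x$meta)
  cols <- Reduce(union, lapply(metas, names))
  metas <- lapply(metas, function(m) {
    for (cc in setdiff(cols, names(m))) m[[cc]] <- NA
    m[cols]
  })
  spectra(wl, vals, kind = kind, meta = do.call(rbind, metas))
}

#' Spectra as a long data frame
#' @param x A `spectra` object.
#' @param ... Ignored.
#' @return Data frame with columns `sample_id`, `wavelength_nm`, `value`.
#' @export
as.data.frame.spectra <- function(x, ...) {
  data.frame(
    sample_id = rep(colnames(x$values), each = length(x$wavelength)),
    wavelength_nm = rep(x$wavelength, ncol(x$values)),
    value = as.vector(x$values),
    stringsAsFactors = FALSE
  )
}

#' The 5 nm analysis grid (350, 355, ..., 2500 nm)
#' @return Numeric vector of 431 wavelengths.
#' @export
analysis_grid <- function() seq(350, 2500, by = 5)
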