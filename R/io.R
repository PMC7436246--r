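#' Read spectra from a wide CSV file
#'
#' The on-disk format is a wide CSV whose first column is `wavelength_nm`
#' and whose remaining columns are samples (one spectrum per column).
#'
#' @param path Path to a CSV file.
#' @param kind Value kind stored in the file, `"reflectance"` (default) or
#'   `"first_derivative"`.
#' @return A [spectra] object.
#' @export
read_spectra <- function(path, kind = c("reflectance", "first_derivative")) {
  kind <- match.arg(kind)
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 1L || names(df)[1L] != "wavelength_nm") {
    stop(sprintf("'%s': first column must be `wavelength_nm`", path), call. = FALSE)
  }
  if (ncol(df) < 2L) {
    stop(sprintf("'%s': no sample columns found", path), call. = FALSE)
  }
  wl <- as.numeric(df[[1L]])
  if (anyNA(wl)) stop(sprintf("'%s': unparsable wavelengths", path), call. = FALSE)
  if (anyDuplicated(wl)) {
    stop(sprintf("'%s': duplicated wavelength rows", path), call. = FALSE)
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    stop(sprintf("'%s': wavelengths not strictly increasing", path), call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop(sprintf("'%s': non-numeric values", path), call. = FALSE)
  spectra(wl, vals, kind = kind)
}

#' Write spectra to a wide CSV file
#'
#' @param x A [spectra] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectra"))
  df <- data.frame(wavelength_nm = x$wavelength, check.names = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a genetic map from CSV
#'
#' Columns `marker,chr,pos_cM`; positions must be non-decreasing within a
#' chromosome and marker names unique.
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns `marker`, `chr`, `pos_cM`.
#' @export
read_genetic_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "chr", "pos_cM")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s': map CSV needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  validate_map(df[need])
}

#' Write a genetic map to CSV
#' @param map Map data frame (`marker`, `chr`, `pos_cM`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  write.csv(validate_map(map), path, row.names = FALSE)
  invisible(path)
}

validate_map <- function(map) {
  map <- as.data.frame(map)
  map$chr <- as.character(map$chr)
  if (anyDuplicated(map$marker)) stop("duplicate marker names", call. = FALSE)
  for (ch in unique(map$chr)) {
    p <- map$pos_cM[map$chr == ch]
    if (is.unsorted(p)) {
      stop(sprintf("positions not non-decreasing on chromosome %s", ch),
           call. = FALSE)
    }
  }
  map
}

#' Read an F2 genotype matrix from CSV
#'
#' Rows are individuals (first column `individual`), remaining columns are
#' markers with codes `AA`, `AB`, `BB` or empty/NA for missing. `A` denotes
#' the glossy-parent allele and `B` the waxy-parent allele.
#'
#' @param path Path to a CSV file.
#' @return Character matrix individuals x markers (NA for missing).
#' @export
read_genotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "individual") {
    stop(sprintf("'%s': first column must be `individual`", path), call. = FALSE)
  }
  g <- as.matrix(df[, -1L, drop = FALSE])
  rownames(g) <- as.character(df$individual)
  g[g == ""] <- NA_character_
  bad <- !is.na(g) & !g %in% c("AA", "AB", "BB")
  if (any(bad)) {
    stop(sprintf("'%s': invalid genotype codes: %s", path,
                 paste(unique(g[bad]), collapse = ", ")), call. = FALSE)
  }
  g
}

#' Write an F2 genotype matrix to CSV
#' @param geno Character matrix individuals x markers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(individual = rownames(geno) %||% seq_len(nrow(geno)),
                   geno, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a phenotype table from CSV
#' @param path CSV with `sample_id` plus one numeric column per trait.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop(sprintf("'%s': phenotype CSV needs a `sample_id` column", path),
         call. = FALSE)
  }
  df
}

#' Write a phenotype table to CSV
#' @param phen Data frame with `sample_id` plus trait columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  write.csv(phen, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
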