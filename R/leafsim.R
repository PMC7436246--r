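#' Parametric green-leaf baseline reflectance
#'
#' A smooth template of a healthy green leaf: low visible reflectance with
#' chlorophyll absorptions near 450 and 680 nm and a green bump near 550 nm,
#' a logistic red edge around 700-750 nm, a near-infrared plateau, and water
#' absorptions near 1450 and 1940 nm with a declining shortwave-infrared
#' tail. Values are clipped to [0.01, 1]. This is a plumbing template for
#' the simulator, not a radiative-transfer model.
#'
#' @param grid Wavelength grid (nm); default [analysis_grid()].
#' @return A single-sample [spectra] object of kind `"reflectance"`.
#' @export
leaf_baseline <- function(grid = analysis_grid()) {
  grid <- as.numeric(grid)
  vis <- 0.08 +
    0.05 * exp(-(grid - 550)^2 / (2 * 30^2)) -
    0.035 * exp(-(grid - 450)^2 / (2 * 25^2)) -
    0.045 * exp(-(grid - 680)^2 / (2 * 20^2))
  red_edge <- 1 / (1 + exp(-(grid - 715) / 15))
  nir <- 0.50 - 0.10 * pmax(grid - 1000, 0) / 1500
  r <- vis * (1 - red_edge) + nir * red_edge
  water <- 1 -
    0.45 * exp(-(grid - 1450)^2 / (2 * 50^2)) -
    0.60 * exp(-(grid - 1940)^2 / (2 * 60^2)) -
    0.30 * exp(-(grid - 2500)^2 / (2 * 150^2))
  r <- pmin(pmax(r * water, 0.01), 1)
  spectra(grid, matrix(r, ncol = 1L, dimnames = list(NULL, "baseline")),
          kind = "reflectance")
}

#' Simulate a leaf reflectance spectrum from wax amounts
#'
#' Builds `baseline + sum_w amount_w * coupling_w * S_w + noise`, where
#' `S_w` is the cumulative-integral (reflectance-scale) form of wax `w`'s
#' first-derivative standard signature, so the wax contribution is strictly
#' linear in the amount and differentiating the leaf spectrum recovers the
#' feature signature at zero noise. Noise is i.i.d. Gaussian per wavelength;
#' the result is clipped to [0, 1].
#'
#' The coupling between adjusted-peak-area units and reflectance magnitude
#' is a free simulator parameter (default 0.002 per unit amount).
#'
#' @param amounts Named non-negative vector of wax amounts (adjusted peak
#'   areas); names must be a subset of `names(feature_tables)`.
#' @param baseline Baseline [spectra] (single sample, reflectance kind);
#'   default [leaf_baseline()].
#' @param feature_tables Feature tables as from [wax_feature_tables()].
#' @param coupling Named coupling coefficients per wax, or a single number
#'   recycled; default 0.002.
#' @param noise_sd Gaussian noise standard deviation (reflectance units);
#'   default 0.
#' @param seed Optional integer seed; equal seeds give identical spectra.
#' @param sample_id Sample id for the output column.
#' @return A single-sample [spectra] object of kind `"reflectance"`.
#' @export
simulate_leaf_spectrum <- function(amounts, baseline = leaf_baseline(),
                                   feature_tables = wax_feature_tables(),
                                   coupling = 0.002, noise_sd = 0,
                                   seed = NULL, sample_id = "leaf") {
  stopifnot(inherits(baseline, "spectra"), baseline$kind == "reflectance")
  if (is.null(names(amounts)) || !all(names(amounts) %in% names(feature_tables))) {
    stop("`amounts` must be named after waxes with feature tables", call. = FALSE)
  }
  if (any(amounts < 0)) stop("wax amounts must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (is.null(names(coupling))) {
    coupling <- setNames(rep_len(coupling, length(amounts)), names(amounts))
  }
  grid <- baseline$wavelength
  r <- baseline$values[, 1L]
  for (w in names(amounts)) {
    if (amounts[[w]] == 0) next
    sig <- build_standard_signature(w, feature_tables[[w]], grid = grid)
    r <- r + amounts[[w]] * coupling[[w]] * integrate_signature(sig)
  }
  if (noise_sd > 0) {
    r <- with_seed(seed, r + rnorm(length(r), sd = noise_sd))
  }
  r <- pmin(pmax(r, 0), 1)
  spectra(grid, matrix(r, ncol = 1L, dimnames = list(NULL, sample_id)),
          kind = "reflectance")
}

#' Accession presets for the wax panel
#'
#' Mean adjusted peak areas and standard errors of the eight leaf waxes for
#' the seven onion accessions (glossy `GL`, semi-glossy `SG`, waxy `WX`).
#' H16, Oct, and Tri means/SEs are the published GCMS values; the five minor
#' waxes (Met, Hex, Octd, Hepc, Hepd) are completed from each accession's
#' published wax-percentage profile scaled to the same total, with SEs set
#' by the median relative SE of the three major waxes (floored at 0.005).
#' Each preset's eight-wax proportions reproduce its published percentage
#' row to within rounding.
#'
#' @return Named list of presets, each a list with `accession_id`,
#'   `phenotype_class`, and data frame `waxes` (`wax`, `mean`, `se`).
#' @export
accession_presets <- function() {
  major <- data.frame(
    accession = c("OGL", "546115", "546192", "B5351", "B9885", "264320", "DH2107"),
    class = c("GL", "SG", "SG", "SG", "GL", "SG", "WX"),
    H16 = c(0.002, 0.532, 0.642, 0.648, 0.700, 1.091, 2.015),
    H16_se = c(0.088, 0.088, 0.124, 0.088, 0.088, 0.088, 0.088),
    Oct = c(0.554, 0.364, 0.454, 0.141, 0.444, 0.586, 0.496),
    Oct_se = c(0.037, 0.037, 0.037, 0.053, 0.037, 0.037, 0.037),
    Tri = c(0.000, 0.223, 0.195, 0.075, 0.140, 0.247, 0.260),
    Tri_se = c(0.025, 0.025, 0.025, 0.036, 0.025, 0.025, 0.025),
    stringsAsFactors = FALSE
  )
  # published percentage profiles over the eight waxes, rows sum to ~100
  pct <- rbind(
    OGL      = c(0.3, 70.7, 0.0, 0.1, 19.2, 9.6, 0.0, 0.0),
    `546115` = c(36.8, 25.1, 15.4, 2.8, 11.1, 0.2, 4.8, 3.7),
    `546192` = c(40.6, 28.7, 12.3, 3.8, 3.2, 1.2, 6.0, 4.1),
    B5351    = c(52.9, 11.5, 6.1, 5.0, 1.1, 2.5, 12.0, 8.9),
    B9885    = c(44.4, 28.2, 8.9, 2.5, 3.8, 3.9, 3.1, 5.2),
    `264320` = c(48.1, 25.8, 10.9, 2.7, 4.5, 1.1, 3.4, 3.4),
    DH2107   = c(65.0, 16.0, 8.4, 1.5, 2.4, 0.9, 2.2, 3.6)
  )
  colnames(pct) <- wax_names()
  presets <- list()
  for (i in seq_len(nrow(major))) {
    acc <- major$accession[i]
    p <- pct[acc, ]
    sum3 <- major$H16[i] + major$Oct[i] + major$Tri[i]
    share3 <- (p[["H16"]] + p[["Oct"]] + p[["Tri"]]) / 100
    total <- sum3 / share3
    means <- c(H16 = major$H16[i], Oct = major$Oct[i], Tri = major$Tri[i],
               total * p[4:8] / 100)
    rel <- c(major$H16_se[i] / major$H16[i], major$Oct_se[i] / major$Oct[i],
             major$Tri_se[i] / major$Tri[i])
    rel <- median(rel[is.finite(rel) & rel > 0])
    ses <- c(major$H16_se[i], major$Oct_se[i], major$Tri_se[i],
             pmax(rel * means[4:8], 0.005))
    presets[[acc]] <- list(
      accession_id = acc,
      phenotype_class = major$class[i],
      waxes = data.frame(wax = wax_names(), mean = unname(means),
                         se = unname(ses), stringsAsFactors = FALSE)
    )
  }
  presets
}

#' Names of the eight quantified leaf waxes
#' @return Character vector.
#' @export
wax_names <- function() c("H16", "Oct", "Tri", "Met", "Hex", "Octd", "Hepc", "Hepd")

#' Simulate a multi-accession wax panel with paired leaf spectra
#'
#' For each accession preset, draws per-plant wax amounts from Gaussians
#' with the preset means and per-plant standard deviation `SE * sqrt(3)`
#' (the published SEs arise from three replications), truncated at zero.
#' A preset mean of exactly zero yields amounts of exactly zero (the wax is
#' absent, not noisy). Each plant gets `n_readings` simulated leaf spectra
#' generated from its true H16/Oct/Tri amounts (minor waxes have no spectral
#' signature and do not enter the spectra).
#'
#' @param presets List of accession presets; default [accession_presets()].
#' @param n_plants Plants per accession per repetition; default 3.
#' @param n_reps Experiment repetitions; default 2.
#' @param n_readings Spectral readings per plant (averaged downstream when
#'   more than 1); default 1.
#' @param noise_sd Reflectance noise sd passed to [simulate_leaf_spectrum()];
#'   default 0.005.
#' @param sd_scale Multiplier on the per-plant sd (`SE * sqrt(3)`); set 0 for
#'   a zero-variance panel; default 1.
#' @param seed Optional integer seed.
#' @return List with `profiles` (data frame: `sample_id`, `accession`,
#'   `phenotype_class`, `rep`, `plant`, one column per wax) and `spectra`
#'   (a [spectra] object; one column per plant-reading, metadata columns
#'   `sample_id`, `plant_id`, `accession`, `rep`, `reading`).
#' @export
simulate_accession_panel <- function(presets = accession_presets(),
                                     n_plants = 3L, n_reps = 2L,
                                     n_readings = 1L, noise_sd = 0.005,
                                     sd_scale = 1, seed = NULL) {
  stopifnot(n_plants >= 1L, n_reps >= 1L, n_readings >= 1L)
  with_seed(seed, {
    base <- leaf_baseline()
    prof <- list()
    spec_list <- list()
    for (acc in names(presets)) {
      ps <- presets[[acc]]
      for (rep_i in seq_len(n_reps)) {
        for (pl in seq_len(n_plants)) {
          id <- sprintf("%s_r%d_p%d", acc, rep_i, pl)
          mu <- setNames(ps$waxes$mean, ps$waxes$wax)
          sdv <- setNames(ps$waxes$se, ps$waxes$wax) * sqrt(3) * sd_scale
          amt <- ifelse(mu == 0, 0, pmax(0, rnorm(length(mu), mu, sdv)))
          names(amt) <- names(mu)
          row <- data.frame(sample_id = id, accession = acc,
                            phenotype_class = ps$phenotype_class,
                            rep = rep_i, plant = pl, stringsAsFactors = FALSE)
          for (w in names(amt)) row[[w]] <- amt[[w]]
          prof[[id]] <- row
          for (rd in seq_len(n_readings)) {
            sid <- if (n_readings > 1L) sprintf("%s_m%d", id, rd) else id
            sp <- simulate_leaf_spectrum(amt[c("H16", "Oct", "Tri")],
                                         baseline = base, noise_sd = noise_sd,
                                         sample_id = sid)
            sp$meta$plant_id <- id
            sp$meta$accession <- acc
            sp$meta$rep <- rep_i
            sp$meta$reading <- rd
            spec_list[[sid]] <- sp
          }
        }
      }
    }
    list(profiles = do.call(rbind, c(prof, list(make.row.names = FALSE))),
         spectra = do.call(cbind_spectra, spec_list))
  })
}
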