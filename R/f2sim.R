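#' QTL presets calibrated to the published chromosome-8 effects
#'
#' Additive (`a`) and dominance (`d`) effects of the waxy-parent allele, the
#' fraction of phenotypic variance explained by the QTL, and the F2
#' population mean for each trait/measurement combination (GCMS-measured or
#' spectroscopy-predicted H16, Oct, and Tri). The residual standard
#' deviation solves `a^2/2 + d^2/4 = f * (a^2/2 + d^2/4 + sd^2)` under 1:2:1
#' F2 genotype frequencies, and the intercept `mu = mean - d/2` makes the
#' population mean hit the published F2 mean.
#'
#' @return Named list of presets (`H16_spectroscopy`, `H16_gcms`,
#'   `Oct_spectroscopy`, `Oct_gcms`, `Tri_spectroscopy`, `Tri_gcms`), each a
#'   list with `wax`, `source`, `chromosome`, `position_cM`, `additive`,
#'   `dominance`, `var_fraction`, `population_mean`, `intercept`,
#'   `residual_sd`.
#' @export
qtl_presets <- function() {
  tab <- data.frame(
    name = c("H16_spectroscopy", "H16_gcms", "Oct_spectroscopy", "Oct_gcms",
             "Tri_spectroscopy", "Tri_gcms"),
    wax = c("H16", "H16", "Oct", "Oct", "Tri", "Tri"),
    source = c("spectroscopy", "gcms", "spectroscopy", "gcms",
               "spectroscopy", "gcms"),
    additive = c(0.10, 0.57, 0.36, 0.36, 0.29, 0.30),
    dominance = c(0.14, 0.33, 0.31, 0.31, 0.28, 0.19),
    var_fraction = c(0.210, 0.456, 0.210, 0.169, 0.364, 0.233),
    population_mean = c(0.83, 0.84, 0.145, 0.143, 0.085, 0.08),
    stringsAsFactors = FALSE
  )
  out <- list()
  for (i in seq_len(nrow(tab))) {
    a <- tab$additive[i]; d <- tab$dominance[i]; f <- tab$var_fraction[i]
    out[[tab$name[i]]] <- list(
      wax = tab$wax[i], source = tab$source[i],
      chromosome = "8", position_cM = 41.1,
      additive = a, dominance = d, var_fraction = f,
      population_mean = tab$population_mean[i],
      intercept = tab$population_mean[i] - d / 2,
      residual_sd = residual_sd_for_fraction(a, d, f)
    )
  }
  out
}

#' Residual sd giving a target QTL variance fraction
#'
#' Under 1:2:1 F2 frequencies the genetic variance of `a*x_a + d*x_d`
#' (with `x_a` in \{-1,0,1\} and `x_d` in \{0,1,0\}) is `a^2/2 + d^2/4`.
#' Returns the residual sd such that the genetic share of total variance
#' equals `fraction`.
#'
#' @param additive Additive effect `a`.
#' @param dominance Dominance effect `d`.
#' @param fraction Target variance fraction in (0, 1).
#' @return Residual standard deviation.
#' @export
residual_sd_for_fraction <- function(additive, dominance, fraction) {
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  vg <- additive^2 / 2 + dominance^2 / 4
  sqrt(vg * (1 - fraction) / fraction)
}

#' Default synthetic genetic map
#'
#' Eight chromosomes of 80 cM with markers every 5 cM. Chromosome 8
#' additionally carries the six named SNPs of the published chromosome-8
#' region; the two with published positions sit at 41.1 (`i19082_1721`) and
#' 46.2 cM (`i20235_630`), and the four flanking SNPs are placed at
#' synthetic positions (26, 31, 36, 51 cM) consistent with their interval
#' roles. Chromosomes 1-7 are decoys that only inform genome-wide
#' permutation thresholds.
#'
#' @return Map data frame with columns `marker`, `chr`, `pos_cM`.
#' @export
default_map <- function() {
  maps <- list()
  for (ch in 1:8) {
    pos <- seq(0, 80, by = 5)
    if (ch == 8L) {
      pos <- setdiff(pos, c(25, 30, 35, 40, 45, 50))
      named <- data.frame(
        marker = c("i29044_2564", "i28432_1302", "i41653_558",
                   "i19082_1721", "i20235_630", "i28633_2705"),
        chr = "8",
        pos_cM = c(26.0, 31.0, 36.0, 41.1, 46.2, 51.0),
        stringsAsFactors = FALSE
      )
      filler <- data.frame(marker = sprintf("c8m%02d", pos), chr = "8",
                           pos_cM = pos, stringsAsFactors = FALSE)
      m <- rbind(filler, named)
      m <- m[order(m$pos_cM), ]
    } else {
      m <- data.frame(marker = sprintf("c%dm%02d", ch, pos),
                      chr = as.character(ch), pos_cM = pos,
                      stringsAsFactors = FALSE)
    }
    maps[[ch]] <- m
  }
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  out
}

# simulate one chromosome's F2 genotypes (count of B alleles, n x m) at
# `pos` (cM) by two independent gamete Markov chains with Haldane
# recombination between adjacent positions.
sim_chromosome_codes <- function(n, pos) {
  m <- length(pos)
  g1 <- matrix(0L, n, m)
  g2 <- matrix(0L, n, m)
  g1[, 1L] <- rbinom(n, 1L, 0.5)
  g2[, 1L] <- rbinom(n, 1L, 0.5)
  if (m >= 2L) {
    for (k in 2L:m) {
      r <- haldane_r(pos[k] - pos[k - 1L])
      sw1 <- rbinom(n, 1L, r)
      sw2 <- rbinom(n, 1L, r)
      g1[, k] <- ifelse(sw1 == 1L, 1L - g1[, k - 1L], g1[, k - 1L])
      g2[, k] <- ifelse(sw2 == 1L, 1L - g2[, k - 1L], g2[, k - 1L])
    }
  }
  g1 + g2
}

#' Simulate an F2 family with one QTL
#'
#' Genotypes are generated chromosome by chromosome with a two-gamete
#' Markov model and Haldane recombination between adjacent positions (no
#' interference). The phenotype is `mu + a*x_a + d*x_d + e` with
#' `x_a = -1/0/+1` and `x_d = 0/1/0` for AA/AB/BB read off the (possibly
#' unobserved) QTL position, and Gaussian residuals. Phenotypes are not
#' truncated at zero: they live on the measurement/prediction scale, where
#' regression-predicted amounts can be negative. With a list of presets
#' (which must agree on the QTL location), one phenotype column per preset
#' is produced from the shared genotypes.
#'
#' @param map Genetic map data frame (`marker`, `chr`, `pos_cM`); default
#'   [default_map()].
#' @param preset A preset from [qtl_presets()], or a named list of such
#'   presets sharing `chromosome`/`position_cM`.
#' @param n Number of F2 individuals; default 94.
#' @param missing_rate Fraction of marker genotypes set missing at random;
#'   default 0.
#' @param seed Optional integer seed.
#' @return List with `map`, `genotypes` (character matrix individuals x
#'   markers, codes AA/AB/BB/NA), `phenotypes` (data frame `sample_id` plus
#'   one column per preset, named by the preset's wax), `qtl_genotype`
#'   (integer 0/1/2 B-allele count at the QTL), and `presets`.
#' @export
simulate_f2_family <- function(map = default_map(), preset = NULL, n = 94L,
                               missing_rate = 0, seed = NULL) {
  if (is.null(preset)) preset <- qtl_presets()$H16_spectroscopy
  presets <- if (!is.null(preset$additive)) list(preset) else preset
  if (is.null(names(presets)) || any(!nzchar(names(presets)))) {
    names(presets) <- vapply(presets, function(p) p$wax, character(1L))
  }
  stopifnot(n >= 2L)
  map <- validate_map(map)
  qchr <- presets[[1L]]$chromosome
  qpos <- presets[[1L]]$position_cM
  for (p in presets) {
    if (!identical(p$chromosome, qchr) || p$position_cM != qpos) {
      stop("all presets must share one QTL location", call. = FALSE)
    }
  }
  chr_pos <- map$pos_cM[map$chr == qchr]
  if (!length(chr_pos)) stop("QTL chromosome not in map", call. = FALSE)
  if (qpos < min(chr_pos) || qpos > max(chr_pos)) {
    stop("QTL position outside the map span of its chromosome", call. = FALSE)
  }
  with_seed(seed, {
    codes <- matrix(NA_integer_, n, nrow(map),
                    dimnames = list(sprintf("F2_%03d", seq_len(n)), map$marker))
    qtl_code <- NULL
    for (ch in unique(map$chr)) {
      idx <- which(map$chr == ch)
      pos <- map$pos_cM[idx]
      if (ch == qchr && !qpos %in% pos) {
        allpos <- sort(c(pos, qpos))
        sim <- sim_chromosome_codes(n, allpos)
        qtl_code <- sim[, which(allpos == qpos)]
        codes[, idx] <- sim[, match(pos, allpos)]
      } else {
        sim <- sim_chromosome_codes(n, pos)
        if (ch == qchr) qtl_code <- sim[, which(pos == qpos)[1L]]
        codes[, idx] <- sim
      }
    }
    xa <- qtl_code - 1L
    xd <- as.integer(qtl_code == 1L)
    phen <- data.frame(sample_id = rownames(codes), stringsAsFactors = FALSE)
    for (nm in names(presets)) {
      p <- presets[[nm]]
      phen[[nm]] <- p$intercept + p$additive * xa + p$dominance * xd +
        rnorm(n, sd = p$residual_sd)
    }
    geno <- matrix(c("AA", "AB", "BB")[codes + 1L], n, nrow(map),
                   dimnames = dimnames(codes))
    if (missing_rate > 0) {
      drop <- runif(length(geno)) < missing_rate
      geno[drop] <- NA_character_
    }
    list(map = map, genotypes = geno, phenotypes = phen,
         qtl_genotype = qtl_code, presets = presets)
  })
}
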