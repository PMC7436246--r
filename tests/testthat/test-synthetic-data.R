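test_that("standard signatures carry each wax's unique fingerprint", {
  grid <- seq(350, 2500, by = 1)
  sigs <- lapply(c(H16 = "H16", Oct = "Oct", Tri = "Tri"),
                 build_standard_signature, grid = grid)
  at <- function(s, wl) s$values[match(wl, s$wavelength), 1]
  expect_gt(abs(at(sigs$H16, 2259)), 0.9)
  expect_lt(abs(at(sigs$Oct, 2259)), 0.05)
  expect_lt(abs(at(sigs$Tri, 2259)), 0.05)
  expect_gt(abs(at(sigs$Oct, 645)), 0.9)
  expect_gt(abs(at(sigs$Tri, 730)), 0.9)
})

test_that("signature evaluation matches a direct sum-of-Gaussians oracle", {
  grid <- analysis_grid()
  for (wax in c("H16", "Oct", "Tri")) {
    ft <- wax_feature_tables()[[wax]]
    sig <- build_standard_signature(wax, ft, grid = grid)
    direct <- sapply(grid, function(x) {
      sum(ft$amplitude * exp(-(x - ft$center)^2 / (2 * ft$width^2)))
    })
    expect_equal(sig$values[, 1], direct, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("empty feature tables and bad inputs are handled", {
  empty <- data.frame(center = numeric(0), amplitude = numeric(0),
                      width = numeric(0))
  sig <- build_standard_signature("H16", empty)
  expect_true(all(sig$values == 0))
  expect_error(build_standard_signature("wax9"), "unknown wax")
  expect_error(build_standard_signature("H16", data.frame(
    center = 100, amplitude = 1, width = 10)), "within 350-2500")
  # a wax's table must not contain another wax's unique center
  expect_error(build_standard_signature("H16", data.frame(
    center = c(2259, 645), amplitude = 1, width = 10)), "unique")
})

test_that("leaf spectra are linear in wax amounts and seed-reproducible", {
  base <- leaf_baseline()
  s0 <- simulate_leaf_spectrum(c(H16 = 0, Oct = 0, Tri = 0), base)
  expect_equal(s0$values[, 1], base$values[, 1], ignore_attr = TRUE)

  s1 <- simulate_leaf_spectrum(c(H16 = 0.5), base)
  s2 <- simulate_leaf_spectrum(c(H16 = 1.0), base)
  inc1 <- s1$values[, 1] - base$values[, 1]
  inc2 <- s2$values[, 1] - base$values[, 1]
  expect_equal(inc2, 2 * inc1, tolerance = 1e-10)

  a <- simulate_leaf_spectrum(c(H16 = 1), base, noise_sd = 0.01, seed = 42)
  b <- simulate_leaf_spectrum(c(H16 = 1), base, noise_sd = 0.01, seed = 42)
  expect_identical(a$values, b$values)
  expect_error(simulate_leaf_spectrum(c(H16 = -1), base), "non-negative")
  expect_true(all(a$values >= 0 & a$values <= 1))
})

test_that("accession panel draws honor the preset means", {
  ap <- accession_presets()
  pan <- simulate_accession_panel(ap["OGL"], n_plants = 50, n_reps = 1,
                                  noise_sd = 0, seed = 1)
  expect_true(all(pan$profiles$Tri == 0))  # absent wax stays absent
  expect_true(all(pan$profiles$H16 >= 0))

  frozen <- simulate_accession_panel(ap["B9885"], n_plants = 5, n_reps = 2,
                                     sd_scale = 0, noise_sd = 0, seed = 2)
  mu <- setNames(ap$B9885$waxes$mean, ap$B9885$waxes$wax)
  for (w in names(mu)) expect_true(all(frozen$profiles[[w]] == mu[[w]]))

  big <- simulate_accession_panel(ap["DH2107"], n_plants = 1500, n_reps = 1,
                                  noise_sd = 0, seed = 3)
  expect_equal(mean(big$profiles$H16), 2.015, tolerance = 0.02)
})

test_that("preset wax proportions reproduce the published percentage rows", {
  pub <- rbind(
    OGL      = c(0.3, 70.7, 0.0, 0.1, 19.2, 9.6, 0.0, 0.0),
    `546115` = c(36.8, 25.1, 15.4, 2.8, 11.1, 0.2, 4.8, 3.7),
    `546192` = c(40.6, 28.7, 12.3, 3.8, 3.2, 1.2, 6.0, 4.1),
    B5351    = c(52.9, 11.5, 6.1, 5.0, 1.1, 2.5, 12.0, 8.9),
    B9885    = c(44.4, 28.2, 8.9, 2.5, 3.8, 3.9, 3.1, 5.2),
    `264320` = c(48.1, 25.8, 10.9, 2.7, 4.5, 1.1, 3.4, 3.4),
    DH2107   = c(65.0, 16.0, 8.4, 1.5, 2.4, 0.9, 2.2, 3.6)
  )
  ap <- accession_presets()
  for (acc in names(ap)) {
    m <- ap[[acc]]$waxes$mean
    got <- 100 * m / sum(m)
    want <- 100 * pub[acc, ] / sum(pub[acc, ])  # rows print to 99.9-100.1
    expect_lt(max(abs(got - want)), 0.1)
    expect_true(all(ap[[acc]]$waxes$se > 0))
  }
})

test_that("F2 genotypes follow Mendelian and Haldane expectations", {
  map <- toy_map()
  preset <- qtl_presets()$H16_spectroscopy
  preset$chromosome <- "1"; preset$position_cM <- 30
  f2 <- simulate_f2_family(map, preset, n = 10000, seed = 4)
  freq <- table(f2$qtl_genotype) / 10000
  expect_equal(as.numeric(freq), c(0.25, 0.5, 0.25), tolerance = 0.03)

  # adjacent markers 10 cM apart: gamete recombinant fraction ~ Haldane.
  # With independent gametes, E|g2 - g1| = 2r - r^2, so r = 1 - sqrt(1 - E)
  # inverts the B-allele-count differences into a recombination estimate
  # over the 2n simulated meioses.
  g1 <- f2$genotypes[, "m1_0"]; g2 <- f2$genotypes[, "m1_1"]
  code <- function(g) match(g, c("AA", "AB", "BB")) - 1
  e_emp <- mean(abs(code(g2) - code(g1)))
  r_emp <- 1 - sqrt(1 - e_emp)
  expect_equal(r_emp, haldane_r(10), tolerance = 0.01)
})

test_that("QTL presets are variance-calibrated and mean-calibrated", {
  ps <- qtl_presets()$H16_gcms
  vg <- ps$additive^2 / 2 + ps$dominance^2 / 4
  expect_equal(vg / (vg + ps$residual_sd^2), ps$var_fraction,
               tolerance = 1e-12)
  map8 <- default_map()
  map8 <- map8[map8$chr == "8", ]
  f2 <- simulate_f2_family(map8, ps, n = 100000, seed = 5)
  r2 <- summary(lm(f2$phenotypes$H16 ~ factor(f2$qtl_genotype)))$r.squared
  expect_equal(r2, ps$var_fraction, tolerance = 0.01)
  expect_equal(mean(f2$phenotypes$H16), ps$population_mean, tolerance = 0.02)
})

test_that("null F2 families rarely exceed their permutation threshold", {
  map8 <- default_map()
  map8 <- map8[map8$chr == "8", ]
  null_preset <- list(chromosome = "8", position_cM = 41.1, additive = 0,
                      dominance = 0, intercept = 0.8, residual_sd = 0.2,
                      wax = "H16")
  below <- 0
  for (i in 1:12) {
    f2 <- simulate_f2_family(map8, null_preset, n = 94, seed = 600 + i)
    pr <- genotype_probs(f2$genotypes, map8)
    sc <- hk_scan(pr, f2$phenotypes$H16)
    thr <- perm_threshold(pr, f2$phenotypes$H16, n_perm = 200,
                          seed = 700 + i)
    if (max(sc$positions$lod) < thr) below <- below + 1
  }
  expect_gte(below, 10)
})

test_that("generator output files round-trip through every reader", {
  tmp <- withr::local_tempdir()
  pan <- simulate_accession_panel(accession_presets()["B5351"], n_plants = 2,
                                  n_reps = 1, seed = 6)
  write_spectra(pan$spectra, file.path(tmp, "spec.csv"))
  back <- read_spectra(file.path(tmp, "spec.csv"))
  expect_equal(back$values, pan$spectra$values, tolerance = 1e-12)

  f2 <- simulate_f2_family(n = 5, seed = 7)
  write_genetic_map(f2$map, file.path(tmp, "map.csv"))
  write_genotypes(f2$genotypes, file.path(tmp, "geno.csv"))
  write_phenotypes(f2$phenotypes, file.path(tmp, "phen.csv"))
  expect_equal(read_genetic_map(file.path(tmp, "map.csv"))$marker,
               f2$map$marker)
  expect_equal(unname(read_genotypes(file.path(tmp, "geno.csv"))),
               unname(f2$genotypes))
  expect_equal(read_phenotypes(file.path(tmp, "phen.csv"))$H16,
               f2$phenotypes$H16, tolerance = 1e-12)
})
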