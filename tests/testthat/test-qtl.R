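sim_toy <- function(seed, n = 94, preset = NULL, map = toy_map()) {
  if (is.null(preset)) {
    preset <- qtl_presets()$Tri_spectroscopy
    preset$chromosome <- "1"
    preset$position_cM <- 30
  }
  simulate_f2_family(map, preset, n = n, seed = seed)
}

test_that("the Haldane map function matches its closed form", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(10), (1 - exp(-0.2)) / 2, tolerance = 1e-12)
  expect_equal(haldane_r(1e5), 0.5, tolerance = 1e-10)
  expect_error(haldane_r(-1), "non-negative")
})

test_that("genotype probabilities are indicators at typed markers", {
  f2 <- sim_toy(1, n = 30)
  pr <- genotype_probs(f2$genotypes, f2$map)
  expect_true(all(abs(apply(pr$prob, 1:2, sum) - 1) < 1e-9))
  at_marker <- which(pr$positions$marker == "m1_2")
  codes <- match(f2$genotypes[, "m1_2"], c("AA", "AB", "BB"))
  for (i in 1:30) {
    expect_equal(unname(pr$prob[i, at_marker, ]),
                 as.numeric(seq_len(3) == codes[i]), tolerance = 1e-12)
  }
})

test_that("probabilities are symmetric between opposite homozygous flanks", {
  map <- data.frame(marker = c("L", "R"), chr = "1", pos_cM = c(0, 20))
  geno <- matrix(c("AA", "BB"), 1, 2, dimnames = list("i1", c("L", "R")))
  pr <- genotype_probs(geno, map, step = 1)
  mid <- which(pr$positions$pos_cM == 10)
  expect_equal(pr$prob[1, mid, "AA"], pr$prob[1, mid, "BB"],
               tolerance = 1e-12)
})

test_that("interior probabilities match brute-force gamete enumeration", {
  map <- data.frame(marker = c("L", "R"), chr = "1", pos_cM = c(0, 25))
  combos <- expand.grid(l = c("AA", "AB", "BB", NA),
                        r = c("AA", "AB", "BB", NA),
                        stringsAsFactors = FALSE)
  combos <- combos[!(is.na(combos$l) & is.na(combos$r)), ]
  geno <- matrix(c(combos$l, combos$r), nrow(combos), 2,
                 dimnames = list(NULL, c("L", "R")))
  pr <- genotype_probs(geno, map, step = 1)
  at <- which(pr$positions$pos_cM == 7)
  for (i in seq_len(nrow(combos))) {
    want <- enum_geno_prob(match(combos$l[i], c("AA", "AB", "BB")) - 1,
                           match(combos$r[i], c("AA", "AB", "BB")) - 1,
                           7, 18)
    expect_equal(unname(pr$prob[i, at, ]), want, tolerance = 1e-9)
  }
})

test_that("HK LOD at a fully typed marker equals the direct regression", {
  f2 <- sim_toy(2)
  pr <- genotype_probs(f2$genotypes, f2$map)
  y <- f2$phenotypes$Tri
  sc <- hk_scan(pr, y)
  at <- which(pr$positions$marker == "m1_3")
  codes <- match(f2$genotypes[, "m1_3"], c("AA", "AB", "BB")) - 1
  expect_equal(sc$positions$lod[at], direct_marker_lod(codes, y),
               tolerance = 1e-9)
})

test_that("marker LOD is invariant to the pseudomarker step size", {
  f2 <- sim_toy(3)
  y <- f2$phenotypes$Tri
  pr1 <- genotype_probs(f2$genotypes, f2$map, step = 1)
  pr5 <- genotype_probs(f2$genotypes, f2$map, step = 5)
  s1 <- hk_scan(pr1, y)
  s5 <- hk_scan(pr5, y)
  at1 <- which(s1$positions$marker == "m1_3")
  at5 <- which(s5$positions$marker == "m1_3")
  expect_equal(s1$positions$lod[at1], s5$positions$lod[at5],
               tolerance = 1e-10)
})

test_that("scans localize a strong simulated QTL near its true position", {
  hits <- sapply(1:25, function(i) {
    f2 <- sim_toy(100 + i)
    pr <- genotype_probs(f2$genotypes, f2$map)
    sc <- hk_scan(pr, f2$phenotypes$Tri)
    c(chr = sc$positions$chr[sc$max], pos = sc$positions$pos_cM[sc$max])
  })
  on_chr1 <- hits["chr", ] == "1"
  expect_gte(mean(on_chr1), 0.9)
  expect_lt(median(abs(as.numeric(hits["pos", on_chr1]) - 30)), 10)
})

test_that("missing genotypes are absorbed by the flanking-marker logic", {
  f2 <- sim_toy(4, n = 60)
  g <- f2$genotypes
  set.seed(5)
  g[sample(length(g), length(g) %/% 10)] <- NA
  pr <- genotype_probs(g, f2$map)
  expect_true(all(abs(apply(pr$prob, 1:2, sum) - 1) < 1e-9))
  sc <- hk_scan(pr, f2$phenotypes$Tri)
  expect_true(all(is.finite(sc$positions$lod)))
})

test_that("permutation thresholds behave and match a brute-force loop", {
  f2 <- sim_toy(6, n = 50)
  pr <- genotype_probs(f2$genotypes, f2$map, step = 5)
  y <- f2$phenotypes$Tri
  thr <- perm_threshold(pr, y, n_perm = 100, seed = 8)
  expect_gt(thr, 0)
  thr20 <- perm_threshold(pr, y, n_perm = 100, alpha = 0.20, seed = 8)
  expect_lte(thr20, thr)

  # brute force: same permutation stream, full rescan per permutation
  maxs <- attr(thr, "max_lods")
  set.seed(8)
  brute <- sapply(1:100, function(i) {
    yp <- sample(y)
    max(hk_scan(pr, yp)$positions$lod)
  })
  expect_equal(unname(maxs), brute, tolerance = 1e-8)
  expect_equal(unname(quantile(brute, 0.95)), as.numeric(thr),
               tolerance = 1e-8)
})

test_that("1.5-LOD support intervals match an exhaustive window scan", {
  f2 <- sim_toy(9)
  pr <- genotype_probs(f2$genotypes, f2$map)
  sc <- hk_scan(pr, f2$phenotypes$Tri)
  iv <- lod_interval(sc)
  on_chr <- sc$positions[sc$positions$chr == iv$chr, ]
  want <- brute_lod_interval(on_chr$pos_cM, on_chr$lod)
  expect_equal(c(iv$lo, iv$hi), want)
  expect_gte(sc$positions$pos_cM[sc$max], iv$lo)
  expect_lte(sc$positions$pos_cM[sc$max], iv$hi)
  # flanking markers lie strictly outside the interval (or at the ends)
  flank_lo_pos <- on_chr$pos_cM[match(iv$flank_lo, on_chr$marker)]
  expect_true(flank_lo_pos <= iv$lo)

  # random synthetic curves exercise the edge cases
  for (seed in 1:5) {
    set.seed(seed)
    fake <- sc
    fake$positions$lod <- abs(rnorm(nrow(sc$positions)))
    fake$max <- which.max(fake$positions$lod)
    iv2 <- lod_interval(fake)
    ch <- fake$positions[fake$positions$chr == iv2$chr, ]
    expect_equal(c(iv2$lo, iv2$hi), brute_lod_interval(ch$pos_cM, ch$lod))
  }
})

test_that("single-QTL fits recover effects and satisfy the LOD identity", {
  f2 <- sim_toy(10, n = 200)
  pr <- genotype_probs(f2$genotypes, f2$map)
  codes <- match(f2$genotypes[, "m1_3"], c("AA", "AB", "BB")) - 1
  y <- 0.5 * (codes - 1) + rnorm(200, 0, 1e-8)
  ft <- fit_qtl(pr, y, "1", 30)
  expect_equal(ft$additive, 0.5, tolerance = 1e-6)
  expect_equal(ft$dominance, 0, tolerance = 1e-6)
  expect_gt(ft$pct_var, 99.99)

  yn <- 0.5 * (codes - 1) + rnorm(200, 0, 0.5)
  fn <- fit_qtl(pr, yn, "1", 30)
  expect_equal(fn$pct_var, 100 * (1 - 10^(-2 * fn$lod / fn$n)),
               tolerance = 1e-9)
})

test_that("stepwise search finds true QTL and stays quiet under the null", {
  map <- toy_map()
  one_qtl <- qtl_presets()$Tri_spectroscopy
  one_qtl$chromosome <- "1"; one_qtl$position_cM <- 30
  n_single <- 0
  for (i in 1:8) {
    f2 <- simulate_f2_family(map, one_qtl, n = 94, seed = 200 + i)
    pr <- genotype_probs(f2$genotypes, f2$map, step = 2)
    out <- stepwise_search(pr, f2$phenotypes$Tri, penalty = 3.2)
    if (nrow(out) == 1 && out$chr == "1") n_single <- n_single + 1
  }
  expect_gte(n_single, 6)

  null_preset <- list(chromosome = "1", position_cM = 30, additive = 0,
                      dominance = 0, intercept = 0, residual_sd = 1,
                      wax = "Tri")
  n_empty <- 0
  for (i in 1:8) {
    f2 <- simulate_f2_family(map, null_preset, n = 94, seed = 300 + i)
    pr <- genotype_probs(f2$genotypes, f2$map, step = 2)
    out <- stepwise_search(pr, f2$phenotypes$Tri, penalty = 3.2)
    if (nrow(out) == 0) n_empty <- n_empty + 1
  }
  expect_gte(n_empty, 7)
})

test_that("stepwise search separates two strong unlinked QTL", {
  map <- toy_map()
  f2 <- sim_toy(11, n = 150, preset = list(chromosome = "1",
                                           position_cM = 30, additive = 0,
                                           dominance = 0, intercept = 0,
                                           residual_sd = 1e-6, wax = "y"))
  c1 <- match(f2$genotypes[, "m1_2"], c("AA", "AB", "BB")) - 2
  c2 <- match(f2$genotypes[, "m2_4"], c("AA", "AB", "BB")) - 2
  set.seed(12)
  y <- 1.0 * c1 + 1.0 * c2 + rnorm(150, 0, 0.5)
  pr <- genotype_probs(f2$genotypes, f2$map, step = 2)
  out <- stepwise_search(pr, y, penalty = 3.2)
  expect_equal(sort(unique(out$chr)), c("1", "2"))
  expect_equal(nrow(out), 2)
  expect_gt(attr(out, "pct_var_joint"), 50)
})

test_that("marker covariates are excluded near the test position", {
  f2 <- sim_toy(13)
  pr <- genotype_probs(f2$genotypes, f2$map)
  y <- f2$phenotypes$Tri
  sc_cov <- hk_scan(pr, y, covariate_markers = "m2_3")
  sc_plain <- hk_scan(pr, y)
  at <- which(pr$positions$marker == "m2_3")
  # at the covariate's own position the covariate is dropped, so the LOD
  # equals the plain interval-mapping LOD there
  expect_equal(sc_cov$positions$lod[at], sc_plain$positions$lod[at],
               tolerance = 1e-9)
  far <- which(pr$positions$marker == "m1_0")
  expect_false(isTRUE(all.equal(sc_cov$positions$lod[far],
                                sc_plain$positions$lod[far])))
})
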