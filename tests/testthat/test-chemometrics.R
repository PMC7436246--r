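test_that("stratified splits draw evenly from all quartiles", {
  set.seed(1)
  y <- setNames(sample(100, 12), paste0("s", 1:12))
  plan <- stratified_split(y, 2 / 3, seed = 5)
  expect_length(plan$calibration, 8)
  expect_length(plan$validation, 4)
  for (qq in 1:4) {
    members <- names(plan$quartile)[plan$quartile == qq]
    expect_equal(sum(members %in% plan$calibration), 2)
  }
  expect_setequal(c(plan$calibration, plan$validation), names(y))
  plan2 <- stratified_split(y, 2 / 3, seed = 5)
  expect_identical(plan$calibration, plan2$calibration)
  expect_error(stratified_split(y, 1.2), "in \\(0, 1\\)")
  expect_error(stratified_split(y[1:6]), "at least 8")
})

test_that("PLSR with one component solves the univariate problem exactly", {
  set.seed(2)
  X <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "wl1"))
  y <- 3 + 2 * X[, 1]
  m <- fit_plsr(X, y, ncomp = 1)
  expect_equal(predict(m, X), y, tolerance = 1e-10)
  # single-predictor standardized coefficient equals the Pearson correlation
  expect_equal(standardized_coefficients(m)$standardized, cor(X[, 1], y),
               tolerance = 1e-10)
})

test_that("full-rank PLSR reproduces ordinary least squares", {
  set.seed(3)
  X <- matrix(rnorm(50), 10, 5)
  y <- rnorm(10)
  m <- fit_plsr(X, y, ncomp = 5)
  ols <- lm(y ~ X)
  expect_equal(predict(m, X), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("PLSR predictions match the independent Krylov oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(30 * 50), 30, 50)
    y <- drop(X[, 1:5] %*% runif(5)) + rnorm(30, 0, 0.3)
    Xnew <- matrix(rnorm(10 * 50), 10, 50)
    for (A in 1:5) {
      m <- fit_plsr(X, y, ncomp = A)
      expect_equal(predict(m, X), pls_krylov_predict(X, y, A),
                   tolerance = 1e-6)
      expect_equal(predict(m, Xnew), pls_krylov_predict(X, y, A, Xnew),
                   tolerance = 1e-6)
    }
  }
})

test_that("scores are orthogonal and training R2 is monotone in ncomp", {
  set.seed(4)
  X <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  m <- fit_plsr(X, y, ncomp = 8)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  r2 <- sapply(1:8, function(a) cor(predict(m, X, ncomp = a), y)^2)
  expect_true(all(diff(r2) > -1e-10))
})

test_that("prediction honors centering and ignores inert wavelengths", {
  set.seed(5)
  X <- cbind(matrix(rnorm(40), 20, 2), 7)  # third wavelength constant
  y <- rnorm(20)
  m <- fit_plsr(X, y, ncomp = 2)
  # training-mean spectrum predicts the training-mean response
  expect_equal(predict(m, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-10)
  # offsets on a zero-coefficient (constant) wavelength change nothing
  expect_equal(m$coefficients[3], 0, tolerance = 1e-12, ignore_attr = TRUE)
  X2 <- X; X2[, 3] <- X2[, 3] + 100
  expect_equal(predict(m, X2), predict(m, X), tolerance = 1e-10)
  expect_error(predict(m, X[, 1:2]), "grid")
  expect_error(fit_plsr(X, rep(1, 20), 2), "zero variance")
  expect_error(fit_plsr(X, y, 0), "at least 1")
  expect_error(fit_plsr(X, y, 25), "may not exceed")
})

test_that("PRESS selection finds the rank-1 structure and is reproducible", {
  set.seed(6)
  X <- outer(rnorm(40), rnorm(30))  # rank-1 predictors
  y <- 2 * X[, 1]                   # noiseless rank-1 response
  pc <- select_components_press(X, y, max_ncomp = 5, n_perm = 60, seed = 7)
  expect_equal(pc$ncomp, 1L)
  expect_true(all(pc$press >= 0))
  pc2 <- select_components_press(X, y, max_ncomp = 5, n_perm = 60, seed = 7)
  expect_identical(pc$press, pc2$press)
  expect_error(select_components_press(X, y, 5, 10, inner_fraction = 1.5),
               "in \\(0, 1\\)")
})

test_that("PRESS equals an independently coded split-refit-accumulate loop", {
  set.seed(8)
  X <- matrix(rnorm(24 * 15), 24, 15)
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(24, 0, 0.2)
  n_perm <- 25; A <- 3; frac <- 0.9
  pc <- select_components_press(X, y, max_ncomp = A, n_perm = n_perm,
                                inner_fraction = frac, seed = 11)
  n_in <- round(frac * nrow(X))
  set.seed(11)
  sse <- matrix(0, n_perm, A)
  for (p in seq_len(n_perm)) {
    tr <- sample(nrow(X), n_in)
    te <- setdiff(seq_len(nrow(X)), tr)
    for (a in seq_len(A)) {
      pred <- pls_krylov_predict(X[tr, ], y[tr], a, X[te, , drop = FALSE])
      sse[p, a] <- sum((pred - y[te])^2)
    }
  }
  expect_equal(pc$press, colMeans(sse), tolerance = 1e-6)
})

test_that("evaluation metrics follow their published definitions", {
  expect_equal(evaluate_predictions(1:5, 1:5)$r2, 1)
  expect_equal(evaluate_predictions(1:5, 1:5)$rmse, 0)
  # hand-summed 5-point oracle
  p <- c(1, 2, 3, 4, 5); o <- c(1.2, 1.9, 3.3, 3.9, 5.1)
  ev <- evaluate_predictions(p, o)
  expect_equal(ev$rmse, sqrt(sum((p - o)^2) / 5), tolerance = 1e-12)
  expect_equal(ev$r2, (sum((p - mean(p)) * (o - mean(o))) /
                         sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2)))^2,
               tolerance = 1e-12)
  expect_equal(ev$rel_rmse_pct, 100 * ev$rmse / (max(o) - min(o)),
               tolerance = 1e-12)
  expect_error(evaluate_predictions(1:3, rep(1, 3)), "zero range")
})

test_that("VIP satisfies the Wold identities and flags active wavelengths", {
  set.seed(9)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- drop(X %*% rnorm(20)) + rnorm(30, 0, 0.1)
  m <- fit_plsr(X, y, ncomp = 4)
  v <- vip(m)
  expect_equal(sum(v$vip^2), 20, tolerance = 1e-10)

  y1 <- 2 * X[, 7] + rnorm(30, 0, 0.05)
  m1 <- fit_plsr(X, y1, ncomp = 3)
  expect_equal(which.max(vip(m1)$vip), 7L)
  expect_true(vip(m1)$important[7])

  mA1 <- fit_plsr(X, y, ncomp = 1)
  vA1 <- vip(mA1)$vip
  expect_equal(vA1 / max(vA1), abs(mA1$W[, 1]) / max(abs(mA1$W[, 1])),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("standardized coefficients are unit-invariant for autoscaled fits", {
  set.seed(10)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- drop(X %*% c(1, -2, 0.5, 0, 0, 1)) + rnorm(30, 0, 0.2)
  m1 <- fit_plsr(X, y, ncomp = 4, scale = TRUE)
  X2 <- X; X2[, 2] <- X2[, 2] * 1000
  m2 <- fit_plsr(X2, y, ncomp = 4, scale = TRUE)
  expect_equal(standardized_coefficients(m1)$standardized,
               standardized_coefficients(m2)$standardized,
               tolerance = 1e-8)
})

test_that("PLSR models survive a JSON round trip", {
  set.seed(12)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rnorm(20)
  m <- fit_plsr(X, y, ncomp = 3)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_plsr_model(m, tmp)
  back <- read_plsr_model(tmp)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-12)
  expect_equal(back$ncomp, m$ncomp)
})

test_that("noise-free simulated panels are predicted perfectly", {
  pan <- simulate_accession_panel(n_plants = 3, n_reps = 2, noise_sd = 0,
                                  seed = 13)
  sp <- resample_5nm(pan$spectra)
  prof <- pan$profiles[match(sample_ids(sp), pan$profiles$sample_id), ]
  tot <- prof$H16 + prof$Oct + prof$Tri
  names(tot) <- prof$sample_id
  plan <- stratified_split(tot, seed = 14)
  for (w in c("H16", "Oct", "Tri")) {
    ycal <- prof[[w]][match(plan$calibration, prof$sample_id)]
    yval <- prof[[w]][match(plan$validation, prof$sample_id)]
    m <- fit_plsr(sp[plan$calibration], ycal, ncomp = 3)
    ev <- evaluate_predictions(predict(m, sp[plan$validation]), yval)
    expect_gt(ev$r2, 0.9999)
  }
})
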