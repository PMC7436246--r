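# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, without touching the package's own code
# path for that quantity.

# PLS1 predictions via the Krylov-subspace characterization: the fitted
# values of a PLS1 model with A components equal the least-squares
# projection of y onto span{X'y, (X'X)X'y, ..., (X'X)^(A-1) X'y} applied to
# the centered predictors. Basis built with modified Gram-Schmidt in
# coefficient space for numerical stability.
pls_krylov_predict <- function(X, y, ncomp, newX = X) {
  X <- as.matrix(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  yc <- y - mean(y)
  S <- crossprod(Xc)
  V <- matrix(0, ncol(X), ncomp)
  v <- crossprod(Xc, yc)[, 1]
  for (a in seq_len(ncomp)) {
    for (b in seq_len(a - 1)) v <- v - sum(v * V[, b]) * V[, b]
    v <- v / sqrt(sum(v^2))
    V[, a] <- v
    v <- S %*% v
  }
  Z <- Xc %*% V
  beta <- qr.solve(qr(Z), yc)
  coefs <- V %*% beta
  drop(sweep(as.matrix(newX), 2, xm) %*% coefs) + mean(y)
}

# Exhaustive local-extrema scan: every interior point that is a positive
# local maximum or negative local minimum with |value| >= min_prominence,
# thinned greedily strongest-first under the separation constraint.
brute_extrema <- function(wl, v, min_prominence, min_separation) {
  cand <- integer(0)
  for (i in 2:(length(v) - 1)) {
    up <- v[i] > 0 && v[i] >= v[i - 1] && v[i] >= v[i + 1]
    dn <- v[i] < 0 && v[i] <= v[i - 1] && v[i] <= v[i + 1]
    if ((up || dn) && abs(v[i]) >= min_prominence) cand <- c(cand, i)
  }
  keep <- integer(0)
  for (i in cand[order(-abs(v[cand]))]) {
    if (!length(keep) || all(abs(wl[i] - wl[keep]) >= min_separation)) {
      keep <- c(keep, i)
    }
  }
  sort(wl[keep])
}

# Brute-force conditional genotype probability at a hidden locus between
# (or beside) observed F2 marker genotypes, by enumerating the allele paths
# of both gametes over the three loci. Distances in cM; observed genotypes
# as B-allele counts (0/1/2) or NA.
enum_geno_prob <- function(gl, gr, d_left, d_right) {
  r1 <- (1 - exp(-2 * d_left / 100)) / 2
  r2 <- (1 - exp(-2 * d_right / 100)) / 2
  step <- function(a, b, r) if (a == b) 1 - r else r
  joint <- matrix(0, 3, 3)        # joint over (g_hidden, counted later)
  p_hidden <- numeric(3)
  norm <- 0
  for (aL1 in 0:1) for (aM1 in 0:1) for (aR1 in 0:1)
    for (aL2 in 0:1) for (aM2 in 0:1) for (aR2 in 0:1) {
      pr <- 0.25 * step(aL1, aM1, r1) * step(aM1, aR1, r2) *
        step(aL2, aM2, r1) * step(aM2, aR2, r2)
      gL <- aL1 + aL2; gM <- aM1 + aM2; gR <- aR1 + aR2
      ok <- (is.na(gl) || gL == gl) && (is.na(gr) || gR == gr)
      if (ok) {
        p_hidden[gM + 1] <- p_hidden[gM + 1] + pr
        norm <- norm + pr
      }
    }
  p_hidden / norm
}

# Direct two-degree-of-freedom regression LOD at a fully typed marker.
direct_marker_lod <- function(geno_codes, y) {
  xa <- geno_codes - 1
  xd <- as.numeric(geno_codes == 1)
  fit1 <- lm(y ~ xa + xd)
  rss1 <- sum(resid(fit1)^2)
  rss0 <- sum((y - mean(y))^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

# Widest contiguous region around the maximum where lod >= max - drop,
# found by exhaustive scanning of all contiguous windows containing the max.
brute_lod_interval <- function(pos, lod, drop = 1.5) {
  k <- which.max(lod)
  thr <- lod[k] - drop
  best <- c(k, k)
  for (lo in 1:k) for (hi in k:length(lod)) {
    if (all(lod[lo:hi] >= thr) && (hi - lo) > (best[2] - best[1])) {
      best <- c(lo, hi)
    }
  }
  c(pos[best[1]], pos[best[2]])
}

# Hand-rolled balanced two-way ANOVA sums of squares.
balanced_anova_ss <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  n <- length(y)
  gm <- mean(y)
  ssa <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cells <- tapply(y, list(A, B), mean)
  counts <- table(A, B)
  ssab <- 0
  for (i in seq_len(nrow(cells))) for (j in seq_len(ncol(cells))) {
    exp_ij <- mean(y[A == levels(A)[i]]) + mean(y[B == levels(B)[j]]) - gm
    ssab <- ssab + counts[i, j] * (cells[i, j] - exp_ij)^2
  }
  sst <- sum((y - gm)^2)
  c(A = ssa, B = ssb, AB = ssab, resid = sst - ssa - ssb - ssab, total = sst)
}

# Tukey-adjusted p-value for one pairwise contrast from means/SEs.
ptukey_pvalue <- function(diff, se_diff, n_means, df) {
  1 - ptukey(abs(diff) / (se_diff / sqrt(2)), n_means, df)
}

# Small random spectra fixture: smooth mixture of Gaussian bumps.
random_derivative_spectrum <- function(seed, grid = seq(350, 2500, by = 5),
                                       n_bumps = 8) {
  set.seed(seed)
  v <- numeric(length(grid))
  centers <- runif(n_bumps, 400, 2450)
  for (k in seq_len(n_bumps)) {
    v <- v + runif(1, -1, 1) * exp(-(grid - centers[k])^2 / (2 * runif(1, 8, 30)^2))
  }
  spectra(grid, matrix(v, ncol = 1, dimnames = list(NULL, "r")),
          kind = "first_derivative")
}

# Two-chromosome toy map for fast QTL tests.
toy_map <- function() {
  rbind(
    data.frame(marker = sprintf("m1_%d", 0:6), chr = "1",
               pos_cM = seq(0, 60, by = 10), stringsAsFactors = FALSE),
    data.frame(marker = sprintf("m2_%d", 0:6), chr = "2",
               pos_cM = seq(0, 60, by = 10), stringsAsFactors = FALSE)
  )
}
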