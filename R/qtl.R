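#' Haldane map function
#'
#' Converts a map distance in centimorgans to a recombination fraction,
#' `r = (1 - exp(-2d/100)) / 2`, assuming no crossover interference.
#'
#' @param d_cM Non-negative map distance (cM); vectorized.
#' @return Recombination fraction(s) in [0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distance must be non-negative", call. = FALSE)
  (1 - exp(-2 * d_cM / 100)) / 2
}

# F2 genotype transition matrix between two loci with recombination r:
# rows = genotype at locus 1, cols at locus 2, states AA/AB/BB (B-allele
# count 0/1/2); the two gametes recombine independently.
f2_transition <- function(r) {
  s <- 1 - r
  matrix(c(s^2,     2 * r * s,     r^2,
           r * s,   s^2 + r^2,     r * s,
           r^2,     2 * r * s,     s^2),
         3L, 3L, byrow = TRUE)
}

#' Conditional genotype probabilities on a pseudomarker grid
#'
#' Evaluates P(genotype | flanking observed markers) every `step` cM (plus
#' at all marker positions) under the two-gamete Markov model with Haldane
#' recombination and no interference. For each individual, the nearest
#' non-missing typed marker on each side is used; missing markers are
#' skipped. At a typed non-missing marker the probabilities are an
#' indicator; with no informative flank the 1:2:1 prior applies.
#'
#' @param genotypes Character matrix individuals x markers (`AA`/`AB`/`BB`/
#'   `NA`), columns named by markers of `map`.
#' @param map Map data frame (`marker`, `chr`, `pos_cM`).
#' @param step Grid step in cM; default 1.
#' @return Object of class `geno_prob_grid`: `positions` (data frame `chr`,
#'   `pos_cM`, `marker` — NA for pseudomarkers), `prob` (array
#'   individuals x positions x 3, genotype order AA/AB/BB), `map`.
#' @export
genotype_probs <- function(genotypes, map, step = 1) {
  map <- validate_map(map)
  if (!all(map$marker %in% colnames(genotypes))) {
    stop("genotype matrix lacks some map markers", call. = FALSE)
  }
  genotypes <- genotypes[, map$marker, drop = FALSE]
  n <- nrow(genotypes)
  code <- matrix(match(genotypes, c("AA", "AB", "BB")), n,
                 ncol(genotypes))  # 1/2/3, NA missing
  pos_list <- list()
  prob_list <- list()
  for (ch in unique(map$chr)) {
    midx <- which(map$chr == ch)
    mpos <- map$pos_cM[midx]
    if (all(is.na(code[, midx]))) {
      stop(sprintf("chromosome %s has no typed markers", ch), call. = FALSE)
    }
    grid <- sort(unique(c(seq(min(mpos), max(mpos), by = step), mpos)))
    gmark <- map$marker[midx][match(grid, mpos)]
    # per individual, index of nearest informative marker at/left and
    # at/right of each grid point
    cc <- code[, midx, drop = FALSE]
    probs <- array(NA_real_, c(n, length(grid), 3L))
    # precompute, per individual, sorted positions of informative markers
    info <- lapply(seq_len(n), function(i) which(!is.na(cc[i, ])))
    for (g in seq_along(grid)) {
      gp <- grid[g]
      # group individuals by their (left, right) informative marker pair
      lr <- vapply(seq_len(n), function(i) {
        ii <- info[[i]]
        l <- ii[mpos[ii] <= gp]
        r <- ii[mpos[ii] >= gp]
        c(if (length(l)) max(l) else NA_integer_,
          if (length(r)) min(r) else NA_integer_)
      }, integer(2L))
      key <- paste(lr[1L, ], lr[2L, ], sep = "|")
      for (k in unique(key)) {
        members <- which(key == k)
        l <- lr[1L, members[1L]]; r <- lr[2L, members[1L]]
        if (!is.na(l) && mpos[l] == gp) {          # at a typed marker
          M <- diag(3L)[code_at(cc, members, l), , drop = FALSE]
        } else if (is.na(l) && is.na(r)) {         # no information
          M <- matrix(rep(c(0.25, 0.5, 0.25), each = length(members)),
                      length(members), 3L)
        } else if (is.na(r)) {                     # left flank only
          Tl <- f2_transition(haldane_r(gp - mpos[l]))
          M <- Tl[code_at(cc, members, l), , drop = FALSE]
        } else if (is.na(l)) {                     # right flank only
          Tr <- f2_transition(haldane_r(mpos[r] - gp))
          M <- Tr[code_at(cc, members, r), , drop = FALSE]
        } else {                                   # both flanks
          Tl <- f2_transition(haldane_r(gp - mpos[l]))
          Tr <- f2_transition(haldane_r(mpos[r] - gp))
          Tlr <- f2_transition(haldane_r(mpos[r] - mpos[l]))
          gl <- code_at(cc, members, l); gr <- code_at(cc, members, r)
          M <- t(vapply(seq_along(members), function(j) {
            num <- Tl[gl[j], ] * Tr[, gr[j]]
            num / Tlr[gl[j], gr[j]]
          }, numeric(3L)))
        }
        probs[members, g, ] <- M
      }
    }
    pos_list[[ch]] <- data.frame(chr = ch, pos_cM = grid, marker = gmark,
                                 stringsAsFactors = FALSE)
    prob_list[[ch]] <- probs
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  prob <- array(NA_real_, c(n, nrow(positions), 3L),
                dimnames = list(rownames(genotypes), NULL,
                                c("AA", "AB", "BB")))
  off <- 0L
  for (ch in names(prob_list)) {
    w <- dim(prob_list[[ch]])[2L]
    prob[, off + seq_len(w), ] <- prob_list[[ch]]
    off <- off + w
  }
  structure(list(positions = positions, prob = prob, map = map),
            class = "geno_prob_grid")
}

code_at <- function(cc, members, j) cc[members, j]

#' @export
print.geno_prob_grid <- function(x, ...) {
  cat(sprintf("<geno_prob_grid> %d individuals x %d positions on %d chromosome(s)\n",
              dim(x$prob)[1L], dim(x$prob)[2L], length(unique(x$positions$chr))))
  invisible(x)
}

# additive / dominance regression codes at every position:
# xa = P(BB) - P(AA) (positive additive effect = waxy-parent allele B
# increases the trait), xd = P(AB).
hk_codes <- function(grid) {
  list(xa = grid$prob[, , "BB"] - grid$prob[, , "AA"],
       xd = grid$prob[, , "AB"])
}

# columns for covariate markers (expected codes at their positions)
covariate_design <- function(grid, markers) {
  idx <- match(markers, grid$positions$marker)
  if (anyNA(idx)) {
    stop("covariate marker(s) not on the probability grid", call. = FALSE)
  }
  codes <- hk_codes(grid)
  X <- cbind(codes$xa[, idx, drop = FALSE], codes$xd[, idx, drop = FALSE])
  colnames(X) <- c(paste0(markers, "_a"), paste0(markers, "_d"))
  list(X = X, pos = grid$positions$pos_cM[idx], chr = grid$positions$chr[idx])
}

rss_of <- function(X, y) {
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Haley-Knott genome scan
#'
#' At every grid position, regresses the phenotype on an intercept, the
#' additive code `P(BB) - P(AA)`, and the dominance code `P(AB)` (plus any
#' covariate-marker codes), and reports
#' `LOD = (n/2) * log10(RSS0 / RSS1)` against the null model with the same
#' covariates. Covariates within `window` cM of the test position (on its
#' chromosome) are dropped from both models at that position.
#'
#' @param grid A [genotype_probs()] object.
#' @param phenotype Numeric vector, one value per individual (NA dropped
#'   listwise).
#' @param covariate_markers Optional character vector of marker names used
#'   as additive+dominance covariates; default none (plain interval
#'   mapping).
#' @param window Exclusion window around the test position in cM; default 10.
#' @return Object of class `scan_result`: `positions` data frame (`chr`,
#'   `pos_cM`, `marker`, `lod`), `max` (row index of the maximum), `n`,
#'   `covariate_markers`, and `threshold` (NA until set).
#' @export
hk_scan <- function(grid, phenotype, covariate_markers = NULL, window = 10) {
  stopifnot(inherits(grid, "geno_prob_grid"))
  n_all <- dim(grid$prob)[1L]
  if (length(phenotype) != n_all) {
    stop("`phenotype` must have one value per individual", call. = FALSE)
  }
  use <- which(!is.na(phenotype))
  y <- phenotype[use]
  n <- length(y)
  codes <- hk_codes(grid)
  xa <- codes$xa[use, , drop = FALSE]
  xd <- codes$xd[use, , drop = FALSE]
  cov <- if (length(covariate_markers)) {
    covariate_design(grid, covariate_markers)
  } else NULL
  if (!is.null(cov)) cov$X <- cov$X[use, , drop = FALSE]
  npos <- nrow(grid$positions)
  lod <- numeric(npos)
  ones <- rep(1, n)
  for (g in seq_len(npos)) {
    keep_cov <- NULL
    if (!is.null(cov)) {
      far <- cov$chr != grid$positions$chr[g] |
        abs(cov$pos - grid$positions$pos_cM[g]) > window
      keep_cov <- cov$X[, rep(far, 2L), drop = FALSE]
    }
    X0 <- cbind(ones, keep_cov)
    X1 <- cbind(X0, xa[, g], xd[, g])
    lod[g] <- (n / 2) * log10(rss_of(X0, y) / rss_of(X1, y))
  }
  lod <- pmax(lod, 0)
  positions <- grid$positions
  positions$lod <- lod
  structure(list(positions = positions, max = which.max(lod), n = n,
                 covariate_markers = covariate_markers, window = window,
                 threshold = NA_real_),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  mx <- x$positions[x$max, ]
  cat(sprintf("<scan_result> %d positions; max LOD %.2f at chr %s, %.1f cM%s\n",
              nrow(x$positions), mx$lod, mx$chr, mx$pos_cM,
              if (is.na(x$threshold)) ""
              else sprintf(" (threshold %.2f)", x$threshold)))
  invisible(x)
}

#' Plot a LOD curve
#' @param x A `scan_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scan_result <- function(x, ...) {
  chrs <- unique(x$positions$chr)
  offs <- setNames(cumsum(c(0, head(vapply(chrs, function(ch) {
    max(x$positions$pos_cM[x$positions$chr == ch]) + 10
  }, numeric(1L)), -1L))), chrs)
  xx <- x$positions$pos_cM + offs[x$positions$chr]
  graphics::plot(xx, x$positions$lod, type = "l", xlab = "position",
                 ylab = "LOD", ...)
  if (!is.na(x$threshold)) graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Permutation LOD threshold
#'
#' Genome-wide significance threshold: the `1 - alpha` sample quantile
#' (linear interpolation) of the maximum LOD over random permutations of
#' the phenotype. The scan design at each position is fixed, so the
#' permutation scans reduce to projections onto precomputed orthonormal
#' bases, making the 1000-permutation default fast.
#'
#' @param grid A [genotype_probs()] object.
#' @param phenotype Numeric phenotype vector (NA dropped listwise).
#' @param n_perm Number of permutations (>= 100); default 1000.
#' @param alpha Significance level; default 0.05.
#' @param seed Optional integer seed.
#' @return Numeric threshold, with the vector of permutation maxima as
#'   attribute `max_lods`.
#' @export
perm_threshold <- function(grid, phenotype, n_perm = 1000L, alpha = 0.05,
                           seed = NULL) {
  stopifnot(inherits(grid, "geno_prob_grid"))
  if (n_perm < 100L) stop("`n_perm` must be at least 100", call. = FALSE)
  use <- which(!is.na(phenotype))
  y <- phenotype[use]
  n <- length(y)
  if (n < 10L) stop("too few phenotyped individuals to permute", call. = FALSE)
  codes <- hk_codes(grid)
  npos <- nrow(grid$positions)
  Qs <- lapply(seq_len(npos), function(g) {
    qr.Q(qr(cbind(1, codes$xa[use, g], codes$xd[use, g])))
  })
  with_seed(seed, {
    Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
    yss <- colSums(Y^2)
    rss0 <- yss - n * colMeans(Y)^2
    maxlod <- rep(-Inf, n_perm)
    for (g in seq_len(npos)) {
      proj <- crossprod(Qs[[g]], Y)      # k x n_perm
      rss1 <- pmax(yss - colSums(proj^2), 1e-12)
      maxlod <- pmax(maxlod, (n / 2) * log10(rss0 / rss1))
    }
    thr <- unname(quantile(maxlod, 1 - alpha, type = 7))
    attr(thr, "max_lods") <- maxlod
    thr
  })
}

#' 1.5-LOD support interval
#'
#' The widest contiguous region, on the chromosome of the scan maximum,
#' over which the LOD stays within `drop` of the maximum, together with the
#' nearest typed markers outside each end (the flanking SNPs).
#'
#' @param scan A `scan_result`.
#' @param drop LOD drop defining the interval; default 1.5.
#' @return List: `chr`, `peak_pos`, `peak_marker` (nearest typed marker to
#'   the peak), `lo`, `hi` (interval ends, cM), `flank_lo`, `flank_hi`
#'   (marker names; the terminal marker when the interval reaches the
#'   chromosome end).
#' @export
lod_interval <- function(scan, drop = 1.5) {
  stopifnot(inherits(scan, "scan_result"))
  pk <- scan$max
  ch <- scan$positions$chr[pk]
  on_chr <- which(scan$positions$chr == ch)
  lodc <- scan$positions$lod[on_chr]
  posc <- scan$positions$pos_cM[on_chr]
  k <- match(pk, on_chr)
  thr <- lodc[k] - drop
  lo <- k
  while (lo > 1L && lodc[lo - 1L] >= thr) lo <- lo - 1L
  hi <- k
  while (hi < length(lodc) && lodc[hi + 1L] >= thr) hi <- hi + 1L
  typed <- !is.na(scan$positions$marker[on_chr])
  nearest_out <- function(side) {
    if (side == "lo") {
      cand <- which(typed & posc < posc[lo])
      if (length(cand)) max(cand) else which(typed)[1L]
    } else {
      cand <- which(typed & posc > posc[hi])
      if (length(cand)) min(cand) else rev(which(typed))[1L]
    }
  }
  peak_marker <- {
    tidx <- which(typed)
    tidx[which.min(abs(posc[tidx] - posc[k]))]
  }
  list(chr = ch, peak_pos = posc[k],
       peak_marker = scan$positions$marker[on_chr][peak_marker],
       lo = posc[lo], hi = posc[hi],
       flank_lo = scan$positions$marker[on_chr][nearest_out("lo")],
       flank_hi = scan$positions$marker[on_chr][nearest_out("hi")])
}

#' Fit a single-QTL model at a position
#'
#' Haley-Knott regression of the phenotype on the additive and dominance
#' codes at one grid position. The additive effect is half the BB-AA
#' contrast (positive = waxy-parent allele increases the trait); the
#' dominance effect is AB minus the homozygote midpoint; the percent
#' variance explained is `100 * (1 - RSS1/RSS0)`.
#'
#' @param grid A [genotype_probs()] object.
#' @param phenotype Numeric phenotype vector (NA dropped listwise).
#' @param chr Chromosome of the position.
#' @param pos_cM Position (must be on the grid).
#' @return Object of class `qtl_fit`: `chr`, `pos_cM`, `additive`,
#'   `dominance`, `pct_var`, `lod`, `n`.
#' @export
fit_qtl <- function(grid, phenotype, chr, pos_cM) {
  stopifnot(inherits(grid, "geno_prob_grid"))
  g <- which(grid$positions$chr == as.character(chr) &
             abs(grid$positions$pos_cM - pos_cM) < 1e-9)
  if (length(g) != 1L) stop("position not on the probability grid", call. = FALSE)
  use <- which(!is.na(phenotype))
  y <- phenotype[use]
  n <- length(y)
  codes <- hk_codes(grid)
  X1 <- cbind(1, codes$xa[use, g], codes$xd[use, g])
  fit <- lm.fit(X1, y)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  structure(list(chr = as.character(chr), pos_cM = pos_cM,
                 additive = unname(coef(fit)[2L]),
                 dominance = unname(coef(fit)[3L]),
                 pct_var = 100 * (1 - rss1 / rss0),
                 lod = (n / 2) * log10(rss0 / rss1), n = n),
            class = "qtl_fit")
}

#' @export
print.qtl_fit <- function(x, ...) {
  cat(sprintf("<qtl_fit> chr %s @ %.1f cM: a=%.3f d=%.3f, %.1f%% var, LOD %.2f\n",
              x$chr, x$pos_cM, x$additive, x$dominance, x$pct_var, x$lod))
  invisible(x)
}

#' Greedy stepwise QTL search
#'
#' Forward addition of QTL: starting from the null model, repeatedly scans
#' with the already-selected QTL positions as covariates (excluded within
#' `window` cM of the test position) and adds the maximum-LOD position
#' while its conditional LOD gain exceeds `penalty` (typically the
#' permutation threshold). All effects are refit jointly at the end.
#'
#' @param grid A [genotype_probs()] object.
#' @param phenotype Numeric phenotype vector.
#' @param penalty LOD penalty per added QTL (e.g. a [perm_threshold()]).
#' @param max_qtl Maximum number of QTL to add; default 5.
#' @param window Covariate exclusion window (cM); default 10.
#' @return Data frame (possibly empty) with one row per QTL: `chr`,
#'   `pos_cM`, `additive`, `dominance`, `lod_gain`, plus attribute
#'   `pct_var_joint` (percent variance of the joint model).
#' @export
stepwise_search <- function(grid, phenotype, penalty, max_qtl = 5L,
                            window = 10) {
  stopifnot(inherits(grid, "geno_prob_grid"))
  use <- which(!is.na(phenotype))
  y <- phenotype[use]
  n <- length(y)
  codes <- hk_codes(grid)
  sel <- integer(0)
  gains <- numeric(0)
  repeat {
    if (length(sel) >= max_qtl) break
    Xcov <- cbind(rep(1, n))
    for (s in sel) Xcov <- cbind(Xcov, codes$xa[use, s], codes$xd[use, s])
    rss0 <- rss_of(Xcov, y)
    best_g <- NA_integer_; best_lod <- -Inf
    for (g in seq_len(nrow(grid$positions))) {
      near_sel <- any(grid$positions$chr[sel] == grid$positions$chr[g] &
                      abs(grid$positions$pos_cM[sel] -
                          grid$positions$pos_cM[g]) <= window)
      if (isTRUE(near_sel)) next
      X1 <- cbind(Xcov, codes$xa[use, g], codes$xd[use, g])
      lod <- (n / 2) * log10(rss0 / rss_of(X1, y))
      if (lod > best_lod) { best_lod <- lod; best_g <- g }
    }
    if (!is.finite(best_lod) || best_lod <= penalty) break
    sel <- c(sel, best_g)
    gains <- c(gains, best_lod)
  }
  if (!length(sel)) {
    out <- data.frame(chr = character(0), pos_cM = numeric(0),
                      additive = numeric(0), dominance = numeric(0),
                      lod_gain = numeric(0))
    attr(out, "pct_var_joint") <- 0
    return(out)
  }
  Xj <- cbind(rep(1, n))
  for (s in sel) Xj <- cbind(Xj, codes$xa[use, s], codes$xd[use, s])
  fit <- lm.fit(Xj, y)
  rssj <- sum(fit$residuals^2)
  rss_null <- sum((y - mean(y))^2)
  cf <- coef(fit)
  out <- data.frame(
    chr = grid$positions$chr[sel],
    pos_cM = grid$positions$pos_cM[sel],
    additive = cf[seq_along(sel) * 2L],
    dominance = cf[seq_along(sel) * 2L + 1L],
    lod_gain = gains,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "pct_var_joint") <- 100 * (1 - rssj / rss_null)
  out
}
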