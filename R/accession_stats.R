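#' Two-way fixed-effects ANOVA for accession wax amounts
#'
#' Fits `y = mu + accession + repetition + accession:repetition + error`
#' with both factors fixed, the model used to estimate accession means.
#' When empty accession-by-repetition cells make the interaction
#' inestimable the model is refit without it and flagged. Sums of squares
#' are Type II (sequential Type I is also retained); marginal accession
#' means are least-squares (estimated marginal) means with standard errors.
#'
#' @param values Numeric response (adjusted peak areas).
#' @param accession Factor (or coercible) of accession labels.
#' @param repetition Factor (or coercible) of repetition labels.
#' @return Object of class `wax_anova`: `lm` (the fit), `anova` (Type II
#'   table), `anova_seq` (Type I), `means` (data frame `accession`,
#'   `emmean`, `se`, `df`, `arith_mean`), `interaction_dropped`.
#' @export
fit_anova <- function(values, accession, repetition) {
  accession <- factor(accession)
  repetition <- factor(repetition)
  if (nlevels(accession) < 2L) stop("need at least 2 accessions", call. = FALSE)
  if (!any(table(accession, repetition) >= 2L)) {
    stop("need at least one cell with 2+ replicates", call. = FALSE)
  }
  d <- data.frame(y = as.numeric(values), accession = accession,
                  repetition = repetition)
  dropped <- any(table(accession, repetition) == 0L)
  fml <- if (dropped) y ~ accession + repetition else
    y ~ accession * repetition
  fit <- lm(fml, data = d)
  a2 <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  emm <- emmeans::emmeans(fit, "accession")
  ems <- as.data.frame(emm)
  arith <- tapply(d$y, d$accession, mean)
  means <- data.frame(accession = as.character(ems$accession),
                      emmean = ems$emmean, se = ems$SE, df = ems$df,
                      arith_mean = as.numeric(arith[as.character(ems$accession)]),
                      stringsAsFactors = FALSE)
  structure(list(lm = fit, anova = a2, anova_seq = anova(fit),
                 emmeans = emm, means = means,
                 interaction_dropped = dropped),
            class = "wax_anova")
}

#' @export
print.wax_anova <- function(x, ...) {
  cat("<wax_anova>", if (x$interaction_dropped) "(interaction dropped)", "\n")
  print(x$means)
  invisible(x)
}

#' Tukey HSD compact letter display
#'
#' All pairwise accession comparisons with Tukey (studentized-range)
#' adjustment, summarized as compact letters by the insert-and-absorb
#' algorithm: two accessions share a letter exactly when their adjusted
#' pairwise difference is not significant at `alpha`. Letters are assigned
#' in order of increasing marginal mean.
#'
#' @param model A [fit_anova()] result.
#' @param alpha Significance level; default 0.05.
#' @return Data frame with columns `accession`, `emmean`, `letters`;
#'   attribute `pairs` holds the adjusted pairwise comparisons.
#' @export
tukey_letters <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "wax_anova"))
  if (sum(model$lm$residuals^2) < 1e-25) {
    stop("zero residual variance: pairwise tests undefined", call. = FALSE)
  }
  prs <- as.data.frame(emmeans::contrast(model$emmeans, method = "pairwise",
                                         adjust = "tukey"))
  split_pair <- function(s) {
    # emmeans labels pairs "a - b" (names with spaces become "(a b)")
    s <- gsub("[()]", "", s)
    strsplit(s, " - ", fixed = TRUE)[[1L]]
  }
  groups <- model$means$accession[order(model$means$emmean)]
  sig <- prs$p.value < alpha
  sig_pairs <- lapply(which(sig), function(i) split_pair(prs$contrast[i]))
  letters_for <- insert_absorb(groups, sig_pairs)
  out <- data.frame(accession = groups,
                    emmean = model$means$emmean[match(groups,
                                                      model$means$accession)],
                    letters = letters_for, stringsAsFactors = FALSE)
  attr(out, "pairs") <- prs
  out
}

# Compact letter display by insert-and-absorb: maintain letter columns
# (sets of groups); for each significantly different pair occurring in a
# shared column, duplicate the column and delete one member from each copy,
# then absorb columns contained in others. Groups share a letter iff no
# significant difference separates them.
insert_absorb <- function(groups, sig_pairs) {
  cols <- list(groups)
  for (pr in sig_pairs) {
    i <- 1L
    while (i <= length(cols)) {
      cc <- cols[[i]]
      if (all(pr %in% cc)) {
        cols[[i]] <- setdiff(cc, pr[1L])
        cols <- append(cols, list(setdiff(cc, pr[2L])), after = i)
        i <- i + 2L
      } else i <- i + 1L
    }
    # absorb duplicated/contained columns
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a != b && keep[b] && keep[a] &&
            all(cols[[a]] %in% cols[[b]]) &&
            (length(cols[[a]]) < length(cols[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    cols <- cols[keep]
  }
  # order columns by the position of their first group for stable letters
  first <- vapply(cols, function(cc) min(match(cc, groups)), numeric(1L))
  cols <- cols[order(first)]
  vapply(groups, function(g) {
    paste(letters[which(vapply(cols, function(cc) g %in% cc, logical(1L)))],
          collapse = "")
  }, character(1L))
}

#' Per-sample wax percentage profiles
#'
#' Converts an eight-wax amount profile into percentages of the sample's
#' total wax: `100 * amount / sum(amounts)` per row.
#'
#' @param profile Data frame with a `sample_id` column (or rownames) and
#'   one non-negative numeric column per wax.
#' @param waxes Wax column names; default [wax_names()] intersected with
#'   the available columns.
#' @return Data frame of the same shape with percentages; rows sum to 100.
#' @export
wax_proportions <- function(profile, waxes = NULL) {
  profile <- as.data.frame(profile)
  if (is.null(waxes)) waxes <- intersect(wax_names(), names(profile))
  if (!length(waxes)) stop("no wax columns found", call. = FALSE)
  amounts <- as.matrix(profile[, waxes, drop = FALSE])
  if (any(amounts < 0)) stop("wax amounts must be non-negative", call. = FALSE)
  tot <- rowSums(amounts)
  if (any(tot == 0)) stop("sample(s) with zero total wax", call. = FALSE)
  pct <- 100 * amounts / tot
  out <- profile
  out[, waxes] <- pct
  out
}
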