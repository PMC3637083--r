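# Supporting group statistics: pooled two-sample t (raw and from printed
# summaries), 2x2 Pearson chi-square without continuity correction, Pearson
# correlation, Kendall tau-b, and one-factor/one-covariate ANCOVA.

#' Pooled two-sample t test from summary statistics
#'
#' Student's pooled-variance t with df = n1 + n2 - 2 and a two-tailed p,
#' computable directly from printed group summaries (mean, SD, n).  A zero
#' pooled variance is handled by convention: p = 1 when the means are equal,
#' p = 0 otherwise.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return A \linkS4class{StatResult} (estimate = mean difference).
#' @export
twoSampleTFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  diff <- mean1 - mean2
  if (sp2 == 0) {
    stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    stat <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(stat), df)
  }
  new("StatResult", statistic = stat, df = df, p.value = p, estimate = diff,
      method = "Two-sample t (pooled)")
}

#' Pooled two-sample t test from raw data
#'
#' @param x,y numeric vectors, one per group.
#' @return A \linkS4class{StatResult}.
#' @export
twoSampleT <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(twoSampleTFromSummary(mean(x), 0, length(x), mean(y), 0, length(y)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  new("StatResult", statistic = unname(tt$statistic),
      df = unname(tt$parameter), p.value = tt$p.value,
      estimate = mean(x) - mean(y), method = "Two-sample t (pooled)")
}

#' 2x2 Pearson chi-square without continuity correction
#'
#' statistic = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), df = 1, two-tailed p.
#' A zero marginal makes the statistic 0 with p = 1 (documented convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = group,
#'   columns = outcome), or the counts a, b, c, d given separately.
#' @param b,c,d counts when \code{tab} is the scalar a.
#' @return A \linkS4class{StatResult}.
#' @export
chiSquare2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) tab <- matrix(c(tab, c, b, d), 2, 2)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  n <- sum(tab)
  if (n < 1) stop("total count must be >= 1")
  a <- tab[1, 1]; bb <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
  marg <- c(a + bb, cc + dd, a + cc, bb + dd)
  if (any(marg == 0)) {
    stat <- 0; p <- 1
  } else {
    stat <- n * (a * dd - bb * cc)^2 / prod(marg)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  new("StatResult", statistic = stat, df = 1, p.value = p,
      method = "Pearson chi-square (2x2, uncorrected)")
}

#' Pearson correlation with t-based p value
#'
#' @param x,y numeric vectors, n >= 3, both nonconstant.
#' @return A \linkS4class{StatResult} (estimate = r, df = n - 2).
#' @export
pearsonR <- function(x, y) {
  n <- length(x)
  if (n < 3 || n != length(y)) stop("need n >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  new("StatResult", statistic = unname(ct$statistic),
      df = unname(ct$parameter), p.value = ct$p.value,
      estimate = unname(ct$estimate), method = "Pearson correlation")
}

#' Kendall tau-b with normal-approximation p value
#'
#' Tie-corrected tau-b with a two-tailed p from the normal approximation.
#'
#' @param x,y numeric vectors, n >= 3, not all pairs tied.
#' @return A \linkS4class{StatResult} (estimate = tau-b, statistic = z).
#' @export
kendallTauB <- function(x, y) {
  n <- length(x)
  if (n < 3 || n != length(y)) stop("need n >= 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("tau-b undefined when one variable is entirely tied")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  new("StatResult", statistic = unname(ct$statistic), df = NA_real_,
      p.value = ct$p.value, estimate = unname(ct$estimate),
      method = "Kendall tau-b (normal approximation)")
}

#' ANCOVA: one two-level factor plus one covariate
#'
#' Fits the additive linear model dependent ~ group + covariate (no
#' interaction) and reports the model r-squared and the adjusted group
#' effect with its t statistic and two-tailed p.
#'
#' @param dependent numeric response.
#' @param group two-level factor (or coercible).
#' @param covariate numeric, nonconstant.
#' @return A \linkS4class{StatResult} (estimate = adjusted group effect for
#'   the second factor level relative to the first).
#' @export
ancovaGroup <- function(dependent, group, covariate) {
  n <- length(dependent)
  if (n <= 3) stop("need n > 3 observations")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  fit <- stats::lm(dependent ~ group + covariate)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient ANCOVA design")
  s <- summary(fit)
  co <- s$coefficients[2, ]  # the group contrast row
  new("StatResult", statistic = unname(co["t value"]),
      df = fit$df.residual, p.value = unname(co["Pr(>|t|)"]),
      estimate = unname(co["Estimate"]), r.squared = s$r.squared,
      method = "ANCOVA (group + covariate)")
}
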