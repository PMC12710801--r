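# Trend fitting and group-comparison inference for dispersal dynamics.
#
# Trunk dispersal is near-linear over its 8-hour analysis window and is
# summarized by the OLS slope; slopes are compared between groups with the
# ANCOVA slope-homogeneity (interaction) F-test. Tip dispersal over a
# 2-hour window is curved and summarized by quadratic coefficients
# (a, b, c), compared between groups with two-sample Hotelling's T-squared
# and Benjamini-Hochberg FDR adjustment across pairs.

#' Fit a linear trend SD = a * t + b
#'
#' @param series a `dispersal_series` (time in minutes).
#' @return a `trend_fit` with `model = "linear"`, coefficients `a` (slope,
#'   px/min) and `b` (intercept, px), residual variance and n.
#' @export
fit_linear_trend <- function(series) {
  assert_that(nrow(series) >= 3, "linear trend needs >= 3 points")
  assert_that(length(unique(series$time)) >= 2, "all time points identical")
  fit <- lm(sd ~ time, data = series)
  cf <- coef(fit)
  new_trend_fit("linear", a = unname(cf["time"]), b = unname(cf["(Intercept)"]),
                n = nrow(series),
                resid_var = sum(fit$residuals^2) / fit$df.residual,
                cluster_id = attr(series, "cluster_id"))
}

#' Fit a quadratic trend SD = a * t^2 + b * t + c
#'
#' @param series a `dispersal_series`.
#' @return a `trend_fit` with `model = "quadratic"` and coefficients
#'   `a` (px/min^2), `b` (px/min), `c` (px).
#' @export
fit_quadratic_trend <- function(series) {
  assert_that(nrow(series) >= 4, "quadratic trend needs >= 4 points")
  assert_that(length(unique(series$time)) >= 3,
              "rank-deficient design: need >= 3 distinct times")
  fit <- lm(sd ~ time + I(time^2), data = series)
  cf <- coef(fit)
  new_trend_fit("quadratic", a = unname(cf["I(time^2)"]), b = unname(cf["time"]),
                c = unname(cf["(Intercept)"]), n = nrow(series),
                resid_var = sum(fit$residuals^2) / max(1, fit$df.residual),
                cluster_id = attr(series, "cluster_id"))
}

new_trend_fit <- function(model, a, b, c = NULL, n, resid_var, cluster_id = NA) {
  structure(list(model = model, a = a, b = b, c = c, n = n,
                 resid_var = resid_var, cluster_id = cluster_id),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  if (x$model == "linear")
    cat(sprintf("<trend_fit linear> SD = %.4g t + %.4g (n = %d)\n", x$a, x$b, x$n))
  else
    cat(sprintf("<trend_fit quadratic> SD = %.4g t^2 + %.4g t + %.4g (n = %d)\n",
                x$a, x$b, x$c, x$n))
  invisible(x)
}

#' Compare dispersal slopes between two groups (ANCOVA)
#'
#' Pools all points of both groups into the model `SD ~ time * group` and
#' tests equality of slopes via the interaction term: the F statistic is
#' the nested-model residual-sum-of-squares comparison of `SD ~ time +
#' group` against the full model.
#'
#' @param groupA,groupB lists of `dispersal_series` (>= 2 each).
#' @param labels length-2 character vector of group labels.
#' @return list with `F`, `df` (numerator, denominator), `p`, the fitted
#'   common and per-group slopes, and point counts.
#' @export
compare_slopes_ancova <- function(groupA, groupB, labels = c("A", "B")) {
  assert_that(is.list(groupA) && length(groupA) >= 2,
              "groupA needs >= 2 dispersal series")
  assert_that(is.list(groupB) && length(groupB) >= 2,
              "groupB needs >= 2 dispersal series")
  pool <- function(gr, lab) do.call(rbind, lapply(gr, function(s)
    data.frame(time = s$time, sd = s$sd, group = lab)))
  dat <- rbind(pool(groupA, labels[1]), pool(groupB, labels[2]))
  dat$group <- factor(dat$group, levels = labels)
  full <- lm(sd ~ time * group, data = dat)
  red <- lm(sd ~ time + group, data = dat)
  av <- anova(red, full)
  cf <- coef(full)
  slopes <- c(unname(cf["time"]),
              unname(cf["time"]) + unname(cf[paste0("time:group", labels[2])]))
  list(F = av$F[2], df = c(av$Df[2], full$df.residual), p = av$`Pr(>F)`[2],
       slopes = setNames(slopes, labels), n = nrow(dat))
}

#' Two-sample Hotelling's T-squared test
#'
#' Tests equality of multivariate means with the pooled covariance:
#' \deqn{T^2 = \frac{n_1 n_2}{n_1 + n_2} (\bar x_1 - \bar x_2)' S_p^{-1}
#'   (\bar x_1 - \bar x_2)}
#' converted to \eqn{F = T^2 (n_1 + n_2 - p - 1) / (p (n_1 + n_2 - 2))} on
#' \eqn{(p, n_1 + n_2 - p - 1)} degrees of freedom.
#'
#' @param coeffsA,coeffsB matrices (rows = observations, columns = the p
#'   coefficients, e.g. quadratic `(a, b, c)`).
#' @param labels group-pair labels.
#' @return a `hotelling_result` list: `T2`, `F`, `df`, `p`, `labels`.
#' @export
hotelling_t2 <- function(coeffsA, coeffsB, labels = c("A", "B")) {
  A <- as.matrix(coeffsA); B <- as.matrix(coeffsB)
  assert_that(ncol(A) == ncol(B), "groups have different dimension")
  p <- ncol(A); n1 <- nrow(A); n2 <- nrow(B)
  assert_that(n1 >= 2 && n2 >= 2, "each group needs >= 2 observations")
  assert_that(n1 + n2 >= p + 2, "need n1 + n2 >= p + 2 for the F conversion")
  d <- colMeans(A) - colMeans(B)
  Sp <- ((n1 - 1) * cov(A) + (n2 - 1) * cov(B)) / (n1 + n2 - 2)
  sol <- tryCatch(solve(Sp, d), error = function(e) NULL)
  if (is.null(sol))
    stop_mf("singular pooled covariance (rank ", qr(Sp)$rank, " < ", p,
            "); groups may be degenerate or collinear")
  T2 <- (n1 * n2 / (n1 + n2)) * sum(d * sol)
  Fs <- T2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))
  df <- c(p, n1 + n2 - p - 1)
  pv <- pf(Fs, df[1], df[2], lower.tail = FALSE)
  structure(list(T2 = T2, F = Fs, df = df, p = pv, labels = labels),
            class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("Hotelling T2 = %.4g, F(%d, %d) = %.4g, p = %.4g  [%s vs %s]\n",
              x$T2, x$df[1], x$df[2], x$F, x$p, x$labels[1], x$labels[2]))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: order the m p-values increasingly, multiply by
#' `m / rank`, enforce monotonicity from the largest down, cap at 1.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the input order; never smaller than the raw
#'   values.
#' @export
adjust_fdr <- function(pvalues) {
  assert_that(length(pvalues) >= 1 && all(is.finite(pvalues)) &&
              all(pvalues >= 0 & pvalues <= 1),
              "p-values must all lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * pvalues[o]))
  adj[order(o)]
}
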