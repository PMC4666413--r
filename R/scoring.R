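# Condensation of raw PVS counts onto the 0-4 clinical visual rating
# categories, and the agreement/association statistics used to develop and
# evaluate the method.

#' Condense a PVS count into the 0-4 rating category
#'
#' Maps a raw basal-ganglia PVS count onto the categories of the clinical
#' visual rating scale: 0 = no PVS; 1 = 1-10; 2 = 11-20; 3 = 21-39;
#' 4 = 40 or more, or any count when the slice has high background
#' intensity (diffuse WMH), mirroring the visual raters' convention of
#' assigning the top category to such cases. The published scales print
#' the boundary counts 10, 20 and 40 ambiguously (10 appears in both
#' categories 1 and 2, 40 in both 3 and 4); the half-open bins
#' `[0], [1,10], [11,20], [21,39], [40,Inf)` are the unique monotone
#' reconciliation and are used here.
#'
#' @param count non-negative integer PVS count (vectorised).
#' @param high_background logical: high background signal present.
#' @return Integer score(s) in 0..4.
#' @examples
#' condense_score(c(0, 10, 11, 21, 40)) # 0 1 2 3 4
#' condense_score(3, high_background = TRUE) # 4
#' @export
condense_score <- function(count, high_background = FALSE) {
  if (any(count < 0) || any(count != floor(count)))
    pvs_stop("bad_count", "`count` must be a non-negative integer")
  s <- ifelse(count == 0, 0L,
       ifelse(count <= 10, 1L,
       ifelse(count <= 20, 2L,
       ifelse(count <= 39, 3L, 4L))))
  if (isTRUE(high_background)) s[] <- 4L
  as.integer(s)
}

#' Bland-Altman agreement statistics
#'
#' Agreement between two series of paired measurements (within- or
#' between-observer): mean and sample (n-1) standard deviation of the
#' differences `a - b`, with 95% limits of agreement at
#' `mean +/- 1.96 * sd`.
#'
#' @param a,b numeric vectors of paired measurements (same length, n >= 2).
#' @return An object of class `pvs_bland_altman` with `n`,
#'   `mean_difference`, `sd_difference`, `loa_lower`, `loa_upper`, and the
#'   paired means/differences for plotting.
#' @examples
#' bland_altman(c(1, 3), c(2, 5)) # mean -1.5, sd ~0.707
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    pvs_stop("bad_pairs", "`a` and `b` must have the same length")
  if (length(a) < 2L)
    pvs_stop("too_few_pairs", "Bland-Altman needs at least 2 pairs")
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b))))
    pvs_stop("bad_pairs", "pairs must be finite")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(n = length(a), mean_difference = m, sd_difference = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 means = (a + b) / 2, differences = d),
            class = "pvs_bland_altman")
}

#' @export
print.pvs_bland_altman <- function(x, ...) {
  cat(sprintf("<Bland-Altman> n = %d pairs\n", x$n))
  cat(sprintf("  mean difference %.4g, SD %.4g\n", x$mean_difference, x$sd_difference))
  cat(sprintf("  95%% limits of agreement [%.4g, %.4g]\n", x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @export
plot.pvs_bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean of pair",
                 ylab = "difference (a - b)", main = "Bland-Altman", ...)
  graphics::abline(h = c(x$mean_difference, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = c("blue", "red", "red"))
  invisible(x)
}

#' Simple linear-regression association
#'
#' Ordinary least squares of `y` on `x` with a 95% confidence interval on
#' the slope and a two-sided p-value from the t statistic, as used to test
#' associations between PVS count/volume and rating scores. A perfect fit
#' (zero residual variance) collapses the interval to the slope and flags
#' the inference as degenerate.
#'
#' @param x predictor values (not constant, n >= 3).
#' @param y response values (same length).
#' @param conf_level confidence level for the slope interval.
#' @return An object of class `pvs_ols` with `slope`, `intercept`,
#'   `se_slope`, `ci_low`, `ci_high`, `p_value`, `n`, `degenerate`.
#' @export
ols_association <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    pvs_stop("bad_pairs", "`x` and `y` must have the same length")
  if (length(x) < 3L)
    pvs_stop("too_few_pairs", "regression needs at least 3 observations")
  if (stats::var(x) == 0)
    pvs_stop("constant_predictor", "`x` is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  degenerate <- rss <= 1e-12 * max(tss, 1)
  if (degenerate) {
    ci <- c(co[["x"]], co[["x"]])
    se <- 0
    p <- NA_real_
  } else {
    sm <- summary(fit)$coefficients
    se <- sm["x", "Std. Error"]
    p <- sm["x", "Pr(>|t|)"]
    ci <- as.numeric(stats::confint(fit, "x", level = conf_level))
  }
  structure(list(slope = unname(co[["x"]]), intercept = unname(co[["(Intercept)"]]),
                 se_slope = se, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, n = length(x), conf_level = conf_level,
                 degenerate = degenerate),
            class = "pvs_ols")
}

#' @export
print.pvs_ols <- function(x, ...) {
  cat(sprintf("<OLS association> n = %d\n", x$n))
  cat(sprintf("  slope %.4g (%.0f%% CI %.4g to %.4g), intercept %.4g\n",
              x$slope, 100 * x$conf_level, x$ci_low, x$ci_high, x$intercept))
  if (x$degenerate) cat("  perfect fit: inference degenerate\n")
  else cat(sprintf("  p = %.3g\n", x$p_value))
  invisible(x)
}
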