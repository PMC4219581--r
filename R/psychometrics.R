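#' Pearson product-moment correlation with preconditions
#'
#' Thin wrapper over [stats::cor()] enforcing the preconditions needed for
#' a meaningful validity coefficient: at least 3 complete pairs and
#' nonzero variance in both instruments.  Incomplete pairs are dropped
#' (their count is reported as an attribute).
#'
#' @param x,y numeric vectors of paired measurements from two instruments.
#' @return correlation in [-1, 1] with attribute `n_dropped`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("pearson_r needs at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance in one instrument")
  r <- stats::cor(x, y)
  attr(r, "n_dropped") <- dropped
  r
}

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean x - mean y)^2), with moments on
#' the n denominator (Lin's original definition), penalising both loss of
#' correlation and location/scale shift between two instruments.  The 95%
#' confidence interval is obtained on Fisher's z scale with Lin's
#' asymptotic standard error and back-transformed.
#'
#' @inheritParams pearson_r
#' @param conf_level confidence level, default 0.95.
#' @return list of class `reliability_result`: `coefficient`, `ci_lower`,
#'   `ci_upper`, `n`, `category` (Landis-Koch label), `method`.
#' @export
lin_ccc <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("lin_ccc needs at least 3 complete pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("undefined CCC: no variance and equal means")
  ccc <- 2 * sxy / denom
  ci <- c(NA_real_, NA_real_)
  if (sx2 > 0 && sy2 > 0 && abs(ccc) < 1) {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mx - my) / (sx2 * sy2)^0.25
    se_z2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    if (is.finite(se_z2) && se_z2 >= 0) {
      z <- atanh(ccc)
      q <- stats::qnorm(1 - (1 - conf_level) / 2)
      ci <- tanh(z + c(-1, 1) * q * sqrt(se_z2))
    }
  } else if (abs(ccc) == 1) ci <- c(ccc, ccc)
  structure(list(coefficient = ccc, ci_lower = ci[1L], ci_upper = ci[2L],
                 n = n, category = landis_koch(ccc), method = "CCC"),
            class = "reliability_result")
}

#' One-way random-effects intraclass correlation
#'
#' ANOVA estimator for repeated measurements on the same subjects:
#' variance components are sigma^2_error = MSW and
#' sigma^2_subject = (MSB - MSW) / n0 where n0 is the effective group size
#' (k for balanced designs, `(N - sum n_i^2 / N) / (a - 1)` when
#' unbalanced), negative estimates truncated at zero.
#' ICC(1) = sigma^2_subject / (sigma^2_subject + sigma^2_error), with the
#' 95% confidence interval from the F-distribution method.
#'
#' @param subject subject identifiers (any type coercible to factor).
#' @param value numeric measurements; one row per subject-occasion.
#' @param conf_level confidence level, default 0.95.
#' @return list of class `reliability_result` with `coefficient`,
#'   `ci_lower`, `ci_upper`, `var_subject`, `var_error`, `n_subjects`,
#'   `category`, `method`.
#' @export
icc_oneway <- function(subject, value, conf_level = 0.95) {
  ok <- is.finite(value) & !is.na(subject)
  subject <- factor(subject[ok]); value <- value[ok]
  ni <- as.vector(table(subject))
  a <- length(ni); N <- sum(ni)
  if (a < 2L) stop("ICC needs at least 2 subjects")
  if (all(ni < 2L))
    stop("insufficient replication: no subject has repeated measurements")
  gm <- mean(value)
  mi <- tapply(value, subject, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((value - mi[subject])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  var_e <- msw
  var_s <- max(0, (msb - msw) / n0)
  icc <- if (var_s + var_e == 0) NA_real_ else var_s / (var_s + var_e)
  alpha <- 1 - conf_level
  Fobs <- msb / msw
  fl <- Fobs / stats::qf(1 - alpha / 2, a - 1, N - a)
  fu <- Fobs * stats::qf(1 - alpha / 2, N - a, a - 1)
  ci <- c((fl - 1) / (fl + n0 - 1), (fu - 1) / (fu + n0 - 1))
  ci <- pmin(1, pmax(-1, ci))
  structure(list(coefficient = icc, ci_lower = ci[1L], ci_upper = ci[2L],
                 var_subject = var_s, var_error = var_e,
                 n_subjects = a, n_obs = N,
                 category = landis_koch(icc), method = "ICC(1)"),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (95%% CI %.3f-%.3f), %s\n", x$method,
              x$coefficient, x$ci_lower, x$ci_upper, x$category))
  if (!is.null(x$var_subject))
    cat(sprintf("  var components: subject %.3f, error %.3f\n",
                x$var_subject, x$var_error))
  invisible(x)
}

#' Bland-Altman agreement between two instruments
#'
#' Differences d_i = x_i - y_i; bias d = mean difference, s = sample SD of
#' the differences (n-1 denominator), limits of agreement d +/- 1.96 s,
#' width = upper - lower, and CV = s/d (flagged undefined when d = 0).
#'
#' @inheritParams pearson_r
#' @return list of class `agreement_summary`: `d`, `s`, `upper`, `lower`,
#'   `width`, `cv`, `n`.
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("bland_altman needs at least 2 complete pairs")
  diffs <- x - y
  d <- mean(diffs)
  s <- stats::sd(diffs)
  loa <- limits_of_agreement(d, s)
  structure(list(d = d, s = s, upper = loa["upper"], lower = loa["lower"],
                 width = loa["width"], cv = if (d == 0) NA_real_ else s / d,
                 n = length(x)),
            class = "agreement_summary")
}

#' Limits of agreement from a bias and an SD of differences
#'
#' Exact affine arithmetic: upper = d + 1.96 s, lower = d - 1.96 s,
#' width = upper - lower.  Rounding happens only at the presentation layer
#' (see [format_agreement()]).
#'
#' @param d mean difference (bias).
#' @param s standard deviation of the differences; must be >= 0.
#' @return named numeric `c(upper, lower, width)`.
#' @export
limits_of_agreement <- function(d, s) {
  if (!is.finite(d) || !is.finite(s)) stop("d and s must be finite")
  if (s < 0) stop("SD of differences must be non-negative")
  upper <- d + 1.96 * s
  lower <- d - 1.96 * s
  c(upper = upper, lower = lower, width = upper - lower)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published agreement tables round
#' half away from zero, so presentation uses this variant.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # round the scaled value to 9 decimals first so that values stored a
  # hair below .5 by binary floating point (e.g. 2.675 * 100) still
  # round up
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

#' Present an agreement summary the way published tables do
#'
#' Rounds the bias, SD and limits half-away-from-zero to `digits` decimal
#' places and reports the width as the difference of the *rounded* limits
#' (the convention used in printed agreement tables, where the width row
#' must reconcile with the printed limit rows).
#'
#' @param ba an [bland_altman()] summary, or a list with `d` and `s`.
#' @param digits decimal places (default 2).
#' @param cv_absolute present CV as |s/d| (some tables print positive CVs
#'   for negative biases).
#' @return named numeric `c(d, s, upper, lower, width, cv)`.
#' @export
format_agreement <- function(ba, digits = 2, cv_absolute = FALSE) {
  loa <- limits_of_agreement(ba$d, ba$s)
  up <- round_half_away(loa["upper"], digits)
  lo <- round_half_away(loa["lower"], digits)
  cv <- if (ba$d == 0) NA_real_ else ba$s / ba$d
  if (cv_absolute && !is.na(cv)) cv <- abs(cv)
  c(d = round_half_away(ba$d, digits), s = round_half_away(ba$s, digits),
    upper = unname(up), lower = unname(lo),
    width = round_half_away(unname(up) - unname(lo), digits),
    cv = round_half_away(cv, digits))
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, SD %.3f\n", x$n, x$d, x$s))
  cat(sprintf("  limits %.3f to %.3f (width %.3f)\n",
              x$lower, x$upper, x$width))
  invisible(x)
}

#' Landis-Koch strength-of-agreement category
#'
#' Conventional qualitative bands: below 0 poor; 0-0.20 slight; 0.21-0.40
#' fair; 0.41-0.60 moderate; 0.61-0.80 substantial; 0.81-1.00 almost
#' perfect.  Boundary values belong to the lower band (0.80 is
#' "substantial").
#'
#' @param coefficient a reliability coefficient, at most 1.
#' @return character label.
#' @export
landis_koch <- function(coefficient) {
  if (is.na(coefficient)) return(NA_character_)
  if (coefficient > 1) stop("reliability coefficient cannot exceed 1")
  if (coefficient < 0) "poor"
  else if (coefficient <= 0.20) "slight"
  else if (coefficient <= 0.40) "fair"
  else if (coefficient <= 0.60) "moderate"
  else if (coefficient <= 0.80) "substantial"
  else "almost perfect"
}
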