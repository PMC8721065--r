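#' Interval estimate container
#'
#' @param estimate point estimate on the full sample.
#' @param lower,upper confidence bounds.
#' @param level confidence level.
#' @param B resample count.
#' @param statistic name of the statistic.
#' @return object of class \code{interval_estimate}.
#' @export
interval_estimate <- function(estimate, lower, upper, level = 0.95,
                              B = NA_integer_, statistic = NA_character_) {
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 level = level, B = B, statistic = statistic),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f (%.0f%% CI %.4f, %.4f)\n",
              if (is.na(x$statistic)) "estimate" else x$statistic,
              x$estimate, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

# Statistic evaluated on resampled level pairs; marginal-only statistics
# avoid building the full C x C table.
stat_from_levels <- function(x, y, C, statistic, k = 0L) {
  switch(statistic,
    PA = 100 * mean(abs(x - y) <= k),
    RP = rp_from_marginals(tabulate(x + 1L, C), tabulate(y + 1L, C)),
    RC = rc_from_marginals(tabulate(x + 1L, C), tabulate(y + 1L, C)),
    RV = {
      counts <- tabulate(x * C + y + 1L, nbins = C * C)
      relative_rank_variance(matrix(counts, C, C, byrow = TRUE))
    },
    stop("unknown statistic '", statistic, "'"))
}

#' Percentile bootstrap confidence interval over subjects
#'
#' Subjects (i.e. level pairs) are resampled with replacement; the
#' statistic is recomputed on each resample and the percentile interval
#' taken.  The subject — not the single assessment — is the resampling
#' unit, so the pairing structure is preserved.  With a fixed seed the
#' interval is exactly reproducible.  In the rare discrete edge case
#' where the percentile interval would exclude the point estimate, the
#' interval is widened to include it.
#'
#' @param sample a [paired_sample()] (or C x C contingency table, whose
#'   pairs are then reconstituted).
#' @param statistic one of \code{"RP"}, \code{"RC"}, \code{"RV"},
#'   \code{"PA"}.
#' @param B number of bootstrap resamples (at least 100).
#' @param level confidence level.
#' @param seed optional integer seed.
#' @param k tolerance when \code{statistic = "PA"}.
#' @return an [interval_estimate()].
#' @export
bootstrap_ci <- function(sample, statistic = c("RP", "RC", "RV", "PA"),
                         B = 2000L, level = 0.95, seed = NULL, k = 0L) {
  statistic <- match.arg(statistic)
  if (B < 100L) stop("B must be at least 100")
  if (is.matrix(sample)) {
    p <- table_to_pairs(as_table(sample))
    sample <- paired_sample(p$x, p$y, C = p$C)
  }
  if (!inherits(sample, "paired_sample")) stop("expected a paired_sample")
  if (!is.null(seed)) set.seed(seed)
  n <- sample$n; C <- sample$C
  est <- stat_from_levels(sample$x, sample$y, C, statistic, k)
  boots <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[b] <- stat_from_levels(sample$x[idx], sample$y[idx], C, statistic, k)
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  interval_estimate(est, min(q[1], est), max(q[2], est), level = level,
                    B = as.integer(B), statistic = statistic)
}

#' Classify a disagreement measure from its confidence interval
#'
#' The classification rules used for RP, RC and RV:
#' \itemize{
#'   \item \code{significant}: |estimate| at or beyond the negligibility
#'     band (0.1) and the CI does not include 0 — a clinically relevant,
#'     statistically significant disagreement;
#'   \item \code{tendency}: |estimate| at or beyond the band but the CI
#'     still includes 0 — a tendency towards non-negligible disagreement;
#'   \item \code{negligible_significant}: |estimate| within the band yet
#'     the CI excludes 0 — statistically significant but negligible;
#'   \item \code{none}: everything else.
#' }
#'
#' @param est an [interval_estimate()], or a numeric point estimate with
#'   \code{lower} and \code{upper} given.
#' @param lower,upper confidence bounds when \code{est} is numeric.
#' @param band negligibility half-width (default 0.1).
#' @return one of \code{"none"}, \code{"negligible_significant"},
#'   \code{"tendency"}, \code{"significant"}.
#' @export
classify_disagreement <- function(est, lower = NULL, upper = NULL,
                                  band = 0.1) {
  if (inherits(est, "interval_estimate")) {
    lower <- est$lower; upper <- est$upper; est <- est$estimate
  }
  if (is.null(lower) || is.null(upper))
    stop("lower and upper must be supplied with a numeric estimate")
  zero_in <- lower <= 0 && upper >= 0
  large <- abs(est) >= band
  if (large && !zero_in) "significant"
  else if (large && zero_in) "tendency"
  else if (!large && !zero_in) "negligible_significant"
  else "none"
}

#' Display rounding for RP/RC/RV values
#'
#' Reporting convention for the disagreement measures: absolute values
#' at or below 0.01 are displayed as \code{"0"}; all other values are
#' shown with two decimals.
#'
#' @param x finite numeric vector.
#' @return character vector of display strings.
#' @export
display_value <- function(x) {
  if (any(!is.finite(x))) stop("display_value requires finite input")
  ifelse(abs(x) <= 0.01, "0", formatC(x, format = "f", digits = 2))
}
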