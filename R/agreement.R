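#' Percentage agreement with point tolerance
#'
#' The share (in percent) of paired assessments whose categories differ
#' by at most \code{k} points.  \code{k = 0} is exact agreement.
#'
#' @param table a C x C contingency table (rows: first assessment) or a
#'   [paired_sample()].
#' @param k nonnegative integer tolerance in category points.
#' @return percentage in \code{[0, 100]}.
#' @export
percentage_agreement <- function(table, k = 0L) {
  if (k < 0) stop("tolerance k must be nonnegative")
  tab <- as_table(table)
  C <- nrow(tab)
  d <- abs(row(tab) - col(tab))
  100 * sum(tab[d <= k]) / sum(tab)
}

#' Minimum tolerance reaching a target agreement
#'
#' The smallest point tolerance k at which the tolerance-k percentage
#' agreement reaches the threshold (70\% by convention: agreement of at
#' least 70\% is considered satisfactory).  Always terminates: at
#' k = C - 1 agreement is 100\%.
#'
#' @inheritParams percentage_agreement
#' @param threshold target agreement percentage in (0, 100].
#' @return integer k in \code{0:(C-1)}.
#' @export
min_tolerance <- function(table, threshold = 70) {
  if (threshold <= 0 || threshold > 100) stop("threshold must be in (0, 100]")
  tab <- as_table(table)
  for (k in 0:(nrow(tab) - 1L))
    if (percentage_agreement(tab, k) >= threshold) return(k)
  nrow(tab) - 1L  # unreachable; PA at C-1 is 100
}

#' Relative position (RP)
#'
#' Systematic shift in position between the two assessments' marginal
#' category distributions: the probability that an independent draw from
#' the second assessment's marginal exceeds one from the first, minus
#' the reverse.  RP lies in \code{[-1, 1]}; positive values mean the
#' second assessment uses higher categories more often.
#'
#' @inheritParams percentage_agreement
#' @return RP in \code{[-1, 1]}.
#' @export
relative_position <- function(table) {
  tab <- as_table(table)
  rp_from_marginals(rowSums(tab), colSums(tab))
}

rp_from_marginals <- function(a, b) {
  n <- sum(a)
  # P(Y > X) - P(Y < X) with X ~ a/n, Y ~ b/n independent
  B_above <- rev(cumsum(rev(b))) - b  # strictly above each category
  B_below <- cumsum(b) - b
  (sum(a * B_above) - sum(a * B_below)) / n^2
}

#' Relative concentration (RC)
#'
#' Whether the second assessment's categories are more concentrated
#' towards the centre of the scale than the first's: the probability
#' that a draw from the second marginal falls strictly between two
#' independent draws from the first marginal (in the unordered-pair
#' sense, hence the factor 2), minus the converse.  Positive RC means
#' the second assessment is the more centrally concentrated.  Under
#' this normalisation the attainable extremes are +/-0.5; values within
#' \code{[-0.1, 0.1]} are conventionally negligible.
#'
#' @inheritParams percentage_agreement
#' @return RC.
#' @export
relative_concentration <- function(table) {
  tab <- as_table(table)
  rc_from_marginals(rowSums(tab), colSums(tab))
}

rc_from_marginals <- function(a, b) {
  n <- sum(a)
  A_below <- cumsum(a) - a; A_above <- rev(cumsum(rev(a))) - a
  B_below <- cumsum(b) - b; B_above <- rev(cumsum(rev(b))) - b
  2 * (sum(b * A_below * A_above) - sum(a * B_below * B_above)) / n^3
}

#' Augmented mean ranks of a contingency table
#'
#' Each assessment's subjects are ranked by their own category, with
#' ties broken by the paired assessment's category; subjects sharing a
#' cell share the cell's mean rank.  For cell (i, j) the rank under the
#' first assessment is
#' \deqn{R^{(1)}_{ij} = \sum_{p<i} a_p + \sum_{q<j} n_{iq} + (n_{ij}+1)/2}
#' and symmetrically under the second.  These augmented ranks are the
#' substrate of the relative rank variance.
#'
#' @inheritParams percentage_agreement
#' @return list with C x C matrices \code{R1} and \code{R2} (defined for
#'   every cell; only cells with \code{n_ij > 0} carry subjects).
#' @export
augmented_mean_ranks <- function(table) {
  tab <- as_table(table)
  C <- nrow(tab)
  a <- rowSums(tab); b <- colSums(tab)
  A_below <- c(0, cumsum(a))[seq_len(C)]        # subjects in lower rows
  B_below <- c(0, cumsum(b))[seq_len(C)]        # subjects in lower columns
  row_cum <- t(apply(tab, 1, function(r) c(0, cumsum(r))[seq_len(C)]))
  col_cum <- apply(tab, 2, function(cl) c(0, cumsum(cl))[seq_len(C)])
  R1 <- matrix(A_below, C, C) + row_cum + (tab + 1) / 2
  R2 <- matrix(B_below, C, C, byrow = TRUE) + col_cum + (tab + 1) / 2
  list(R1 = R1, R2 = R2)
}

#' Relative rank variance (RV)
#'
#' The random (individual) component of disagreement: the normalised
#' sum of squared differences between each subject's augmented mean
#' ranks under the two assessments,
#' \deqn{RV = \frac{6}{n^3} \sum_{ij} n_{ij} (R^{(1)}_{ij} - R^{(2)}_{ij})^2.}
#' RV is 0 exactly when all disagreement is systematic (in particular
#' for diagonal tables); values below 0.1 are conventionally negligible.
#'
#' @inheritParams percentage_agreement
#' @return nonnegative RV.
#' @export
relative_rank_variance <- function(table) {
  tab <- as_table(table)
  r <- augmented_mean_ranks(tab)
  n <- sum(tab)
  6 * sum(tab * (r$R1 - r$R2)^2) / n^3
}

#' ROC-style cumulative marginal curve
#'
#' The paired cumulative proportions (u, v) of the two assessments'
#' marginal distributions at each category cutoff, from (0, 0) to
#' (1, 1).  A curve bowed off the diagonal signals a position shift
#' (RP); an S-shape signals a concentration difference (RC).
#'
#' @inheritParams percentage_agreement
#' @return data frame with columns \code{cutoff} (category c, from -1),
#'   \code{u} (first assessment, P(level <= c)) and \code{v} (second).
#' @export
roc_points <- function(table) {
  tab <- as_table(table)
  n <- sum(tab)
  data.frame(cutoff = seq_len(nrow(tab) + 1L) - 2L,
             u = c(0, cumsum(rowSums(tab)) / n),
             v = c(0, cumsum(colSums(tab)) / n))
}

#' Fit a rank-invariant agreement analysis to a paired ordinal sample
#'
#' The one-stop estimator for a single comparison: computes the
#' percentage agreement (exact and at requested point tolerances), the
#' minimum tolerance reaching the satisfactory-agreement threshold, the
#' systematic disagreement measures RP (position) and RC
#' (concentration), the random disagreement measure RV (rank variance),
#' the ROC-style marginal curve, and — unless disabled — subject-level
#' percentile bootstrap confidence intervals with the CI-based
#' disagreement classification for RP, RC and RV.
#'
#' @param x a [paired_sample()], a C x C contingency table, or an
#'   integer vector of first-assessment levels (with \code{y}).
#' @param y second-assessment levels when \code{x} is a vector.
#' @param C category count when \code{x}, \code{y} are vectors
#'   (default: smallest count covering the observed levels).
#' @param tolerances additional point tolerances at which to report
#'   percentage agreement.
#' @param threshold satisfactory-agreement threshold in percent for the
#'   minimum-tolerance search.
#' @param band negligibility half-width for RP/RC/RV classification.
#' @param ci logical: compute bootstrap confidence intervals?
#' @param B bootstrap resamples (subjects resampled with replacement).
#' @param level confidence level.
#' @param seed optional integer seed for the bootstrap.
#' @return object of class \code{rank_agreement}.
#' @examples
#' tab <- matrix(c(2, 1, 0, 2), 2, 2, byrow = TRUE)
#' fit <- rank_agreement(tab, ci = FALSE)
#' coef(fit)  # PA 80, RP 0.2, RC 0, RV 0
#' @export
rank_agreement <- function(x, y = NULL, C = NULL, tolerances = integer(),
                           threshold = 70, band = 0.1, ci = TRUE,
                           B = 2000L, level = 0.95, seed = NULL) {
  sample <- if (inherits(x, "paired_sample")) x
    else if (is.matrix(x)) {
      p <- table_to_pairs(as_table(x))
      paired_sample(p$x, p$y, C = p$C)
    } else paired_sample(x, y, C = C)
  tab <- build_contingency(sample)
  tolerances <- sort(unique(as.integer(tolerances)))
  pa_k <- vapply(tolerances, function(k) percentage_agreement(tab, k), 0)
  if (length(tolerances)) names(pa_k) <- paste0("PA_", tolerances)
  fit <- list(
    sample = sample, table = tab, n = sample$n, C = sample$C,
    pa = percentage_agreement(tab, 0L), pa_k = pa_k,
    min_k = min_tolerance(tab, threshold), threshold = threshold,
    rp = relative_position(tab), rc = relative_concentration(tab),
    rv = relative_rank_variance(tab), roc = roc_points(tab),
    band = band, ci = NULL, flags = NULL, call = match.call())
  if (ci) {
    if (!is.null(seed)) set.seed(seed)
    fit$ci <- lapply(c(RP = "RP", RC = "RC", RV = "RV"), function(s)
      bootstrap_ci(sample, s, B = B, level = level))
    fit$flags <- vapply(fit$ci, classify_disagreement, "", band = band)
  }
  class(fit) <- "rank_agreement"
  fit
}

#' @export
print.rank_agreement <- function(x, digits = 3, ...) {
  lbl <- if (!is.null(x$sample$spec)) paste0(" [", x$sample$spec$label,
             if (!is.null(x$sample$unit)) paste0(", ", x$sample$unit), "]")
         else ""
  cat(sprintf("Rank-invariant agreement analysis%s\n", lbl))
  cat(sprintf("  n = %d subjects, C = %d categories\n", x$n, x$C))
  cat(sprintf("  PA = %.1f%%", x$pa))
  if (length(x$pa_k))
    cat("  (", paste(sprintf("%s = %.1f%%", names(x$pa_k), x$pa_k),
                     collapse = ", "), ")", sep = "")
  cat(sprintf("\n  minimum tolerance for >= %.0f%% agreement: %d point(s)\n",
              x$threshold, x$min_k))
  for (s in c("RP", "RC", "RV")) {
    est <- switch(s, RP = x$rp, RC = x$rc, RV = x$rv)
    line <- sprintf("  %s = %s", s, display_value(est))
    if (!is.null(x$ci)) {
      iv <- x$ci[[s]]
      line <- paste0(line, sprintf(" (%.0f%% CI %.2f, %.2f) [%s]",
                                   100 * iv$level, iv$lower, iv$upper,
                                   x$flags[[s]]))
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' @export
summary.rank_agreement <- function(object, ...) {
  est <- data.frame(
    statistic = c("PA", "RP", "RC", "RV"),
    estimate = c(object$pa, object$rp, object$rc, object$rv),
    lower = NA_real_, upper = NA_real_, flag = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(object$ci)) {
    for (s in names(object$ci)) {
      i <- match(s, est$statistic)
      est$lower[i] <- object$ci[[s]]$lower
      est$upper[i] <- object$ci[[s]]$upper
      est$flag[i] <- object$flags[[s]]
    }
  }
  structure(list(estimates = est, pa_k = object$pa_k, min_k = object$min_k,
                 n = object$n, C = object$C, threshold = object$threshold),
            class = "summary.rank_agreement")
}

#' @export
print.summary.rank_agreement <- function(x, ...) {
  cat(sprintf("n = %d, C = %d\n", x$n, x$C))
  print(x$estimates, row.names = FALSE, digits = 4)
  if (length(x$pa_k)) {
    cat("Tolerance agreement:",
        paste(sprintf("%s = %.1f%%", names(x$pa_k), x$pa_k), collapse = ", "),
        "\n")
  }
  cat(sprintf("Minimum tolerance for >= %.0f%%: %d point(s)\n",
              x$threshold, x$min_k))
  invisible(x)
}

#' @export
coef.rank_agreement <- function(object, ...) {
  c(PA = object$pa, RP = object$rp, RC = object$rc, RV = object$rv)
}

#' @export
confint.rank_agreement <- function(object, parm, level, ...) {
  if (is.null(object$ci))
    stop("fit was computed with ci = FALSE; refit with ci = TRUE")
  m <- t(vapply(object$ci, function(iv) c(iv$lower, iv$upper), c(0, 0)))
  colnames(m) <- paste0(100 * c((1 - object$ci[[1]]$level) / 2,
                                1 - (1 - object$ci[[1]]$level) / 2), " %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Plot the ROC-style marginal curve of an agreement fit
#'
#' @param x a [rank_agreement()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rank_agreement <- function(x, ...) {
  args <- list(x = x$roc$u, y = x$roc$v, type = "s",
               xlab = "Cumulative proportion, first assessment",
               ylab = "Cumulative proportion, second assessment",
               xlim = c(0, 1), ylim = c(0, 1),
               main = "Cumulative marginal (ROC) curve")
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(graphics::plot, args)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::points(x$roc$u, x$roc$v, pch = 16, cex = 0.7)
  invisible(x)
}

#' @export
residuals.rank_agreement <- function(object, ...) {
  r <- augmented_mean_ranks(object$table)
  idx <- cbind(object$sample$x + 1L, object$sample$y + 1L)
  stats::setNames(r$R1[idx] - r$R2[idx], object$sample$subject_ids)
}
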