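#' Configure a synthetic multi-rater two-occasion rating study
#'
#' The generator emulates a reliability study in which every subject is
#' assessed by one pair of raters, simultaneously but independently, on
#' each of two occasions.  Each subject carries a latent true level per
#' item drawn from that item's marginal distribution; between occasion 1
#' and occasion 2 the latent level increments by one (capped at the item
#' maximum) with probability \code{shift_prob} — a single-category
#' systematic shift, e.g. spontaneous recovery; each recorded rating is
#' independently perturbed by one category with probability
#' \code{noise_prob}, the perturbation direction symmetric and reflected
#' at the scale bounds — rater variability.
#'
#' @param n_subjects number of subjects (default 60).
#' @param raters character vector of rater ids; subjects are assigned
#'   round-robin to the unordered rater pairs from this pool.
#' @param occasions number of assessment occasions (default 2; the
#'   systematic shift applies to each occasion after the first,
#'   cumulatively).
#' @param scale an [ordinal_scale()] or scale source (default the
#'   built-in FMA-LE).
#' @param item_marginals per-item probability vector over levels (a
#'   single vector recycled to all items, or a named list by item id).
#'   Default \code{c(0.15, 0.25, 0.60)} for 3-level items: a cohort with
#'   mostly mild-to-moderate impairment, scores skewed towards the top
#'   of the scale.
#' @param shift_prob probability of the +1 between-occasion latent shift.
#' @param noise_prob probability a recorded rating is perturbed by one
#'   category.
#' @param seed integer seed; the same seed yields an identical dataset.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_subjects = 60L, raters = c("A", "B", "C"),
                             occasions = 2L, scale = "fma_le",
                             item_marginals = NULL,
                             shift_prob = 0, noise_prob = 0, seed = NULL) {
  scale <- load_scale(scale)
  if (n_subjects < 1L) stop("n_subjects must be positive")
  if (shift_prob < 0 || shift_prob > 1 || noise_prob < 0 || noise_prob > 1)
    stop("shift_prob and noise_prob must lie in [0, 1]")
  items <- scale$items
  marg <- vector("list", nrow(items))
  names(marg) <- items$item_id
  for (i in seq_len(nrow(items))) {
    C <- items$max_level[i] - items$min_level[i] + 1L
    m <- if (is.null(item_marginals)) {
      if (C == 3L) c(0.15, 0.25, 0.60) else rep(1 / C, C)
    } else if (is.list(item_marginals)) {
      if (is.null(item_marginals[[items$item_id[i]]]))
        stop("item_marginals missing item '", items$item_id[i], "'")
      item_marginals[[items$item_id[i]]]
    } else item_marginals
    if (length(m) != C) stop("marginal for item '", items$item_id[i],
                             "' must have ", C, " probabilities")
    if (any(m < 0) || abs(sum(m) - 1) > 1e-8)
      stop("marginal for item '", items$item_id[i],
           "' is not a probability vector")
    marg[[i]] <- m / sum(m)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 raters = as.character(raters),
                 occasions = as.integer(occasions), scale = scale,
                 item_marginals = marg, shift_prob = shift_prob,
                 noise_prob = noise_prob, seed = seed),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d subjects, raters {%s} in pairs, %d occasions\n",
    x$n_subjects, paste(x$raters, collapse = ", "), x$occasions))
  cat(sprintf("  scale: %s (%d items); shift_prob = %g, noise_prob = %g\n",
              x$scale$name, nrow(x$scale$items), x$shift_prob, x$noise_prob))
  invisible(x)
}

# One-step symmetric perturbation with reflection at the bounds:
# from an interior level, down/up each with prob eps/2; from a boundary
# the out-of-range step reflects back inside (level 0 -> 1, max -> max-1).
perturb_levels <- function(lev, C, eps, rng_n) {
  if (eps == 0 || C == 1L) return(lev)
  hit <- stats::runif(rng_n) < eps
  dir <- ifelse(stats::runif(rng_n) < 0.5, -1L, 1L)
  out <- lev + ifelse(hit, dir, 0L)
  out[out < 0L] <- 1L         # reflect -1 about 0
  out[out > C - 1L] <- C - 2L # reflect C about C-1
  out
}

#' Generate a synthetic rating study
#'
#' Draws a complete long-format ratings dataset from a
#' [synthetic_config()]: latent levels per subject and item, the
#' between-occasion systematic shift, per-rating symmetric noise, and
#' round-robin assignment of subjects to rater pairs.
#'
#' @param config a [synthetic_config()].
#' @return validated ratings data frame (columns \code{subject_id},
#'   \code{rater_id}, \code{occasion}, \code{item_id}, \code{score}),
#'   byte-identical across runs with the same seed.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a synthetic_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  items <- config$scale$items
  n <- config$n_subjects
  subj <- sprintf("S%03d", seq_len(n))
  pairs <- if (length(config$raters) >= 2L)
    utils::combn(config$raters, 2L, simplify = FALSE)
  else list(config$raters)
  assignment <- pairs[((seq_len(n) - 1L) %% length(pairs)) + 1L]
  rec <- vector("list", nrow(items))
  for (i in seq_len(nrow(items))) {
    C <- items$max_level[i] - items$min_level[i] + 1L
    latent <- matrix(0L, nrow = n, ncol = config$occasions)
    latent[, 1L] <- sample.int(C, n, replace = TRUE,
                               prob = config$item_marginals[[i]]) - 1L
    if (config$occasions > 1L) for (o in 2:config$occasions) {
      shift <- stats::runif(n) < config$shift_prob
      latent[, o] <- pmin(latent[, o - 1L] + as.integer(shift), C - 1L)
    }
    per_rater <- lengths(assignment)
    rows <- data.frame(
      subject_id = rep(rep(subj, times = per_rater), times = config$occasions),
      rater_id = rep(unlist(assignment), times = config$occasions),
      occasion = rep(seq_len(config$occasions), each = sum(per_rater)),
      item_id = items$item_id[i],
      stringsAsFactors = FALSE)
    lat <- latent[cbind(match(rows$subject_id, subj), rows$occasion)]
    rows$score <- perturb_levels(lat, C, config$noise_prob, nrow(rows)) +
      items$min_level[i]
    rec[[i]] <- rows
  }
  out <- do.call(rbind, rec)
  out <- out[order(out$subject_id, out$rater_id, out$occasion,
                   match(out$item_id, items$item_id)), , drop = FALSE]
  rownames(out) <- NULL
  validate_ratings(out, config$scale)
}

#' Exact recorded category distributions implied by a config
#'
#' Propagates one item's latent marginal through the between-occasion
#' shift and the symmetric recording noise, giving the exact recorded
#' score distributions at occasions 1 and 2.  Useful as an analytic
#' reference for parameter-recovery checks: e.g. the population RP
#' between the two occasions is [relative_position()] applied to these
#' two vectors (scaled to counts).
#'
#' @param config a [synthetic_config()].
#' @param item item id.
#' @return list with probability vectors \code{occasion1} and
#'   \code{occasion2} (recorded, i.e. post-shift and post-noise) and
#'   their latent counterparts \code{latent1}, \code{latent2}.
#' @export
induced_marginals <- function(config, item) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a synthetic_config")
  i <- match(item, config$scale$items$item_id)
  if (is.na(i)) stop("unknown item '", item, "'")
  C <- config$scale$items$max_level[i] - config$scale$items$min_level[i] + 1L
  p1 <- config$item_marginals[[i]]
  d <- config$shift_prob
  p2 <- (1 - d) * p1
  if (C > 1L) {
    p2[2:C] <- p2[2:C] + d * p1[1:(C - 1L)]
    p2[C] <- p2[C] + d * p1[C]          # shift capped at the maximum
  } else p2 <- p1
  list(occasion1 = noise_matrix(C, config$noise_prob) %*% p1,
       occasion2 = noise_matrix(C, config$noise_prob) %*% p2,
       latent1 = p1, latent2 = p2) |>
    lapply(function(v) as.numeric(v))
}

# Column-stochastic one-step noise kernel with boundary reflection.
noise_matrix <- function(C, eps) {
  M <- diag(1 - eps, C)
  if (C == 1L) return(matrix(1, 1, 1))
  for (l in seq_len(C)) {
    down <- if (l == 1L) 2L else l - 1L
    up <- if (l == C) C - 1L else l + 1L
    M[down, l] <- M[down, l] + eps / 2
    M[up, l] <- M[up, l] + eps / 2
  }
  M
}
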