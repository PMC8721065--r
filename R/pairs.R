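#' Enumerate intra- and inter-rater comparisons for a study design
#'
#' In the two-occasion paired-rater design, each subject is assessed by
#' one pair of raters on each of two occasions.  The comparisons of
#' interest are then: one \emph{intra}-rater comparison per rater (its
#' occasion-1 vs occasion-2 assessments, over the subjects that rater
#' saw) and one \emph{inter}-rater comparison per occasion (the two
#' paired raters of every subject, at that occasion).
#'
#' @param data validated ratings data frame.
#' @param design optional list with elements \code{occasions}
#'   (default the occasions present in the data) and \code{pairing}
#'   (\code{"infer"}, the default, or a named list mapping subject id to
#'   its two rater ids).
#' @param mode which comparison families to enumerate.
#' @return list of comparison specifications (class
#'   \code{comparison_spec}), empty when the design cannot support the
#'   requested mode (single rater or single occasion).
#' @export
enumerate_comparisons <- function(data, design = NULL,
                                  mode = c("both", "intra", "inter")) {
  mode <- match.arg(mode)
  design <- resolve_design(data, design)
  out <- list()
  if (mode %in% c("both", "intra") && length(design$occasions) >= 2L) {
    for (r in design$raters)
      out[[length(out) + 1L]] <- comparison_spec(
        mode = "intra", rater = r,
        occasions = design$occasions[1:2])
  }
  if (mode %in% c("both", "inter") && length(design$raters) >= 2L) {
    for (o in design$occasions)
      out[[length(out) + 1L]] <- comparison_spec(mode = "inter", occasion = o)
  }
  out
}

comparison_spec <- function(mode, rater = NULL, occasions = NULL,
                            occasion = NULL) {
  label <- if (mode == "intra") paste0("intra:", rater)
           else paste0("inter:occ", occasion)
  structure(list(mode = mode, rater = rater, occasions = occasions,
                 occasion = occasion, label = label),
            class = "comparison_spec")
}

#' @export
print.comparison_spec <- function(x, ...) {
  if (x$mode == "intra")
    cat(sprintf("Intra-rater comparison: rater %s, occasion %d vs %d\n",
                x$rater, x$occasions[1], x$occasions[2]))
  else
    cat(sprintf("Inter-rater comparison: paired raters at occasion %d\n",
                x$occasion))
  invisible(x)
}

# Resolve the study design: rater pool, occasions, and the per-subject
# rater pairing.  "infer" derives the pairing from the data and errors
# when any subject was not rated by exactly two raters.
resolve_design <- function(data, design = NULL) {
  occasions <- design$occasions
  if (is.null(occasions)) occasions <- sort(unique(data$occasion))
  pairing <- design$pairing
  if (is.null(pairing)) pairing <- "infer"
  if (identical(pairing, "infer")) {
    by_subj <- split(data$rater_id, data$subject_id)
    pairing <- lapply(by_subj, function(r) sort(unique(r)))
    bad <- vapply(pairing, length, 1L) != 2L
    if (any(bad))
      stop("pairwise design requires exactly 2 raters per subject; ",
           "violated by subject(s): ",
           paste(utils::head(names(pairing)[bad], 5L), collapse = ", "))
  } else {
    pairing <- lapply(pairing, as.character)
    if (any(vapply(pairing, length, 1L) != 2L))
      stop("explicit pairing must give exactly 2 raters per subject")
  }
  list(occasions = as.integer(occasions),
       raters = sort(unique(data$rater_id)),
       pairing = pairing)
}

#' Extract the paired ordinal sample for one comparison
#'
#' Builds the per-subject (x, y) level pairs for a comparison at a given
#' analysis unit — a single item or a sum group.  For an intra-rater
#' comparison x is the rater's occasion-1 level and y its occasion-2
#' level; for an inter-rater comparison x and y are the subject's
#' first- and second-listed paired raters at the given occasion.  Levels
#' are shifted to 0-based categories; the category count C spans the
#' full theoretical range of the unit (e.g. 35 categories for a 0-34
#' total), so unobserved levels stay part of the metric.
#'
#' @param data validated ratings data frame.
#' @param scale an [ordinal_scale()] or scale source.
#' @param spec a comparison from [enumerate_comparisons()].
#' @param unit item id or sum-group name.
#' @param design optional design (see [enumerate_comparisons()]); needed
#'   to resolve rater pairs for inter-rater comparisons.
#' @return object of class \code{paired_sample}: integer vectors
#'   \code{x}, \code{y} in \code{0:(C-1)}, \code{C}, \code{subject_ids},
#'   the unit's original score offset, and the spec.
#' @export
extract_pairs <- function(data, scale, spec, unit, design = NULL) {
  scale <- load_scale(scale)
  if (unit %in% scale$items$item_id) {
    i <- match(unit, scale$items$item_id)
    lo <- scale$items$min_level[i]; hi <- scale$items$max_level[i]
    scores <- data[data$item_id == unit,
                   c("subject_id", "rater_id", "occasion", "score")]
  } else if (unit %in% names(scale$sum_groups)) {
    r <- group_range(scale, unit)
    lo <- r[1]; hi <- r[2]
    scores <- sum_scores(data, scale, unit)
  } else {
    stop("unit '", unit, "' is neither an item nor a sum group of scale '",
         scale$name, "'")
  }
  if (spec$mode == "intra") {
    sel1 <- scores$rater_id == spec$rater & scores$occasion == spec$occasions[1]
    sel2 <- scores$rater_id == spec$rater & scores$occasion == spec$occasions[2]
    s1 <- scores[sel1, ]; s2 <- scores[sel2, ]
  } else {
    design <- resolve_design(data, design)
    occ <- scores[scores$occasion == spec$occasion, ]
    pr <- design$pairing[occ$subject_id]
    first <- mapply(function(p) p[1], pr)
    second <- mapply(function(p) p[2], pr)
    s1 <- occ[occ$rater_id == first, ]
    s2 <- occ[occ$rater_id == second, ]
  }
  subjects <- intersect(s1$subject_id, s2$subject_id)
  dropped <- setdiff(union(s1$subject_id, s2$subject_id), subjects)
  if (length(dropped))
    warning(length(dropped), " subject(s) dropped from comparison ",
            spec$label, " (unit ", unit, "): missing one side: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  if (length(subjects) == 0L)
    stop("no usable subjects for comparison ", spec$label,
         " at unit '", unit, "'")
  subjects <- sort(subjects)
  x <- s1$score[match(subjects, s1$subject_id)] - lo
  y <- s2$score[match(subjects, s2$subject_id)] - lo
  paired_sample(x, y, C = hi - lo + 1L, subject_ids = subjects,
                offset = lo, unit = unit, spec = spec)
}

#' Construct a paired ordinal sample
#'
#' @param x,y integer category levels in \code{0:(C-1)}, one pair per
#'   subject; \code{x} from the first assessment, \code{y} from the
#'   second.
#' @param C number of ordered categories; defaults to the smallest count
#'   covering the observed levels.
#' @param subject_ids optional subject identifiers.
#' @param offset original score of category 0 (display only).
#' @param unit,spec optional provenance.
#' @return object of class \code{paired_sample}.
#' @export
paired_sample <- function(x, y, C = NULL, subject_ids = NULL, offset = 0L,
                          unit = NULL, spec = NULL) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) == 0L) stop("empty paired sample")
  if (is.null(C)) C <- max(x, y) + 1L
  C <- as.integer(C)
  if (any(x < 0L | x >= C) || any(y < 0L | y >= C))
    stop("levels must lie in 0:(C-1)")
  if (is.null(subject_ids)) subject_ids <- as.character(seq_along(x))
  structure(list(x = x, y = y, C = C, n = length(x),
                 subject_ids = subject_ids, offset = as.integer(offset),
                 unit = unit, spec = spec),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("Paired ordinal sample: n = %d subjects, C = %d categories\n",
              x$n, x$C))
  if (!is.null(x$unit)) cat("  unit:", x$unit, "\n")
  if (!is.null(x$spec)) cat("  comparison:", x$spec$label, "\n")
  invisible(x)
}

#' Tally a paired sample into a C x C contingency table
#'
#' Rows index the first assessment's category, columns the second's;
#' the statistics of the rank-invariant analysis are all functions of
#' this table.
#'
#' @param sample a [paired_sample()], or an integer vector \code{x} with
#'   \code{y} supplied.
#' @param y,C see [paired_sample()].
#' @return integer C x C matrix of counts.
#' @export
build_contingency <- function(sample, y = NULL, C = NULL) {
  if (!inherits(sample, "paired_sample"))
    sample <- paired_sample(sample, y, C = C)
  C <- sample$C
  counts <- tabulate(sample$x * C + sample$y + 1L, nbins = C * C)
  tab <- matrix(as.integer(counts), nrow = C, ncol = C, byrow = TRUE,
                dimnames = list(first = 0:(C - 1), second = 0:(C - 1)))
  tab
}

# Accept a contingency matrix or a paired sample everywhere.
as_table <- function(x) {
  if (inherits(x, "paired_sample")) return(build_contingency(x))
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("contingency table must be square")
    if (any(x < 0) || any(x != round(x))) stop("counts must be nonnegative integers")
    if (sum(x) < 1) stop("empty contingency table")
    return(x)
  }
  stop("expected a paired_sample or a square count matrix")
}

# Expand a contingency table back to level pairs (subject order lost).
table_to_pairs <- function(tab) {
  C <- nrow(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  x <- rep(idx[, 1] - 1L, tab[idx])
  y <- rep(idx[, 2] - 1L, tab[idx])
  list(x = as.integer(x), y = as.integer(y), C = C)
}
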