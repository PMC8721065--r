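#' Run the full reliability analysis for a rating study
#'
#' End-to-end driver: validates the ratings against the scale, infers or
#' applies the rater-pair design, enumerates all intra-rater (occasion 1
#' vs 2 per rater) and inter-rater (paired raters per occasion)
#' comparisons, and for every analysis unit — each item and each sum
#' group — computes percentage agreement (with extra point tolerances
#' and the minimum tolerance reaching the satisfactory threshold for
#' sum groups), RP, RC and RV with bootstrap confidence intervals and
#' disagreement flags, plus a floor/ceiling check on the scale's total
#' score at the first occasion.
#'
#' @param ratings path to a ratings CSV/TSV or a ratings data frame.
#' @param scale an [ordinal_scale()] or scale source (default the
#'   built-in FMA-LE).
#' @param design optional design list (see [enumerate_comparisons()]).
#' @param units analysis units; default all items then all sum groups.
#' @param tolerances extra point tolerances reported for sum-group
#'   agreement (default 1 and 2).
#' @param threshold satisfactory-agreement threshold in percent.
#' @param band negligibility half-width for RP/RC/RV.
#' @param B bootstrap resamples per interval.
#' @param level confidence level.
#' @param seed integer seed making the whole report reproducible.
#' @return object of class \code{reliability_report}: \code{pa_table}
#'   (units x comparisons percentage agreement, with tolerance rows for
#'   sum groups), \code{measures} (one data frame per comparison with
#'   estimates, CIs, flags and display strings), \code{min_tolerance}
#'   (sum groups x comparisons), \code{floor_ceiling}, and
#'   \code{metadata}.
#' @export
run_analysis <- function(ratings, scale = "fma_le", design = NULL,
                         units = NULL, tolerances = c(1L, 2L),
                         threshold = 70, band = 0.1, B = 2000L,
                         level = 0.95, seed = NULL) {
  scale <- load_scale(scale)
  if (is.character(ratings)) ratings <- read_ratings(ratings, scale)
  else ratings <- validate_ratings(ratings, scale)
  if (!is.null(seed)) set.seed(seed)
  specs <- enumerate_comparisons(ratings, design)
  if (length(specs) == 0L) stop("design supports no comparisons")
  labels <- vapply(specs, function(s) s$label, "")
  groups <- names(scale$sum_groups)
  if (is.null(units)) units <- c(scale$items$item_id, groups)
  unit_groups <- intersect(units, groups)

  pa_rows <- c(units, unlist(lapply(unit_groups, function(g)
    paste0(g, " (+", tolerances, ")"))))
  pa_table <- matrix(NA_real_, length(pa_rows), length(labels),
                     dimnames = list(pa_rows, labels))
  min_tol <- matrix(NA_integer_, length(unit_groups), length(labels),
                    dimnames = list(unit_groups, labels))
  measures <- stats::setNames(vector("list", length(labels)), labels)
  for (ci_spec in seq_along(specs)) {
    spec <- specs[[ci_spec]]
    rows <- list()
    for (u in units) {
      smp <- tryCatch(
        extract_pairs(ratings, scale, spec, u, design = design),
        error = function(e) {
          warning("comparison ", spec$label, ", unit '", u, "' skipped: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(smp)) next
      is_group <- u %in% unit_groups
      fit <- rank_agreement(smp,
                            tolerances = if (is_group) tolerances else integer(),
                            threshold = threshold, band = band,
                            ci = TRUE, B = B, level = level)
      pa_table[u, spec$label] <- fit$pa
      if (is_group) {
        for (j in seq_along(tolerances))
          pa_table[paste0(u, " (+", tolerances[j], ")"), spec$label] <-
            fit$pa_k[j]
        min_tol[u, spec$label] <- fit$min_k
      }
      rows[[u]] <- data.frame(
        unit = u,
        statistic = c("RP", "RC", "RV"),
        estimate = c(fit$rp, fit$rc, fit$rv),
        lower = vapply(fit$ci, function(iv) iv$lower, 0),
        upper = vapply(fit$ci, function(iv) iv$upper, 0),
        flag = unname(fit$flags),
        display = display_value(c(fit$rp, fit$rc, fit$rv)),
        n = fit$n,
        stringsAsFactors = FALSE)
    }
    m <- do.call(rbind, rows)
    rownames(m) <- NULL
    measures[[spec$label]] <- m
  }

  fc <- NULL
  total_group <- total_group_name(scale)
  if (!is.null(total_group)) {
    occ1 <- min(sort(unique(ratings$occasion)))
    totals <- sum_scores(ratings[ratings$occasion == occ1, , drop = FALSE],
                         scale, total_group)
    # one total per subject: average over the subject's raters would break
    # integer scores, so take the first-listed rater's assessment
    totals <- totals[!duplicated(totals$subject_id), , drop = FALSE]
    r <- group_range(scale, total_group)
    fc <- floor_ceiling(totals$score, r[1], r[2])
  }

  structure(list(pa_table = as.data.frame(pa_table),
                 measures = measures,
                 min_tolerance = as.data.frame(min_tol),
                 floor_ceiling = fc,
                 comparisons = specs,
                 metadata = list(
                   scale = scale$name,
                   n_records = nrow(ratings),
                   threshold = threshold, tolerances = tolerances,
                   band = band, B = B, level = level, seed = seed,
                   package_version = as.character(utils::packageVersion("rankagree")),
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "reliability_report")
}

# The sum group covering every item, if the scale defines one.
total_group_name <- function(scale) {
  for (g in names(scale$sum_groups))
    if (setequal(scale$sum_groups[[g]], scale$items$item_id)) return(g)
  if (length(scale$sum_groups)) names(scale$sum_groups)[
    which.max(lengths(scale$sum_groups))]
  else NULL
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Reliability report —", x$metadata$scale, "\n")
  cat(sprintf("  %d comparison(s): %s\n", length(x$comparisons),
              paste(names(x$measures), collapse = ", ")))
  cat("\nPercentage agreement:\n")
  print(round(x$pa_table, 1))
  if (nrow(x$min_tolerance)) {
    cat(sprintf("\nMinimum tolerance (points) for >= %.0f%% agreement:\n",
                x$metadata$threshold))
    print(x$min_tolerance)
  }
  if (!is.null(x$floor_ceiling)) {
    cat("\n"); print(x$floor_ceiling)
  }
  flagged <- do.call(rbind, lapply(names(x$measures), function(l) {
    m <- x$measures[[l]]
    m <- m[m$flag != "none", , drop = FALSE]
    if (nrow(m)) cbind(comparison = l, m) else NULL
  }))
  if (!is.null(flagged) && nrow(flagged)) {
    cat("\nFlagged disagreements:\n")
    print(flagged[, c("comparison", "unit", "statistic", "display",
                      "lower", "upper", "flag")], row.names = FALSE)
  } else cat("\nNo flagged disagreements.\n")
  invisible(x)
}

#' Write a reliability report to disk
#'
#' Writes the percentage-agreement table and one measures table per
#' comparison as CSV (display-rounded values alongside the raw
#' estimates), a JSON file with full-precision values and run metadata,
#' and optionally the ROC coordinates per comparison and unit.  The
#' JSON omits the wall-clock timestamp so that identical inputs, options
#' and seed reproduce byte-identical output.
#'
#' @param report a [run_analysis()] result.
#' @param out_dir output directory (created if needed).
#' @param formats subset of \code{c("csv", "json")}.
#' @param roc optional data frame of ROC requests with columns
#'   \code{comparison} and \code{unit}; requires \code{ratings} and
#'   \code{scale} used for the report.
#' @param ratings,scale,design original inputs, only needed for
#'   \code{roc}.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir, formats = c("csv", "json"),
                         roc = NULL, ratings = NULL, scale = NULL,
                         design = NULL) {
  if (!inherits(report, "reliability_report"))
    stop("report must be a reliability_report")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("cannot write to directory: ", out_dir)
  paths <- character()
  if ("csv" %in% formats) {
    p <- file.path(out_dir, "pa_table.csv")
    pa <- cbind(unit = rownames(report$pa_table),
                round(report$pa_table, 1))
    utils::write.csv(pa, p, row.names = FALSE)
    paths <- c(paths, p)
    for (l in names(report$measures)) {
      m <- report$measures[[l]]
      p <- file.path(out_dir,
                     paste0("measures_", gsub("[^A-Za-z0-9]+", "_", l), ".csv"))
      utils::write.csv(m, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    if (nrow(report$min_tolerance)) {
      p <- file.path(out_dir, "min_tolerance.csv")
      utils::write.csv(cbind(unit = rownames(report$min_tolerance),
                             report$min_tolerance), p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(out_dir, "report.json")
    meta <- report$metadata
    meta$timestamp <- NULL
    payload <- list(
      metadata = meta,
      pa_table = cbind(unit = rownames(report$pa_table), report$pa_table),
      min_tolerance = if (nrow(report$min_tolerance))
        cbind(unit = rownames(report$min_tolerance), report$min_tolerance)
        else NULL,
      measures = report$measures,
      floor_ceiling = if (!is.null(report$floor_ceiling))
        unclass(report$floor_ceiling) else NULL)
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "rows", pretty = TRUE)
    paths <- c(paths, p)
  }
  if (!is.null(roc)) {
    if (is.null(ratings) || is.null(scale))
      stop("roc output needs the original ratings and scale")
    scale <- load_scale(scale)
    if (is.character(ratings)) ratings <- read_ratings(ratings, scale)
    spec_by_label <- stats::setNames(report$comparisons,
                                     vapply(report$comparisons,
                                            function(s) s$label, ""))
    for (i in seq_len(nrow(roc))) {
      spec <- spec_by_label[[roc$comparison[i]]]
      if (is.null(spec)) stop("unknown comparison '", roc$comparison[i], "'")
      smp <- extract_pairs(ratings, scale, spec, roc$unit[i], design = design)
      pts <- roc_points(build_contingency(smp))
      p <- file.path(out_dir, paste0(
        "roc_", gsub("[^A-Za-z0-9]+", "_", roc$comparison[i]), "_",
        gsub("[^A-Za-z0-9]+", "_", roc$unit[i]), ".csv"))
      utils::write.csv(pts, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
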