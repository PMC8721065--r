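#' Define an ordinal rating instrument
#'
#' An ordinal scale is an ordered set of items, each scored on a small
#' integer range, together with named sum-score groups (subscales).  The
#' built-in Fugl-Meyer Assessment of the Lower Extremity (FMA-LE) has 17
#' items scored 0/1/2 and the standard subscale sums (SUM E II, SUM E III,
#' SUM E IV, SUM E, SUM F, TOTAL E-F with maxima 14, 4, 4, 28, 6, 34).
#'
#' @param name scale name.
#' @param items data frame with columns \code{item_id}, \code{label},
#'   \code{section}, \code{min_level}, \code{max_level}.  \code{item_id}
#'   must be unique and \code{min_level < max_level} for every item.
#' @param sum_groups named list of character vectors of item ids; each
#'   group defines a sum score.
#' @return an object of class \code{ordinal_scale}.
#' @seealso [load_scale()] for the built-in FMA-LE and config files.
#' @export
ordinal_scale <- function(name, items, sum_groups = list()) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  required <- c("item_id", "label", "section", "min_level", "max_level")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols))
    stop("items is missing column(s): ", paste(missing_cols, collapse = ", "))
  items$item_id <- as.character(items$item_id)
  items$min_level <- as.integer(items$min_level)
  items$max_level <- as.integer(items$max_level)
  if (anyDuplicated(items$item_id))
    stop("duplicate item_id in scale '", name, "': ",
         paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", "))
  bad <- items$max_level <= items$min_level
  if (any(bad))
    stop("max_level must exceed min_level for item(s): ",
         paste(items$item_id[bad], collapse = ", "))
  sum_groups <- lapply(sum_groups, as.character)
  for (g in names(sum_groups)) {
    unknown <- setdiff(sum_groups[[g]], items$item_id)
    if (length(unknown))
      stop("sum_group '", g, "' references unknown item(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(name = name, items = items, sum_groups = sum_groups),
            class = "ordinal_scale")
}

#' @export
print.ordinal_scale <- function(x, ...) {
  cat("Ordinal scale:", x$name, "\n")
  cat(" ", nrow(x$items), "items in",
      length(unique(x$items$section)), "section(s)\n")
  for (g in names(x$sum_groups)) {
    r <- group_range(x, g)
    cat(sprintf("  %-12s %d item(s), range %d-%d\n",
                g, length(x$sum_groups[[g]]), r[1], r[2]))
  }
  invisible(x)
}

# 17 FMA-LE items: sections E.I-E.V (lower extremity) and F (speed/
# coordination), all scored 0 (none) / 1 (partial) / 2 (full).
fma_le_scale <- function() {
  items <- data.frame(
    item_id = c("e1_flexors", "e1_extensors",
                "e2_hip_flexion", "e2_knee_flexion", "e2_ankle_dorsiflexion",
                "e2_hip_extension", "e2_hip_adduction", "e2_knee_extension",
                "e2_ankle_plantarflexion",
                "e3_knee_flexion", "e3_ankle_dorsiflexion",
                "e4_knee_flexion_90", "e4_ankle_dorsiflexion",
                "e5_normal_reflex_activity",
                "f_tremor", "f_dysmetria", "f_time"),
    label = c("Reflex activity: flexors", "Reflex activity: extensors",
              "Hip flexion (supine)", "Knee flexion (supine)",
              "Ankle dorsiflexion (supine)", "Hip extension (supine)",
              "Hip adduction (supine)", "Knee extension (supine)",
              "Ankle plantar flexion (supine)",
              "Knee flexion (sitting)", "Ankle dorsiflexion (sitting)",
              "Knee flexion to 90 degrees (standing)",
              "Ankle dorsiflexion (standing)",
              "Normal reflex activity (knee flexors, patellar, Achilles)",
              "Tremor", "Dysmetria", "Time"),
    section = c("E.I", "E.I",
                rep("E.II", 7), rep("E.III", 2), rep("E.IV", 2), "E.V",
                rep("F", 3)),
    min_level = 0L, max_level = 2L,
    stringsAsFactors = FALSE)
  e_items <- items$item_id[items$section != "F"]
  f_items <- items$item_id[items$section == "F"]
  ordinal_scale("fma_le", items, sum_groups = list(
    "SUM E II"  = items$item_id[items$section == "E.II"],
    "SUM E III" = items$item_id[items$section == "E.III"],
    "SUM E IV"  = items$item_id[items$section == "E.IV"],
    "SUM E"     = e_items,
    "SUM F"     = f_items,
    "TOTAL E-F" = items$item_id))
}

#' Load an ordinal scale definition
#'
#' Loads a scale from the built-in registry (currently only
#' \code{"fma_le"}), from a YAML or JSON config file, or from an
#' already-parsed list.  Config files use keys \code{name},
#' \code{items} (list of \code{id}, \code{label}, \code{section},
#' \code{min}, \code{max}) and \code{sum_groups} (name to item-id list).
#'
#' @param source built-in name, file path, or list.
#' @return an [ordinal_scale()].
#' @examples
#' scale <- load_scale("fma_le")
#' nrow(scale$items)  # 17
#' @export
load_scale <- function(source) {
  if (inherits(source, "ordinal_scale")) return(source)
  if (is.character(source) && length(source) == 1L) {
    if (identical(source, "fma_le")) return(fma_le_scale())
    if (!file.exists(source))
      stop("unknown built-in scale or missing file: '", source, "'")
    cfg <- if (grepl("\\.json$", source, ignore.case = TRUE))
      jsonlite::read_json(source, simplifyVector = FALSE)
    else yaml::read_yaml(source)
    return(load_scale(cfg))
  }
  if (!is.list(source)) stop("cannot interpret scale source")
  cfg <- source
  if (is.null(cfg$name) || is.null(cfg$items))
    stop("scale config must have 'name' and 'items'")
  items <- do.call(rbind, lapply(cfg$items, function(it) {
    if (is.null(it$id)) stop("scale config item without 'id'")
    data.frame(item_id = it$id,
               label = if (is.null(it$label)) it$id else it$label,
               section = if (is.null(it$section)) "" else it$section,
               min_level = if (is.null(it$min)) 0L else as.integer(it$min),
               max_level = if (is.null(it$max)) 2L else as.integer(it$max),
               stringsAsFactors = FALSE)
  }))
  groups <- if (is.null(cfg$sum_groups)) list() else
    lapply(cfg$sum_groups, function(g) unlist(g, use.names = FALSE))
  ordinal_scale(cfg$name, items, groups)
}

#' Score range of a sum group
#'
#' @param scale an [ordinal_scale()].
#' @param group sum-group name.
#' @return integer vector \code{c(min, max)} of the attainable sum range.
#' @export
group_range <- function(scale, group) {
  scale <- load_scale(scale)
  if (!group %in% names(scale$sum_groups))
    stop("unknown sum group '", group, "' for scale '", scale$name, "'")
  ids <- scale$sum_groups[[group]]
  idx <- match(ids, scale$items$item_id)
  c(sum(scale$items$min_level[idx]), sum(scale$items$max_level[idx]))
}

#' Read and validate long-format ratings
#'
#' Ratings are long-format records, one row per (subject, rater, occasion,
#' item) with an integer score.  Extra columns (age, NIHSS, ...) are kept
#' as uninterpreted metadata.
#'
#' @param path CSV/TSV file with header columns \code{subject_id},
#'   \code{rater_id}, \code{occasion}, \code{item_id}, \code{score}.
#' @param scale optional scale to validate against.
#' @param sep field separator; inferred from the extension by default.
#' @return validated data frame of ratings.
#' @export
read_ratings <- function(path, scale = NULL, sep = NULL) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  validate_ratings(df, scale = scale)
}

#' Validate a ratings data frame
#'
#' Checks required columns, the uniqueness of the
#' (subject, rater, occasion, item) key, and — when a scale is given —
#' that every item id exists and every score lies in its item's level
#' range.  Errors name the offending records.
#'
#' @param data data frame of ratings.
#' @param scale optional [ordinal_scale()] to validate items/scores against.
#' @return the validated data frame (invisibly unchanged apart from type
#'   normalisation of the key columns).
#' @export
validate_ratings <- function(data, scale = NULL) {
  required <- c("subject_id", "rater_id", "occasion", "item_id", "score")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("ratings are missing column(s): ", paste(missing_cols, collapse = ", "))
  data$subject_id <- as.character(data$subject_id)
  data$rater_id <- as.character(data$rater_id)
  data$item_id <- as.character(data$item_id)
  data$occasion <- as.integer(data$occasion)
  data$score <- as.integer(data$score)
  if (any(is.na(data$occasion)) || any(data$occasion < 1L))
    stop("occasion must be a positive integer")
  if (any(is.na(data$score)))
    stop("non-integer or missing score in ratings")
  key <- paste(data$subject_id, data$rater_id, data$occasion, data$item_id,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf(
      "duplicate rating record at row %d: subject %s, rater %s, occasion %d, item %s",
      d, data$subject_id[d], data$rater_id[d], data$occasion[d], data$item_id[d]))
  }
  if (!is.null(scale)) {
    scale <- load_scale(scale)
    unknown <- setdiff(unique(data$item_id), scale$items$item_id)
    if (length(unknown))
      stop("unknown item id(s) for scale '", scale$name, "': ",
           paste(unknown, collapse = ", "))
    idx <- match(data$item_id, scale$items$item_id)
    bad <- which(data$score < scale$items$min_level[idx] |
                 data$score > scale$items$max_level[idx])
    if (length(bad)) {
      b <- bad[1L]
      stop(sprintf(
        "score %d out of range [%d, %d] at row %d (subject %s, rater %s, occasion %d, item %s)",
        data$score[b], scale$items$min_level[idx[b]],
        scale$items$max_level[idx[b]], b, data$subject_id[b],
        data$rater_id[b], data$occasion[b], data$item_id[b]))
    }
  }
  data
}

#' Sum scores per assessment
#'
#' Sums the item scores of one sum group for every assessment, i.e. every
#' (subject, rater, occasion) combination.  Assessments missing one or
#' more items of the group are excluded from the result with a warning:
#' a partial sum is not comparable to a complete one.
#'
#' @param data validated ratings data frame.
#' @param scale an [ordinal_scale()] (or its name / config source).
#' @param group sum-group name defined in the scale.
#' @return data frame with columns \code{subject_id}, \code{rater_id},
#'   \code{occasion}, \code{score} (the integer sum).
#' @export
sum_scores <- function(data, scale, group) {
  scale <- load_scale(scale)
  if (!group %in% names(scale$sum_groups))
    stop("unknown sum group '", group, "' for scale '", scale$name, "'")
  data <- validate_ratings(data, scale)
  ids <- scale$sum_groups[[group]]
  sub <- data[data$item_id %in% ids, , drop = FALSE]
  key <- interaction(sub$subject_id, sub$rater_id, sub$occasion,
                     drop = TRUE, sep = "\r")
  n_items <- tapply(sub$item_id, key, function(x) length(unique(x)))
  sums <- tapply(sub$score, key, sum)
  keys <- do.call(rbind, strsplit(names(sums), "\r", fixed = TRUE))
  out <- data.frame(subject_id = keys[, 1L], rater_id = keys[, 2L],
                    occasion = as.integer(keys[, 3L]),
                    score = as.integer(sums),
                    stringsAsFactors = FALSE)
  complete <- n_items == length(ids)
  if (any(!complete)) {
    warning(sum(!complete), " assessment(s) excluded from '", group,
            "' sums for missing items: ",
            paste(utils::head(names(sums)[!complete], 5L), collapse = ", "),
            if (sum(!complete) > 5L) ", ..." else "")
    out <- out[complete, , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(out$subject_id, out$rater_id, out$occasion), , drop = FALSE]
}

#' Floor and ceiling effect detection
#'
#' A floor (ceiling) effect is flagged when strictly more than
#' \code{threshold} of the subjects score at the scale minimum (maximum).
#' With the default 15\% threshold, 9 of 60 subjects at the maximum
#' (exactly 15\%) is \emph{not} a ceiling effect; 10 of 60 is.
#'
#' @param totals integer vector of one total score per subject.
#' @param scale_min,scale_max the attainable score range.
#' @param threshold proportion above which an effect is flagged
#'   (strict inequality; default 0.15).
#' @return object of class \code{floor_ceiling} with counts and logical
#'   \code{floor_effect} / \code{ceiling_effect} flags.
#' @export
floor_ceiling <- function(totals, scale_min, scale_max, threshold = 0.15) {
  if (length(totals) == 0L) stop("no totals supplied")
  totals <- as.integer(totals)
  if (any(totals < scale_min | totals > scale_max))
    stop("totals outside [", scale_min, ", ", scale_max, "]")
  n <- length(totals)
  n_min <- sum(totals == scale_min)
  n_max <- sum(totals == scale_max)
  structure(list(n_subjects = n, n_at_min = n_min, n_at_max = n_max,
                 threshold = threshold,
                 floor_effect = n_min / n > threshold,
                 ceiling_effect = n_max / n > threshold),
            class = "floor_ceiling")
}

#' @export
print.floor_ceiling <- function(x, ...) {
  cat(sprintf("Floor/ceiling check (n = %d, threshold > %.0f%%)\n",
              x$n_subjects, 100 * x$threshold))
  cat(sprintf("  at minimum: %d (%.1f%%) -> floor effect: %s\n",
              x$n_at_min, 100 * x$n_at_min / x$n_subjects,
              if (x$floor_effect) "yes" else "no"))
  cat(sprintf("  at maximum: %d (%.1f%%) -> ceiling effect: %s\n",
              x$n_at_max, 100 * x$n_at_max / x$n_subjects,
              if (x$ceiling_effect) "yes" else "no"))
  invisible(x)
}
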