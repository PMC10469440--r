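#' Remove background features using blank samples
#'
#' A feature is treated as background if it is detected in *every* blank
#' sample and its representative intensity in the study samples is less than
#' `fold` times its representative intensity in the blanks. Features absent
#' from at least one blank are always retained, as are features whose sample
#' signal exceeds the fold threshold.
#'
#' @param table Study samples as a [feature_table()].
#' @param blank_table Blank injections as a [feature_table()]; must share
#'   feature ids with `table`.
#' @param fold Required sample-to-blank intensity ratio (default 5).
#' @param stat Summary statistic for the representative intensity over
#'   detected values; the default is the median.
#' @return The filtered [feature_table()]. The per-feature disposition is
#'   attached as attribute `"report"` (a data frame with columns
#'   `feature_id`, `in_all_blanks`, `sample_stat`, `blank_stat`, `kept`,
#'   `reason`).
#' @export
blank_filter <- function(table, blank_table, fold = 5, stat = median) {
  stopifnot(inherits(table, "feature_table"),
            inherits(blank_table, "feature_table"))
  shared <- intersect(colnames(table$intensities),
                      colnames(blank_table$intensities))
  if (length(shared) == 0L) {
    stop("blank table shares no feature ids with the sample table",
         call. = FALSE)
  }
  ids <- colnames(table$intensities)
  in_all_blanks <- rep(FALSE, length(ids))
  sample_stat <- blank_stat <- rep(NA_real_, length(ids))
  names(in_all_blanks) <- names(sample_stat) <- names(blank_stat) <- ids

  bm <- blank_table$intensities[, shared, drop = FALSE]
  in_all_blanks[shared] <- colSums(is.na(bm)) == 0L
  blank_stat[shared] <- apply(bm, 2, function(v) stat(v[!is.na(v)]))
  sample_stat <- apply(table$intensities, 2,
                       function(v) if (all(is.na(v))) NA_real_ else stat(v[!is.na(v)]))

  drop <- in_all_blanks &
    !is.na(sample_stat) &
    sample_stat < fold * blank_stat
  drop[in_all_blanks & is.na(sample_stat)] <- TRUE # blank-only feature

  report <- data.frame(
    feature_id = ids,
    in_all_blanks = unname(in_all_blanks),
    sample_stat = unname(sample_stat),
    blank_stat = unname(blank_stat),
    kept = unname(!drop),
    reason = ifelse(!drop, "kept",
                    sprintf("background: sample signal < %g-fold blank", fold)),
    stringsAsFactors = FALSE
  )
  out <- subset_features(table, ids[!drop])
  attr(out, "report") <- report
  out
}

#' Keep features detected in a minimum fraction of samples
#'
#' Retains exactly the features whose detection rate (fraction of samples
#' with a present value) is at least `min_rate`. The comparison is `>=` on
#' the exact fraction, with no rounding, so a feature detected in 40 of 100
#' samples survives the default 40% threshold and one detected in 39 does
#' not.
#'
#' @param table A [feature_table()].
#' @param min_rate Minimum detection rate in (0, 1]; default 0.40.
#' @return The filtered [feature_table()], with a `"report"` attribute
#'   giving each feature's detection rate and disposition.
#' @export
detection_filter <- function(table, min_rate = 0.40) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(min_rate) || length(min_rate) != 1L ||
      min_rate <= 0 || min_rate > 1) {
    stop("`min_rate` must lie in (0, 1]", call. = FALSE)
  }
  rate <- colMeans(!is.na(table$intensities))
  keep <- rate >= min_rate
  report <- data.frame(feature_id = colnames(table$intensities),
                       detection_rate = unname(rate),
                       kept = unname(keep),
                       stringsAsFactors = FALSE)
  out <- subset_features(table, colnames(table$intensities)[keep])
  attr(out, "report") <- report
  out
}

subset_features <- function(table, ids) {
  feature_table(table$intensities[, ids, drop = FALSE],
                table$features[table$features$feature_id %in% ids, ,
                               drop = FALSE])
}

#' Per-feature limit of detection and detection rate
#'
#' The limit of detection (LOD) of a feature is defined as its lowest
#' detected intensity; nondetects are later treated as left-censored at this
#' value. Features with no detected value have no LOD and are rejected.
#'
#' @param table A [feature_table()].
#' @return A data frame (`feature_id`, `lod`, `detection_rate`,
#'   `blank_flag`); `blank_flag` is `NA` unless filled in by
#'   [blank_filter()] reporting.
#' @export
compute_lod <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$intensities
  all_missing <- colSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    stop("feature(s) with no detected values: ",
         paste(colnames(m)[all_missing], collapse = ", "), call. = FALSE)
  }
  data.frame(
    feature_id = colnames(m),
    lod = apply(m, 2, min, na.rm = TRUE),
    detection_rate = unname(colMeans(!is.na(m))),
    blank_flag = NA,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
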