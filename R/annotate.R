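#' Match features to an annotation database by mass and retention time
#'
#' Each feature with a known mass and retention time is compared against
#' every database entry; entries within both the mass tolerance (parts per
#' million relative to the database mass, `|m_feat - m_db| / m_db * 1e6`)
#' and the absolute retention-time tolerance are reported as candidate
#' annotations, ranked by combined closeness
#' `|dppm| / ppm_tol + |drt| / rt_tol` (smaller is better) and capped at
#' `max_matches` per feature.
#'
#' @param table A [feature_table()] whose `features` carry `mass` and `rt`.
#' @param db Annotation database: a data frame with columns `name`, `mass`
#'   (Da), `rt` (min) and optionally `class` and `pathways`.
#' @param ppm_tol Mass tolerance in ppm (default 10).
#' @param rt_tol Retention-time tolerance in minutes (default 0.15).
#' @param max_matches Cap on candidate annotations per feature (default 10).
#' @return A data frame with one row per (feature, candidate) pair:
#'   `feature_id`, `name`, `delta_ppm`, `delta_rt`, `score`, `rank`, plus
#'   `class`/`pathways` when present in `db`. Features lacking mass or
#'   retention time are skipped with a warning.
#' @export
annotate_features <- function(table, db, ppm_tol = 10, rt_tol = 0.15,
                              max_matches = 10L) {
  stopifnot(inherits(table, "feature_table"), is.data.frame(db))
  need <- c("name", "mass", "rt")
  if (!all(need %in% names(db))) {
    stop("`db` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(db$mass <= 0)) stop("database masses must be positive", call. = FALSE)
  fi <- table$features
  if (!all(c("mass", "rt") %in% names(fi))) {
    stop("feature table carries no mass/rt annotations", call. = FALSE)
  }
  skipped <- is.na(fi$mass) | is.na(fi$rt)
  if (any(skipped)) {
    warning(sum(skipped), " feature(s) skipped: missing mass or retention time",
            call. = FALSE)
  }
  extra <- intersect(c("class", "pathways"), names(db))
  res <- lapply(which(!skipped), function(i) {
    dppm <- abs(fi$mass[i] - db$mass) / db$mass * 1e6
    drt <- abs(fi$rt[i] - db$rt)
    hit <- which(dppm <= ppm_tol & drt <= rt_tol)
    if (!length(hit)) return(NULL)
    score <- dppm[hit] / ppm_tol + drt[hit] / rt_tol
    ord <- order(score, db$name[hit])
    hit <- hit[ord][seq_len(min(length(hit), max_matches))]
    out <- data.frame(feature_id = fi$feature_id[i],
                      name = db$name[hit],
                      delta_ppm = dppm[hit],
                      delta_rt = drt[hit],
                      score = dppm[hit] / ppm_tol + drt[hit] / rt_tol,
                      rank = seq_along(hit),
                      stringsAsFactors = FALSE)
    for (cl in extra) out[[cl]] <- db[[cl]][hit]
    out
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    out <- data.frame(feature_id = character(), name = character(),
                      delta_ppm = numeric(), delta_rt = numeric(),
                      score = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Collapse multiple features annotated as the same compound
#'
#' When several features (different ions, isomers or duplicated peaks) map
#' to one compound, only the feature with the highest posterior-median ICC is
#' reported for that compound. Ties are broken by the narrower credible
#' interval, then by lexicographic feature id, so the result is
#' deterministic.
#'
#' @param icc_results Data frame of per-feature results with columns
#'   `feature_id`, `icc` and (optionally) `lower`, `upper`.
#' @param annotation Data frame mapping `feature_id` to compound `name`
#'   (e.g. the output of [annotate_features()]).
#' @return A data frame with one row per unique compound: the winning
#'   feature's result plus a `name` column. Dropped features are listed in
#'   the `"dropped"` attribute; compounds whose features all lack a fitted
#'   ICC are omitted with a warning.
#' @export
collapse_duplicates <- function(icc_results, annotation) {
  stopifnot(is.data.frame(icc_results), is.data.frame(annotation))
  if (!all(c("feature_id", "icc") %in% names(icc_results))) {
    stop("`icc_results` needs `feature_id` and `icc` columns", call. = FALSE)
  }
  if (!all(c("feature_id", "name") %in% names(annotation))) {
    stop("`annotation` needs `feature_id` and `name` columns", call. = FALSE)
  }
  ann <- unique(annotation[, c("feature_id", "name")])
  merged <- merge(ann, icc_results, by = "feature_id")
  missing <- setdiff(unique(ann$name), unique(merged$name[!is.na(merged$icc)]))
  merged <- merged[!is.na(merged$icc), , drop = FALSE]
  if (length(missing)) {
    warning("compound(s) without a fitted feature omitted: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(merged)) {
    stop("no annotated compound has a fitted ICC", call. = FALSE)
  }
  width <- if (all(c("lower", "upper") %in% names(merged))) {
    merged$upper - merged$lower
  } else {
    rep(0, nrow(merged))
  }
  ord <- order(merged$name, -merged$icc, width, merged$feature_id)
  merged <- merged[ord, , drop = FALSE]
  win <- !duplicated(merged$name)
  dropped <- merged[!win, c("name", "feature_id", "icc"), drop = FALSE]
  out <- merged[win, , drop = FALSE]
  rownames(out) <- NULL
  rownames(dropped) <- NULL
  attr(out, "dropped") <- dropped
  out
}
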