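#' Summarize ICCs by group (chemical class, pathway, centre, ...)
#'
#' Median and interquartile range of the posterior-median ICCs within each
#' group of a user-supplied mapping. Groups smaller than `min_group_size`
#' are excluded from the main report but listed in the `"excluded"`
#' attribute. The IQR is `Q3 - Q1` with linear-interpolation quantiles.
#'
#' @param results Data frame with `icc` and an id column (`feature_id` or
#'   `name`).
#' @param grouping Data frame mapping the same id column to a `group`
#'   column; may cover only a subset of `results`.
#' @param min_group_size Minimum members for a group to be reported
#'   (default 4).
#' @param id_col Name of the id column shared by `results` and `grouping`.
#' @return Data frame (`group`, `n`, `median_icc`, `q25`, `q75`, `iqr`)
#'   sorted by decreasing median ICC, with the undersized groups in
#'   `attr(, "excluded")`.
#' @export
summarize_groups <- function(results, grouping, min_group_size = 4L,
                             id_col = "feature_id") {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("`results` must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(id_col %in% names(results), id_col %in% names(grouping),
            "group" %in% names(grouping), "icc" %in% names(results))
  merged <- merge(grouping[, c(id_col, "group")], results[, c(id_col, "icc")],
                  by = id_col)
  merged <- merged[!is.na(merged$icc), , drop = FALSE]
  if (!nrow(merged)) stop("no grouped feature has an ICC", call. = FALSE)
  summ <- do.call(rbind, lapply(split(merged$icc, merged$group), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), median_icc = q[2], q25 = q[1], q75 = q[3],
               iqr = q[3] - q[1])
  }))
  summ <- data.frame(group = rownames(summ), summ, row.names = NULL,
                     stringsAsFactors = FALSE)
  keep <- summ$n >= min_group_size
  out <- summ[keep, , drop = FALSE]
  out <- out[order(-out$median_icc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- summ[!keep, , drop = FALSE]
  out
}

#' Centre-stratified two-level ICCs
#'
#' Refits the two-level model separately within each centre to check
#' whether repeatability differs by recruitment site. Centres without any
#' subject with replicate samples cannot separate within- from
#' between-subject variance and are skipped with a warning.
#'
#' @param table A [feature_table()].
#' @param metadata Sample metadata (see [run_feature_batch()]).
#' @param spec A two-level [model_spec()]; a three-level spec is demoted to
#'   two levels within each stratum.
#' @param mcmc An [mcmc_settings()].
#' @param master_seed Master seed; each centre uses an offset stream.
#' @return Data frame of per-feature results with a `center_id` column.
#' @export
stratify_by_center <- function(table, metadata, spec = model_spec(levels = 2),
                               mcmc = mcmc_settings(), master_seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (spec$levels != 2L) spec <- model_spec(levels = 2L,
                                            fixed_effects = spec$fixed_effects,
                                            age_df = spec$age_df,
                                            prior_nu = spec$prior_nu,
                                            prior_scale_mult = spec$prior_scale_mult)
  centers <- unique(metadata$center_id)
  out <- list()
  for (ci in seq_along(centers)) {
    cc <- centers[ci]
    md <- metadata[metadata$center_id == cc, , drop = FALSE]
    if (!any(duplicated(md$subject_id))) {
      warning("centre ", cc, " has no replicated subjects; skipped",
              call. = FALSE)
      next
    }
    sub <- feature_table(
      table$intensities[rownames(table$intensities) %in% md$sample_id, ,
                        drop = FALSE],
      table$features)
    batch <- run_feature_batch(sub, md, spec = spec, mcmc = mcmc,
                               master_seed = feature_seed(master_seed,
                                                          1000003L * ci))
    batch$results$center_id <- cc
    out[[cc]] <- batch$results
  }
  if (!length(out)) stop("no centre has replicated subjects", call. = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
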