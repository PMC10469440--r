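#' Per-feature seed stream
#'
#' Derives a deterministic per-feature seed from a master seed so that
#' fitting a single feature alone reproduces its fit within a batch.
#' @param master_seed Integer master seed.
#' @param index Feature index (1-based).
#' @return An integer seed below 2^31.
#' @export
feature_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 7919 * as.numeric(index)) %%
               .Machine$integer.max)
}

#' Fit the censored model to every feature of a table
#'
#' Orchestrates independent per-feature fits of the censored hierarchical
#' model. Each feature is log-transformed (natural log), its limit of
#' detection taken as the lowest detected intensity, nondetects flagged as
#' left-censored, and the model fitted with a per-feature seed derived from
#' `master_seed`. Failures (e.g. an all-censored feature) are caught,
#' reported in the result, and do not abort the remaining features.
#'
#' @param table A [feature_table()].
#' @param metadata Sample metadata with `sample_id`, `subject_id`,
#'   `center_id` and any covariates; must cover every sample in `table`.
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_settings()].
#' @param master_seed Integer master seed for the per-feature streams.
#' @param keep_draws If `TRUE`, attach each feature's full `metabicc_fit`
#'   (memory-heavy; default `FALSE`).
#' @param estimands Character subset of `c("three_level", "within_center",
#'   "two_level_datascale")` to compute per feature (data-scale only for
#'   two-level specs).
#' @return A list with `results` (data frame, one row per feature x
#'   estimand: ICC summaries plus posterior-median variance components,
#'   convergence flag and status) and, when requested, `fits`.
#' @export
run_feature_batch <- function(table, metadata, spec = model_spec(),
                              mcmc = mcmc_settings(), master_seed = 1L,
                              keep_draws = FALSE,
                              estimands = if (spec$levels == 3L)
                                c("three_level", "within_center")
                              else "two_level_log") {
  stopifnot(inherits(table, "feature_table"))
  ids <- rownames(table$intensities)
  if (!all(ids %in% metadata$sample_id)) {
    stop("metadata does not cover all samples in the feature table",
         call. = FALSE)
  }
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  covars <- md[, intersect(c("age", "sex", "bmi"), names(md)), drop = FALSE]

  rows <- list()
  fits <- list()
  for (f in seq_len(ncol(table$intensities))) {
    fid <- colnames(table$intensities)[f]
    v <- table$intensities[, f]
    res <- tryCatch({
      if (all(is.na(v))) stop("all values censored")
      lod <- min(v, na.rm = TRUE)
      y <- log(v)
      fit <- fit_censored_model(
        y, lod = log(lod),
        subject = md$subject_id,
        center = if (spec$levels == 3L) md$center_id else NULL,
        covariates = if (!is.null(spec$fixed_effects)) covars else NULL,
        spec = spec, mcmc = mcmc, seed = feature_seed(master_seed, f)
      )
      if (keep_draws) fits[[fid]] <- fit
      med <- apply(fit$draws[, intersect(colnames(fit$draws),
                                         c("sigma1_sq", "sigma2_sq",
                                           "sigma3_sq")), drop = FALSE],
                   2, median)
      out <- lapply(estimands, function(est) {
        r <- switch(est,
          three_level = icc_three_level(fit, id = fid),
          within_center = icc_within_center(fit, id = fid),
          two_level_log = {
            tot <- fit$draws[, "sigma1_sq"] + fit$draws[, "sigma2_sq"]
            icc_summary(fid, "two_level_log",
                        fit$draws[, "sigma2_sq"] / tot,
                        variance_proportions(fit))
          },
          two_level_datascale = icc_two_level_datascale(fit, id = fid),
          stop("unknown estimand: ", est)
        )
        r
      })
      out <- do.call(rbind, out)
      out$sigma1_sq <- med["sigma1_sq"]
      out$sigma2_sq <- med["sigma2_sq"]
      out$sigma3_sq <- if ("sigma3_sq" %in% names(med)) med["sigma3_sq"] else NA_real_
      out$converged <- fit$convergence$pass
      out$degenerate <- fit$degenerate
      if (fit$degenerate) { # ICC undefined when the data have no spread
        out$icc <- NA_real_
        out$class <- NA_character_
      }
      out$status <- "ok"
      out
    }, error = function(e) {
      data.frame(feature_id = fid, estimand = estimands[1],
                 icc = NA_real_, lower = NA_real_, upper = NA_real_,
                 prop_within = NA_real_, prop_subject = NA_real_,
                 prop_center = NA_real_, class = NA_character_,
                 sigma1_sq = NA_real_, sigma2_sq = NA_real_,
                 sigma3_sq = NA_real_, converged = FALSE, degenerate = NA,
                 status = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    rows[[f]] <- res
  }
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- list(results = results)
  if (keep_draws) out$fits <- fits
  out
}
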