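# ICC estimands computed draw-wise on the joint posterior, then summarized
# by the median and an equal-tailed 95% credible interval. Computing the
# ratio per draw (rather than from median variances) keeps the estimate
# faithful to the joint posterior when the variance components are
# correlated.

draws_matrix <- function(x, need_center = FALSE) {
  m <- if (inherits(x, "metabicc_fit")) x$draws else x
  if (!is.matrix(m) || !all(c("sigma1_sq", "sigma2_sq") %in% colnames(m))) {
    stop("need posterior draws with `sigma1_sq` and `sigma2_sq` columns",
         call. = FALSE)
  }
  if (need_center && !"sigma3_sq" %in% colnames(m)) {
    stop("three-level estimand requires `sigma3_sq` draws", call. = FALSE)
  }
  vc <- intersect(c("sigma1_sq", "sigma2_sq", "sigma3_sq"), colnames(m))
  if (any(m[, vc] < 0)) {
    stop("negative variance draw found; sampler contract violated",
         call. = FALSE)
  }
  m
}

icc_summary <- function(id, estimand, icc_draws, props) {
  data.frame(
    feature_id = id,
    estimand = estimand,
    icc = median(icc_draws),
    lower = unname(quantile(icc_draws, 0.025)),
    upper = unname(quantile(icc_draws, 0.975)),
    prop_within = props[1], prop_subject = props[2], prop_center = props[3],
    class = classify_repeatability(median(icc_draws)),
    stringsAsFactors = FALSE
  )
}

#' Three-level log-scale ICC from posterior draws
#'
#' The repeatability estimand for the nested model: the correlation between
#' two measurements of the same subject at the same centre,
#' `(sigma2_sq + sigma3_sq) / (sigma1_sq + sigma2_sq + sigma3_sq)`,
#' computed for every retained draw and summarized by the posterior median
#' and an equal-tailed 95% credible interval. Treating the between-centre
#' variance as part of the numerator assumes between-centre differences
#' reflect true biological differences between the recruited populations.
#'
#' @param x A `metabicc_fit` or a draws matrix with columns `sigma1_sq`,
#'   `sigma2_sq`, `sigma3_sq`.
#' @param id Identifier copied into the result (default "feature").
#' @return One-row data frame: `feature_id`, `estimand`, `icc` (posterior
#'   median), `lower`, `upper` (95% CrI), the three posterior-median
#'   variance proportions and the repeatability `class`.
#' @export
icc_three_level <- function(x, id = "feature") {
  m <- draws_matrix(x, need_center = TRUE)
  tot <- m[, "sigma1_sq"] + m[, "sigma2_sq"] + m[, "sigma3_sq"]
  icc <- (m[, "sigma2_sq"] + m[, "sigma3_sq"]) / tot
  icc_summary(id, "three_level", icc, variance_proportions(m))
}

#' Within-centre ICC from posterior draws
#'
#' Correlation between two measurements of the same subject when subjects
#' are only compared within their own centre:
#' `sigma2_sq / (sigma1_sq + sigma2_sq + sigma3_sq)` per draw. Never exceeds
#' the three-level ICC, draw-wise, because its numerator drops the
#' between-centre component.
#'
#' @inheritParams icc_three_level
#' @return One-row data frame as in [icc_three_level()].
#' @export
icc_within_center <- function(x, id = "feature") {
  m <- draws_matrix(x, need_center = TRUE)
  tot <- m[, "sigma1_sq"] + m[, "sigma2_sq"] + m[, "sigma3_sq"]
  icc <- m[, "sigma2_sq"] / tot
  icc_summary(id, "within_center", icc, variance_proportions(m))
}

#' Data-scale ICC for the two-level model under lognormality
#'
#' When log-intensities follow the two-level model with between-subject
#' variance `sigma_b_sq` and within-subject variance `sigma_w_sq`, the
#' intensities themselves are lognormal and their correlation across
#' replicates is `(exp(sigma_b_sq) - 1) / (exp(sigma_b_sq + sigma_w_sq) - 1)`.
#' This back-transformed ICC is defined for the two-level model only (no
#' published closed form exists for the three-level nesting) and never
#' exceeds the log-scale ICC.
#'
#' Given scalars, returns the closed-form value; given a two-level fit or
#' draws matrix, applies the formula per draw and summarizes by the median.
#'
#' @param x Either a two-level `metabicc_fit`/draws matrix, or the
#'   between-subject variance `sigma_b_sq` (log scale) with `sigma_w_sq`
#'   supplied.
#' @param sigma_w_sq Within-subject log-scale variance (scalar use only).
#' @param id Identifier for the result row (draws use only).
#' @return A scalar in \[0, 1\] for scalar input; otherwise a one-row data
#'   frame as in [icc_three_level()].
#' @export
icc_two_level_datascale <- function(x, sigma_w_sq = NULL, id = "feature") {
  datascale <- function(b, w) {
    ifelse(b + w == 0, 0, (exp(b) - 1) / (exp(b + w) - 1))
  }
  if (is.numeric(x) && !is.matrix(x)) {
    if (is.null(sigma_w_sq)) stop("`sigma_w_sq` required", call. = FALSE)
    if (any(x < 0) || any(sigma_w_sq < 0)) {
      stop("variances must be nonnegative", call. = FALSE)
    }
    return(datascale(x, sigma_w_sq))
  }
  m <- if (inherits(x, "metabicc_fit")) x$draws else x
  if ("sigma3_sq" %in% colnames(m)) {
    stop("data-scale ICC is defined for the two-level model only",
         call. = FALSE)
  }
  m <- draws_matrix(m)
  icc <- datascale(m[, "sigma2_sq"], m[, "sigma1_sq"])
  props <- variance_proportions(m)
  icc_summary(id, "two_level_datascale", icc, props)
}

#' Posterior variance proportions
#'
#' Fraction of total variance attributable to within-subject,
#' between-subject and between-centre variation, computed per draw and
#' summarized by the posterior median — the same convention used for the
#' ICC. Median proportions do not sum to exactly one (each is a marginal
#' summary of a skewed joint posterior) but stay within a few percent of it;
#' with constant draws they are exact.
#'
#' @inheritParams icc_three_level
#' @return Named numeric vector `(within, subject, center)` of posterior
#'   medians, summing to 1 up to posterior skewness; `center` is 0 for
#'   two-level draws.
#' @export
variance_proportions <- function(x) {
  m <- if (inherits(x, "metabicc_fit")) x$draws else x
  m <- draws_matrix(m)
  s3 <- if ("sigma3_sq" %in% colnames(m)) m[, "sigma3_sq"] else 0
  tot <- m[, "sigma1_sq"] + m[, "sigma2_sq"] + s3
  p <- cbind(within = m[, "sigma1_sq"] / tot,
             subject = m[, "sigma2_sq"] / tot,
             center = s3 / tot)
  apply(p, 2, median)
}

#' Classify an ICC into repeatability classes
#'
#' Conventional cut-offs for biomarker reliability: below 0.40 poor,
#' 0.40 to 0.75 fair, above 0.75 excellent.
#'
#' @param icc Numeric vector of ICC values in \[0, 1\].
#' @return Character vector of class labels
#'   (`"poor"`, `"fair"`, `"excellent"`).
#' @export
classify_repeatability <- function(icc) {
  if (any(icc < 0 | icc > 1, na.rm = TRUE)) {
    stop("ICC values must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(icc > 0.75, "excellent", ifelse(icc >= 0.40, "fair", "poor"))
  out[is.na(icc)] <- NA_character_
  out
}
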