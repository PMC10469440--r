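#' Describe a multicentre repeated-measures study design
#'
#' Captures the sampling structure of a multicentre biomarker-repeatability
#' study: how many subjects each centre recruited, which fraction of subjects
#' provided two samples (the remainder provided one), and the covariate
#' distributions used when generating synthetic metadata. Defaults reproduce
#' the four-centre serum study the package models: centres of 48, 25, 43 and
#' 41 subjects, 141 of 157 subjects with duplicate samples, age 60.5 (SD 6.6)
#' years, 61% female, BMI 25.3 (SD 4.1) kg/m^2, and a median 107-day
#' (IQR 34) gap between collections.
#'
#' @param center_sizes Integer vector of subjects per centre (all >= 1).
#' @param repeat_fraction Fraction of subjects with two samples, in \[0, 1\].
#' @param age_mean,age_sd Age distribution (years), truncated to \[35, 85\].
#' @param sex_prop Proportion female; sex is coded 1 = female, 0 = male.
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2), truncated to \[16, 50\].
#' @param days_between_median,days_between_iqr Gap between the two
#'   collections in days (metadata only; the model does not use dates).
#' @param deterministic_repeats If `TRUE`, exactly
#'   `round(repeat_fraction * n)` subjects (the first ones in enumeration
#'   order) get two samples, so counts are exact; if `FALSE` (default) each
#'   subject independently gets a second sample with probability
#'   `repeat_fraction`.
#' @return An object of class `study_design`.
#' @export
study_design <- function(center_sizes = c(48L, 25L, 43L, 41L),
                         repeat_fraction = 141 / 157,
                         age_mean = 60.5, age_sd = 6.6,
                         sex_prop = 0.61,
                         bmi_mean = 25.3, bmi_sd = 4.1,
                         days_between_median = 107,
                         days_between_iqr = 34,
                         deterministic_repeats = FALSE) {
  center_sizes <- as.integer(center_sizes)
  if (length(center_sizes) < 1L || any(is.na(center_sizes)) ||
      any(center_sizes < 1L)) {
    stop("all centre sizes must be integers >= 1", call. = FALSE)
  }
  if (!is.numeric(repeat_fraction) || repeat_fraction < 0 ||
      repeat_fraction > 1) {
    stop("`repeat_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (age_sd < 0 || bmi_sd < 0) {
    stop("covariate SDs must be nonnegative", call. = FALSE)
  }
  structure(list(center_sizes = center_sizes,
                 repeat_fraction = repeat_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_prop = sex_prop,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 days_between_median = days_between_median,
                 days_between_iqr = days_between_iqr,
                 deterministic_repeats = deterministic_repeats),
            class = "study_design")
}

#' Describe the feature population to simulate
#'
#' Each feature gets a grand mean on the natural-log intensity scale and a
#' triple of variance components (within-subject `sigma1_sq`, between-subject
#' `sigma2_sq`, between-centre `sigma3_sq`), each either fixed (scalar) or
#' drawn uniformly from a length-2 range. The default ranges are calibrated
#' so that across features the between-centre component averages about 6% of
#' the total variance and the implied ICC distribution is centred near 0.5,
#' the regime observed for serum LC-HRMS features.
#'
#' @param n_features Number of features to simulate.
#' @param mu_range Range of grand means on the natural-log intensity scale.
#' @param sigma_within_sq,sigma_subject_sq,sigma_center_sq Scalar (fixed
#'   value) or length-2 range for each variance component; all values must be
#'   nonnegative.
#' @param detection_target Per-feature target detection rate: scalar, a
#'   length-2 range sampled uniformly, or a length-`n_features` vector.
#'   Values must lie in (0, 1]; 1 means no censoring.
#' @param covariate_effects Optional named list with any of `age`, `sex`,
#'   `bmi`: fixed-effect coefficients on the log scale applied to the
#'   (centred) covariates.
#' @param mass_range,rt_range Ranges for the synthetic feature mass (Da) and
#'   retention time (min) used by annotation matching.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(n_features = 50L,
                         mu_range = c(9, 16),
                         sigma_within_sq = c(0.15, 0.75),
                         sigma_subject_sq = c(0.15, 0.75),
                         sigma_center_sq = c(0.01, 0.10),
                         detection_target = c(0.4, 1),
                         covariate_effects = NULL,
                         mass_range = c(80, 1000),
                         rt_range = c(0.5, 13)) {
  n_features <- as.integer(n_features)
  if (is.na(n_features) || n_features < 1L) {
    stop("`n_features` must be >= 1", call. = FALSE)
  }
  for (nm in c("sigma_within_sq", "sigma_subject_sq", "sigma_center_sq")) {
    v <- get(nm)
    if (!is.numeric(v) || !length(v) %in% 1:2 || any(v < 0)) {
      stop("`", nm, "` must be a nonnegative scalar or range", call. = FALSE)
    }
  }
  dt <- detection_target
  if (!is.numeric(dt) || any(dt <= 0) || any(dt > 1)) {
    stop("detection-rate targets must lie in (0, 1]", call. = FALSE)
  }
  if (!length(dt) %in% c(1L, 2L, n_features)) {
    stop("`detection_target` must be scalar, a range, or one value per feature",
         call. = FALSE)
  }
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), c("age", "sex", "bmi"))
    if (length(bad)) {
      stop("unknown covariate effects: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(n_features = n_features, mu_range = mu_range,
                 sigma_within_sq = sigma_within_sq,
                 sigma_subject_sq = sigma_subject_sq,
                 sigma_center_sq = sigma_center_sq,
                 detection_target = dt,
                 covariate_effects = covariate_effects,
                 mass_range = mass_range, rt_range = rt_range),
            class = "feature_spec")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

draw_component <- function(x, n) {
  if (length(x) == 1L) rep(x, n) else runif(n, x[1], x[2])
}

#' Left-censor an intensity vector at a target detection rate
#'
#' Places the censoring threshold at the empirical quantile such that the
#' detected fraction equals `target_rate` (up to one observation for ties),
#' and replaces values strictly below the threshold by `NA`. This inverts the
#' observed detection rates of a feature table: given a desired detection
#' rate, it constructs the limit of detection that would have produced it.
#'
#' @param values Numeric vector of (positive) intensities, no missing values.
#' @param target_rate Desired fraction of detected values, in (0, 1].
#' @return A list with `values` (censored vector, nondetects `NA`) and
#'   `threshold` (the limit of detection used; below `min(values)` when
#'   `target_rate` is 1 so that nothing is removed).
#' @export
censor_at_rate <- function(values, target_rate) {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      target_rate <= 0 || target_rate > 1) {
    stop("`target_rate` must lie in (0, 1]", call. = FALSE)
  }
  n <- length(values)
  k <- max(1L, round(target_rate * n)) # number detected
  sorted <- sort(values)
  if (k >= n) {
    thr <- sorted[1] * (1 - 1e-9) - 1e-12
  } else {
    thr <- sorted[n - k + 1] # smallest surviving value
  }
  out <- values
  out[out < thr] <- NA_real_
  list(values = out, threshold = thr)
}

#' Simulate a multicentre repeated-measures feature table with known truth
#'
#' Draws log-intensities from the three-level nested random-intercept model:
#' for sample *i* of subject *j* in centre *k*,
#' `log y_ijk = mu + u_k + u_jk + e_ijk`, with independent normal
#' centre, subject and residual terms of variances `sigma3_sq`, `sigma2_sq`
#' and `sigma1_sq`. Intensities are exponentiated to the data scale and then
#' left-censored per feature at the threshold matching its target detection
#' rate; nondetects are emitted as missing. The returned ground truth stores
#' the generating variances, the implied ICC
#' `(sigma2_sq + sigma3_sq) / (sigma1_sq + sigma2_sq + sigma3_sq)`, and the
#' censoring threshold (the feature's true limit of detection).
#'
#' @param design A [study_design()].
#' @param spec A [feature_spec()].
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list of class `metabicc_sim` with elements `features` (a
#'   [feature_table()]), `metadata` (one row per sample: `sample_id`,
#'   `subject_id`, `center_id`, `session`, `age`, `sex`, `bmi`, `date`) and
#'   `truth` (one row per feature with the generating parameters).
#' @examples
#' sim <- simulate_study(study_design(center_sizes = c(5, 5)),
#'                       feature_spec(n_features = 3), seed = 1)
#' dim(sim$features$intensities)
#' @export
simulate_study <- function(design = study_design(), spec = feature_spec(),
                           seed) {
  stopifnot(inherits(design, "study_design"), inherits(spec, "feature_spec"))
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  set.seed(as.integer(seed))

  n_cent <- length(design$center_sizes)
  n_subj <- sum(design$center_sizes)
  if (n_subj < 1L) stop("design has zero subjects", call. = FALSE)

  center_id <- rep(paste0("C", seq_len(n_cent)), design$center_sizes)
  subject_id <- sprintf("S%03d", seq_len(n_subj))

  if (design$deterministic_repeats) {
    n_two <- round(design$repeat_fraction * n_subj)
    n_rep <- rep(c(2L, 1L), c(n_two, n_subj - n_two))
  } else {
    n_rep <- 1L + rbinom(n_subj, 1L, design$repeat_fraction)
  }

  age <- rtruncnorm1(n_subj, design$age_mean, design$age_sd, 35, 85)
  bmi <- rtruncnorm1(n_subj, design$bmi_mean, design$bmi_sd, 16, 50)
  sex <- rbinom(n_subj, 1L, design$sex_prop)

  idx <- rep(seq_len(n_subj), n_rep)
  session <- unlist(lapply(n_rep, seq_len), use.names = FALSE)
  n_samp <- length(idx)

  first_date <- as.Date("2014-03-25") + round(rnorm(n_subj, 0, 45))
  gap_sd <- design$days_between_iqr / (2 * stats::qnorm(0.75))
  gap <- pmax(7, round(rnorm(n_subj, design$days_between_median, gap_sd)))
  date <- first_date[idx] + ifelse(session == 2L, gap[idx], 0L)

  metadata <- data.frame(
    sample_id = sprintf("SMP%04d", seq_len(n_samp)),
    subject_id = subject_id[idx],
    center_id = center_id[idx],
    session = session,
    age = round(age[idx], 1),
    sex = sex[idx],
    bmi = round(bmi[idx], 1),
    date = date,
    stringsAsFactors = FALSE
  )

  nf <- spec$n_features
  mu <- runif(nf, spec$mu_range[1], spec$mu_range[2])
  s1 <- draw_component(spec$sigma_within_sq, nf)
  s2 <- draw_component(spec$sigma_subject_sq, nf)
  s3 <- draw_component(spec$sigma_center_sq, nf)
  target <- if (length(spec$detection_target) == nf) {
    spec$detection_target
  } else {
    draw_component(spec$detection_target, nf)
  }

  eff <- spec$covariate_effects
  covar_shift <- rep(0, n_samp)
  if (!is.null(eff)) {
    if (!is.null(eff$age)) covar_shift <- covar_shift + eff$age * (metadata$age - mean(metadata$age))
    if (!is.null(eff$sex)) covar_shift <- covar_shift + eff$sex * (metadata$sex - mean(metadata$sex))
    if (!is.null(eff$bmi)) covar_shift <- covar_shift + eff$bmi * (metadata$bmi - mean(metadata$bmi))
  }

  cent_idx <- match(metadata$center_id, unique(center_id))
  feature_id <- sprintf("F%04d", seq_len(nf))
  intens <- matrix(NA_real_, n_samp, nf,
                   dimnames = list(metadata$sample_id, feature_id))
  lod <- numeric(nf)
  for (f in seq_len(nf)) {
    u_c <- rnorm(n_cent, 0, sqrt(s3[f]))
    u_s <- rnorm(n_subj, 0, sqrt(s2[f]))
    e <- rnorm(n_samp, 0, sqrt(s1[f]))
    logy <- mu[f] + covar_shift + u_c[cent_idx] + u_s[idx] + e
    cz <- censor_at_rate(exp(logy), target[f])
    intens[, f] <- cz$values
    lod[f] <- cz$threshold
  }

  feats <- data.frame(
    feature_id = feature_id,
    mass = round(runif(nf, spec$mass_range[1], spec$mass_range[2]), 5),
    rt = round(runif(nf, spec$rt_range[1], spec$rt_range[2]), 3),
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    feature_id = feature_id,
    mu = mu,
    sigma1_sq = s1, sigma2_sq = s2, sigma3_sq = s3,
    icc = (s2 + s3) / (s1 + s2 + s3),
    lod = lod,
    detection_target = target,
    stringsAsFactors = FALSE
  )
  if (!is.null(eff)) {
    for (nm in names(eff)) truth[[paste0("beta_", nm)]] <- eff[[nm]]
  }

  structure(list(features = feature_table(intens, feats),
                 metadata = metadata, truth = truth,
                 design = design, spec = spec, seed = as.integer(seed)),
            class = "metabicc_sim")
}

#' Write a simulation to delimited text files
#'
#' Emits the feature table (samples x features, empty cell = nondetect), the
#' sample metadata and the ground truth as CSV into `dir`.
#'
#' @param sim A `metabicc_sim` from [simulate_study()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "metabicc_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("feature_table.csv", "sample_metadata.csv",
                            "ground_truth.csv", "feature_info.csv"))
  tab <- data.frame(sample_id = rownames(sim$features$intensities),
                    sim$features$intensities, check.names = FALSE)
  write.csv(tab, paths[1], row.names = FALSE, na = "")
  write.csv(sim$metadata, paths[2], row.names = FALSE)
  write.csv(sim$truth, paths[3], row.names = FALSE)
  write.csv(sim$features$features, paths[4], row.names = FALSE)
  invisible(paths)
}
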