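# Shared fixtures built in code.

# Tiny feature table: counts of detected samples per feature are controlled.
toy_table <- function(n_samples = 10, detect_counts = c(10, 8, 4),
                      seed = 99, mass = NULL, rt = NULL) {
  set.seed(seed)
  nf <- length(detect_counts)
  m <- matrix(exp(rnorm(n_samples * nf, 10)), n_samples, nf,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("F%02d", seq_len(nf))))
  for (f in seq_len(nf)) {
    k <- detect_counts[f]
    if (k < n_samples) m[sample(n_samples, n_samples - k), f] <- NA
  }
  info <- data.frame(feature_id = colnames(m),
                     mass = mass %||% rep(NA_real_, nf),
                     rt = rt %||% rep(NA_real_, nf))
  feature_table(m, info)
}

# Sample/blank pair with one feature: blanks at 100, samples at ratio * 100.
make_blank_pair <- function(sample_over_blank, blank_complete = TRUE) {
  blank <- matrix(c(100, 100, 100), 3, 1,
                  dimnames = list(paste0("b", 1:3), "F01"))
  if (!blank_complete) blank[2, 1] <- NA
  samp <- matrix(rep(100 * sample_over_blank, 6), 6, 1,
                 dimnames = list(paste0("s", 1:6), "F01"))
  list(samples = feature_table(samp), blanks = feature_table(blank))
}

# Constant-draw posterior matrices for exact ICC arithmetic.
const_draws <- function(s1, s2, s3 = NULL, n = 10) {
  if (is.null(s3)) {
    cbind(sigma1_sq = rep(s1, n), sigma2_sq = rep(s2, n))
  } else {
    cbind(sigma1_sq = rep(s1, n), sigma2_sq = rep(s2, n),
          sigma3_sq = rep(s3, n))
  }
}

# Small simulated study + fit, reused across model tests.
quick_sim <- function(n_features = 1, detection = 1, seed = 7,
                      centers = c(20, 20), s = c(0.5, 0.5, 0.1),
                      repeat_fraction = 1) {
  simulate_study(
    study_design(center_sizes = centers, repeat_fraction = repeat_fraction,
                 deterministic_repeats = TRUE),
    feature_spec(n_features = n_features, mu_range = c(12, 12),
                 sigma_within_sq = s[1], sigma_subject_sq = s[2],
                 sigma_center_sq = s[3], detection_target = detection),
    seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
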