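#' Specify the censored hierarchical model
#'
#' @param levels 3 for the nested subjects-within-centres model, 2 for the
#'   subjects-only model (no centre intercepts).
#' @param fixed_effects Character vector naming metadata covariates to
#'   adjust for; `"age"` enters through a centred spline basis (see
#'   [build_age_smooth()]), others as linear terms. `NULL` fits the
#'   intercept-only model.
#' @param age_df Degrees of freedom of the age smooth (default 3).
#' @param prior_nu Degrees of freedom of the half-t priors on standard
#'   deviations and of the intercept t prior (default 3).
#' @param prior_scale_mult Prior scale multiplier: SD priors are
#'   half-t(`prior_nu`, 0, `prior_scale_mult` * sd(y)) and the intercept
#'   prior t(`prior_nu`, median(y), `prior_scale_mult` * sd(y)), the weakly
#'   informative family scaled to the observed log-intensities (default 2.5).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(levels = 3L, fixed_effects = NULL, age_df = 3L,
                       prior_nu = 3, prior_scale_mult = 2.5) {
  levels <- as.integer(levels)
  if (!levels %in% c(2L, 3L)) stop("`levels` must be 2 or 3", call. = FALSE)
  if (!is.null(fixed_effects)) {
    bad <- setdiff(fixed_effects, c("age", "sex", "bmi"))
    if (length(bad)) {
      stop("unsupported fixed effects: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(levels = levels, fixed_effects = fixed_effects,
                 age_df = as.integer(age_df), prior_nu = prior_nu,
                 prior_scale_mult = prior_scale_mult),
            class = "model_spec")
}

#' MCMC settings
#'
#' Defaults mirror common practice for per-feature variance-component
#' models: 10 000 iterations in each of 4 chains with the first half
#' discarded as burn-in and no thinning.
#'
#' @param iterations Iterations per chain.
#' @param chains Number of chains (>= 2, so that split-R-hat is defined).
#' @param burn_in Burn-in per chain; default half the iterations.
#' @param thin Thinning interval.
#' @param rhat_threshold Convergence threshold on split-R-hat (default 1.05).
#' @param ess_threshold Minimum effective sample size per variance parameter
#'   (default 400).
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 10000L, chains = 4L,
                          burn_in = iterations %/% 2L, thin = 1L,
                          rhat_threshold = 1.05, ess_threshold = 400) {
  iterations <- as.integer(iterations); chains <- as.integer(chains)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (chains < 2L) stop("`chains` must be >= 2 for diagnostics", call. = FALSE)
  if (!(iterations > burn_in && burn_in >= 0L)) {
    stop("need iterations > burn_in >= 0", call. = FALSE)
  }
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  structure(list(iterations = iterations, chains = chains,
                 burn_in = burn_in, thin = thin,
                 rhat_threshold = rhat_threshold,
                 ess_threshold = ess_threshold),
            class = "mcmc_settings")
}

#' Centred spline basis for a smooth age effect
#'
#' Natural cubic spline basis whose columns are centred so they enter the
#' model as ordinary fixed effects orthogonal to the intercept. With
#' `df = 1` the basis degenerates to a single centred linear term.
#'
#' @param age Numeric vector of ages (years).
#' @param df Degrees of freedom, >= 1; `df >= 2` gives a curved basis and
#'   requires at least `df + 1` distinct ages.
#' @return A numeric matrix with `length(age)` rows and `df` columns, column
#'   means zero. Attribute `"centers"` stores the subtracted column means.
#' @export
build_age_smooth <- function(age, df = 3L) {
  df <- as.integer(df)
  if (df < 1L) stop("`df` must be >= 1", call. = FALSE)
  if (length(unique(age)) < 2L) {
    stop("age is constant; no smooth term can be built", call. = FALSE)
  }
  if (length(unique(age)) < df + 1L) {
    stop("need at least df + 1 distinct ages", call. = FALSE)
  }
  basis <- if (df == 1L) {
    matrix(age, ncol = 1L)
  } else {
    unclass(splines::ns(age, df = df))
  }
  ctr <- colMeans(basis)
  basis <- sweep(basis, 2, ctr)
  colnames(basis) <- paste0("age_s", seq_len(df))
  attr(basis, "centers") <- ctr
  basis
}

# Dispersed per-chain initial variances around a crude moment estimate.
init_sigma_sq <- function(y_obs, levels) {
  v <- max(var(y_obs), 1e-6)
  jit <- exp(runif(3, -1, 1))
  c(v * 0.5, v * 0.5, if (levels == 3L) v * 0.1 else 0) * jit
}

#' Fit the left-censored nested random-intercept model to one feature
#'
#' Gibbs sampler for the multilevel tobit model of log-intensities:
#' `y_ijk = x' beta + u_k + u_jk + e_ijk` with centre intercepts
#' `u_k ~ N(0, sigma3_sq)` (three-level only), subject intercepts
#' `u_jk ~ N(0, sigma2_sq)` and residuals `e_ijk ~ N(0, sigma1_sq)`.
#' Observations flagged as censored are treated as latent values known only
#' to lie below the feature's log limit of detection and are integrated out
#' by truncated-normal data augmentation. Standard deviations carry
#' half-t(3) priors scaled to the observed data; the intercept a t(3) prior
#' centred at the observed median; covariate coefficients are flat.
#'
#' @param y Numeric vector of log-intensities. Censored entries may be `NA`
#'   (with `censored` left `NULL`) or carry any value with `censored`
#'   flagging them.
#' @param lod Log-scale limit of detection: scalar or per-observation vector.
#' @param subject,center Grouping vectors (coerced to factor); `center` may
#'   be `NULL` for the two-level model.
#' @param covariates Optional data frame of sample-level covariates
#'   (columns among `age`, `sex`, `bmi`) aligned with `y`.
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_settings()].
#' @param seed Optional integer seed set before sampling.
#' @return An object of class `metabicc_fit`: list with `draws` (matrix,
#'   one row per retained draw across chains, columns `sigma1_sq`,
#'   `sigma2_sq`, `sigma3_sq` (three-level), then coefficients), `chain`
#'   (chain label per draw), `convergence` (see [convergence_report()]),
#'   `spec`, `mcmc`, and `degenerate` (`TRUE` when the observed values have
#'   zero spread, in which case the ICC is undefined).
#' @examples
#' sim <- simulate_study(study_design(center_sizes = c(20, 20),
#'                                    repeat_fraction = 1),
#'                       feature_spec(n_features = 1, detection_target = 1),
#'                       seed = 7)
#' y <- log(sim$features$intensities[, 1])
#' fit <- fit_censored_model(y, lod = min(y) - 1,
#'                           subject = sim$metadata$subject_id,
#'                           center = sim$metadata$center_id,
#'                           mcmc = mcmc_settings(400, 2), seed = 1)
#' apply(fit$draws[, 1:3], 2, median)
#' @export
fit_censored_model <- function(y, lod, subject, center = NULL,
                               covariates = NULL, spec = model_spec(),
                               mcmc = mcmc_settings(), seed = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_settings"))
  n <- length(y)
  if (length(subject) != n) stop("`subject` length mismatch", call. = FALSE)
  censored <- is.na(y)
  if (all(censored)) {
    stop("all observations are censored; model not identifiable", call. = FALSE)
  }
  lod <- rep_len(as.numeric(lod), n)
  if (any(!is.finite(lod[censored]))) {
    stop("censoring thresholds must be finite", call. = FALSE)
  }

  subject <- factor(subject)
  if (!any(duplicated(subject))) {
    stop("no subject has replicate measurements; within- and between-subject ",
         "variance are jointly unidentifiable", call. = FALSE)
  }
  three_level <- spec$levels == 3L
  if (three_level) {
    if (is.null(center)) {
      stop("three-level model requires centre ids", call. = FALSE)
    }
    center <- factor(center)
    if (nlevels(center) < 2L) {
      stop("three-level model requires >= 2 centres", call. = FALSE)
    }
    cross <- rowSums(table(subject, center) > 0L)
    if (any(cross > 1L)) {
      stop("subjects must be nested within centres", call. = FALSE)
    }
  } else {
    center <- factor(rep("all", n))
  }

  X <- matrix(numeric(0), n, 0)
  scaling <- NULL
  if (!is.null(spec$fixed_effects)) {
    if (is.null(covariates)) {
      stop("`covariates` required for the adjusted model", call. = FALSE)
    }
    Xc <- NULL
    for (fe in spec$fixed_effects) {
      if (!fe %in% names(covariates)) {
        stop("covariate `", fe, "` not found", call. = FALSE)
      }
      v <- covariates[[fe]]
      cols <- if (fe == "age") {
        build_age_smooth(v, spec$age_df)
      } else {
        matrix(v - mean(v), ncol = 1, dimnames = list(NULL, fe))
      }
      Xc <- cbind(Xc, cols)
    }
    # standardize for sampling; coefficients rescaled on output
    scaling <- apply(Xc, 2, function(col) max(sd(col), 1e-12))
    Xc <- sweep(Xc, 2, scaling, "/")
    X <- cbind(X, Xc)
  }

  y_obs <- y[!censored]
  spread <- sd(y_obs)
  degenerate <- is.na(spread) || spread < 1e-12
  A <- spec$prior_scale_mult * if (degenerate) 1e-3 else spread
  b0_mean <- median(y_obs)
  b0_scale <- A
  y_fill <- ifelse(censored, lod, y) # value slot unused for censored entries

  # map each subject to its (single) centre
  subj_cent <- as.integer(center[match(levels(subject), as.character(subject))]) - 1L

  if (!is.null(seed)) set.seed(as.integer(seed))
  keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  draws <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    draws[[ch]] <- .gibbs_chain(
      y_fill, as.integer(censored), lod, X,
      as.integer(subject) - 1L, as.integer(center) - 1L, subj_cent,
      nlevels(subject), nlevels(center), three_level,
      mcmc$iterations, mcmc$burn_in, mcmc$thin,
      spec$prior_nu, A, A, A, b0_mean, b0_scale,
      init_sigma_sq(y_obs, spec$levels)
    )
  }
  par_names <- c("sigma1_sq", "sigma2_sq", "sigma3_sq", "intercept",
                 colnames(X))
  arr <- array(unlist(draws), dim = c(keep, length(par_names), mcmc$chains))
  all_draws <- do.call(rbind, draws)
  colnames(all_draws) <- par_names
  chain <- rep(seq_len(mcmc$chains), each = keep)

  # rescale standardized covariate coefficients back to the data scale
  if (!is.null(scaling)) {
    ix <- match(names(scaling), par_names)
    all_draws[, ix] <- sweep(all_draws[, ix, drop = FALSE], 2, scaling, "/")
    for (j in seq_along(ix)) arr[, ix[j], ] <- arr[, ix[j], ] / scaling[j]
  }

  monitor <- c("sigma1_sq", "sigma2_sq", if (three_level) "sigma3_sq",
               colnames(X))
  if (!three_level) {
    all_draws <- all_draws[, setdiff(par_names, "sigma3_sq"), drop = FALSE]
  }
  conv <- convergence_report(arr, par_names, monitor,
                             mcmc$rhat_threshold, mcmc$ess_threshold)

  structure(list(draws = all_draws, chain = chain, convergence = conv,
                 spec = spec, mcmc = mcmc, degenerate = degenerate,
                 n_obs = n, n_censored = sum(censored),
                 n_subjects = nlevels(subject),
                 n_centers = if (three_level) nlevels(center) else NA_integer_),
            class = "metabicc_fit")
}

#' @export
print.metabicc_fit <- function(x, ...) {
  cat(sprintf("<metabicc_fit> %d-level model, %d obs (%d censored), %d draws\n",
              x$spec$levels, x$n_obs, x$n_censored, nrow(x$draws)))
  med <- apply(x$draws[, intersect(colnames(x$draws),
                                   c("sigma1_sq", "sigma2_sq", "sigma3_sq")),
                       drop = FALSE], 2, median)
  print(round(med, 4))
  cat(sprintf("convergence: %s (max R-hat %.3f, min ESS %.0f)\n",
              if (x$convergence$pass) "ok" else "FLAGGED",
              max(x$convergence$table$rhat),
              min(x$convergence$table$ess)))
  invisible(x)
}
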