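# Split-chain convergence diagnostics computed on the retained draws.

split_chains <- function(mat) {
  # mat: draws x chains -> draws/2 x 2*chains
  L <- nrow(mat) %/% 2L
  cbind(mat[seq_len(L), , drop = FALSE],
        mat[nrow(mat) - L + seq_len(L), , drop = FALSE])
}

#' Split R-hat for one parameter
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends register as apparent nonconvergence.
#'
#' @param mat Matrix of retained draws, one column per chain.
#' @return The split-R-hat value (>= 1 in expectation at convergence).
#' @export
split_rhat <- function(mat) {
  m <- split_chains(mat)
  L <- nrow(m)
  if (L < 2L) return(NA_real_)
  means <- colMeans(m)
  vars <- apply(m, 2, var)
  W <- mean(vars)
  B <- L * var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Effective sample size across chains
#'
#' Autocorrelation-based effective sample size pooled over split chains,
#' with Geyer's initial-positive-sequence truncation of the lag sum.
#'
#' @param mat Matrix of retained draws, one column per chain.
#' @return Estimated effective number of independent draws.
#' @export
ess_bulk <- function(mat) {
  m <- split_chains(mat)
  L <- nrow(m); C <- ncol(m)
  if (L < 4L) return(NA_real_)
  W <- mean(apply(m, 2, var))
  if (W < .Machine$double.eps) return(L * C)
  max_lag <- min(L - 1L, 200L)
  rho_ch <- sapply(seq_len(C), function(c) {
    a <- acf(m[, c], lag.max = max_lag, plot = FALSE,
             demean = TRUE)$acf[-1]
    a * var(m[, c])
  })
  rho <- rowMeans(rho_ch) / W
  # Geyer: sum consecutive lag pairs while their sums remain positive
  s <- 0
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- L * C / max(1 + 2 * s, 1e-12)
  min(ess, L * C)
}

#' Convergence report over monitored parameters
#'
#' @param arr Array of retained draws, `draws x parameters x chains`.
#' @param par_names Parameter names (second dimension).
#' @param monitor Names of parameters to check.
#' @param rhat_threshold,ess_threshold Pass thresholds.
#' @return A list with `table` (per-parameter `rhat` and `ess`) and `pass`.
#' @export
convergence_report <- function(arr, par_names, monitor,
                               rhat_threshold = 1.05, ess_threshold = 400) {
  ix <- match(monitor, par_names)
  tab <- data.frame(
    parameter = monitor,
    rhat = vapply(ix, function(j) split_rhat(arr[, j, ]), numeric(1)),
    ess = vapply(ix, function(j) ess_bulk(arr[, j, ]), numeric(1)),
    stringsAsFactors = FALSE
  )
  var_pars <- grepl("^sigma", tab$parameter)
  pass <- all(tab$rhat < rhat_threshold, na.rm = TRUE) &&
    all(tab$ess[var_pars] > ess_threshold, na.rm = TRUE)
  list(table = tab, pass = pass,
       rhat_threshold = rhat_threshold, ess_threshold = ess_threshold)
}
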