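#' Simulate a collection of test-accuracy studies with known truth
#'
#' Generates study-level 2x2 tables from the same generative model the
#' package fits: each study draws a (logit-sensitivity,
#' logit-specificity) pair from a bivariate normal with means
#' `(beta1, beta0)`, SDs `(tau1, tau0)` and correlation `rho`, and a
#' logit-prevalence from an independent `N(alpha, tau_alpha^2)`; then
#' `n1 ~ Bin(N, prev)`, `r11 ~ Bin(n1, sens)`, `r00 ~ Bin(n0, spec)`.
#' The default parameters emulate the ear-thermometry meta-analysis that
#' motivates the package: a moderately sensitive, highly specific test
#' with substantial heterogeneity in both margins, a negative
#' between-study correlation, outcome prevalence near one half, and
#' study sizes from a few dozen to several hundred patients.
#'
#' Prevalence is simulated independently of the accuracy latents; a
#' `prev_coupling` coefficient adds a linear dependence of
#' logit-prevalence on the (standardised) sensitivity latent for
#' stress-testing prevalence-aware prediction strategies. A study whose
#' sampled `n1` or `n0` is zero is redrawn (bounded retries) so every
#' study carries both margins.
#'
#' @param k number of studies.
#' @param beta1,beta0 mean logit-sensitivity and logit-specificity.
#' @param tau1,tau0 between-study SDs (>= 0).
#' @param rho between-study correlation in `[-1, 1]`.
#' @param alpha,tau_alpha mean and SD of the logit-prevalence.
#' @param n_range inclusive range of study sizes (drawn uniformly), or a
#'   single number for a fixed size.
#' @param prev_coupling coefficient linking logit-prevalence to the
#'   standardised sensitivity latent (default 0 = independent).
#' @param seed integer seed; fixed seed gives an identical dataset.
#' @param max_retries redraw budget per study for degenerate samples.
#' @return list with `data` (an [acc_dataset()]) and `truth` (data.frame
#'   of the per-study latent sensitivity, specificity and prevalence).
#' @examples
#' sim <- simulate_dataset(k = 5, seed = 1)
#' sim$data
#' @export
simulate_dataset <- function(k = 11, beta1 = 0.62, beta0 = 4.0,
                             tau1 = 0.9, tau0 = 0.8, rho = -0.6,
                             alpha = -0.16, tau_alpha = 0.45,
                             n_range = c(40, 900), prev_coupling = 0,
                             seed = NULL, max_retries = 100) {
  stopifnot(k >= 2, tau1 >= 0, tau0 >= 0, abs(rho) <= 1, tau_alpha >= 0)
  if (length(n_range) == 1) n_range <- rep(n_range, 2)
  if (n_range[1] < 2) stop("study size must be at least 2")
  if (!is.null(seed)) set.seed(seed)

  one_study <- function(i) {
    for (try in seq_len(max_retries)) {
      z1 <- stats::rnorm(1)
      z2 <- stats::rnorm(1)
      l_sens <- beta1 + tau1 * z1
      l_spec <- beta0 + tau0 * (rho * z1 + sqrt(1 - rho^2) * z2)
      l_prev <- alpha + prev_coupling * z1 + tau_alpha * stats::rnorm(1)
      N <- if (n_range[1] == n_range[2]) n_range[1]
           else sample(n_range[1]:n_range[2], 1)
      n1 <- stats::rbinom(1, N, stats::plogis(l_prev))
      n0 <- N - n1
      if (n1 == 0 || n0 == 0) next
      return(data.frame(
        study_id = sprintf("sim%02d", i),
        r11 = stats::rbinom(1, n1, stats::plogis(l_sens)), n1 = n1,
        r00 = stats::rbinom(1, n0, stats::plogis(l_spec)), n0 = n0,
        sens_true = stats::plogis(l_sens),
        spec_true = stats::plogis(l_spec),
        prev_true = stats::plogis(l_prev),
        logit_sens = l_sens, logit_spec = l_spec,
        stringsAsFactors = FALSE))
    }
    stop("could not draw a non-degenerate study after ", max_retries,
         " retries (study ", i, ")")
  }
  df <- do.call(rbind, lapply(seq_len(k), one_study))
  list(data = acc_dataset(df[, c("study_id", "r11", "n1", "r00", "n0")],
                          name = "simulated"),
       truth = df[, c("study_id", "sens_true", "spec_true", "prev_true",
                      "logit_sens", "logit_spec")])
}

#' Simulate study collections of continuous test scores with known c
#'
#' For each study a true c statistic `theta_i ~ N(mu_c, tau_c^2)`
#' (redrawn, with logging, if it falls outside (0.5, 1)) is converted to
#' a binormal score model: non-diseased scores are `N(0, 1)` and
#' diseased scores are `N(sqrt(2) * qnorm(theta_i), 1)`, for which the
#' population AUC equals `theta_i` exactly.
#'
#' @param k number of studies.
#' @param mu_c summary c statistic in `(0.5, 1)`.
#' @param tau_c between-study SD of the true c (>= 0).
#' @param n patients per study (single value or length-k vector).
#' @param prev expected proportion diseased per study.
#' @param seed integer seed.
#' @return list of `k` study records, each with `study_id`, `scores`,
#'   `labels`, and the latent `theta`.
#' @export
simulate_cstat_collection <- function(k = 5, mu_c = 0.9, tau_c = 0.04,
                                      n = 100, prev = 0.25, seed = NULL) {
  stopifnot(mu_c > 0.5, mu_c < 1, tau_c >= 0, prev > 0, prev < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- rep_len(n, k)
  lapply(seq_len(k), function(i) {
    theta <- stats::rnorm(1, mu_c, tau_c)
    tries <- 0
    while (theta <= 0.5 || theta >= 1) {
      tries <- tries + 1
      if (tries > 100) stop("could not draw theta inside (0.5, 1)")
      theta <- stats::rnorm(1, mu_c, tau_c)
    }
    if (tries > 0)
      message("study ", i, ": redrew theta ", tries, " time(s)")
    repeat {
      lab <- stats::rbinom(n[i], 1, prev)
      if (sum(lab) > 0 && sum(lab) < n[i]) break
    }
    mu_d <- sqrt(2) * stats::qnorm(theta)
    sc <- ifelse(lab == 1, stats::rnorm(n[i], mu_d, 1),
                 stats::rnorm(n[i], 0, 1))
    list(study_id = sprintf("sim%02d", i), scores = sc, labels = lab,
         theta = theta)
  })
}
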