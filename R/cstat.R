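#' Concordance (c) statistic of a continuous test
#'
#' Mann-Whitney estimator of the area under the ROC curve: the
#' probability that a randomly chosen diseased patient has a higher test
#' value than a randomly chosen non-diseased patient, with ties counted
#' one half. Computed from midranks in O(n log n).
#'
#' @param scores numeric test values.
#' @param labels binary outcome per patient (1/TRUE = diseased).
#' @return c statistic in `[0, 1]`.
#' @examples
#' c_statistic(c(3, 5, 1, 4), c(1, 1, 0, 0))  # 0.75
#' @export
c_statistic <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- as.numeric(sum(labels)); n0 <- as.numeric(sum(!labels))
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)  # midranks handle ties as 0.5
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap standard error of the c statistic
#'
#' SD of the c statistic over `B` resamples stratified by outcome class
#' (diseased and non-diseased patients are resampled within class, so
#' every replicate retains both classes and the observed prevalence).
#'
#' @inheritParams c_statistic
#' @param B bootstrap replicates (at least 100; default 1000).
#' @param seed integer seed for reproducibility.
#' @return bootstrap SE (a single number).
#' @export
bootstrap_se_c <- function(scores, labels, B = 1000, seed = NULL) {
  labels <- as.logical(labels)
  if (B < 100) stop("B must be at least 100")
  i1 <- which(labels); i0 <- which(!labels)
  if (!length(i1) || !length(i0)) stop("both outcome classes must be present")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cs <- vapply(seq_len(B), function(b) {
    s1 <- sample(i1, replace = TRUE)
    s0 <- sample(i0, replace = TRUE)
    c_statistic(scores[c(s1, s0)],
                c(rep(TRUE, length(s1)), rep(FALSE, length(s0))))
  }, 0)
  stats::sd(cs)
}

#' Random-effects meta-analysis by the method of moments
#'
#' DerSimonian-Laird pooling of study estimates with known sampling
#' standard errors: the between-study variance is
#' \deqn{\hat\tau^2 = \max\left(0, \frac{Q - (k-1)}
#'   {\sum w_i - \sum w_i^2 / \sum w_i}\right)}
#' with fixed-effect weights \eqn{w_i = 1/s_i^2} and Cochran's Q, after
#' which random-effects weights \eqn{1/(s_i^2 + \hat\tau^2)} give the
#' pooled mean. Used for c statistics and for the log observed/expected
#' ratios of the cross-validation engine.
#'
#' @param estimate per-study estimates.
#' @param se per-study sampling SEs (all positive).
#' @return Object of class `re_moments`: `mu`, `se_mu`, `tau2`, `tau`,
#'   `k`, `Q`, `I2` (percent), `method = "moments"`, and the inputs.
#' @export
fit_re_moments <- function(estimate, se) {
  if (length(estimate) != length(se)) stop("length mismatch")
  k <- length(estimate)
  if (k < 2) stop("at least 2 studies are required")
  if (any(!is.finite(se) | se <= 0)) stop("all standard errors must be > 0")
  w <- 1 / se^2
  mu_fe <- sum(w * estimate) / sum(w)
  Q <- sum(w * (estimate - mu_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  mu <- sum(wr * estimate) / sum(wr)
  structure(list(mu = mu, se_mu = sqrt(1 / sum(wr)), tau2 = tau2,
                 tau = sqrt(tau2), k = k, Q = Q,
                 I2 = max(0, (Q - (k - 1)) / Q) * 100,
                 method = "moments", estimate = estimate, se = se),
            class = "re_moments")
}

#' @export
print.re_moments <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (method of moments), k = %d\n",
              x$k))
  cat(sprintf("  mu = %.4f (SE %.4f), tau = %.4f, Q = %.2f, I2 = %.0f%%\n",
              x$mu, x$se_mu, x$tau, x$Q, x$I2))
  invisible(x)
}

#' Prediction interval for the c statistic in a new population
#'
#' \eqn{\hat\mu \pm t_{k-2}\sqrt{\hat\tau^2 + \mathrm{Var}(\hat\mu)}},
#' reported truncated to `[0, 1]`; the untruncated bounds are attached as
#' attribute `untruncated`.
#'
#' @param fit a [fit_re_moments()] result with `k >= 3`.
#' @param level coverage probability.
#' @export
c_prediction_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "re_moments"))
  if (fit$k < 3) stop("prediction interval needs k >= 3")
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$k - 2)
  s <- sqrt(fit$tau2 + fit$se_mu^2)
  raw <- c(fit$mu - tq * s, fit$mu + tq * s)
  out <- structure(list(lower = max(0, raw[1]), upper = min(1, raw[2]),
                        level = level, df = fit$k - 2, margin = "c statistic"),
                   class = "pred_interval")
  attr(out, "untruncated") <- raw
  out
}

jags_cstat <- "
model {
  for (i in 1:k) {
    c[i] ~ dnorm(theta[i], pow(s[i], -2))
    theta[i] ~ dnorm(mu, prec)
  }
  mu ~ dunif(mu_lo, mu_hi)
  tau ~ dunif(tau_lo, tau_hi)
  prec <- pow(tau, -2)
  theta_new ~ dnorm(mu, prec)
}"

#' Bayesian meta-analysis of c statistics with exceedance probabilities
#'
#' Normal-likelihood hierarchical model for study c statistics with
#' uniform priors on the summary mean (default `U(0.5, 1)`: no worse than
#' chance, no better than perfect) and the between-study SD (default
#' `U(0, 0.25)`). At each retained iteration a predictive c for a new
#' population is drawn, from which `P(c_new > threshold)` is estimated
#' for each requested threshold.
#'
#' @inheritParams fit_re_moments
#' @param thresholds thresholds for exceedance probabilities.
#' @param priors list with `mu` (length-2 support of the uniform prior on
#'   the mean) and `tau` (support of the uniform prior on the SD).
#' @param n_iter,burn_in,seed MCMC settings.
#' @return Object of class `cstat_bayes`: posterior `draws` (`mu`, `tau`,
#'   `c_new`), `exceedance` named by threshold, and posterior summaries.
#' @export
bayes_c_meta <- function(estimate, se, thresholds = c(0.8, 0.9),
                         priors = list(), n_iter = 20000, burn_in = 2000,
                         seed = 1) {
  if (any(se <= 0)) stop("all standard errors must be > 0")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must be in (0, 1)")
  pr <- utils::modifyList(list(mu = c(0.5, 1), tau = c(0, 0.25)), priors)
  if (all(estimate < pr$mu[1]) || all(estimate > pr$mu[2]))
    warning("all estimates lie outside the prior support for mu ",
            "(prior-data conflict)")
  dat <- list(c = estimate, s = se, k = length(estimate),
              mu_lo = pr$mu[1], mu_hi = pr$mu[2],
              tau_lo = pr$tau[1], tau_hi = pr$tau[2])
  inits <- list(mu = mean(pmin(pmax(estimate, pr$mu[1] + 1e-3),
                               pr$mu[2] - 1e-3)),
                tau = mean(pr$tau),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed))
  jm <- rjags::jags.model(textConnection(jags_cstat), data = dat,
                          inits = inits, n.chains = 1, n.adapt = 1000,
                          quiet = TRUE)
  stats::update(jm, burn_in, progress.bar = "none")
  sam <- rjags::coda.samples(jm, c("mu", "tau", "theta_new"),
                             n.iter = n_iter, progress.bar = "none")
  m <- as.matrix(sam[[1]])
  colnames(m) <- c("mu", "tau", "c_new")
  exc <- vapply(thresholds, function(t) mean(m[, "c_new"] > t), 0)
  names(exc) <- paste0("P(c_new > ", thresholds, ")")
  structure(list(draws = m, exceedance = exc,
                 mu = stats::median(m[, "mu"]),
                 tau = stats::median(m[, "tau"]),
                 priors = pr, n_iter = n_iter, burn_in = burn_in,
                 seed = seed, k = length(estimate)),
            class = "cstat_bayes")
}

#' @export
print.cstat_bayes <- function(x, ...) {
  cat(sprintf("Bayesian c-statistic meta-analysis, k = %d\n", x$k))
  cat(sprintf("  posterior median mu = %.3f, tau = %.3f\n", x$mu, x$tau))
  for (nm in names(x$exceedance))
    cat(sprintf("  %s = %.3f\n", nm, x$exceedance[nm]))
  invisible(x)
}
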