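#' Bivariate binomial logit-normal meta-analysis by maximum likelihood
#'
#' Jointly pools sensitivity and specificity across studies. The true
#' positives and true negatives of each study are modelled with exact
#' binomial likelihoods, and the study-specific logit-sensitivity and
#' logit-specificity pairs are assumed bivariate normal with means
#' \eqn{(\beta_1, \beta_0)}, between-study SDs \eqn{(\tau_1, \tau_0)}
#' and correlation \eqn{\rho}. The marginal likelihood is integrated by
#' adaptive Gauss-Hermite quadrature (tensor grid, per-study
#' mode/curvature centering) and maximised over the unconstrained
#' parameterisation \eqn{(\beta_1, \beta_0, \log\tau_1, \log\tau_0,
#' \mathrm{atanh}\,\rho)}; up to five jittered restarts are attempted on
#' non-convergence.
#'
#' @param data an [acc_dataset()] with at least 2 studies.
#' @param n_quad quadrature nodes per dimension (default 10).
#' @param start optional start values `c(beta1, beta0, log tau1, log tau0,
#'   atanh rho)`; defaults to continuity-corrected observed logits (the
#'   correction seeds the optimiser only, never the likelihood).
#' @param tau_zero if `TRUE`, fixes both between-study SDs at zero so the
#'   model collapses to two pooled binomial proportions (useful as a
#'   no-heterogeneity reference).
#' @return Object of class `bivfit_ml` with elements `beta1`, `beta0`,
#'   `tau1`, `tau0`, `rho`, `vcov_means` (2x2 covariance of the mean
#'   logits), `loglik`, `k`, `converged`, `n_quad`.
#' @examples
#' fit <- fit_bivariate_ml(load_fixture("temperature"))
#' summary_accuracy(fit)
#' @export
fit_bivariate_ml <- function(data, n_quad = 10, start = NULL,
                             tau_zero = FALSE) {
  stopifnot(inherits(data, "acc_dataset"))
  k <- nrow(data)
  if (k < 2) stop("at least 2 studies are required")
  if (k < 5)
    warning("fewer than 5 studies: between-study variance estimates are ",
            "unstable")
  if (n_quad < 3) stop("n_quad must be at least 3")
  if (all(data$r11 %in% c(0, data$n1)) && all(data$r00 %in% c(0, data$n0)))
    warning("all studies have observed sensitivity and specificity of 0 or ",
            "1; estimates will sit at the boundary")

  if (tau_zero) {
    # product of two pooled binomials; no integration needed
    nll <- function(b)
      -sum(stats::dbinom(data$r11, data$n1, stats::plogis(b[1]), log = TRUE)) -
       sum(stats::dbinom(data$r00, data$n0, stats::plogis(b[2]), log = TRUE))
    op <- stats::optim(c(0, 0), nll, method = "BFGS",
                       control = list(reltol = 1e-14))
    V <- solve(stats::optimHess(op$par, nll))
    out <- list(beta1 = op$par[1], beta0 = op$par[2], tau1 = 0, tau0 = 0,
                rho = NA_real_, vcov_means = V, loglik = -op$value, k = k,
                converged = op$convergence == 0, n_quad = n_quad,
                data_name = attr(data, "name"))
    class(out) <- "bivfit_ml"
    return(out)
  }

  f <- fit_biv_core(data$r11, data$n1, data$r00, data$n0,
                    X1 = matrix(1, k, 1), X0 = matrix(1, k, 1),
                    n_quad = n_quad, start = start)
  if (!f$converged)
    stop("bivariate ML fit failed to converge after restarts; ",
         "best log-likelihood ", signif(f$loglik, 8))
  out <- list(beta1 = f$b1, beta0 = f$b0, tau1 = f$tau1, tau0 = f$tau0,
              rho = f$rho, vcov_means = f$vcov_fixed, loglik = f$loglik,
              k = k, converged = f$converged, n_quad = n_quad,
              par = f$par, data_name = attr(data, "name"))
  class(out) <- "bivfit_ml"
  out
}

#' @export
print.bivfit_ml <- function(x, ...) {
  cat("Bivariate binomial logit-normal meta-analysis (ML, ", x$n_quad,
      "^2-point adaptive quadrature)\n", sep = "")
  cat(sprintf("  k = %d studies, logLik = %.4f\n", x$k, x$loglik))
  cat(sprintf("  summary sensitivity %.3f, specificity %.3f\n",
              stats::plogis(x$beta1), stats::plogis(x$beta0)))
  cat(sprintf("  tau1 = %.3f, tau0 = %.3f, rho = %.3f\n",
              x$tau1, x$tau0, x$rho))
  invisible(x)
}

# Between-study covariance matrix Omega of a fit
omega_matrix <- function(fit) {
  rho <- if (is.na(fit$rho)) 0 else fit$rho
  matrix(c(fit$tau1^2, rho * fit$tau1 * fit$tau0,
           rho * fit$tau1 * fit$tau0, fit$tau0^2), 2)
}

jags_bivariate <- "
model {
  for (i in 1:k) {
    r1[i] ~ dbin(p1[i], n1[i])
    r0[i] ~ dbin(p0[i], n0[i])
    logit(p1[i]) <- u[i, 1]
    logit(p0[i]) <- u[i, 2]
    u[i, 1:2] ~ dmnorm(mu[1:2], T[1:2, 1:2])
  }
  mu[1] ~ dnorm(0, mean_prec)
  mu[2] ~ dnorm(0, mean_prec)
  T[1:2, 1:2] ~ dwish(R[1:2, 1:2], wish_df)
  Omega[1:2, 1:2] <- inverse(T[, ])
  tau1 <- sqrt(Omega[1, 1])
  tau0 <- sqrt(Omega[2, 2])
  rho <- Omega[1, 2] / (tau1 * tau0)
  unew[1:2] ~ dmnorm(mu[1:2], T[1:2, 1:2])
}"

#' Bivariate meta-analysis by MCMC with predictive draws
#'
#' Bayesian counterpart of [fit_bivariate_ml()], estimated by Gibbs
#' sampling (JAGS). Vague normal priors are placed on the mean logits and
#' a Wishart prior on the inverse between-study covariance matrix. At
#' every retained iteration one *predictive* pair of (logit-sensitivity,
#' logit-specificity) for a new population is drawn from the bivariate
#' normal at that iteration's parameter values, so the returned draws
#' propagate full parameter uncertainty into statements about new
#' populations ([joint_probability()], [prediction_interval()],
#' [prediction_region()]).
#'
#' The Wishart hyperparameters default to scale `0.1 * I` with 2 degrees
#' of freedom - weakly informative and proper; both are exposed through
#' `priors` so sensitivity analyses can rerun the fit under alternatives.
#'
#' @param data an [acc_dataset()].
#' @param priors list with `mean_prec` (precision of the normal prior on
#'   each mean logit, default `1e-5`), `wishart_scale` (2x2 matrix,
#'   default `0.1 * diag(2)`), `wishart_df` (default 2).
#' @param n_iter retained iterations per chain (default 100000).
#' @param burn_in burn-in iterations (default 10000).
#' @param seed integer seed; chain `c` uses `seed + c - 1`. Fixed seed
#'   gives identical draws.
#' @param chains number of chains (default 2; split potential
#'   scale-reduction factors are reported when `chains > 1`).
#' @param n_adapt adaptation iterations (default 1000).
#' @return Object of class `bivfit_bayes`: `draws` is a matrix with
#'   columns `beta1`, `beta0`, `tau1`, `tau0`, `rho`, `logit_p1_new`,
#'   `logit_p0_new` (all chains stacked); plus the MCMC settings and
#'   `rhat` when multiple chains were run.
#' @export
fit_bivariate_bayes <- function(data, priors = list(), n_iter = 100000,
                                burn_in = 10000, seed = 1, chains = 2,
                                n_adapt = 1000) {
  stopifnot(inherits(data, "acc_dataset"))
  if (nrow(data) < 2) stop("at least 2 studies are required")
  if (n_iter <= 0 || burn_in < 0) stop("invalid MCMC lengths")
  pr <- utils::modifyList(list(mean_prec = 1e-5,
                               wishart_scale = diag(2) * 0.1,
                               wishart_df = 2), priors)
  dat <- list(r1 = data$r11, n1 = data$n1, r0 = data$r00, n0 = data$n0,
              k = nrow(data), R = pr$wishart_scale,
              wish_df = pr$wishart_df, mean_prec = pr$mean_prec)
  inits <- lapply(seq_len(chains), function(c)
    list(mu = c(0, 0), T = diag(2),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed + c - 1)))
  jm <- rjags::jags.model(textConnection(jags_bivariate), data = dat,
                          inits = inits, n.chains = chains,
                          n.adapt = n_adapt, quiet = TRUE)
  stats::update(jm, burn_in, progress.bar = "none")
  vars <- c("mu", "tau1", "tau0", "rho", "unew")
  sam <- rjags::coda.samples(jm, vars, n.iter = n_iter,
                             progress.bar = "none")
  cols <- c(beta1 = "mu[1]", beta0 = "mu[2]", tau1 = "tau1", tau0 = "tau0",
            rho = "rho", logit_p1_new = "unew[1]", logit_p0_new = "unew[2]")
  per_chain <- lapply(sam, function(m) {
    m <- as.matrix(m)[, unname(cols), drop = FALSE]
    colnames(m) <- names(cols)
    m
  })
  rhat <- NULL
  if (chains > 1) {
    rhat <- vapply(names(cols), function(cn)
      split_rhat(lapply(per_chain, function(m) m[, cn])), 0)
    if (any(rhat > 1.05, na.rm = TRUE))
      warning("split-Rhat above 1.05 for: ",
              paste(names(rhat)[rhat > 1.05], collapse = ", "))
  }
  out <- list(draws = do.call(rbind, per_chain), k = nrow(data),
              n_iter = n_iter, burn_in = burn_in, seed = seed,
              chains = chains, priors = pr, rhat = rhat,
              data_name = attr(data, "name"))
  class(out) <- "bivfit_bayes"
  out
}

# split-half potential scale reduction factor over a list of chains
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  mu <- vapply(halves, mean, 0); v <- vapply(halves, stats::var, 0)
  B <- n * stats::var(mu); W <- mean(v)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.bivfit_bayes <- function(x, ...) {
  cat("Bivariate binomial logit-normal meta-analysis (MCMC)\n")
  cat(sprintf("  k = %d studies; %d chain(s) x %d retained (burn-in %d)\n",
              x$k, x$chains, x$n_iter, x$burn_in))
  s <- summary_accuracy(x)
  cat(sprintf("  posterior median sensitivity %.3f (%.3f, %.3f)\n",
              s$estimate[1], s$lower[1], s$upper[1]))
  cat(sprintf("  posterior median specificity %.3f (%.3f, %.3f)\n",
              s$estimate[2], s$lower[2], s$upper[2]))
  if (!is.null(x$rhat))
    cat("  max split-Rhat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Summary sensitivity and specificity with uncertainty interval
#'
#' For an ML fit, Wald intervals on the logit scale (back-transformed);
#' for an MCMC fit, posterior medians and equal-tailed credible intervals
#' of the inverse-logit means.
#'
#' @param fit a `bivfit_ml` or `bivfit_bayes` object.
#' @param level coverage probability (default 0.95).
#' @return data.frame with rows `sensitivity` and `specificity` and
#'   columns `estimate`, `lower`, `upper`.
#' @export
summary_accuracy <- function(fit, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  UseMethod("summary_accuracy")
}

#' @export
summary_accuracy.bivfit_ml <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$vcov_means))
  b <- c(fit$beta1, fit$beta0)
  data.frame(measure = c("sensitivity", "specificity"),
             estimate = stats::plogis(b),
             lower = stats::plogis(b - z * se),
             upper = stats::plogis(b + z * se))
}

#' @export
summary_accuracy.bivfit_bayes <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  qs <- function(col) stats::quantile(stats::plogis(fit$draws[, col]),
                                      c(0.5, a, 1 - a), names = FALSE)
  s1 <- qs("beta1"); s0 <- qs("beta0")
  data.frame(measure = c("sensitivity", "specificity"),
             estimate = c(s1[1], s0[1]),
             lower = c(s1[2], s0[2]),
             upper = c(s1[3], s0[3]))
}
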