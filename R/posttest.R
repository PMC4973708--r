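#' Prevalence meta-analysis (binomial logit-normal)
#'
#' Pools the outcome prevalence across cohort (or cross-sectional)
#' studies with an exact binomial likelihood for the number of diseased
#' patients in each study and a normal distribution for the study
#' logit-prevalences. Fitted by adaptive Gauss-Hermite maximum
#' likelihood, or by MCMC with a vague normal prior on the mean logit and
#' a uniform prior on the between-study SD. Case-control studies cannot
#' inform prevalence and are dropped with a message.
#'
#' @param data an [acc_dataset()].
#' @param framework `"ml"` (default) or `"bayes"`.
#' @param n_quad quadrature nodes (ML).
#' @param n_iter,burn_in,seed MCMC settings (Bayesian).
#' @return Object of class `prev_fit`: `alpha` (mean logit-prevalence),
#'   `tau_alpha`, `se_alpha`, `prevalence` (summary prevalence
#'   `expit(alpha)`), `k`; Bayesian fits also carry posterior `draws`.
#' @examples
#' fit_prevalence_meta(load_fixture("temperature"))
#' @export
fit_prevalence_meta <- function(data, framework = c("ml", "bayes"),
                                n_quad = 21, n_iter = 20000,
                                burn_in = 2000, seed = 1) {
  stopifnot(inherits(data, "acc_dataset"))
  framework <- match.arg(framework)
  keep <- data$design != "case_control"
  if (!any(keep)) stop("no prevalence-informative (cohort) studies")
  if (!all(keep))
    message("excluding ", sum(!keep),
            " case_control study(ies) from prevalence meta-analysis")
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 2) stop("at least 2 cohort studies are required")
  N <- d$n1 + d$n0

  if (framework == "ml") {
    f <- fit_binom_logitnorm(d$n1, N, off = 0, n_quad = n_quad)
    out <- list(alpha = f$a, tau_alpha = f$tau, se_alpha = f$se_a,
                prevalence = stats::plogis(f$a), loglik = f$loglik,
                k = f$k, framework = "ml")
  } else {
    ms <- "
model {
  for (i in 1:k) {
    n1[i] ~ dbin(p[i], N[i])
    logit(p[i]) <- u[i]
    u[i] ~ dnorm(alpha, prec)
  }
  alpha ~ dnorm(0, 1.0E-5)
  tau ~ dunif(0, 2)
  prec <- pow(tau, -2)
}"
    jm <- rjags::jags.model(textConnection(ms),
                            data = list(n1 = d$n1, N = N, k = nrow(d)),
                            inits = list(alpha = 0, tau = 0.5,
                                         .RNG.name = "base::Mersenne-Twister",
                                         .RNG.seed = as.integer(seed)),
                            n.chains = 1, n.adapt = 1000, quiet = TRUE)
    stats::update(jm, burn_in, progress.bar = "none")
    m <- as.matrix(rjags::coda.samples(jm, c("alpha", "tau"),
                                       n.iter = n_iter,
                                       progress.bar = "none")[[1]])
    out <- list(alpha = stats::median(m[, "alpha"]),
                tau_alpha = stats::median(m[, "tau"]),
                se_alpha = stats::sd(m[, "alpha"]),
                prevalence = stats::median(stats::plogis(m[, "alpha"])),
                draws = m, k = nrow(d), framework = "bayes")
  }
  class(out) <- "prev_fit"
  out
}

#' @export
print.prev_fit <- function(x, ...) {
  cat(sprintf(
    "Prevalence meta-analysis (%s), k = %d: summary prevalence %.3f (alpha %.3f, tau %.3f)\n",
    x$framework, x$k, x$prevalence, x$alpha, x$tau_alpha))
  invisible(x)
}

# Bayes-theorem conversion shared by options A and B. Degenerate
# denominators (possible only when sensitivity/specificity/prevalence sit
# exactly at 0 or 1) yield NA with a flag rather than a division error.
bayes_ppv_npv <- function(sens, spec, prev) {
  den_p <- sens * prev + (1 - spec) * (1 - prev)
  den_n <- (1 - sens) * prev + spec * (1 - prev)
  ppv <- if (den_p > 0) sens * prev / den_p else NA_real_
  npv <- if (den_n > 0) spec * (1 - prev) / den_n else NA_real_
  list(ppv = ppv, npv = npv,
       undefined = c(ppv = den_p <= 0, npv = den_n <= 0))
}

new_posttest <- function(ppv, npv, option, prev, source, inputs,
                         undefined = c(ppv = FALSE, npv = FALSE)) {
  structure(list(ppv = ppv, npv = npv, option = option,
                 prevalence_used = prev, prevalence_source = source,
                 inputs = inputs, undefined = undefined),
            class = "posttest_prediction")
}

#' @export
print.posttest_prediction <- function(x, ...) {
  cat(sprintf(
    "Post-test prediction (option %s, prevalence %.3f [%s]): PPV = %.3f, NPV = %.3f\n",
    x$option, x$prevalence_used, x$prevalence_source, x$ppv, x$npv))
  invisible(x)
}

#' Post-test probabilities, option A: all summary values
#'
#' Plugs the summary sensitivity, summary specificity and summary
#' (meta-analysed) prevalence into Bayes' theorem:
#' \deqn{PPV = \frac{se \cdot \pi}{se \cdot \pi + (1-sp)(1-\pi)}, \quad
#'       NPV = \frac{sp (1-\pi)}{(1-se)\pi + sp(1-\pi)}}
#' This mimics knowing nothing about the target population.
#'
#' @param sens_ma,spec_ma,prev_ma summary sensitivity, specificity and
#'   prevalence, all in `(0, 1)`.
#' @return A `posttest_prediction` with `option = "A"`.
#' @examples
#' option_a(0.93, 0.81, 0.26)
#' @export
option_a <- function(sens_ma, spec_ma, prev_ma) {
  check_prob(sens_ma, "sens_ma"); check_prob(spec_ma, "spec_ma")
  check_prob(prev_ma, "prev_ma")
  b <- bayes_ppv_npv(sens_ma, spec_ma, prev_ma)
  new_posttest(b$ppv, b$npv, "A", prev_ma, "meta-analysis",
               c(sensitivity = sens_ma, specificity = spec_ma), b$undefined)
}

#' Post-test probabilities, option B: summary accuracy, local prevalence
#'
#' Same computation as [option_a()] but with the prevalence of the
#' intended population substituted, tailoring PPV and NPV to that
#' population. `prev_source` records whether the supplied value is a
#' known population prevalence or an observed-sample proxy.
#'
#' @inheritParams option_a
#' @param prev_local prevalence in the target population.
#' @param prev_source `"known"` or `"observed"` (provenance of
#'   `prev_local`).
#' @return A `posttest_prediction` with `option = "B"`.
#' @export
option_b <- function(sens_ma, spec_ma, prev_local,
                     prev_source = c("known", "observed")) {
  check_prob(sens_ma, "sens_ma"); check_prob(spec_ma, "spec_ma")
  check_prob(prev_local, "prev_local")
  prev_source <- match.arg(prev_source)
  b <- bayes_ppv_npv(sens_ma, spec_ma, prev_local)
  new_posttest(b$ppv, b$npv, "B", prev_local, prev_source,
               c(sensitivity = sens_ma, specificity = spec_ma), b$undefined)
}

check_prob <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(nm, " must be a probability in [0, 1]")
  invisible(x)
}

#' Bivariate meta-regression of PPV and NPV on prevalence
#'
#' Option C models the post-test probabilities directly: in each cohort
#' study the diseased among the test positives (`r11` of `n+`) and the
#' non-diseased among the test negatives (`r00` of `n-`) get exact
#' binomial likelihoods, and the study logit-PPV and logit-NPV pairs are
#' bivariate normal with means linear in the study's observed prevalence
#' (natural scale):
#' \deqn{\mathrm{logit}(PPV_i) = \delta_1 + \gamma_1 \cdot prev_i, \quad
#'       \mathrm{logit}(NPV_i) = \delta_0 + \gamma_0 \cdot prev_i.}
#' Internally the covariate is centred at its mean for numerical
#' stability; estimates are reported on the uncentred scale. A study
#' margin with zero test positives (or negatives) drops that margin's
#' likelihood term with a warning. Fitted by the same adaptive
#' quadrature machinery as [fit_bivariate_ml()].
#'
#' @param data an [acc_dataset()]; case-control studies are excluded.
#' @param slopes if `FALSE`, the prevalence slopes are omitted and the
#'   fit reduces to a plain bivariate meta-analysis of PPV and NPV.
#' @param n_quad quadrature nodes per dimension.
#' @return Object of class `ppv_npv_metareg` with `delta1`, `gamma1`,
#'   `delta0`, `gamma0`, `tau_ppv`, `tau_npv`, `rho`, `vcov_fixed`,
#'   `prev_range` and the centring constant.
#' @export
fit_ppv_npv_metareg <- function(data, slopes = TRUE, n_quad = 10) {
  stopifnot(inherits(data, "acc_dataset"))
  keep <- data$design != "case_control"
  if (!all(keep))
    message("excluding ", sum(!keep), " case_control study(ies)")
  d <- data[keep, , drop = FALSE]
  k <- nrow(d)
  if (k < 2) stop("at least 2 cohort studies are required")
  if (k < 5)
    warning("meta-regression of PPV/NPV on prevalence with fewer than 5 ",
            "studies is unlikely to be reliable")
  m <- study_measures(d)
  n_pos <- m$test_pos; n_neg <- m$test_neg
  inc1 <- as.numeric(n_pos > 0); inc0 <- as.numeric(n_neg > 0)
  if (any(inc1 == 0))
    warning("study with no test positives: PPV margin dropped for ",
            paste(d$study_id[inc1 == 0], collapse = ", "))
  if (any(inc0 == 0))
    warning("study with no test negatives: NPV margin dropped for ",
            paste(d$study_id[inc0 == 0], collapse = ", "))
  prev <- m$prevalence_obs
  ctr <- mean(prev)
  X <- if (slopes) cbind(1, prev - ctr) else matrix(1, k, 1)
  f <- fit_biv_core(r1 = d$r11, n1 = pmax(n_pos, 1),
                    r0 = d$r00, n0 = pmax(n_neg, 1),
                    X1 = X, X0 = X, n_quad = n_quad,
                    inc1 = inc1, inc0 = inc0)
  p <- ncol(X)
  if (slopes) {
    # uncentre the intercepts
    delta1 <- f$b1[1] - f$b1[2] * ctr; gamma1 <- f$b1[2]
    delta0 <- f$b0[1] - f$b0[2] * ctr; gamma0 <- f$b0[2]
  } else {
    delta1 <- f$b1[1]; gamma1 <- 0
    delta0 <- f$b0[1]; gamma0 <- 0
  }
  out <- list(delta1 = delta1, gamma1 = gamma1, delta0 = delta0,
              gamma0 = gamma0, tau_ppv = f$tau1, tau_npv = f$tau0,
              rho = f$rho, vcov_fixed = f$vcov_fixed, loglik = f$loglik,
              k = k, slopes = slopes, center = ctr,
              prev_range = range(prev), converged = f$converged)
  class(out) <- "ppv_npv_metareg"
  out
}

#' @export
print.ppv_npv_metareg <- function(x, ...) {
  cat(sprintf("Bivariate meta-regression of PPV/NPV on prevalence, k = %d\n",
              x$k))
  cat(sprintf("  logit PPV = %.3f + %.3f * prev (tau %.3f)\n",
              x$delta1, x$gamma1, x$tau_ppv))
  cat(sprintf("  logit NPV = %.3f + %.3f * prev (tau %.3f); rho = %.3f\n",
              x$delta0, x$gamma0, x$tau_npv, x$rho))
  invisible(x)
}

#' Post-test probabilities, option C: meta-regression prediction
#'
#' Evaluates the fitted logit-linear predictors of
#' [fit_ppv_npv_metareg()] at the target population's prevalence and
#' back-transforms. Warns when the prevalence lies outside the range the
#' regression was fitted on.
#'
#' @param fit a `ppv_npv_metareg` object.
#' @param prev_local target-population prevalence in `(0, 1)`.
#' @param prev_source provenance of `prev_local` (see [option_b()]).
#' @return A `posttest_prediction` with `option = "C"`.
#' @export
option_c_predict <- function(fit, prev_local,
                             prev_source = c("known", "observed")) {
  stopifnot(inherits(fit, "ppv_npv_metareg"))
  prev_source <- match.arg(prev_source)
  check_prob(prev_local, "prev_local")
  if (prev_local < fit$prev_range[1] || prev_local > fit$prev_range[2])
    warning("prevalence ", signif(prev_local, 3),
            " lies outside the fitted range [",
            signif(fit$prev_range[1], 3), ", ",
            signif(fit$prev_range[2], 3), "]: extrapolating")
  ppv <- stats::plogis(fit$delta1 + fit$gamma1 * prev_local)
  npv <- stats::plogis(fit$delta0 + fit$gamma0 * prev_local)
  new_posttest(ppv, npv, "C", prev_local, prev_source,
               c(delta1 = fit$delta1, gamma1 = fit$gamma1,
                 delta0 = fit$delta0, gamma0 = fit$gamma0))
}
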