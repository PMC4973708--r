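#' Observed and expected outcome counts in a validation study
#'
#' Given a study's 2x2 counts and a post-test prediction derived without
#' that study, returns the observed outcome count O and the expected
#' count E implied by the predicted PPV/NPV:
#' \deqn{E = PPV \cdot n_+ + (1 - NPV) \cdot n_-}
#' where \eqn{n_+} and \eqn{n_-} are the study's test-positive and
#' test-negative totals. `scope` restricts the comparison to one test
#' arm: for test positives O is the true-positive count and
#' `E = PPV * n+`; for test negatives O is the false-negative count and
#' `E = (1 - NPV) * n-`. The overall O and E are exactly the sums of the
#' two arms. Unrounded predictions should always be supplied.
#'
#' @param study one-row [acc_dataset()] (or a list with `r11`, `n1`,
#'   `r00`, `n0`).
#' @param pred a `posttest_prediction`.
#' @param scope `"overall"`, `"test_positive"` or `"test_negative"`.
#' @return named vector `c(O, E)`.
#' @export
expected_events <- function(study, pred,
                            scope = c("overall", "test_positive",
                                      "test_negative")) {
  scope <- match.arg(scope)
  stopifnot(inherits(pred, "posttest_prediction"))
  n_pos <- study$r11 + (study$n0 - study$r00)
  n_neg <- study$r00 + (study$n1 - study$r11)
  out <- switch(scope,
    overall = c(O = study$n1,
                E = pred$ppv * n_pos + (1 - pred$npv) * n_neg),
    test_positive = c(O = study$r11, E = pred$ppv * n_pos),
    test_negative = c(O = study$n1 - study$r11,
                      E = (1 - pred$npv) * n_neg))
  if (out["E"] <= 0)
    stop("expected count is zero for scope '", scope, "'")
  out
}

#' ln(O/E) and its standard error
#'
#' The log observed/expected ratio with the expected proportion treated
#' as fixed, so that the SE of ln(O/E) is the SE of the log observed
#' proportion: \eqn{s = \sqrt{(1 - P_O) / (N P_O)}} with
#' \eqn{P_O = O/N}. When O = 0 or O = N the SE does not exist; the
#' record is flagged (`se = NA`) and must be handled by the exact
#' binomial calibration model instead of the normal-approximation
#' meta-analysis.
#'
#' @param O observed outcome count.
#' @param E expected outcome count (> 0).
#' @param N total study size.
#' @return list with `ln_oe` (NA when O = 0) and `se` (NA when O = 0 or
#'   O = N).
#' @export
ln_oe_with_se <- function(O, E, N) {
  if (E <= 0) stop("E must be positive")
  if (O < 0 || O > N) stop("O must be in [0, N]")
  ln_oe <- if (O > 0) log(O / E) else NA_real_
  se <- if (O > 0 && O < N) sqrt((1 - O / N) / (N * (O / N))) else NA_real_
  list(ln_oe = ln_oe, se = se)
}

#' Internal-external cross-validation of post-test predictions
#'
#' The leave-one-study-out engine: each eligible (cohort) study is
#' omitted in turn, the chosen prediction strategy is rebuilt from the
#' remaining studies (bivariate accuracy meta-analysis, prevalence
#' meta-analysis and/or PPV-NPV meta-regression, as the option
#' requires), the resulting PPV/NPV are applied to the omitted study,
#' and observed/expected statistics are recorded. Records carry the O, E
#' and ln(O/E) of all three scopes so that overall calibration
#' ([meta_oe()]) and arm-specific calibration
#' ([fit_exact_calibration()]) can both be summarised from one run.
#'
#' Options: `"A"` uses summary sensitivity, specificity and summary
#' prevalence from the remaining studies; `"B"` replaces the prevalence
#' with the omitted study's population prevalence (the observed
#' prevalence stands in when no external value is supplied, and the
#' provenance is recorded); `"C"` predicts from the PPV-NPV
#' meta-regression at the omitted study's prevalence.
#'
#' @param data an [acc_dataset()] with at least 3 studies.
#' @param option prediction strategy, `"A"`, `"B"` or `"C"`.
#' @param framework `"ml"` (default) or `"bayes"` (posterior medians are
#'   then used as the summary inputs).
#' @param keep study_id never to omit (e.g. a dominant large study);
#'   it still contributes to every cycle's meta-analysis.
#' @param external_prev optional named vector of known population
#'   prevalences by study_id (options B/C); observed prevalence is the
#'   proxy otherwise.
#' @param warm_start reuse each cycle's estimates as the next cycle's
#'   optimiser start (results are identical to cold starts within
#'   optimiser tolerance).
#' @param n_quad,mcmc fitting controls; `mcmc` is a list with `n_iter`,
#'   `burn_in`, `seed`, `chains` for `framework = "bayes"`.
#' @return data.frame of class `iocv_records`, one row per omitted
#'   study: the summary inputs used, predicted PPV/NPV, O, E, O/E,
#'   ln(O/E) and its SE (overall scope), the per-arm counts and expected
#'   values, and a `failed` flag (a failed cycle does not abort the
#'   run).
#' @examples
#' \donttest{
#' rec <- run_iocv(load_fixture("temperature"), option = "A")
#' meta_oe(rec)
#' }
#' @export
run_iocv <- function(data, option = c("A", "B", "C"),
                     framework = c("ml", "bayes"), keep = NULL,
                     external_prev = NULL, warm_start = TRUE,
                     n_quad = 10, mcmc = list()) {
  stopifnot(inherits(data, "acc_dataset"))
  option <- match.arg(option)
  framework <- match.arg(framework)
  if (nrow(data) < 3) stop("at least 3 studies are required")
  mc <- utils::modifyList(list(n_iter = 20000, burn_in = 2000, seed = 1,
                               chains = 1), mcmc)
  eligible <- data$design != "case_control"
  if (!is.null(keep)) {
    if (!keep %in% data$study_id) stop("unknown study_id in 'keep'")
    eligible <- eligible & data$study_id != keep
  }
  if (option == "C" && sum(data$design != "case_control") - 1 < 5)
    warning("option C with fewer than 5 remaining cohort studies per ",
            "cycle is unlikely to be reliable")

  meas <- study_measures(data)
  start <- NULL
  rows <- vector("list", sum(eligible))
  ri <- 0
  for (L in which(eligible)) {
    ri <- ri + 1
    s <- data[L, , drop = FALSE]
    rest <- data[-L, , drop = FALSE]  # subsetting preserves the class
    prev_L <- if (!is.null(external_prev) &&
                  s$study_id %in% names(external_prev))
      unname(external_prev[s$study_id]) else meas$prevalence_obs[L]
    prev_src <- if (!is.null(external_prev) &&
                    s$study_id %in% names(external_prev)) "known"
                else "observed"

    cyc <- tryCatch({
      if (option %in% c("A", "B")) {
        if (framework == "ml") {
          bf <- suppressWarnings(
            fit_bivariate_ml(rest, n_quad = n_quad, start = start))
          if (warm_start) start <- bf$par
          sens <- stats::plogis(bf$beta1)
          spec <- stats::plogis(bf$beta0)
        } else {
          bf <- fit_bivariate_bayes(rest, n_iter = mc$n_iter,
                                    burn_in = mc$burn_in, seed = mc$seed,
                                    chains = mc$chains)
          sa <- summary_accuracy(bf)
          sens <- sa$estimate[1]; spec <- sa$estimate[2]
        }
        if (option == "A") {
          pf <- fit_prevalence_meta(rest, framework = framework,
                                    n_iter = mc$n_iter,
                                    burn_in = mc$burn_in, seed = mc$seed)
          pred <- option_a(sens, spec, pf$prevalence)
          prev_sum <- pf$prevalence
        } else {
          pred <- option_b(sens, spec, prev_L, prev_source = prev_src)
          prev_sum <- NA_real_
        }
      } else {
        mr <- suppressWarnings(fit_ppv_npv_metareg(rest, n_quad = n_quad))
        pred <- suppressWarnings(
          option_c_predict(mr, prev_L, prev_source = prev_src))
        sens <- NA_real_; spec <- NA_real_; prev_sum <- NA_real_
      }

      oe_all <- expected_events(s, pred, "overall")
      oe_pos <- expected_events(s, pred, "test_positive")
      oe_neg <- expected_events(s, pred, "test_negative")
      lo <- ln_oe_with_se(oe_all["O"], oe_all["E"], meas$N[L])
      data.frame(study_id = s$study_id, O = unname(oe_all["O"]),
                 N = meas$N[L], prev_obs = meas$prevalence_obs[L],
                 prev_used = pred$prevalence_used, prev_summary = prev_sum,
                 sens = sens, spec = spec,
                 ppv = pred$ppv, npv = pred$npv,
                 E = unname(oe_all["E"]),
                 oe = unname(oe_all["O"] / oe_all["E"]),
                 ln_oe = lo$ln_oe, se_ln_oe = lo$se,
                 r11 = s$r11, n_pos = meas$test_pos[L],
                 O_pos = unname(oe_pos["O"]), E_pos = unname(oe_pos["E"]),
                 r00 = s$r00, n_neg = meas$test_neg[L],
                 O_neg = unname(oe_neg["O"]), E_neg = unname(oe_neg["E"]),
                 failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("cycle omitting '", s$study_id, "' failed: ",
              conditionMessage(e))
      data.frame(study_id = s$study_id, O = s$n1, N = meas$N[L],
                 prev_obs = meas$prevalence_obs[L], prev_used = NA_real_,
                 prev_summary = NA_real_, sens = NA_real_, spec = NA_real_,
                 ppv = NA_real_, npv = NA_real_, E = NA_real_,
                 oe = NA_real_, ln_oe = NA_real_, se_ln_oe = NA_real_,
                 r11 = s$r11, n_pos = meas$test_pos[L], O_pos = s$r11,
                 E_pos = NA_real_, r00 = s$r00, n_neg = meas$test_neg[L],
                 O_neg = s$n1 - s$r11, E_neg = NA_real_, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    rows[[ri]] <- cyc
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "option") <- option
  attr(out, "framework") <- framework
  attr(out, "data_name") <- attr(data, "name")
  class(out) <- c("iocv_records", "data.frame")
  out
}

jags_oe <- "
model {
  for (i in 1:k) {
    y[i] ~ dnorm(theta[i], pow(s[i], -2))
    theta[i] ~ dnorm(beta, prec)
  }
  beta ~ dnorm(0, 1.0E-6)
  tau ~ dunif(tau_lo, tau_hi)
  prec <- pow(tau, -2)
  theta_new ~ dnorm(beta, prec)
}"

#' Meta-analysis of ln(O/E) calibration statistics
#'
#' Pools the per-cycle log observed/expected ratios of [run_iocv()] with
#' a random-effects meta-analysis and reports everything on the O/E
#' scale: summary O/E with confidence interval, the between-study SD,
#' I-squared, and a t-based (`df = k - 2`) prediction interval for the
#' O/E in a new population. Records with O = 0 or O = N carry no SE and
#' are excluded with a notice (they remain usable in
#' [fit_exact_calibration()], which needs no SE). The Bayesian variant
#' places a vague normal prior on the mean ln(O/E) and a uniform prior
#' (default `U(0, 0.25)`) on the between-study SD, and reports the
#' posterior predictive probability that the O/E of a new population
#' falls inside `bounds` (default 0.9 to 1.1, i.e. calibration within
#' 10 percent).
#'
#' @param records an `iocv_records` data.frame.
#' @param method `"moments"` (DerSimonian-Laird, default) or `"bayes"`.
#' @param level coverage probability.
#' @param bounds O/E interval for the Bayesian probability statement.
#' @param priors Bayesian priors: list with `tau` (uniform support,
#'   default `c(0, 0.25)`).
#' @param n_iter,burn_in,seed MCMC settings.
#' @return Object of class `oe_meta`: `summary_oe`, `ci`, `pi`
#'   (prediction interval, O/E scale), `tau`, `I2`, the underlying
#'   [fit_re_moments()] fit (or posterior draws), per-study forest data
#'   (`forest`), and the ids of any excluded records.
#' @export
meta_oe <- function(records, method = c("moments", "bayes"), level = 0.95,
                    bounds = c(0.9, 1.1), priors = list(),
                    n_iter = 100000, burn_in = 10000, seed = 1) {
  stopifnot(inherits(records, "iocv_records"))
  method <- match.arg(method)
  ok <- !records$failed & is.finite(records$ln_oe) &
        is.finite(records$se_ln_oe)
  excluded <- records$study_id[!ok]
  if (length(excluded))
    message("excluded from ln(O/E) meta-analysis (no SE or failed cycle): ",
            paste(excluded, collapse = ", "))
  r <- records[ok, , drop = FALSE]
  k <- nrow(r)
  if (k < 2) stop("fewer than 2 usable records")
  a <- (1 - level) / 2
  z <- stats::qnorm(1 - a)
  forest <- data.frame(study_id = r$study_id, oe = r$oe,
                       lower = exp(r$ln_oe - z * r$se_ln_oe),
                       upper = exp(r$ln_oe + z * r$se_ln_oe))

  if (method == "moments") {
    f <- fit_re_moments(r$ln_oe, r$se_ln_oe)
    ci <- exp(f$mu + c(-1, 1) * z * f$se_mu)
    pi_oe <- if (k >= 3)
      exp(f$mu + c(-1, 1) * stats::qt(1 - a, k - 2) *
            sqrt(f$tau2 + f$se_mu^2))
    else {
      message("k - 2 < 1: prediction interval omitted")
      c(NA_real_, NA_real_)
    }
    wr <- 1 / (r$se_ln_oe^2 + f$tau2)
    forest$weight <- wr / sum(wr) * 100
    out <- list(summary_oe = exp(f$mu), ci = ci, pi = pi_oe, tau = f$tau,
                I2 = f$I2, fit = f, k = k, method = "moments",
                level = level, forest = forest, excluded = excluded)
  } else {
    pr <- utils::modifyList(list(tau = c(0, 0.25)), priors)
    jm <- rjags::jags.model(
      textConnection(jags_oe),
      data = list(y = r$ln_oe, s = r$se_ln_oe, k = k,
                  tau_lo = pr$tau[1], tau_hi = pr$tau[2]),
      inits = list(beta = 0, tau = mean(pr$tau),
                   .RNG.name = "base::Mersenne-Twister",
                   .RNG.seed = as.integer(seed)),
      n.chains = 1, n.adapt = 1000, quiet = TRUE)
    stats::update(jm, burn_in, progress.bar = "none")
    m <- as.matrix(rjags::coda.samples(jm, c("beta", "tau", "theta_new"),
                                       n.iter = n_iter,
                                       progress.bar = "none")[[1]])
    oe_new <- exp(m[, "theta_new"])
    out <- list(summary_oe = exp(stats::median(m[, "beta"])),
                ci = exp(stats::quantile(m[, "beta"], c(a, 1 - a),
                                         names = FALSE)),
                pi = stats::quantile(oe_new, c(a, 1 - a), names = FALSE),
                tau = stats::median(m[, "tau"]),
                tau_ci = stats::quantile(m[, "tau"], c(a, 1 - a),
                                         names = FALSE),
                prob_in_bounds = mean(oe_new > bounds[1] &
                                        oe_new < bounds[2]),
                bounds = bounds, draws = m, k = k, method = "bayes",
                level = level, priors = pr, forest = forest,
                excluded = excluded)
  }
  class(out) <- "oe_meta"
  out
}

#' @export
print.oe_meta <- function(x, ...) {
  cat(sprintf("Meta-analysis of ln(O/E) (%s), k = %d\n", x$method, x$k))
  cat(sprintf("  summary O/E = %.3f (%.0f%% CI %.3f to %.3f)\n",
              x$summary_oe, 100 * x$level, x$ci[1], x$ci[2]))
  cat(sprintf("  %.0f%% prediction interval for O/E: %.3f to %.3f\n",
              100 * x$level, x$pi[1], x$pi[2]))
  if (x$method == "moments")
    cat(sprintf("  tau = %.3f, I2 = %.0f%%\n", x$tau, x$I2))
  else
    cat(sprintf("  tau = %.3f; P(%.2f < O/E < %.2f) = %.2f\n",
                x$tau, x$bounds[1], x$bounds[2], x$prob_in_bounds))
  if (length(x$excluded))
    cat("  excluded (boundary/failed):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

jags_exact <- "
model {
  for (i in 1:k) {
    r[i] ~ dbin(p[i], n[i])
    logit(p[i]) <- alpha[i] + off[i]
    alpha[i] ~ dnorm(a, prec)
  }
  a ~ dnorm(0, 1.0E-6)
  tau ~ dunif(tau_lo, tau_hi)
  prec <- pow(tau, -2)
  alpha_new ~ dnorm(a, prec)
}"

#' Exact binomial calibration model for PPV or NPV
#'
#' Arm-specific calibration-in-the-large that models each
#' cross-validation cycle's counts directly, so cycles with zero events
#' or zero non-events — where ln(O/E) has no standard error — still
#' contribute. For the PPV arm the diseased among the omitted study's
#' test positives follow a binomial whose logit is the predicted
#' logit-PPV (a fixed offset) plus a study-level calibration intercept
#' \eqn{\alpha_L \sim N(a, \tau_a^2)}; the NPV arm is analogous with the
#' non-diseased among test negatives. The summary `a` is the average log
#' odds ratio of observed to predicted odds: 0 means perfect average
#' calibration. Fitted by adaptive quadrature ML (the no-heterogeneity
#' boundary `tau_a = 0` is admissible) or by MCMC with a vague normal
#' prior on `a` and a uniform prior (default `U(0, 1)`) on `tau_a`.
#'
#' @param records an `iocv_records` data.frame.
#' @param scope `"ppv"` (test positives) or `"npv"` (test negatives).
#' @param framework `"ml"` (default) or `"bayes"`.
#' @param priors Bayesian priors: list with `tau` (default `c(0, 1)`).
#' @param n_quad quadrature nodes (ML).
#' @param n_iter,burn_in,seed MCMC settings.
#' @return Object of class `exact_calib`: `a`, `tau_a`, `se_a`, `k`,
#'   `framework`, `scope`; Bayesian fits carry posterior `draws`
#'   including the predictive calibration intercept `alpha_new`.
#' @export
fit_exact_calibration <- function(records, scope = c("ppv", "npv"),
                                  framework = c("ml", "bayes"),
                                  priors = list(), n_quad = 21,
                                  n_iter = 100000, burn_in = 10000,
                                  seed = 1) {
  stopifnot(inherits(records, "iocv_records"))
  scope <- match.arg(scope)
  framework <- match.arg(framework)
  r <- records[!records$failed, , drop = FALSE]
  if (nrow(r) < 2) stop("fewer than 2 usable records")
  if (scope == "ppv") {
    succ <- r$r11; tot <- r$n_pos; pred <- r$ppv
  } else {
    succ <- r$r00; tot <- r$n_neg; pred <- r$npv
  }
  if (any(tot == 0)) {
    message("dropping cycle(s) with no patients in the ", scope, " arm: ",
            paste(r$study_id[tot == 0], collapse = ", "))
    keep <- tot > 0
    succ <- succ[keep]; tot <- tot[keep]; pred <- pred[keep]
  }
  clip <- pred <= 1e-6 | pred >= 1 - 1e-6
  if (any(clip)) {
    warning("predicted probability at 0/1 clipped to logit(1e-6) bounds")
    pred <- pmin(pmax(pred, 1e-6), 1 - 1e-6)
  }
  off <- stats::qlogis(pred)
  k <- length(succ)

  if (framework == "ml") {
    f <- fit_binom_logitnorm(succ, tot, off = off, n_quad = n_quad)
    out <- list(a = f$a, tau_a = f$tau, se_a = f$se_a, loglik = f$loglik,
                k = k, framework = "ml", scope = scope)
  } else {
    pr <- utils::modifyList(list(tau = c(0, 1)), priors)
    jm <- rjags::jags.model(
      textConnection(jags_exact),
      data = list(r = succ, n = tot, off = off, k = k,
                  tau_lo = pr$tau[1], tau_hi = pr$tau[2]),
      inits = list(a = 0, tau = mean(pr$tau),
                   .RNG.name = "base::Mersenne-Twister",
                   .RNG.seed = as.integer(seed)),
      n.chains = 1, n.adapt = 1000, quiet = TRUE)
    stats::update(jm, burn_in, progress.bar = "none")
    m <- as.matrix(rjags::coda.samples(jm, c("a", "tau", "alpha_new"),
                                       n.iter = n_iter,
                                       progress.bar = "none")[[1]])
    out <- list(a = stats::median(m[, "a"]),
                tau_a = stats::median(m[, "tau"]),
                se_a = stats::sd(m[, "a"]), draws = m, k = k,
                framework = "bayes", scope = scope, priors = pr)
  }
  class(out) <- "exact_calib"
  out
}

#' @export
print.exact_calib <- function(x, ...) {
  cat(sprintf(
    "Exact binomial calibration model (%s scope, %s), k = %d\n",
    toupper(x$scope), x$framework, x$k))
  cat(sprintf("  calibration-in-the-large a = %.4f (SE %.4f), tau_a = %.4f\n",
              x$a, x$se_a, x$tau_a))
  invisible(x)
}

#' Prediction interval from the exact calibration model
#'
#' For a population with predicted PPV (or NPV) `pred_value`, the
#' interval for the *true* value:
#' \deqn{\hat a \pm t_{k-2}\sqrt{\hat\tau_a^2 + \mathrm{Var}(\hat a)} +
#'   \mathrm{logit}(pred)}
#' back-transformed to the probability scale, and divided by
#' `pred_value` for the O/E scale. The Bayesian variant uses the
#' posterior predictive draws of the calibration intercept and also
#' reports the probability that the O/E falls inside `bounds`.
#'
#' @param fit an `exact_calib` object with `k >= 3`.
#' @param pred_value predicted probability in `(0, 1)`.
#' @param level coverage probability.
#' @param bounds O/E interval for the Bayesian probability statement.
#' @return list with `logit`, `probability` and `oe` interval bounds
#'   (and `prob_in_bounds` for Bayesian fits).
#' @export
exact_prediction_interval <- function(fit, pred_value, level = 0.95,
                                      bounds = c(0.9, 1.1)) {
  stopifnot(inherits(fit, "exact_calib"))
  if (fit$k < 3) stop("prediction interval needs k >= 3")
  check_prob(pred_value, "pred_value")
  if (pred_value <= 0 || pred_value >= 1)
    stop("pred_value must be strictly inside (0, 1)")
  a <- (1 - level) / 2
  if (fit$framework == "ml") {
    tq <- stats::qt(1 - a, df = fit$k - 2)
    lg <- fit$a + c(-1, 1) * tq * sqrt(fit$tau_a^2 + fit$se_a^2) +
      stats::qlogis(pred_value)
    p <- stats::plogis(lg)
    list(logit = lg, probability = p, oe = p / pred_value, level = level)
  } else {
    lg_draw <- fit$draws[, "alpha_new"] + stats::qlogis(pred_value)
    p_draw <- stats::plogis(lg_draw)
    oe_draw <- p_draw / pred_value
    list(logit = stats::quantile(lg_draw, c(a, 1 - a), names = FALSE),
         probability = stats::quantile(p_draw, c(a, 1 - a), names = FALSE),
         oe = stats::quantile(oe_draw, c(a, 1 - a), names = FALSE),
         prob_in_bounds = mean(oe_draw > bounds[1] & oe_draw < bounds[2]),
         bounds = bounds, level = level)
  }
}
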