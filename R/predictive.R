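#' Prediction interval for sensitivity or specificity in a new population
#'
#' From a maximum-likelihood fit, a t-based interval that widens the
#' confidence interval by the between-study heterogeneity:
#' \deqn{\hat\beta \pm t_{k-2, 1-\alpha/2}\sqrt{\hat\tau^2 +
#'   \mathrm{Var}(\hat\beta)}}
#' back-transformed to the probability scale. The t distribution (rather
#' than normal) partially accounts for the uncertainty in the estimated
#' between-study variance.
#'
#' @param fit a `bivfit_ml` object with at least 3 studies.
#' @param margin `"sensitivity"` or `"specificity"`.
#' @param level coverage probability.
#' @return list of class `pred_interval`: `lower`, `upper` (probability
#'   scale), `logit` (bounds on the logit scale), `level`, `df`.
#' @examples
#' fit <- fit_bivariate_ml(load_fixture("temperature"))
#' prediction_interval_t(fit, "sensitivity")
#' @export
prediction_interval_t <- function(fit, margin = c("sensitivity",
                                                  "specificity"),
                                  level = 0.95) {
  stopifnot(inherits(fit, "bivfit_ml"))
  margin <- match.arg(margin)
  if (fit$k < 3) stop("prediction interval needs k >= 3 (df = k - 2)")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  i <- if (margin == "sensitivity") 1L else 2L
  b <- c(fit$beta1, fit$beta0)[i]
  tau <- c(fit$tau1, fit$tau0)[i]
  s <- sqrt(tau^2 + fit$vcov_means[i, i])
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$k - 2)
  lg <- c(b - tq * s, b + tq * s)
  structure(list(lower = stats::plogis(lg[1]), upper = stats::plogis(lg[2]),
                 logit = lg, level = level, df = fit$k - 2,
                 margin = margin),
            class = "pred_interval")
}

#' Predictive interval from posterior draws
#'
#' Equal-tailed interval of the posterior predictive distribution for the
#' chosen margin in a new population, with all parameter uncertainty
#' propagated through the MCMC draws.
#'
#' @param fit a `bivfit_bayes` object.
#' @inheritParams prediction_interval_t
#' @export
prediction_interval <- function(fit, margin = c("sensitivity",
                                                "specificity"),
                                level = 0.95) {
  UseMethod("prediction_interval")
}

#' @export
prediction_interval.bivfit_ml <- function(fit, margin = c("sensitivity",
                                                          "specificity"),
                                          level = 0.95) {
  prediction_interval_t(fit, margin, level)
}

#' @export
prediction_interval.bivfit_bayes <- function(fit,
                                             margin = c("sensitivity",
                                                        "specificity"),
                                             level = 0.95) {
  margin <- match.arg(margin)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  col <- if (margin == "sensitivity") "logit_p1_new" else "logit_p0_new"
  a <- (1 - level) / 2
  q <- stats::quantile(fit$draws[, col], c(a, 1 - a), names = FALSE)
  structure(list(lower = stats::plogis(q[1]), upper = stats::plogis(q[2]),
                 logit = q, level = level, df = NA_integer_,
                 margin = margin),
            class = "pred_interval")
}

#' @export
print.pred_interval <- function(x, ...) {
  cat(sprintf("%.0f%% prediction interval for %s in a new population: %.3f to %.3f\n",
              100 * x$level, x$margin, x$lower, x$upper))
  invisible(x)
}

#' Probability that sensitivity and specificity jointly exceed thresholds
#'
#' The fraction of posterior predictive draws for a new population in
#' which sensitivity exceeds `sens_min` *and* specificity exceeds
#' `spec_min`, together with each marginal exceedance probability and
#' Monte Carlo standard errors. This is the joint statement a pooled
#' estimate cannot make: with heterogeneity, both margins being
#' individually adequate on average does not imply they are jointly
#' adequate in any one population.
#'
#' Only available for MCMC fits: the statement needs a predictive
#' distribution with parameter uncertainty propagated, which a point
#' estimate cannot supply.
#'
#' @param fit a `bivfit_bayes` object.
#' @param sens_min,spec_min thresholds in `[0, 1]`.
#' @return list with `joint`, `sens_marginal`, `spec_marginal`, and the
#'   Monte Carlo SE of each.
#' @export
joint_probability <- function(fit, sens_min, spec_min) {
  if (!inherits(fit, "bivfit_bayes"))
    stop("joint probability statements require a Bayesian fit ",
         "(fit_bivariate_bayes); an ML point estimate cannot supply a ",
         "predictive distribution with parameter uncertainty")
  if (sens_min < 0 || sens_min > 1 || spec_min < 0 || spec_min > 1)
    stop("thresholds must be in [0, 1]")
  se_draw <- stats::plogis(fit$draws[, "logit_p1_new"])
  sp_draw <- stats::plogis(fit$draws[, "logit_p0_new"])
  n <- length(se_draw)
  p_joint <- mean(se_draw > sens_min & sp_draw > spec_min)
  p_se <- mean(se_draw > sens_min)
  p_sp <- mean(sp_draw > spec_min)
  mc <- function(p) sqrt(p * (1 - p) / n)
  list(joint = p_joint, sens_marginal = p_se, spec_marginal = p_sp,
       mc_se = c(joint = mc(p_joint), sens = mc(p_se), spec = mc(p_sp)),
       thresholds = c(sensitivity = sens_min, specificity = spec_min),
       n_draws = n)
}

#' Joint prediction region for (specificity, sensitivity)
#'
#' Boundary of a region expected to contain the true (sensitivity,
#' specificity) pair of a new population with the stated probability.
#' For an ML fit the region is an ellipse on the logit plane centred at
#' the mean logits with shape \eqn{\hat\Omega + \mathrm{Var}(\hat\beta)}
#' and, by default, a chi-square(2) quantile radius; `type = "t"` uses a
#' Hotelling-style F radius with `k - 2` degrees of freedom, which widens
#' the region for small meta-analyses. For an MCMC fit the region is a
#' highest-density contour of the predictive draws obtained by 2-D
#' binning (no kernel smoothing).
#'
#' @param fit a `bivfit_ml` or `bivfit_bayes` object.
#' @param level coverage probability.
#' @param type radius rule for ML fits: `"chisq"` (default) or `"t"`.
#' @param n_points number of boundary points (ML ellipse).
#' @param n_bins grid resolution per axis (Bayesian contour).
#' @return data.frame of ordered boundary points with columns
#'   `specificity` and `sensitivity`, suitable for lines/polygon plots;
#'   the coverage level is attached as attribute `level`.
#' @export
prediction_region <- function(fit, level = 0.95, type = c("chisq", "t"),
                              n_points = 200, n_bins = 100) {
  type <- match.arg(type)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (inherits(fit, "bivfit_ml")) {
    shape <- omega_matrix(fit) + fit$vcov_means
    centre <- c(fit$beta1, fit$beta0)
    if (all(shape == 0)) {
      out <- data.frame(specificity = stats::plogis(centre[2]),
                        sensitivity = stats::plogis(centre[1]))
      attr(out, "level") <- level
      return(out)
    }
    if (min(eigen(shape, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("singular prediction-region shape matrix")
    r2 <- if (type == "chisq") stats::qchisq(level, 2)
          else 2 * stats::qf(level, 2, fit$k - 2)
    th <- seq(0, 2 * pi, length.out = n_points)
    circ <- rbind(cos(th), sin(th)) * sqrt(r2)
    pts <- centre + t(chol(shape)) %*% circ
    out <- data.frame(specificity = stats::plogis(pts[2, ]),
                      sensitivity = stats::plogis(pts[1, ]))
  } else if (inherits(fit, "bivfit_bayes")) {
    x <- fit$draws[, "logit_p0_new"]
    y <- fit$draws[, "logit_p1_new"]
    bx <- seq(min(x), max(x), length.out = n_bins + 1)
    by <- seq(min(y), max(y), length.out = n_bins + 1)
    ix <- findInterval(x, bx, rightmost.closed = TRUE)
    iy <- findInterval(y, by, rightmost.closed = TRUE)
    cnt <- matrix(0, n_bins, n_bins)
    tab <- table(factor(ix, levels = 1:n_bins), factor(iy, levels = 1:n_bins))
    cnt[] <- as.numeric(tab)
    # highest-density threshold: smallest count c with
    # sum(cnt[cnt >= c]) >= level * n
    srt <- sort(as.vector(cnt), decreasing = TRUE)
    cum <- cumsum(srt)
    thr <- srt[which(cum >= level * length(x))[1]]
    cl <- grDevices::contourLines(x = (bx[-1] + bx[-length(bx)]) / 2,
                                  y = (by[-1] + by[-length(by)]) / 2,
                                  z = cnt, levels = thr)
    if (!length(cl)) stop("could not trace a contour at this level")
    main <- cl[[which.max(vapply(cl, function(c) length(c$x), 0))]]
    out <- data.frame(specificity = stats::plogis(main$x),
                      sensitivity = stats::plogis(main$y))
  } else stop("unsupported fit object")
  attr(out, "level") <- level
  out
}
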