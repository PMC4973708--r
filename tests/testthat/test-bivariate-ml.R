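test_that("with zero heterogeneity the model collapses to pooled binomial logits", {
  d <- toy_dataset(4)
  f <- suppressWarnings(fit_bivariate_ml(d, tau_zero = TRUE))
  # direct binomial ML: logit of the pooled proportions
  expect_equal(f$beta1, qlogis(sum(d$r11) / sum(d$n1)), tolerance = 1e-6)
  expect_equal(f$beta0, qlogis(sum(d$r00) / sum(d$n0)), tolerance = 1e-6)
  # and the integrated likelihood equals the product of binomial pmfs
  ll_direct <- sum(dbinom(d$r11, d$n1, sum(d$r11) / sum(d$n1), log = TRUE)) +
    sum(dbinom(d$r00, d$n0, sum(d$r00) / sum(d$n0), log = TRUE))
  expect_equal(f$loglik, ll_direct, tolerance = 1e-6)
})

test_that("symmetric large studies give beta near 0 and tau near 0", {
  d <- acc_dataset(data.frame(study_id = c("a", "b"),
                              r11 = c(500, 500), n1 = c(1000, 1000),
                              r00 = c(500, 500), n0 = c(1000, 1000)))
  f <- suppressWarnings(fit_bivariate_ml(d))
  expect_lt(abs(f$beta1), 0.02)
  expect_lt(abs(f$beta0), 0.02)
  expect_lt(f$tau1, 0.05)
  expect_lt(f$tau0, 0.05)
})

test_that("ML fit of the thermometry data agrees with an independent GLMM fit", {
  d <- load_fixture("temperature")
  f <- fit_bivariate_ml(d)
  expect_equal(plogis(f$beta1), 0.65, tolerance = 0.02)
  expect_equal(plogis(f$beta0), 0.98, tolerance = 0.01)
  dd <- data.frame(study = factor(rep(d$study_id, 2)),
                   marg = factor(rep(c("se", "sp"), each = nrow(d))),
                   r = c(d$r11, d$r00), n = c(d$n1, d$n0))
  g <- glmmTMB::glmmTMB(cbind(r, n - r) ~ 0 + marg + (0 + marg | study),
                        family = stats::binomial, data = dd)
  fe <- glmmTMB::fixef(g)$cond
  # Laplace (glmmTMB) vs 10^2-node adaptive quadrature: close, not identical
  expect_equal(unname(f$beta1), unname(fe[1]), tolerance = 0.02)
  expect_equal(unname(f$beta0), unname(fe[2]), tolerance = 0.02)
  vc <- glmmTMB::VarCorr(g)$cond$study
  expect_equal(f$tau1, attr(vc, "stddev")[[1]], tolerance = 0.03)
  expect_equal(f$tau0, attr(vc, "stddev")[[2]], tolerance = 0.03)
  expect_equal(f$rho, attr(vc, "correlation")[1, 2], tolerance = 0.05)
})

test_that("swapping the two margins swaps the parameters", {
  d <- load_fixture("pth_0_20min")
  f <- suppressWarnings(fit_bivariate_ml(d))
  swapped <- acc_dataset(data.frame(study_id = d$study_id,
                                    r11 = d$r00, n1 = d$n0,
                                    r00 = d$r11, n0 = d$n1))
  g <- suppressWarnings(fit_bivariate_ml(swapped))
  expect_equal(g$beta1, f$beta0, tolerance = 1e-3)
  expect_equal(g$beta0, f$beta1, tolerance = 1e-3)
  expect_equal(g$tau1, f$tau0, tolerance = 5e-3)
  expect_equal(g$tau0, f$tau1, tolerance = 5e-3)
  expect_equal(g$rho, f$rho, tolerance = 5e-3)
})

test_that("estimates are stable when the quadrature order increases", {
  d <- load_fixture("temperature")
  f10 <- fit_bivariate_ml(d, n_quad = 10)
  f20 <- fit_bivariate_ml(d, n_quad = 20)
  expect_lt(abs(f10$beta1 - f20$beta1), 1e-3)
  expect_lt(abs(f10$beta0 - f20$beta0), 1e-3)
})

test_that("parameters are recovered from data simulated under the model", {
  truth <- list(beta1 = 1.5, beta0 = 2.5, tau1 = 0.6, tau0 = 0.4,
                rho = -0.5)
  sim <- simulate_dataset(k = 200, beta1 = truth$beta1, beta0 = truth$beta0,
                          tau1 = truth$tau1, tau0 = truth$tau0,
                          rho = truth$rho, alpha = 0, tau_alpha = 0,
                          n_range = 1000, seed = 314)
  f <- fit_bivariate_ml(sim$data)
  se_b <- sqrt(diag(f$vcov_means))
  expect_lt(abs(f$beta1 - truth$beta1), 3 * se_b[1])
  expect_lt(abs(f$beta0 - truth$beta0), 3 * se_b[2])
  # variance components: generous Monte-Carlo bands
  expect_equal(f$tau1, truth$tau1, tolerance = 0.15)
  expect_equal(f$tau0, truth$tau0, tolerance = 0.15)
  expect_equal(f$rho, truth$rho, tolerance = 0.2)
})

test_that("summary_accuracy performs the Wald arithmetic on the logit scale", {
  fake <- structure(list(beta1 = 0, beta0 = 1,
                         vcov_means = diag(c(0.25, 0.04)),
                         tau1 = 0.3, tau0 = 0.2, rho = 0, k = 10),
                    class = "bivfit_ml")
  s <- summary_accuracy(fake, level = 0.95)
  z <- qnorm(0.975)
  expect_equal(s$estimate[1], 0.5)
  expect_equal(s$lower[1], plogis(-z * 0.5), tolerance = 1e-12)
  expect_equal(s$upper[1], plogis(z * 0.5), tolerance = 1e-12)
  # the worked magnitude: expit(+-0.98) is about (0.27, 0.73)
  expect_equal(round(c(s$lower[1], s$upper[1]), 2), c(0.27, 0.73))
  expect_error(summary_accuracy(fake, level = 1.2), "level")
})

test_that("degenerate inputs are rejected or warned about", {
  expect_error(fit_bivariate_ml(toy_dataset(2), n_quad = 2), "n_quad")
  one <- acc_dataset(data.frame(study_id = "a", r11 = 5, n1 = 8,
                                r00 = 6, n0 = 9))
  expect_error(fit_bivariate_ml(one), "at least 2")
  expect_warning(fit_bivariate_ml(toy_dataset(3)), "fewer than 5")
  allb <- acc_dataset(data.frame(study_id = c("a", "b", "c", "d", "e"),
                                 r11 = c(5, 6, 7, 8, 4),
                                 n1 = c(5, 6, 7, 8, 4),
                                 r00 = c(9, 8, 7, 9, 10),
                                 n0 = c(9, 8, 7, 9, 10)))
  expect_warning(try(fit_bivariate_ml(allb), silent = TRUE), "boundary")
})
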