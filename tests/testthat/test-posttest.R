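test_that("Bayes-theorem conversions are exact in closed form", {
  # perfect test
  p <- option_a(1, 1, 0.3)
  expect_equal(c(p$ppv, p$npv), c(1, 1))
  # uninformative test: PPV = prevalence, NPV = 1 - prevalence
  p2 <- option_a(0.5, 0.5, 0.37)
  expect_equal(p2$ppv, 0.37, tolerance = 1e-12)
  expect_equal(p2$npv, 0.63, tolerance = 1e-12)
  # worked NPV: 0.81 * 0.8 / (0.07 * 0.2 + 0.81 * 0.8)
  p3 <- option_a(0.93, 0.81, 0.2)
  expect_equal(p3$npv, 0.648 / 0.662, tolerance = 1e-10)
  expect_error(option_a(1.2, 0.5, 0.5), "probability")
})

test_that("prevalence can be reconstructed from PPV/NPV (Bayes identity)", {
  set.seed(42)
  for (i in 1:50) {
    sens <- runif(1, 0.05, 0.99); spec <- runif(1, 0.05, 0.99)
    prev <- runif(1, 0.01, 0.99)
    p <- option_b(sens, spec, prev)
    q <- sens * prev + (1 - spec) * (1 - prev)  # P(test positive)
    expect_equal(p$ppv * q + (1 - p$npv) * (1 - q), prev,
                 tolerance = 1e-12)
  }
})

test_that("PPV rises and NPV falls with prevalence; A == B at the pooled value", {
  prevs <- seq(0.05, 0.95, by = 0.05)
  ppvs <- vapply(prevs, function(p) option_b(0.8, 0.7, p)$ppv, 0)
  npvs <- vapply(prevs, function(p) option_b(0.8, 0.7, p)$npv, 0)
  expect_true(all(diff(ppvs) > 0))
  expect_true(all(diff(npvs) < 0))
  a <- option_a(0.8, 0.7, 0.33)
  b <- option_b(0.8, 0.7, 0.33)
  expect_identical(c(a$ppv, a$npv), c(b$ppv, b$npv))
  # limiting behaviour
  expect_lt(option_b(0.8, 0.7, 1e-9)$ppv, 1e-6)
  expect_gt(option_b(0.8, 0.7, 1e-9)$npv, 1 - 1e-6)
})

test_that("prevalence meta-analysis agrees with an independent GLMM and recovers truth", {
  d <- load_fixture("temperature")
  f <- fit_prevalence_meta(d)
  dd <- data.frame(n1 = d$n1, N = d$n1 + d$n0, s = factor(d$study_id))
  g <- lme4::glmer(cbind(n1, N - n1) ~ 1 + (1 | s),
                   family = stats::binomial, data = dd, nAGQ = 15)
  expect_equal(f$alpha, unname(lme4::fixef(g)[1]), tolerance = 1e-3)
  expect_equal(f$tau_alpha, sqrt(unname(lme4::VarCorr(g)$s[1])),
               tolerance = 1e-2)

  sim <- simulate_dataset(k = 100, alpha = -1, tau_alpha = 0.3,
                          n_range = c(100, 400), seed = 21)
  fr <- fit_prevalence_meta(sim$data)
  expect_lt(abs(fr$alpha - (-1)), 3 * fr$se_alpha)
})

test_that("balanced large studies give prevalence one half with no heterogeneity", {
  d <- acc_dataset(data.frame(study_id = letters[1:6],
                              r11 = 400, n1 = 500, r00 = 450, n0 = 500))
  f <- fit_prevalence_meta(d)
  expect_equal(f$prevalence, 0.5, tolerance = 1e-3)
  expect_lt(f$tau_alpha, 0.01)
})

test_that("case-control studies are excluded from prevalence pooling", {
  df <- rbind(data.frame(study_id = c("c1", "c2", "c3"), r11 = c(40, 42, 38),
                         n1 = 50, r00 = c(45, 44, 46), n0 = 50,
                         design = "cohort"),
              data.frame(study_id = "cc", r11 = 90, n1 = 100, r00 = 90,
                         n0 = 100, design = "case_control"))
  d <- suppressWarnings(acc_dataset(df))
  expect_message(f <- fit_prevalence_meta(d), "case_control")
  expect_equal(f$k, 3)
  dcc <- suppressWarnings(acc_dataset(df[df$design == "case_control", ]))
  expect_error(fit_prevalence_meta(dcc), "prevalence-informative")
})

test_that("metareg without slopes equals a plain bivariate fit of PPV/NPV", {
  sim <- simulate_dataset(k = 30, seed = 55, n_range = c(100, 300))
  m <- study_measures(sim$data)
  f0 <- fit_ppv_npv_metareg(sim$data, slopes = FALSE)
  # the same model expressed through the plain bivariate fitter, with
  # test-positive/negative margins playing the role of the two binomials
  flipped <- acc_dataset(data.frame(study_id = sim$data$study_id,
                                    r11 = sim$data$r11, n1 = m$test_pos,
                                    r00 = sim$data$r00, n0 = m$test_neg))
  f1 <- fit_bivariate_ml(flipped)
  expect_equal(f0$delta1, f1$beta1, tolerance = 1e-3)
  expect_equal(f0$delta0, f1$beta0, tolerance = 1e-3)
  expect_equal(f0$tau_ppv, f1$tau1, tolerance = 5e-3)
  expect_equal(f0$tau_npv, f1$tau0, tolerance = 5e-3)
})

test_that("meta-regression recovers simulated intercepts and slopes", {
  set.seed(77)
  k <- 100
  N <- 2000
  truth <- list(d1 = 1, g1 = 3, d0 = 3, g0 = -4)
  x <- runif(k, 0.15, 0.45)          # target observed prevalence
  ppv_m <- plogis(truth$d1 + truth$g1 * x)
  npv_m <- plogis(truth$d0 + truth$g0 * x)
  # split each study into test positives/negatives so that the expected
  # observed prevalence equals x: t*PPV + (1-t)*(1-NPV) = x
  t_pos <- (x - (1 - npv_m)) / (ppv_m - (1 - npv_m))
  n_pos <- round(t_pos * N); n_neg <- N - n_pos
  z1 <- rnorm(k); z2 <- rnorm(k)
  lp <- truth$d1 + truth$g1 * x + 0.15 * z1
  ln <- truth$d0 + truth$g0 * x +
    0.15 * (0.3 * z1 + sqrt(1 - 0.09) * z2)
  r11 <- rbinom(k, n_pos, plogis(lp))
  r00 <- rbinom(k, n_neg, plogis(ln))
  # reconstruct the 2x2: diseased = TP + FN, non-diseased = FP + TN
  n1 <- r11 + (n_neg - r00)
  n0 <- (n_pos - r11) + r00
  d <- acc_dataset(data.frame(study_id = paste0("s", 1:k),
                              r11 = r11, n1 = n1, r00 = r00, n0 = n0))
  f <- fit_ppv_npv_metareg(d)
  se <- sqrt(diag(f$vcov_fixed))
  # recovered curve: predictions close to the truth across the range
  for (pv in c(0.2, 0.4)) {
    pred <- suppressWarnings(option_c_predict(f, pv))
    expect_equal(pred$ppv, plogis(truth$d1 + truth$g1 * pv),
                 tolerance = 0.04)
    expect_equal(pred$npv, plogis(truth$d0 + truth$g0 * pv),
                 tolerance = 0.04)
  }
  # slopes within sampling error plus a margin for the mild
  # errors-in-variables attenuation of the observed-prevalence covariate
  expect_lt(abs(f$gamma1 - truth$g1), 3 * se[2] + 0.6)
  expect_lt(abs(f$gamma0 - truth$g0), 3 * se[4] + 0.6)
})

test_that("option C predictions respect the logistic form", {
  fake <- structure(list(delta1 = 0, gamma1 = 0, delta0 = 1, gamma0 = -2,
                         tau_ppv = 0.1, tau_npv = 0.1, rho = 0,
                         prev_range = c(0.1, 0.6), center = 0.3,
                         k = 6, slopes = TRUE),
                    class = "ppv_npv_metareg")
  expect_equal(option_c_predict(fake, 0.2)$ppv, 0.5)
  expect_equal(option_c_predict(fake, 0.5)$ppv, 0.5)
  # prediction at the centring prevalence equals expit of the centred
  # intercept (algebraic identity: delta + gamma * c = delta_centred)
  expect_equal(option_c_predict(fake, 0.3)$npv, plogis(1 - 2 * 0.3))
  # monotone in prevalence when the slope is positive
  fake$gamma1 <- 2.5
  pp <- vapply(seq(0.1, 0.6, 0.1),
               function(p) option_c_predict(fake, p)$ppv, 0)
  expect_true(all(diff(pp) > 0))
  expect_warning(option_c_predict(fake, 0.9), "extrapolating")
})

test_that("a study margin with no test negatives is dropped with a warning", {
  df <- data.frame(study_id = paste0("s", 1:5),
                   r11 = c(20, 18, 25, 22, 30),
                   n1 = c(20, 20, 28, 25, 33),
                   r00 = c(0, 30, 28, 26, 35),
                   n0 = c(25, 33, 30, 29, 38))
  # study s1: test_neg = r00 + (n1 - r11) = 0 + 0 = 0
  d <- acc_dataset(df)
  expect_warning(fit_ppv_npv_metareg(d), "no test negatives")
})
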