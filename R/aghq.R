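# Internal adaptive Gauss-Hermite machinery shared by the maximum-likelihood
# fitters: the bivariate binomial logit-normal model (with or without
# study-level covariates on the means) and the univariate binomial
# logit-normal model (prevalence meta-analysis; exact calibration model,
# where the linear predictor carries a fixed per-study offset).

# Gauss-Hermite nodes/weights (physicists' convention, weight exp(-x^2))
# via Golub-Welsch on the Jacobi matrix.
gh_rule <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2 * sqrt(pi))
}

# Tensor-product grid for the bivariate integrals. lw already folds in the
# exp(x'x) correction so that integral = |C| * 2 * sum exp(h + lw) for nodes
# u = mode + sqrt(2) C x.
gh_grid2 <- function(n) {
  gh <- gh_rule(n)
  gx <- as.matrix(expand.grid(x1 = gh$x, x2 = gh$x))
  list(x1 = gx[, 1], x2 = gx[, 2],
       lw = log(as.vector(outer(gh$w, gh$w))) + gx[, 1]^2 + gx[, 2]^2)
}

# Vectorised (over studies) log marginal likelihood of the bivariate model:
#   r1_i ~ Bin(n1_i, expit(u1_i)), r0_i ~ Bin(n0_i, expit(u0_i)),
#   (u1_i, u0_i) ~ N((mu1_i, mu0_i), Sigma),
# integrated by adaptive Gauss-Hermite with per-study mode/curvature
# centering. inc1/inc0 switch a margin's binomial term off (used when a
# study has no test positives or negatives in the PPV/NPV regression);
# the corresponding latent then integrates out through the normal alone.
biv_loglik <- function(mu1, mu0, tau1, tau0, rho, r1, n1, r0, n0,
                       inc1, inc0, grid) {
  k <- length(r1)
  tau1 <- max(tau1, 1e-6)
  tau0 <- max(tau0, 1e-6)
  det_s <- tau1^2 * tau0^2 * (1 - rho^2)
  if (det_s <= 0) return(-Inf)
  # closed-form 2x2 inverse of Sigma
  s11 <- tau0^2 / det_s
  s00 <- tau1^2 / det_s
  s10 <- -rho * tau1 * tau0 / det_s
  ld <- log(det_s)

  # Newton ascent to the per-study mode of the integrand (joint log density
  # of data and latents); gradient/Hessian are analytic.
  u1 <- mu1; u0 <- mu0
  for (it in 1:100) {
    p1 <- stats::plogis(u1); p0 <- stats::plogis(u0)
    d1 <- u1 - mu1; d0 <- u0 - mu0
    g1 <- inc1 * (r1 - n1 * p1) - (s11 * d1 + s10 * d0)
    g0 <- inc0 * (r0 - n0 * p0) - (s10 * d1 + s00 * d0)
    # negative Hessian entries (positive definite)
    a <- inc1 * n1 * p1 * (1 - p1) + s11
    d <- inc0 * n0 * p0 * (1 - p0) + s00
    b <- s10
    det_h <- a * d - b * b
    st1 <- (d * g1 - b * g0) / det_h
    st0 <- (a * g0 - b * g1) / det_h
    if (!all(is.finite(st1)) || !all(is.finite(st0))) return(-Inf)
    u1 <- u1 + st1; u0 <- u0 + st0
    if (max(abs(st1), abs(st0)) < 1e-10) break
  }

  p1 <- stats::plogis(u1); p0 <- stats::plogis(u0)
  a <- inc1 * n1 * p1 * (1 - p1) + s11
  d <- inc0 * n0 * p0 * (1 - p0) + s00
  b <- s10
  det_h <- a * d - b * b
  if (!all(is.finite(det_h)) || any(det_h <= 0)) return(-Inf)
  # lower Cholesky of the inverse negative Hessian, per study
  v11 <- d / det_h; v00 <- a / det_h; v10 <- -b / det_h
  l11 <- sqrt(v11)
  l21 <- v10 / l11
  l22 <- sqrt(pmax(v00 - l21^2, 1e-300))

  # transformed nodes, k x J
  J <- length(grid$x1)
  U1 <- u1 + sqrt(2) * outer(l11, grid$x1)
  U0 <- u0 + sqrt(2) * (outer(l21, grid$x1) + outer(l22, grid$x2))
  P1 <- stats::plogis(U1); P0 <- stats::plogis(U0)
  H <- inc1 * stats::dbinom(r1, n1, P1, log = TRUE) +
       inc0 * stats::dbinom(r0, n0, P0, log = TRUE)
  D1 <- U1 - mu1; D0 <- U0 - mu0
  H <- H - 0.5 * (s11 * D1^2 + 2 * s10 * D1 * D0 + s00 * D0^2) -
       0.5 * ld - log(2 * pi)
  H <- H + rep(grid$lw, each = k)
  mx <- apply(H, 1, max)
  lint <- log(2) + log(l11 * l22) + mx + log(rowSums(exp(H - mx)))
  if (!all(is.finite(lint))) return(-Inf)
  sum(lint)
}

# Generic ML driver for the bivariate model with per-margin design matrices
# X1 (k x p1) and X0 (k x p0) on the means. Parameter vector:
# (b1[1..p1], b0[1..p0], log tau1, log tau0, atanh rho).
fit_biv_core <- function(r1, n1, r0, n0, X1, X0, n_quad = 10, start = NULL,
                         inc1 = NULL, inc0 = NULL, max_restarts = 5) {
  k <- length(r1)
  p1 <- ncol(X1); p0 <- ncol(X0)
  if (is.null(inc1)) inc1 <- rep(1, k)
  if (is.null(inc0)) inc0 <- rep(1, k)
  grid <- gh_grid2(n_quad)

  negll <- function(par) {
    b1 <- par[seq_len(p1)]
    b0 <- par[p1 + seq_len(p0)]
    v <- biv_loglik(as.vector(X1 %*% b1), as.vector(X0 %*% b0),
                    exp(par[p1 + p0 + 1]), exp(par[p1 + p0 + 2]),
                    tanh(par[p1 + p0 + 3]),
                    r1, n1, r0, n0, inc1, inc0, grid)
    if (!is.finite(v)) 1e10 else -v
  }

  if (is.null(start)) {
    # continuity-corrected observed logits seed the means and the
    # between-study SDs; the correction never enters the likelihood
    l1 <- stats::qlogis((r1 + 0.5) / (n1 + 1))
    l0 <- stats::qlogis((r0 + 0.5) / (n0 + 1))
    b1s <- qr.solve(X1, l1)
    b0s <- qr.solve(X0, l0)
    start <- c(b1s, b0s,
               log(max(stats::sd(l1), 0.1)), log(max(stats::sd(l0), 0.1)),
               atanh(-0.2))
  }

  best <- NULL
  st <- start
  for (try in 0:max_restarts) {
    op <- stats::optim(st, negll, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-10))
    op <- stats::optim(op$par, negll, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || op$value < best$value - 1e-8) best <- op
    if (op$convergence == 0 && op$value < 1e9) break
    st <- start + stats::rnorm(length(start), 0, 0.3)
  }
  op <- best
  H <- stats::optimHess(op$par, negll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(st), length(st)))

  list(b1 = op$par[seq_len(p1)], b0 = op$par[p1 + seq_len(p0)],
       tau1 = exp(op$par[p1 + p0 + 1]), tau0 = exp(op$par[p1 + p0 + 2]),
       rho = tanh(op$par[p1 + p0 + 3]),
       vcov_fixed = V[seq_len(p1 + p0), seq_len(p1 + p0), drop = FALSE],
       loglik = -op$value, converged = op$convergence == 0,
       par = op$par, k = k, n_quad = n_quad)
}

# Univariate binomial logit-normal model, ML by adaptive Gauss-Hermite:
#   r_i ~ Bin(n_i, expit(u_i + off_i)), u_i ~ N(a, tau^2).
# With off = 0 this is the prevalence meta-analysis model; with
# off = logit(predicted value) it is the exact calibration-in-the-large
# model. tau is optimised on its natural scale with a box at zero so the
# no-heterogeneity boundary is an admissible estimate (the tau = 0 branch
# is the plain binomial likelihood).
fit_binom_logitnorm <- function(r, n, off = 0, n_quad = 21) {
  k <- length(r)
  off <- rep_len(off, k)
  gh <- gh_rule(n_quad)

  loglik1 <- function(a, tau) {
    if (tau < 1e-8)
      return(sum(stats::dbinom(r, n, stats::plogis(a + off), log = TRUE)))
    u <- rep(a, k)
    for (it in 1:100) {
      p <- stats::plogis(u + off)
      g <- (r - n * p) - (u - a) / tau^2
      hd <- n * p * (1 - p) + 1 / tau^2
      st <- g / hd
      u <- u + st
      if (max(abs(st)) < 1e-11) break
    }
    p <- stats::plogis(u + off)
    s2 <- 1 / (n * p * (1 - p) + 1 / tau^2)
    Z <- u + sqrt(2) * outer(sqrt(s2), gh$x)
    H <- stats::dbinom(r, n, stats::plogis(Z + off), log = TRUE) +
         stats::dnorm(Z, a, tau, log = TRUE)
    H <- H + rep(gh$x^2 + log(gh$w), each = k)
    mx <- apply(H, 1, max)
    v <- sum(0.5 * log(2 * s2) + mx + log(rowSums(exp(H - mx))))
    if (is.finite(v)) v else -Inf
  }

  negll <- function(p) -loglik1(p[1], p[2])
  a0 <- mean(stats::qlogis((r + 0.5) / (n + 1)) - off)
  op <- stats::nlminb(c(a0, 0.5), negll, lower = c(-Inf, 0))
  a <- op$par[1]; tau <- op$par[2]
  if (tau > 1e-6) {
    Hm <- stats::optimHess(op$par, negll)
    V <- tryCatch(solve(Hm), error = function(e) matrix(NA_real_, 2, 2))
    se_a <- sqrt(V[1, 1])
  } else {
    tau <- 0
    h <- stats::optimHess(a, function(x) negll(c(x, 0)))
    se_a <- sqrt(1 / h[1, 1])
  }
  list(a = a, tau = tau, se_a = se_a, loglik = -op$objective, k = k,
       converged = op$convergence == 0)
}
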