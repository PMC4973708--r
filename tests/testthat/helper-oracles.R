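# Independent oracles used across test files.

# c statistic by exhaustive enumeration over diseased x non-diseased pairs
brute_force_c <- function(scores, labels) {
  labels <- as.logical(labels)
  sd_ <- scores[labels]; sn <- scores[!labels]
  tot <- 0
  for (a in sd_) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sd_) * length(sn))
}

# DerSimonian-Laird by explicit sums, written independently of the package
naive_dl <- function(y, s) {
  w <- 1 / s^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  k <- length(y)
  tau2 <- (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))
  tau2 <- max(0, tau2)
  wstar <- 1 / (s^2 + tau2)
  list(mu = sum(wstar * y) / sum(wstar), tau2 = tau2, Q = Q,
       se_mu = sqrt(1 / sum(wstar)), I2 = max(0, (Q - (k - 1)) / Q) * 100)
}

# printed per-study accuracy columns of the packaged datasets, for checking
# the derived measures against the source tables (2 dp)
printed_measures <- list(
  temperature = data.frame(
    study_id = c("Brennan", "Davis", "Green", "Greenes", "Hoffman",
                 "Hooker", "Lanham", "Muma", "Nypaver", "Rhoads", "Stewart"),
    sens = c(0.74, 0.50, 0.89, 0.49, 0.71, 0.67, 0.51, 0.55, 0.66, 0.26, 0.97),
    spec = c(0.93, 0.96, 1.00, 0.99, 0.97, 1.00, 0.99, 1.00, 0.98, 1.00, 1.00),
    prev = c(0.55, 0.27, 0.43, 0.36, 0.42, 0.38, 0.58, 0.39, 0.48, 0.42, 0.75)),
  pth_0_20min = data.frame(
    study_id = c("Lo", "Lombardi", "McLeod", "Warren, 2002", "Warren, 2004"),
    sens = c(1.0, 0.81, 0.69, 0.75, 0.67),
    spec = c(0.63, 0.89, 0.77, 0.83, 0.87),
    prev = c(0.11, 0.31, 0.23, 0.25, 0.12)),
  pth_1_2h = data.frame(
    study_id = c("Lam", "Lombardi", "McLeod", "Warren, 2002", "Warren, 2004"),
    sens = c(1.0, 0.94, 0.92, 0.50, 1.0),
    spec = c(0.92, 0.83, 0.76, 0.75, 0.74),
    prev = c(0.32, 0.31, 0.32, 0.20, 0.12)))

# tiny deterministic dataset for cheap fits
toy_dataset <- function(k = 4, seed = 42) {
  set.seed(seed)
  acc_dataset(data.frame(
    study_id = paste0("s", seq_len(k)),
    r11 = c(45, 30, 52, 38, 60, 25)[seq_len(k)],
    n1 = c(60, 40, 70, 50, 80, 35)[seq_len(k)],
    r00 = c(70, 55, 80, 62, 90, 40)[seq_len(k)],
    n0 = c(80, 60, 90, 70, 100, 45)[seq_len(k)]), name = "toy")
}
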