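# Independent oracles used by the tests. These deliberately re-derive each
# quantity by the most direct route available (brute-force double sums,
# direct normalization, eigen-decomposition) and share no code with the
# package internals they check.

# Identity calibration curve: c14 age == cal age, constant sigma.
identity_curve <- function(sigma = 1e-3, cal_min = -500, cal_max = 16500, by = 10) {
  grid <- seq(cal_min, cal_max, by = by)
  cal_curve(grid, grid, rep(sigma, length(grid)))
}

# Wiggly synthetic curve used in calibration oracle tests.
wiggly_curve <- function() make_synthetic_curve()

# Brute-force calibration: evaluate the Normal likelihood on the full 1-yr
# curve grid and normalize by direct summation. No support restriction, no
# tail truncation.
calibrate_oracle <- function(c14_age, c14_error, curve) {
  grid <- seq(ceiling(min(curve$cal_bp)), max(curve$cal_bp), by = 1)
  mu <- approx(curve$cal_bp, curve$c14_age, xout = grid)$y
  sg <- approx(curve$cal_bp, curve$c14_sigma, xout = grid)$y
  dens <- dnorm(c14_age, mu, sqrt(c14_error^2 + sg^2))
  data.frame(cal_bp = grid, mass = dens / sum(dens))
}

median_oracle <- function(dist) {
  cum <- cumsum(dist$mass)
  dist$cal_bp[which(cum >= 0.5)[1]]
}

# Direct implementation of the Sheather-Jones solve-the-equation bandwidth:
# exact pairwise density-functional sums (no binning) and uniroot on the
# plug-in equation, with the published pilot constants on the IQR scale.
sj_ste_oracle <- function(x) {
  n <- length(x)
  lambda <- min(1.349 * sd(x), IQR(x))
  phi <- function(u) exp(-u^2 / 2) / sqrt(2 * pi)
  phi4 <- function(u) (u^4 - 6 * u^2 + 3) * phi(u)
  phi6 <- function(u) (u^6 - 15 * u^4 + 45 * u^2 - 15) * phi(u)
  d <- outer(x, x, "-")
  SD <- function(h) sum(phi4(d / h)) / (n * (n - 1) * h^5)
  TD <- function(h) -sum(phi6(d / h)) / (n * (n - 1) * h^7)
  a <- 0.920 * lambda * n^(-1 / 7)
  b <- 0.912 * lambda * n^(-1 / 9)
  alpha2 <- function(h) 1.357 * (SD(a) / TD(b))^(1 / 7) * h^(5 / 7)
  f <- function(h) (1 / (2 * sqrt(pi)) / (n * SD(alpha2(h))))^(1 / 5) - h
  h0 <- 0.9 * min(sd(x), IQR(x) / 1.349) * n^(-1 / 5)
  uniroot(f, lower = 0.05 * h0, upper = 5 * h0, tol = 1e-9)$root
}

# A small in-memory record table with every field populated.
toy_records <- function(n = 5, c14 = seq(1000, 5000, length.out = n)) {
  tibble::tibble(
    lab_id = sprintf("LAB-%03d", seq_len(n)),
    c14_age = c14,
    c14_error = rep(30, n),
    site_id = sprintf("23AB%d", seq_len(n)),
    lon = seq(-90, -86, length.out = n),
    lat = seq(36, 39, length.out = n),
    context = "archaeological",
    anomalous = FALSE
  )
}
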