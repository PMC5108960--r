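test_that("SJ bandwidth is translation-invariant and scale-equivariant", {
  set.seed(4)
  x <- rnorm(200, 5000, 1500)
  h <- sj_bandwidth(x)
  expect_equal(sj_bandwidth(x + 500), h, tolerance = 1e-4)
  expect_equal(sj_bandwidth(x * 2), 2 * h, tolerance = 1e-3)
  expect_error(sj_bandwidth(rep(1000, 50)), class = "chronopop_degenerate_error")
})

test_that("SJ bandwidth matches the direct solve-the-equation oracle", {
  for (n in c(100, 1000)) {
    set.seed(42)
    x <- rnorm(n)
    expect_equal(sj_bandwidth(x), sj_ste_oracle(x), tolerance = 0.02)
  }
})

test_that("a single date yields a Gaussian-shaped KDE series", {
  s <- kde_series(5000, bw = 300)
  g <- cal_grid()
  expect_s3_class(s, "grid_series")
  expect_equal(nrow(s), 151)
  expect_equal(s$value, dnorm(g, 5000, 300))
  expect_false(any(s$corrected))
})

test_that("the KDE integrates to ~1 away from grid edges", {
  set.seed(6)
  x <- rnorm(500, 7000, 800)
  fine <- seq(0, 15000, by = 1)
  s <- kde_series(x, bw = 250, grid = fine)
  integral <- sum((s$value[-1] + s$value[-length(fine)]) / 2)
  expect_equal(integral, 1, tolerance = 0.01)
})

test_that("KDE grid values equal a brute-force sum of kernels", {
  set.seed(16)
  x <- runif(200, 0, 15000)
  bw <- 400
  s <- kde_series(x, bw = bw)
  brute <- sapply(cal_grid(), function(g) {
    acc <- 0
    for (xi in x) acc <- acc + exp(-(g - xi)^2 / (2 * bw^2)) / (bw * sqrt(2 * pi))
    acc / length(x)
  })
  expect_lt(max(abs(s$value - brute)), 1e-12)
})

test_that("site counts deduplicate sites within bins but not across bins", {
  tab <- tibble::tibble(
    site_id = c("1AA1", "2BB2", "2BB2"),
    median_cal_bp = c(150, 250, 260)
  )
  s <- site_count_series(tab)
  expect_equal(s$value[s$cal_bp == 100], 1)
  expect_equal(s$value[s$cal_bp == 200], 1)
  # one site dated in two different bins counts once in each
  tab2 <- tibble::tibble(site_id = c("1AA1", "1AA1"), median_cal_bp = c(150, 950))
  s2 <- site_count_series(tab2)
  expect_equal(s2$value[s2$cal_bp == 100], 1)
  expect_equal(s2$value[s2$cal_bp == 900], 1)
})

test_that("incomplete trinomials are excluded from site counts", {
  expect_true(all(is_complete_trinomial(c("40CF111", "23ab4", "9XYZ12"))))
  expect_false(any(is_complete_trinomial(c("", "40CF", "CF111", NA, "site 5"))))
  tab <- tibble::tibble(
    site_id = c("40CF111", "", "40CF"),
    median_cal_bp = c(150, 150, 150)
  )
  expect_equal(site_count_series(tab)$value[2], 1)
})

test_that("site counts match a brute-force set-per-bin oracle on a random fixture", {
  set.seed(23)
  tab <- tibble::tibble(
    site_id = rep(sprintf("%dAB%d", sample(1:48, 50, TRUE), 1:50), each = 5),
    median_cal_bp = runif(250, 0, 15100)
  )
  s <- site_count_series(tab)
  for (t in seq(0, 15000, by = 100)) {
    hi <- if (t == 15000) t + 100 else t + 100 # final bin closed above
    inbin <- tab$median_cal_bp >= t & (tab$median_cal_bp < t + 100 |
      (t == 15000 & tab$median_cal_bp <= t + 100))
    expect_equal(s$value[s$cal_bp == t], length(unique(tab$site_id[inbin])))
  }
})

test_that("taphonomic survival is normalized, decreasing, and matches closed form", {
  m <- taph_model()
  expect_equal(taph_survival(0, m), 1)
  expect_lt(taph_survival(5000, m), taph_survival(1000, m))
  # direct closed-form evaluation: ((t + b) / b)^c
  expect_equal(taph_survival(5000, m), ((5000 + 2176.4) / 2176.4)^(-1.3925309),
    tolerance = 1e-12
  )
  expect_error(taph_survival(-1, m), class = "chronopop_domain_error")
  expect_error(taph_model(b = -1), class = "chronopop_usage_error")
})

test_that("taphonomic correction is a pointwise rescaling with s(0) = 1", {
  s <- kde_series(runif(50, 0, 15000), bw = 500)
  cor <- apply_taph_correction(s)
  expect_equal(cor$value[cor$cal_bp == 0], s$value[s$cal_bp == 0])
  expect_true(all(cor$corrected))
  expect_error(apply_taph_correction(cor), class = "chronopop_usage_error")
  # zeros stay zero; ratios at a grid point are preserved across series
  z <- site_count_series(
    tibble::tibble(site_id = "1AA1", median_cal_bp = 150)
  )
  zc <- apply_taph_correction(z)
  expect_equal(sum(zc$value != 0), 1)
  # a flat observed series becomes monotone increasing toward the past
  flat <- chronopop:::new_grid_series(cal_grid(), rep(2, 151), "kde_density", FALSE)
  corflat <- apply_taph_correction(flat)
  expect_true(all(diff(corflat$value) > 0))
})

test_that("correcting a taphonomically thinned constant record recovers flatness", {
  sc <- make_scenario("constant")
  ages <- sample_calendar_dates(sc, 2000, taph_loss = TRUE, seed = 55)
  sites <- tibble::tibble(
    site_id = sprintf("1AA%d", sample(1:400, 2000, TRUE)),
    median_cal_bp = ages
  )
  cnt <- site_count_series(sites)
  cor <- apply_taph_correction(cnt)
  fit <- fit_glm(cor)
  ci <- suppressMessages(stats::confint.default(fit$model))["t", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("build_proxies returns exactly the four tagged series", {
  set.seed(61)
  med <- tibble::tibble(
    site_id = sprintf("3CC%d", sample(1:40, 300, TRUE)),
    median_cal_bp = runif(300, 0, 15000)
  )
  px <- build_proxies(med)
  combos <- dplyr::distinct(px[, c("proxy", "corrected")])
  expect_equal(nrow(combos), 4)
  expect_setequal(combos$proxy, c("kde_density", "site_count"))
  expect_equal(nrow(px), 4 * 151)
  expect_true(all(px$value >= 0))
  obs <- px$value[px$proxy == "site_count" & !px$corrected]
  expect_equal(obs, round(obs)) # integer before correction
})

test_that("degenerate bootstrap cases behave as specified", {
  set.seed(71)
  med <- tibble::tibble(
    site_id = sprintf("5DD%d", sample(1:30, 120, TRUE)),
    median_cal_bp = runif(120, 2000, 9000)
  )
  one <- bootstrap_envelope(med, "kde_density", n_iter = 1, frac = 0.5, seed = 1)
  expect_equal(one$lo, one$hi)
  full <- bootstrap_envelope(med, "site_count", n_iter = 5, frac = 1, seed = 1)
  expect_equal(full$lo, full$hi) # frac = 1 without replacement: identical replicates
  expect_error(bootstrap_envelope(med[1:3, ], "kde_density", frac = 0.1),
    class = "chronopop_usage_error"
  )
})

test_that("bootstrap envelopes are deterministic under a fixed seed", {
  set.seed(81)
  med <- tibble::tibble(
    site_id = sprintf("7EE%d", sample(1:30, 150, TRUE)),
    median_cal_bp = runif(150, 1000, 14000)
  )
  a <- bootstrap_envelope(med, "site_count", n_iter = 20, seed = 33)
  b <- bootstrap_envelope(med, "site_count", n_iter = 20, seed = 33)
  expect_identical(a$lo, b$lo)
  expect_identical(a$hi, b$hi)
  expect_true(all(a$lo <= a$hi))
})
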