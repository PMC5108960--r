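test_that("read_curve parses IntCal-style files and sorts ascending", {
  path <- withr::local_tempfile(fileext = ".14c")
  writeLines(c(
    "# synthetic curve",
    "# CAL BP, 14C age, Sigma, extra",
    "400,410,12,999",
    "300,305,11,999",
    "200,206,10,999",
    "100,98,10,999",
    "0,5,10,999"
  ), path)
  crv <- read_curve(path)
  expect_s3_class(crv, "cal_curve")
  expect_equal(nrow(crv), 5)
  expect_equal(crv$cal_bp, c(0, 100, 200, 300, 400))
  expect_equal(crv$c14_age[1], 5)
})

test_that("curve read/write round-trips through the IntCal layout", {
  crv <- cal_curve(seq(0, 1000, 100), seq(0, 1000, 100) + 5, rep(8, 11))
  path <- withr::local_tempfile(fileext = ".14c")
  write_curve(crv, path)
  expect_equal(as.data.frame(read_curve(path)), as.data.frame(crv))
})

test_that("curve files with too few rows or bad sigma are rejected", {
  path <- withr::local_tempfile(fileext = ".14c")
  writeLines("100,100,10", path)
  expect_error(read_curve(path), class = "chronopop_format_error")
  writeLines(c("100,100,10", "200,200,0"), path)
  expect_error(read_curve(path), class = "chronopop_format_error")
})

test_that("curve interpolation matches a brute-force two-point oracle", {
  set.seed(31)
  knots <- sort(sample(0:5000, 40))
  crv <- cal_curve(knots, knots + rnorm(40, 0, 50), runif(40, 5, 30))
  q <- runif(100, min(knots), max(knots))
  at <- chronopop:::curve_at(crv, q)
  for (i in seq_along(q)) {
    j <- findInterval(q[i], crv$cal_bp, rightmost.closed = TRUE)
    w <- (q[i] - crv$cal_bp[j]) / (crv$cal_bp[j + 1] - crv$cal_bp[j])
    expect_equal(at$mu[i], (1 - w) * crv$c14_age[j] + w * crv$c14_age[j + 1],
      tolerance = 1e-10
    )
    expect_equal(at$sigma[i], (1 - w) * crv$c14_sigma[j] + w * crv$c14_sigma[j + 1],
      tolerance = 1e-10
    )
  }
  expect_error(chronopop:::curve_at(crv, 6000), class = "chronopop_range_error")
})

test_that("calibration on the identity curve returns a centred Gaussian posterior", {
  crv <- identity_curve(sigma = 1e-3)
  d10 <- calibrate(3000, 10, crv)
  expect_equal(median_cal(d10), 3000)
  expect_equal(sum(d10$mass), 1, tolerance = 1e-9)
  expect_equal(d10$cal_bp[which.max(d10$mass)], 3000)
  # wider lab error widens the 95% interval ~ proportionally
  d50 <- calibrate(3000, 50, crv)
  expect_equal(median_cal(d50), 3000)
  spread <- function(d) {
    cum <- cumsum(d$mass)
    d$cal_bp[which(cum >= 0.975)[1]] - d$cal_bp[which(cum >= 0.025)[1]]
  }
  expect_equal(spread(d50) / spread(d10), 5, tolerance = 0.05)
})

test_that("posteriors match the brute-force normalize-and-sum oracle on a wiggly curve", {
  crv <- wiggly_curve()
  dist <- calibrate(3000, 25, crv)
  orc <- calibrate_oracle(3000, 25, crv)
  orc <- orc[match(dist$cal_bp, orc$cal_bp), ]
  # point-by-point equality once the oracle is conditioned on the same
  # (tail-truncated) support
  expect_lt(max(abs(dist$mass - orc$mass / sum(orc$mass))), 1e-10)
  expect_equal(median_cal(dist), median_oracle(calibrate_oracle(3000, 25, crv)))
})

test_that("calibration errors when the date lies outside curve support", {
  crv <- cal_curve(seq(0, 1000, 10), seq(0, 1000, 10), rep(5, 101))
  expect_error(calibrate(5000, 20, crv), class = "chronopop_range_error")
})

test_that("median convention takes the smallest grid year reaching half mass", {
  d <- tibble::tibble(cal_bp = c(1000, 2000), mass = c(0.4, 0.6))
  expect_equal(median_cal(d), 2000)
  d2 <- tibble::tibble(cal_bp = c(1000, 2000), mass = c(0.5, 0.5))
  expect_equal(median_cal(d2), 1000)
})

test_that("medians of random posteriors match a cumulative-sum oracle exactly", {
  crv <- wiggly_curve()
  set.seed(99)
  ages <- runif(50, 500, 14500)
  for (a in ages) {
    d <- calibrate(a, 30, crv)
    expect_equal(median_cal(d), median_oracle(d))
  }
})

test_that("calibration is shift-equivariant on the identity curve", {
  crv <- identity_curve(sigma = 1e-3)
  base <- calibrate(4000, 20, crv)
  shifted <- calibrate(4500, 20, crv)
  expect_equal(shifted$cal_bp, base$cal_bp + 500)
  expect_equal(shifted$mass, base$mass, tolerance = 1e-12)
})

test_that("batch calibration composes per-record calibrate + median", {
  crv <- wiggly_curve()
  recs <- toy_records(8, c14 = seq(800, 12000, length.out = 8))
  out <- calibrate_batch(recs, crv)
  expect_equal(nrow(out), 8)
  expect_equal(out$lab_id, recs$lab_id)
  for (i in 1:8) {
    expect_equal(
      out$median_cal_bp[i],
      median_cal(calibrate(recs$c14_age[i], recs$c14_error[i], crv))
    )
  }
})

test_that("batch calibration reports failing records without aborting", {
  crv <- cal_curve(seq(0, 2000, 10), seq(0, 2000, 10), rep(5, 201))
  recs <- toy_records(3, c14 = c(500, 30000, 1500))
  out <- calibrate_batch(recs, crv)
  expect_equal(nrow(out), 2)
  failed <- attr(out, "failed")
  expect_equal(failed$lab_id, "LAB-002")
  expect_equal(nrow(calibrate_batch(recs[0, ], crv)), 0)
})

test_that("identity-curve medians recover true calendar ages from simulated measurements", {
  crv <- make_synthetic_curve()
  set.seed(12)
  truth <- runif(200, 1000, 14000)
  meas <- uncalibrate(truth, crv, lab_error = 25)
  ok <- 0
  for (i in seq_along(truth)) {
    d <- calibrate(meas$c14_age[i], meas$c14_error[i], crv)
    tot <- sqrt(25^2 + 10^2)
    if (abs(median_cal(d) - truth[i]) <= 2 * tot) ok <- ok + 1
  }
  expect_gte(ok / length(truth), 0.95)
})
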