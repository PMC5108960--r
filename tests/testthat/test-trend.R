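make_series <- function(values, proxy = "site_count", corrected = FALSE) {
  chronopop:::new_grid_series(cal_grid(), values, proxy, corrected)
}

test_that("the GLM recovers an exact log-linear trend", {
  t <- -cal_grid()
  y <- exp(1.2 + 2e-4 * t)
  fit <- fit_glm(make_series(y))
  expect_equal(unname(coef(fit$model)["t"]), 2e-4, tolerance = 1e-6)
  expect_equal(fit$grid$fitted, y, tolerance = 1e-6, ignore_attr = TRUE)
  expect_gt(fit$pseudo_r2, 0.999)
})

test_that("a constant series gives a null GLM slope and ~0 pseudo-r2", {
  set.seed(2)
  y <- rpois(151, 20)
  fit <- fit_glm(make_series(y))
  ci <- suppressMessages(stats::confint.default(fit$model))["t", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_lt(fit$pseudo_r2, 0.05)
  expect_error(fit_glm(make_series(rep(0, 151))), class = "chronopop_degenerate_error")
})

test_that("GLM slope recovery is unbiased over Poisson replicates", {
  t <- -cal_grid()
  b <- 1.5e-4
  mu <- exp(2 + b * t)
  set.seed(10)
  est <- replicate(20, {
    fit <- fit_glm(make_series(rpois(151, mu)))
    unname(coef(fit$model)["t"])
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - b), 2 * mc_se + 1e-9)
})

test_that("the GAM shrinks to near-linear on log-linear data", {
  t <- -cal_grid()
  set.seed(20)
  y <- rpois(151, exp(2 + 1.5e-4 * t))
  gam_fit <- fit_gam(make_series(y))
  glm_fit <- fit_glm(make_series(y))
  expect_lt(gam_fit$edf, 3.5)
  expect_lt(
    max(abs(log(gam_fit$grid$fitted) - log(glm_fit$grid$fitted))),
    0.25
  )
})

test_that("a zero-noise smooth signal is interpolated closely by the GAM", {
  t <- cal_grid()
  y <- 40 + 25 * sin(t / 2400) + 10 * cos(t / 5000)
  fit <- fit_gam(make_series(y), basis_dim = 30)
  inner <- 10:141
  expect_lt(max(abs(fit$grid$fitted[inner] - y[inner]) / y[inner]), 0.01)
})

test_that("GAM fit error decreases with noise level (consistency)", {
  t <- cal_grid()
  mu <- exp(3 + 0.5 * sin(t / 2000) + 0.4 * dnorm(t, 6000, 1200) * 2000)
  mise <- sapply(c(4, 0.25), function(scl) {
    set.seed(30)
    mean(replicate(10, {
      y <- rpois(151, mu * scl) / scl # larger scl = smaller relative noise
      fit <- fit_gam(make_series(y))
      mean((fit$grid$fitted - mu)^2)
    }))
  })
  expect_lt(mise[1], mise[2])
})

test_that("in the infinite-penalty limit the GAM reproduces the GLM", {
  set.seed(40)
  y <- rpois(151, exp(2 - 1e-4 * cal_grid()))
  glm_fit <- fit_glm(make_series(y))
  gam_fit <- fit_gam(make_series(y), sp = 1e12)
  expect_lt(max(abs(gam_fit$grid$fitted - glm_fit$grid$fitted)), 1e-6)
  expect_lt(gam_fit$edf, 2 + 1e-3)
})

test_that("derivatives of linear and constant fits behave exactly", {
  t <- -cal_grid()
  fit <- fit_glm(make_series(exp(1 + 1e-4 * t)))
  d <- derivative(fit)
  # exactly exponential fit: response-scale slope proportional to the fit,
  # constant ratio slope/fitted
  ratio <- d$slope / fit$grid$fitted[match(d$cal_bp, fit$grid$cal_bp)]
  inner <- 2:150
  expect_lt(diff(range(ratio[inner])), 1e-6)
  set.seed(50)
  flat <- fit_glm(make_series(rpois(151, 30)))
  dflat <- derivative(flat)
  expect_true(all(dflat$lo < 0 & dflat$hi > 0))
})

test_that("derivative slope and CI equal the brute-force contrast oracle", {
  set.seed(60)
  y <- rpois(151, exp(3 + 0.6 * sin(cal_grid() / 2500)))
  fit <- fit_gam(make_series(y))
  d <- derivative(fit, alpha = 0.05)
  d <- dplyr::arrange(d, dplyr::desc(cal_bp))
  nd <- data.frame(t = sort(-cal_grid()))
  Xp <- predict(fit$model, newdata = nd, type = "lpmatrix")
  beta <- coef(fit$model)
  V <- vcov(fit$model)
  mu <- as.numeric(exp(Xp %*% beta))
  idx <- sort(sample(2:150, 50))
  for (i in idx) {
    cvec <- rep(0, 151)
    cvec[i + 1] <- 0.5
    cvec[i - 1] <- -0.5
    slope <- sum(cvec * mu)
    grad <- as.numeric(t(cvec * mu) %*% Xp) # chain rule through the log link
    se <- sqrt(as.numeric(t(grad) %*% V %*% grad))
    row <- which(d$cal_bp == -nd$t[i])
    expect_equal(d$slope[row], slope, tolerance = 1e-10)
    expect_equal(d$se[row], se, tolerance = 1e-8)
    expect_equal(d$lo[row], slope - qnorm(0.975) * se, tolerance = 1e-8)
  }
})

test_that("significant periods are maximal runs with the cal BP convention", {
  grid <- cal_grid()
  d <- tibble::tibble(
    cal_bp = grid,
    slope = 0, se = 1,
    lo = -1, hi = 1
  )
  expect_equal(nrow(significant_periods(d)), 0)
  # increase flagged exactly on 5500..6400
  inc <- d$cal_bp >= 5500 & d$cal_bp <= 6400
  d2 <- d
  d2$lo[inc] <- 0.1
  p <- significant_periods(d2)
  expect_equal(nrow(p), 1)
  expect_equal(p$start, 6400)
  expect_equal(p$end, 5500)
  expect_equal(p$direction, "increase")
  # single-point runs are not reported as periods
  d3 <- d
  d3$hi[d3$cal_bp == 8000] <- -0.1
  expect_equal(nrow(significant_periods(d3)), 0)
})

test_that("random significance masks match a run-length-encoding oracle", {
  set.seed(70)
  grid <- cal_grid()
  for (rep in 1:10) {
    state <- sample(c("inc", "dec", "none"), 151, TRUE, prob = c(0.2, 0.2, 0.6))
    d <- tibble::tibble(
      cal_bp = grid, slope = 0, se = 1,
      lo = ifelse(state == "inc", 0.5, -1),
      hi = ifelse(state == "dec", -0.5, 1)
    )
    p <- significant_periods(d)
    # oracle: walk the grid old -> young collecting runs of length >= 2
    st <- rev(state)
    gr <- rev(grid)
    runs <- list()
    i <- 1
    while (i <= 151) {
      j <- i
      while (j < 151 && st[j + 1] == st[i]) j <- j + 1
      if (st[i] != "none" && j > i) {
        runs[[length(runs) + 1]] <- c(gr[i], gr[j], st[i])
      }
      i <- j + 1
    }
    expect_equal(nrow(p), length(runs))
    for (k in seq_along(runs)) {
      expect_equal(p$start[k], as.numeric(runs[[k]][1]))
      expect_equal(p$end[k], as.numeric(runs[[k]][2]))
      expect_equal(p$direction[k], c(inc = "increase", dec = "decrease")[[runs[[k]][3]]])
    }
  }
})

test_that("significance flags are invariant to positive rescaling of the series", {
  set.seed(80)
  y <- rpois(151, exp(2.5 + 0.5 * sin(cal_grid() / 2000)))
  d1 <- derivative(fit_gam(make_series(y)))
  d2 <- derivative(fit_gam(make_series(y * 7)))
  expect_equal(d1$lo > 0, d2$lo > 0)
  expect_equal(d1$hi < 0, d2$hi < 0)
})

test_that("analyze_all fits all four proxies and supports identical inputs", {
  set.seed(90)
  med <- tibble::tibble(
    site_id = sprintf("9FF%d", sample(1:80, 600, TRUE)),
    median_cal_bp = runif(600, 0, 15000)
  )
  px <- build_proxies(med)
  an <- analyze_all(px, alpha = 0.05)
  expect_equal(nrow(an), 4)
  expect_true(all(is.na(an$error)))
  expect_s3_class(an$gam[[1]], "trend_fit")
  expect_equal(attr(an, "alpha"), 0.05)
  cg <- common_growth(an)
  expect_equal(nrow(cg), 151)
  # four copies of one series give four identical period lists
  one <- chronopop:::pick_proxy(px, "site_count", FALSE)
  four <- dplyr::bind_rows(
    one,
    dplyr::mutate(one, corrected = TRUE),
    dplyr::mutate(one, proxy = "kde_density"),
    dplyr::mutate(one, proxy = "kde_density", corrected = TRUE)
  )
  attr(four, "n_dates") <- NA_integer_
  an4 <- analyze_all(four)
  pers <- purrr::map(an4$periods, as.data.frame)
  expect_equal(pers[[2]], pers[[1]])
  expect_equal(pers[[3]], pers[[1]])
  expect_equal(pers[[4]], pers[[1]])
  expect_error(analyze_all(px[0, ]), class = "chronopop_usage_error")
})

test_that("per-proxy failures propagate without aborting the rest", {
  set.seed(95)
  med <- tibble::tibble(
    site_id = sprintf("8GG%d", sample(1:40, 300, TRUE)),
    median_cal_bp = runif(300, 0, 15000)
  )
  px <- build_proxies(med)
  px$value[px$proxy == "site_count" & !px$corrected] <- 0
  an <- analyze_all(px)
  bad <- an$proxy == "site_count" & !an$corrected
  expect_false(is.na(an$error[bad]))
  expect_true(all(is.na(an$error[!bad])))
})
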