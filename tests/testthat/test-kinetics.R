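test_that("fit windows follow the per-series rules", {
  expect_equal(select_fit_window("K", "dark_sucrose"), c(0, 32))
  expect_equal(select_fit_window("A", "dark_sucrose"), c(0, 64))
  expect_equal(select_fit_window("R", "dark_sucrose"), c(0, 64))
  expect_equal(select_fit_window("T", "dark_sucrose"), c(0, 64))
  expect_equal(select_fit_window("W", "dark_sucrose"), c(0, 64))
  expect_equal(select_fit_window("W", "light_no_sucrose"), c(0, 64))
  expect_equal(select_fit_window("S", "light_sucrose"), c(0, 16))
  expect_equal(select_fit_window("ZZ", "light_sucrose"), c(0, 16))
  ov <- data.frame(code = "S", condition = "light_sucrose",
                   t_min = 0, t_max = 128)
  expect_equal(select_fit_window("S", "light_sucrose", ov), c(0, 128))
})

test_that("noiseless curves are recovered essentially exactly", {
  t <- c(0, 1, 2, 4, 8, 16)
  f1 <- m0_decay(t, m0_curve(0.85, 0.13, t))
  expect_equal(unname(coef(f1)), c(0.85, 0.13), tolerance = 1e-4 / 0.85)
  expect_true(f1$converged)

  td <- c(0, 0.25, 0.5, 1, 2, 4, 8, 16)
  f2 <- m0_decay(td, m0_curve(1.51, 0.25, td))
  expect_equal(unname(coef(f2)), c(1.51, 0.25), tolerance = 1e-6)
})

test_that("every published parameter pair survives a noiseless round trip", {
  ref <- reference_kinetics()
  for (i in seq_len(nrow(ref))) {
    tg <- condition_time_grid(ref$condition[i])
    win <- select_fit_window(ref$code[i], ref$condition[i])
    fit <- m0_decay(tg, m0_curve(ref$k[i], ref$c[i], tg), window = win)
    cf <- coef(fit)
    expect_lt(abs(cf[["k"]] - ref$k[i]) / ref$k[i], 1e-3)
    expect_lt(abs(cf[["c"]] - ref$c[i]) / max(ref$c[i], 1e-6), 1e-3)
  }
})

test_that("the formula interface matches the default interface", {
  t <- rep(c(0, 1, 2, 4, 8, 16), 2)
  set.seed(8)
  y <- pmin(1, pmax(0, m0_curve(0.5, 0.2, t) + rnorm(length(t), 0, 0.02)))
  f1 <- m0_decay(m0_fraction ~ time_h,
                 data = data.frame(time_h = t, m0_fraction = y))
  f2 <- m0_decay(t, y)
  expect_equal(coef(f1), coef(f2))
})

test_that("observations outside the fit window are ignored", {
  t <- c(0, 1, 2, 4, 8, 16, 32, 64, 128)
  y <- m0_curve(0.85, 0.13, t)
  y[t > 16] <- 0.9   # corrupt out-of-window points
  fit <- m0_decay(t, y, window = c(0, 16))
  expect_equal(unname(coef(fit)), c(0.85, 0.13), tolerance = 1e-6)
  expect_equal(fit$n_obs, 6)
})

test_that("degenerate and invalid inputs are rejected or flagged", {
  expect_error(m0_decay(c(0, 1), c(1, 0.5)), "3 distinct time points")
  expect_error(m0_decay(c(0, 1, 2), c(1.2, 0.5, 0.4)), "\\[0, 1\\]")
  expect_error(m0_decay(c(-1, 1, 2), c(1, 0.5, 0.4)), "negative")
  # constant series: no decay information
  fc <- m0_decay(c(0, 1, 2, 4, 8, 16), rep(1, 6))
  expect_false(fc$converged)
  fc2 <- m0_decay(c(0, 1, 2, 4, 8, 16), rep(0.5, 6))
  expect_equal(unname(coef(fc2)["c"]), 0.5, tolerance = 1e-8)
})

test_that("standard errors shrink with replicate count", {
  t6 <- c(0, 1, 2, 4, 8, 16)
  make <- function(nrep, seed) {
    set.seed(seed)
    t <- rep(t6, nrep)
    y <- pmin(1, pmax(0, m0_curve(0.85, 0.13, t) + rnorm(length(t), 0, 0.02)))
    m0_decay(t, y)
  }
  se3 <- make(3, 21)$se
  se10 <- make(10, 21)$se
  expect_lt(se10[["k"]], se3[["k"]])
  expect_lt(se10[["c"]], se3[["c"]])
})

test_that("stochastic recovery is unbiased across seeds", {
  t6 <- c(0, 1, 2, 4, 8, 16)
  ks <- vapply(1:60, function(s) {
    set.seed(s)
    t <- rep(t6, 5)
    y <- pmin(1, pmax(0, m0_curve(0.85, 0.13, t) + rnorm(length(t), 0, 0.02)))
    coef(m0_decay(t, y))[["k"]]
  }, numeric(1))
  mc_se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.85), 3 * mc_se)
})

test_that("model methods are mutually consistent", {
  t <- rep(c(0, 1, 2, 4, 8, 16), 3)
  set.seed(4)
  y <- pmin(1, pmax(0, m0_curve(0.6, 0.2, t) + rnorm(length(t), 0, 0.01)))
  fit <- m0_decay(t, y)
  expect_equal(fitted(fit) + residuals(fit), fit$data$m0_fraction)
  cf <- coef(fit)
  expect_equal(predict(fit, c(0, 3)), m0_curve(cf["k"], cf["c"], c(0, 3)))
  expect_equal(predict(fit, data.frame(time_h = 2)), predict(fit, 2))
  expect_equal(sum(residuals(fit)^2), fit$rss)
  s <- summary(fit)
  expect_s3_class(s, "summary.m0_decay")
  expect_equal(s$coefficients["k", "Estimate"], cf[["k"]])
  expect_output(print(fit), "plateau|Plateau")
  expect_output(print(s), "Residual sigma")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(t), 4L))
  expect_true(all(sims[, -1] >= 0 & sims[, -1] <= 1))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("fit_all fits every pair and honours exclusions", {
  sim <- noiseless_sim()
  fits <- fit_all(sim$observations)
  ref <- reference_kinetics()
  # excluded pairs reported, not fitted
  h <- fits[fits$code == "H", ]
  expect_true(all(h$excluded))
  expect_match(h$reason[1], "excluded")
  expect_true(all(fits$excluded[fits$code == "V" &
                                  fits$condition != "light_sucrose"]))
  # fitted pairs recover the generating parameters
  m <- merge(fits[!fits$excluded, ], ref, by = c("code", "condition"),
             suffixes = c("_fit", "_ref"))
  expect_gt(nrow(m), 35)
  expect_lt(max(abs(m$k_fit - m$k_ref) / m$k_ref), 1e-3)
  fitlist <- attr(fits, "fits")
  expect_s3_class(fitlist[[1]], "m0_decay")
})
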