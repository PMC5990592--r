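test_that("EIC extraction picks sticks within the ppm window only", {
  run <- fake_run(rt_min = c(1.0, 1.1, 1.2),
                  sticks = list(c(150.0, 500), c(150.0 + 150e-6 * 20, 300),
                                c(149.0, 100)))
  eic <- extract_eic(run, 150.0, ppm_tol = 10, rt_window = c(0.9, 1.3))
  # exact match kept; a stick displaced by 2x the tolerance is not
  expect_equal(eic$intensity, c(500, 0, 0))
  expect_error(extract_eic(run, 150, ppm_tol = 10, rt_window = c(2, 1)),
               "rt_window")
  expect_error(extract_eic(run, 150, ppm_tol = 0, rt_window = c(0, 2)))
})

test_that("EIC extraction respects the retention window", {
  run <- fake_run(rt_min = c(0.5, 1.0, 1.5, 2.0),
                  sticks = rep(list(c(100, 10)), 4))
  eic <- extract_eic(run, 100, rt_window = c(0.9, 1.6))
  expect_equal(eic$rt_min, c(1.0, 1.5))
})

test_that("trapezoidal integration recovers a Gaussian peak area", {
  rt <- seq(0, 2, by = 0.01)
  area_true <- 1234
  sigma <- 0.05
  run <- fake_run(rt, lapply(rt, function(r) {
    c(200, area_true * dnorm(r, 1, sigma))
  }))
  eic <- extract_eic(run, 200, rt_window = c(0, 2))
  area <- integrate_eic(eic)
  expect_equal(as.numeric(area), area_true, tolerance = 0.01)
  expect_equal(attr(area, "qc"), "ok")
  # constant baseline subtraction
  run2 <- fake_run(rt, lapply(rt, function(r) {
    c(200, 50 + area_true * dnorm(r, 1, sigma))
  }))
  eic2 <- extract_eic(run2, 200, rt_window = c(0, 2))
  expect_equal(as.numeric(integrate_eic(eic2, baseline = 50)), area_true,
               tolerance = 0.01)
})

test_that("degenerate chromatograms integrate to flagged zero", {
  a <- integrate_eic(data.frame(rt_min = 1, intensity = 10))
  expect_equal(as.numeric(a), 0)
  expect_equal(attr(a, "qc"), "too_few_points")
})

test_that("envelope fractions normalise and flag empty envelopes", {
  expect_equal(envelope_fractions(c(10, 0, 0)), c(1, 0, 0))
  z <- envelope_fractions(c(0, 0))
  expect_true(all(is.na(z)))
  expect_equal(attr(z, "qc"), "empty_envelope")
  set.seed(3)
  for (i in 1:10) {
    a <- runif(sample(2:5, 1), 0, 100)
    expect_equal(sum(envelope_fractions(a)), 1)
  }
})

test_that("extraction is linear in spectrum intensity", {
  rt <- seq(0.9, 1.5, by = 0.01)
  mk <- function(scale) fake_run(rt, lapply(rt, function(r) {
    rbind(c(120, scale * 800 * dnorm(r, 1.2, 0.05)),
          c(121, scale * 200 * dnorm(r, 1.2, 0.05)))
  }))
  a1 <- vapply(c(120, 121), function(mz) {
    as.numeric(integrate_eic(extract_eic(mk(1), mz, rt_window = c(0.9, 1.5))))
  }, numeric(1))
  a2 <- vapply(c(120, 121), function(mz) {
    as.numeric(integrate_eic(extract_eic(mk(2), mz, rt_window = c(0.9, 1.5))))
  }, numeric(1))
  expect_equal(a2, 2 * a1)
  expect_equal(envelope_fractions(a1)[1], envelope_fractions(a2)[1])
})

test_that("the 10 ppm default cannot merge 15N and 13C isotopologues", {
  gap <- 1.003355 - delta_15N()   # 13C vs 15N M+1 spacing difference, Da
  specs <- amino_acid_specs()
  for (i in seq_len(nrow(specs))) {
    ser <- isotopomer_mz_series(specs[i, ])
    half_window <- max(ser$mz) * 10e-6
    expect_lt(half_window, gap / 2)
  }
})

test_that("mzML files round-trip through write and read", {
  sim <- noiseless_sim()
  sid <- "light_sucrose_r1_t0"
  env <- sim$envelopes[sim$envelopes$sample_id == sid, ]
  path <- tempfile(fileext = ".mzML")
  write_mzml_fixture(env, sim$config$specs, path)
  run <- read_mzml(path)
  specs <- sim$config$specs
  n_scans <- length(seq(min(specs$rt_start_min), max(specs$rt_end_min),
                        by = 0.01))
  expect_equal(length(run$rt_min), n_scans)
  expect_false(is.unsorted(run$rt_min))
})

test_that("empty and malformed mzML inputs are handled", {
  p <- empty_mzml(tempfile(fileext = ".mzML"))
  run <- read_mzml(p)
  expect_equal(length(run$rt_min), 0)

  bad <- tempfile(fileext = ".mzML")
  writeLines("this is not mass spectrometry data", bad)
  expect_error(read_mzml(bad), "parse")
  expect_error(read_mzml(tempfile()), "no such file")
})

test_that("full extraction recovers simulated areas and M0 fractions", {
  sim <- noiseless_sim()
  sid <- "dark_sucrose_r1_t1"
  env <- sim$envelopes[sim$envelopes$sample_id == sid, ]
  path <- tempfile(fileext = ".mzML")
  write_mzml_fixture(env, sim$config$specs, path)
  ex <- extract_envelopes(
    data.frame(sample_id = sid, path = path, condition = "dark_sucrose",
               time_h = 1, replicate = 1),
    sim$config$specs)
  m <- merge(ex$envelopes, env, by = c("code", "n_label"))
  major <- m$area.y > 1e-6 * max(m$area.y)
  expect_lt(max(abs(m$area.x - m$area.y)[major] / m$area.y[major]), 0.01)
  ob <- merge(ex$observations,
              sim$observations[sim$observations$sample_id == sid, ],
              by = "code")
  expect_lt(max(abs(ob$m0_fraction.x - ob$m0_fraction.y)), 0.005)
  expect_error(extract_envelopes(data.frame(sample_id = sid, path = path),
                                 sim$config$specs),
               "missing sample metadata")
})
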