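make_obs <- function(params, times = c(0, 1, 2, 4, 8, 16, 32),
                     condition = "light_sucrose") {
  do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
    data.frame(code = params$code[i], condition = condition,
               time_h = times, replicate = 1L,
               m0_fraction = m0_curve(params$k[i], params$c[i], times),
               stringsAsFactors = FALSE)
  }))
}

test_that("the feature matrix has one row per amino acid over in-window times", {
  pars <- data.frame(code = c("A", "B", "C"), k = c(1, 1, 0.2),
                     c = c(0.1, 0.1, 0.5))
  obs <- make_obs(pars, times = c(0, 1, 2, 4, 8, 16, 32, 64, 128))
  mat <- build_feature_matrix(obs, t_max = 32)
  expect_equal(sort(rownames(mat)), c("A", "B", "C"))
  expect_equal(as.numeric(colnames(mat)), c(0, 1, 2, 4, 8, 16, 32))
  # identical trajectories give identical rows
  expect_equal(unname(mat["A", ]), unname(mat["B", ]))
  # incomplete series are dropped and reported
  obs2 <- rbind(obs, data.frame(code = "D", condition = "light_sucrose",
                                time_h = 0, replicate = 1L, m0_fraction = 1))
  mat2 <- build_feature_matrix(obs2, t_max = 32)
  expect_false("D" %in% rownames(mat2))
  expect_equal(attr(mat2, "dropped"), "D")
  expect_error(build_feature_matrix(rbind(obs,
    within(obs, condition <- "dark_sucrose"))), "one condition")
})

test_that("replicate means enter the feature matrix", {
  obs <- data.frame(code = "A", condition = "x", time_h = c(0, 0, 1, 1),
                    replicate = c(1, 2, 1, 2),
                    m0_fraction = c(0.9, 1.0, 0.4, 0.6))
  mat <- build_feature_matrix(obs, t_max = 32)
  expect_equal(unname(mat["A", ]), c(0.95, 0.5))
})

test_that("k-means boundary cases behave", {
  set.seed(2)
  x <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], NULL))
  r_all <- kmeans_hw(x, 6, seed = 1)
  expect_equal(r_all$within_ss, 0, tolerance = 1e-12)
  r1 <- kmeans_hw(x, 1, seed = 1)
  expect_equal(unname(r1$centroids[1, ]), unname(colMeans(x)))
  expect_equal(r1$between_ss, 0, tolerance = 1e-10)
  expect_error(kmeans_hw(x, 7, seed = 1), "exceeds")
  expect_error(kmeans_hw(x, 0, seed = 1), "at least 1")
})

test_that("every item is assigned once and SS decomposition is exact", {
  set.seed(9)
  x <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
  for (k in c(2, 3, 4)) {
    r <- kmeans_hw(x, k, seed = 3, n_restarts = 50)
    expect_setequal(names(r$assignments), letters[1:8])
    expect_equal(length(r$assignments), 8)
    expect_lt(abs(r$within_ss + r$between_ss - r$total_ss) /
                r$total_ss, 1e-8)
  }
})

test_that("Hartigan-Wong with restarts attains the enumeration optimum", {
  # 1-D, six points: global optimum by exhaustive partition enumeration
  x1 <- c(a = 0.1, b = 0.2, c = 0.35, d = 4.1, e = 4.4, f = 9)
  r <- kmeans_hw(x1, 2, seed = 5, n_restarts = 50)
  expect_equal(r$within_ss, brute_force_within_ss(x1, 2), tolerance = 1e-12)

  # trajectory-like rows
  set.seed(31)
  t7 <- c(0, 1, 2, 4, 8, 16, 32)
  truth <- data.frame(code = letters[1:8],
                      k = rep(c(1.0, 0.4, 0.1, 0.8), 2),
                      c = rep(c(0.15, 0.4, 0.6, 0.2), 2))
  obs <- make_obs(truth, t7)
  obs$m0_fraction <- pmin(1, pmax(0, obs$m0_fraction + rnorm(nrow(obs), 0, 0.03)))
  mat <- build_feature_matrix(obs, 32)
  for (k in 2:3) {
    r <- kmeans_hw(mat, k, seed = 7, n_restarts = 50)
    expect_equal(r$within_ss, brute_force_within_ss(mat, k), tolerance = 1e-10)
  }
})

test_that("deterministic seeding and canonical labels give stable partitions", {
  set.seed(14)
  x <- rbind(matrix(rnorm(10, 0, 0.05), 5), matrix(rnorm(10, 2, 0.05), 5),
             matrix(rnorm(10, 5, 0.05), 5))
  rownames(x) <- sprintf("m%02d", 1:15)
  r1 <- kmeans_hw(x, 3, seed = 1)
  r2 <- kmeans_hw(x, 3, seed = 1)
  expect_identical(r1$assignments, r2$assignments)
  # different seeds may permute ids but the partition is identical
  r3 <- kmeans_hw(x, 3, seed = 999)
  part <- function(r) unname(lapply(split(names(r$assignments),
                                          r$assignments), sort))
  expect_setequal(part(r1), part(r3))
  # canonical labels: first row always in cluster 1
  expect_equal(unname(r1$assignments[1]), 1L)
})

test_that("k selection finds well-separated groups and handles edge cases", {
  set.seed(6)
  x <- rbind(matrix(rnorm(10, 0, 0.02), 5), matrix(rnorm(10, 2, 0.02), 5),
             matrix(rnorm(10, 4, 0.02), 5))
  rownames(x) <- sprintf("g%02d", 1:15)
  k <- select_k(x, 1:6, seed = 2)
  expect_equal(as.integer(k), 3L)
  scan <- attr(k, "scan")
  expect_true(all(c("k", "within_ss", "between_ratio") %in% names(scan)))
  # identical rows: degenerate, smallest k reported
  xi <- matrix(1, 5, 3, dimnames = list(letters[1:5], NULL))
  ki <- select_k(xi, 1:4, seed = 2)
  expect_equal(as.integer(ki), 1L)
  expect_true(attr(ki, "degenerate"))
  # zero threshold: most parsimonious k in range
  expect_equal(as.integer(select_k(x, 2:5, seed = 2, threshold = 0)), 2L)
})

test_that("cluster models recover pooled generating parameters", {
  t7 <- c(0, 0.25, 0.5, 1, 2, 4, 8, 16)
  pars <- data.frame(code = c("Q", "E", "D"), k = 1.002, c = 0.179)
  obs <- make_obs(pars, t7)
  res <- kmeans_hw(build_feature_matrix(obs, 32), 1, seed = 1)
  models <- fit_cluster_models(obs, res)
  expect_equal(models$k, 1.002, tolerance = 1e-3)
  expect_equal(models$c, 0.179, tolerance = 1e-3)
  # singleton cluster equals the member's own fit
  pars2 <- data.frame(code = c("A", "B"), k = c(1.0, 0.05), c = c(0.1, 0.7))
  obs2 <- make_obs(pars2, t7)
  res2 <- kmeans_hw(build_feature_matrix(obs2, 32), 2, seed = 1)
  m2 <- fit_cluster_models(obs2, res2)
  own <- coef(m0_decay(m0_fraction ~ time_h,
                       data = obs2[obs2$code == "A", ]))
  row_a <- m2[m2$members == "A", ]
  expect_equal(c(row_a$k, row_a$c), unname(own), tolerance = 1e-9)
  # assignments naming absent codes are skipped with a report
  res3 <- res2
  res3$assignments <- c(res3$assignments, Z = 3L)
  m3 <- fit_cluster_models(obs2, res3)
  expect_equal(attr(m3, "skipped"), 3L)
})

test_that("flux clustering uses condition-specific default cluster counts", {
  set.seed(8)
  fx <- setNames(abs(rnorm(12, 0.01, 0.005)), sprintf("aa%02d", 1:12))
  r_ls <- cluster_flux(fx, condition = "light_sucrose", seed = 1)
  expect_equal(r_ls$k, 4L)
  r_dk <- cluster_flux(fx, condition = "dark_sucrose", seed = 1)
  expect_equal(r_dk$k, 3L)
  # k capped at the number of values; NAs dropped
  r_small <- cluster_flux(c(a = 1, b = 2, NA), condition = "light_sucrose")
  expect_equal(r_small$k, 2L)
  expect_error(cluster_flux(c(a = NA_real_)), "no flux values")
})
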