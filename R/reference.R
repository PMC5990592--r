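#' Growth-condition labels
#'
#' Canonical labels for the three metabolic growth conditions:
#' `light_sucrose` (mixotrophic: light cycle, supplemental sucrose),
#' `light_no_sucrose` (photoautotrophic: light cycle, no sucrose),
#' `dark_sucrose` (heterotrophic: dark, supplemental sucrose).
#'
#' @return Character vector of length 3.
#' @export
growth_conditions <- function() {
  c("light_sucrose", "light_no_sucrose", "dark_sucrose")
}

#' Reference turnover parameters for S. polyrhiza amino acids
#'
#' Published plateau-exponential parameters (turnover constant `k`, per
#' hour, and labeling plateau `c`, fraction) for free amino acids in
#' *Spirodela polyrhiza* under the three growth conditions, with their
#' standard errors. These are the defaults from which the synthetic-data
#' generator draws its per-amino-acid, per-condition truth.
#'
#' Rows where the original fit was reported as unstable carry
#' `unstable = TRUE`; amino acid x condition pairs with no usable model
#' are absent from the table (histidine outside light+sucrose, glutamate
#' in the dark, tyrosine and valine outside light+sucrose).
#'
#' @return data.frame with columns `code`, `condition`, `k`, `se_k`,
#'   `c`, `se_c`, `unstable`.
#' @export
reference_kinetics <- function() {
  ls <- "light_sucrose"; ln <- "light_no_sucrose"; dk <- "dark_sucrose"
  rows <- list(
    list("A",   ls, 0.85, 0.05,  0.13, 0.01, FALSE),
    list("A",   ln, 0.47, 0.03,  0.16, 0.02, FALSE),
    list("A",   dk, 0.03, 0.01,  0.15, 0.09, FALSE),
    list("R",   ls, 1.16, 0.11,  0.24, 0.01, FALSE),
    list("R",   ln, 0.43, 0.03,  0.11, 0.02, FALSE),
    list("R",   dk, 0.25, 0.03,  0.30, 0.03, FALSE),
    list("N",   ls, 0.70, 0.05,  0.11, 0.02, FALSE),
    list("N",   ln, 0.39, 0.02,  0.13, 0.01, FALSE),
    list("N",   dk, 0.32, 0.02,  0.29, 0.01, FALSE),
    list("D",   ls, 0.38, 0.03,  0.32, 0.02, FALSE),
    list("D",   ln, 0.11, 0.02,  0.15, 0.10, TRUE),
    list("D",   dk, 0.12, 0.04,  0.59, 0.08, FALSE),
    list("E",   ls, 0.78, 0.05,  0.17, 0.01, FALSE),
    list("E",   ln, 0.32, 0.10,  0.44, 0.06, FALSE),
    list("Q",   ls, 0.44, 0.027, 0.41, 0.01, FALSE),
    list("Q",   ln, 0.16, 0.02,  0.54, 0.03, FALSE),
    list("Q",   dk, 0.19, 0.05,  0.74, 0.03, FALSE),
    list("G",   ls, 0.09, 0.02,  0.22, 0.08, FALSE),
    list("G",   ln, 0.17, 0.09,  0.20, 0.18, TRUE),
    list("G",   dk, 0.04, 0.02,  0.80, 0.06, FALSE),
    list("H",   ls, 0.44, 0.03,  0.41, 0.01, FALSE),
    list("I/L", ls, 0.35, 0.02,  0.24, 0.01, FALSE),
    list("I/L", ln, 0.26, 0.07,  0.28, 0.08, FALSE),
    list("I/L", dk, 0.04, 0.002, 0.07, 0.02, FALSE),
    list("K",   ls, 0.10, 0.01,  0.34, 0.05, FALSE),
    list("K",   ln, 0.25, 0.05,  0.48, 0.04, FALSE),
    list("K",   dk, 0.09, 0.05,  0.77, 0.07, FALSE),
    list("F",   ls, 0.39, 0.03,  0.33, 0.01, FALSE),
    list("F",   ln, 0.82, 0.05,  0.03, 0.02, FALSE),
    list("F",   dk, 1.51, 0.11,  0.25, 0.01, FALSE),
    list("P",   ls, 1.17, 0.07,  0.03, 0.01, FALSE),
    list("P",   ln, 0.32, 0.15,  0.27, 0.12, FALSE),
    list("P",   dk, 0.02, 0.004, 0.40, 0.07, FALSE),
    list("S",   ls, 0.32, 0.04,  0.17, 0.04, FALSE),
    list("S",   ln, 0.36, 0.03,  0.15, 0.03, FALSE),
    list("S",   dk, 0.03, 0.02,  0.45, 0.24, TRUE),
    list("T",   ls, 0.84, 0.04,  0.18, 0.01, FALSE),
    list("T",   ln, 0.14, 0.03,  0.25, 0.08, FALSE),
    list("T",   dk, 0.06, 0.005, 0.54, 0.03, FALSE),
    list("W",   ls, 0.25, 0.02,  0.30, 0.02, FALSE),
    list("W",   ln, 0.06, 0.03,  0.30, 0.13, FALSE),
    list("W",   dk, 0.04, 0.01,  0.46, 0.04, FALSE),
    list("Y",   ls, 0.16, 0.021, 0.37, 0.04, FALSE),
    list("V",   ls, 0.36, 0.02,  0.37, 0.01, FALSE)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(code = r[[1]], condition = r[[2]], k = r[[3]], se_k = r[[4]],
               c = r[[5]], se_c = r[[6]], unstable = r[[7]],
               stringsAsFactors = FALSE)
  }))
  out
}

#' Reference per-cluster decay models
#'
#' Published plateau-exponential parameters fitted to the pooled
#' trajectories of each k-means cluster of labeling patterns, per growth
#' condition. Useful as truth for cluster-level parameter-recovery checks.
#'
#' @return data.frame with columns `condition`, `cluster`, `k`, `se_k`,
#'   `c`, `se_c`.
#' @export
reference_cluster_models <- function() {
  data.frame(
    condition = c(rep("light_sucrose", 3), rep("light_no_sucrose", 4),
                  rep("dark_sucrose", 4)),
    cluster = c(1:3, 1:4, 1:4),
    k = c(1.002, 0.437, 0.205,
          0.472, 0.128, 0.360, 0.149,
          1.659, 0.286, 0.061, 0.008),
    se_k = c(0.05, 0.02, 0.03,
             0.04, 0.05, 0.10, 0.08,
             0.12, 0.03, 0.03, 0.08),
    c = c(0.179, 0.380, 0.530,
          0.110, 0.000, 0.529, 0.547,
          0.278, 0.302, 0.514, 0.000),
    se_c = c(0.01, 0.01, 0.04,
             0.03, 0.25, 0.06, 0.15,
             0.02, 0.03, 0.19, 9.26),
    stringsAsFactors = FALSE
  )
}

#' Sampling time grid for a growth condition
#'
#' The light-with-sucrose experiment was sampled at 0, 1, 2, 4, 8, 16,
#' 32, 64 and 128 h; the light-without-sucrose and dark experiments took
#' additional 15- and 30-minute samples.
#'
#' @param condition One of [growth_conditions()].
#' @return Numeric vector of labeling times in hours.
#' @export
condition_time_grid <- function(condition) {
  base <- c(0, 1, 2, 4, 8, 16, 32, 64, 128)
  condition <- match.arg(condition, growth_conditions())
  if (condition == "light_sucrose") base else sort(c(0.25, 0.5, base))
}
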