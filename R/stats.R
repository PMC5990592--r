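#' Two-sided variance-ratio F test
#'
#' Tests equality of variances between two replicate samples with the
#' F distribution on `(n_x - 1, n_y - 1)` degrees of freedom. Used as
#' the gate that decides between pooled-variance and Welch t tests.
#'
#' @param x,y Numeric replicate vectors, each with at least 2 values.
#' @return List with `f` (variance ratio var(x)/var(y)), `df`, and `p`
#'   (two-sided).
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 values per sample for the variance test", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(list(f = NA_real_, df = c(length(x) - 1L, length(y) - 1L),
                p = NA_real_, degenerate = TRUE))
  }
  ht <- stats::var.test(x, y)
  list(f = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), degenerate = FALSE)
}

#' F-test-gated two-sample t test
#'
#' Two-tailed t test assuming unequal variances (Welch), except where
#' the variance-ratio F test indicates equal sample variances
#' (`p >= alpha_variance`), in which case the pooled-variance Student
#' t test is applied.
#'
#' @param x,y Numeric replicate vectors.
#' @param alpha_variance Significance level for the variance gate
#'   (default 0.05).
#' @return One-row data.frame: `f_p`, `test_used`
#'   (`"equal-variance"` / `"unequal-variance"`), `t_stat`, `df`,
#'   `p_value`, `mean_diff`, `n_a`, `n_b`.
#' @export
pairwise_t <- function(x, y, alpha_variance = 0.05) {
  ft <- variance_f_test(x, y)
  equal <- !isTRUE(ft$degenerate) && ft$p >= alpha_variance
  ht <- stats::t.test(x, y, var.equal = equal)
  data.frame(
    f_p = ft$p,
    test_used = if (equal) "equal-variance" else "unequal-variance",
    t_stat = unname(ht$statistic), df = unname(ht$parameter),
    p_value = unname(ht$p.value), mean_diff = mean(x) - mean(y),
    n_a = length(x), n_b = length(y), stringsAsFactors = FALSE)
}

#' All pairwise condition comparisons of pool quantities
#'
#' Compares replicate-level pool quantities between the three condition
#' pairs (light+sucrose vs light-sucrose, light+sucrose vs dark,
#' light-sucrose vs dark) for every amino acid and every requested
#' quantity. No multiplicity correction is applied by default, matching
#' per-pair reporting practice; set `adjust = "BH"` for
#' Benjamini-Hochberg adjusted p values in an extra column.
#'
#' @param replicate_table data.frame with columns `code`, `condition`,
#'   `replicate` and one column per quantity (e.g. the output of
#'   [pool_replicates()], optionally augmented with `p_active`, `flux`,
#'   `flux_active` columns).
#' @param quantities Character vector of quantity column names.
#' @param alpha_variance Variance-gate level for [pairwise_t()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `code`, `quantity`, `condition_a`, `condition_b`,
#'   plus the [pairwise_t()] columns (and `p_adj` when `adjust = "BH"`).
#' @export
run_all_comparisons <- function(replicate_table,
                                quantities = "p_initial",
                                alpha_variance = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pairs <- list(c("light_sucrose", "light_no_sucrose"),
                c("light_sucrose", "dark_sucrose"),
                c("light_no_sucrose", "dark_sucrose"))
  rows <- list()
  for (code in sort(unique(replicate_table$code))) {
    for (q in quantities) {
      for (pr in pairs) {
        a <- replicate_table[replicate_table$code == code &
                               replicate_table$condition == pr[1], q]
        b <- replicate_table[replicate_table$code == code &
                               replicate_table$condition == pr[2], q]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2L || length(b) < 2L) next
        res <- tryCatch(pairwise_t(a, b, alpha_variance),
                        error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(code = code, quantity = q, condition_a = pr[1],
                     condition_b = pr[2], stringsAsFactors = FALSE),
          res)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}
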