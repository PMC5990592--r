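.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Trajectory feature matrix for clustering
#'
#' One row per amino acid, one column per shared time point up to
#' `t_max`, entries the replicate-mean M0 fraction. Amino acids missing
#' any in-window time point are dropped and reported in the `"dropped"`
#' attribute.
#'
#' @param observations Observation table for a single condition (columns
#'   `code`, `time_h`, `m0_fraction`).
#' @param t_max Last labeling time (hours) to include; default 32.
#' @return Numeric matrix, rownames codes, colnames times.
#' @export
build_feature_matrix <- function(observations, t_max = 32) {
  if (length(unique(observations$condition)) > 1) {
    stop("build_feature_matrix expects observations from one condition",
         call. = FALSE)
  }
  obs <- observations[observations$time_h <= t_max &
                        !is.na(observations$m0_fraction), , drop = FALSE]
  times <- sort(unique(obs$time_h))
  agg <- stats::aggregate(m0_fraction ~ code + time_h, data = obs, mean)
  wide <- stats::reshape(agg, idvar = "code", timevar = "time_h",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$code
  colnames(mat) <- sub("^m0_fraction\\.", "", colnames(mat))
  mat <- mat[, order(as.numeric(colnames(mat))), drop = FALSE]
  complete <- stats::complete.cases(mat)
  dropped <- rownames(mat)[!complete]
  mat <- mat[complete, , drop = FALSE]
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  attr(mat, "dropped") <- dropped
  mat
}

.canonical_labels <- function(assign) {
  # renumber clusters by first appearance so labels are deterministic
  map <- stats::setNames(seq_along(unique(assign)), unique(assign))
  out <- map[as.character(assign)]
  names(out) <- names(assign)
  out
}

#' K-means clustering with Hartigan-Wong updates
#'
#' Clusters rows by squared Euclidean distance using the Hartigan-Wong
#' algorithm, keeping the best of `n_restarts` random starts;
#' deterministic for a fixed seed. Cluster ids are renumbered by first
#' appearance over the row order so equal-SS solutions resolve to a
#' single labelling.
#'
#' @param x Numeric matrix (rows = items) or vector (1-D clustering).
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed RNG seed for the restarts.
#' @param n_restarts Number of random starts (default 25).
#' @return List of class `cluster_result`: `k`, `assignments` (named),
#'   `centroids`, `within_ss`, `between_ss`, `total_ss`, `sizes`,
#'   `seed`, `n_restarts`.
#' @export
kmeans_hw <- function(x, k, seed = 1L, n_restarts = 25L) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  if (k > nrow(x)) stop("k exceeds the number of rows", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  tss <- sum(sweep(x, 2, colMeans(x))^2)
  if (k == nrow(x)) {
    # trivial partition: every row its own cluster, within-SS zero
    km <- list(cluster = seq_len(k), withinss = rep(0, k),
               betweenss = tss, totss = tss)
  } else {
    km <- .with_seed(seed,
      stats::kmeans(x, centers = k, algorithm = "Hartigan-Wong",
                    nstart = n_restarts, iter.max = 100))
  }
  assign <- .canonical_labels(stats::setNames(km$cluster, rownames(x)))
  # rebuild centroids in canonical label order
  cent <- t(vapply(seq_len(k), function(j) {
    colMeans(x[assign == j, , drop = FALSE])
  }, numeric(ncol(x))))
  if (ncol(x) == 1L) cent <- matrix(cent, ncol = 1)
  structure(list(
    k = k, assignments = assign, centroids = cent,
    within_ss = sum(km$withinss), between_ss = km$betweenss,
    total_ss = km$totss, sizes = as.integer(table(assign)),
    seed = seed, n_restarts = n_restarts
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means (Hartigan-Wong): k = %d, within SS %.4g, between/total %.3f\n",
              x$k, x$within_ss,
              if (x$total_ss > 0) x$between_ss / x$total_ss else 0))
  print(split(names(x$assignments), x$assignments))
  invisible(x)
}

#' Choose the number of clusters
#'
#' Scans `k_range` and picks the smallest k whose between-cluster share
#' of total sum-of-squares first reaches `threshold` (default 0.85) —
#' i.e. maximal between-group and minimal within-group variation at the
#' most parsimonious k. If no k reaches the threshold, falls back to the
#' elbow of the within-SS curve (maximum negative curvature).
#'
#' @param x Matrix or vector as for [kmeans_hw()].
#' @param k_range Candidate cluster counts.
#' @param seed,n_restarts Passed to [kmeans_hw()].
#' @param threshold Between/total SS ratio required.
#' @return Integer k, with the scan as attribute `"scan"` (data.frame
#'   `k`, `within_ss`, `between_ratio`).
#' @export
select_k <- function(x, k_range = 1:6, seed = 1L, n_restarts = 25L,
                     threshold = 0.85) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), NULL))
  k_range <- k_range[k_range >= 1 & k_range <= nrow(x)]
  if (!length(k_range)) stop("empty k_range", call. = FALSE)
  tss <- sum(sweep(x, 2, colMeans(x))^2)
  if (tss == 0) {
    # all rows identical: any split is arbitrary, report the degenerate k
    return(structure(min(k_range),
                     scan = data.frame(k = min(k_range), within_ss = 0,
                                       between_ratio = 1),
                     degenerate = TRUE))
  }
  scan <- do.call(rbind, lapply(k_range, function(k) {
    r <- kmeans_hw(x, k, seed = seed, n_restarts = n_restarts)
    data.frame(k = k, within_ss = r$within_ss,
               between_ratio = if (r$total_ss > 0) r$between_ss / r$total_ss else 1)
  }))
  hit <- scan$k[scan$between_ratio >= threshold]
  if (length(hit)) {
    k <- min(hit)
  } else if (nrow(scan) >= 3) {
    curv <- diff(scan$within_ss, differences = 2)  # aligned with interior ks
    k <- scan$k[which.max(curv) + 1L]
  } else {
    k <- scan$k[which.min(scan$within_ss)]
  }
  structure(as.integer(k), scan = scan)
}

#' Decay models for each trajectory cluster
#'
#' Pools the member observations of each cluster and fits one
#' plateau-exponential model per cluster.
#'
#' @param observations Observation table for the clustered condition.
#' @param result A `cluster_result` whose assignment names are amino
#'   acid codes present in `observations`.
#' @param window Fit window, hours.
#' @return data.frame `cluster`, `members`, `k`, `se_k`, `c`, `se_c`,
#'   `n_obs`, `converged`; fits attached as attribute `"fits"`. Empty
#'   clusters are skipped and listed in attribute `"skipped"`.
#' @export
fit_cluster_models <- function(observations, result, window = c(0, 16)) {
  rows <- list(); fits <- list(); skipped <- integer(0)
  for (j in sort(unique(result$assignments))) {
    members <- names(result$assignments)[result$assignments == j]
    d <- observations[observations$code %in% members, , drop = FALSE]
    if (!nrow(d)) { skipped <- c(skipped, j); next }
    fit <- m0_decay(m0_fraction ~ time_h, data = d, window = window)
    fits[[as.character(j)]] <- fit
    cf <- coef(fit)
    rows[[as.character(j)]] <- data.frame(
      cluster = j, members = paste(sort(members), collapse = ","),
      k = cf["k"], se_k = fit$se["k"], c = cf["c"], se_c = fit$se["c"],
      n_obs = fit$n_obs, converged = fit$converged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "skipped") <- skipped
  out
}

#' Cluster flux-dimension values
#'
#' One-dimensional k-means on turnover-adjusted pool sizes for one
#' condition. Default cluster counts follow the trajectory analysis:
#' 3 clusters, except 4 for the light-with-sucrose condition.
#'
#' @param flux_values Named numeric vector (names = amino-acid codes) of
#'   flux-dimension values for one condition.
#' @param k Number of clusters; `NULL` picks the condition default.
#' @param condition Condition label, used only for the default k.
#' @param seed,n_restarts Passed to [kmeans_hw()].
#' @return A `cluster_result`.
#' @export
cluster_flux <- function(flux_values, k = NULL, condition = "light_sucrose",
                         seed = 1L, n_restarts = 25L) {
  flux_values <- flux_values[!is.na(flux_values)]
  if (!length(flux_values)) stop("no flux values to cluster", call. = FALSE)
  if (is.null(k)) k <- if (condition == "light_sucrose") 4L else 3L
  k <- min(k, length(flux_values))
  kmeans_hw(flux_values, k, seed = seed, n_restarts = n_restarts)
}
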