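#' Fit-window rule for an amino acid x condition
#'
#' Labeling curves are fitted on the 0-16 h window by default; a few
#' slow-labeling series need longer windows to constrain the plateau:
#' 0-32 h for lysine in the dark, and 0-64 h for tryptophan without
#' sucrose in the light and for alanine, arginine, threonine and
#' tryptophan in the dark. Unknown pairs get the default; `overrides`
#' wins over everything.
#'
#' @param code One-letter amino-acid code (`"I/L"` for the joint
#'   leucine/isoleucine series).
#' @param condition One of [growth_conditions()].
#' @param overrides Optional data.frame with columns `code`,
#'   `condition`, `t_min`, `t_max`.
#' @return Numeric `c(t_min, t_max)` in hours.
#' @export
select_fit_window <- function(code, condition, overrides = NULL) {
  if (!is.null(overrides)) {
    hit <- overrides$code == code & overrides$condition == condition
    if (any(hit)) {
      i <- which(hit)[1]
      return(c(overrides$t_min[i], overrides$t_max[i]))
    }
  }
  if (condition == "dark_sucrose" && code == "K") return(c(0, 32))
  if (condition == "dark_sucrose" && code %in% c("A", "R", "T", "W")) return(c(0, 64))
  if (condition == "light_no_sucrose" && code == "W") return(c(0, 64))
  c(0, 16)
}

.m0_control <- function(maxiter = 1000, ftol = 1e-10) {
  minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol)
}

#' Fit the plateau-exponential labeling model
#'
#' Fits `M0(t) = (1 - c) * exp(-k * t) + c` to replicate M0-fraction
#' observations by bounded nonlinear least squares
#' (Levenberg-Marquardt with box constraints `k >= 0`, `0 <= c <= 1`).
#' All replicate observations inside the fit window are fitted jointly.
#'
#' Starting values: `c` starts at the mean M0 of the last in-window time
#' point, and `k` at the slope of a log-linear regression of
#' `M0 - c0` on time over the points above the provisional plateau — a
#' robust initialization for plateau-exponentials.
#'
#' @param x A formula such as `m0_fraction ~ time_h` (with `data`), or a
#'   numeric vector of times (with `m0` the matching fractions).
#' @param ... Passed on to methods.
#' @return Object of class `m0_decay`; see [coef.m0_decay()],
#'   [summary.m0_decay()], [predict.m0_decay()], [plot.m0_decay()].
#' @examples
#' t <- c(0, 1, 2, 4, 8, 16)
#' fit <- m0_decay(t, m0_curve(0.85, 0.13, t))
#' coef(fit)
#' @export
m0_decay <- function(x, ...) UseMethod("m0_decay")

#' @rdname m0_decay
#' @param data data.frame holding the formula variables.
#' @param window Fit window `c(t_min, t_max)` in hours; observations
#'   outside it are dropped before fitting.
#' @param start Optional named list `list(k=, c=)` of starting values.
#' @param maxiter,ftol Optimizer control: iteration cap and relative
#'   cost-reduction tolerance.
#' @export
m0_decay.formula <- function(x, data, window = c(0, 16), start = NULL,
                             maxiter = 1000, ftol = 1e-10, ...) {
  mf <- stats::model.frame(x, data)
  fit <- m0_decay.default(mf[[2L]], mf[[1L]], window = window, start = start,
                          maxiter = maxiter, ftol = ftol, ...)
  fit$call <- match.call()
  fit
}

#' @rdname m0_decay
#' @param m0 M0 fractions matching the time vector.
#' @export
m0_decay.default <- function(x, m0, window = c(0, 16), start = NULL,
                             maxiter = 1000, ftol = 1e-10, ...) {
  t_all <- as.numeric(x); y_all <- as.numeric(m0)
  if (length(t_all) != length(y_all)) stop("time and m0 lengths differ", call. = FALSE)
  ok <- !is.na(t_all) & !is.na(y_all)
  t_all <- t_all[ok]; y_all <- y_all[ok]
  if (any(t_all < 0)) stop("negative labeling times", call. = FALSE)
  if (any(y_all < 0 | y_all > 1)) stop("m0 fractions must be in [0, 1]", call. = FALSE)
  inw <- t_all >= window[1] & t_all <= window[2]
  tt <- t_all[inw]; yy <- y_all[inw]
  if (length(unique(tt)) < 3L) {
    stop("need at least 3 distinct time points inside the fit window",
         call. = FALSE)
  }

  if (is.null(start)) {
    c0 <- mean(yy[tt == max(tt)])
    c0 <- min(max(c0, 0), 1 - 1e-6)
    above <- yy > c0 + 1e-8
    k0 <- NA_real_
    if (sum(above) >= 2L && length(unique(tt[above])) >= 2L) {
      sl <- stats::coef(stats::lm(log(yy[above] - c0) ~ tt[above]))[2]
      if (is.finite(sl) && sl < 0) k0 <- -sl
    }
    if (!is.finite(k0) || k0 <= 0) k0 <- 0.1
    start <- list(k = as.numeric(k0), c = as.numeric(c0))
  }

  dat <- data.frame(tt = tt, yy = yy)
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ (1 - c) * exp(-k * tt) + c, data = dat,
                      start = start, lower = c(k = 0, c = 0),
                      upper = c(k = Inf, c = 1),
                      control = .m0_control(maxiter, ftol)),
    error = function(e) e)

  out <- list(window = window, n_obs = length(yy),
              data = data.frame(time_h = tt, m0_fraction = yy),
              start = start, call = match.call())
  if (inherits(nls_fit, "error")) {
    out$coefficients <- c(k = NA_real_, c = NA_real_)
    out$se <- c(k = NA_real_, c = NA_real_)
    out$vcov <- matrix(NA_real_, 2, 2, dimnames = list(c("k", "c"), c("k", "c")))
    out$rss <- NA_real_; out$sigma <- NA_real_
    out$converged <- FALSE
    out$message <- conditionMessage(nls_fit)
  } else {
    cf <- stats::coef(nls_fit)
    out$coefficients <- c(k = unname(cf["k"]), c = unname(cf["c"]))
    vc <- tryCatch(stats::vcov(nls_fit), error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(diag(vc)))) {
      out$vcov <- matrix(NA_real_, 2, 2, dimnames = list(c("k", "c"), c("k", "c")))
      out$se <- c(k = NA_real_, c = NA_real_)
    } else {
      out$vcov <- vc
      out$se <- sqrt(diag(vc))[c("k", "c")]
    }
    out$rss <- sum(stats::residuals(nls_fit)^2)
    df_res <- max(length(yy) - 2L, 1L)
    out$sigma <- sqrt(out$rss / df_res)
    out$converged <- isTRUE(nls_fit$convInfo$isConv)
    out$nls <- nls_fit
  }
  class(out) <- "m0_decay"
  out
}

#' @export
coef.m0_decay <- function(object, ...) object$coefficients

#' @export
vcov.m0_decay <- function(object, ...) object$vcov

#' @export
fitted.m0_decay <- function(object, ...) {
  predict(object, object$data$time_h)
}

#' @export
residuals.m0_decay <- function(object, ...) {
  object$data$m0_fraction - fitted(object)
}

#' Predict M0 fractions from a fitted decay model
#'
#' @param object An `m0_decay` fit.
#' @param newdata Times in hours (numeric vector), or a data.frame with
#'   a `time_h` column; defaults to the fitted times.
#' @param ... Unused.
#' @export
predict.m0_decay <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$time_h
  t <- if (is.data.frame(newdata)) newdata$time_h else as.numeric(newdata)
  cf <- object$coefficients
  m0_curve(cf["k"], cf["c"], t)
}

#' Simulate replicate observations from a fitted decay model
#'
#' Draws `nsim` sets of observations at the fitted time points, adding
#' Gaussian noise with the fit's residual standard deviation (or `sd`),
#' clipped to `[0, 1]`.
#'
#' @param object An `m0_decay` fit.
#' @param nsim Number of simulated replicate sets.
#' @param seed Optional RNG seed.
#' @param sd Noise standard deviation; defaults to the residual sigma.
#' @param ... Unused.
#' @export
simulate.m0_decay <- function(object, nsim = 1, seed = NULL, sd = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  if (is.null(sd)) sd <- object$sigma
  mu <- fitted(object)
  out <- as.data.frame(replicate(nsim, pmin(1, pmax(0, mu + stats::rnorm(length(mu), 0, sd)))))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(time_h = object$data$time_h), out)
}

#' @export
print.m0_decay <- function(x, digits = 4, ...) {
  cat("Plateau-exponential labeling fit: M0(t) = (1 - c) exp(-k t) + c\n")
  cat(sprintf("  window: %g-%g h, n = %d%s\n", x$window[1], x$window[2],
              x$n_obs, if (x$converged) "" else "  [NOT CONVERGED]"))
  cf <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(cf, digits))
  invisible(x)
}

#' Summary of a plateau-exponential fit
#'
#' @param object An `m0_decay` fit.
#' @param ... Unused.
#' @return Object of class `summary.m0_decay` with the coefficient
#'   table, residual sigma, RSS and convergence flag.
#' @export
summary.m0_decay <- function(object, ...) {
  cf <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
              `t value` = object$coefficients / object$se)
  structure(list(coefficients = cf, sigma = object$sigma, rss = object$rss,
                 n_obs = object$n_obs, window = object$window,
                 converged = object$converged, call = object$call),
            class = "summary.m0_decay")
}

#' @export
print.summary.m0_decay <- function(x, digits = 4, ...) {
  cat("Plateau-exponential labeling fit\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("Window %g-%g h; n = %d; converged: %s\n",
              x$window[1], x$window[2], x$n_obs, x$converged))
  print(round(x$coefficients, digits))
  cat(sprintf("Residual sigma %.4g on %d observations (RSS %.4g)\n",
              x$sigma, x$n_obs, x$rss))
  invisible(x)
}

#' Plot a fitted labeling curve over its observations
#'
#' @param x An `m0_decay` fit.
#' @param npoints Curve resolution.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.m0_decay <- function(x, npoints = 200, ...) {
  d <- x$data
  graphics::plot(d$time_h, d$m0_fraction, xlab = "labeling time (h)",
                 ylab = "M0 fraction", ylim = c(0, 1), ...)
  tg <- seq(min(d$time_h), max(d$time_h), length.out = npoints)
  graphics::lines(tg, predict(x, tg))
  cf <- x$coefficients
  graphics::abline(h = cf["c"], lty = 3)
  invisible(x)
}

#' Fit labeling models for every amino acid x condition
#'
#' Applies [m0_decay()] to each amino acid x condition group of an
#' observation table, using [select_fit_window()] per group and skipping
#' pairs excluded in the definition table (with the reason recorded).
#' The joint leucine/isoleucine series is a single `"I/L"` code.
#'
#' @param observations data.frame with columns `code`, `condition`,
#'   `time_h`, `m0_fraction` (e.g. from [extract_envelopes()] or
#'   [simulate_dataset()]); rows flagged other than `"ok"` in a
#'   `qc_flag` column are dropped.
#' @param specs Amino-acid definition table (for exclusions).
#' @param windows Optional window overrides; see [select_fit_window()].
#' @return data.frame, one row per pair: `code`, `condition`, `k`,
#'   `se_k`, `c`, `se_c`, `n_obs`, `rss`, `t_min`, `t_max`, `converged`,
#'   `excluded`, `reason`. The `m0_decay` objects are attached as
#'   attribute `"fits"` (named `code|condition`).
#' @export
fit_all <- function(observations, specs = amino_acid_specs(), windows = NULL) {
  if ("qc_flag" %in% names(observations)) {
    observations <- observations[observations$qc_flag == "ok", , drop = FALSE]
  }
  groups <- unique(observations[, c("code", "condition")])
  excl <- strsplit(specs$excluded_conditions, ",[ ]*")
  names(excl) <- specs$code
  rows <- list(); fits <- list()
  for (i in seq_len(nrow(groups))) {
    code <- groups$code[i]; cond <- groups$condition[i]
    key <- paste(code, cond, sep = "|")
    if (code %in% names(excl) && cond %in% excl[[code]]) {
      rows[[key]] <- data.frame(
        code = code, condition = cond, k = NA_real_, se_k = NA_real_,
        c = NA_real_, se_c = NA_real_, n_obs = 0L, rss = NA_real_,
        t_min = NA_real_, t_max = NA_real_, converged = NA,
        excluded = TRUE, reason = "excluded: low data quality in this condition",
        stringsAsFactors = FALSE)
      next
    }
    d <- observations[observations$code == code & observations$condition == cond, ]
    win <- select_fit_window(code, cond, windows)
    fit <- tryCatch(
      m0_decay(m0_fraction ~ time_h, data = d, window = win),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[key]] <- data.frame(
        code = code, condition = cond, k = NA_real_, se_k = NA_real_,
        c = NA_real_, se_c = NA_real_, n_obs = nrow(d), rss = NA_real_,
        t_min = win[1], t_max = win[2], converged = FALSE,
        excluded = FALSE, reason = conditionMessage(fit),
        stringsAsFactors = FALSE)
      next
    }
    fits[[key]] <- fit
    cf <- coef(fit)
    rows[[key]] <- data.frame(
      code = code, condition = cond, k = cf["k"], se_k = fit$se["k"],
      c = cf["c"], se_c = fit$se["c"], n_obs = fit$n_obs, rss = fit$rss,
      t_min = win[1], t_max = win[2], converged = fit$converged,
      excluded = FALSE, reason = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
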