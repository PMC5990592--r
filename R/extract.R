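#' Read MS1 spectra from an mzML file
#'
#' Thin wrapper around mzR. Only MS1 spectra are kept and they are
#' returned ordered by retention time.
#'
#' @param path Path to an mzML file.
#' @return List of class `ms_run` with `rt_min` (numeric, minutes) and
#'   `peaks` (list of two-column matrices `mz`, `intensity`).
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("failed to parse '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  if (!nrow(hdr)) {
    return(structure(list(rt_min = numeric(0), peaks = list(), path = path),
                     class = "ms_run"))
  }
  keep <- which(hdr$msLevel == 1L)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  pk <- pk[keep]
  rt <- hdr$retentionTime[keep] / 60
  o <- order(rt)
  structure(list(rt_min = rt[o], peaks = pk[o], path = path), class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  cat("MS1 run:", length(x$rt_min), "spectra")
  if (length(x$rt_min)) {
    cat(sprintf(", rt %.2f-%.2f min", min(x$rt_min), max(x$rt_min)))
  }
  cat("\n")
  invisible(x)
}

#' Extract an ion chromatogram
#'
#' Sums, for each spectrum whose retention time falls in `rt_window`, the
#' intensity of all ions within `ppm_tol` parts-per-million of
#' `target_mz`. Spectra with no matching ions contribute zero. The
#' default 10 ppm tolerance keeps the 15N series separate from 13C
#' isotopologues (spacing difference 0.0063 Da, i.e. 42 ppm at m/z 150)
#' for all amino-acid masses.
#'
#' @param run An `ms_run` from [read_mzml()].
#' @param target_mz Target m/z.
#' @param ppm_tol Tolerance in ppm, `> 0`.
#' @param rt_window Length-2 numeric, retention window in minutes.
#' @return data.frame with columns `rt_min`, `intensity`.
#' @export
extract_eic <- function(run, target_mz, ppm_tol = 10, rt_window) {
  stopifnot(ppm_tol > 0)
  if (missing(rt_window) || length(rt_window) != 2L || rt_window[1] >= rt_window[2]) {
    stop("rt_window must be c(start, end) with start < end", call. = FALSE)
  }
  tol <- target_mz * ppm_tol * 1e-6
  idx <- which(run$rt_min >= rt_window[1] & run$rt_min <= rt_window[2])
  inten <- vapply(idx, function(i) {
    p <- run$peaks[[i]]
    if (!nrow(p)) return(0)
    hit <- abs(p[, 1] - target_mz) <= tol
    sum(p[hit, 2])
  }, numeric(1))
  data.frame(rt_min = run$rt_min[idx], intensity = inten)
}

#' Integrate an ion chromatogram
#'
#' Trapezoidal integration of intensity over retention time (minutes)
#' across the whole chromatogram, less an optional constant baseline.
#' Chromatograms with fewer than two points integrate to zero and are
#' flagged.
#'
#' @param eic data.frame from [extract_eic()].
#' @param baseline Constant baseline intensity to subtract.
#' @return Numeric area (intensity x minutes) with attribute `qc`
#'   (`"ok"` or `"too_few_points"`).
#' @export
integrate_eic <- function(eic, baseline = 0) {
  y <- pmax(eic$intensity - baseline, 0)
  x <- eic$rt_min
  if (length(x) < 2L) {
    return(structure(0, qc = "too_few_points"))
  }
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(area, qc = "ok")
}

#' Normalize an isotopologue envelope to fractions
#'
#' @param areas Non-negative areas for M0..Mn.
#' @return Fractions summing to 1, or all-`NA` with attribute
#'   `qc = "empty_envelope"` when the total is zero.
#' @export
envelope_fractions <- function(areas) {
  stopifnot(length(areas) >= 1L, all(areas >= 0 | is.na(areas)))
  tot <- sum(areas)
  if (!isTRUE(tot > 0)) {
    return(structure(rep(NA_real_, length(areas)), qc = "empty_envelope"))
  }
  areas / tot
}

#' Summarise long-format envelopes into per-sample observations
#'
#' Collapses a long isotopologue table (one row per sample x amino acid x
#' isotopologue) to one row per sample x amino acid with the M0 fraction
#' of the total envelope.
#'
#' @param envelopes data.frame with columns `sample_id`, `code`,
#'   `condition`, `time_h`, `replicate`, `n_label`, `area`.
#' @param min_total_area QC floor: envelopes whose summed area falls
#'   below it are flagged `"low_signal"`.
#' @return data.frame with one row per sample x code: `m0_fraction`,
#'   `total_area`, `qc_flag`.
#' @export
envelope_observations <- function(envelopes, min_total_area = 0) {
  key <- interaction(envelopes$sample_id, envelopes$code, drop = TRUE)
  rows <- lapply(split(envelopes, key), function(d) {
    d <- d[order(d$n_label), ]
    tot <- sum(d$area)
    fr <- envelope_fractions(d$area)
    qc <- attr(fr, "qc")
    if (is.null(qc)) qc <- if (tot < min_total_area) "low_signal" else "ok"
    data.frame(sample_id = d$sample_id[1], code = d$code[1],
               condition = d$condition[1], time_h = d$time_h[1],
               replicate = d$replicate[1], m0_fraction = fr[1],
               total_area = tot, qc_flag = qc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition, out$code, out$time_h, out$replicate), ]
}

#' Extract isotopologue envelopes from mzML files
#'
#' The full extraction stage: for each sample file and each amino acid,
#' extract one EIC per 15N isotopologue in the retention window,
#' integrate, and compute the M0 fraction of the envelope. Missing
#' isotopologues integrate to zero area (absence of signal is
#' informative for fractions).
#'
#' @param files data.frame with columns `sample_id`, `path`, plus sample
#'   metadata columns `condition`, `time_h`, `replicate` (or a metadata
#'   data.frame given separately via `metadata`).
#' @param specs Amino-acid definition table.
#' @param metadata Optional data.frame keyed by `sample_id` supplying
#'   `condition`, `time_h`, `replicate`.
#' @param ppm_tol m/z tolerance, ppm.
#' @param rt_pad_min Widening applied to each retention window, minutes.
#' @param min_total_area QC floor for [envelope_observations()].
#' @param adduct Adduct for the m/z series.
#' @return List with `envelopes` (long areas) and `observations`
#'   (per sample x code M0 fractions).
#' @export
extract_envelopes <- function(files, specs, metadata = NULL, ppm_tol = 10,
                              rt_pad_min = 0, min_total_area = 0,
                              adduct = "[M+H]+") {
  if (!is.null(metadata)) {
    files <- merge(files, metadata, by = "sample_id", sort = FALSE)
  }
  need <- c("sample_id", "path", "condition", "time_h", "replicate")
  miss <- setdiff(need, names(files))
  if (length(miss)) {
    stop("missing sample metadata column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  series <- lapply(seq_len(nrow(specs)), function(i) {
    isotopomer_mz_series(specs[i, ], adduct)
  })
  env <- list()
  for (i in seq_len(nrow(files))) {
    run <- read_mzml(files$path[i])
    for (j in seq_len(nrow(specs))) {
      sp <- specs[j, ]
      win <- c(sp$rt_start_min - rt_pad_min, sp$rt_end_min + rt_pad_min)
      areas <- vapply(series[[j]]$mz, function(mz) {
        as.numeric(integrate_eic(extract_eic(run, mz, ppm_tol, win)))
      }, numeric(1))
      env[[paste(files$sample_id[i], sp$code)]] <- data.frame(
        sample_id = files$sample_id[i], code = sp$code,
        condition = files$condition[i], time_h = files$time_h[i],
        replicate = files$replicate[i], n_label = series[[j]]$n_label,
        area = areas, stringsAsFactors = FALSE)
    }
  }
  envelopes <- do.call(rbind, env)
  rownames(envelopes) <- NULL
  list(envelopes = envelopes,
       observations = envelope_observations(envelopes, min_total_area))
}
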