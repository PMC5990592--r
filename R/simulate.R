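#' Plateau-exponential decay of the unlabeled fraction
#'
#' The labeling model: during continuous 15N feeding the unlabeled (M0)
#' fraction of an amino-acid pool decays as
#' `M0(t) = (1 - c) * exp(-k * t) + c`, where `k` (per hour) is the
#' first-order turnover constant and `c` is the plateau — the fraction of
#' the pool that never exchanges label (interpreted as metabolically
#' inactive).
#'
#' @param k Turnover constant, per hour, `>= 0`.
#' @param c Plateau fraction in `[0, 1]`.
#' @param times Labeling times in hours, `>= 0`.
#' @return M0 fractions, same length as `times`, in `[c, 1]`.
#' @examples
#' m0_curve(0.85, 0.13, c(0, 1, 2, 4, 8, 16))
#' @export
m0_curve <- function(k, c, times) {
  stopifnot(length(k) == 1L, length(c) == 1L, k >= 0, c >= 0, c <= 1)
  if (any(times < 0)) stop("labeling times must be non-negative", call. = FALSE)
  (1 - c) * exp(-k * times) + c
}

#' Per-atom 15N enrichment implied by an M0 fraction
#'
#' Under uniform independent labeling of a molecule's `n` nitrogens with
#' per-atom enrichment `p`, the unlabeled fraction is `(1 - p)^n`.
#' Inverting gives `p = 1 - m0^(1/n)`.
#'
#' @param m0 M0 fraction, in `(0, 1]`.
#' @param n_nitrogen Number of nitrogen atoms, `>= 1`.
#' @return Per-atom enrichment `p` in `[0, 1)`.
#' @export
enrichment_from_m0 <- function(m0, n_nitrogen) {
  if (any(m0 <= 0)) stop("m0 must be positive", call. = FALSE)
  if (any(m0 > 1)) stop("m0 must be at most 1", call. = FALSE)
  stopifnot(n_nitrogen >= 1)
  1 - m0^(1 / n_nitrogen)
}

#' Simulate one isotopologue envelope
#'
#' Expected isotopologue fractions are binomial: the species with `i`
#' heavy nitrogens has probability `dbinom(i, n_nitrogen, p)`. The
#' envelope is scaled to `total_intensity` and perturbed by multiplicative
#' Gaussian noise of coefficient of variation `intensity_cv`, truncated so
#' areas stay non-negative. Uses the current RNG state.
#'
#' `p` may be a vector of length `n_nitrogen` to give each nitrogen site
#' its own enrichment (e.g. the amide vs. amino nitrogen of glutamine);
#' the envelope is then the distribution of a sum of independent
#' non-identical Bernoulli draws (Poisson-binomial), computed by direct
#' convolution.
#'
#' @param p Per-atom enrichment(s) in `[0, 1]`; length 1 or `n_nitrogen`.
#' @param n_nitrogen Number of nitrogen atoms.
#' @param total_intensity Total envelope area before noise.
#' @param intensity_cv Multiplicative noise CV; 0 for noiseless.
#' @return Numeric vector of areas, length `n_nitrogen + 1` (M0..Mn).
#' @export
simulate_envelope <- function(p, n_nitrogen, total_intensity = 1e6,
                              intensity_cv = 0) {
  stopifnot(all(p >= 0), all(p <= 1), n_nitrogen >= 1)
  if (length(p) == 1L) {
    frac <- stats::dbinom(0:n_nitrogen, n_nitrogen, p)
  } else if (length(p) == n_nitrogen) {
    frac <- 1
    for (pi in p) frac <- c(frac * (1 - pi), 0) + c(0, frac * pi)
  } else {
    stop("p must have length 1 or n_nitrogen", call. = FALSE)
  }
  areas <- frac * total_intensity
  if (intensity_cv > 0) {
    areas <- areas * pmax(0, 1 + stats::rnorm(length(areas), 0, intensity_cv))
  }
  areas
}

#' Simulation configuration
#'
#' Bundles the generator's study conditions. Defaults reproduce the
#' duckweed labeling experiment: the 17-species amino-acid table, the
#' published per-condition `(k, c)` truth, the per-condition sampling
#' grids (0-128 h, with 15- and 30-min samples added outside
#' light+sucrose), 5 biological replicates, additive Gaussian noise of
#' sd 0.02 on the M0 fraction, 10% multiplicative area noise, and a
#' 0.02 mM fully labeled internal standard spiked into residue
#' reconstituted at 2 mg/mL.
#'
#' @param params data.frame with columns `code`, `condition`, `k`, `c`
#'   giving the true kinetics; defaults to [reference_kinetics()].
#' @param specs Amino-acid definition table; see [amino_acid_specs()].
#' @param conditions Conditions to simulate.
#' @param times Named list of time grids (hours) per condition, or NULL
#'   for [condition_time_grid()].
#' @param n_replicates Integer, or named vector per condition.
#' @param noise_sd Additive Gaussian sd on the M0 fraction (clipped to
#'   `[0, 1]`).
#' @param intensity_cv Multiplicative CV on isotopologue areas.
#' @param total_intensity Area of the internal-standard peak; analyte
#'   envelope areas scale relative to it via the pool sizes.
#' @param pool_umol_per_mg True pool sizes, umol per mg extract residue;
#'   scalar or named by `code`.
#' @param standard_conc_mM Internal-standard concentration in the
#'   reconstituted sample, mM.
#' @param residue_mass_mg Dry residue mass per sample, mg.
#' @param reconstitution_mg_per_ml Residue reconstitution density, mg
#'   extract per mL (volume = mass / density).
#' @param seed Default RNG seed for [simulate_dataset()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(params = reference_kinetics(),
                       specs = amino_acid_specs(),
                       conditions = growth_conditions(),
                       times = NULL,
                       n_replicates = 5L,
                       noise_sd = 0.02,
                       intensity_cv = 0.1,
                       total_intensity = 1e6,
                       pool_umol_per_mg = 0.004,
                       standard_conc_mM = 0.02,
                       residue_mass_mg = 1,
                       reconstitution_mg_per_ml = 2,
                       seed = 1L) {
  stopifnot(all(params$k >= 0), all(params$c >= 0), all(params$c <= 1),
            all(n_replicates >= 1), noise_sd >= 0, intensity_cv >= 0,
            standard_conc_mM > 0, residue_mass_mg > 0)
  if (is.null(times)) {
    times <- stats::setNames(lapply(conditions, condition_time_grid), conditions)
  }
  if (any(unlist(times) < 0)) stop("times must be non-negative", call. = FALSE)
  structure(list(
    params = params, specs = specs, conditions = conditions, times = times,
    n_replicates = n_replicates, noise_sd = noise_sd,
    intensity_cv = intensity_cv, total_intensity = total_intensity,
    pool_umol_per_mg = pool_umol_per_mg, standard_conc_mM = standard_conc_mM,
    residue_mass_mg = residue_mass_mg,
    reconstitution_mg_per_ml = reconstitution_mg_per_ml, seed = seed
  ), class = "sim_config")
}

.replicates_for <- function(config, condition) {
  n <- config$n_replicates
  if (!is.null(names(n)) && condition %in% names(n)) n[[condition]] else n[[1]]
}

.pool_for <- function(config, code) {
  p <- config$pool_umol_per_mg
  if (!is.null(names(p)) && code %in% names(p)) p[[code]] else p[[1]]
}

#' Simulate a full labeling dataset
#'
#' For every amino acid x condition pair present in `config$params`,
#' every replicate and every time point, draws an isotopologue envelope
#' whose noiseless M0 fraction follows [m0_curve()], plus an
#' internal-standard area per sample consistent with the configured pool
#' sizes under the pool-size estimator's model. Deterministic for a fixed
#' seed.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return List of class `isokin_sim` with elements
#'   \describe{
#'     \item{metadata}{one row per sample: `sample_id`, `condition`,
#'       `time_h`, `replicate`, `residue_mass_mg`, `standard_conc_mM`,
#'       `reconstitution_volume_ml`.}
#'     \item{envelopes}{long table: `sample_id`, `code`, `condition`,
#'       `time_h`, `replicate`, `n_label`, `area`.}
#'     \item{observations}{per sample x code: `m0_fraction`,
#'       `total_area`, `qc_flag`.}
#'     \item{standards}{per sample x code internal-standard areas.}
#'     \item{truth}{the `(k, c, pool)` truth used.}
#'     \item{config, seed}{inputs, for the manifest.}
#'   }
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  specs <- config$specs
  recon_vol <- config$residue_mass_mg / config$reconstitution_mg_per_ml
  std_amount <- config$standard_conc_mM * recon_vol            # umol
  response <- config$total_intensity / std_amount              # area per umol

  meta <- list(); env <- list(); std <- list(); truth <- list()
  for (cond in config$conditions) {
    pars <- config$params[config$params$condition == cond, , drop = FALSE]
    pars <- pars[pars$code %in% specs$code, , drop = FALSE]
    if (!nrow(pars)) next
    tgrid <- config$times[[cond]]
    nrep <- .replicates_for(config, cond)
    for (rep_i in seq_len(nrep)) {
      for (t in tgrid) {
        sid <- sprintf("%s_r%d_t%g", cond, rep_i, t)
        meta[[sid]] <- data.frame(
          sample_id = sid, condition = cond, time_h = t, replicate = rep_i,
          residue_mass_mg = config$residue_mass_mg,
          standard_conc_mM = config$standard_conc_mM,
          reconstitution_volume_ml = recon_vol, stringsAsFactors = FALSE)
        for (j in seq_len(nrow(pars))) {
          code <- pars$code[j]
          nN <- specs$n_nitrogen[specs$code == code]
          pool <- .pool_for(config, code)
          m0 <- m0_curve(pars$k[j], pars$c[j], t)
          if (config$noise_sd > 0) {
            m0 <- min(1, max(0, m0 + stats::rnorm(1, 0, config$noise_sd)))
          }
          p <- enrichment_from_m0(max(m0, 1e-12), nN)
          total <- pool * config$residue_mass_mg * response
          areas <- simulate_envelope(p, nN, total, config$intensity_cv)
          env[[paste(sid, code)]] <- data.frame(
            sample_id = sid, code = code, condition = cond, time_h = t,
            replicate = rep_i, n_label = 0:nN, area = areas,
            stringsAsFactors = FALSE)
          std_area <- config$total_intensity
          if (config$intensity_cv > 0) {
            std_area <- std_area * max(0, 1 + stats::rnorm(1, 0, config$intensity_cv))
          }
          std[[paste(sid, code)]] <- data.frame(
            sample_id = sid, code = code, condition = cond, time_h = t,
            replicate = rep_i, standard_area = std_area,
            stringsAsFactors = FALSE)
        }
      }
    }
    tr <- pars[, c("code", "condition", "k", "c")]
    tr$pool_umol_per_mg <- vapply(tr$code, function(cd) .pool_for(config, cd), numeric(1))
    truth[[cond]] <- tr
  }
  envelopes <- do.call(rbind, env); rownames(envelopes) <- NULL
  obs <- envelope_observations(envelopes)
  out <- list(
    metadata = do.call(rbind, meta), envelopes = envelopes,
    observations = obs, standards = do.call(rbind, std),
    truth = do.call(rbind, truth), config = config, seed = seed)
  rownames(out$metadata) <- rownames(out$standards) <- rownames(out$truth) <- NULL
  class(out) <- "isokin_sim"
  out
}

#' @export
print.isokin_sim <- function(x, ...) {
  cat("Simulated 15N labeling dataset\n")
  cat("  conditions:", paste(unique(x$metadata$condition), collapse = ", "), "\n")
  cat("  samples:", nrow(x$metadata),
      " envelopes:", nrow(x$observations),
      " amino acids:", length(unique(x$envelopes$code)), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Write a simulated sample as an mzML file
#'
#' Renders one sample's isotopologue envelope areas as centroided MS1
#' spectra: each isotopologue becomes a Gaussian chromatographic peak at
#' its m/z, centred in the amino acid's retention-time window, with total
#' area (intensity integrated over minutes) equal to the input area.
#' Extracting and integrating these peaks with [extract_eic()] /
#' [integrate_eic()] recovers the areas.
#'
#' @param sample_envelopes data.frame with columns `code`, `n_label`,
#'   `area` for one sample.
#' @param specs Amino-acid definition table with retention windows.
#' @param path Output mzML path.
#' @param peak_sigma_min Chromatographic Gaussian sigma, minutes.
#' @param scan_interval_min Scan spacing, minutes.
#' @param adduct Adduct for the m/z series.
#' @return `path`, invisibly.
#' @export
write_mzml_fixture <- function(sample_envelopes, specs, path,
                               peak_sigma_min = 0.04,
                               scan_interval_min = 0.01,
                               adduct = "[M+H]+") {
  codes <- unique(sample_envelopes$code)
  specs <- specs[specs$code %in% codes, , drop = FALSE]
  if (!nrow(specs)) stop("no matching amino-acid specs", call. = FALSE)
  rt_lo <- min(specs$rt_start_min); rt_hi <- max(specs$rt_end_min)
  scans <- seq(rt_lo, rt_hi, by = scan_interval_min)

  # per-code stick lists: m/z series + per-isotopologue areas + RT centre
  sticks <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    ser <- isotopomer_mz_series(sp, adduct)
    ar <- sample_envelopes[sample_envelopes$code == sp$code, ]
    ar <- ar[order(ar$n_label), ]
    list(mz = ser$mz[ar$n_label + 1], area = ar$area,
         centre = (sp$rt_start_min + sp$rt_end_min) / 2,
         lo = sp$rt_start_min, hi = sp$rt_end_min)
  })

  peaks <- vector("list", length(scans))
  for (s in seq_along(scans)) {
    rt <- scans[s]
    mzv <- numeric(0); inten <- numeric(0)
    for (st in sticks) {
      if (rt < st$lo || rt > st$hi) next
      h <- st$area * stats::dnorm(rt, st$centre, peak_sigma_min)
      keep <- h > 0
      mzv <- c(mzv, st$mz[keep]); inten <- c(inten, h[keep])
    }
    o <- order(mzv)
    peaks[[s]] <- cbind(mz = mzv[o], intensity = inten[o])
  }
  nsc <- length(scans)
  npk <- vapply(peaks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(nsc), acquisitionNum = seq_len(nsc),
    msLevel = rep(1L, nsc), polarity = rep(1L, nsc), peaksCount = npk,
    totIonCurrent = vapply(peaks, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = scans * 60,
    basePeakMZ = vapply(peaks, function(p) if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(peaks, function(p) if (nrow(p)) max(p[, 2]) else 0, numeric(1)),
    collisionEnergy = rep(NA_real_, nsc), ionisationEnergy = rep(0, nsc),
    lowMZ = vapply(peaks, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(peaks, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = rep(NA_integer_, nsc), precursorMZ = rep(NA_real_, nsc),
    precursorCharge = rep(NA_integer_, nsc), precursorIntensity = rep(NA_real_, nsc),
    mergedScan = rep(NA_integer_, nsc), mergedResultScanNum = rep(NA_integer_, nsc),
    mergedResultStartScanNum = rep(NA_integer_, nsc),
    mergedResultEndScanNum = rep(NA_integer_, nsc),
    injectionTime = rep(0, nsc), filterString = rep(NA_character_, nsc),
    spectrumId = paste0("scan=", seq_len(nsc)), centroided = rep(TRUE, nsc),
    ionMobilityDriftTime = rep(NA_real_, nsc),
    isolationWindowTargetMZ = rep(NA_real_, nsc),
    isolationWindowLowerOffset = rep(NA_real_, nsc),
    isolationWindowUpperOffset = rep(NA_real_, nsc),
    scanWindowLowerLimit = rep(NA_real_, nsc),
    scanWindowUpperLimit = rep(NA_real_, nsc), stringsAsFactors = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  mzR::writeMSData(peaks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Write every sample of a simulated dataset as mzML
#'
#' @param sim An `isokin_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param ... Passed to [write_mzml_fixture()].
#' @return data.frame mapping `sample_id` to `path`.
#' @export
write_mzml_dataset <- function(sim, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- unique(sim$envelopes$sample_id)
  paths <- vapply(ids, function(sid) {
    p <- file.path(dir, paste0(sid, ".mzML"))
    write_mzml_fixture(sim$envelopes[sim$envelopes$sample_id == sid, ],
                       sim$config$specs, p, ...)
    p
  }, character(1))
  data.frame(sample_id = ids, path = unname(paths), stringsAsFactors = FALSE)
}
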