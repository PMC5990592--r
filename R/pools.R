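#' Pool size from the internal-standard ratio
#'
#' Pool sizes are estimated from time-zero samples relative to a fully
#' labeled internal standard spiked into the reconstituted dry residue
#' at known concentration, assuming equimolar detector response between
#' an amino acid and its labeled standard:
#' `pool = (analyte_area / standard_area) * standard_conc_mM *
#' reconstitution_volume_ml / residue_mass_mg`, in umol per mg sample
#' extract residue (mM x mL = umol).
#'
#' @param analyte_area_t0 Envelope area(s) of the analyte at time zero.
#' @param standard_area Matching internal-standard area(s), `> 0`.
#' @param standard_conc_mM Standard concentration, mM (default 0.02).
#' @param reconstitution_volume_ml Reconstitution volume, mL.
#' @param residue_mass_mg Dry residue mass, mg, `> 0`.
#' @return Pool size in umol/mg residue, averaged over the replicates
#'   supplied.
#' @export
estimate_pool_size <- function(analyte_area_t0, standard_area,
                               standard_conc_mM = 0.02,
                               reconstitution_volume_ml,
                               residue_mass_mg) {
  if (any(standard_area <= 0)) stop("standard area must be positive", call. = FALSE)
  stopifnot(all(residue_mass_mg > 0), all(analyte_area_t0 >= 0))
  per_rep <- (analyte_area_t0 / standard_area) *
    (standard_conc_mM * reconstitution_volume_ml) / residue_mass_mg
  mean(per_rep)
}

#' Active pool size
#'
#' The labeling plateau `c` is read as the metabolically inactive
#' proportion of a pool, so the active pool is the total pool scaled by
#' the labeled fraction: `p_active = p_initial * (1 - c)`.
#'
#' @param p_initial Total pool size, umol/mg.
#' @param c Plateau fraction in `[0, 1]`.
#' @return Active pool size, umol/mg.
#' @export
active_pool <- function(p_initial, c) {
  stopifnot(all(c >= 0 & c <= 1, na.rm = TRUE))
  p_initial * (1 - c)
}

#' Turnover-adjusted pool size (flux dimension)
#'
#' `flux = k * pool`, umol per mg residue per hour. Not a pathway flux:
#' it aggregates every reaction exchanging nitrogen through the pool,
#' but puts amino acids with very different pool sizes on a comparable
#' scale.
#'
#' @param k Turnover constant, per hour, `>= 0`.
#' @param pool Pool size, umol/mg, `>= 0`.
#' @return Flux-dimension value, umol/mg/h.
#' @export
flux <- function(k, pool) {
  stopifnot(all(k >= 0, na.rm = TRUE), all(pool >= 0, na.rm = TRUE))
  k * pool
}

#' Per-replicate pool estimates at time zero
#'
#' One pool estimate per time-zero replicate per amino acid x condition,
#' the raw material for pairwise condition comparisons.
#'
#' @param observations Per-sample observations (with `total_area`), e.g.
#'   from [simulate_dataset()] or [extract_envelopes()].
#' @param standards data.frame with `sample_id`, `code`,
#'   `standard_area`.
#' @param metadata Sample metadata with `sample_id`, `residue_mass_mg`,
#'   `standard_conc_mM`, `reconstitution_volume_ml`.
#' @return data.frame: `code`, `condition`, `replicate`, `p_initial`.
#' @export
pool_replicates <- function(observations, standards, metadata) {
  obs0 <- observations[observations$time_h == 0, , drop = FALSE]
  d <- merge(obs0, standards[, c("sample_id", "code", "standard_area")],
             by = c("sample_id", "code"))
  d <- merge(d, metadata[, c("sample_id", "residue_mass_mg",
                             "standard_conc_mM", "reconstitution_volume_ml")],
             by = "sample_id")
  d$p_initial <- (d$total_area / d$standard_area) *
    (d$standard_conc_mM * d$reconstitution_volume_ml) / d$residue_mass_mg
  out <- d[, c("code", "condition", "replicate", "p_initial")]
  out[order(out$condition, out$code, out$replicate), ]
}

#' Pool, active-pool and flux table
#'
#' Combines time-zero pool estimates with fitted kinetics into the full
#' pool summary: initial pool, active pool (`p_initial * (1 - c)`),
#' turnover-adjusted pool (`k * p_initial`) and its active counterpart
#' (`k * p_active`), all in umol/mg residue (per hour for the flux
#' columns).
#'
#' @param pool_reps Per-replicate pools from [pool_replicates()].
#' @param fits Fit table from [fit_all()].
#' @return data.frame: `code`, `condition`, `p_initial`, `p_active`,
#'   `flux`, `flux_active`, `k`, `c`, `n_replicates`.
#' @export
pool_table <- function(pool_reps, fits) {
  agg <- stats::aggregate(p_initial ~ code + condition, data = pool_reps, mean)
  n <- stats::aggregate(p_initial ~ code + condition, data = pool_reps, length)
  names(n)[3] <- "n_replicates"
  d <- merge(agg, n, by = c("code", "condition"))
  d <- merge(d, fits[, c("code", "condition", "k", "c", "excluded")],
             by = c("code", "condition"), all.x = TRUE)
  d$p_active <- active_pool(d$p_initial, ifelse(is.na(d$c), NA, d$c))
  d$flux <- flux(ifelse(is.na(d$k), NA, d$k), d$p_initial)
  d$flux_active <- flux(ifelse(is.na(d$k), NA, d$k), d$p_active)
  d <- d[, c("code", "condition", "p_initial", "p_active", "flux",
             "flux_active", "k", "c", "n_replicates")]
  d[order(d$condition, d$code), ]
}
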