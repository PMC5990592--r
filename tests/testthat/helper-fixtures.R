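# Shared fixtures, built in code at test time.

# Small noiseless simulation reused across tests (memoised per session).
.fixture_env <- new.env(parent = emptyenv())

noiseless_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(noise_sd = 0, intensity_cv = 0)
    .fixture_env$sim <- simulate_dataset(cfg, seed = 101)
  }
  .fixture_env$sim
}

# In-memory MS1 run: one stick spectrum per (rt, mz, intensity) row.
fake_run <- function(rt_min, sticks) {
  structure(list(
    rt_min = rt_min,
    peaks = lapply(sticks, function(s) {
      m <- matrix(s, ncol = 2)
      colnames(m) <- c("mz", "intensity")
      m
    }),
    path = "<in-memory>"), class = "ms_run")
}

# Exhaustive k-means oracle: minimum within-cluster SS over every
# surjective assignment of rows to k labels. Independent of kmeans_hw.
brute_force_within_ss <- function(x, k) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  grids <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (i in seq_len(nrow(grids))) {
    a <- as.integer(grids[i, ])
    if (length(unique(a)) != k) next
    ss <- 0
    for (j in seq_len(k)) {
      xs <- x[a == j, , drop = FALSE]
      ss <- ss + sum(sweep(xs, 2, colMeans(xs))^2)
    }
    if (ss < best) best <- ss
  }
  best
}

# Minimal empty-but-valid mzML document (zero spectra).
empty_mzml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="empty">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="http://psidev.info/ms"/></cvList>',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="0" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
    '<run id="r" defaultInstrumentConfigurationRef="ic">',
    '<spectrumList count="0" defaultDataProcessingRef="dp"></spectrumList>',
    '</run></mzML></indexedmzML>'), path)
  path
}
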