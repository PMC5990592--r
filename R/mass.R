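# Monoisotopic atomic masses (Da), IUPAC/CODATA values.  Only the elements
# found in proteinogenic amino acids are supported; 15N and the proton are
# needed for the isotopologue ladder and the protonated adduct.
.atomic_mass <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.mass_15N <- 15.0001088989
.mass_proton <- 1.007276466812

#' Mass difference between one 15N and one 14N atom
#'
#' The spacing, in Da, between consecutive members of a pure-15N
#' isotopologue series. Distinct from the 13C spacing (1.003355 Da), which
#' this package never generates: the tracer is nitrogen.
#'
#' @return Numeric scalar, approximately 0.997035 Da.
#' @export
delta_15N <- function() .mass_15N - .atomic_mass[["N"]]

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas over C, H, N, O, S such as `"C2H5NO2"`.
#' An element symbol without a count means one atom.
#'
#' @param formula Character scalar, or an already-parsed named numeric
#'   vector (returned unchanged after validation).
#' @return Named numeric vector of element counts.
#' @examples
#' parse_formula("C2H5NO2")  # glycine
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1L)
    if (!grepl("^([A-Z][a-z]?[0-9]*)*$", formula)) {
      stop("malformed formula: ", formula, call. = FALSE)
    }
    m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
    tokens <- regmatches(formula, list(m))[[1]]
    elems <- sub("[0-9]*$", "", tokens)
    n <- sub("^[A-Z][a-z]?", "", tokens)
    counts <- ifelse(n == "", 1, as.numeric(n))
    names(counts) <- elems
    # collapse repeated symbols (e.g. "CH3COOH" style inputs)
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  bad <- setdiff(names(counts), names(.atomic_mass))
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(names(.atomic_mass), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("negative element count", call. = FALSE)
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times monoisotopic atomic masses, all-14N species.
#'
#' @param formula Character formula (see [parse_formula()]) or named
#'   numeric vector of element counts.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C2H5NO2")  # 75.03203
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) return(0)
  sum(counts * .atomic_mass[names(counts)])
}

#' m/z series for the 15N isotopologues of an amino acid
#'
#' Entry `i + 1` is the m/z of the species carrying `i` heavy nitrogens,
#' for `i = 0 .. n_nitrogen`. Only nitrogen substitution is modelled; the
#' 13C ladder is deliberately not generated because the tracer is 15N.
#'
#' @param spec One row of an amino-acid definition table (see
#'   [amino_acid_specs()]), or anything with `$formula` and `$n_nitrogen`.
#' @param adduct Adduct to apply. Only the protonated molecular ion
#'   `"[M+H]+"` (the default, positive mode) and the neutral species
#'   `"M"` are built in.
#' @return A data.frame with columns `code`, `adduct`, `n_label`
#'   (0..n_nitrogen) and `mz`, strictly increasing in `mz` with constant
#'   spacing [delta_15N()].
#' @export
isotopomer_mz_series <- function(spec, adduct = "[M+H]+") {
  formula <- spec$formula
  n_nitrogen <- spec$n_nitrogen
  code <- if (!is.null(spec$code)) spec$code else NA_character_
  counts <- parse_formula(formula)
  n_formula <- if ("N" %in% names(counts)) counts[["N"]] else 0
  if (!is.null(n_nitrogen) && !is.na(n_nitrogen)) {
    if (n_nitrogen != n_formula) {
      stop("n_nitrogen (", n_nitrogen, ") does not match the formula N count (",
           n_formula, ")", call. = FALSE)
    }
  }
  if (n_formula < 1) stop("species has no nitrogen to label", call. = FALSE)
  base <- monoisotopic_mass(counts)
  shift <- switch(adduct,
    "[M+H]+" = .mass_proton,
    "M" = 0,
    stop("unknown adduct: ", adduct, call. = FALSE)
  )
  data.frame(
    code = code,
    adduct = adduct,
    n_label = 0:n_formula,
    mz = base + shift + (0:n_formula) * delta_15N(),
    stringsAsFactors = FALSE
  )
}

#' Built-in amino-acid definition table
#'
#' The 17 proteinogenic amino-acid species measured in the duckweed
#' labeling experiment, as free amino acids. Leucine and isoleucine are
#' structural isomers that co-elute on the cHILIC system and are quantified
#' as one species (code `"I/L"`). `excluded_conditions` records the
#' condition-specific data-quality omissions used by [fit_all()]:
#' histidine is excluded everywhere; valine, tyrosine and (for the dark
#' condition) glutamate lack usable reference series outside the
#' light-with-sucrose experiment.
#'
#' Retention-time windows are synthetic: plausible, non-overlapping HILIC
#' windows assigned for simulation fixtures, not measured values.
#'
#' @return data.frame with columns `name`, `code`, `formula`,
#'   `n_nitrogen`, `rt_start_min`, `rt_end_min`, `quantify_jointly_with`,
#'   `excluded_conditions` (comma-separated condition labels, `""` if
#'   none).
#' @export
amino_acid_specs <- function() {
  df <- read.csv(
    system.file("extdata", "amino_acids.csv", package = "isokin"),
    stringsAsFactors = FALSE
  )
  df$excluded_conditions[is.na(df$excluded_conditions)] <- ""
  df
}

#' Read an amino-acid definition table from CSV
#'
#' Expected columns: `name`, `code`, `formula`, `rt_start_min`,
#' `rt_end_min`; optional `quantify_jointly_with`, `excluded_conditions`.
#' The nitrogen count is derived from the formula and validated.
#'
#' @param path Path to a CSV file.
#' @return data.frame in the layout of [amino_acid_specs()].
#' @export
read_amino_acid_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "code", "formula", "rt_start_min", "rt_end_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("amino-acid table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$n_nitrogen <- vapply(df$formula, function(f) {
    counts <- parse_formula(f)
    if ("N" %in% names(counts)) counts[["N"]] else 0
  }, numeric(1))
  if (any(df$n_nitrogen < 1)) {
    stop("every species must contain at least one nitrogen", call. = FALSE)
  }
  if (any(df$rt_start_min >= df$rt_end_min) || any(df$rt_start_min < 0)) {
    stop("retention-time windows must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!"quantify_jointly_with" %in% names(df)) df$quantify_jointly_with <- NA_character_
  if (!"excluded_conditions" %in% names(df)) df$excluded_conditions <- ""
  df$excluded_conditions[is.na(df$excluded_conditions)] <- ""
  df
}
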