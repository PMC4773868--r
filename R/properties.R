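# Predicted-property interface. The original pipeline fed outputs of
# external predictors (folding rate, solubility, disorder, transmembrane
# topology, surface exposure, secondary structure) into the feature table.
# Those programs are replaced here by a pluggable suite of deterministic
# sequence-derived stand-ins; users with access to the original tools can
# substitute their outputs function-by-function.

PROPERTY_NAMES <- c("logPFR", "nlogPFR", "solubility", "unfoldability",
                    "disordered_count", "transmembrane", "exposed_fraction",
                    "contact_number", "helix_propensity", "sheet_propensity",
                    "coil_propensity")

scale_mean <- function(sequence, scale) {
  mean(scale[strsplit(sequence, "", fixed = TRUE)[[1L]]])
}

# Square-root-of-length folding-rate law: ln(kf) = 16.15 - 1.28 * sqrt(L).
folding_rate_ln_default <- function(sequence) {
  16.15 - 1.28 * sqrt(nchar(sequence))
}

# Count of disjoint hydrophobic segments: windows of 19 residues whose mean
# Kyte-Doolittle hydropathy is >= 1.6, merged when overlapping.
transmembrane_default <- function(sequence) {
  kd <- KD_HYDROPATHY[strsplit(sequence, "", fixed = TRUE)[[1L]]]
  w <- 19L
  n <- length(kd)
  if (n < w) return(0)
  cs <- cumsum(c(0, kd))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  hit <- means >= 1.6
  if (!any(hit)) return(0)
  runs <- rle(hit)
  sum(runs$values)
}

#' Default predicted-property suite
#'
#' A named list of deterministic `function(sequence_string) -> numeric`
#' contracts, one per registered property. The defaults are documented
#' sequence-derived stand-ins for external structure/kinetics predictors:
#' per-residue scale averages (Kyte-Doolittle hydropathy, TOP-IDP disorder,
#' Chou-Fasman secondary-structure propensities), a disorder-prone residue
#' count, a sliding-window hydrophobic-segment count for transmembrane
#' occurrence, and a square-root-of-length folding-rate law. The two folding
#' rate features satisfy `nlogPFR = logPFR * ln(10)` by construction. Any
#' entry may be replaced, e.g. with real predictor output, as long as it is
#' deterministic and returns a finite value.
#'
#' @return Named list of 11 property functions.
#' @export
default_property_suite <- function() {
  list(
    logPFR = function(s) folding_rate_ln_default(s) / log(10),
    nlogPFR = function(s) folding_rate_ln_default(s),
    # hydrophilic sequences score higher
    solubility = function(s) -scale_mean(s, KD_HYDROPATHY),
    unfoldability = function(s) scale_mean(s, TOP_IDP),
    disordered_count = function(s) {
      sum(strsplit(s, "", fixed = TRUE)[[1L]] %in% DISORDER_PRONE)
    },
    transmembrane = transmembrane_default,
    exposed_fraction = function(s) {
      mean(KD_HYDROPATHY[strsplit(s, "", fixed = TRUE)[[1L]]] < 0)
    },
    # hydropathy-proportional contact-number stand-in (typical 4-9 range)
    contact_number = function(s) 6 + 0.5 * scale_mean(s, KD_HYDROPATHY),
    helix_propensity = function(s) scale_mean(s, CF_HELIX),
    sheet_propensity = function(s) scale_mean(s, CF_SHEET),
    coil_propensity = function(s) scale_mean(s, CF_TURN)
  )
}

#' Evaluate a predicted-property suite on a sequence
#'
#' Applies every property contract in the suite and validates that each
#' returns a single finite number; a failing or non-finite property raises a
#' property-unavailable error naming it.
#'
#' @inheritParams aa_composition
#' @param suite Named list of property functions (default
#'   [default_property_suite()]).
#' @return Named numeric vector, one finite value per property.
#' @export
predicted_properties <- function(seq, suite = default_property_suite()) {
  rec <- as_sequence_record(seq)
  missing <- setdiff(PROPERTY_NAMES, names(suite))
  if (length(missing) > 0L) {
    stop(sprintf("property unavailable: suite lacks '%s'", missing[1L]),
         call. = FALSE)
  }
  vals <- vapply(PROPERTY_NAMES, function(nm) {
    v <- tryCatch(suite[[nm]](rec$sequence), error = function(e) {
      stop(sprintf("property unavailable: '%s' failed (%s)",
                   nm, conditionMessage(e)), call. = FALSE)
    })
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("property unavailable: '%s' returned a non-finite value", nm),
           call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1))
  vals
}
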