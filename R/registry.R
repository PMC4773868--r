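#' Build the feature registry
#'
#' The ordered, named scheme of all 7,903 features: 122 base features, the
#' 7,381 pairwise interaction products between them (each unordered pair
#' once, no self-pairs), and 400 overlapping dipeptide occurrence counts.
#'
#' The 122 base features are, in order: peptide length; the 20 residue
#' occurrence frequencies; the 20 residue occurrence counts; the 20
#' per-residue maximum consecutive runs; frequency, count and maximum
#' consecutive run for each of the 16 physicochemical groups (48); absolute
#' charge per residue; isoelectric point; and the 11 predicted/derived
#' properties. Editing the group list so the total is no longer exactly 122
#' fails validation: the downstream interaction block is defined as
#' (122 x 121)/2 = 7,381 pairs.
#'
#' @param groups Named list of residue groups; default [residue_groups()].
#' @return An object of class `FeatureRegistry` with fields `base_names`
#'   (122), `interactive_pairs` (7,381 x 2 index matrix into the base
#'   block), `interactive_names`, `dipeptide_names` (400) and `groups`.
#' @export
feature_registry <- function(groups = residue_groups()) {
  if (is.null(names(groups)) || anyDuplicated(names(groups)) > 0L) {
    stop("registry validation: groups must be uniquely named", call. = FALSE)
  }
  for (g in groups) {
    if (length(g) == 0L || !all(g %in% AA_ALPHABET)) {
      stop("registry validation: each group must be a non-empty subset of the alphabet",
           call. = FALSE)
    }
  }
  base_names <- c(
    "length",
    paste0("freq_", AA_ALPHABET),
    paste0("count_", AA_ALPHABET),
    paste0("maxrun_", AA_ALPHABET),
    as.vector(vapply(names(groups), function(g) {
      paste0(c("freq_group_", "count_group_", "maxrun_group_"), g)
    }, character(3))),
    "abs_charge_per_residue", "pI",
    paste0("prop_", PROPERTY_NAMES)
  )
  if (length(base_names) != 122L) {
    stop(sprintf(
      "registry validation: base block has %d features, expected exactly 122 (got %d groups, need 16)",
      length(base_names), length(groups)), call. = FALSE)
  }
  if (anyDuplicated(base_names) > 0L) {
    stop("registry validation: duplicate base feature names", call. = FALSE)
  }
  idx <- which(upper.tri(matrix(0, 122, 122)), arr.ind = TRUE)
  pairs <- cbind(i = idx[, "row"], j = idx[, "col"])
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  stopifnot(nrow(pairs) == 7381L)
  interactive_names <- paste0(base_names[pairs[, 1L]], " x ",
                              base_names[pairs[, 2L]])
  dipeptide_names <- paste0(
    "dipep_", as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0))))
  structure(list(base_names = base_names,
                 interactive_pairs = pairs,
                 interactive_names = interactive_names,
                 dipeptide_names = dipeptide_names,
                 groups = groups),
            class = "FeatureRegistry")
}

#' @export
print.FeatureRegistry <- function(x, ...) {
  cat(sprintf(
    "FeatureRegistry: %d base + %d interactive + %d dipeptide = %d features\n",
    length(x$base_names), nrow(x$interactive_pairs),
    length(x$dipeptide_names), length(full_feature_names(x))))
  invisible(x)
}

#' All 7,903 feature names in registry order
#'
#' @param registry A [feature_registry()].
#' @return Character vector: base block, then interactive block, then
#'   dipeptide block.
#' @export
full_feature_names <- function(registry) {
  c(registry$base_names, registry$interactive_names, registry$dipeptide_names)
}

#' Canonical name of an interactive feature
#'
#' Interaction features are stored once per unordered pair, with the member
#' of lower registry index first; this helper returns the stored name for
#' any ordering of the two base-feature names.
#'
#' @param a,b Base feature names.
#' @param registry A [feature_registry()].
#' @return The registry name of the pair feature, e.g. `"freq_T x maxrun_F"`.
#' @export
interactive_name <- function(a, b, registry) {
  ia <- match(a, registry$base_names)
  ib <- match(b, registry$base_names)
  if (is.na(ia) || is.na(ib)) {
    stop(sprintf("unknown base feature in pair: '%s'",
                 if (is.na(ia)) a else b), call. = FALSE)
  }
  if (ia == ib) stop("self-pairs are not registered", call. = FALSE)
  paste0(registry$base_names[min(ia, ib)], " x ",
         registry$base_names[max(ia, ib)])
}

#' Compute the 122 base features for one sequence
#'
#' @inheritParams aa_composition
#' @param registry A [feature_registry()].
#' @param suite Property suite, see [default_property_suite()].
#' @return Named numeric vector of length 122 in registry order.
#' @export
base_feature_vector <- function(seq, registry = feature_registry(),
                                suite = default_property_suite()) {
  rec <- as_sequence_record(seq)
  counts <- aa_counts(rec)
  len <- nchar(rec$sequence)
  freqs <- counts / len
  runs <- vapply(AA_ALPHABET, function(a) max_consecutive_run(rec, a),
                 numeric(1))
  grp <- as.vector(vapply(registry$groups, function(g) {
    c(sum(counts[g]) / len, sum(counts[g]), max_consecutive_run(rec, g))
  }, numeric(3)))
  abs_charge <- abs((counts[["K"]] + counts[["R"]] + counts[["H"]]) -
                      (counts[["D"]] + counts[["E"]])) / len
  props <- predicted_properties(rec, suite)
  out <- c(len, freqs, counts, runs, grp, abs_charge,
           isoelectric_point(rec), props)
  names(out) <- registry$base_names
  out
}

#' Pairwise interaction products of a base vector
#'
#' One value per unordered pair (i < j) of base features, defined as the
#' arithmetic product of the two raw (pre-standardization) base values.
#'
#' @param base Numeric vector of length 122 from [base_feature_vector()].
#' @param registry A [feature_registry()].
#' @return Named numeric vector of length 7,381.
#' @export
interactive_features <- function(base, registry = feature_registry()) {
  if (length(base) != length(registry$base_names)) {
    stop(sprintf("contract violation: base vector has length %d, expected %d",
                 length(base), length(registry$base_names)), call. = FALSE)
  }
  p <- registry$interactive_pairs
  stats::setNames(as.numeric(base[p[, 1L]] * base[p[, 2L]]),
                  registry$interactive_names)
}

#' The full 7,903-feature vector
#'
#' Concatenation of the base block (122), the interaction block (7,381) and
#' the dipeptide block (400), in registry order.
#'
#' @inheritParams base_feature_vector
#' @return Named numeric vector of length 7,903; all values finite.
#' @export
full_feature_vector <- function(seq, registry = feature_registry(),
                                suite = default_property_suite()) {
  base <- base_feature_vector(seq, registry, suite)
  out <- c(base,
           interactive_features(base, registry),
           dipeptide_occurrences(seq))
  names(out) <- full_feature_names(registry)
  out
}

#' Feature matrix for a list of sequences
#'
#' @param records List of [sequence_record()] objects.
#' @inheritParams base_feature_vector
#' @return Numeric matrix, one row per sequence (rownames = ids), 7,903
#'   named columns.
#' @export
feature_matrix <- function(records, registry = feature_registry(),
                           suite = default_property_suite()) {
  rows <- lapply(records, full_feature_vector, registry = registry,
                 suite = suite)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(records, function(r) r$id, character(1))
  m
}

#' Feature subsets selected for each prediction task
#'
#' The published feature subsets for the four tasks, as named character
#' vectors mapping the short published label (e.g. `QD`, `T x MCPhe`) to the
#' registry feature name. The classification subset has 7 features, the
#' high/medium/low regression subsets 3/6/4.
#'
#' The tyrosine-by-transmembrane interaction in the low-yield subset is
#' described as an *occurrence* (count) of tyrosine while the
#' tyrosine-by-folding-rate feature uses the occurrence *frequency*; both
#' variants exist in the registry and `tyrosine_tm_variant` selects which is
#' wired in (default `"count"`).
#'
#' @param registry A [feature_registry()].
#' @param tyrosine_tm_variant `"count"` (default) or `"freq"`.
#' @return Named list with elements `classification`, `reg_high`,
#'   `reg_medium`, `reg_low`.
#' @export
paper_feature_subsets <- function(registry = feature_registry(),
                                  tyrosine_tm_variant = c("count", "freq")) {
  tyrosine_tm_variant <- match.arg(tyrosine_tm_variant)
  y_tm <- interactive_name(
    if (tyrosine_tm_variant == "count") "count_Y" else "freq_Y",
    "prop_transmembrane", registry)
  inm <- function(a, b) interactive_name(a, b, registry)
  list(
    classification = c(
      BPC = "freq_group_bpc",
      Sulfur = "freq_group_sulfur",
      MCBPC = "maxrun_group_bpc",
      logPFR = "prop_logPFR",
      CL = "dipep_CL",
      QD = "dipep_QD",
      VE = "dipep_VE"),
    reg_high = c(
      TP = "dipep_TP",
      VT = "dipep_VT",
      `T x MCPhe` = inm("freq_T", "maxrun_F")),
    reg_medium = c(
      ER = "dipep_ER",
      WQ = "dipep_WQ",
      VT = "dipep_VT",
      `R x AbsCharge` = inm("freq_R", "abs_charge_per_residue"),
      `ANC x MCAliphatic` = inm("freq_group_anc", "maxrun_group_aliphatic"),
      `MCCys x pI` = inm("maxrun_C", "pI")),
    reg_low = c(
      `F x logPFR` = inm("freq_F", "prop_logPFR"),
      `S x MCNPH` = inm("freq_S", "maxrun_group_nph"),
      `y x transmembrane` = y_tm,
      `Y x nlogPFR` = inm("freq_Y", "prop_nlogPFR"))
  )
}

#' Named feature subset values for one sequence
#'
#' Computes exactly the published feature subset for a task, returning the
#' values under their short published labels.
#'
#' @inheritParams base_feature_vector
#' @param task One of `"classification"`, `"reg_high"`, `"reg_medium"`,
#'   `"reg_low"`.
#' @param tyrosine_tm_variant See [paper_feature_subsets()].
#' @return Named numeric vector (7, 3, 6 or 4 values).
#' @export
named_subset <- function(seq, task, registry = feature_registry(),
                         suite = default_property_suite(),
                         tyrosine_tm_variant = "count") {
  subsets <- paper_feature_subsets(registry, tyrosine_tm_variant)
  if (!task %in% names(subsets)) {
    stop(sprintf("invalid argument: unknown task '%s' (expected one of %s)",
                 task, paste(names(subsets), collapse = ", ")), call. = FALSE)
  }
  full <- full_feature_vector(seq, registry, suite)
  sel <- subsets[[task]]
  stats::setNames(full[sel], names(sel))
}
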