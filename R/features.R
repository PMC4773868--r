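#' Amino-acid composition
#'
#' Occurrence frequency of each of the 20 residues: count divided by
#' sequence length.
#'
#' @param seq A [sequence_record()] (or a plain sequence string).
#' @return Named numeric vector of 20 frequencies, in [AA_ALPHABET] order;
#'   sums to 1.
#' @export
aa_composition <- function(seq) {
  aa_counts(seq) / nchar(as_sequence_record(seq)$sequence)
}

#' Amino-acid occurrence counts
#'
#' Raw residue counts, the unnormalized companion of [aa_composition()].
#'
#' @inheritParams aa_composition
#' @return Named integer-valued numeric vector of 20 counts.
#' @export
aa_counts <- function(seq) {
  rec <- as_sequence_record(seq)
  tab <- table(factor(seq_chars(rec), levels = AA_ALPHABET))
  stats::setNames(as.numeric(tab), AA_ALPHABET)
}

#' Longest consecutive run of group members
#'
#' Length of the longest contiguous substring whose residues all belong to
#' the given group; 0 when no member occurs. For a single-letter group this
#' is the per-residue maximum consecutive run.
#'
#' @inheritParams aa_composition
#' @param group Character vector of residue letters (non-empty, subset of
#'   the 20-letter alphabet).
#' @return Non-negative integer.
#' @examples
#' max_consecutive_run(sequence_record("x", "HKRAHKR"), c("H", "K", "R"))
#' @export
max_consecutive_run <- function(seq, group) {
  rec <- as_sequence_record(seq)
  if (length(group) == 0L || !all(group %in% AA_ALPHABET)) {
    stop("invalid input: 'group' must be a non-empty subset of the amino-acid alphabet",
         call. = FALSE)
  }
  inside <- seq_chars(rec) %in% group
  if (!any(inside)) return(0L)
  runs <- rle(inside)
  max(runs$lengths[runs$values])
}

#' Overlapping dipeptide occurrence counts
#'
#' Counts of each of the 400 ordered residue pairs at adjacent positions
#' (overlapping windows). The counts sum to `length - 1`. These are raw
#' counts, not frequencies.
#'
#' @inheritParams aa_composition
#' @return Named numeric vector of length 400 (names like `"QD"`), in
#'   row-major [AA_ALPHABET] order.
#' @export
dipeptide_occurrences <- function(seq) {
  rec <- as_sequence_record(seq)
  chars <- seq_chars(rec)
  n <- length(chars)
  pairs <- paste0(chars[-n], chars[-1L])
  lv <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  tab <- table(factor(pairs, levels = lv))
  stats::setNames(as.numeric(tab), lv)
}

# Net peptide charge at a given pH under the package pKa table
# (Henderson-Hasselbalch per ionizable site, plus the two termini).
net_charge_at_ph <- function(counts, ph, pka = PKA_TABLE) {
  pos <- 1 / (1 + 10^(ph - pka$nterm))
  for (res in names(pka$positive)) {
    pos <- pos + counts[[res]] / (1 + 10^(ph - pka$positive[[res]]))
  }
  neg <- 1 / (1 + 10^(pka$cterm - ph))
  for (res in names(pka$negative)) {
    neg <- neg + counts[[res]] / (1 + 10^(pka$negative[[res]] - ph))
  }
  pos - neg
}

#' Isoelectric point
#'
#' pH at which the peptide's net charge is zero, solved by bisection of the
#' Henderson-Hasselbalch net-charge function (EMBOSS pKa table, both termini
#' included) to a tolerance of 1e-3 pH units.
#'
#' @inheritParams aa_composition
#' @param tol Bisection tolerance in pH units.
#' @return The pI, a value in (0, 14).
#' @export
isoelectric_point <- function(seq, tol = 1e-3) {
  counts <- aa_counts(seq)
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH, so the root is unique
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge_at_ph(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical scalar features
#'
#' Length, group occurrence frequencies, absolute charge per residue and the
#' isoelectric point. Absolute charge per residue is
#' `|(nK + nR + nH) - (nD + nE)| / length` (histidine counted positive,
#' consistent with the basic/positively-charged group H, K, R).
#'
#' @inheritParams aa_composition
#' @param groups Named list of residue groups (default [residue_groups()]).
#' @return Named list with `length`, `group_freq` (named numeric vector),
#'   `abs_charge_per_residue` and `pI`.
#' @export
physchem_scalars <- function(seq, groups = residue_groups()) {
  rec <- as_sequence_record(seq)
  counts <- aa_counts(rec)
  len <- nchar(rec$sequence)
  gf <- vapply(groups, function(g) sum(counts[g]) / len, numeric(1))
  abs_charge <- abs((counts[["K"]] + counts[["R"]] + counts[["H"]]) -
                      (counts[["D"]] + counts[["E"]])) / len
  list(length = len,
       group_freq = gf,
       abs_charge_per_residue = abs_charge,
       pI = isoelectric_point(rec))
}
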