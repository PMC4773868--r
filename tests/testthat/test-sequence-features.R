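test_that("sequence records validate and normalize input", {
  r <- sequence_record("x", " mkik tga ")
  expect_equal(r$sequence, "MKIKTGA")
  expect_error(sequence_record("x", "A"), "length 1")
  expect_error(sequence_record("bad", "ACDX"), "illegal residue 'X' at position 4")
  expect_error(sequence_record("bad", "ACBU"), "illegal residue 'B' at position 3")
  expect_error(sequence_record("", "ACDE"), "id")
})

test_that("aa_composition matches hand counts and sums to 1", {
  comp <- aa_composition(rec("AAAA"))
  expect_equal(comp[["A"]], 1)
  expect_equal(sum(comp), 1)
  expect_true(all(comp[setdiff(AA_ALPHABET, "A")] == 0))

  comp <- aa_composition(rec("ACDE"))
  expect_equal(unname(comp[c("A", "C", "D", "E")]), rep(0.25, 4))

  comp <- aa_composition(rec("HKRA"))
  expect_equal(unname(comp[c("H", "K", "R", "A")]), rep(0.25, 4))

  for (seed in 1:5) {
    comp <- aa_composition(rec(random_sequence(80, seed)))
    expect_equal(sum(comp), 1, tolerance = 1e-12)
    expect_true(all(comp >= 0 & comp <= 1))
  }
})

test_that("max_consecutive_run handles groups, singletons and absences", {
  expect_equal(max_consecutive_run(rec("HKRAHKR"), c("H", "K", "R")), 3)
  expect_equal(max_consecutive_run(rec("AAKAA"), "A"), 2)
  expect_equal(max_consecutive_run(rec("DDDD"), c("H", "K", "R")), 0)
  # group runs join different members, single-letter runs do not
  expect_equal(max_consecutive_run(rec("HKHKHK"), c("H", "K")), 6)
  expect_equal(max_consecutive_run(rec("HKHKHK"), "H"), 1)
  expect_error(max_consecutive_run(rec("AAAA"), character(0)), "group")
})

test_that("dipeptide occurrences are overlapping counts summing to L-1", {
  d <- dipeptide_occurrences(rec("AQDQDA"))
  expect_equal(d[["QD"]], 2)
  d <- dipeptide_occurrences(rec("AAA"))
  expect_equal(d[["AA"]], 2)
  expect_equal(sum(d), 2)
  expect_length(d, 400)
  for (seed in 1:5) {
    d <- dipeptide_occurrences(rec(random_sequence(50, seed)))
    expect_equal(sum(d), 49)
  }
})

test_that("physchem scalars: charge, group frequencies, pI", {
  ps <- physchem_scalars(rec("KKDD"))
  expect_equal(ps$abs_charge_per_residue, 0)
  ps <- physchem_scalars(rec("HKRA"))
  expect_equal(unname(ps$group_freq["bpc"]), 0.75)
  expect_equal(ps$abs_charge_per_residue, 0.75)

  # independent root-finding oracle over the same pKa table
  for (s in c("GGGGG", "KKKAAA", "DDEEAA", random_sequence(60, 3))) {
    counts <- aa_counts(rec(s))
    oracle <- stats::uniroot(function(ph) {
      periyield:::net_charge_at_ph(counts, ph)
    }, c(0, 14), tol = 1e-9)$root
    expect_equal(isoelectric_point(rec(s)), oracle, tolerance = 2e-3)
  }
  # acidic peptide below 7, basic above 7
  expect_lt(isoelectric_point(rec("DDEEAA")), 7)
  expect_gt(isoelectric_point(rec("KKRRAA")), 7)
})

test_that("predicted properties honour the suite contract", {
  vals <- predicted_properties(rec("ACDEFG"), stub_suite(1.0))
  expect_true(all(vals == 1.0))
  expect_named(vals, periyield:::PROPERTY_NAMES)

  vals <- predicted_properties(rec(random_sequence(100, 1)))
  expect_true(all(is.finite(vals)))
  expect_equal(vals[["nlogPFR"]], vals[["logPFR"]] * log(10), tolerance = 1e-12)

  polyA <- rec(strrep("A", 20))
  expect_equal(predicted_properties(polyA)[["helix_propensity"]],
               periyield:::CF_HELIX[["A"]])

  broken <- stub_suite(1.0)
  broken$solubility <- function(s) NaN
  expect_error(predicted_properties(rec("ACDE"), broken),
               "property unavailable: 'solubility'")
  expect_error(predicted_properties(rec("ACDE"), stub_suite()[-1]),
               "property unavailable")
})

test_that("registry has the exact feature scheme cardinalities", {
  reg <- feature_registry()
  expect_length(reg$base_names, 122)
  expect_equal(nrow(reg$interactive_pairs), 7381)
  expect_length(reg$dipeptide_names, 400)
  expect_length(full_feature_names(reg), 7903)
  expect_equal(anyDuplicated(full_feature_names(reg)), 0)
  # pair-index audit: no self pairs, each unordered pair once
  p <- reg$interactive_pairs
  expect_true(all(p[, 1] < p[, 2]))
  expect_equal(anyDuplicated(p), 0)
  expect_equal(nrow(p), 122 * 121 / 2)
  # editing groups so the count changes fails validation
  expect_error(feature_registry(residue_groups()[-1]), "expected exactly 122")
})

test_that("interactive features are pairwise products", {
  reg <- feature_registry()
  zero <- interactive_features(rep(0, 122), reg)
  expect_true(all(zero == 0))
  base <- rep(1, 122)
  base[1] <- 2; base[2] <- 3
  inter <- interactive_features(base, reg)
  expect_equal(inter[[interactive_name(reg$base_names[1],
                                       reg$base_names[2], reg)]], 6)
  expect_length(inter, 7381)
  expect_error(interactive_features(rep(0, 121), reg), "contract violation")
  # order of arguments does not matter for the name lookup
  expect_equal(interactive_name("freq_T", "maxrun_F", reg),
               interactive_name("maxrun_F", "freq_T", reg))
  expect_error(interactive_name("freq_T", "freq_T", reg), "self-pairs")
})

test_that("full vector = base + interactive + dipeptide, componentwise", {
  reg <- feature_registry()
  r <- rec(random_sequence(70, 11))
  v <- full_feature_vector(r, reg)
  expect_length(v, 7903)
  expect_true(all(is.finite(v)))
  # independent per-family recomputation
  base <- base_feature_vector(r, reg)
  expect_equal(unname(v[1:122]), unname(base))
  expect_equal(unname(v[123:7503]), unname(interactive_features(base, reg)))
  expect_equal(unname(v[7504:7903]), unname(dipeptide_occurrences(r)))
  # pure function: repeated calls agree bit-for-bit
  expect_identical(v, full_feature_vector(r, reg))
  # reversal preserves composition features, not necessarily dipeptides
  fwd <- rec("AQDQDAHKR")
  rev <- rec(paste(base::rev(strsplit(fwd$sequence, "")[[1]]), collapse = ""))
  expect_equal(aa_composition(fwd), aa_composition(rev))
  expect_false(identical(dipeptide_occurrences(fwd),
                         dipeptide_occurrences(rev)))
})

test_that("named task subsets match the full vector entries", {
  reg <- feature_registry()
  sub <- named_subset(rec("AQDQDA"), "classification", reg)
  expect_length(sub, 7)
  expect_named(sub, c("BPC", "Sulfur", "MCBPC", "logPFR", "CL", "QD", "VE"))
  expect_equal(sub[["QD"]], 2)

  high <- named_subset(rec("TTTFFF"), "reg_high", reg)
  expect_equal(high[["T x MCPhe"]], 0.5 * 3)
  expect_length(named_subset(rec("ACDEFG"), "reg_medium", reg), 6)
  expect_length(named_subset(rec("ACDEFG"), "reg_low", reg), 4)
  expect_error(named_subset(rec("ACDE"), "reg_ultra", reg), "invalid argument")

  # cross-indexing against the full vector
  r <- rec(random_sequence(90, 5))
  v <- full_feature_vector(r, reg)
  subs <- paper_feature_subsets(reg)
  for (task in names(subs)) {
    got <- named_subset(r, task, reg)
    expect_equal(unname(got), unname(v[subs[[task]]]), tolerance = 1e-15)
  }
  # the tyrosine-transmembrane variant switches between count and frequency
  cnt <- paper_feature_subsets(reg, "count")$reg_low[["y x transmembrane"]]
  frq <- paper_feature_subsets(reg, "freq")$reg_low[["y x transmembrane"]]
  expect_match(cnt, "count_Y")
  expect_match(frq, "freq_Y")
})
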