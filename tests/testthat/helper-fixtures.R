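# Shared fixtures. Everything is generated in code; nothing is read from
# disk except temp files the tests themselves write.

rec <- function(s, id = "t") sequence_record(id, s)

random_sequence <- function(len, seed) {
  withr::with_seed(seed, paste(sample(AA_ALPHABET, len, replace = TRUE),
                               collapse = ""))
}

# Reduced exponential grids: same shape as the defaults, cut down so the
# suite stays inside the CPU budget.
small_config <- function(...) {
  default_config(
    svc_grid = list(C = 2^seq(-1, 9, 2), gamma = 2^seq(-7, 1, 2)),
    svr_grid = list(C = 2^seq(-1, 13, 2), gamma = 2^seq(-7, 1, 2),
                    epsilon = c(0.01, 0.1, 1)),
    ...)
}

# Constant-output property suite for stub tests.
stub_suite <- function(value = 1.0) {
  stats::setNames(
    lapply(periyield:::PROPERTY_NAMES, function(nm) function(s) value),
    periyield:::PROPERTY_NAMES)
}

# A small labelled dataset with a planted QD-count yield law:
# yield = 10 * (QD occurrences) + 0.2 mg/l, exactly the kind of relation the
# two-stage model should recover. Sequences embed 0..12 QD pairs in a random
# backbone, so zero QD lands in the low class, >= 10 QD in the high class,
# and the rest in medium.
qd_law_dataset <- function(n = 60, seed = 42) {
  withr::with_seed(seed, {
    records <- lapply(seq_len(n), function(i) {
      k <- sample(0:12, 1)
      backbone <- sample(setdiff(AA_ALPHABET, c("Q", "D")), 40, replace = TRUE)
      insert_at <- sort(sample(seq_along(backbone), k))
      seqs <- character(0)
      prev <- 1L
      for (pos in insert_at) {
        seqs <- c(seqs, paste(backbone[prev:pos], collapse = ""), "QD")
        prev <- pos + 1L
      }
      seqs <- c(seqs, paste(backbone[prev:length(backbone)], collapse = ""))
      sequence_record(sprintf("qd%03d", i), paste(seqs, collapse = ""))
    })
    qd <- vapply(records, function(r) {
      dipeptide_occurrences(r)[["QD"]]
    }, numeric(1))
    # jitter so no two yields tie; small enough to never cross a threshold
    labelled_dataset(records, 10 * qd + 0.2 + stats::runif(n, -0.05, 0.05))
  })
}
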