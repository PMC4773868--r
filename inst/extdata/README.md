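# extdata

No data files ship with the package; all test fixtures are generated in
code.

Optional: if you have the curated yield table (98 instances), place it here
as `curated_yields.tsv` (tab-separated, columns `id` and `yield_mg_per_l`)
before installing. The acceptance test
"criterion 3" in `tests/testthat/test-acceptance.R` will then verify that
the class thresholds (low <= 0.5 mg/l, high >= 100 mg/l) reproduce the
published class counts 16/58/24; without the file that test is skipped.
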