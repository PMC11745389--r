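# One-time search that produced the frozen antibody-like fixture shipped
# in inst/extdata/.  Run from the package root after installing/loading
# the package; takes tens of minutes.  The accepted (seed, attempt) pair
# is recorded in R/synthetic-data.R (.fixture_frozen) so the fixture can
# be regenerated instantly and exactly.

library(epiland)

res <- make_antibody_like_landscape(seed = 20260909, max_attempts = 200000,
                                    check_dynamics = TRUE, wf_replicates = 120)
cat("accepted attempt:", res$attempt, "\n")
write_coefficients(res$coefficients,
                   "inst/extdata/synthetic_antibody_like_coefficients.json")
write_genotype_table(res$landscape,
                     "inst/extdata/synthetic_antibody_like_landscape.tsv", digits = 10)
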