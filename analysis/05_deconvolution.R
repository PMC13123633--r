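#!/usr/bin/env Rscript
# Stage 5: leukocyte deconvolution on synthetic mixtures and group tests.
#
# Builds a synthetic reference of four leukocyte-like profiles, mixes them
# with known proportions plus 10% multiplicative noise, recovers the
# fractions by signature-gene NNLS, and compares two cohorts whose true
# compositions differ (lymphocyte-like type down, monocyte-like type up in
# the exposed group) with per-type Welch tests.

suppressMessages(library(wolfscan))
out <- "results"
set.seed(5)

mx <- simulate_mixtures(n_genes = 300, n_types = 4, n_samples = 9, seed = 51)
props <- deconvolve_samples(mx$mixtures, mx$ref)
write_tsv(props, file.path(out, "cell_proportions.tsv"))
mae <- mean(abs(as.matrix(props[, colnames(mx$ref)]) - mx$truth))
message(sprintf("recovered %d samples; mean absolute proportion error %.4f",
                nrow(props), mae))

# two cohorts with a planted composition shift
shift_group <- function(n, lym, mono) {
  data.frame(lymphocyte = rnorm(n, lym, 0.04),
             monocyte = rnorm(n, mono, 0.04),
             granulocyte = rnorm(n, 1 - lym - mono, 0.04))
}
exposed <- shift_group(9, 0.40, 0.20)
reference <- shift_group(9, 0.55, 0.10)
cmp <- compare_celltype_proportions(exposed, reference)
write_tsv(cmp, file.path(out, "celltype_comparison.tsv"))
message("per-type Welch tests (exposed vs reference):")
for (i in seq_len(nrow(cmp))) {
  message(sprintf("  %-12s t = %6.2f, df = %5.2f, p = %.3g",
                  cmp$cell_type[i], cmp$t[i], cmp$df[i], cmp$p[i]))
}
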