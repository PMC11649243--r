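#!/usr/bin/env Rscript
# Step 3: which attentional mechanism predicts the similarity-dependence
# of attentional modulation?
#
# For every mechanism x population kind, computes the per-participant
# Pearson correlation (across the six category pairs) between the
# attentional effect and the category distance, then the group mean with
# its 95% CI. Reads the pair-level tables written by step 2.

library(attnshift)

uni <- read.csv("results/pair_results_univariate.csv",
                stringsAsFactors = FALSE)
mv <- read.csv("results/pair_results_multivariate.csv",
               stringsAsFactors = FALSE)

summarize <- function(tab, ycol, analysis) {
  do.call(rbind, lapply(split(tab, list(tab$mechanism, tab$roi), sep = " / "),
    function(g) {
      r <- shift_distance_correlation(g, ycol = ycol)$r
      ci <- t.test(r[is.finite(r)])$conf.int
      data.frame(analysis = analysis, mechanism = g$mechanism[1],
                 population = g$roi[1], mean_r = mean(r, na.rm = TRUE),
                 ci_lo = ci[1], ci_hi = ci[2],
                 n_participants = length(unique(g$participant)))
    }))
}

sig <- rbind(summarize(uni, "shift", "univariate"),
             summarize(mv, "delta_w", "multivariate"))
rownames(sig) <- NULL
sig <- sig[order(sig$analysis, sig$population, sig$mechanism), ]
write.csv(sig, "results/mechanism_signatures.csv", row.names = FALSE)

print(transform(sig, mean_r = round(mean_r, 3), ci_lo = round(ci_lo, 3),
                ci_hi = round(ci_hi, 3)), row.names = FALSE)

cat("\nReading the table: the response gain model leaves every\n",
    "effect-vs-distance correlation indistinguishable from zero, while\n",
    "tuning sharpening produces strongly positive correlations for the\n",
    "univariate shift in both populations and for the weight shift in the\n",
    "category-selective population. The labeled-line model predicts the\n",
    "univariate effect only where all neurons share a preference. The\n",
    "object-selective weight-shift correlation under tuning is unstable at\n",
    "this scale because i.i.d. category rates give that population no\n",
    "structural between-pair similarity differences (see the methods\n",
    "vignette).\n", sep = "")
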