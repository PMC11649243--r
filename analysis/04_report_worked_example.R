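#!/usr/bin/env Rscript
# Step 4: assemble the full report for the tuning-sharpening simulation
# and print the worked weight-share example.
#
# Reads the pair-level tables from step 2, builds the per-ROI report
# tables (pair summaries, per-participant correlations, group tests) for
# the tuning mechanism, and walks through the weight-share arithmetic on
# reported group-average linear-combination weights.

library(attnshift)

uni <- read.csv("results/pair_results_univariate.csv",
                stringsAsFactors = FALSE)
mv <- read.csv("results/pair_results_multivariate.csv",
               stringsAsFactors = FALSE)

tun_uni <- uni[uni$mechanism == "tuning", ]
tun_mv <- mv[mv$mechanism == "tuning", ]
rep <- build_report(tun_uni, tun_mv, output_dir = "results/report_tuning")
cat("report sections:", paste(rep$sections, collapse = "; "), "\n")
cat("group test of weight-shift-vs-distance correlations (tuning):\n")
print(transform(rep$multivariate_group,
                t_stat = round(t_stat, 2), p_raw = signif(p_raw, 2),
                mean = round(mean, 3), sem = round(sem, 3),
                ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3)),
      row.names = FALSE)

# --- worked example: shares from group-average weights -------------------
# In object-selective cortex, the paired Body-Car response decomposes into
# the isolated patterns with weights 0.79 (body) and 0.31 (car) when bodies
# are attended, and 0.43 / 0.68 when cars are attended.
share_att <- weight_share(0.79, 0.31)
share_ign <- weight_share(0.43, 0.68)
cat(sprintf("\nattended body share: 0.79 / (0.79 + 0.31) = %.4f (~%.2f)\n",
            share_att, round(share_att, 2)))
cat(sprintf("unattended body share: 0.43 / (0.43 + 0.68) = %.4f (~%.2f)\n",
            share_ign, round(share_ign, 2)))
cat(sprintf("weight shift from these group-average weights: %.4f\n",
            weight_shift(0.79, 0.31, 0.43, 0.68)))
cat("(computing shares per participant before averaging instead yields\n",
    "shares 0.72 / 0.38 and a weight shift of 0.34)\n", sep = "")
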