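#!/usr/bin/env Rscript
# Step 1: demonstrate the population simulator.
#
# Builds a small neural population, shows how the three attentional
# mechanisms (response gain, tuning sharpening, labeled line) reshape a
# neuron's category tuning, and emits a demo beta table that round-trips
# through the tabular reader.

library(attnshift)

dir.create("results", showWarnings = FALSE)

# --- mechanism arithmetic on one example neuron --------------------------
nrn <- neuron_population("cat",
                         matrix(c(body = 20, car = 25, cat = 40, house = 10),
                                nrow = 1, dimnames = list(NULL, categories())),
                         beta = 2)
tuning_tab <- do.call(rbind, lapply(c("gain", "tuning", "labeled_line"),
  function(mech) {
    data.frame(mechanism = mech, category = categories(),
               baseline = as.vector(nrn$rates),
               attended = vapply(categories(), function(ctg)
                 attended_rate(nrn, ctg, mech), numeric(1)))
  }))
write.csv(tuning_tab, "results/mechanism_tuning_demo.csv", row.names = FALSE)

cat("Example neuron (prefers cat, baseline 40 sp/s, attention factor 2):\n")
print(tuning_tab, row.names = FALSE)
cat("\nGain scales every attended response by 2; tuning sharpening doubles\n",
    "the optimal response but suppresses the weak house response\n",
    "(2 * 10/40 * 10 = 5 < 10); the labeled line only boosts 'cat'.\n\n",
    sep = "")

# --- a small fMRI-like dataset ------------------------------------------
cfg <- population_config(n_neurons = 4000, neurons_per_voxel = 100,
                         n_voxels = 8, mechanism = "tuning", seed = 20)
sim <- simulate_dataset(cfg, n_participants = 2, n_runs = 2)
write_beta_table(sim, "results/simulated_beta_table_demo.csv")
back <- read_beta_table("results/simulated_beta_table_demo.csv")
stopifnot(identical(back[[1]]$betas, sim[[1]]$betas))
cat("Wrote results/simulated_beta_table_demo.csv (",
    2 * 8 * 16 * 2, " cells); round-trip through read_beta_table() is",
    " exact.\n", sep = "")
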