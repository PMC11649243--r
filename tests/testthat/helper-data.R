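# Shared fixture builders: tiny ROI datasets constructed in code.

cond_ids <- function() condition_table()$condition

# roi_dataset with betas from a filler function(voxel, condition, run) or
# a constant/random pool
toy_dataset <- function(n_voxels = 4, n_runs = 2, fill = NULL,
                        participant = "p1", roi = "LO") {
  conds <- cond_ids()
  arr <- array(0, dim = c(n_voxels, length(conds), n_runs),
               dimnames = list(paste0("v", seq_len(n_voxels)), conds,
                               sprintf("run%02d", seq_len(n_runs))))
  if (is.function(fill)) {
    for (v in seq_len(n_voxels)) {
      for (ci in seq_along(conds)) {
        for (r in seq_len(n_runs)) arr[v, ci, r] <- fill(v, conds[ci], r)
      }
    }
  } else if (!is.null(fill)) {
    arr[] <- fill
  } else {
    arr[] <- rnorm(length(arr))
  }
  roi_dataset(arr, participant, roi)
}

# long-format data.frame matching the beta-table schema
dataset_to_df <- function(ds) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_beta_table(ds, tmp)
  utils::read.csv(tmp, stringsAsFactors = FALSE)
}

# null dataset: no attentional modulation (beta == 1), i.i.d. noise only
null_config <- function(..., seed = NULL) {
  population_config(n_neurons = 4000, neurons_per_voxel = 50, n_voxels = 40,
                    beta_range = c(1, 1), seed = seed, ...)
}

# small single-neuron population for mechanism arithmetic
one_neuron <- function(rates, preferred, beta) {
  neuron_population(preferred,
                    matrix(rates[categories()], nrow = 1,
                           dimnames = list(NULL, categories())),
                    beta)
}
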