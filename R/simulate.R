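# Neural-population simulator: neuron-level baseline rates, attentional
# modulation under response-gain / tuning-sharpening / labeled-line
# mechanisms, Poisson spiking noise, voxelization by averaging similarly
# selective neurons, and multi-run multi-participant fMRI-like datasets.

#' Configuration of a simulated neural population
#'
#' Collects all knobs of the population simulator. The defaults are the
#' study-scale conditions: 4e5 neurons in equal proportions selective for
#' the four categories, per-stimulus baseline rates drawn from a normal
#' distribution with mean 30 spikes/s and SD 10 (truncated at 0), a
#' per-neuron attention factor uniform on \[1, 10\], Poisson spiking
#' noise, and voxels formed by averaging 1000 similarly selective
#' neurons.
#'
#' @param n_neurons Population size (default `4e5`).
#' @param population_kind `"object_selective"` (equal proportions of the
#'   four preferences, voxels of every preference — like LO/pFs) or
#'   `"category_selective"` (every neuron and voxel prefers
#'   `selective_category` — like EBA/PPA).
#' @param selective_category Preferred category of a category-selective
#'   population.
#' @param rate_mean,rate_sd Mean and SD (spikes/s) of the baseline-rate
#'   distribution.
#' @param beta_range Range of the uniform per-neuron attention factor;
#'   must lie within \[1, 10\].
#' @param neurons_per_voxel Neurons averaged into one voxel (default
#'   1000).
#' @param n_voxels Number of simulated voxels per region (default 400;
#'   must be divisible by 4 for an object-selective population).
#' @param mechanism Attentional mechanism: `"gain"` (constant
#'   multiplicative factor), `"tuning"` (factor scaled by the neuron's
#'   selectivity for the attended stimulus, sharpening the tuning
#'   curve) or `"labeled_line"` (factor applied only when the attended
#'   stimulus is the neuron's preferred one).
#' @param pair_combination How a neuron combines the two stimuli of a
#'   paired condition: `"average"` (default) or `"sum"`.
#' @param modulation Where the attention factor acts in paired
#'   conditions: `"response"` (default; the factor earned by the
#'   attended stimulus multiplies the neuron's combined response to the
#'   pair, so e.g. pure gain enhances the pair identically whichever
#'   stimulus is attended) or `"stimulus"` (the factor multiplies only
#'   the attended component, the ignored component stays at baseline).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param preference_boost Spikes/s added to the mean of the preferred
#'   category's rate before the preference is enforced (default 0; the
#'   default rule draws all four rates i.i.d. and swaps the largest draw
#'   into the preferred slot).
#' @param seed Optional integer seed making the population and every
#'   dataset built from this config reproducible.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_neurons = 4e5,
                              population_kind = c("object_selective",
                                                  "category_selective"),
                              selective_category = "body",
                              rate_mean = 30, rate_sd = 10,
                              beta_range = c(1, 10),
                              neurons_per_voxel = 1000,
                              n_voxels = 400,
                              mechanism = c("gain", "tuning", "labeled_line"),
                              pair_combination = c("average", "sum"),
                              modulation = c("response", "stimulus"),
                              noise = c("poisson", "none"),
                              preference_boost = 0,
                              seed = NULL) {
  population_kind <- match.arg(population_kind)
  mechanism <- match.arg(mechanism)
  pair_combination <- match.arg(pair_combination)
  modulation <- match.arg(modulation)
  noise <- match.arg(noise)
  assert_category(selective_category)
  stopifnot(n_neurons >= neurons_per_voxel, n_voxels >= 1,
            rate_mean > 0, rate_sd >= 0,
            length(beta_range) == 2, beta_range[1] <= beta_range[2],
            beta_range[1] >= 1, beta_range[2] <= 10)
  if (population_kind == "object_selective") {
    if (n_neurons %% 4L != 0L) {
      stop("object-selective populations need n_neurons divisible by 4",
           call. = FALSE)
    }
    if (n_voxels %% 4L != 0L) {
      stop("object-selective populations need n_voxels divisible by 4",
           call. = FALSE)
    }
    if (neurons_per_voxel > n_neurons / 4) {
      stop("not enough neurons of each preference for a voxel",
           call. = FALSE)
    }
  }
  structure(list(n_neurons = as.integer(n_neurons),
                 population_kind = population_kind,
                 selective_category = selective_category,
                 rate_mean = rate_mean, rate_sd = rate_sd,
                 beta_range = beta_range,
                 neurons_per_voxel = as.integer(neurons_per_voxel),
                 n_voxels = as.integer(n_voxels),
                 mechanism = mechanism,
                 pair_combination = pair_combination,
                 modulation = modulation,
                 noise = noise,
                 preference_boost = preference_boost,
                 seed = seed),
            class = "population_config")
}

#' Construct a neuron population directly
#'
#' Low-level constructor used by [build_population()] and handy for
#' single-neuron examples. Each neuron has one baseline rate per
#' category, a preferred category whose rate must be the row maximum,
#' and an attention factor.
#'
#' @param preferred Character vector of preferred categories, one per
#'   neuron.
#' @param rates Numeric `neuron x category` matrix of baseline rates
#'   (spikes/s, non-negative) with the four categories as column names.
#' @param beta Numeric vector of per-neuron attention factors.
#' @param config Optional [population_config()] to attach.
#' @return A list of class `neuron_population` with elements `preferred`,
#'   `rates`, `beta`, `rmax` (per-neuron optimal-stimulus rate) and
#'   `config`.
#' @export
neuron_population <- function(preferred, rates, beta, config = NULL) {
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1,
                                           dimnames = list(NULL, names(rates)))
  stopifnot(!is.null(colnames(rates)), setequal(colnames(rates), CATEGORIES),
            nrow(rates) == length(preferred),
            length(beta) == length(preferred),
            all(rates >= 0), all(beta >= 1))
  assert_category(preferred)
  rates <- rates[, CATEGORIES, drop = FALSE]
  pref_rate <- rates[cbind(seq_along(preferred), match(preferred, CATEGORIES))]
  rmax <- apply(rates, 1, max)
  if (any(pref_rate < rmax)) {
    stop("each neuron's preferred-category rate must be its maximum rate",
         call. = FALSE)
  }
  structure(list(preferred = preferred, rates = rates, beta = beta,
                 rmax = rmax, config = config),
            class = "neuron_population")
}

#' @export
print.neuron_population <- function(x, ...) {
  cat(sprintf("<neuron_population> %d neurons (%s)\n", length(x$beta),
              paste(sprintf("%s: %d", names(table(x$preferred)),
                            as.integer(table(x$preferred))), collapse = ", ")))
  invisible(x)
}

#' Build a neural population from a configuration
#'
#' Draws per-neuron baseline rates for all four categories i.i.d. from a
#' normal distribution truncated at 0, then enforces the assigned
#' preference by swapping each neuron's largest rate into its preferred
#' category's slot (preserving the marginal rate distribution while
#' guaranteeing that every neuron responds most to its preferred
#' category, and to the other categories to a lesser and variable
#' degree). Attention factors are drawn uniformly from
#' `cfg$beta_range`. Object-selective populations assign the four
#' preferences in exactly equal proportions.
#'
#' @param cfg A [population_config()].
#' @return A [neuron_population()].
#' @export
build_population <- function(cfg) {
  stopifnot(inherits(cfg, "population_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_neurons
  preferred <- if (cfg$population_kind == "object_selective") {
    rep(CATEGORIES, each = n / 4L)
  } else {
    rep(cfg$selective_category, n)
  }
  rates <- matrix(rtrunc_norm(n * 4L, cfg$rate_mean, cfg$rate_sd),
                  nrow = n, ncol = 4L, dimnames = list(NULL, CATEGORIES))
  pref_idx <- match(preferred, CATEGORIES)
  if (cfg$preference_boost != 0) {
    rates[cbind(seq_len(n), pref_idx)] <-
      rtrunc_norm(n, cfg$rate_mean + cfg$preference_boost, cfg$rate_sd)
  }
  # swap the row maximum into the preferred slot
  max_idx <- max.col(rates, ties.method = "first")
  row_i <- seq_len(n)
  pref_val <- rates[cbind(row_i, pref_idx)]
  max_val <- rates[cbind(row_i, max_idx)]
  rates[cbind(row_i, max_idx)] <- pref_val
  rates[cbind(row_i, pref_idx)] <- max_val
  beta <- stats::runif(n, cfg$beta_range[1], cfg$beta_range[2])
  neuron_population(preferred, rates, beta, config = cfg)
}

# normal draws truncated at 0 by redraw (negligible rejection at 30 +/- 10)
rtrunc_norm <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(neg <- x < 0)) {
    x[neg] <- stats::rnorm(sum(neg), mean, sd)
  }
  x
}

# per-neuron multiplicative modulation earned by attending `attended`
attention_factor <- function(pop, attended, mechanism) {
  switch(mechanism,
         gain = pop$beta,
         tuning = pop$beta * pop$rates[, attended] / pop$rmax,
         labeled_line = ifelse(pop$preferred == attended, pop$beta, 1))
}

#' Neuron response to an attended isolated stimulus
#'
#' Response of each neuron when `attended` is presented alone and
#' attended, under the given mechanism: gain scales the baseline rate by
#' the neuron's attention factor `beta`; tuning sharpening scales it by
#' `beta * s` with selectivity `s = R(attended) / Rmax` (so optimal
#' stimuli are strongly enhanced and non-optimal ones can be
#' suppressed); labeled line applies `beta` only when the attended
#' stimulus is the neuron's preferred one.
#'
#' @param pop A [neuron_population()] (a single neuron is a population
#'   of one).
#' @param attended Attended category.
#' @param mechanism Mechanism override; defaults to the population
#'   config's.
#' @return Numeric vector of per-neuron rates (spikes/s).
#' @export
attended_rate <- function(pop, attended,
                          mechanism = pop$config$mechanism) {
  stopifnot(inherits(pop, "neuron_population"))
  assert_category(attended)
  mechanism <- match.arg(mechanism, c("gain", "tuning", "labeled_line"))
  unname(attention_factor(pop, attended, mechanism) * pop$rates[, attended])
}

#' Neuron response to one task condition
#'
#' Isolated conditions reduce to [attended_rate()]. For paired
#' conditions the two stimulus drives are combined by
#' `pair_combination` (`"average"` default, `"sum"` optional) and the
#' attentional modulation earned by the attended stimulus is applied
#' according to `modulation`: with `"response"` (default) the factor
#' multiplies the combined response — so a pure gain factor modulates
#' the pair identically whichever member is attended, while tuning and
#' labeled-line factors depend on which stimulus is attended; with
#' `"stimulus"` the factor multiplies only the attended component and
#' the ignored component enters at its unmodulated baseline.
#'
#' @inheritParams attended_rate
#' @param ignored Ignored category, or `"none"` for an isolated
#'   condition.
#' @param pair_combination,modulation Overrides of the config settings.
#' @return Numeric vector of per-neuron rates (non-negative).
#' @export
condition_rate <- function(pop, attended, ignored = NONE,
                           mechanism = pop$config$mechanism,
                           pair_combination = pop$config$pair_combination,
                           modulation = pop$config$modulation) {
  stopifnot(inherits(pop, "neuron_population"))
  mechanism <- match.arg(mechanism, c("gain", "tuning", "labeled_line"))
  if (identical(ignored, NONE) || is.null(ignored)) {
    return(attended_rate(pop, attended, mechanism))
  }
  pair_combination <- match.arg(pair_combination, c("average", "sum"))
  modulation <- match.arg(modulation, c("response", "stimulus"))
  assert_category(attended); assert_category(ignored)
  stopifnot(attended != ignored)
  combine <- function(x, y) {
    if (pair_combination == "average") (x + y) / 2 else x + y
  }
  g <- attention_factor(pop, attended, mechanism)
  if (modulation == "response") {
    unname(g * combine(pop$rates[, attended], pop$rates[, ignored]))
  } else {
    unname(combine(g * pop$rates[, attended], pop$rates[, ignored]))
  }
}

# neuron x 16 matrix of noiseless condition rates
condition_rate_matrix <- function(pop, cfg = pop$config) {
  ct <- condition_table()
  out <- vapply(seq_len(nrow(ct)), function(i) {
    condition_rate(pop, ct$attended[i], ct$ignored[i],
                   mechanism = cfg$mechanism,
                   pair_combination = cfg$pair_combination,
                   modulation = cfg$modulation)
  }, numeric(length(pop$beta)))
  colnames(out) <- ct$condition
  out
}

#' Apply spiking noise to rates
#'
#' Poisson noise replaces each rate by an independent Poisson draw with
#' that mean (one draw per neuron per condition); `"none"` is the
#' identity.
#'
#' @param rate Non-negative numeric vector (or matrix) of rates.
#' @param noise `"poisson"` or `"none"`.
#' @return Noisy rates with the same shape.
#' @export
apply_noise <- function(rate, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  stopifnot(all(rate >= 0))
  if (noise == "none") return(rate)
  out <- stats::rpois(length(rate), rate)
  if (!is.null(dim(rate))) dim(out) <- dim(rate)
  out
}

# sample the neuron membership of every voxel: neurons of one preference
# per voxel, without replacement within a voxel
voxel_membership <- function(pop, cfg = pop$config) {
  nv <- cfg$n_voxels
  npv <- cfg$neurons_per_voxel
  voxel_cat <- if (cfg$population_kind == "object_selective") {
    rep(CATEGORIES, each = nv / 4L)
  } else {
    rep(cfg$selective_category, nv)
  }
  by_cat <- split(seq_along(pop$preferred), pop$preferred)
  mem <- matrix(0L, nrow = nv, ncol = npv)
  for (v in seq_len(nv)) {
    avail <- by_cat[[voxel_cat[v]]]
    if (length(avail) < npv) {
      stop(sprintf("not enough %s-selective neurons (%d) for a voxel of %d",
                   voxel_cat[v], length(avail), npv), call. = FALSE)
    }
    mem[v, ] <- sample(avail, npv)
  }
  attr(mem, "voxel_category") <- voxel_cat
  mem
}

#' Form simulated voxels from a population
#'
#' Each voxel averages the (optionally Poisson-noisy) condition rates of
#' a random sample of similarly selective neurons. An object-selective
#' population builds equal numbers of voxels of every preference; a
#' category-selective population builds all voxels from its selective
#' category.
#'
#' @param pop A [neuron_population()] built from a config.
#' @param cfg The [population_config()] (defaults to the one attached to
#'   `pop`).
#' @param membership Optional precomputed `voxel x neuron` index matrix
#'   (reused across runs by [simulate_dataset()]).
#' @return Numeric `voxel x condition` matrix (16 columns); attribute
#'   `membership` stores the neuron sample of each voxel.
#' @export
form_voxels <- function(pop, cfg = pop$config, membership = NULL) {
  stopifnot(inherits(pop, "neuron_population"),
            inherits(cfg, "population_config"))
  if (is.null(membership)) membership <- voxel_membership(pop, cfg)
  rates16 <- condition_rate_matrix(pop, cfg)
  nv <- nrow(membership)
  idx <- as.vector(membership)
  out <- matrix(vapply(seq_len(ncol(rates16)), function(ci) {
    lam <- rates16[idx, ci]
    rowMeans(matrix(apply_noise(lam, cfg$noise), nrow = nv))
  }, numeric(nv)), nrow = nv,
  dimnames = list(paste0("v", seq_len(nv)), colnames(rates16)))
  attr(out, "membership") <- membership
  out
}

#' Simulate a multi-run, multi-participant fMRI-like dataset
#'
#' Builds an independent population per simulated participant, fixes the
#' voxel memberships, and emits one [roi_dataset()] per participant with
#' independent spiking-noise draws per run plus additive Gaussian
#' measurement noise on voxel values. The output is structurally
#' identical to [read_beta_table()]'s, so the whole analysis pipeline
#' runs on it unmodified. Identical seeds give bit-identical datasets.
#'
#' @param cfg A [population_config()]; its `seed` governs all
#'   randomness.
#' @param n_participants Number of simulated participants (study scale:
#'   17).
#' @param n_runs Runs per participant (study scale: 12-16; >= 2 allows
#'   [split_runs()]).
#' @param run_noise_sd SD (beta units) of i.i.d. Gaussian measurement
#'   noise added to every voxel x condition value of every run
#'   (default 0: the simulated populations' only stated noise source is
#'   Poisson spiking).
#' @param att_noise_sd SD of an optional attention-state noise
#'   component: one Gaussian draw per voxel x run x attended category,
#'   added to every condition sharing that attended category. It models
#'   run-to-run fluctuations of attentional engagement that correlate
#'   conditions with a common attention target (as GLM betas estimated
#'   from common runs do) and is off (0) by default.
#' @return Named list of `roi_dataset` objects, one per participant;
#'   ROI name is the population kind.
#' @export
simulate_dataset <- function(cfg, n_participants = 17, n_runs = 12,
                             run_noise_sd = 0, att_noise_sd = 0) {
  stopifnot(inherits(cfg, "population_config"), n_participants >= 1,
            n_runs >= 1, run_noise_sd >= 0, att_noise_sd >= 0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_stream <- cfg
  cfg_stream$seed <- NULL  # participants share one RNG stream
  ct <- condition_table()
  att_col <- match(ct$attended, CATEGORIES)
  out <- lapply(seq_len(n_participants), function(p) {
    pop <- build_population(cfg_stream)
    mem <- voxel_membership(pop, cfg_stream)
    runs <- lapply(seq_len(n_runs), function(r) {
      vm <- form_voxels(pop, cfg_stream, membership = mem)
      if (att_noise_sd > 0) {
        eta <- matrix(stats::rnorm(nrow(vm) * 4L, 0, att_noise_sd),
                      nrow = nrow(vm))
        vm <- vm + eta[, att_col]
      }
      if (run_noise_sd > 0) {
        vm <- vm + stats::rnorm(length(vm), 0, run_noise_sd)
      }
      vm
    })
    arr <- array(unlist(runs, use.names = FALSE),
                 dim = c(nrow(runs[[1]]), ncol(runs[[1]]), n_runs),
                 dimnames = list(rownames(runs[[1]]), colnames(runs[[1]]),
                                 sprintf("run%02d", seq_len(n_runs))))
    roi_dataset(arr, participant = sprintf("sim%02d", p),
                roi = cfg$population_kind)
  })
  names(out) <- vapply(out, function(d) paste(d$participant, d$roi, sep = "/"),
                       character(1))
  out
}
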