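# Population construction, mechanism arithmetic, noise, voxelization,
# and dataset emission.

test_that("population construction honours proportions and preferences", {
  cfg <- population_config(n_neurons = 4000, neurons_per_voxel = 100,
                           n_voxels = 8, seed = 1)
  pop <- build_population(cfg)
  expect_equal(as.vector(table(pop$preferred)), rep(1000, 4))
  # preferred-category rate is the row maximum for every neuron
  pref_rate <- pop$rates[cbind(seq_len(4000),
                               match(pop$preferred, categories()))]
  expect_equal(pref_rate, apply(pop$rates, 1, max))
  expect_true(all(pop$beta >= 1 & pop$beta <= 10))
  expect_true(all(pop$rates >= 0))

  catsel <- build_population(population_config(
    n_neurons = 1000, neurons_per_voxel = 100, n_voxels = 5,
    population_kind = "category_selective", selective_category = "house",
    seed = 2))
  expect_true(all(catsel$preferred == "house"))
})

test_that("drawn rates match the truncated-normal moments", {
  cfg <- population_config(n_neurons = 4e5, neurons_per_voxel = 100,
                           n_voxels = 4, seed = 3)
  pop <- build_population(cfg)
  # closed-form moments of N(30, 10) truncated at 0 (alpha = -3):
  # mean = mu + sd * lambda(alpha), lambda = phi(-3) / (1 - Phi(-3))
  lam <- dnorm(-3) / (1 - pnorm(-3))
  m_expect <- 30 + 10 * lam
  v_expect <- 100 * (1 + (-3) * lam - lam^2)
  expect_equal(mean(pop$rates), m_expect, tolerance = 0.005)
  expect_equal(var(as.vector(pop$rates)), v_expect, tolerance = 0.01)
})

test_that("attended rates implement gain, tuning, and labeled line", {
  rates <- c(body = 20, car = 25, cat = 40, house = 10)
  nrn <- one_neuron(rates, preferred = "cat", beta = 2)
  # gain: beta scales every attended response
  expect_equal(attended_rate(nrn, "house", "gain"), 20)
  expect_equal(attended_rate(nrn, "cat", "gain"), 80)
  # tuning: beta * (R / Rmax) * R; optimal stimulus doubled, weak one
  # suppressed below baseline (2 * 0.25 * 10 = 5 < 10)
  expect_equal(attended_rate(nrn, "cat", "tuning"), 80)
  expect_equal(attended_rate(nrn, "house", "tuning"), 5)
  # labeled line: enhancement only for the preferred stimulus
  expect_equal(attended_rate(nrn, "house", "labeled_line"), 10)
  expect_equal(attended_rate(nrn, "cat", "labeled_line"), 80)
})

test_that("mechanisms reshape tuning curves as intended", {
  cfg <- population_config(n_neurons = 400, neurons_per_voxel = 10,
                           n_voxels = 4, seed = 4)
  pop <- build_population(cfg)
  ratio <- function(mech, att) attended_rate(pop, att, mech) / pop$rates[, att]
  # gain preserves tuning-curve shape: ratio == beta for every category
  for (ctg in categories()) expect_equal(ratio("gain", ctg), pop$beta)
  # tuning sharpening: enhancement strictly increases with the baseline
  for (i in sample(400, 30)) {
    ord <- order(pop$rates[i, ])
    rr <- vapply(categories()[ord], function(ctg) ratio("tuning", ctg)[i],
                 numeric(1))
    expect_true(all(diff(rr) > 0))
  }
  # labeled line departs from baseline only at the preferred category
  for (ctg in categories()) {
    r <- attended_rate(pop, ctg, "labeled_line")
    changed <- r != pop$rates[, ctg]
    expect_equal(changed, pop$preferred == ctg & pop$beta != 1)
  }
})

test_that("condition rates combine pairs under both scopes", {
  rates <- c(body = 40, car = 20, cat = 35, house = 10)
  nrn <- one_neuron(rates, preferred = "body", beta = 2)
  # isolated conditions are the attended rate by definition
  expect_equal(condition_rate(nrn, "body", mechanism = "gain",
                              pair_combination = "average",
                              modulation = "response"),
               attended_rate(nrn, "body", "gain"))
  # stimulus-scope: modulated attended component (80) averaged/summed with
  # the ignored baseline (20)
  expect_equal(condition_rate(nrn, "body", "car", mechanism = "gain",
                              pair_combination = "average",
                              modulation = "stimulus"), 50)
  expect_equal(condition_rate(nrn, "body", "car", mechanism = "gain",
                              pair_combination = "sum",
                              modulation = "stimulus"), 100)
  # response-scope: the attention factor scales the combined drive, so a
  # pure gain factor modulates the pair the same whichever member is
  # attended
  expect_equal(condition_rate(nrn, "body", "car", mechanism = "gain",
                              pair_combination = "average",
                              modulation = "response"), 60)
  expect_equal(condition_rate(nrn, "car", "body", mechanism = "gain",
                              pair_combination = "average",
                              modulation = "response"), 60)
  # ...while the tuning factor depends on which member is attended
  t_att_body <- condition_rate(nrn, "body", "car", mechanism = "tuning",
                               pair_combination = "average",
                               modulation = "response")
  t_att_car <- condition_rate(nrn, "car", "body", mechanism = "tuning",
                              pair_combination = "average",
                              modulation = "response")
  expect_equal(t_att_body, 2 * 1 * 30)
  expect_equal(t_att_car, 2 * 0.5 * 30)
  expect_gt(t_att_body, t_att_car)
})

test_that("poisson noise has matching mean and variance; none is identity", {
  expect_equal(apply_noise(numeric(10), "poisson"), rep(0, 10))
  x <- runif(5, 0, 100)
  expect_identical(apply_noise(x, "none"), x)
  set.seed(6)
  draws <- apply_noise(rep(30, 1e5), "poisson")
  se_mean <- sqrt(30 / 1e5)
  expect_lt(abs(mean(draws) - 30), 3 * se_mean)
  se_var <- sqrt(2 * 30^2 / 1e5 + 30 / 1e5)  # approx SE of Poisson variance
  expect_lt(abs(var(draws) - 30), 4 * se_var)
})

test_that("voxels average their sampled neurons", {
  # degenerate voxel of identical neurons reproduces the neuron profile
  rates <- matrix(rep(c(30, 20, 25, 10), each = 50), ncol = 4,
                  dimnames = list(NULL, c("body", "car", "cat", "house")))
  pop <- neuron_population(rep("body", 50), rates, rep(2, 50),
                           config = population_config(
                             n_neurons = 50, neurons_per_voxel = 50,
                             n_voxels = 1,
                             population_kind = "category_selective",
                             mechanism = "gain", noise = "none", seed = 8))
  vm <- form_voxels(pop)
  expect_equal(dim(vm), c(1, 16))
  expect_equal(unname(vm[1, "body.none"]), 60)

  # voxel means equal brute-force recomputation from the stored sample
  cfg <- population_config(n_neurons = 400, neurons_per_voxel = 20,
                           n_voxels = 8, mechanism = "tuning",
                           noise = "none", seed = 9)
  pop <- build_population(cfg)
  vm <- form_voxels(pop)
  mem <- attr(vm, "membership")
  for (v in c(1, 5, 8)) {
    sub <- neuron_population(pop$preferred[mem[v, ]],
                             pop$rates[mem[v, ], ], pop$beta[mem[v, ]],
                             config = cfg)
    for (cond in c("cat.none", "body.house")) {
      ct <- condition_table()
      i <- match(cond, ct$condition)
      expect_equal(unname(vm[v, cond]),
                   mean(condition_rate(sub, ct$attended[i], ct$ignored[i])))
    }
  }
  # object-selective voxel counts split equally over preferences
  expect_equal(as.vector(table(attr(mem, "voxel_category"))), rep(2, 4))
})

test_that("simulated datasets are reproducible and splittable", {
  cfg <- population_config(n_neurons = 800, neurons_per_voxel = 20,
                           n_voxels = 8, mechanism = "tuning", seed = 10)
  a <- simulate_dataset(cfg, n_participants = 2, n_runs = 3)
  b <- simulate_dataset(cfg, n_participants = 2, n_runs = 3)
  expect_identical(a, b)
  expect_length(a, 2)
  expect_equal(n_runs(a[[1]]), 3)
  expect_s3_class(split_runs(a[[1]])$half1, "roi_dataset")
  # different participants get different populations
  expect_false(identical(a[[1]]$betas, a[[2]]$betas))

  # no spiking noise, no measurement noise -> identical runs
  cfg0 <- population_config(n_neurons = 800, neurons_per_voxel = 20,
                            n_voxels = 8, noise = "none", seed = 11)
  d0 <- simulate_dataset(cfg0, n_participants = 1, n_runs = 3,
                         run_noise_sd = 0)
  expect_equal(d0[[1]]$betas[, , 1], d0[[1]]$betas[, , 2])
  expect_equal(d0[[1]]$betas[, , 1], d0[[1]]$betas[, , 3])

  # emitted tables round-trip through the reader
  p <- tempfile(fileext = ".csv")
  write_beta_table(a, p)
  back <- read_beta_table(p)
  expect_equal(back[[1]]$betas, a[[1]]$betas)
})

test_that("tuning data show larger shifts for more distant pairs", {
  cfg <- population_config(n_neurons = 4000, neurons_per_voxel = 50,
                           n_voxels = 40, mechanism = "tuning",
                           population_kind = "category_selective",
                           seed = 12)
  ds <- simulate_dataset(cfg, n_participants = 8, n_runs = 4)
  uni <- analyze_univariate(ds)
  rho <- vapply(split(uni, uni$participant), function(g) {
    cor(g$distance, g$shift, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho), 0)
})
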