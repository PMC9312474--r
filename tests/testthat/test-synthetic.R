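test_that("the default design yields one record per transect pass, reproducibly", {
  cfg <- simulation_config(seed = 9, n_species = 3)
  sim <- simulate_study(cfg)
  expect_length(sim$records, 540)
  expect_identical(length(sim$records), as.integer(n_observations(cfg$design)))
  meta <- transectvar:::.records_meta(sim$records)
  expect_equal(length(unique(meta$transect)), 30)
  expect_true(all(table(meta$transect) == 18))
  ## same seed, same study, bit for bit
  sim2 <- simulate_study(simulation_config(seed = 9, n_species = 3))
  expect_identical(sim$truth$eta, sim2$truth$eta)
  expect_identical(sim$records[[17]]$events, sim2$records[[17]]$events)
  ## adding species leaves the earlier species' draws untouched
  tr4 <- default_species_traits(4, seed = 9)
  sim3 <- simulate_study(simulation_config(seed = 9, traits = tr4[1:3, ]))
  sim4 <- simulate_study(simulation_config(seed = 9, traits = tr4))
  expect_identical(sim3$truth$eta, sim4$truth$eta[, 1:3])
})

test_that("a degenerate configuration reduces to pure Poisson counting noise", {
  des <- study_design(2, 2, 2, 3, 3)
  cfg <- simulation_config(design = des, sigma2 = zero_sigma2, seed = 21,
                           traits = flat_traits(6), turbidity = 0)
  sim <- simulate_study(cfg)
  cm <- community_matrix(sim$records, "max_count",
                         species = cfg$traits$species)
  ## every pass of every transect has the same expected count lambda = 4;
  ## dispersion index within transect should be ~1 (Poisson)
  di <- unlist(lapply(split(seq_len(nrow(cm$counts)),
                            cm$row_meta$transect), function(ix)
    apply(cm$counts[ix, ], 2, function(v) var(v) / mean(v))))
  expect_equal(mean(di), 1, tolerance = 0.1)
  expect_equal(mean(cm$counts), 4, tolerance = 0.15)
})

test_that("the COM-Poisson sampler matches its pmf and known limits", {
  set.seed(1)
  ## nu = 1 is Poisson: mean within 3 Monte-Carlo SE
  y <- rcompois(2e4, lambda = 3, nu = 1)
  expect_lt(abs(mean(y) - 3), 3 * sqrt(3 / 2e4))
  ## strong underdispersion with lambda < 1: mass concentrates on {0, 1}
  y2 <- rcompois(5e3, lambda = 0.8, nu = 8)
  expect_gt(mean(y2 %in% c(0, 1)), 0.99)
  ## empirical pmf at (2, 0.7) matches brute-force normalization
  y3 <- rcompois(4e4, lambda = 2, nu = 0.7)
  for (v in 0:6) {
    p_true <- compois_pmf_oracle(v, 2, 0.7)
    mc_se <- sqrt(p_true * (1 - p_true) / 4e4)
    expect_lt(abs(mean(y3 == v) - p_true), 4 * mc_se + 1e-4)
  }
})

test_that("trait priors give the one-third underdispersed mix and matching counts", {
  tr <- default_species_traits(36, seed = 4)
  expect_equal(sum(tr$nu > 1), 12)
  expect_equal(sum(tr$nu < 1), 24)
  ## generated dispersion separates the two groups
  traits <- flat_traits(10, base = log(6))
  traits$nu <- rep(c(0.5, 2), each = 5)
  cfg <- simulation_config(design = study_design(1, 1, 2, 3, 6),
                           sigma2 = zero_sigma2, seed = 8,
                           traits = traits, turbidity = 0)
  cm <- community_matrix(simulate_study(cfg)$records, species = traits$species)
  di <- apply(cm$counts, 2, function(v) var(v) / mean(v))
  expect_gt(mean(di[1:5]), 1)     # overdispersed group
  expect_lt(mean(di[6:10]), 1)    # underdispersed group
  expect_gt(mean(di[1:5]), mean(di[6:10]))
})

test_that("order effects tilt detection across passes in the injected direction", {
  base <- flat_traits(2, base = log(1.2))
  base$detectability <- 0.6
  base$gamma_order <- c(-0.4, 0.4)
  cfg <- simulation_config(design = study_design(2, 2, 2, 3, 3),
                           sigma2 = zero_sigma2, seed = 13, traits = base,
                           turbidity = 0)
  cm <- community_matrix(simulate_study(cfg)$records, "presence_absence",
                         species = base$species)
  first <- cm$row_meta$order_index <= 3
  last <- cm$row_meta$order_index >= 7
  ## deterred species seen more early, attracted species more late
  expect_gt(mean(cm$counts[first, 1]), mean(cm$counts[last, 1]))
  expect_lt(mean(cm$counts[first, 2]), mean(cm$counts[last, 2]))
})

test_that("turbidity sensitivity lowers detected counts monotonically", {
  tr0 <- flat_traits(5, base = log(5)); tr0$detectability <- 0.8
  tr1 <- tr0; tr1$turbidity_sensitivity <- 0.6
  des <- study_design(2, 2, 2, 3, 3)
  mean_count <- function(traits) {
    cfg <- simulation_config(design = des, sigma2 = zero_sigma2, seed = 31,
                             traits = traits, turbidity = c(1, 2, 3))
    mean(community_matrix(simulate_study(cfg)$records,
                          species = traits$species)$counts)
  }
  expect_lt(mean_count(tr1), mean_count(tr0))
  ## negative variance is rejected up front
  expect_error(simulation_config(sigma2 = c(location = -1, transect = 0,
                                            observer = 0,
                                            observer_location = 0,
                                            observer_transect = 0,
                                            residual = 0)),
               ">= 0")
})
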