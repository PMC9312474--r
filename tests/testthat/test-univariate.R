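full_fac <- design_factors(study_design())

test_that("ICC tables satisfy the decomposition identities exactly", {
  ## single factor, equal variances: 0.5 / 0.5
  t1 <- icc_table(c(Location = 1, Residual = 1))
  expect_equal(unname(t1$icc["Location"]), 0.5)
  expect_equal(t1$icc_residual, 0.5)
  ## identities on random inputs, to numerical precision
  set.seed(8)
  for (i in 1:25) {
    s2 <- stats::setNames(runif(6), c(transectvar:::.re_names, "Residual"))
    tt <- icc_table(s2)
    expect_equal(sum(tt$icc), tt$icc_total, tolerance = 1e-12)
    expect_equal(tt$icc_total + tt$icc_residual, 1, tolerance = 1e-12)
    expect_equal(tt$icc_sampling,
                 tt$icc_residual + tt$icc[["Observer:Transect"]] +
                   tt$icc[["Observer:Location"]], tolerance = 1e-12)
    expect_true(all(tt$icc >= 0 & tt$icc <= 1))
  }
  ## all-zero variances: undefined, flagged
  t0 <- icc_table(stats::setNames(numeric(6),
                                  c(transectvar:::.re_names, "Residual")))
  expect_true(t0$undefined)
  expect_error(icc_table(c(Location = -1, Residual = 1)), ">= 0")
})

test_that("reported component ICCs compose into the sampling-variability ICC", {
  ## species density at 50 m and Shannon diversity at 10 m
  expect_equal(icc_sampling(0.662, 0.099, 0.007), 0.444, tolerance = 1e-12)
  expect_equal(icc_sampling(0.436, 0.082, 0.065), 0.711, tolerance = 1e-12)
})

test_that("method-of-moments components match the one-way closed form", {
  set.seed(12)
  g <- rep(paste0("G", 1:6), each = 30)
  y <- rnorm(180) + rnorm(6, 0, 1.5)[as.integer(factor(g))]
  terms <- list(list(label = "Group", factors = "g", live = "g",
                     random = TRUE))
  tab <- permanova(dist(y), data = data.frame(g = g), terms = terms,
                   n_perm = 0)
  a <- anova(lm(y ~ g))
  msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
  expect_equal(tab$sigma2[tab$term == "Group"], (msb - msw) / 30,
               tolerance = 1e-6)
  expect_equal(tab$sigma2[tab$term == "Residual"], msw, tolerance = 1e-6)
})

test_that("constant responses give all-zero components", {
  f <- fit_lmm(rep(2, nrow(full_fac)), full_fac, method = "anova")
  expect_equal(unname(f$sigma2), rep(0, 6))
})

test_that("REML and ANOVA estimators agree on balanced data with interior optima", {
  set.seed(3)
  fac <- full_fac
  y <- rnorm(540, sd = 1) +
    rnorm(10, 0, 1)[as.integer(factor(fac$location))] +
    rnorm(30, 0, 0.8)[as.integer(factor(fac$transect))] +
    rnorm(3, 0, 0.5)[as.integer(factor(fac$observer))] +
    rnorm(30, 0, 0.4)[as.integer(interaction(fac$observer, fac$location))] +
    rnorm(90, 0, 0.4)[as.integer(interaction(fac$observer, fac$transect))]
  fa <- fit_lmm(y, fac, method = "anova")
  fr <- fit_lmm(y, fac, method = "reml")
  expect_true(fr$converged)
  expect_equal(fa$sigma2, fr$sigma2, tolerance = 1e-3)
  ## ICC built from either route agrees
  expect_equal(icc_table(fa)$icc_sampling, icc_table(fr)$icc_sampling,
               tolerance = 1e-3)
})

test_that("single-dataset variance recovery lands near the injected truth", {
  set.seed(21)
  fac <- full_fac
  y <- rnorm(540, sd = 1) +
    rnorm(10, 0, 1)[as.integer(factor(fac$location))] +
    rnorm(30, 0, sqrt(0.5))[as.integer(factor(fac$transect))]
  f <- fit_lmm(y, fac, method = "anova")
  expect_equal(unname(f$sigma2["Location"]), 1, tolerance = 0.75)
  expect_equal(unname(f$sigma2["Transect"]), 0.5, tolerance = 0.5)
  expect_equal(unname(f$sigma2["Residual"]), 1, tolerance = 0.15)
  expect_lt(f$sigma2["Observer"], 0.1)
})

test_that("the COM-Poisson log-pmf matches Poisson and brute-force normalization", {
  for (lam in c(0.5, 2, 10))
    expect_equal(com_poisson_logpmf(0:50, lam, 1), dpois(0:50, lam, log = TRUE),
                 tolerance = 1e-12)
  ## probabilities sum to one
  for (nu in c(0.5, 1, 2))
    expect_equal(sum(exp(com_poisson_logpmf(0:400, 2, nu))), 1,
                 tolerance = 1e-10)
  ## brute-force series oracle at (y = 3, lambda = 2, nu = 0.5)
  expect_equal(exp(com_poisson_logpmf(3, 2, 0.5)),
               compois_pmf_oracle(3, 2, 0.5), tolerance = 1e-10)
  expect_error(com_poisson_logpmf(-1, 2, 1))
})

test_that("zero-inflated COM-Poisson fits recover Poisson data and survive degenerate input", {
  set.seed(9)
  fac <- design_factors(study_design(2, 5, 3, 1, 6))   # 180 obs, no observer
  loc_re <- rnorm(10, 0, 0.3)[as.integer(factor(fac$location))]
  y <- rpois(nrow(fac), exp(1 + loc_re))
  f <- fit_zicomp_glmm(y, fac, family = "compois", random = "Location")
  expect_true(f$converged)
  expect_equal(f$nu, 1, tolerance = 0.35)
  expect_lt(f$pi, 0.08)
  expect_equal(unname(f$coefficients["(Intercept)"]), 1, tolerance = 0.3)
  ## all counts zero except one: flagged, no crash
  y0 <- c(3L, rep(0L, nrow(fac) - 1))
  f0 <- fit_zicomp_glmm(y0, fac, family = "compois", random = "Location")
  expect_true(f0$boundary || !f0$converged)
  expect_error(fit_zicomp_glmm(rep(0L, 10), fac[1:10, ]), "all counts")
})

test_that("AIC family comparison orders candidate count distributions", {
  set.seed(14)
  fac <- design_factors(study_design(1, 2, 3, 1, 6))   # 36 obs
  y <- rpois(36, 4)
  cmp <- compare_count_families(y, fac, zero_inflation = FALSE,
                                random = "Location")
  expect_equal(nrow(cmp), 3)
  expect_true(!is.unsorted(cmp$AIC, na.rm = TRUE))
  expect_true(all(c("poisson", "nbinom2", "compois") %in% cmp$family))
})
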