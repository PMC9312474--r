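test_that("SE/mean ratios hit their deterministic endpoints", {
  ## constant nonzero series: zero SD, ratio 0 for all k
  v <- rep(5, 36); tr <- rep(c("T1", "T2"), each = 18)
  for (k in c(2, 9, 18)) {
    pt <- univariate_precision(v, tr, k, n_sim = 20, seed = 1)
    expect_equal(pt$estimate, 0)
    expect_equal(pt$n_excluded, 0L)
  }
  expect_error(univariate_precision(v, tr, 1), "k must be >= 2")
  ## zero-mean draws are excluded and counted, never NaN
  v2 <- c(rep(0, 16), 3, 4, rep(5, 18))
  pt2 <- univariate_precision(v2, tr, 2, n_sim = 200, seed = 2)
  expect_gt(pt2$n_excluded, 0)
  expect_true(is.finite(pt2$estimate))
})

test_that("the ratio shrinks with k like the analytic sqrt(k) scaling", {
  set.seed(6)
  tr <- rep(sprintf("T%02d", 1:12), each = 18)
  v <- rlnorm(length(tr), log(8), 0.4)
  est <- vapply(c(2, 4, 8, 16), function(k)
    univariate_precision(v, tr, k, n_sim = 400, seed = 3)$estimate, 0)
  expect_true(all(diff(est) < 0))
  ## against the analytic i.i.d. expectation (sd/mean)/sqrt(k)
  analytic <- (sd(v) / mean(v)) / sqrt(c(2, 4, 8, 16))
  expect_equal(est / analytic, rep(1, 4), tolerance = 0.25)
  ## CI contains the mean estimate
  pt <- univariate_precision(v, tr, 4, n_sim = 200, seed = 4)
  expect_true(pt$ci_lo <= pt$estimate && pt$estimate <= pt$ci_hi)
})

test_that("matched swim distance comparison reports minima and ties", {
  curve <- data.frame(length_m = c(10, 20, 10, 20),
                      repeats = c(4, 2, 2, 4),
                      distance_m = c(40, 40, 20, 80),
                      estimate = c(0.2, 0.2, 0.5, 0.1))
  cmp <- precision_vs_swim_distance(curve)
  expect_equal(cmp$n_tied[cmp$distance_m == 40], c(2, 2))  # exact tie kept
  expect_equal(nrow(cmp[cmp$distance_m == 20, ]), 1)
  ## single-length input degenerates to that curve
  single <- curve[curve$length_m == 10, ]
  expect_equal(nrow(precision_vs_swim_distance(single)), nrow(single))
})

test_that("turbidity terciles split 30 transects into groups of 10", {
  sim <- simulate_study(simulation_config(seed = 2, n_species = 6))
  meta <- transectvar:::.records_meta(sim$records)
  turb <- tapply(meta$turbidity, meta$transect, `[`, 1)
  r <- rank(turb, ties.method = "first")
  expect_equal(as.integer(table(ceiling(3 * r / 30))), rep(10L, 3))
  out <- turbidity_stratified_precision(sim$records, lengths = 50,
                                        ks = c(2, 6), n_sim = 30, seed = 1)
  expect_equal(sort(unique(out$tercile)), c("high", "low", "mid"))
  expect_equal(nrow(out), 6)
})

test_that("multSE equals the classical within-group answer on Euclidean data", {
  set.seed(11)
  tr <- rep(c("T1", "T2", "T3"), each = 6)
  y <- rnorm(18, 10, 2)
  meta <- data.frame(transect = tr)
  ## k = all observations per transect: subsampling is the identity, so
  ## multSE = sqrt(MS_within / k) exactly
  pt <- mult_se(as.matrix(dist(y)), meta, k = 6, n_sim = 5, seed = 1)
  msw <- anova(lm(y ~ tr))$`Mean Sq`[2]
  expect_equal(pt$estimate, sqrt(msw / 6), tolerance = 1e-10)
  expect_equal(sd(pt$draws), 0)
  ## identical observations within transects: zero residual
  y0 <- rep(c(1, 5, 9), each = 6)
  pt0 <- mult_se(as.matrix(dist(y0)), meta, k = 3, n_sim = 10, seed = 1)
  expect_equal(pt0$estimate, 0)
  ## doubling the within-transect spread doubles multSE
  mu <- ave(y, tr)
  y2 <- mu + 2 * (y - mu)
  pt2 <- mult_se(as.matrix(dist(y2)), meta, k = 6, n_sim = 5, seed = 1)
  expect_equal(pt2$estimate, 2 * pt$estimate, tolerance = 1e-10)
  expect_error(mult_se(as.matrix(dist(y)), meta, k = 1), "k must be >= 2")
})

test_that("multSE decreases with the number of repeats on i.i.d. data", {
  set.seed(13)
  tr <- rep(sprintf("T%02d", 1:10), each = 18)
  cm <- matrix(rpois(180 * 8, 5), 180, 8)
  D <- dissimilarity(cm^0.25, "bray_curtis")
  meta <- data.frame(transect = tr)
  est <- vapply(c(2, 6, 12, 18), function(k)
    mult_se(D, meta, k = k, n_sim = 100, seed = 5)$estimate, 0)
  expect_true(all(diff(est) < 0))
  ## roughly the 1/sqrt(k) envelope
  expect_equal(est[1] / est[4], sqrt(18 / 2), tolerance = 0.35)
})
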