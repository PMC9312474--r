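test_that("the per-transect ACF matches its defining formula", {
  expect_equal(as.numeric(species_acf(c(1, 2, 3, 4), max_lag = 1)),
               c(1, 0.25))  # numerator 1.25, denominator 5
  r <- species_acf(c(3, 3, 3, 3), max_lag = 2)
  expect_true(all(is.na(r)))
  expect_true(attr(r, "undefined"))
  expect_error(species_acf(c(1), max_lag = 0), "length >= 2")
  expect_error(species_acf(1:5, max_lag = 5), "K < n")
  ## any non-constant series has r_0 = 1; brute-force oracle on random series
  set.seed(42)
  for (i in 1:100) {
    y <- rpois(sample(5:18, 1), 2)
    if (var(y) == 0) next
    K <- length(y) - 1
    r <- species_acf(y, K)
    expect_equal(unname(r[1]), 1)
    for (k in 0:K) expect_equal(unname(r[k + 1]), acf_oracle(y, k),
                                tolerance = 1e-12)
  }
})

test_that("the mean ACF averages only over transects where it is defined", {
  a <- species_acf(c(1, 2, 3, 4), 1)   # r_1 = 0.25
  b <- species_acf(c(4, 3, 2, 1), 1)
  cst <- species_acf(c(2, 2, 2, 2), 1)
  m <- mean_acf(list(a, a))
  expect_equal(m$mean_r, as.numeric(a))   # idempotent
  m2 <- mean_acf(list(a, cst))
  expect_equal(m2$mean_r[2], 0.25)        # the defined transect only
  expect_equal(m2$n, c(1L, 1L))
  two <- mean_acf(list(
    structure(c(`0` = 1, `1` = 0.2), undefined = FALSE),
    structure(c(`0` = 1, `1` = 0.4), undefined = FALSE)))
  expect_equal(two$mean_r[2], 0.3)
  m3 <- mean_acf(list(cst, cst))
  expect_true(is.na(m3$mean_r[1]))
})

test_that("order-effect models recover the direction of injected attraction", {
  ## null: presence independent of order -> beta near zero, p not extreme
  gen_presence <- function(gamma, n_tr = 24, seed) {
    set.seed(seed)
    ord <- rep(1:18, n_tr)
    tr <- rep(sprintf("T%02d", 1:n_tr), each = 18)
    b <- rnorm(n_tr, 0, 0.4)[as.integer(factor(tr))]
    p <- plogis(-0.3 + gamma * (ord - 9.5) + b)
    data.frame(presence = rbinom(length(p), 1, p), ord, tr)
  }
  cm_from <- function(df) {
    structure(list(counts = matrix(df$presence,
                                   dimnames = list(NULL, "spA")),
                   row_meta = data.frame(transect = df$tr,
                                         observer = "Obs1",
                                         order_index = df$ord,
                                         repeat_index = df$ord)),
              class = "community_matrix")
  }
  f0 <- fit_order_effect(cm_from(gen_presence(0, seed = 1)), "spA")
  expect_lt(abs(f0$beta), 0.08)
  f_att <- fit_order_effect(cm_from(gen_presence(0.3, seed = 2)), "spA")
  expect_gt(f_att$beta, 0)
  expect_lt(f_att$p_value, 0.05)
  f_det <- fit_order_effect(cm_from(gen_presence(-0.3, seed = 3)), "spA")
  expect_lt(f_det$beta, 0)
  ## all-present series: separation flag, no crash
  df_all1 <- gen_presence(0, seed = 4); df_all1$presence <- 1L
  f1 <- fit_order_effect(cm_from(df_all1), "spA")
  expect_true(f1$separation)
})

test_that("a constant dissimilarity matrix gives a zero correlogram statistic", {
  meta <- data.frame(transect = rep(c("T1", "T2"), each = 6),
                     observer = rep(rep(c("O1", "O2"), each = 3), 2),
                     order_index = rep(1:6, 2))
  D <- matrix(0.5, 12, 12); diag(D) <- 0
  mc <- partial_mantel_correlogram(D, meta, n_perm = 99, seed = 1)
  expect_true(all(abs(mc$statistic) < 1e-10))
  expect_true(all(mc$p_value > 0 & mc$p_value <= 1))
})

test_that("the correlogram detects an injected lag-1 similarity structure", {
  ## passes adjacent in time are constructed to be more similar
  set.seed(7)
  n_tr <- 6; n_pass <- 9
  rows <- list(); meta <- list()
  for (t in seq_len(n_tr)) {
    base <- matrix(rpois(5 * 20, 4), n_pass + 1, 20)[1, ]
    walk <- matrix(0, n_pass, 20)
    walk[1, ] <- rpois(20, 5)
    for (i in 2:n_pass)
      walk[i, ] <- pmax(0, round(0.9 * walk[i - 1, ] + rpois(20, 0.5)))
    rows[[t]] <- walk
    meta[[t]] <- data.frame(transect = sprintf("T%d", t),
                            observer = rep(c("O1", "O2", "O3"), each = 3),
                            order_index = 1:n_pass)
  }
  cmat <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  D <- dissimilarity(cmat^0.25, "bray_curtis")$values
  mc <- partial_mantel_correlogram(D, meta, n_perm = 199, seed = 3)
  expect_gt(mc$statistic[mc$lag == 1], 0)
  expect_lt(mc$p_value[mc$lag == 1], 0.05)
  ## permutation p-values have the (b+1)/(m+1) form, in (0, 1]
  expect_true(all(mc$p_value >= 1 / 200 & mc$p_value <= 1))
})
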