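one_way_terms <- list(list(label = "Group", factors = "g", live = "g",
                           random = FALSE))

test_that("Euclidean PERMANOVA on one variable is classical ANOVA", {
  y <- c(0, 1, 10, 11)
  dat <- data.frame(g = c("A", "A", "B", "B"))
  tab <- permanova(dist(y), data = dat, terms = one_way_terms, n_perm = 0)
  expect_equal(tab$SS, c(100, 1))          # MSB = 100, MSW = 0.5
  expect_equal(tab$pseudo_F[1], 200)
  a <- anova(lm(y ~ g, data = dat))
  expect_equal(tab$pseudo_F[1], a$`F value`[1], tolerance = 1e-12)
})

test_that("identical observations give zero total SS and zero components", {
  D <- matrix(0, 6, 6)
  dat <- data.frame(g = rep(c("A", "B"), each = 3))
  tab <- permanova(D, data = dat, terms = one_way_terms, n_perm = 0)
  expect_equal(attr(tab, "total_SS"), 0)
  expect_equal(tab$SS, c(0, 0))
  expect_equal(tab$sigma2, c(0, 0))
})

test_that("exhaustive permutation p-values match enumeration of relabelings", {
  set.seed(2)
  y <- c(0.3, 1.2, 0.8, 3.1, 2.4, 2.9)
  dat <- data.frame(g = rep(c("A", "B"), each = 3))
  tab <- permanova(dist(y), data = dat, terms = one_way_terms,
                   exhaustive = TRUE)
  ## oracle: classical F over all distinct relabelings (choose 3 of 6)
  Fs <- vapply(utils::combn(6, 3, simplify = FALSE), function(ix) {
    g <- rep("B", 6); g[ix] <- "A"
    anova(lm(y ~ factor(g)))$`F value`[1]
  }, 0)
  expect_equal(tab$p_value[1], mean(Fs >= tab$pseudo_F[1] - 1e-12),
               tolerance = 1e-12)
  ## also holds on a 7-point unbalanced-free two-group instance
  y7 <- c(y, 1.5)
  dat7 <- data.frame(g = c(rep(c("A", "B"), each = 3), "A"))
  expect_error(permanova(dist(y7), data = dat7, terms = one_way_terms,
                         exhaustive = TRUE), "unbalanced")
})

test_that("every term of the full design reproduces classical ANOVA", {
  des <- study_design(2, 3, 2, 3, 3)
  fac <- design_factors(des)
  set.seed(10)
  y <- rnorm(nrow(fac)) +
    rnorm(6, 0, 1)[as.integer(factor(fac$location))] +
    rnorm(12, 0, 0.7)[as.integer(factor(fac$transect))] +
    rnorm(3, 0, 0.3)[as.integer(factor(fac$observer))]
  tab <- permanova(dist(y), data = fac, n_perm = 0)
  oracle <- anova_ss_oracle(y, fac)
  expect_equal(stats::setNames(tab$SS, tab$term), oracle, tolerance = 1e-8)
  ## SS additivity and R2 bounds
  expect_equal(sum(tab$SS), attr(tab, "total_SS"), tolerance = 1e-8)
  expect_true(all(tab$R2 >= 0 & tab$R2 <= 1))
  expect_equal(sum(tab$pct_variation), 100, tolerance = 1e-8)
  ## signed square-root convention for components of variation
  expect_equal(sign(tab$sigma_prime), sign(tab$sigma2))
  expect_equal(tab$sigma_prime^2, abs(tab$sigma2), tolerance = 1e-12)
})

test_that("permutation tests reject injected effects and hold the null", {
  des <- study_design(2, 3, 2, 3, 3)
  fac <- design_factors(des)
  set.seed(4)
  y <- rnorm(nrow(fac)) + rnorm(6, 0, 2)[as.integer(factor(fac$location))]
  tab <- permanova(dist(y), data = fac, n_perm = 199, seed = 8)
  p <- stats::setNames(tab$p_value, tab$term)
  expect_lt(p["Location"], 0.05)
  expect_gt(p["Observer"], 0.1)
  expect_gt(p["Transect"], 0.05)
  expect_true(all(na.omit(tab$p_value) > 0 & na.omit(tab$p_value) <= 1))
})

test_that("undefined dissimilarities and missing factors are rejected", {
  D <- matrix(0.4, 4, 4); diag(D) <- 0; D[1, 2] <- D[2, 1] <- NA
  expect_error(permanova(D, data = data.frame(g = c("A", "A", "B", "B")),
                         terms = one_way_terms), "undefined")
  expect_error(permanova(matrix(0, 4, 4)), "design factors")
})

test_that("component percentages follow the truncation convention", {
  sp <- c(A = 2, B = -1, Residual = 1)
  pct <- component_percentages(sp)
  expect_equal(unname(pct), c(80, 0, 20))
  pct2 <- component_percentages(sp, truncate_negative = FALSE)
  expect_equal(unname(pct2), 100 * c(4, -1, 1) / 4)
  expect_equal(sum(pct), 100)
})
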