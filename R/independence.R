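#' Autocorrelation of the ordered counts of one transect
#'
#' For the temporally ordered counts `Y_1..Y_n` of one transect, the lag-k
#' autocorrelation is `r_k = sum_{i=1}^{n-k} (Y_i - Ybar)(Y_{i+k} - Ybar) /
#' sum_{i=1}^{n} (Y_i - Ybar)^2`, with the full-series mean and denominator
#' (the biased estimator).  A constant series has a zero denominator; its
#' ACF is undefined and returned as `NA` with the `undefined` attribute set,
#' never silently zero.
#'
#' @param series Numeric vector of ordered counts (length >= 2).
#' @param max_lag Largest lag `K < length(series)`; default
#'   `length(series) - 1`.
#' @return Numeric vector of `r_0..r_K` named by lag, with attribute
#'   `undefined` (logical).
#' @examples
#' species_acf(c(1, 2, 3, 4), max_lag = 1) # r_1 = 0.25
#' @export
species_acf <- function(series, max_lag = length(series) - 1) {
  n <- length(series)
  if (n < 2) stop("series must have length >= 2")
  if (max_lag >= n || max_lag < 0) stop("max_lag must satisfy 0 <= K < n")
  ybar <- mean(series)
  dev <- series - ybar
  denom <- sum(dev^2)
  lags <- 0:max_lag
  if (denom == 0) {
    r <- rep(NA_real_, length(lags))
  } else {
    r <- vapply(lags, function(k)
      sum(dev[seq_len(n - k)] * dev[seq_len(n - k) + k]) / denom, 0)
  }
  names(r) <- lags
  attr(r, "undefined") <- denom == 0
  r
}

#' Average ACF over transects, per lag
#'
#' Arithmetic mean of per-transect ACFs at each lag, over the transects
#' whose ACF is defined; the number of contributing transects is reported
#' per lag.  A lag with no defined value is `NA`.
#'
#' @param acfs List of vectors as returned by [species_acf()] (equal
#'   lengths).
#' @return A data frame with columns `lag`, `mean_r`, `n`.
#' @export
mean_acf <- function(acfs) {
  stopifnot(length(acfs) >= 1)
  m <- do.call(rbind, lapply(acfs, as.numeric))
  lags <- as.integer(names(acfs[[1]]))
  data.frame(lag = lags,
             mean_r = apply(m, 2, function(v)
               if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)),
             n = colSums(!is.na(m)), row.names = NULL)
}

#' Per-species ACF over all transects of a study
#'
#' Convenience wrapper: builds the ordered count series of each transect
#' from a community matrix and averages the per-transect ACFs.
#'
#' @param cm A [community_matrix()] with untransformed counts.
#' @param species Character vector of species to assess; default all.
#' @param max_lag Largest lag.
#' @return A list per species with elements `per_transect` (list of ACF
#'   vectors) and `mean` (data frame from [mean_acf()]).
#' @export
study_acf <- function(cm, species = colnames(cm$counts), max_lag = 5) {
  meta <- cm$row_meta
  out <- lapply(species, function(sp) {
    per_tr <- lapply(split(seq_len(nrow(meta)), meta$transect), function(ix) {
      ix <- ix[order(meta$order_index[ix])]
      species_acf(cm$counts[ix, sp], max_lag = max_lag)
    })
    list(per_transect = per_tr, mean = mean_acf(per_tr))
  })
  names(out) <- species
  out
}

#' Observation-order effect on detection (binomial mixed model)
#'
#' Fits a mixed logistic regression of the presence/absence of one species
#' on the order of the pass, with a Gaussian random intercept per transect:
#' `logit(p) = alpha + beta * Order + b_transect`.  A positive `beta` means
#' the species is recorded increasingly often over consecutive passes
#' (attraction), a negative `beta` deterrence.  Only series (transects, or
#' transect-observer combinations for the per-observer scope) with at least
#' one observed presence enter the fit.  Estimation is maximum likelihood
#' via the Laplace approximation; the reported p-value for `beta` is a Wald
#' test (a likelihood-ratio test is available via `test = "LRT"`).
#'
#' @param cm A [community_matrix()] (counts or presence/absence).
#' @param species Single species name (column of `cm`).
#' @param scope `"all_18"` uses the full within-transect pass order
#'   (1..observers*repeats); `"per_observer_6"` uses the repeat number
#'   within each observer (series unit = transect x observer).
#' @param test `"Wald"` (default) or `"LRT"` for the `beta` p-value.
#' @return A list of class `order_effect_fit`: `species`, `scope`, `alpha`,
#'   `beta`, `se_beta`, `p_value`, `var_transect`, `n_series`, `separation`
#'   (logical flag for complete separation / boundary fits) and `fit`.
#' @export
fit_order_effect <- function(cm, species, scope = c("all_18", "per_observer_6"),
                             test = c("Wald", "LRT")) {
  scope <- match.arg(scope)
  test <- match.arg(test)
  meta <- cm$row_meta
  presence <- as.integer(cm$counts[, species] > 0)
  ord <- if (scope == "all_18") meta$order_index else meta$repeat_index
  series <- if (scope == "all_18") meta$transect
            else paste(meta$transect, meta$observer, sep = ":")
  keep_series <- names(which(tapply(presence, series, sum) > 0))
  keep <- series %in% keep_series
  if (sum(keep) == 0)
    stop("no series with at least one presence for species ", species)
  df <- data.frame(presence = presence[keep], order = ord[keep],
                   transect = factor(meta$transect[keep]))
  n_series <- length(keep_series)
  if (all(df$presence == 1) || all(df$presence == 0) || n_series < 2) {
    return(structure(list(species = species, scope = scope,
                          alpha = NA_real_, beta = NA_real_,
                          se_beta = NA_real_, p_value = NA_real_,
                          var_transect = NA_real_, n_series = n_series,
                          separation = TRUE, fit = NULL),
                     class = "order_effect_fit"))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(presence ~ order + (1 | transect), data = df,
                family = stats::binomial())))
  co <- summary(fit)$coefficients
  beta <- co["order", "Estimate"]
  se <- co["order", "Std. Error"]
  separation <- !is.finite(beta) || abs(beta) > 10 || se > 50
  p <- if (separation) 1 else co["order", "Pr(>|z|)"]
  if (test == "LRT" && !separation) {
    fit0 <- suppressMessages(suppressWarnings(
      lme4::glmer(presence ~ 1 + (1 | transect), data = df,
                  family = stats::binomial())))
    p <- stats::anova(fit0, fit)[2, "Pr(>Chisq)"]
  }
  structure(list(species = species, scope = scope,
                 alpha = co["(Intercept)", "Estimate"], beta = beta,
                 se_beta = se, p_value = p,
                 var_transect = as.numeric(lme4::VarCorr(fit)$transect),
                 n_series = n_series, separation = separation, fit = fit),
            class = "order_effect_fit")
}

#' @export
print.order_effect_fit <- function(x, ...) {
  cat(sprintf("<order_effect_fit> %s (%s): beta = %.4f (p = %.4g)%s\n",
              x$species, x$scope, x$beta, x$p_value,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Partial Mantel correlogram of assemblage dissimilarity versus pass lag
#'
#' Correlates, per temporal lag class, the community similarity (negated
#' dissimilarity) of pairs of passes of the same transect with membership
#' in that lag class, partialling out transect identity and observer
#' sharing (dummy model matrices) -- so a positive statistic at lag 1
#' means temporally adjacent passes resemble each other more than
#' expected.  Only within-transect pairs are used: pairs from different
#' transects carry no temporal order.  Significance is assessed by
#' restricted permutation of the pass order within each transect
#' (one-sided, for positive dependence), with p-values
#' `(b + 1) / (n_perm + 1)` and a Holm correction across lags.
#'
#' @param D A [dissimilarity()] matrix or square symmetric matrix over all
#'   observations.
#' @param meta Data frame with columns `transect`, `observer`,
#'   `order_index`, matching the rows of `D` (defaults to the metadata
#'   attached to `D`).
#' @param lags Integer lag classes to assess; classes with fewer than two
#'   pairs are skipped.
#' @param n_perm Number of permutations (warning below 99).
#' @param seed Integer seed.
#' @return A data frame of class `mantel_correlogram` with columns `lag`,
#'   `statistic` (partial correlation), `n_pairs`, `p_value`, `p_holm`.
#' @export
partial_mantel_correlogram <- function(D, meta = attr(D, "row_meta"),
                                       lags = NULL, n_perm = 199, seed = 1) {
  Dm <- if (inherits(D, "dissimilarity_matrix")) D$values else as.matrix(D)
  stopifnot(nrow(Dm) == nrow(meta))
  if (n_perm < 99) warning("n_perm < 99 gives a coarse p-value resolution")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))

  ## within-transect pairs
  tr <- as.character(meta$transect)
  pair_i <- pair_j <- integer(0)
  for (t in unique(tr)) {
    ix <- which(tr == t)
    cmb <- utils::combn(ix, 2)
    pair_i <- c(pair_i, cmb[1, ]); pair_j <- c(pair_j, cmb[2, ])
  }
  d <- Dm[cbind(pair_i, pair_j)]
  ok <- is.finite(d)
  pair_i <- pair_i[ok]; pair_j <- pair_j[ok]; d <- d[ok]
  pair_tr <- factor(tr[pair_i])
  same_obs <- as.numeric(meta$observer[pair_i] == meta$observer[pair_j])
  Z <- stats::model.matrix(~ pair_tr + same_obs)
  d_res <- stats::lm.fit(Z, d)$residuals

  max_lag <- max(meta$order_index) - min(meta$order_index)
  if (is.null(lags)) lags <- seq_len(max_lag)
  ord <- meta$order_index
  lag_of <- function(o) abs(o[pair_i] - o[pair_j])

  ## statistic on the similarity scale: positive values mean passes in the
  ## lag class resemble each other more than expected
  stat_for <- function(o) {
    lg <- lag_of(o)
    vapply(lags, function(k) {
      x <- as.numeric(lg == k)
      if (sum(x) < 2 || stats::var(x) == 0) return(NA_real_)
      x_res <- stats::lm.fit(Z, x)$residuals
      if (stats::sd(x_res) < 1e-12 || stats::sd(d_res) < 1e-12) return(0)
      -stats::cor(d_res, x_res)
    }, 0)
  }
  obs_stat <- stat_for(ord)
  n_pairs <- vapply(lags, function(k) sum(lag_of(ord) == k), 0L)

  exceed <- integer(length(lags))
  tr_groups <- split(seq_len(nrow(meta)), tr)
  for (b in seq_len(n_perm)) {
    o_perm <- ord
    for (g in tr_groups) o_perm[g] <- sample(ord[g])
    ps <- stat_for(o_perm)
    exceed <- exceed + as.integer(!is.na(ps) & !is.na(obs_stat) &
                                    ps >= obs_stat)
  }
  p <- (exceed + 1) / (n_perm + 1)
  p[is.na(obs_stat)] <- NA
  out <- data.frame(lag = lags, statistic = obs_stat, n_pairs = n_pairs,
                    p_value = p,
                    p_holm = stats::p.adjust(p, method = "holm"))
  out <- out[n_pairs >= 2, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}
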