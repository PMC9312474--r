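#' Monte-Carlo pooling of observations and dissimilarity distributions
#'
#' Quantifies the design error associated with short transects: per level
#' of a spatial factor (transect or location), two disjoint random subsets
#' of `pool_size` observations are drawn without replacement, the raw
#' counts are averaged within each subset, transformed, and the
#' Bray-Curtis dissimilarity between the two pooled profiles is recorded.
#' Low dissimilarities indicate that observations within the level are
#' solid repeats; values of 1 (no shared species) and undefined values
#' (both pooled profiles empty) are uninformative and counted.
#'
#' Pooling averages raw counts and transforms afterwards; the reverse
#' order (transform, then average) is available via
#' `transform_after_pooling = FALSE`.
#'
#' @param cm A [community_matrix()] with untransformed counts.
#' @param factor `"transect"` or `"location"`.
#' @param pool_size Number of observations per pooled subset `k`; each
#'   level must contain at least `2k` observations.
#' @param n_perm Monte-Carlo draws per level.
#' @param seed Integer seed.
#' @param transform Transformation applied to the pooled profiles
#'   (default `"fourth_root"`).
#' @param transform_after_pooling Logical; see Details.
#' @param bin_width Histogram bin width on `[0, 1]`.
#' @return A list of class `pooling_distribution`: `samples` (levels x
#'   `n_perm` matrix, `NA` = undefined pair), per-level `histograms`, the
#'   `average_histogram` over levels, `uninformative` (count of samples
#'   equal to 1), `undefined` (count of both-empty pairs) and the call
#'   parameters.
#' @export
pooled_dissimilarity <- function(cm, factor = c("transect", "location"),
                                 pool_size = 1, n_perm = 999, seed = 1,
                                 transform = "fourth_root",
                                 transform_after_pooling = TRUE,
                                 bin_width = 0.05) {
  factor <- match.arg(factor)
  stopifnot(inherits(cm, "community_matrix"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  k <- as.integer(pool_size)
  if (k < 1) stop("pool_size must be >= 1")
  lev <- cm$row_meta[[factor]]
  groups <- split(seq_len(nrow(cm$counts)), lev)
  too_small <- vapply(groups, length, 0L) < 2L * k
  if (any(too_small))
    stop("each ", factor, " level needs at least 2*pool_size observations")

  tf <- function(m) {
    tmp <- structure(list(counts = m, transform = "none"),
                     class = "community_matrix")
    transform_counts(tmp, transform)$counts
  }
  x <- cm$counts
  if (!transform_after_pooling) x <- tf(x)

  breaks <- seq(0, 1, by = bin_width)
  samples <- matrix(NA_real_, length(groups), n_perm,
                    dimnames = list(names(groups), NULL))
  for (g in seq_along(groups)) {
    ix <- groups[[g]]
    for (b in seq_len(n_perm)) {
      pick <- sample(ix, 2L * k)
      a <- colMeans(x[pick[seq_len(k)], , drop = FALSE])
      bb <- colMeans(x[pick[k + seq_len(k)], , drop = FALSE])
      if (transform_after_pooling) {
        a <- tf(matrix(a, 1)); bb <- tf(matrix(bb, 1))
      }
      ta <- sum(a); tb <- sum(bb)
      samples[g, b] <- if (ta + tb == 0) NA_real_ else
        sum(abs(a - bb)) / (ta + tb)
    }
  }
  hists <- lapply(seq_len(nrow(samples)), function(g) {
    v <- samples[g, ]; v <- v[!is.na(v)]
    h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    h$counts / max(1, length(v))
  })
  names(hists) <- rownames(samples)
  avg <- Reduce(`+`, hists) / length(hists)
  structure(list(samples = samples, histograms = hists,
                 average_histogram = data.frame(
                   bin_lo = utils::head(breaks, -1),
                   bin_hi = breaks[-1], frequency = avg),
                 uninformative = as.integer(count_uninformative(samples)),
                 undefined = sum(is.na(samples)),
                 factor = factor, pool_size = k, n_perm = n_perm,
                 transform = transform,
                 transform_after_pooling = transform_after_pooling),
            class = "pooling_distribution")
}

#' @export
print.pooling_distribution <- function(x, ...) {
  cat(sprintf("<pooling_distribution> factor=%s, pool_size=%d, %d levels x %d draws\n",
              x$factor, x$pool_size, nrow(x$samples), x$n_perm))
  cat(sprintf("  mean dissimilarity %.3f; uninformative (==1): %d; undefined (both empty): %d\n",
              mean(x$samples, na.rm = TRUE), x$uninformative, x$undefined))
  invisible(x)
}

#' Count uninformative dissimilarity values
#'
#' A dissimilarity sample is uninformative when it equals 1 (the two
#' pooled profiles share no species).  Pairs where both profiles are
#' entirely empty have an undefined dissimilarity; they are recorded as
#' `NA` by [pooled_dissimilarity()] and reported via the `undefined`
#' attribute here, never imputed.
#'
#' @param samples Numeric vector or matrix of dissimilarity samples
#'   (`NA` = undefined pair).
#' @return Integer count of samples equal to 1, with attribute
#'   `undefined` giving the count of `NA` samples.
#' @export
count_uninformative <- function(samples) {
  out <- sum(samples == 1, na.rm = TRUE)
  attr(out, "undefined") <- sum(is.na(samples))
  out
}
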