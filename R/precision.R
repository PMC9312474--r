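#' Standard-error-to-mean ratio of repeated observations of one transect
#'
#' For each transect, draws subsamples of `k` of its repeated observations
#' without replacement and computes the ratio of the standard error of the
#' mean (`sd / sqrt(k)`) to the mean (precision is the inverse of this
#' ratio).  Draws whose subsample mean is zero leave the ratio undefined;
#' they are excluded and their frequency reported rather than propagated.
#' The curve point is the average over transects of the per-transect mean
#' ratio; the 95% confidence interval uses the pooled standard deviation
#' of the per-transect estimates.
#'
#' @param values Numeric vector of the response, one per observation.
#' @param transect Factor of transect labels, one per observation.
#' @param k Number of repeats per subsample (`2 <= k <=` passes per
#'   transect).
#' @param n_sim Monte-Carlo draws per transect.
#' @param seed Integer seed.
#' @param replace Logical; `TRUE` switches to a with-replacement
#'   bootstrap (default subsamples without replacement).
#' @return A list of class `precision_point`: `estimate` (mean SE/mean),
#'   `ci_lo`, `ci_hi`, `per_transect` (named vector), `n_excluded`
#'   (zero-mean draws), `k`, `n_sim`.
#' @export
univariate_precision <- function(values, transect, k, n_sim = 200,
                                 seed = 1, replace = FALSE) {
  if (k < 2) stop("k must be >= 2 (standard error undefined for k < 2)")
  stopifnot(length(values) == length(transect))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  groups <- split(values, transect)
  if (any(vapply(groups, length, 0L) < k))
    stop("every transect needs at least k observations")
  n_excluded <- 0L
  per_tr_mean <- per_tr_var <- rep(NA_real_, length(groups))
  for (g in seq_along(groups)) {
    y <- groups[[g]]
    ratios <- numeric(n_sim)
    ok <- logical(n_sim)
    for (b in seq_len(n_sim)) {
      s <- sample(y, k, replace = replace)
      m <- mean(s)
      if (m == 0) next
      ratios[b] <- (stats::sd(s) / sqrt(k)) / m
      ok[b] <- TRUE
    }
    n_excluded <- n_excluded + sum(!ok)
    if (any(ok)) {
      per_tr_mean[g] <- mean(ratios[ok])
      per_tr_var[g] <- stats::var(ratios[ok])
    }
  }
  names(per_tr_mean) <- names(groups)
  est <- mean(per_tr_mean, na.rm = TRUE)
  n_tr <- sum(!is.na(per_tr_mean))
  pooled_sd <- sqrt(mean(per_tr_var[!is.na(per_tr_var)]))
  half <- 1.96 * pooled_sd / sqrt(max(1, n_tr))
  structure(list(estimate = est, ci_lo = est - half, ci_hi = est + half,
                 per_transect = per_tr_mean, n_excluded = n_excluded,
                 k = k, n_sim = n_sim),
            class = "precision_point")
}

#' @export
print.precision_point <- function(x, ...) {
  cat(sprintf("<precision_point> k=%d: SE/mean = %.4f [%.4f, %.4f] (%d zero-mean draws excluded)\n",
              x$k, x$estimate, x$ci_lo, x$ci_hi, x$n_excluded))
  invisible(x)
}

#' Precision curve over repeats and transect lengths
#'
#' Tabulates the SE/mean ratio of a univariate response (species density,
#' Shannon diversity or a species count) for every combination of distance
#' window length and number of repeats, together with the total swim
#' distance (`repeats x length`).
#'
#' @param records List of [observation_record()].
#' @param response `"species_density"`, `"shannon_diversity"`, or a
#'   species name (count response).
#' @param lengths Nominal transect lengths (centred windows).
#' @param ks Numbers of repeats to assess.
#' @param metric Counting metric for species responses.
#' @param total_m Full transect length.
#' @param n_sim,seed,replace Passed to [univariate_precision()].
#' @return Data frame of class `precision_curve` with columns `response`,
#'   `length_m`, `repeats`, `distance_m`, `estimate`, `ci_lo`, `ci_hi`,
#'   `n_excluded`.
#' @export
precision_curve <- function(records, response = "species_density",
                            lengths = c(10, 20, 30, 40, 50), ks = 2:18,
                            metric = "max_count", total_m = 50,
                            n_sim = 200, seed = 1, replace = FALSE) {
  species <- sort(unique(unlist(lapply(records,
                                       function(r) r$events$species))))
  rows <- list()
  for (len in lengths) {
    cm <- community_matrix(records, metric = metric,
                           window = window_for_length(len, total_m),
                           length_m = total_m, species = species)
    vals <- switch(response,
                   species_density = species_density(cm),
                   shannon_diversity = shannon_diversity(cm),
                   { if (!response %in% species)
                       stop("unknown response: ", response)
                     cm$counts[, response] })
    for (k in ks) {
      pt <- univariate_precision(vals, cm$row_meta$transect, k,
                                 n_sim = n_sim, seed = seed,
                                 replace = replace)
      rows[[length(rows) + 1]] <-
        data.frame(response = response, length_m = len, repeats = k,
                   distance_m = len * k, estimate = pt$estimate,
                   ci_lo = pt$ci_lo, ci_hi = pt$ci_hi,
                   n_excluded = pt$n_excluded)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("precision_curve", "data.frame")
  out
}

#' Compare precision at matched total swim distance
#'
#' Aligns the (length, repeats) combinations of a precision curve on
#' their total swim distance and reports, per distance, the
#' configuration(s) minimizing the SE/mean ratio (ties are all reported).
#'
#' @param curve A [precision_curve()] data frame (or [mult_se_curve()]).
#' @param tol Relative tolerance for declaring a tie.
#' @return Data frame with one row per (distance, best configuration):
#'   `distance_m`, `length_m`, `repeats`, `estimate`, `n_tied`.
#' @export
precision_vs_swim_distance <- function(curve, tol = 1e-8) {
  out <- lapply(split(curve, curve$distance_m), function(d) {
    best <- min(d$estimate)
    sel <- d[d$estimate <= best * (1 + tol) + tol, , drop = FALSE]
    data.frame(distance_m = sel$distance_m, length_m = sel$length_m,
               repeats = sel$repeats, estimate = sel$estimate,
               n_tied = nrow(sel))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$distance_m), ]
}

#' Precision stratified by turbidity terciles
#'
#' Ranks the transects by their visually graded turbidity, splits them
#' into three equally sized groups (stable order breaks ties) and
#' computes a precision curve within each tercile.
#'
#' @param records List of [observation_record()] (turbidity is read from
#'   the records).
#' @inheritParams precision_curve
#' @return Data frame: `precision_curve` columns plus `tercile`
#'   (`"low"`, `"mid"`, `"high"`).
#' @export
turbidity_stratified_precision <- function(records,
                                           response = "species_density",
                                           lengths = 50, ks = 2:18,
                                           metric = "max_count",
                                           total_m = 50, n_sim = 200,
                                           seed = 1) {
  meta <- .records_meta(records)
  turb <- tapply(meta$turbidity, meta$transect, `[`, 1)
  n_tr <- length(turb)
  if (n_tr < 3) stop("need at least 3 transects for terciles")
  r <- rank(turb, ties.method = "first")  # stable: ties keep input order
  tercile <- c("low", "mid", "high")[ceiling(3 * r / n_tr)]
  names(tercile) <- names(turb)
  out <- lapply(c("low", "mid", "high"), function(tc) {
    keep_tr <- names(tercile)[tercile == tc]
    recs <- records[meta$transect %in% keep_tr]
    cv <- precision_curve(recs, response = response, lengths = lengths,
                          ks = ks, metric = metric, total_m = total_m,
                          n_sim = n_sim, seed = seed)
    cv$tercile <- tc
    cv
  })
  do.call(rbind, out)
}

#' Multivariate pseudo standard error (multSE)
#'
#' For `k` repeats subsampled (without replacement) from the ordered
#' observations of each transect, fits the reduced spatial model (Island
#' fixed, Location and Transect nested random, no observer factor) and
#' computes `multSE = sqrt(MS_residual / k)`.  In the balanced design the
#' residual mean square of that model is the within-transect mean square,
#' computed directly from the pairwise dissimilarities:
#' `SS_within = sum_transects (1/k) sum_{i<j} d_ij^2`.  The curve point
#' is the mean over draws with a 95% interval from the pooled standard
#' deviation of the draw estimates.
#'
#' @param D A [dissimilarity()] object (all observations), or square
#'   matrix.
#' @param meta Data frame with `transect` (defaults to metadata attached
#'   to `D`).
#' @param k Repeats per transect (`2 <= k <=` passes per transect).
#' @param n_sim Monte-Carlo draws.
#' @param seed Integer seed.
#' @param replace Logical; with-replacement bootstrap if `TRUE`.
#' @return A list of class `multse_point`: `estimate`, `ci_lo`, `ci_hi`,
#'   `k`, `n_sim`, `draws`.
#' @export
mult_se <- function(D, meta = NULL, k, n_sim = 200, seed = 1,
                    replace = FALSE) {
  if (k < 2) stop("k must be >= 2")
  Dm <- .as_dist_matrix(D)
  if (is.null(meta) && inherits(D, "dissimilarity_matrix")) meta <- D$row_meta
  stopifnot(nrow(Dm) == nrow(meta))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  groups <- split(seq_len(nrow(Dm)), meta$transect)
  if (any(vapply(groups, length, 0L) < k))
    stop("every transect needs at least k observations")
  n_tr <- length(groups)
  draws <- numeric(n_sim)
  for (b in seq_len(n_sim)) {
    ss <- 0
    for (g in groups) {
      pick <- sample(g, k, replace = replace)
      sub <- Dm[pick, pick]
      ss <- ss + sum(sub[upper.tri(sub)]^2) / k
    }
    ms_res <- ss / (n_tr * (k - 1))
    draws[b] <- sqrt(ms_res / k)
  }
  est <- mean(draws)
  half <- 1.96 * stats::sd(draws)
  structure(list(estimate = est, ci_lo = est - half, ci_hi = est + half,
                 k = k, n_sim = n_sim, draws = draws),
            class = "multse_point")
}

#' @export
print.multse_point <- function(x, ...) {
  cat(sprintf("<multse_point> k=%d: multSE = %.4f [%.4f, %.4f]\n",
              x$k, x$estimate, x$ci_lo, x$ci_hi))
  invisible(x)
}

#' multSE curve over repeats and transect lengths
#'
#' @param records List of [observation_record()].
#' @param lengths Nominal transect lengths (centred windows).
#' @param ks Numbers of repeats.
#' @param metric Counting metric.
#' @param transform Transformation before the dissimilarity.
#' @param method Dissimilarity method.
#' @param total_m Full transect length.
#' @param n_sim,seed Passed to [mult_se()].
#' @return Data frame of class `multse_curve` with columns `length_m`,
#'   `repeats`, `distance_m`, `estimate`, `ci_lo`, `ci_hi`.
#' @export
mult_se_curve <- function(records, lengths = c(10, 20, 30, 40, 50),
                          ks = 2:18, metric = "max_count",
                          transform = "fourth_root",
                          method = "bray_curtis", total_m = 50,
                          n_sim = 100, seed = 1) {
  species <- sort(unique(unlist(lapply(records,
                                       function(r) r$events$species))))
  rows <- list()
  for (len in lengths) {
    cm <- community_matrix(records, metric = metric,
                           window = window_for_length(len, total_m),
                           length_m = total_m, transform = transform,
                           species = species)
    D <- dissimilarity(cm, method = method)
    if (anyNA(D$values))
      stop("undefined dissimilarities (empty observations) at length ", len)
    for (k in ks) {
      pt <- mult_se(D, k = k, n_sim = n_sim, seed = seed)
      rows[[length(rows) + 1]] <-
        data.frame(length_m = len, repeats = k, distance_m = len * k,
                   estimate = pt$estimate, ci_lo = pt$ci_lo,
                   ci_hi = pt$ci_hi)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("multse_curve", "data.frame")
  out
}
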