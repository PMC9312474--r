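#' Pairwise dissimilarities of a community matrix
#'
#' Computes the symmetric observation-by-observation dissimilarity matrix
#' under one of four methods: Bray-Curtis `sum|x-y| / sum(x+y)`, Euclidean,
#' Gower (mean over species of `|x-y| / range_s`, zero-range species
#' contributing 0) and quantitative Kulczynski
#' `1 - (sum(min)/sum(x) + sum(min)/sum(y)) / 2`.  Pairs where both rows
#' are entirely zero are undefined for the `[0, 1]` indices and returned
#' as `NA`.
#'
#' @param cm A [community_matrix()] (already transformed as desired) or a
#'   non-negative numeric matrix.
#' @param method One of `"bray_curtis"`, `"euclidean"`, `"gower"`,
#'   `"kulczynski"`.
#' @return An object of class `dissimilarity_matrix`: list with `values`
#'   (n x n symmetric matrix, zero diagonal), `method`, `transform`, and
#'   the observation metadata `row_meta` when available.
#' @examples
#' m <- rbind(c(1, 2), c(2, 1))
#' dissimilarity(m, "bray_curtis")$values[1, 2] # 1/3
#' @export
dissimilarity <- function(cm, method = c("bray_curtis", "euclidean",
                                         "gower", "kulczynski")) {
  method <- match.arg(method)
  x <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  veg_method <- c(bray_curtis = "bray", euclidean = "euclidean",
                  gower = "gower", kulczynski = "kulczynski")[method]
  D <- as.matrix(vegan::vegdist(x, method = veg_method))
  if (method %in% c("bray_curtis", "kulczynski", "gower")) {
    empty <- rowSums(x) == 0
    if (any(empty)) {
      D[empty, empty] <- NA_real_
      diag(D) <- 0
    }
  }
  dimnames(D) <- NULL
  structure(list(values = D, method = method,
                 transform = if (inherits(cm, "community_matrix"))
                   cm$transform else NA_character_,
                 row_meta = if (inherits(cm, "community_matrix"))
                   cm$row_meta else NULL),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d x %d, method=%s, transform=%s\n",
              nrow(x$values), ncol(x$values), x$method, x$transform))
  invisible(x)
}

.as_dist_matrix <- function(D) {
  if (inherits(D, "dissimilarity_matrix")) D$values
  else if (inherits(D, "dist")) as.matrix(D)
  else as.matrix(D)
}

## Gower-centered inner-product matrix G = (I - J/n) (-D^2/2) (I - J/n)
.gower_center <- function(Dm) {
  A <- -0.5 * Dm^2
  n <- nrow(A)
  rm <- rowMeans(A); gm <- mean(A)
  G <- A - matrix(rm, n, n) - matrix(rm, n, n, byrow = TRUE) + gm
  (G + t(G)) / 2
}

.all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.all_perms(v[-i]), function(r) c(v[i], r)))
  out
}

#' PERMANOVA for balanced nested/crossed mixed designs
#'
#' Partitions the total sum of squares of a dissimilarity matrix over the
#' terms of a balanced design via the Gower-centered inner-product matrix
#' and sequential orthogonal projections onto the term cell spaces.  For
#' each term the pseudo-F uses the denominator implied by the
#' expected-mean-square (Cornfield-Tukey) table -- a linear combination of
#' mean squares (quasi-F) where no single term matches.  Components of
#' variation are solved from `MS = C sigma2` and reported as signed square
#' roots `sigma' = sign(sigma2) sqrt(|sigma2|)`; the percentage of
#' variation of each component truncates negative components to zero by
#' default.  Permutation p-values use permutation of residuals under the
#' reduced model (Freedman-Lane), with rows permuted within the levels of
#' the factors each term is nested in.
#'
#' @param D A [dissimilarity()] object, `dist`, or square symmetric matrix.
#' @param data Data frame of design factors (defaults to the metadata
#'   attached to `D`).
#' @param terms Term list as in [default_design_terms()].
#' @param n_perm Number of permutations per testable term; `0` skips the
#'   permutation tests.
#' @param seed Integer seed for the permutations.
#' @param exhaustive Logical; enumerate all (restricted) permutations
#'   instead of sampling (small designs only).
#' @param truncate_negative Logical; truncate negative variance components
#'   to zero before computing percentages of variation (the signed
#'   components are always reported).
#' @return An object of class `permanova_table`: a data frame with one row
#'   per term plus Residual and columns `term`, `df`, `SS`, `MS`,
#'   `pseudo_F`, `p_value`, `sigma2`, `sigma_prime`, `pct_variation`,
#'   `R2`; attributes `total_SS`, `total_R2`, `ems`.
#' @export
permanova <- function(D, data = NULL, terms = default_design_terms(),
                      n_perm = 999, seed = 1, exhaustive = FALSE,
                      truncate_negative = TRUE) {
  Dm <- .as_dist_matrix(D)
  if (is.null(data) && inherits(D, "dissimilarity_matrix")) data <- D$row_meta
  if (is.null(data)) stop("design factors must be supplied via 'data'")
  n <- nrow(Dm)
  stopifnot(nrow(data) == n, isTRUE(all.equal(Dm, t(Dm))))
  if (anyNA(Dm)) stop("dissimilarity matrix contains undefined entries")
  G <- .gower_center(Dm)
  total_SS <- sum(diag(G))

  ems <- ems_table(data, terms)
  k <- length(terms)
  labels <- vapply(terms, `[[`, "", "label")

  ## sequential orthonormal bases per term
  X <- matrix(1, n, 1)
  ranks <- 1L
  blocks <- vector("list", k)
  for (t in seq_len(k)) {
    ind <- stats::model.matrix(~ 0 + .term_cells(data, terms[[t]]))
    X <- cbind(X, ind)
    qrX <- qr(X)
    r_new <- qrX$rank
    blocks[[t]] <- (ranks + 1L):r_new
    ranks <- r_new
  }
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  df <- vapply(blocks, length, 0L)
  df_res <- n - qrX$rank
  if (!all(df == unname(ems$df[seq_len(k)])))
    stop("design is not balanced/complete: rank increments ",
         paste(df, collapse = ","), " do not match EMS df ",
         paste(ems$df[seq_len(k)], collapse = ","))

  GQ <- G %*% Q
  ss_cols <- colSums(Q * GQ)
  SS <- vapply(blocks, function(b) sum(ss_cols[b]), 0)
  SS_res <- total_SS - sum(SS)
  SS_all <- stats::setNames(c(SS, SS_res), c(labels, "Residual"))
  df_all <- stats::setNames(c(df, df_res), c(labels, "Residual"))
  MS_all <- SS_all / df_all

  sigma2 <- solve(ems$coefficients, MS_all)
  sigma_prime <- sign(sigma2) * sqrt(abs(sigma2))
  s2_for_pct <- if (truncate_negative) pmax(sigma2, 0) else sigma2
  pct <- 100 * s2_for_pct / sum(s2_for_pct)

  wts <- lapply(seq_len(k), function(u) .denominator_weights(ems, u))
  denom <- vapply(seq_len(k), function(u)
    sum(wts[[u]] * MS_all[names(wts[[u]])]), 0)
  Fs <- c(MS_all[seq_len(k)] / denom, NA)

  p <- rep(NA_real_, k + 1)
  if (n_perm > 0 || exhaustive) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed %% 2147483647))
    for (u in seq_len(k)) {
      if (!is.finite(Fs[u]) || denom[u] <= 0) next
      p[u] <- .fl_pvalue(G, Q, blocks, u, terms, data, df_all, wts[[u]],
                         ems, Fs[u], total_SS, n_perm, exhaustive)
    }
  }

  out <- data.frame(term = c(labels, "Residual"), df = df_all, SS = SS_all,
                    MS = MS_all, pseudo_F = Fs, p_value = p,
                    sigma2 = as.numeric(sigma2),
                    sigma_prime = as.numeric(sigma_prime),
                    pct_variation = as.numeric(pct),
                    R2 = SS_all / total_SS,
                    row.names = NULL)
  attr(out, "total_SS") <- total_SS
  attr(out, "total_R2") <- sum(SS) / total_SS
  attr(out, "ems") <- ems
  class(out) <- c("permanova_table", "data.frame")
  out
}

## Exchangeable units for the permutation test of term u: whole cells of
## the coarsest purely-nested positive-weight denominator term (rows when
## the denominator is the residual), permuted within strata given by the
## unit factors that are neither live subscripts of u nor nested under u.
.permutation_units <- function(u, terms, data, w) {
  k <- length(terms)
  labels <- vapply(terms, `[[`, "", "label")
  sub_u <- terms[[u]]$factors
  primary <- function(f) {
    for (t in terms) if (identical(t$live, f)) return(t$factors)
    f
  }
  nested_under_u <- function(f) all(sub_u %in% primary(f))
  cand <- which(vapply(seq_len(k), function(t) {
    t != u && isTRUE(w[labels[t]] > 1e-10) &&
      all(sub_u %in% terms[[t]]$factors)
  }, TRUE))
  if (length(cand)) {
    pure <- vapply(cand, function(t)
      all(vapply(terms[[t]]$live, nested_under_u, TRUE)), TRUE)
    if (any(pure)) cand <- cand[pure]
    sizes <- vapply(cand, function(t)
      nlevels(.term_cells(data, terms[[t]])), 0L)
    d <- cand[which.min(sizes)]
    unit_cells <- .term_cells(data, terms[[d]])
    d_factors <- terms[[d]]$factors
  } else {
    unit_cells <- factor(seq_len(nrow(data)))       # rows
    d_factors <- unique(unlist(lapply(terms, `[[`, "factors")))
  }
  strata_f <- d_factors[!(d_factors %in% terms[[u]]$live) &
                          !vapply(d_factors, nested_under_u, TRUE)]
  strata <- if (length(strata_f))
    interaction(data[strata_f], drop = TRUE) else factor(rep(1, nrow(data)))
  list(unit = unit_cells, strata = strata)
}

## row permutation induced by permuting whole unit blocks within strata
.block_perm_groups <- function(unit, strata) {
  n <- length(unit)
  out <- list()
  for (s in levels(strata)) {
    rows <- which(strata == s)
    blocks <- split(rows, droplevels(unit[rows]))
    if (length(unique(lengths(blocks))) != 1L)
      stop("unequal exchangeable unit sizes; design not balanced")
    out[[s]] <- blocks
  }
  out
}

.draw_block_perm <- function(groups, n) {
  perm <- seq_len(n)
  for (blocks in groups) {
    shuffled <- sample(length(blocks))
    for (j in seq_along(blocks))
      perm[blocks[[j]]] <- blocks[[shuffled[j]]]
  }
  perm
}

## Freedman-Lane permutation p-value for one term.  The reduced model
## drops the tested term and every term whose span contains it (terms
## nested under it would absorb its effect); y* = H_red y + P (I-H_red) y
## with P permuting whole exchangeable units.  All sums of squares are
## evaluated on G* = M G M' with M = H_red + P (I - H_red), using only
## products with the fixed orthonormal basis Q (no per-permutation
## eigenwork).
.fl_pvalue <- function(G, Q, blocks, u, terms, data, df_all, w, ems, F_obs,
                       total_SS, n_perm, exhaustive) {
  n <- nrow(G)
  k <- length(terms)
  sub_u <- terms[[u]]$factors
  reduced <- which(vapply(seq_len(k), function(t)
    !all(sub_u %in% terms[[t]]$factors), TRUE))
  Xr <- matrix(1, n, 1)
  for (t in reduced)
    Xr <- cbind(Xr, stats::model.matrix(~ 0 + .term_cells(data, terms[[t]])))
  qr_r <- qr(Xr)
  Qr <- qr.Q(qr_r)[, seq_len(qr_r$rank), drop = FALSE]

  Hq <- function(Xm) Qr %*% crossprod(Qr, Xm)   # H_red %*% Xm
  HQ <- Hq(Q)                                   # fixed across permutations
  GH <- G %*% Qr
  B1 <- (GH - Qr %*% crossprod(Qr, GH)) %*% t(Qr)  # (I-H) G H

  pu <- .permutation_units(u, terms, data, w)
  groups <- .block_perm_groups(pu$unit, pu$strata)

  stat_for_perm <- function(perm) {
    inv <- integer(n); inv[perm] <- seq_len(n)
    PQ <- Q[inv, , drop = FALSE]                # P' Q
    V <- HQ + PQ - Hq(PQ)                       # M' Q
    GV <- G %*% V
    ss_cols <- colSums(V * GV)
    SSs <- vapply(blocks, function(b) sum(ss_cols[b]), 0)
    tr_star <- total_SS + 2 * sum(B1[cbind(perm, seq_len(n))])
    SS_res <- tr_star - sum(SSs)
    MSs <- c(SSs, SS_res) / df_all
    den <- sum(w * MSs[names(w)])
    if (den <= 0) return(NA_real_)
    MSs[u] / den
  }

  if (exhaustive) {
    block_sets <- lapply(groups, function(blocks) .all_perms(seq_along(blocks)))
    total <- prod(vapply(block_sets, length, 0))
    if (total > 50000)
      stop("exhaustive enumeration would require ", total, " permutations")
    grid <- do.call(expand.grid, lapply(block_sets, seq_along))
    Fp <- vapply(seq_len(nrow(grid)), function(r) {
      perm <- seq_len(n)
      for (g in seq_along(groups)) {
        blocks <- groups[[g]]
        shuffled <- block_sets[[g]][[grid[r, g]]]
        for (j in seq_along(blocks))
          perm[blocks[[j]]] <- blocks[[shuffled[j]]]
      }
      stat_for_perm(perm)
    }, 0)
    return(mean(Fp >= F_obs - 1e-12, na.rm = TRUE))
  }
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    Fp <- stat_for_perm(.draw_block_perm(groups, n))
    if (!is.na(Fp) && Fp >= F_obs - 1e-12) exceed <- exceed + 1L
  }
  (exceed + 1) / (n_perm + 1)
}

#' @export
print.permanova_table <- function(x, ...) {
  cat("PERMANOVA table (balanced mixed design)\n")
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], function(v) round(v, 4))
  print(y, row.names = FALSE)
  cat(sprintf("Total SS = %.4f; model R2 = %.4f\n",
              attr(x, "total_SS"), attr(x, "total_R2")))
  invisible(x)
}

#' Percentages of variation from components of variation
#'
#' Converts signed square-root components of variation (`sigma'`) into the
#' percentage each squared component contributes to the total, truncating
#' negative components to zero by default.
#'
#' @param sigma_prime Named numeric vector of signed `sigma'` values.
#' @param truncate_negative Truncate negative components before squaring.
#' @return Named numeric vector of percentages summing to 100.
#' @export
component_percentages <- function(sigma_prime, truncate_negative = TRUE) {
  s2 <- sign(sigma_prime) * sigma_prime^2
  if (truncate_negative) s2 <- pmax(s2, 0)
  100 * s2 / sum(s2)
}

#' Sampling-variability share of a PERMANOVA table
#'
#' The combined percentage of variation of the residual and the
#' observer-by-location and observer-by-transect interactions: the proxy
#' for sampling variability (observer effects, instantaneous fish
#' displacement and counting/detection errors).
#'
#' @param tab A [permanova()] table, or a named vector of percentages.
#' @param sampling_terms Terms counted as sampling variability.
#' @return Numeric percentage.
#' @export
sampling_variability_pct <- function(tab,
                                     sampling_terms = c("Residual",
                                                        "Location:Observer",
                                                        "Transect:Observer")) {
  if (inherits(tab, "permanova_table")) {
    pct <- stats::setNames(tab$pct_variation, tab$term)
  } else pct <- tab
  sum(pct[intersect(sampling_terms, names(pct))])
}
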