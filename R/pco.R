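#' Principal coordinates analysis (classical scaling)
#'
#' Eigen-decomposition of the Gower-centered inner-product matrix of a
#' dissimilarity matrix.  Axes are ordered by decreasing eigenvalue;
#' negative-eigenvalue axes (arising from semi-metric dissimilarities such
#' as Bray-Curtis) are reported but carry no real-valued scores and are
#' excluded from downstream canonical analysis.
#'
#' @param D A [dissimilarity()] object, `dist`, or square symmetric matrix.
#' @param tol Eigenvalues with absolute value below `tol * max(|lambda|)`
#'   are treated as null.
#' @return A list of class `pco`: `scores` (n x m matrix for the m
#'   positive axes, scaled to `sqrt(lambda)`), `eigenvalues` (all n, in
#'   decreasing order), `n_positive`, `n_negative`.
#' @export
pco <- function(D, tol = 1e-8) {
  Dm <- .as_dist_matrix(D)
  G <- .gower_center(Dm)
  e <- eigen(G, symmetric = TRUE)
  lam <- e$values
  thr <- tol * max(abs(lam), 1e-300)
  pos <- lam > thr
  scores <- sweep(e$vectors[, pos, drop = FALSE], 2, sqrt(lam[pos]), `*`)
  structure(list(scores = scores, eigenvalues = lam,
                 vectors = e$vectors, n_positive = sum(pos),
                 n_negative = sum(lam < -thr)),
            class = "pco")
}

#' @export
print.pco <- function(x, ...) {
  cat(sprintf("<pco> %d observations; %d positive, %d negative eigenvalues\n",
              length(x$eigenvalues), x$n_positive, x$n_negative))
  invisible(x)
}

## Project a held-out observation onto the PCO axes of a training set.
## a = -d^2/2 against the training observations; double centering uses the
## training row means and grand mean; q = g' V Lambda^{-1/2}.
.pco_project <- function(p, d_new) {
  A_means <- attr(p, "a_rowmeans"); A_grand <- attr(p, "a_grand")
  a <- -0.5 * d_new^2
  g <- a - A_means - mean(a) + A_grand
  lam <- p$eigenvalues[seq_len(ncol(p$scores))]
  as.numeric(crossprod(g, p$scores) / lam)
}

#' Canonical analysis of principal coordinates with leave-one-out CV
#'
#' CAP: a discriminant analysis of group membership on the first `m` PCO
#' axes of a dissimilarity matrix, assessed by leave-one-out
#' cross-validation.  For each held-out observation the PCO is recomputed
#' on the remaining observations, the held-out point is projected onto the
#' retained axes, linear discriminant analysis is fitted on the training
#' scores, and the held-out point is classified to the nearest group in
#' canonical space.  The classification error is the percentage of
#' misclassified observations.
#'
#' @param D A [dissimilarity()] object, `dist`, or square symmetric matrix.
#' @param groups Factor (or coercible) of group labels, one per
#'   observation; every group needs at least two members.
#' @param m Number of PCO axes retained (default 8); clipped with a
#'   warning when it exceeds the available positive axes.
#' @return A list of class `cap_result`: `groups`, `m` (possibly clipped),
#'   `predicted` (LOO predictions), `error_pct`, `confusion`.
#' @export
cap_loocv <- function(D, groups, m = 8) {
  Dm <- .as_dist_matrix(D)
  groups <- factor(groups)
  n <- nrow(Dm)
  stopifnot(length(groups) == n, nlevels(groups) >= 2)
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  if (m < 1) stop("m must be >= 1")
  predicted <- character(n)
  m_used <- integer(n)
  for (i in seq_len(n)) {
    Dt <- Dm[-i, -i, drop = FALSE]
    A <- -0.5 * Dt^2
    p <- pco(Dt)
    attr(p, "a_rowmeans") <- rowMeans(A)
    attr(p, "a_grand") <- mean(A)
    mi <- min(m, p$n_positive, nrow(Dt) - nlevels(groups))
    m_used[i] <- mi
    tr_scores <- p$scores[, seq_len(mi), drop = FALSE]
    colnames(tr_scores) <- paste0("PCO", seq_len(mi))
    p$scores <- tr_scores
    q <- .pco_project(p, Dm[-i, i])
    fit <- MASS::lda(tr_scores, grouping = droplevels(groups[-i]))
    predicted[i] <- as.character(stats::predict(
      fit, matrix(q, 1, dimnames = list(NULL, colnames(tr_scores))))$class)
  }
  if (any(m_used < m))
    warning("m clipped to ", min(m_used), " available axes for some folds")
  err <- 100 * mean(predicted != as.character(groups))
  structure(list(groups = groups, m = m, m_used = m_used,
                 predicted = predicted, error_pct = err,
                 confusion = table(observed = groups,
                                   predicted = factor(predicted,
                                                      levels(groups)))),
            class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("<cap_result> %d groups, m = %d axes: LOO classification error %.2f%%\n",
              nlevels(x$groups), x$m, x$error_pct))
  invisible(x)
}
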