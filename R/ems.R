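## Expected mean squares for balanced mixed designs via the
## Cornfield-Tukey auxiliary-table rules.
##
## A term is described by its full subscript set (`factors`: the data
## columns whose interaction defines its cells, including the factors it
## is nested in) and its live subscripts (`live`: the non-bracketed ones).
## The variance component of term t contributes to E[MS] of term u iff
## t's subscript set contains u's and every live subscript of t outside
## u's set is a random factor (a fixed extra live subscript zeroes the
## multiplier).  The coefficient is N / cells(t).  The residual component
## has coefficient 1 in every row.

#' Terms of the standard survey design
#'
#' The PERMANOVA / mixed-model structure used throughout: Island as fixed
#' factor, Location nested in Island and Transect nested in Location as
#' random factors, Observer as crossed random factor with its interactions
#' Island:Observer, Location:Observer and Transect:Observer.
#'
#' @param include_observer Logical; `FALSE` drops the observer factor and
#'   its interactions (the reduced model used for the multivariate
#'   pseudo standard error).
#' @return A list of term descriptions (label, factors, live, random).
#' @export
default_design_terms <- function(include_observer = TRUE) {
  terms <- list(
    list(label = "Island", factors = "island", live = "island",
         random = FALSE),
    list(label = "Location", factors = c("island", "location"),
         live = "location", random = TRUE),
    list(label = "Transect", factors = c("island", "location", "transect"),
         live = "transect", random = TRUE))
  if (include_observer) {
    terms <- c(terms, list(
      list(label = "Observer", factors = "observer", live = "observer",
           random = TRUE),
      list(label = "Island:Observer", factors = c("island", "observer"),
           live = c("island", "observer"), random = TRUE),
      list(label = "Location:Observer",
           factors = c("island", "location", "observer"),
           live = c("location", "observer"), random = TRUE),
      list(label = "Transect:Observer",
           factors = c("island", "location", "transect", "observer"),
           live = c("transect", "observer"), random = TRUE)))
  }
  terms
}

.term_cells <- function(data, term)
  interaction(data[term$factors], drop = TRUE, lex.order = TRUE)

#' Expected-mean-square coefficient table for a balanced mixed design
#'
#' Builds the coefficient of each variance component in the expected mean
#' square of each term, by the Cornfield-Tukey rules for balanced designs
#' (fixed factors enter through a finite-population multiplier of zero
#' when they appear as an extra live subscript).  The resulting
#' upper-triangular system is what components of variation are solved
#' from, and what pseudo-F denominators are derived from.
#'
#' @param data Data frame holding the factor columns named in `terms`.
#' @param terms List of term descriptions as in [default_design_terms()].
#'   The randomness of a base factor is taken from the `random` flag of
#'   the term whose live set is exactly that factor.
#' @return A list of class `ems_table`: `coefficients` (terms + Residual
#'   square matrix: row = E[MS] of the term, column = component), `df`
#'   (degrees of freedom per row) and `n_cells` per term.
#' @examples
#' d <- expand.grid(island = c("A", "B"), rep = 1:5)
#' # one-way random: E[MS_between] = sigma2_e + 5 sigma2_A
#' @export
ems_table <- function(data, terms) {
  n <- nrow(data)
  labels <- vapply(terms, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicated term labels")

  ## randomness per base factor
  base_random <- list()
  for (t in terms)
    if (length(t$live) == 1) base_random[[t$live]] <- t$random
  all_factors <- unique(unlist(lapply(terms, `[[`, "factors")))
  missing_status <- setdiff(all_factors, names(base_random))
  for (f in missing_status) base_random[[f]] <- TRUE

  cells <- lapply(terms, .term_cells, data = data)
  n_cells <- vapply(cells, nlevels, 0L)
  for (i in seq_along(terms)) {
    tab <- table(cells[[i]])
    if (length(unique(tab)) != 1L)
      stop("unsupported design: term '", labels[i], "' is unbalanced")
  }

  k <- length(terms)
  C <- matrix(0, k + 1, k + 1,
              dimnames = list(c(labels, "Residual"), c(labels, "Residual")))
  for (u in seq_len(k)) {
    for (t in seq_len(k)) {
      if (!all(terms[[u]]$factors %in% terms[[t]]$factors)) next
      extra_live <- setdiff(terms[[t]]$live, terms[[u]]$factors)
      if (length(extra_live) &&
          !all(vapply(extra_live, function(f) isTRUE(base_random[[f]]), TRUE)))
        next
      C[u, t] <- n / n_cells[t]
    }
  }
  C[, k + 1] <- 1            # residual component in every E[MS]
  C[k + 1, seq_len(k)] <- 0  # E[MS_residual] = sigma2_e

  ## degrees of freedom by Moebius over contained terms
  df <- integer(k)
  for (u in order(vapply(terms, function(t) length(t$factors), 0L))) {
    contained <- vapply(seq_len(k), function(t)
      t != u && all(terms[[t]]$factors %in% terms[[u]]$factors), TRUE)
    df[u] <- n_cells[u] - 1L - sum(df[contained])
  }
  df <- c(df, n - 1L - sum(df))
  names(df) <- rownames(C)
  if (any(df < 0)) stop("inconsistent term list: negative degrees of freedom")
  structure(list(coefficients = C, df = df,
                 n_cells = stats::setNames(c(n_cells, n), rownames(C)),
                 terms = terms),
            class = "ems_table")
}

#' @export
print.ems_table <- function(x, ...) {
  cat("<ems_table> expected mean square coefficients:\n")
  print(round(x$coefficients, 4))
  cat("df:", paste(names(x$df), x$df, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

## Denominator weights for the pseudo-F of term u: weights w over the
## other rows with sum_t w_t E[MS_t] = E[MS_u] minus the contribution of
## u's own component (quasi-F when several rows are needed).
.denominator_weights <- function(ems, u) {
  C <- ems$coefficients
  target <- C[u, ]
  target[u] <- 0
  others <- setdiff(seq_len(nrow(C)), u)
  A <- t(C[others, , drop = FALSE])
  w <- qr.solve(A, target, tol = 1e-10)
  if (max(abs(A %*% w - target)) > 1e-8)
    stop("no exact denominator expectation for term ", rownames(C)[u])
  ## drop numerically-zero weights
  w[abs(w) < 1e-10] <- 0
  stats::setNames(w, rownames(C)[others])
}
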