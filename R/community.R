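#' Build an observations-by-species community matrix
#'
#' Applies (in order) the distance-window restriction, the counting metric
#' (MaxCount, MinCount or presence/absence) and the data transformation to
#' a set of observation records.
#'
#' @param records List of [observation_record()] objects.
#' @param metric `"max_count"` (total individuals per species over the
#'   pass), `"min_count"` (maximum simultaneous count, a.k.a. MaxN) or
#'   `"presence_absence"`.
#' @param window Optional distance window `c(lo, hi)` in meters passed to
#'   [split_distance_window()]; `NULL` keeps every event.
#' @param length_m Full transect length in meters (used for the
#'   time-to-distance mapping).
#' @param transform Transformation applied to the counts; see
#'   [transform_counts()].
#' @param species Optional character vector fixing the species set and
#'   column order; defaults to all species present in `records`.
#' @return An object of class `community_matrix`: a list with the numeric
#'   matrix `counts` (rows = observations), the factor table `row_meta`,
#'   and the `metric`, `window` and `transform` provenance fields.
#' @export
community_matrix <- function(records,
                             metric = c("max_count", "min_count",
                                        "presence_absence"),
                             window = NULL, length_m = 50,
                             transform = c("none", "fourth_root", "log1p",
                                           "presence_absence"),
                             species = NULL) {
  metric <- match.arg(metric)
  transform <- match.arg(transform)
  meta <- .check_records(records)
  if (!is.null(window))
    records <- lapply(records, split_distance_window, window = window,
                      length_m = length_m)
  if (is.null(species)) {
    species <- sort(unique(unlist(lapply(records,
                                         function(r) r$events$species))))
    if (!length(species)) species <- character()
  }
  counter <- if (metric == "min_count") min_count else max_count
  counts <- t(vapply(records, function(r) counter(r$events, species),
                     numeric(length(species))))
  if (length(species) == 1L) counts <- matrix(counts, ncol = 1L,
                                              dimnames = list(NULL, species))
  if (metric == "presence_absence") counts <- (counts > 0) + 0
  obj <- structure(list(counts = counts, row_meta = meta, metric = metric,
                        window = window, transform = "none"),
                   class = "community_matrix")
  transform_counts(obj, transform)
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> %d observations x %d species; metric=%s, transform=%s",
              nrow(x$counts), ncol(x$counts), x$metric, x$transform))
  if (!is.null(x$window))
    cat(sprintf(", window=[%g,%g] m", x$window[1], x$window[2]))
  cat("\n")
  invisible(x)
}

#' Transform community counts
#'
#' `fourth_root` is `y^(1/4)`, `log1p` is `log(1+y)` (an offset of one is
#' used because counts contain zeros), `presence_absence` is the indicator
#' `y > 0`, and `none` is the identity.
#'
#' @param x A [community_matrix()].
#' @param transform One of `"none"`, `"fourth_root"`, `"log1p"`,
#'   `"presence_absence"`.
#' @return The transformed `community_matrix` with updated provenance.
#' @export
transform_counts <- function(x, transform) {
  stopifnot(inherits(x, "community_matrix"))
  if (!is.character(transform) || length(transform) != 1L ||
      !transform %in% c("none", "fourth_root", "log1p", "presence_absence"))
    stop("unknown transform: ", paste(transform, collapse = ","))
  y <- x$counts
  x$counts <- switch(transform,
                     none = y,
                     fourth_root = y^0.25,
                     log1p = log1p(y),
                     presence_absence = (y > 0) + 0)
  if (transform != "none")
    x$transform <- if (x$transform == "none") transform
                   else paste(x$transform, transform, sep = "+")
  x
}

#' Species density per observation
#'
#' The number of species with a positive count in each row of the
#' community matrix (species recorded per fixed transect area).
#'
#' @param x A [community_matrix()] or a numeric matrix/vector of counts.
#' @return Integer vector, one value per observation.
#' @export
species_density <- function(x) {
  y <- if (inherits(x, "community_matrix")) x$counts else x
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  as.integer(rowSums(y > 0))
}

#' Shannon diversity per observation
#'
#' `H = -sum(p_s * log(p_s))` with `p_s = y_s / sum(y)`, using the natural
#' logarithm by default (configurable via `base`).  Rows with zero total or
#' a single species have `H = 0`.
#'
#' @inheritParams species_density
#' @param base Logarithm base; default `exp(1)`.
#' @return Numeric vector, one value per observation.
#' @export
shannon_diversity <- function(x, base = exp(1)) {
  y <- if (inherits(x, "community_matrix")) x$counts else x
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  apply(y, 1, function(row) {
    tot <- sum(row)
    if (tot <= 0) return(0)
    p <- row[row > 0] / tot
    if (length(p) <= 1L) return(0)
    -sum(p * log(p, base = base))
  })
}
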