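#' Hierarchical study design for repeated video transects
#'
#' Describes a balanced survey layout: islands, locations nested in islands,
#' fixed transects nested in locations, a crossed set of observers, and a
#' number of consecutive repeats per observer.  The default corresponds to
#' 2 islands x 5 locations x 3 transects x 3 observers x 6 repeats, i.e.
#' 540 transect passes on 50 m transects surveyed 2.5 m to either side of
#' the line.
#'
#' @param n_islands Number of islands (fixed spatial factor).
#' @param locations_per_island Locations nested within each island.
#' @param transects_per_location Fixed transects nested within each location.
#' @param n_observers Observers; each observer covers every transect.
#' @param repeats_per_observer Consecutive passes per observer and transect.
#' @param transect_length_m Transect length in meters.
#' @param half_width_m Half strip width in meters (fish are counted within
#'   this distance of the line on either side).
#'
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design()
#' n_observations(d) # 540
#' @export
study_design <- function(n_islands = 2,
                         locations_per_island = 5,
                         transects_per_location = 3,
                         n_observers = 3,
                         repeats_per_observer = 6,
                         transect_length_m = 50,
                         half_width_m = 2.5) {
  dims <- c(n_islands = n_islands, locations_per_island = locations_per_island,
            transects_per_location = transects_per_location,
            n_observers = n_observers, repeats_per_observer = repeats_per_observer)
  if (any(dims < 1) || any(dims != round(dims)))
    stop("all design dimensions must be positive integers")
  if (transect_length_m <= 0 || half_width_m <= 0)
    stop("transect_length_m and half_width_m must be positive")
  structure(list(n_islands = as.integer(n_islands),
                 locations_per_island = as.integer(locations_per_island),
                 transects_per_location = as.integer(transects_per_location),
                 n_observers = as.integer(n_observers),
                 repeats_per_observer = as.integer(repeats_per_observer),
                 transect_length_m = transect_length_m,
                 half_width_m = half_width_m),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_islands, "islands x", x$locations_per_island,
      "locations x", x$transects_per_location, "transects x", x$n_observers,
      "observers x", x$repeats_per_observer, "repeats =",
      n_observations(x), "observations\n")
  cat("Transect:", x$transect_length_m, "m long,", 2 * x$half_width_m,
      "m strip width\n")
  invisible(x)
}

#' Total number of observations implied by a design
#'
#' @param design A [study_design()].
#' @return Integer: the product of the five design dimensions.
#' @export
n_observations <- function(design) {
  stopifnot(inherits(design, "study_design"))
  with(design, n_islands * locations_per_island * transects_per_location *
         n_observers * repeats_per_observer)
}

#' Expand a design into its observation-level factor table
#'
#' One row per transect pass, with globally unique location and transect
#' labels (locations are nested in islands, transects in locations) and the
#' temporal order of the passes.  Observers cover each transect back to
#' back: observer 1 makes passes 1..r, observer 2 passes r+1..2r, and so
#' on, alternating direction between consecutive passes.
#'
#' @param design A [study_design()].
#' @return A data frame with columns `island`, `location`, `transect`,
#'   `observer`, `repeat_index`, `order_index` (1..observers*repeats within
#'   each transect) and `direction`.
#' @export
design_factors <- function(design) {
  stopifnot(inherits(design, "study_design"))
  d <- design
  islands <- paste0("I", seq_len(d$n_islands))
  rows <- expand.grid(
    repeat_index = seq_len(d$repeats_per_observer),
    observer = paste0("Obs", seq_len(d$n_observers)),
    transect_i = seq_len(d$transects_per_location),
    location_i = seq_len(d$locations_per_island),
    island = islands,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$location <- paste0(rows$island, "L", rows$location_i)
  rows$transect <- paste0(rows$location, "T", rows$transect_i)
  obs_idx <- match(rows$observer, paste0("Obs", seq_len(d$n_observers)))
  rows$order_index <- (obs_idx - 1L) * d$repeats_per_observer + rows$repeat_index
  rows$direction <- ifelse(rows$order_index %% 2L == 1L, "forward", "reverse")
  out <- rows[order(rows$island, rows$location, rows$transect, rows$order_index),
              c("island", "location", "transect", "observer",
                "repeat_index", "order_index", "direction")]
  rownames(out) <- NULL
  out
}

## Distance window on a transect of total length L, centred: a window of
## length w runs from (L-w)/2 to (L+w)/2.  The canonical five windows on a
## 50 m transect are 0-50, 5-45, 10-40, 15-35 and 20-30 m.

#' Centred distance window for a nominal transect length
#'
#' @param length_m Nominal window length in meters.
#' @param total_m Full transect length in meters.
#' @return Numeric vector `c(lo, hi)`.
#' @examples
#' window_for_length(30) # c(10, 40)
#' @export
window_for_length <- function(length_m, total_m = 50) {
  if (length_m <= 0 || length_m > total_m)
    stop("length_m must be in (0, total_m]")
  c((total_m - length_m) / 2, (total_m + length_m) / 2)
}
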