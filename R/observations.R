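#' Detection events for one transect pass
#'
#' Events are stored as a data frame with one row per detection: the species
#' label, the on-screen interval `[t_start, t_end]` in seconds from the start
#' of the pass, and the number of individuals counted in the event.
#'
#' @param species Character vector of species labels.
#' @param t_start,t_end Numeric vectors, seconds from the start of the pass;
#'   `0 <= t_start <= t_end`.
#' @param n_individuals Positive integer counts per event.
#' @return A data frame with columns `species`, `t_start`, `t_end`,
#'   `n_individuals`.
#' @export
detection_events <- function(species = character(), t_start = numeric(),
                             t_end = t_start, n_individuals = integer()) {
  ev <- data.frame(species = as.character(species),
                   t_start = as.numeric(t_start),
                   t_end = as.numeric(t_end),
                   n_individuals = as.integer(n_individuals),
                   stringsAsFactors = FALSE)
  if (nrow(ev)) {
    if (any(ev$t_start < 0)) stop("t_start must be >= 0")
    if (any(ev$t_end < ev$t_start)) stop("t_end must be >= t_start")
    if (any(ev$n_individuals < 1)) stop("n_individuals must be >= 1")
  }
  ev
}

#' A single covered transect pass by one observer
#'
#' @param island,location,transect,observer Factor labels. Locations must be
#'   globally unique (nested in island) and transects globally unique
#'   (nested in location).
#' @param repeat_index Repeat number within (transect, observer).
#' @param order_index Temporal order of this pass among all passes of the
#'   transect (1..observers*repeats).
#' @param direction `"forward"` or `"reverse"`.
#' @param duration_s Pass duration in seconds (positive).
#' @param turbidity Ordinal turbidity grade of the transect (larger =
#'   more turbid).
#' @param events A [detection_events()] data frame.
#' @param window Optional distance window annotation `c(lo, hi)` in meters.
#' @return An object of class `observation_record`.
#' @export
observation_record <- function(island, location, transect, observer,
                               repeat_index, order_index,
                               direction = "forward", duration_s,
                               turbidity = NA_real_,
                               events = detection_events(),
                               window = NULL) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (!direction %in% c("forward", "reverse"))
    stop("direction must be 'forward' or 'reverse'")
  structure(list(island = as.character(island),
                 location = as.character(location),
                 transect = as.character(transect),
                 observer = as.character(observer),
                 repeat_index = as.integer(repeat_index),
                 order_index = as.integer(order_index),
                 direction = direction,
                 duration_s = as.numeric(duration_s),
                 turbidity = as.numeric(turbidity),
                 events = events,
                 window = window),
            class = "observation_record")
}

#' @export
print.observation_record <- function(x, ...) {
  cat(sprintf("<observation_record> %s / %s / pass %d (%s, repeat %d), %.0f s, %d events\n",
              x$transect, x$observer, x$order_index, x$direction,
              x$repeat_index, x$duration_s, nrow(x$events)))
  invisible(x)
}

.records_meta <- function(records) {
  data.frame(island = vapply(records, `[[`, "", "island"),
             location = vapply(records, `[[`, "", "location"),
             transect = vapply(records, `[[`, "", "transect"),
             observer = vapply(records, `[[`, "", "observer"),
             repeat_index = vapply(records, `[[`, 0L, "repeat_index"),
             order_index = vapply(records, `[[`, 0L, "order_index"),
             direction = vapply(records, `[[`, "", "direction"),
             duration_s = vapply(records, `[[`, 0, "duration_s"),
             turbidity = vapply(records, `[[`, NA_real_, "turbidity"),
             stringsAsFactors = FALSE)
}

.check_records <- function(records) {
  meta <- .records_meta(records)
  ## nesting: a location label may not appear under two islands, a transect
  ## label not under two locations
  if (anyDuplicated(unique(meta[c("island", "location")])$location))
    stop("integrity error: location labels are not nested within islands")
  if (anyDuplicated(unique(meta[c("location", "transect")])$transect))
    stop("integrity error: transect labels are not nested within locations")
  if (anyDuplicated(meta[c("transect", "order_index")]))
    stop("integrity error: duplicated order_index within a transect")
  if (anyDuplicated(meta[c("transect", "observer", "repeat_index")]))
    stop("integrity error: duplicated repeat_index within (transect, observer)")
  invisible(meta)
}

.record_cols <- c("island", "location", "transect", "observer",
                  "repeat_index", "order_index", "direction", "duration_s",
                  "turbidity")
.event_cols <- c("species", "t_start", "t_end", "n_individuals")

#' Write observation records to a long-format CSV file
#'
#' One row per detection event, carrying the pass-level factor labels;
#' passes without any detection are kept as a single row with an empty
#' species field and zero count so that the full design round-trips.
#'
#' @param records List of [observation_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(records, path) {
  .check_records(records)
  rows <- lapply(records, function(r) {
    head <- as.data.frame(r[.record_cols], stringsAsFactors = FALSE)
    ev <- r$events
    if (!nrow(ev))
      ev <- data.frame(species = "", t_start = NA_real_, t_end = NA_real_,
                       n_individuals = 0L, stringsAsFactors = FALSE)
    cbind(head[rep(1L, nrow(ev)), , drop = FALSE], ev, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read observation records from a long-format CSV file
#'
#' The expected dialect is the one produced by [write_observations()]:
#' comma-delimited UTF-8, one detection event per row, with pass-level
#' columns `island`, `location`, `transect`, `observer`, `repeat_index`,
#' `order_index`, `direction`, `duration_s`, `turbidity` and event-level
#' columns `species`, `t_start`, `t_end`, `n_individuals`.  Rows with an
#' empty species field mark passes without detections.
#'
#' @param path Input file path.
#' @return A list of [observation_record()] objects, ordered by island,
#'   location, transect and pass order.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(.record_cols, .event_cols)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing columns: ", paste(missing, collapse = ", "))
  key <- interaction(df$island, df$location, df$transect, df$observer,
                     df$repeat_index, drop = TRUE, lex.order = TRUE)
  records <- lapply(split(seq_len(nrow(df)), key), function(ix) {
    h <- df[ix[1L], .record_cols]
    ev <- df[ix, .event_cols]
    ev <- ev[!(is.na(ev$species) | ev$species == ""), , drop = FALSE]
    observation_record(h$island, h$location, h$transect, h$observer,
                       h$repeat_index, h$order_index, h$direction,
                       h$duration_s, h$turbidity,
                       events = detection_events(ev$species, ev$t_start,
                                                 ev$t_end, ev$n_individuals))
  })
  meta <- .check_records(records)
  ord <- order(meta$island, meta$location, meta$transect, meta$order_index)
  unname(records[ord])
}

#' Restrict a pass to a distance window along the transect
#'
#' Detection times are mapped to along-transect distances assuming a
#' constant swimming speed within the pass: `d = (t_start / duration_s) *
#' length_m`.  An event is kept when its mapped start distance lies in the
#' closed interval `[lo, hi]`.  For reverse passes the distance is measured
#' from the pass starting end, which is immaterial for the centred windows
#' used throughout.
#'
#' @param record An [observation_record()].
#' @param window Numeric `c(lo, hi)` in meters, `0 <= lo < hi <= length_m`.
#' @param length_m Full transect length in meters.
#' @return A new `observation_record` containing only the events inside the
#'   window, annotated with `window`.
#' @export
split_distance_window <- function(record, window, length_m = 50) {
  lo <- window[1]; hi <- window[2]
  if (lo >= hi) stop("window must satisfy lo < hi")
  if (lo < 0 || hi > length_m) stop("window must lie within [0, length_m]")
  r <- record
  if (nrow(r$events)) {
    d <- (r$events$t_start / r$duration_s) * length_m
    r$events <- r$events[d >= lo & d <= hi, , drop = FALSE]
    rownames(r$events) <- NULL
  }
  r$window <- c(lo, hi)
  r
}

#' Total count per species over a pass (MaxCount)
#'
#' MaxCount is the total number of individuals of each species recorded
#' over the whole pass: the sum of the per-event counts.
#'
#' @param events A [detection_events()] data frame.
#' @param species Optional character vector fixing the species set (and
#'   column order) of the result; defaults to the species present.
#' @return Named integer vector of counts per species.
#' @export
max_count <- function(events, species = NULL) {
  if (is.null(species)) species <- sort(unique(events$species))
  out <- stats::setNames(integer(length(species)), species)
  if (nrow(events)) {
    s <- tapply(events$n_individuals, events$species, sum)
    out[names(s)] <- as.integer(s)
  }
  out
}

#' Maximum simultaneous count per species (MinCount / MaxN)
#'
#' MinCount is the maximum, over time, of the number of individuals of a
#' species visible simultaneously: the interval-stabbing maximum of the
#' event presence intervals `[t_start, t_end]` weighted by the event
#' counts.  Because intervals are closed, the maximum is attained at some
#' event start, so the sweep evaluates the overlap sum at each start time.
#'
#' @inheritParams max_count
#' @return Named integer vector of counts per species.
#' @export
min_count <- function(events, species = NULL) {
  if (is.null(species)) species <- sort(unique(events$species))
  out <- stats::setNames(integer(length(species)), species)
  if (nrow(events)) {
    for (sp in unique(events$species)) {
      e <- events[events$species == sp, , drop = FALSE]
      stab <- vapply(e$t_start, function(t)
        sum(e$n_individuals[e$t_start <= t & e$t_end >= t]), 0)
      out[sp] <- as.integer(max(stab))
    }
  }
  out
}
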