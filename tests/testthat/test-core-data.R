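test_that("detection events and records enforce their invariants", {
  expect_error(detection_events("a", -1, 0, 1), "t_start")
  expect_error(detection_events("a", 5, 4, 1), "t_end")
  expect_error(detection_events("a", 0, 1, 0), "n_individuals")
  expect_error(make_record(duration_s = 0), "duration_s")

  ## duplicated order_index within a transect is an integrity error
  recs <- list(make_record(order_index = 1),
               make_record(order_index = 1, repeat_index = 2))
  expect_error(transectvar:::.check_records(recs), "order_index")
  ## location label appearing under two islands breaks nesting
  r1 <- make_record()
  r2 <- make_record(); r2$island <- "I2"; r2$order_index <- 2L
  expect_error(transectvar:::.check_records(list(r1, r2)), "nested")
})

test_that("long-format CSV round-trips records exactly", {
  sim <- small_sim(seed = 11, n_species = 4,
                   design = study_design(2, 2, 1, 2, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(sim$records, path)
  back <- read_observations(path)
  expect_length(back, length(sim$records))
  key <- function(r) paste(r$transect, r$observer, r$repeat_index)
  back <- back[match(vapply(sim$records, key, ""), vapply(back, key, ""))]
  for (i in seq_along(back)) {
    expect_equal(back[[i]][transectvar:::.record_cols],
                 sim$records[[i]][transectvar:::.record_cols])
    expect_equal(back[[i]]$events, sim$records[[i]]$events,
                 tolerance = 1e-12)
  }
  ## a well-formed small file: one pass, three events
  r <- make_record(events = detection_events(c("a", "b", "a"),
                                             c(1, 2, 3), c(2, 3, 4),
                                             c(2, 1, 3)))
  write_observations(list(r), path)
  one <- read_observations(path)
  expect_length(one, 1)
  expect_equal(nrow(one[[1]]$events), 3)
  ## missing column is a format error
  df <- utils::read.csv(path)
  utils::write.csv(df[setdiff(names(df), "species")], path,
                   row.names = FALSE)
  expect_error(read_observations(path), "missing columns")
})

test_that("distance windows follow the linear time-to-distance map", {
  ev <- detection_events(c("a", "b", "c"), t_start = c(4, 50, 98),
                         t_end = c(5, 51, 99), n_individuals = c(1, 1, 1))
  r <- make_record(duration_s = 100, events = ev)
  ## mapped distances on a 50 m transect: 2, 25, 49
  full <- split_distance_window(r, c(0, 50), 50)
  expect_equal(nrow(full$events), 3)
  mid <- split_distance_window(r, c(20, 30), 50)
  expect_equal(mid$events$species, "b")      # midpoint maps to 25 m
  win <- split_distance_window(r, c(5, 45), 50)
  expect_equal(win$events$species, "b")      # only d = 25 retained
  expect_equal(win$window, c(5, 45))
  expect_error(split_distance_window(r, c(30, 30), 50), "lo < hi")
  ## closed window: event exactly on the boundary is retained
  r2 <- make_record(duration_s = 100,
                    events = detection_events("a", 10, 11, 1)) # d = 5
  expect_equal(nrow(split_distance_window(r2, c(5, 45), 50)$events), 1)
})

test_that("MaxCount sums events and MinCount is the interval-stabbing maximum", {
  ev <- detection_events(c("A", "A"), c(0, 10), c(2, 12), c(2, 3))
  expect_equal(max_count(ev), c(A = 5L))
  expect_equal(min_count(ev), c(A = 3L))     # disjoint intervals
  ev2 <- detection_events(c("A", "A"), c(0, 1), c(5, 4), c(2, 3))
  expect_equal(min_count(ev2), c(A = 5L))    # full overlap
  ## sweep-line case: [0,2], [1,3], [2.5,4] each of 1 -> max 2
  ev3 <- detection_events(rep("A", 3), c(0, 1, 2.5), c(2, 3, 4), c(1, 1, 1))
  expect_equal(min_count(ev3), c(A = 2L))
  ev4 <- detection_events(c("A", "B", "A"), c(0, 0, 9), c(1, 1, 10),
                          c(1, 1, 1))
  expect_equal(max_count(ev4), c(A = 2L, B = 1L))
  expect_equal(max_count(detection_events(), species = c("A", "B")),
               c(A = 0L, B = 0L))
  ## MinCount <= MaxCount on generated data, always
  sim <- small_sim(seed = 3)
  sp <- sort(unique(unlist(lapply(sim$records, function(r) r$events$species))))
  for (r in sim$records[seq(1, length(sim$records), by = 7)])
    expect_true(all(min_count(r$events, sp) <= max_count(r$events, sp)))
})

test_that("community matrices respect window nesting and transform identities", {
  sim <- small_sim(seed = 5)
  sp <- sort(unique(unlist(lapply(sim$records, function(r) r$events$species))))
  cm50 <- community_matrix(sim$records, window = c(0, 50), species = sp)
  cm45 <- community_matrix(sim$records, window = c(5, 45), species = sp)
  cm40 <- community_matrix(sim$records, window = c(10, 40), species = sp)
  expect_true(all(cm40$counts <= cm45$counts))
  expect_true(all(cm45$counts <= cm50$counts))

  expect_equal(transform_counts(cm50, "fourth_root")$counts, cm50$counts^0.25)
  expect_equal(unname(transform_counts(
    structure(list(counts = matrix(16), transform = "none"),
              class = "community_matrix"), "fourth_root")$counts[1]), 2)
  expect_equal(unname(transform_counts(
    structure(list(counts = matrix(7), transform = "none"),
              class = "community_matrix"), "presence_absence")$counts[1]), 1)
  expect_error(transform_counts(cm50, "sqrt"), "unknown transform")
  ## zero preserved by all transforms; PA is idempotent over monotone ones
  for (tf in c("fourth_root", "log1p", "presence_absence", "none")) {
    y <- transform_counts(cm50, tf)$counts
    expect_true(all((y == 0) == (cm50$counts == 0)))
    expect_equal((y > 0) + 0, (cm50$counts > 0) + 0)
  }
})

test_that("species density and Shannon diversity match direct formulas", {
  expect_equal(species_density(c(10, 10)), 2L)
  expect_equal(shannon_diversity(c(10, 10)), log(2))
  expect_equal(species_density(c(5, 0, 0)), 1L)
  expect_equal(shannon_diversity(c(5, 0, 0)), 0)
  p <- c(1, 2, 3) / 6
  expect_equal(shannon_diversity(c(1, 2, 3)), -sum(p * log(p)))
  expect_equal(round(shannon_diversity(c(1, 2, 3)), 4), 1.0114)
  expect_equal(species_density(c(0, 0)), 0L)
  expect_equal(shannon_diversity(c(0, 0)), 0)
  ## maximal on uniform rows, base configurable
  expect_equal(shannon_diversity(rep(4, 7)), log(7))
  expect_equal(shannon_diversity(c(10, 10), base = 2), 1)
  set.seed(1)
  for (i in 1:20) {
    row <- rpois(6, 3)
    expect_lte(shannon_diversity(row), log(6) + 1e-12)
  }
})
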