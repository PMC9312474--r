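#' Species trait table for the synthetic-data generator
#'
#' Draws a table of per-species traits controlling abundance, dispersion,
#' detectability and behaviour.  One third of the species are
#' underdispersed (`nu > 1`) and two thirds overdispersed (`nu < 1`),
#' mirroring the dispersion mix typical of reef fish count data.  Traits
#' for shy/attracted species (`gamma_order`), short-term site fidelity
#' (`ar1_rho`), schooling (`schooling_k`, gamma clump-size dispersion,
#' `Inf` = no schooling) and turbidity sensitivity are sparse: most species
#' are unaffected.
#'
#' @param n_species Number of species.
#' @param n_islands Number of islands (per-island assemblage effects).
#' @param seed Integer seed; trait generation is reproducible.
#' @return A data frame with one row per species and columns `species`,
#'   `base_log_abundance`, `island_effect_<i>`, `nu`,
#'   `structural_zero_prob`, `detectability`, `gamma_order`, `ar1_rho`,
#'   `schooling_k`, `turbidity_sensitivity`.
#' @export
default_species_traits <- function(n_species = 36, n_islands = 2, seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  n_under <- round(n_species / 3)
  nu <- c(stats::runif(n_under, 1.2, 2.0),
          stats::runif(n_species - n_under, 0.45, 0.9))
  nu <- sample(nu)
  tr <- data.frame(species = sprintf("sp%02d", seq_len(n_species)),
                   base_log_abundance = stats::rnorm(n_species, 0.5, 1.1),
                   stringsAsFactors = FALSE)
  for (i in seq_len(n_islands))
    tr[[paste0("island_effect_", i)]] <- stats::rnorm(n_species, 0, 0.5)
  tr$nu <- nu
  tr$structural_zero_prob <- stats::runif(n_species, 0, 0.25)
  tr$detectability <- stats::runif(n_species, 0.5, 1)
  tr$gamma_order <- ifelse(stats::runif(n_species) < 0.3,
                           sample(c(-1, 1), n_species, TRUE) *
                             stats::runif(n_species, 0.05, 0.25), 0)
  tr$ar1_rho <- ifelse(stats::runif(n_species) < 0.4,
                       stats::runif(n_species, 0.2, 0.6), 0)
  tr$schooling_k <- ifelse(stats::runif(n_species) < 0.2,
                           stats::runif(n_species, 0.5, 2), Inf)
  tr$turbidity_sensitivity <- stats::runif(n_species, 0, 0.3)
  tr
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Configuration for a simulated survey
#'
#' Bundles the study design, the latent variance components (on the
#' log-abundance scale, matching the log-link mixed models used for the
#' analyses), the species traits and the seed.  All generation from a
#' given configuration is reproducible bit for bit.
#'
#' @param design A [study_design()].
#' @param n_species Number of species (ignored when `traits` is supplied).
#' @param sigma2 Named numeric vector of latent variance components:
#'   `location`, `transect`, `observer`, `observer_location`,
#'   `observer_transect`, `residual` (all `>= 0`).
#' @param seed Integer seed driving every random draw.
#' @param traits Optional explicit trait table as returned by
#'   [default_species_traits()].
#' @param turbidity Optional numeric vector of ordinal turbidity grades per
#'   transect (recycled); default cycles grades 1..3 over transects.
#' @param duration_mean_s,duration_sd_s Pass duration distribution in
#'   seconds (approximately 4.6 minutes with 0.7 minute spread).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(design = study_design(), n_species = 36,
                              sigma2 = c(location = 0.30, transect = 0.20,
                                         observer = 0.01,
                                         observer_location = 0.03,
                                         observer_transect = 0.08,
                                         residual = 0.25),
                              seed = 1, traits = NULL, turbidity = NULL,
                              duration_mean_s = 276, duration_sd_s = 42) {
  stopifnot(inherits(design, "study_design"))
  need <- c("location", "transect", "observer", "observer_location",
            "observer_transect", "residual")
  if (!all(need %in% names(sigma2)))
    stop("sigma2 must be named with: ", paste(need, collapse = ", "))
  sigma2 <- sigma2[need]
  if (any(sigma2 < 0)) stop("variance components must be >= 0")
  if (is.null(traits))
    traits <- default_species_traits(n_species, design$n_islands, seed = seed)
  n_transects <- design$n_islands * design$locations_per_island *
    design$transects_per_location
  if (is.null(turbidity))
    turbidity <- rep_len(1:3, n_transects)
  else turbidity <- rep_len(turbidity, n_transects)
  structure(list(design = design, sigma2 = sigma2, traits = traits,
                 seed = as.integer(seed), turbidity = turbidity,
                 duration_mean_s = duration_mean_s,
                 duration_sd_s = duration_sd_s),
            class = "simulation_config")
}

.species_seed <- function(seed, s) as.integer((seed + 104729 * s) %% 2147483647)

#' Simulate a full repeated video-transect survey
#'
#' Generates one observation record per transect pass under the
#' hierarchical design.  For each species, the latent log-mean of a pass
#' is the sum of the base log-abundance, the island effect, Gaussian
#' random effects for location, transect, observer and the
#' observer-by-location and observer-by-transect interactions, and an
#' AR(1) pass-level deviation along the temporally ordered passes of the
#' transect.  True abundance is drawn from a COM-Poisson with the species'
#' dispersion, rate-parameterized as `mu^nu` so that the latent mean
#' `mu = exp(eta)` is (approximately) the distribution mean -- the same
#' mean parameterization the log-link COM-Poisson mixed models assume
#' (after an optional gamma-distributed schooling multiplier
#' and structural zeros per location); the detected count is a binomial
#' thinning whose probability combines detectability, turbidity and a
#' log-odds tilt linear in the pass order (attraction or deterrence).
#' Detected individuals are grouped into timestamped events with short
#' presence intervals so that MinCount and MaxCount differ.
#'
#' Draws are organised per species in independent, seed-derived substreams
#' (record-level attributes first, then species 1, 2, ...), so adding
#' species does not reshuffle earlier draws.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_study` with elements `records` (list
#'   of [observation_record()]) and `truth` (the configuration, traits and
#'   every latent draw, for parameter-recovery scoring).
#' @examples
#' sim <- simulate_study(simulation_config(seed = 42, n_species = 5))
#' length(sim$records)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  d <- config$design
  fac <- design_factors(d)
  n <- nrow(fac)
  traits <- config$traits
  n_species <- nrow(traits)
  s2 <- config$sigma2

  ## record-level attributes (substream 0)
  set.seed(.species_seed(config$seed, 0))
  durations <- pmax(120, stats::rnorm(n, config$duration_mean_s,
                                      config$duration_sd_s))
  transects <- unique(fac$transect)
  turb <- stats::setNames(config$turbidity, transects)
  turb_norm <- (turb - min(turb)) / max(1e-12, diff(range(turb)))
  if (all(turb == turb[1])) turb_norm[] <- 0

  locs <- unique(fac$location)
  obs <- unique(fac$observer)
  lo_cells <- as.vector(outer(locs, obs, paste, sep = ":"))
  to_cells <- as.vector(outer(transects, obs, paste, sep = ":"))
  passes_per_transect <- d$n_observers * d$repeats_per_observer
  order_center <- (passes_per_transect + 1) / 2

  events_by_record <- rep(list(NULL), n)
  eta_mat <- matrix(NA_real_, n, n_species,
                    dimnames = list(NULL, traits$species))
  true_n <- det_n <- matrix(0L, n, n_species,
                            dimnames = list(NULL, traits$species))
  re_truth <- vector("list", n_species)
  names(re_truth) <- traits$species

  for (s in seq_len(n_species)) {
    set.seed(.species_seed(config$seed, s))
    tr <- traits[s, ]
    u_loc <- stats::setNames(stats::rnorm(length(locs), 0, sqrt(s2["location"])), locs)
    u_tr <- stats::setNames(stats::rnorm(length(transects), 0, sqrt(s2["transect"])), transects)
    u_obs <- stats::setNames(stats::rnorm(length(obs), 0, sqrt(s2["observer"])), obs)
    u_lo <- stats::setNames(stats::rnorm(length(lo_cells), 0, sqrt(s2["observer_location"])), lo_cells)
    u_to <- stats::setNames(stats::rnorm(length(to_cells), 0, sqrt(s2["observer_transect"])), to_cells)
    zero_loc <- stats::setNames(stats::runif(length(locs)) < tr$structural_zero_prob, locs)

    ## AR(1) pass-level deviations with stationary variance sigma2_residual
    sd_e <- sqrt(s2["residual"])
    rho <- tr$ar1_rho
    e <- numeric(n)
    for (t in transects) {
      ix <- which(fac$transect == t)
      ix <- ix[order(fac$order_index[ix])]
      z <- stats::rnorm(length(ix))
      ee <- numeric(length(ix))
      ee[1] <- sd_e * z[1]
      if (length(ix) > 1)
        for (i in 2:length(ix))
          ee[i] <- rho * ee[i - 1] + sd_e * sqrt(1 - rho^2) * z[i]
      e[ix] <- ee
    }

    isl_eff <- unlist(tr[paste0("island_effect_",
                                seq_len(d$n_islands))], use.names = FALSE)
    eta <- tr$base_log_abundance +
      isl_eff[match(fac$island, paste0("I", seq_len(d$n_islands)))] +
      u_loc[fac$location] + u_tr[fac$transect] + u_obs[fac$observer] +
      u_lo[paste(fac$location, fac$observer, sep = ":")] +
      u_to[paste(fac$transect, fac$observer, sep = ":")] + e
    eta_mat[, s] <- eta

    lambda <- exp(eta)
    if (is.finite(tr$schooling_k))
      lambda <- lambda * stats::rgamma(n, shape = tr$schooling_k,
                                       rate = tr$schooling_k)
    lambda[zero_loc[fac$location]] <- 0

    ## mean-parameterized COM-Poisson: rate mu^nu gives mean ~ mu, so the
    ## latent log scale is the log-mean scale the log-link GLMMs assume
    N <- integer(n)
    pos <- lambda > 0
    N[pos] <- rcompois(sum(pos), lambda[pos]^tr$nu, tr$nu)

    p_base <- tr$detectability *
      (1 - tr$turbidity_sensitivity * turb_norm[fac$transect])
    p_base <- pmin(pmax(p_base, 1e-6), 1 - 1e-6)
    p <- stats::plogis(stats::qlogis(p_base) +
                         tr$gamma_order * (fac$order_index - order_center))
    C <- stats::rbinom(n, N, p)

    has <- which(C > 0)
    for (i in has) {
      cnt <- C[i]
      n_ev <- if (cnt == 1) 1L else sample.int(min(cnt, 4L), 1L)
      sizes <- as.vector(stats::rmultinom(1, cnt - n_ev, rep(1, n_ev))) + 1L
      t0 <- stats::runif(n_ev, 0, max(1, durations[i] - 10))
      ev <- data.frame(species = tr$species, t_start = t0,
                       t_end = t0 + stats::runif(n_ev, 2, 10),
                       n_individuals = sizes, stringsAsFactors = FALSE)
      events_by_record[[i]] <- rbind(events_by_record[[i]], ev)
    }
    true_n[, s] <- N
    det_n[, s] <- C
    re_truth[[s]] <- list(u_location = u_loc, u_transect = u_tr,
                          u_observer = u_obs, u_observer_location = u_lo,
                          u_observer_transect = u_to,
                          structural_zero = zero_loc)
  }

  records <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- events_by_record[[i]]
    if (is.null(ev)) ev <- detection_events()
    else { ev <- ev[order(ev$t_start), , drop = FALSE]; rownames(ev) <- NULL }
    records[[i]] <- observation_record(
      fac$island[i], fac$location[i], fac$transect[i], fac$observer[i],
      fac$repeat_index[i], fac$order_index[i], fac$direction[i],
      durations[i], turb[fac$transect[i]], events = ev)
  }
  structure(list(records = records,
                 truth = list(config = config, factors = fac,
                              turbidity = turb, eta = eta_mat,
                              true_abundance = true_n,
                              detected_count = det_n,
                              random_effects = re_truth)),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d observations, %d species, seed %d\n",
              length(x$records), nrow(x$truth$config$traits),
              x$truth$config$seed))
  invisible(x)
}
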