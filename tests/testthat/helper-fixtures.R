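## Shared fixtures and independent oracles used across the test files.

## a pass with hand-chosen events
make_record <- function(transect = "I1L1T1", observer = "Obs1",
                        repeat_index = 1, order_index = 1,
                        duration_s = 100, events = detection_events()) {
  location <- sub("T[0-9]+$", "", transect)
  island <- sub("L[0-9]+.*$", "", transect)
  observation_record(island, location, transect, observer, repeat_index,
                     order_index, "forward", duration_s, 1, events = events)
}

## small but complete simulated survey
small_sim <- function(seed = 1, n_species = 8,
                      design = study_design(2, 2, 2, 3, 3), ...) {
  simulate_study(simulation_config(design = design, n_species = n_species,
                                   seed = seed, ...))
}

## traits with all behavioural effects switched off
flat_traits <- function(n_species, n_islands = 2, base = log(4), nu = 1) {
  tr <- data.frame(species = sprintf("sp%02d", seq_len(n_species)),
                   base_log_abundance = base, stringsAsFactors = FALSE)
  for (i in seq_len(n_islands)) tr[[paste0("island_effect_", i)]] <- 0
  tr$nu <- nu
  tr$structural_zero_prob <- 0
  tr$detectability <- 1
  tr$gamma_order <- 0
  tr$ar1_rho <- 0
  tr$schooling_k <- Inf
  tr$turbidity_sensitivity <- 0
  tr
}

zero_sigma2 <- c(location = 0, transect = 0, observer = 0,
                 observer_location = 0, observer_transect = 0, residual = 0)

## brute-force double-loop oracle for the lag-k autocorrelation with
## full-series mean and denominator
acf_oracle <- function(y, k) {
  yb <- mean(y)
  num <- 0
  for (i in seq_len(length(y) - k)) num <- num + (y[i] - yb) * (y[i + k] - yb)
  den <- 0
  for (i in seq_along(y)) den <- den + (y[i] - yb)^2
  if (den == 0) NA_real_ else num / den
}

## brute-force COM-Poisson pmf by direct normalization over 0..cap
compois_pmf_oracle <- function(y, lambda, nu, cap = 1000) {
  terms <- exp((0:cap) * log(lambda) - nu * lgamma((0:cap) + 1))
  terms[y + 1] / sum(terms)
}

## classical balanced ANOVA sums of squares from cell totals (independent
## of the projection/Gower route used by the package)
anova_ss_oracle <- function(y, fac) {
  U <- function(f) {
    if (is.null(f)) return(sum(y)^2 / length(y))
    f <- interaction(f, drop = TRUE)
    sums <- tapply(y, f, sum)
    counts <- tapply(y, f, length)
    sum(sums^2 / counts)
  }
  uI <- U(fac["island"]); uL <- U(fac[c("island", "location")])
  uT <- U(fac[c("island", "location", "transect")])
  uO <- U(fac["observer"]); u1 <- U(NULL)
  uIO <- U(fac[c("island", "observer")])
  uLO <- U(fac[c("island", "location", "observer")])
  uTO <- U(fac[c("island", "location", "transect", "observer")])
  tot <- sum(y^2)
  c(Island = uI - u1, Location = uL - uI, Transect = uT - uL,
    Observer = uO - u1, `Island:Observer` = uIO - uI - uO + u1,
    `Location:Observer` = uLO - uL - uIO + uI,
    `Transect:Observer` = uTO - uT - uLO + uL,
    Residual = tot - uTO)
}
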