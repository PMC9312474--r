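#' Terms of the univariate mixed models
#'
#' Random structure of the univariate variance-partitioning models:
#' Island fixed, Location and Transect nested random, Observer crossed
#' random, plus the Observer:Location and Observer:Transect interactions
#' (the observer interaction cells span islands, so no separate
#' Island:Observer term is fitted).
#'
#' @return A term list for [ems_table()] / [permanova()].
#' @export
univariate_design_terms <- function() {
  list(
    list(label = "Island", factors = "island", live = "island",
         random = FALSE),
    list(label = "Location", factors = c("island", "location"),
         live = "location", random = TRUE),
    list(label = "Transect", factors = c("island", "location", "transect"),
         live = "transect", random = TRUE),
    list(label = "Observer", factors = "observer", live = "observer",
         random = TRUE),
    list(label = "Observer:Location",
         factors = c("island", "location", "observer"),
         live = c("location", "observer"), random = TRUE),
    list(label = "Observer:Transect",
         factors = c("island", "location", "transect", "observer"),
         live = c("transect", "observer"), random = TRUE))
}

.re_names <- c("Location", "Transect", "Observer", "Observer:Location",
               "Observer:Transect")

#' Linear mixed model variance components for a univariate response
#'
#' Partitions the variance of a per-observation response (species density,
#' Shannon diversity, ...) over the survey factors: Island as fixed
#' effect, Location and Transect as nested random effects, Observer as
#' crossed random effect with its Observer:Location and Observer:Transect
#' interactions.  Two estimation routes are available: `"reml"` fits the
#' model with [lme4::lmer()]; `"anova"` uses the closed-form
#' method-of-moments (expected-mean-squares) estimators for the balanced
#' design, which REML reproduces whenever all estimates are interior.
#' Negative method-of-moments components are truncated to zero in
#' `sigma2` (the signed values are kept in `sigma2_raw`).
#'
#' @param response Numeric vector, one value per observation.
#' @param data Data frame with columns `island`, `location`, `transect`,
#'   `observer` (one row per observation).
#' @param method `"reml"` or `"anova"`.
#' @return A list of class `uni_variance_components`: `sigma2` (named:
#'   the five random terms plus `Residual`), `sigma2_raw`, `island_effect`
#'   (fixed-effect contrast), `method`, `converged`, `AIC` (REML route),
#'   `response_label`.
#' @export
fit_lmm <- function(response, data, method = c("reml", "anova")) {
  method <- match.arg(method)
  stopifnot(length(response) == nrow(data))
  label <- deparse(substitute(response))[1]
  if (stats::var(response) == 0) {
    s2 <- stats::setNames(numeric(6), c(.re_names, "Residual"))
    return(structure(list(sigma2 = s2, sigma2_raw = s2, island_effect = 0,
                          method = method, converged = TRUE, AIC = NA_real_,
                          response_label = label),
                     class = "uni_variance_components"))
  }
  if (method == "anova") {
    tab <- permanova(stats::dist(response), data = data,
                     terms = univariate_design_terms(), n_perm = 0)
    s2_raw <- stats::setNames(tab$sigma2, tab$term)
    isl_means <- tapply(response, data$island, mean)
    out <- list(sigma2 = pmax(s2_raw[c(.re_names, "Residual")], 0),
                sigma2_raw = s2_raw[c(.re_names, "Residual")],
                island_effect = unname(diff(isl_means)),
                method = "anova", converged = TRUE, AIC = NA_real_,
                response_label = label)
    return(structure(out, class = "uni_variance_components"))
  }
  df <- data.frame(y = response,
                   island = factor(data$island),
                   location = factor(data$location),
                   transect = factor(data$transect),
                   observer = factor(data$observer))
  df$obs_loc <- interaction(df$observer, df$location, drop = TRUE)
  df$obs_tr <- interaction(df$observer, df$transect, drop = TRUE)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ island + (1 | location) + (1 | transect) +
                 (1 | observer) + (1 | obs_loc) + (1 | obs_tr),
               data = df, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(g) vc$vcov[vc$grp == g]
  s2 <- c(Location = pick("location"), Transect = pick("transect"),
          Observer = pick("observer"),
          `Observer:Location` = pick("obs_loc"),
          `Observer:Transect` = pick("obs_tr"),
          Residual = vc$vcov[vc$grp == "Residual"])
  conv <- length(fit@optinfo$conv$lme4) == 0
  structure(list(sigma2 = s2, sigma2_raw = s2,
                 island_effect = unname(lme4::fixef(fit)[-1])[1],
                 method = "reml", converged = conv,
                 AIC = stats::AIC(fit), response_label = label, fit = fit),
            class = "uni_variance_components")
}

#' @export
print.uni_variance_components <- function(x, ...) {
  cat(sprintf("<uni_variance_components> %s (%s%s)\n", x$response_label,
              x$method, if (!x$converged) ", NOT converged" else ""))
  print(round(x$sigma2, 5))
  invisible(x)
}

#' Intraclass correlation decomposition of variance components
#'
#' For random-factor variances `sigma2_r` and residual variance
#' `sigma2_e`: `ICC_r = sigma2_r / (sum_r sigma2_r + sigma2_e)`,
#' `ICC_Total = sum_r ICC_r`, `ICC_e = 1 - ICC_Total`, and the sampling
#' variability share `ICC_Sampling = ICC_e + ICC_Observer:Transect +
#' ICC_Observer:Location`.
#'
#' @param components A [fit_lmm()] result or a named non-negative vector
#'   of variances including `Residual`.
#' @return A list of class `icc_table`: `icc` (per random factor),
#'   `icc_total`, `icc_residual`, `icc_sampling`.
#' @export
icc_table <- function(components) {
  s2 <- if (inherits(components, "uni_variance_components"))
    components$sigma2 else components
  if (!"Residual" %in% names(s2)) stop("components must include 'Residual'")
  if (any(s2 < 0)) stop("variances must be >= 0 (truncate upstream)")
  tot <- sum(s2)
  if (tot == 0) {
    out <- list(icc = s2[setdiff(names(s2), "Residual")] * NA_real_,
                icc_total = NA_real_, icc_residual = NA_real_,
                icc_sampling = NA_real_, undefined = TRUE)
    return(structure(out, class = "icc_table"))
  }
  icc <- s2 / tot
  r_names <- setdiff(names(s2), "Residual")
  icc_total <- sum(icc[r_names])
  icc_res <- unname(icc["Residual"])
  icc_sampling <- icc_res +
    sum(icc[intersect(c("Observer:Transect", "Observer:Location"), r_names)])
  structure(list(icc = icc[r_names], icc_total = icc_total,
                 icc_residual = icc_res, icc_sampling = icc_sampling,
                 undefined = FALSE),
            class = "icc_table")
}

#' @export
print.icc_table <- function(x, ...) {
  if (isTRUE(x$undefined)) { cat("<icc_table> undefined (zero variance)\n")
    return(invisible(x)) }
  print(round(c(x$icc, Total = x$icc_total, Residual = x$icc_residual,
                Sampling = x$icc_sampling), 4))
  invisible(x)
}

#' Sampling-variability ICC from reported component ICCs
#'
#' Worked-arithmetic form of the ICC decomposition:
#' `ICC_Sampling = (1 - ICC_Total) + ICC_Observer:Transect +
#' ICC_Observer:Location`.
#'
#' @param icc_total Total ICC explained by the random factors.
#' @param icc_obs_transect,icc_obs_location Component ICCs of the
#'   observer interactions.
#' @return Numeric `ICC_Sampling`.
#' @examples
#' icc_sampling(0.662, 0.099, 0.007) # 0.444
#' @export
icc_sampling <- function(icc_total, icc_obs_transect, icc_obs_location)
  (1 - icc_total) + icc_obs_transect + icc_obs_location

#' Zero-inflated COM-Poisson mixed model for one species' counts
#'
#' Fits a generalized linear mixed model to the per-observation counts of
#' a single species: log link, Island fixed, the five random terms of the
#' survey design, constant (intercept-only) zero inflation on the logit
#' scale, maximum likelihood via the Laplace approximation (glmmTMB).
#' The count family is `"compois"` (Conway-Maxwell-Poisson,
#' mean-parameterized) by default; `"poisson"` and `"nbinom2"` are
#' available so families can be compared by AIC.
#'
#' @param counts Non-negative integer vector, one per observation (at
#'   least one nonzero).
#' @param data Data frame with columns `island`, `location`, `transect`,
#'   `observer`.
#' @param family `"compois"`, `"poisson"` or `"nbinom2"`.
#' @param zero_inflation Logical; include the intercept-only
#'   zero-inflation component.
#' @param random Character vector of random terms to include (default all
#'   five; reduce for small or sparse data).
#' @return A list of class `compois_fit`: `coefficients` (fixed effects,
#'   log-mean scale), `nu` (COM-Poisson dispersion; `NA` for other
#'   families), `pi` (zero-inflation probability), `sigma2` (random-effect
#'   variances), `logLik`, `AIC`, `converged`, `boundary`, `family`,
#'   `fit`.
#' @export
fit_zicomp_glmm <- function(counts, data,
                            family = c("compois", "poisson", "nbinom2"),
                            zero_inflation = TRUE,
                            random = .re_names) {
  family <- match.arg(family)
  stopifnot(length(counts) == nrow(data))
  if (all(counts == 0)) stop("all counts are zero; nothing to fit")
  df <- data.frame(y = counts,
                   island = factor(data$island),
                   location = factor(data$location),
                   transect = factor(data$transect),
                   observer = factor(data$observer))
  df$obs_loc <- interaction(df$observer, df$location, drop = TRUE)
  df$obs_tr <- interaction(df$observer, df$transect, drop = TRUE)
  re_map <- c(Location = "(1 | location)", Transect = "(1 | transect)",
              Observer = "(1 | observer)",
              `Observer:Location` = "(1 | obs_loc)",
              `Observer:Transect` = "(1 | obs_tr)")
  re_terms <- re_map[intersect(random, names(re_map))]
  rhs <- paste(c("island", re_terms), collapse = " + ")
  if (nlevels(df$island) < 2) rhs <- paste(c("1", re_terms), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  fam <- switch(family, compois = glmmTMB::compois(),
                poisson = stats::poisson(), nbinom2 = glmmTMB::nbinom2())
  fit <- try(suppressWarnings(
    glmmTMB::glmmTMB(form, data = df, family = fam,
                     ziformula = if (zero_inflation) ~1 else ~0)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(coefficients = NULL, nu = NA_real_, pi = NA_real_,
                          sigma2 = NULL, logLik = NA_real_, AIC = NA_real_,
                          converged = FALSE, boundary = TRUE,
                          family = family, fit = NULL),
                     class = "compois_fit"))
  }
  conv <- isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
  disp <- tryCatch(stats::sigma(fit), error = function(e) NA_real_)
  ## glmmTMB's compois dispersion is on the overdispersion scale
  ## (> 1 = overdispersed), i.e. 1/nu of the lambda-parameterization
  nu <- if (family == "compois") 1 / disp else NA_real_
  vc <- tryCatch(glmmTMB::VarCorr(fit)$cond, error = function(e) NULL)
  s2 <- stats::setNames(rep(0, length(re_terms)),
                        names(re_map)[match(re_terms, re_map)])
  if (!is.null(vc)) {
    grp_map <- c(location = "Location", transect = "Transect",
                 observer = "Observer", obs_loc = "Observer:Location",
                 obs_tr = "Observer:Transect")
    for (g in names(vc)) s2[grp_map[g]] <- as.numeric(vc[[g]])
  }
  pi_hat <- if (zero_inflation)
    stats::plogis(glmmTMB::fixef(fit)$zi[["(Intercept)"]]) else 0
  boundary <- !conv || (is.finite(nu) && (nu < 1e-3 || nu > 1e3)) ||
    (zero_inflation && pi_hat > 1 - 1e-6)
  structure(list(coefficients = glmmTMB::fixef(fit)$cond, nu = nu,
                 pi = pi_hat, sigma2 = s2,
                 logLik = as.numeric(stats::logLik(fit)),
                 AIC = stats::AIC(fit), converged = conv,
                 boundary = boundary, family = family, fit = fit),
            class = "compois_fit")
}

#' @export
print.compois_fit <- function(x, ...) {
  cat(sprintf("<compois_fit> family=%s%s%s\n", x$family,
              if (!x$converged) " [not converged]" else "",
              if (x$boundary) " [boundary]" else ""))
  if (!is.null(x$coefficients)) {
    cat(sprintf("  nu = %.3f, pi = %.3f, AIC = %.1f\n", x$nu, x$pi, x$AIC))
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' Compare count families by AIC
#'
#' Fits the same zero-inflated mixed count model under the Poisson,
#' negative binomial (NB2) and COM-Poisson families and tabulates their
#' AIC.
#'
#' @inheritParams fit_zicomp_glmm
#' @return Data frame with columns `family`, `AIC`, `converged`, sorted
#'   by AIC.
#' @export
compare_count_families <- function(counts, data, zero_inflation = TRUE,
                                   random = .re_names) {
  fams <- c("poisson", "nbinom2", "compois")
  out <- do.call(rbind, lapply(fams, function(f) {
    fit <- fit_zicomp_glmm(counts, data, family = f,
                           zero_inflation = zero_inflation, random = random)
    data.frame(family = f, AIC = fit$AIC, converged = fit$converged)
  }))
  out[order(out$AIC), ]
}
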