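#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML/JSON file path) with
#' components: `seed` (required), `design` (optional arguments for
#' [study_design()]), `simulate` (arguments for [simulation_config()]) or
#' `input` (path to a long-format observation CSV), `stages` (character
#' vector among `simulate`, `independence`, `pooling`, `univariate`,
#' `multivariate`, `precision`) and per-stage parameter lists
#' (`n_perm`, `lengths`, `metrics`, `transforms`, `methods`, `m`,
#' `n_sim`, ...).  Every stochastic stage inherits `seed` unless it sets
#' its own.
#'
#' @param config Named list, or path to a YAML or JSON file.
#' @return The validated configuration (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed))
    stop("validation error: config must set an explicit seed")
  config$seed <- as.integer(config$seed)
  if (is.null(config$stages))
    config$stages <- c("simulate", "independence", "pooling", "univariate",
                       "multivariate", "precision")
  bad <- setdiff(config$stages, c("simulate", "independence", "pooling",
                                  "univariate", "multivariate", "precision"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (is.null(config$input) && !"simulate" %in% config$stages)
    stop("config needs either an 'input' CSV or the 'simulate' stage")
  structure(config, class = c("pipeline_config", "list"))
}

.analysis_params <- function(config) {
  x <- unclass(config)
  x[sort(intersect(names(x), c("seed", "design", "simulate", "input",
                               "stages", "independence", "pooling",
                               "univariate", "multivariate", "precision")))]
}

#' Run the full survey-assessment pipeline
#'
#' Executes the requested stages in order -- simulate (or load) the
#' observations, independence diagnostics, pooling design-error
#' simulation, univariate ICC tables, multivariate PERMANOVA / CAP /
#' sweep, precision curves -- writing tidy CSV outputs and a
#' machine-readable JSON manifest (stage status, timing, seeds and a
#' parameter hash) into `out_dir`.  A stage failure is recorded in the
#' manifest and stages depending on the observations are skipped if the
#' data stage failed.  Reruns with the same configuration produce
#' byte-identical CSV outputs.
#'
#' @param config A [pipeline_config()] (or list / file path coercible to
#'   one).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage_seed <- function(stage, default_offset)
    as.integer(config[[stage]]$seed %||% (seed + default_offset))
  manifest <- list(package_version = as.character(
    utils::packageVersion("transectvar")),
    r_version = as.character(getRversion()),
    seed = seed,
    parameter_hash = rlang::hash(.analysis_params(config)),
    stages = list())
  t_all <- proc.time()[3]

  records <- NULL
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             message = conditionMessage(e)))
    manifest$stages[[name]] <<- list(
      status = if (res$ok) "ok" else "failed",
      message = if (res$ok) NULL else res$message,
      seconds = round(proc.time()[3] - t0, 2))
    if (res$ok) res$value else NULL
  }
  csv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }

  ## data stage
  if ("simulate" %in% config$stages) {
    records <- run_stage("simulate", function() {
      des <- do.call(study_design, config$design %||% list())
      sim_args <- config$simulate %||% list()
      sim_args$design <- des
      sim_args$seed <- stage_seed("simulate", 0)
      sim <- simulate_study(do.call(simulation_config, sim_args))
      write_observations(sim$records,
                         file.path(out_dir, "observations.csv"))
      sim$records
    })
  } else {
    records <- run_stage("load", function() read_observations(config$input))
  }

  if (is.null(records)) {
    manifest$skipped <- setdiff(config$stages, "simulate")
  } else {
    species <- sort(unique(unlist(lapply(records,
                                         function(r) r$events$species))))
    cm_raw <- community_matrix(records, metric = "max_count",
                               species = species)
    if ("independence" %in% config$stages) run_stage("independence", function() {
      acfs <- study_acf(cm_raw, max_lag = config$independence$max_lag %||% 5)
      acf_df <- do.call(rbind, lapply(names(acfs), function(sp)
        cbind(species = sp, acfs[[sp]]$mean)))
      csv(acf_df, "independence_acf.csv")
      oe <- do.call(rbind, lapply(species, function(sp) {
        f <- tryCatch(fit_order_effect(cm_raw, sp),
                      error = function(e) NULL)
        if (is.null(f)) return(NULL)
        data.frame(species = sp, alpha = f$alpha, beta = f$beta,
                   p_value = f$p_value, n_series = f$n_series,
                   separation = f$separation)
      }))
      csv(oe, "independence_order_effects.csv")
      cmt <- transform_counts(cm_raw, "fourth_root")
      D <- dissimilarity(cmt, "bray_curtis")
      mc <- partial_mantel_correlogram(
        D, cm_raw$row_meta,
        n_perm = config$independence$n_perm %||% 199,
        seed = stage_seed("independence", 1))
      csv(as.data.frame(mc), "independence_mantel.csv")
      TRUE
    })
    if ("pooling" %in% config$stages) run_stage("pooling", function() {
      rows <- list()
      for (fac in c("transect", "location"))
        for (k in config$pooling$pool_sizes %||% 1:3) {
          pd <- pooled_dissimilarity(cm_raw, fac, pool_size = k,
                                     n_perm = config$pooling$n_perm %||% 199,
                                     seed = stage_seed("pooling", 2))
          rows[[paste(fac, k)]] <- cbind(factor = fac, pool_size = k,
                                         pd$average_histogram,
                                         uninformative = pd$uninformative,
                                         undefined = pd$undefined)
        }
      csv(do.call(rbind, rows), "pooling_histograms.csv")
      TRUE
    })
    if ("univariate" %in% config$stages) run_stage("univariate", function() {
      meta <- cm_raw$row_meta
      rows <- list()
      for (len in config$univariate$lengths %||% c(10, 50)) {
        cml <- community_matrix(records, metric = "max_count",
                                window = window_for_length(len),
                                species = species)
        for (resp in c("species_density", "shannon_diversity")) {
          vals <- if (resp == "species_density") species_density(cml)
                  else shannon_diversity(cml)
          comp <- fit_lmm(vals, meta,
                          method = config$univariate$method %||% "anova")
          icc <- icc_table(comp)
          rows[[paste(resp, len)]] <- data.frame(
            response = resp, length_m = len,
            t(icc$icc), icc_total = icc$icc_total,
            icc_residual = icc$icc_residual,
            icc_sampling = icc$icc_sampling, check.names = FALSE)
        }
      }
      csv(do.call(rbind, rows), "univariate_icc.csv")
      TRUE
    })
    if ("multivariate" %in% config$stages) run_stage("multivariate", function() {
      cmt <- transform_counts(cm_raw, "fourth_root")
      D <- dissimilarity(cmt, "bray_curtis")
      tab <- permanova(D, n_perm = config$multivariate$n_perm %||% 199,
                       seed = stage_seed("multivariate", 3))
      csv(as.data.frame(tab), "permanova_full.csv")
      cap <- cap_loocv(D, cm_raw$row_meta$location,
                       m = config$multivariate$m %||% 8)
      csv(data.frame(grouping = "location", m = cap$m,
                     error_pct = cap$error_pct), "cap_location.csv")
      if (isTRUE(config$multivariate$sweep)) {
        sw <- sweep_configurations(records,
                                   n_perm = 0,
                                   seed = stage_seed("multivariate", 4))
        csv(sw$results, "sweep_r2.csv")
        csv(sw$r2_tests, "sweep_r2_tests.csv")
      }
      TRUE
    })
    if ("precision" %in% config$stages) run_stage("precision", function() {
      pc <- precision_curve(records,
                            response = config$precision$response %||%
                              "species_density",
                            lengths = config$precision$lengths %||%
                              c(10, 30, 50),
                            ks = config$precision$ks %||% c(2, 6, 12, 18),
                            n_sim = config$precision$n_sim %||% 100,
                            seed = stage_seed("precision", 5))
      csv(pc, "precision_univariate.csv")
      ms <- mult_se_curve(records,
                          lengths = config$precision$lengths %||%
                            c(10, 30, 50),
                          ks = config$precision$ks %||% c(2, 6, 12, 18),
                          n_sim = config$precision$n_sim %||% 100,
                          seed = stage_seed("precision", 6))
      csv(ms, "multse_curve.csv")
      TRUE
    })
  }
  manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
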