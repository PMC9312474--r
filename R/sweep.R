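#' Sweep of PERMANOVA configurations over methodological parameters
#'
#' Fits one PERMANOVA per combination of transect length (distance
#' window), counting metric, data transformation and dissimilarity method
#' -- 5 x 2 x 3 x 4 = 120 models under the defaults -- and compares the
#' goodness-of-fit (total model R2) across the levels of each parameter
#' with pairwise paired t-tests, Bonferroni-corrected within parameters.
#'
#' @param records List of [observation_record()] covering the full design.
#' @param lengths Nominal transect lengths in meters (centred windows).
#' @param metrics Counting metrics.
#' @param transforms Data transformations.
#' @param methods Dissimilarity methods.
#' @param terms Design terms for [permanova()].
#' @param total_m Full transect length for the window mapping.
#' @param n_perm Permutations per model (`0` skips permutation tests,
#'   which the R2 comparison does not need).
#' @param seed Integer seed.
#' @return A list of class `config_sweep`: `results` (one row per model:
#'   parameters, total R2, per-term R2), `r2_tests` (pairwise paired
#'   t-tests per parameter with Bonferroni-adjusted p-values) and
#'   `n_models`.
#' @export
sweep_configurations <- function(records,
                                 lengths = c(10, 20, 30, 40, 50),
                                 metrics = c("max_count", "min_count"),
                                 transforms = c("fourth_root", "log1p",
                                                "presence_absence"),
                                 methods = c("bray_curtis", "euclidean",
                                             "gower", "kulczynski"),
                                 terms = default_design_terms(),
                                 total_m = 50, n_perm = 0, seed = 1) {
  grid <- expand.grid(length_m = lengths, metric = metrics,
                      transform = transforms, method = methods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  species <- sort(unique(unlist(lapply(records,
                                       function(r) r$events$species))))
  rows <- vector("list", nrow(grid))
  term_labels <- vapply(terms, `[[`, "", "label")
  ## cache community matrices per (length, metric, transform)
  cm_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    key <- paste(g$length_m, g$metric, g$transform, sep = "|")
    if (is.null(cm_cache[[key]]))
      cm_cache[[key]] <- community_matrix(
        records, metric = g$metric,
        window = window_for_length(g$length_m, total_m),
        length_m = total_m, transform = g$transform, species = species)
    D <- dissimilarity(cm_cache[[key]], method = g$method)
    if (anyNA(D$values))
      stop("undefined dissimilarities (empty observations) at length ",
           g$length_m, "; pool observations or drop the configuration")
    tab <- permanova(D, terms = terms, n_perm = n_perm, seed = seed + i)
    r2 <- stats::setNames(tab$R2[match(term_labels, tab$term)],
                          paste0("R2_", gsub("[ :]", "_", term_labels)))
    rows[[i]] <- cbind(g, total_R2 = attr(tab, "total_R2"),
                       as.data.frame(as.list(r2)))
  }
  results <- do.call(rbind, rows)

  r2_tests <- do.call(rbind, lapply(
    c("length_m", "metric", "transform", "method"), function(param) {
      lev <- unique(results[[param]])
      if (length(lev) < 2) return(NULL)
      pairs <- utils::combn(as.character(lev), 2)
      others <- setdiff(c("length_m", "metric", "transform", "method"), param)
      key <- interaction(results[others], drop = TRUE)
      out <- lapply(seq_len(ncol(pairs)), function(j) {
        a <- results$total_R2[results[[param]] == pairs[1, j]]
        b <- results$total_R2[results[[param]] == pairs[2, j]]
        ka <- key[results[[param]] == pairs[1, j]]
        kb <- key[results[[param]] == pairs[2, j]]
        b <- b[match(ka, kb)]
        tt <- stats::t.test(a, b, paired = TRUE)
        data.frame(parameter = param, level_a = pairs[1, j],
                   level_b = pairs[2, j],
                   mean_diff = mean(a - b), t = unname(tt$statistic),
                   p_value = tt$p.value, stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, out)
      out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
      out
    }))
  structure(list(results = results, r2_tests = r2_tests,
                 n_models = nrow(results)),
            class = "config_sweep")
}

#' @export
print.config_sweep <- function(x, ...) {
  cat(sprintf("<config_sweep> %d PERMANOVA models\n", x$n_models))
  agg <- stats::aggregate(total_R2 ~ length_m, data = x$results, FUN = mean)
  cat("mean total R2 by transect length:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}
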