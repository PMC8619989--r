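# Comparative experiment harness: run IPC-MB over every feature of a dataset
# under each configured backend, sharing each configuration's optimization
# structures (static/dynamic AD-tree, JHT + DoF cache) across its runs, and
# collect the comparison metrics: per-target and total CI-test counts, JHT hit
# rate, and structure entry counts. Assertions about backends are always on
# counts, rates and set equality — wall-clock time is recorded but never a
# result.

#' Configuration of a comparative experiment
#'
#' @param network A [bayesian_network()], or a list
#'   `list(m =, max_parents =, arity_range =)` describing a random network to
#'   generate per seed.
#' @param sample_sizes Integer vector of dataset sizes to instantiate.
#' @param backends Character vector drawn from the four backend names.
#' @param llt_values Leaf-list threshold percentages attached to the AD-tree
#'   backends (ignored by the others).
#' @param alpha Significance of the G-test.
#' @param seed Master seed; per-(dataset, n) child seeds are derived with
#'   [derive_seed()] so any cell of the result table can be re-run alone.
#' @param targets Optional subset of feature indices to run (default: every
#'   feature, the exhaustive blanket-reconstruction use case).
#' @param max_static_cells Memory guard: static AD-trees are skipped (and
#'   recorded as such) when `N * M` exceeds this bound.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(network, sample_sizes = c(2000L),
                              backends = c("default", "static-adtree",
                                           "dynamic-adtree", "dcmi"),
                              llt_values = c(0, 5, 10), alpha = 0.05,
                              seed = 1L, targets = NULL,
                              max_static_cells = 5e7) {
  stopifnot(all(sample_sizes >= 1))
  backends <- match.arg(backends, c("default", "static-adtree",
                                    "dynamic-adtree", "dcmi"),
                        several.ok = TRUE)
  structure(list(network = network, sample_sizes = as.integer(sample_sizes),
                 backends = backends, llt_values = llt_values, alpha = alpha,
                 seed = as.integer(seed), targets = targets,
                 max_static_cells = max_static_cells),
            class = "experiment_config")
}

# One (backend, llt) configuration group: build/initialize the shared
# structure once, then loop IPC-MB over all targets.
run_config_group <- function(ds, backend, llt, alpha, targets, dataset_id,
                             spouse_conditioning = "sepset_union_x",
                             max_static_cells = 5e7) {
  cfg <- ci_test_config(alpha = alpha, backend = backend, llt = llt,
                        spouse_conditioning = spouse_conditioning)
  if (backend == "static-adtree" &&
      as.numeric(ds$N) * ds$M > max_static_cells) {
    return(structure(list(backend = backend, llt = llt,
                          dataset_id = dataset_id, n = ds$N, skipped = TRUE,
                          reason = "static AD-tree memory guard exceeded"),
                     class = "run_metrics"))
  }
  engine <- ci_engine(ds, cfg)
  per_target <- integer(length(targets))
  blankets <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tester <- data_tester(engine)
    res <- find_mb(targets[i], tester, ds$M, cfg$spouse_conditioning)
    per_target[i] <- res$ci_tests_performed
    blankets[[i]] <- res$mb
  }
  structure(list(backend = backend, llt = llt, dataset_id = dataset_id,
                 n = ds$N, skipped = FALSE,
                 total_ci_tests = engine$n_tests,
                 per_target_tests = per_target,
                 targets = targets, blankets = blankets,
                 jht_hit_rate = if (backend == "dcmi" &&
                                    engine$jht$hits + engine$jht$misses > 0)
                   hit_rate(engine$jht) else NA_real_,
                 structure_entry_counts =
                   as.list(engine_structure_counts(engine))),
            class = "run_metrics")
}

#' Run the four-configuration comparative experiment
#'
#' For each sample size, samples a dataset from the network, then for each
#' (backend, llt) combination initializes the shared optimization structure
#' once and discovers the Markov blanket of every target feature with it,
#' accumulating metrics. AD-tree backends are expanded over `llt_values`;
#' `default` and `dcmi` run once per dataset. Deterministic given
#' `cfg$seed`. A static-tree build exceeding the memory guard is recorded as
#' skipped rather than attempted.
#'
#' @param cfg An [experiment_config()].
#' @return A list of `run_metrics` (one per configuration cell), class
#'   `experiment_result`.
#' @export
run_experiment <- function(cfg) {
  out <- list()
  for (ni in seq_along(cfg$sample_sizes)) {
    n <- cfg$sample_sizes[ni]
    child <- derive_seed(cfg$seed, ni)
    bn <- if (inherits(cfg$network, "bayesian_network")) cfg$network
          else random_network(cfg$network$m,
                              cfg$network$max_parents %||% 2L,
                              cfg$network$arity_range %||% c(2L, 3L),
                              seed = derive_seed(cfg$seed, 1000L + ni))
    ds <- sample_network(bn, n, seed = child)
    dataset_id <- sprintf("n%d", n)
    targets <- cfg$targets %||% seq_len(ds$M)
    for (backend in cfg$backends) {
      llts <- if (backend %in% c("static-adtree", "dynamic-adtree"))
        cfg$llt_values else NA_real_
      for (llt in llts) {
        rm_ <- run_config_group(ds, backend,
                                if (is.na(llt)) 0 else llt,
                                cfg$alpha, targets, dataset_id,
                                max_static_cells = cfg$max_static_cells)
        if (is.na(llt)) rm_$llt <- NA_real_
        out[[length(out) + 1L]] <- rm_
      }
    }
  }
  class(out) <- "experiment_result"
  out
}

#' Summarize experiment metrics as a table
#'
#' One row per configuration cell, sorted by (n, backend, llt), with total
#' CI-test counts, JHT hit rate where applicable, and structure entry counts.
#'
#' @param metrics An `experiment_result` from [run_experiment()].
#' @return A `data.frame`.
#' @export
summarize_experiment <- function(metrics) {
  stopifnot(length(metrics) > 0)
  rows <- lapply(metrics, function(r) {
    sc <- r$structure_entry_counts %||% list()
    data.frame(
      dataset_id = r$dataset_id, n = r$n, backend = r$backend,
      llt = if (is.null(r$llt) || is.na(r$llt)) NA_real_ else r$llt,
      skipped = isTRUE(r$skipped),
      total_ci_tests = if (isTRUE(r$skipped)) NA_integer_ else r$total_ci_tests,
      jht_hit_rate = if (isTRUE(r$skipped)) NA_real_ else r$jht_hit_rate,
      jht_entries = sc$jht_entries %||% NA_integer_,
      dof_entries = sc$dof_entries %||% NA_integer_,
      ad_nodes = sc$ad_nodes %||% NA_integer_,
      vary_nodes = sc$vary_nodes %||% NA_integer_,
      leaf_lists = sc$leaf_lists %||% NA_integer_)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$n, df$backend, df$llt, na.last = FALSE), ]
  rownames(df) <- NULL
  df
}

#' Write experiment metrics to JSON and/or CSV
#'
#' @param metrics An `experiment_result`.
#' @param json_path,csv_path Optional output paths.
#' @return The summary data frame, invisibly.
#' @export
write_experiment <- function(metrics, json_path = NULL, csv_path = NULL) {
  df <- summarize_experiment(metrics)
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, dataframe = "rows", na = "null",
                         digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(df)
}
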