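# The black-box CI-test API consumed by IPC-MB: an engine owns a data source
# plus one counting/caching strategy, answers (x, y | z) queries with full
# G-test results, and counts the tests it performs. The four engines differ
# only in how counts are obtained; their results are identical.

#' Create a conditional-independence test engine
#'
#' Binds a dataset to one of the four G-test backends:
#' \describe{
#'   \item{default}{direct row counting for every test (the unoptimized
#'     reference).}
#'   \item{static-adtree}{counts assembled from a fully pre-built AD-tree.}
#'   \item{dynamic-adtree}{counts from an AD-tree expanded on demand.}
#'   \item{dcmi}{G from cached joint-entropy terms and DoF from the
#'     permutation-filled DoF cache; the data set is touched only on cache
#'     misses.}
#' }
#' Optimization structures (`jht`, `dof_cache`, or a shared tree) may be
#' passed in to share them across runs on the same data set.
#'
#' @param ds A [discrete_dataset()].
#' @param cfg A [ci_test_config()]; `cfg$backend` selects the engine.
#' @param jht,dof_cache Optional shared caches (dcmi backend).
#' @param tree Optional shared `adtree` (AD-tree backends); must match the
#'   backend mode and `cfg$llt`.
#' @return An object of class `ci_engine` (environment): call [ci_test()] on
#'   it; `$n_tests` counts tests served.
#' @export
ci_engine <- function(ds, cfg = ci_test_config(), jht = NULL,
                      dof_cache = NULL, tree = NULL) {
  e <- new.env(parent = emptyenv())
  e$ds <- ds
  e$cfg <- cfg
  e$n_tests <- 0L
  if (cfg$backend == "static-adtree") {
    e$tree <- tree %||% build_static_adtree(ds, llt_percent = cfg$llt)
  } else if (cfg$backend == "dynamic-adtree") {
    e$tree <- tree %||% build_dynamic_adtree(ds, llt_percent = cfg$llt)
  } else if (cfg$backend == "dcmi") {
    e$jht <- jht %||% new_jht()
    e$dof_cache <- dof_cache %||% new_dof_cache()
  }
  class(e) <- "ci_engine"
  e
}

#' @export
print.ci_engine <- function(x, ...) {
  cat(sprintf("CI-test engine [%s]: %d tests performed\n",
              x$cfg$backend, x$n_tests))
  invisible(x)
}

#' Conditional-independence G-test through a backend
#'
#' The single entry point used by IPC-MB: assembles counts from the engine's
#' backend, computes the statistic, degrees of freedom, p-value and verdict,
#' and increments the engine's test counter. All four backends return
#' identical results on the same data (the AD-trees hold the very counts a
#' row scan yields, and the entropy decomposition is an identity).
#'
#' A bare [discrete_dataset()] may be passed instead of an engine for a
#' one-shot test with the default backend.
#'
#' @param engine A [ci_engine()] or a [discrete_dataset()].
#' @param x,y Feature indices (1-based), distinct, neither in `z`.
#' @param z Conditioning feature-index vector (default empty).
#' @param cfg Used only when `engine` is a dataset.
#' @return A `gtest_result`.
#' @export
ci_test <- function(engine, x, y, z = integer(0), cfg = ci_test_config()) {
  if (inherits(engine, "discrete_dataset"))
    engine <- ci_engine(engine, cfg)
  if (!inherits(engine, "ci_engine")) stop("engine must be a ci_engine")
  x <- as.integer(x); y <- as.integer(y); z <- as.integer(z)
  if (x == y) stop("x and y must be distinct")
  if (x %in% z || y %in% z) stop("x and y must not be in z")
  e <- engine
  e$n_tests <- e$n_tests + 1L
  b <- e$cfg$backend
  if (b == "dcmi")
    return(g_test_dcmi(e$ds, x, y, z, e$jht, e$dof_cache, e$cfg))
  feats <- sort(c(x, y, z))
  joint <- if (b == "default") count_joint(e$ds, feats)
           else contingency_from_tree(e$tree, feats)
  ci_test_from_counts(joint, x, y, z, e$cfg)
}

#' Optimization-structure entry counts of an engine
#'
#' @param engine A [ci_engine()].
#' @return Named integer vector of entry/node counts for whatever structures
#'   the backend maintains (empty for the default backend).
#' @export
engine_structure_counts <- function(engine) {
  b <- engine$cfg$backend
  if (b == "dcmi") {
    c(jht_entries = length(ls(engine$jht$entries)),
      dof_entries = length(ls(engine$dof_cache$entries)))
  } else if (b %in% c("static-adtree", "dynamic-adtree")) {
    adtree_node_counts(engine$tree)
  } else {
    c(jht_entries = 0L)[0]
  }
}

# --- testers: the true/false oracle interface IPC-MB consumes ---------------

# A tester is an environment with $is_indep(x, y, z) -> logical, a test
# counter $n_tests, and an optional verdict trace for backend-equivalence
# audits.

#' Build a CI tester from a data-backed engine
#'
#' @param engine A [ci_engine()].
#' @param record_trace Record `(x, y, z, verdict)` per test for audits.
#' @return A tester environment for [find_mb()] and friends.
#' @export
data_tester <- function(engine, record_trace = FALSE) {
  t <- new.env(parent = emptyenv())
  t$n_tests <- 0L
  t$trace <- if (record_trace) list() else NULL
  t$is_indep <- function(x, y, z) {
    res <- ci_test(engine, x, y, z)
    t$n_tests <- t$n_tests + 1L
    if (!is.null(t$trace))
      t$trace[[length(t$trace) + 1L]] <-
        list(x = x, y = y, z = sort(as.integer(z)),
             independent = res$independent)
    res$independent
  }
  class(t) <- "ci_tester"
  t
}

#' Build a d-separation oracle tester from a Bayesian network
#'
#' Answers CI queries from graph structure instead of data: the validation
#' oracle for blanket discovery (a recovered blanket must match graph truth
#' when this tester is used).
#'
#' @param bn A [bayesian_network()]; feature indices follow declaration order.
#' @param record_trace Record per-test verdicts.
#' @return A tester environment.
#' @export
dsep_tester <- function(bn, record_trace = FALSE) {
  t <- new.env(parent = emptyenv())
  t$n_tests <- 0L
  t$trace <- if (record_trace) list() else NULL
  t$is_indep <- function(x, y, z) {
    v <- d_separated(bn, bn$nodes[x], bn$nodes[y], bn$nodes[z])
    t$n_tests <- t$n_tests + 1L
    if (!is.null(t$trace))
      t$trace[[length(t$trace) + 1L]] <-
        list(x = x, y = y, z = sort(as.integer(z)), independent = v)
    v
  }
  class(t) <- "ci_tester"
  t
}
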