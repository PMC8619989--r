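# IPC-MB: iterative parent-child Markov blanket discovery through the
# black-box CI-test interface. The algorithm sees only feature indices and
# true/false independence answers; how counts are obtained is the backend's
# business, which is what makes the four G-test engines interchangeable.

chr <- function(i) as.character(i)

#' Parent-child candidate recognition
#'
#' Shrinks a candidate set around the target by conditioning on subsets of
#' increasing size: all size-0 (unconditional) tests first, then size 1, 2,
#' and so on. Within a sweep, subsets are enumerated in lexicographic order
#' over sorted indices and a candidate is removed the moment a separating set
#' is found, immediately leaving the pool for subsequent tests. Stops when the
#' subset size exceeds the remaining pool minus one.
#'
#' @param target Feature index.
#' @param candidates Candidate feature indices (excluding `target`).
#' @param tester A tester from [data_tester()] or [dsep_tester()].
#' @return List with `pc` (surviving candidates, sorted) and `sepsets`
#'   (named list mapping each removed candidate to its separating set).
#' @export
recognize_pc <- function(target, candidates, tester) {
  remaining <- sort(setdiff(as.integer(candidates), target))
  sepsets <- list()
  k <- 0L
  while (k <= length(remaining) - 1L) {
    for (x in remaining) {
      if (!(x %in% remaining)) next    # removed earlier in this sweep
      pool <- setdiff(remaining, x)
      if (length(pool) < k) next
      for (s in subsets_of_size(pool, k)) {
        if (tester$is_indep(target, x, s)) {
          remaining <- setdiff(remaining, x)
          sepsets[[chr(x)]] <- s
          break
        }
      }
    }
    k <- k + 1L
  }
  list(pc = remaining, sepsets = sepsets)
}

# Memoized recognize_pc over the full feature pool F \ {target}; memo is an
# environment shared within one find_mb run (deterministic, so CI-test counts
# stay identical across backends).
recognize_full <- function(target, m, tester, memo = NULL) {
  key <- chr(target)
  if (!is.null(memo)) {
    got <- get0(key, envir = memo, inherits = FALSE)
    if (!is.null(got)) return(got)
  }
  res <- recognize_pc(target, setdiff(seq_len(m), target), tester)
  if (!is.null(memo)) assign(key, res, envir = memo)
  res
}

#' Parents-and-children set of a target feature
#'
#' Runs [recognize_pc()] over all other features, then applies the symmetry
#' correction: a surviving candidate X is kept only if the target survives
#' the reverse recognition around X. Asymmetric false positives are removed;
#' their separating sets (found during the reverse run) are recorded.
#'
#' @param target Feature index.
#' @param m Total number of features.
#' @param tester A CI tester.
#' @param memo Optional environment memoizing recognition runs.
#' @return List with `pc` (sorted indices) and `sepsets` for every feature
#'   separated from the target in either direction.
#' @export
find_pc <- function(target, m, tester, memo = NULL) {
  r1 <- recognize_full(target, m, tester, memo)
  seps <- r1$sepsets
  keep <- integer(0)
  for (x in r1$pc) {
    rx <- recognize_full(x, m, tester, memo)
    if (target %in% rx$pc) {
      keep <- c(keep, x)
    } else {
      seps[[chr(x)]] <- rx$sepsets[[chr(target)]]
    }
  }
  list(pc = sort(keep), sepsets = seps)
}

#' Spouse discovery
#'
#' For each parent/child X of the target, computes PC(X) and tests every
#' member Y outside PC(T) and the target for conditional independence with
#' the target. Under the default `sepset_union_x` rule the conditioning set
#' is the recorded separating set of (T, Y) plus X — re-opening the collider
#' at the shared child while keeping all other paths blocked; `pc_only`
#' conditions on PC(T) as a whole. A dependent verdict marks Y as a spouse.
#'
#' @param target Feature index.
#' @param pc The target's parents-and-children set.
#' @param m Total number of features.
#' @param tester A CI tester.
#' @param sepsets Named list of separating sets from [find_pc()].
#' @param spouse_conditioning `"sepset_union_x"` or `"pc_only"`.
#' @param memo Optional memo environment shared with [find_pc()].
#' @return Sorted integer vector of spouse indices.
#' @export
find_spouses <- function(target, pc, m, tester, sepsets = list(),
                         spouse_conditioning = "sepset_union_x",
                         memo = NULL) {
  sp <- integer(0)
  for (x in pc) {
    pcx <- find_pc(x, m, tester, memo)$pc
    for (y in setdiff(pcx, c(pc, target, sp))) {
      cond <- if (spouse_conditioning == "pc_only") pc
              else sort(unique(c(sepsets[[chr(y)]], x)))
      if (!tester$is_indep(target, y, cond)) sp <- c(sp, y)
    }
  }
  sort(sp)
}

#' Discover the Markov blanket of a target feature
#'
#' Full IPC-MB: parent-child recognition with conditioning sets of increasing
#' size, symmetry correction, then spouse discovery — all through the
#' black-box CI tester, so the result depends only on the tester's verdicts.
#' With a [dsep_tester()] the recovered blanket equals the graph-truth
#' blanket; with a [data_tester()] it is the finite-sample estimate.
#'
#' @param target Feature index.
#' @param tester A CI tester.
#' @param m Total number of features.
#' @param spouse_conditioning See [find_spouses()].
#' @return An object of class `mb_result`: `target`, `pc`, `sp`,
#'   `mb = pc` \eqn{\cup} `sp`, `sepsets`, and `ci_tests_performed` (the
#'   tester counter delta for this run).
#' @export
find_mb <- function(target, tester, m,
                    spouse_conditioning = "sepset_union_x") {
  n0 <- tester$n_tests
  memo <- new.env(parent = emptyenv())
  fp <- find_pc(target, m, tester, memo)
  sp <- find_spouses(target, fp$pc, m, tester, fp$sepsets,
                     spouse_conditioning, memo)
  structure(list(target = as.integer(target), pc = fp$pc, sp = sp,
                 mb = sort(union(fp$pc, sp)), sepsets = fp$sepsets,
                 ci_tests_performed = tester$n_tests - n0),
            class = "mb_result")
}

#' @export
print.mb_result <- function(x, ...) {
  cat(sprintf("Markov blanket of feature %d: {%s}\n", x$target,
              paste(x$mb, collapse = ", ")))
  cat(sprintf("  parents/children: {%s}; spouses: {%s}; CI tests: %d\n",
              paste(x$pc, collapse = ", "), paste(x$sp, collapse = ", "),
              x$ci_tests_performed))
  invisible(x)
}

#' Markov blanket discovery on discrete data
#'
#' The main fitting interface: runs IPC-MB for one target feature against a
#' dataset with the selected G-test backend (or against a Bayesian network,
#' in which case d-separation answers the CI queries and the result is the
#' graph-truth blanket).
#'
#' @param data A [discrete_dataset()], a path to a CSV of integer-coded
#'   samples, or a [bayesian_network()] (oracle mode).
#' @param target Feature index or feature name.
#' @param backend G-test backend (ignored in oracle mode): `"default"`,
#'   `"static-adtree"`, `"dynamic-adtree"` or `"dcmi"`.
#' @param alpha Significance level of the G-test.
#' @param llt Leaf-list threshold percentage for AD-tree backends.
#' @param config Optional [ci_test_config()] overriding the above.
#' @param engine Optional pre-built [ci_engine()] (for sharing optimization
#'   structures across calls); overrides `backend`/`config`.
#' @return An object of class `ipcmb` wrapping the `mb_result`, with feature
#'   names resolved, the engine's structure counts, and (for the dcmi
#'   backend) the JHT hit rate so far.
#' @examples
#' bn <- random_network(6, max_parents = 2, seed = 42)
#' ds <- sample_network(bn, 2000, seed = 7)
#' fit <- ipcmb(ds, target = 1, backend = "dcmi")
#' print(fit)
#' @export
ipcmb <- function(data, target, backend = "dcmi", alpha = 0.05, llt = 0,
                  config = NULL, engine = NULL) {
  cl <- match.call()
  if (is.character(data) && length(data) == 1L && file.exists(data))
    data <- read_discrete_dataset(data)
  oracle <- inherits(data, "bayesian_network")
  names_ <- if (oracle) data$nodes else data$feature_names
  m <- length(names_)
  if (is.character(target)) {
    ti <- match(target, names_)
    if (is.na(ti)) stop("unknown feature: ", target)
  } else ti <- as.integer(target)
  if (ti < 1L || ti > m) stop("target index out of range")
  cfg <- config %||% ci_test_config(alpha = alpha, backend = backend,
                                    llt = llt)
  if (oracle) {
    tester <- dsep_tester(data)
    engine <- NULL
  } else {
    engine <- engine %||% ci_engine(data, cfg)
    tester <- data_tester(engine)
  }
  res <- find_mb(ti, tester, m, cfg$spouse_conditioning)
  out <- list(result = res, target = names_[ti],
              blanket = names_[res$mb], pc = names_[res$pc],
              sp = names_[res$sp],
              ci_tests = res$ci_tests_performed,
              backend = if (oracle) "d-separation oracle" else cfg$backend,
              alpha = cfg$alpha, engine = engine, call = cl)
  if (!oracle) {
    out$structure_counts <- engine_structure_counts(engine)
    if (cfg$backend == "dcmi" && engine$jht$hits + engine$jht$misses > 0)
      out$jht_hit_rate <- hit_rate(engine$jht)
  }
  class(out) <- "ipcmb"
  out
}

#' @export
print.ipcmb <- function(x, ...) {
  cat("IPC-MB Markov blanket discovery\n")
  cat(sprintf("  target:  %s\n", x$target))
  cat(sprintf("  blanket: {%s}\n", paste(x$blanket, collapse = ", ")))
  cat(sprintf("  backend: %s, alpha = %g, CI tests: %d\n",
              x$backend, x$alpha, x$ci_tests))
  invisible(x)
}

#' @export
summary.ipcmb <- function(object, ...) {
  x <- object
  cat("IPC-MB Markov blanket discovery\n")
  cat(sprintf("  target:           %s\n", x$target))
  cat(sprintf("  parents/children: {%s}\n", paste(x$pc, collapse = ", ")))
  cat(sprintf("  spouses:          {%s}\n", paste(x$sp, collapse = ", ")))
  cat(sprintf("  blanket:          {%s}\n", paste(x$blanket, collapse = ", ")))
  cat(sprintf("  backend: %s, alpha = %g\n", x$backend, x$alpha))
  cat(sprintf("  CI tests performed: %d\n", x$ci_tests))
  if (!is.null(x$jht_hit_rate))
    cat(sprintf("  JHT hit rate so far: %.3f\n", x$jht_hit_rate))
  if (!is.null(x$structure_counts) && length(x$structure_counts))
    cat("  structures:", paste(names(x$structure_counts),
                               x$structure_counts, sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a blanket-discovery result to a JSON record
#'
#' @param x An `ipcmb` fit.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mb_json <- function(x, path) {
  res <- x$result
  obj <- list(target = x$target, blanket = x$blanket, pc = x$pc, sp = x$sp,
              target_index = res$target, mb_indices = res$mb,
              ci_tests = res$ci_tests_performed,
              backend = x$backend, alpha = x$alpha)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
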