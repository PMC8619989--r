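# Decomposed conditional mutual information (dcMI): the G statistic written as
# 2N * [H(X,Z) + H(Y,Z) - H(X,Y,Z) - H(Z)] over cached joint-entropy terms.
# Because joint entropy is indifferent to argument order, tests on permutations
# of the same features reuse previously computed terms, and the data set is
# touched only on cache misses. No approximation: the value is identical to
# the canonical statistic.

#' Create an empty Joint Entropy Table (JHT)
#'
#' An associative cache mapping canonical (order-free) feature-index sets to
#' joint entropies in nats, with hit/miss counters. Any permutation of a set
#' addresses the same entry.
#'
#' @return An object of class `jht` (environment-based; mutated in place).
#' @export
new_jht <- function() {
  e <- new.env(parent = emptyenv())
  e$entries <- new.env(parent = emptyenv())
  e$hits <- 0L
  e$misses <- 0L
  class(e) <- "jht"
  e
}

#' @export
print.jht <- function(x, ...) {
  cat(sprintf("Joint Entropy Table: %d entries, %d hits, %d misses\n",
              length(ls(x$entries)), x$hits, x$misses))
  invisible(x)
}

#' Create an empty degrees-of-freedom cache
#'
#' Maps canonical (pair, conditioning-set) keys to precomputed DoF values.
#' Filled opportunistically whenever a joint probability mass function is
#' built for a JHT miss — the only moment the zeros of that PMF are available
#' without touching the data set again.
#'
#' @return An object of class `dof_cache` (environment-based).
#' @export
new_dof_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$entries <- new.env(parent = emptyenv())
  class(e) <- "dof_cache"
  e
}

#' @export
print.dof_cache <- function(x, ...) {
  cat(sprintf("DoF cache: %d entries\n", length(ls(x$entries))))
  invisible(x)
}

#' Joint entropy of a contingency table, in nats
#'
#' `H = -sum (c/N) ln(c/N)` over the stored (non-zero) cells.
#'
#' @param counts A [contingency_table()] with `total >= 1`.
#' @return Joint entropy in nats, in `[0, ln(prod arities)]`.
#' @export
joint_entropy <- function(counts) {
  if (length(counts$counts) == 0L) stop("empty contingency table")
  p <- counts$counts / counts$total
  -sum(p * log(p))
}

#' Conditional mutual information from four joint-entropy terms
#'
#' `I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(X,Y,Z) - H(Z)`, with tiny negative values
#' from floating-point cancellation clamped to 0 (CMI is non-negative).
#' `H(Z) = 0` for an empty conditioning set, so the unconditional case needs
#' no special handling.
#'
#' @param h_xz,h_yz,h_xyz,h_z Joint entropies in nats.
#' @return Non-negative CMI in nats.
#' @export
cmi_decomposed <- function(h_xz, h_yz, h_xyz, h_z) {
  v <- h_xz + h_yz - h_xyz - h_z
  if (v < 0) v <- 0
  v
}

#' Look up or compute one joint-entropy term
#'
#' On a hit the stored entropy is returned. On a miss the features are
#' retrieved from the data set, their joint PMF is counted, its entropy is
#' computed and stored — and, when the set has two or more members and a DoF
#' cache is supplied, the cache is filled with the degrees of freedom of every
#' unordered pair of the set conditioned on the remaining members, because the
#' just-built PMF is the only chance to see its zero cells.
#'
#' The empty set returns `H() = 0` without touching the cache or counters.
#'
#' @param jht A [new_jht()].
#' @param ds A [discrete_dataset()].
#' @param s Feature-index set (any order; canonicalized internally).
#' @param dof_cache Optional [new_dof_cache()] to fill on misses.
#' @return The joint entropy of `s` in nats.
#' @export
get_or_compute_term <- function(jht, ds, s, dof_cache = NULL) {
  s <- as.integer(s)
  if (length(s) == 0L) return(0)
  if (any(s < 1L | s > ds$M)) stop("feature index out of range")
  key <- set_key(s)
  hit <- get0(key, envir = jht$entries, inherits = FALSE)
  if (!is.null(hit)) {
    jht$hits <- jht$hits + 1L
    return(hit)
  }
  ct <- count_joint(ds, sort(s))
  h <- joint_entropy(ct)
  assign(key, h, envir = jht$entries)
  jht$misses <- jht$misses + 1L
  if (length(s) >= 2L && !is.null(dof_cache)) {
    ss <- sort(s)
    prs <- utils::combn(ss, 2L, simplify = FALSE)
    for (pr in prs) {
      rest <- setdiff(ss, pr)
      dk <- pair_key(pr[1], pr[2], rest)
      if (is.null(get0(dk, envir = dof_cache$entries, inherits = FALSE))) {
        dof <- degrees_of_freedom(ct, pr[1], pr[2], rest)
        assign(dk, dof, envir = dof_cache$entries)
      }
    }
  }
  h
}

#' dcMI G-test of conditional independence
#'
#' Computes `G(X,Y|Z) = 2N * [H(X,Z) + H(Y,Z) - H(X,Y,Z) - H(Z)]` from at most
#' four JHT terms (three when `z` is empty, since `H() = 0`), and takes the
#' degrees of freedom from the DoF cache, which the `{x,y} union z` term fill
#' is guaranteed to have populated. The data set is accessed only on cache
#' misses; the value equals the canonical statistic exactly (up to float
#' round-off), as the decomposition is an identity, not an approximation.
#'
#' @param ds A [discrete_dataset()].
#' @param x,y Feature indices, distinct, not in `z`.
#' @param z Conditioning feature indices (may be empty).
#' @param jht A [new_jht()], shared across tests and runs on the same data.
#' @param dof_cache A [new_dof_cache()], shared likewise.
#' @param cfg A [ci_test_config()].
#' @return A `gtest_result`, identical to the canonical backend's.
#' @export
g_test_dcmi <- function(ds, x, y, z = integer(0), jht, dof_cache,
                        cfg = ci_test_config()) {
  x <- as.integer(x); y <- as.integer(y); z <- as.integer(z)
  if (x == y) stop("x and y must be distinct")
  if (x %in% z || y %in% z) stop("x and y must not be in z")
  # term order: H(X,Z), H(Y,Z), H(X,Y,Z), then H(Z) when z is non-empty
  h_xz <- get_or_compute_term(jht, ds, c(x, z), dof_cache)
  h_yz <- get_or_compute_term(jht, ds, c(y, z), dof_cache)
  h_xyz <- get_or_compute_term(jht, ds, c(x, y, z), dof_cache)
  h_z <- get_or_compute_term(jht, ds, z, dof_cache)
  g <- 2 * ds$N * cmi_decomposed(h_xz, h_yz, h_xyz, h_z)
  dk <- pair_key(x, y, z)
  dof <- get0(dk, envir = dof_cache$entries, inherits = FALSE)
  if (is.null(dof)) {
    # defensive: a warm JHT paired with a cold DoF cache (e.g. deserialized
    # separately) forces one recount; normal operation never reaches this
    dof <- degrees_of_freedom(count_joint(ds, sort(c(x, y, z))), x, y, z)
    assign(dk, dof, envir = dof_cache$entries)
  }
  finalize_gtest(g, dof, x, y, z, ds$N,
                 prod(ds$arities[c(x, y, z)]), cfg)
}

#' JHT hit rate
#'
#' @param jht A [new_jht()] that has served at least one lookup.
#' @return `hits / (hits + misses)`.
#' @export
hit_rate <- function(jht) {
  tot <- jht$hits + jht$misses
  if (tot < 1L) stop("no lookups performed yet")
  jht$hits / tot
}

#' Serialize a JHT or DoF cache to JSON
#'
#' Flat documented format so optimization structures can be shared between
#' runs on the same data set across processes: for a JHT,
#' `{"entries": {"1,3": h, ...}, "hits": n, "misses": n}`; for a DoF cache,
#' `{"entries": {"1,3|2": dof, ...}}`.
#'
#' @param x A `jht` or `dof_cache`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
cache_write_json <- function(x, path) {
  ent <- as.list(x$entries)
  ent <- ent[order(names(ent))]
  obj <- if (inherits(x, "jht"))
    list(type = "jht", entries = ent, hits = x$hits, misses = x$misses)
  else list(type = "dof_cache", entries = ent)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deserialize a JHT or DoF cache from JSON
#'
#' @param path File written by [cache_write_json()].
#' @return A `jht` or `dof_cache`, per the file's `type` field.
#' @export
cache_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "jht")) {
    j <- new_jht()
    for (k in names(obj$entries)) assign(k, obj$entries[[k]], envir = j$entries)
    j$hits <- as.integer(obj$hits)
    j$misses <- as.integer(obj$misses)
    j
  } else if (identical(obj$type, "dof_cache")) {
    d <- new_dof_cache()
    for (k in names(obj$entries))
      assign(k, as.integer(obj$entries[[k]]), envir = d$entries)
    d
  } else stop("unrecognized cache file: ", path)
}
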