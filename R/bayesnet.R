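# Discrete Bayesian networks: the data source (ancestral sampling) and the
# validation oracle (d-separation, graph-truth Markov blankets) for blanket
# discovery.

#' Construct a discrete Bayesian network
#'
#' @param nodes Character vector of node names, in declaration order.
#' @param arities Integer vector of node arities (same order as `nodes`).
#' @param parents Named list mapping each node to its ordered character vector
#'   of parent names (possibly empty).
#' @param cpts Named list mapping each node to a numeric matrix with one row
#'   per joint parent configuration and one column per node value. Parent
#'   configurations are indexed mixed-radix with the FIRST parent varying
#'   fastest; a parentless node has a single row.
#' @param value_labels Optional named list of per-node value label vectors.
#' @return An object of class `bayesian_network`.
#' @export
bayesian_network <- function(nodes, arities, parents, cpts,
                             value_labels = NULL) {
  nodes <- as.character(nodes)
  arities <- as.integer(arities)
  names(arities) <- nodes
  parents <- parents[nodes]
  cpts <- cpts[nodes]
  if (is.null(value_labels))
    value_labels <- lapply(arities, function(a) paste0("v", seq_len(a) - 1L))
  names(value_labels) <- nodes
  bn <- structure(list(nodes = nodes, arities = arities, parents = parents,
                       cpts = cpts, value_labels = value_labels),
                  class = "bayesian_network")
  ord <- topological_order(bn)   # errors on cycles
  for (v in nodes) {
    pa <- parents[[v]]
    nconf <- if (length(pa)) prod(arities[pa]) else 1L
    cpt <- cpts[[v]]
    if (!is.matrix(cpt) || nrow(cpt) != nconf || ncol(cpt) != arities[[v]])
      stop(sprintf("CPT of '%s' must be %d x %d", v, nconf, arities[[v]]))
    if (any(cpt < 0)) stop(sprintf("negative probability in CPT of '%s'", v))
    if (any(abs(rowSums(cpt) - 1) > 1e-6))
      stop(sprintf("CPT rows of '%s' do not sum to 1", v))
  }
  attr(bn, "order") <- ord
  bn
}

#' @export
print.bayesian_network <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat(sprintf("Bayesian network: %d nodes, %d edges\n", length(x$nodes), ne))
  invisible(x)
}

# Topological order of node names; errors if the parent graph has a cycle.
topological_order <- function(bn) {
  remaining <- bn$nodes
  placed <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v)
      all(bn$parents[[v]] %in% placed), logical(1))]
    if (!length(ready)) stop("parent graph contains a cycle")
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

children_of <- function(bn, v) {
  bn$nodes[vapply(bn$nodes, function(u) v %in% bn$parents[[u]], logical(1))]
}

#' Graph-truth Markov blanket of a node
#'
#' The blanket is the union of the node's parents, children and spouses
#' (nodes sharing at least one child with it), read directly off the DAG.
#'
#' @param bn A [bayesian_network()].
#' @param target Node name.
#' @return A list with components `target`, `parents`, `children`, `spouses`
#'   and `blanket` (character vectors, sorted).
#' @export
true_markov_blanket <- function(bn, target) {
  if (!target %in% bn$nodes) stop("unknown node: ", target)
  pa <- bn$parents[[target]]
  ch <- children_of(bn, target)
  sp <- unique(unlist(lapply(ch, function(c) bn$parents[[c]])))
  sp <- setdiff(sp, c(target, pa, ch))
  list(target = target, parents = sort(pa), children = sort(ch),
       spouses = sort(sp),
       blanket = sort(unique(c(pa, ch, sp))))
}

#' Test d-separation of two nodes given a conditioning set
#'
#' Uses the ancestral-moral-graph construction: restrict to the ancestors of
#' `x`, `y` and `z`, marry co-parents, drop the conditioning nodes, and test
#' undirected reachability. This is equivalent to Bayes-ball path blocking
#' (chains and forks blocked by conditioning, colliders opened by conditioning
#' on them or a descendant).
#'
#' @param bn A [bayesian_network()].
#' @param x,y Distinct node names, not in `z`.
#' @param z Character vector of conditioning node names (may be empty).
#' @return `TRUE` iff `x` and `y` are d-separated given `z`.
#' @export
d_separated <- function(bn, x, y, z = character(0)) {
  z <- as.character(z)
  all_named <- c(x, y, z)
  if (!all(all_named %in% bn$nodes))
    stop("unknown node: ", paste(setdiff(all_named, bn$nodes), collapse = ", "))
  if (x == y) stop("x and y must be distinct")
  if (x %in% z || y %in% z) stop("x and y must not be in z")

  # ancestors of {x, y} union z, inclusive
  anc <- unique(c(x, y, z))
  repeat {
    more <- unique(unlist(lapply(anc, function(v) bn$parents[[v]])))
    new <- setdiff(more, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  idx <- match(anc, bn$nodes)
  k <- length(anc)
  adj <- matrix(FALSE, k, k, dimnames = list(anc, anc))
  for (v in anc) {
    pa <- intersect(bn$parents[[v]], anc)
    for (p in pa) adj[p, v] <- adj[v, p] <- TRUE
    # moralize: marry all co-parents of v
    if (length(pa) > 1L)
      for (i in seq_along(pa)) for (j in seq_along(pa))
        if (i != j) adj[pa[i], pa[j]] <- TRUE
  }
  keep <- setdiff(anc, z)
  adj <- adj[keep, keep, drop = FALSE]
  # BFS from x
  reach <- structure(rep(FALSE, length(keep)), names = keep)
  frontier <- x
  reach[x] <- TRUE
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, function(v) keep[adj[v, ]])))
    frontier <- nb[!reach[nb]]
    reach[frontier] <- TRUE
  }
  !reach[[y]]
}

#' Ancestral sampling from a Bayesian network
#'
#' Draws `n` full sample vectors in topological order, each node sampled from
#' its CPT row selected by the already-sampled parent values. Deterministic
#' given `seed`. Column order follows the network's declaration order.
#'
#' @param bn A [bayesian_network()].
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @return A [discrete_dataset()] with one column per node.
#' @export
sample_network <- function(bn, n, seed) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  ord <- attr(bn, "order")
  vals <- matrix(0L, n, length(bn$nodes),
                 dimnames = list(NULL, bn$nodes))
  for (v in ord) {
    pa <- bn$parents[[v]]
    cpt <- bn$cpts[[v]]
    if (length(pa)) {
      conf <- encode_cells(vals[, pa, drop = FALSE], bn$arities[pa])
    } else {
      conf <- rep(1, n)
    }
    cum <- t(apply(cpt, 1, cumsum))
    if (ncol(cpt) == 1L) cum <- matrix(cum, nrow = nrow(cpt))
    u <- stats::runif(n)
    drawn <- rowSums(u > cum[conf, , drop = FALSE])
    vals[, v] <- pmin(as.integer(drawn), bn$arities[[v]] - 1L)
  }
  discrete_dataset(vals, arities = unname(bn$arities),
                   feature_names = bn$nodes)
}

#' Generate a random discrete Bayesian network
#'
#' Fixture generator standing in for reference networks: draws a random
#' topological order, gives each node up to `max_parents` parents among its
#' predecessors, and fills CPT rows with draws from a symmetric Dirichlet.
#' Deterministic given `seed`.
#'
#' @param m Number of nodes.
#' @param max_parents Maximum in-degree (< m).
#' @param arity_range Integer pair `(lo, hi)`; node arities drawn uniformly.
#' @param seed Integer seed.
#' @param dirichlet_alpha Concentration of the CPT row prior; values below 1
#'   favour sharper (more informative) conditional distributions.
#' @return A [bayesian_network()] with nodes `X1..Xm`.
#' @export
random_network <- function(m, max_parents = 2L, arity_range = c(2L, 3L),
                           seed = 1L, dirichlet_alpha = 0.5) {
  stopifnot(m >= 1, max_parents < m || m == 1L)
  set.seed(as.integer(seed))
  nodes <- paste0("X", seq_len(m))
  ord <- sample(nodes)
  arities <- sample(seq(arity_range[1], arity_range[2]), m, replace = TRUE)
  names(arities) <- nodes
  parents <- stats::setNames(vector("list", m), nodes)
  for (i in seq_len(m)) {
    v <- ord[i]
    pool <- ord[seq_len(i - 1L)]
    k <- if (length(pool)) sample(0:min(max_parents, length(pool)), 1L) else 0L
    parents[[v]] <- if (k > 0L) sample(pool, k) else character(0)
  }
  cpts <- stats::setNames(vector("list", m), nodes)
  for (v in nodes) {
    pa <- parents[[v]]
    nconf <- if (length(pa)) prod(arities[pa]) else 1L
    g <- matrix(stats::rgamma(nconf * arities[[v]], shape = dirichlet_alpha),
                nrow = nconf)
    g <- pmax(g, 1e-12)
    cpts[[v]] <- g / rowSums(g)
  }
  bayesian_network(nodes, unname(arities), parents, cpts)
}
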