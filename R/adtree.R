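# AD-trees: a tree of AD-nodes (sample counts) and Vary-nodes (features)
# answering arbitrary sample-count queries, with the two classic memory
# optimizations: Most-Common-Value (MCV) elision — the subtree of a
# Vary-node's most common value is never built and its counts are
# reconstructed as parent minus siblings — and Leaf-Lists, which replace
# subtrees below a sample-count threshold (a percentage of N) with stored row
# indices scanned at query time. Zero-count nodes are never created. Static
# trees are fully built before the first query; dynamic trees start empty and
# expand on demand.

new_adnode <- function(tree, rows, keep_rows) {
  e <- new.env(parent = emptyenv())
  e$count <- length(rows)
  e$leaf <- e$count < tree$llt_abs
  e$rows <- if (keep_rows || e$leaf) rows else NULL
  e$vary <- new.env(parent = emptyenv())
  tree$n_adnodes <- tree$n_adnodes + 1L
  if (e$leaf) tree$n_leaflists <- tree$n_leaflists + 1L
  e
}

# Create the Vary-node of `node` for feature `f`, counting all values of f
# among the node's rows to pick the MCV (ties: smallest value index), and
# materializing AD-node children for every non-MCV value with positive count.
# `after_pos` is f's position in the tree ordering; static mode recurses.
make_vary <- function(tree, node, f, rows, static_expand, after_pos) {
  ar <- tree$ds$arities[f]
  col <- tree$ds$values[rows, f]
  cnt <- tabulate(col + 1L, nbins = ar)
  mcv <- which.max(cnt) - 1L          # which.max takes the first (smallest) tie
  children <- vector("list", ar)
  for (v in seq_len(ar) - 1L) {
    if (v == mcv || cnt[v + 1L] == 0L) next
    sub <- rows[col == v]
    child <- new_adnode(tree, sub, keep_rows = tree$mode == "dynamic")
    if (static_expand && !child$leaf)
      expand_all(tree, child, sub, after_pos)
    children[[v + 1L]] <- child
  }
  vn <- list(feature = f, mcv = mcv, children = children)
  assign(as.character(f), vn, envir = node$vary)
  tree$n_varynodes <- tree$n_varynodes + 1L
  vn
}

# Static construction: expand Vary-nodes of `node` for every feature strictly
# after position `pos` in the ordering.
expand_all <- function(tree, node, rows, pos) {
  ord <- tree$ordering
  if (pos >= length(ord)) return(invisible())
  for (p in seq(pos + 1L, length(ord)))
    make_vary(tree, node, ord[p], rows, static_expand = TRUE, after_pos = p)
  invisible()
}

# Fetch the Vary-node of `node` for feature `f`, expanding it on demand in
# dynamic mode. `pos` is f's position in the tree ordering.
get_vary <- function(tree, node, f, pos) {
  vn <- get0(as.character(f), envir = node$vary, inherits = FALSE)
  if (!is.null(vn)) return(vn)
  if (tree$mode != "dynamic")
    stop("internal error: missing Vary-node in a static AD-tree")
  if (is.null(node$rows)) stop("dynamic AD-tree requires dataset row access")
  make_vary(tree, node, f, node$rows, static_expand = FALSE, after_pos = pos)
}

#' Build a static AD-tree
#'
#' Fully expands the tree before any query, subject to zero-count skipping,
#' MCV elision and the Leaf-List cutoff: a node whose sample count is strictly
#' below `ceil(llt_percent/100 * N)` stores its row indices instead of a
#' subtree (so `llt_percent = 0` disables Leaf-Lists entirely).
#'
#' @param ds A [discrete_dataset()].
#' @param ordering Feature indices fixing the expansion order (default:
#'   natural column order). Queries are re-sorted to this ordering internally.
#' @param llt_percent Leaf-List threshold as a percentage of N in `[0, 100]`.
#' @return An object of class `adtree` (environment; holds a dataset
#'   reference, needed to resolve Leaf-Lists).
#' @export
build_static_adtree <- function(ds, ordering = seq_len(ds$M), llt_percent = 0) {
  build_adtree(ds, ordering, llt_percent, mode = "static")
}

#' Create a dynamic AD-tree
#'
#' The tree starts as a bare root and expands exactly the branches that
#' queries require. Determining a Vary-node's MCV requires counting all its
#' sibling values at expansion time; that cost is accepted to keep counts
#' exact. Requires dataset access for the whole lifetime of the tree.
#'
#' @inheritParams build_static_adtree
#' @return An object of class `adtree` with `mode = "dynamic"`.
#' @export
build_dynamic_adtree <- function(ds, ordering = seq_len(ds$M), llt_percent = 0) {
  build_adtree(ds, ordering, llt_percent, mode = "dynamic")
}

build_adtree <- function(ds, ordering, llt_percent, mode) {
  ordering <- as.integer(ordering)
  if (!setequal(ordering, seq_len(ds$M)) || length(ordering) != ds$M)
    stop("ordering must be a permutation of the feature indices")
  if (llt_percent < 0 || llt_percent > 100)
    stop("llt_percent must be in [0, 100]")
  tree <- new.env(parent = emptyenv())
  tree$ds <- ds
  tree$ordering <- ordering
  tree$mode <- mode
  tree$llt_percent <- llt_percent
  tree$llt_abs <- as.integer(ceiling(llt_percent / 100 * ds$N))
  tree$n_adnodes <- 0L
  tree$n_varynodes <- 0L
  tree$n_leaflists <- 0L
  class(tree) <- "adtree"
  tree$root <- new_adnode(tree, seq_len(ds$N), keep_rows = mode == "dynamic")
  if (mode == "static" && !tree$root$leaf)
    expand_all(tree, tree$root, seq_len(ds$N), 0L)
  tree
}

#' @export
print.adtree <- function(x, ...) {
  cat(sprintf("%s AD-tree: %d AD-nodes, %d Vary-nodes, %d Leaf-Lists (LLT %g%% -> <%d), N = %d\n",
              x$mode, x$n_adnodes, x$n_varynodes, x$n_leaflists,
              x$llt_percent, x$llt_abs, x$ds$N))
  invisible(x)
}

# Count rows of a Leaf-List node matching the assignments (feats, vals).
leaf_count <- function(tree, node, feats, vals) {
  rows <- node$rows
  for (j in seq_along(feats))
    rows <- rows[tree$ds$values[rows, feats[j]] == vals[j]]
  length(rows)
}

count_rec <- function(tree, node, feats, vals, poss) {
  if (length(feats) == 0L) return(node$count)
  if (node$leaf) return(leaf_count(tree, node, feats, vals))
  f <- feats[1L]; v <- vals[1L]
  vn <- get_vary(tree, node, f, poss[1L])
  rest_f <- feats[-1L]; rest_v <- vals[-1L]; rest_p <- poss[-1L]
  if (v == vn$mcv) {
    # reconstruct the elided branch: parent-without-f minus non-MCV siblings
    tot <- count_rec(tree, node, rest_f, rest_v, rest_p)
    for (ch in vn$children)
      if (!is.null(ch))
        tot <- tot - count_rec(tree, ch, rest_f, rest_v, rest_p)
    return(tot)
  }
  ch <- vn$children[[v + 1L]]
  if (is.null(ch)) return(0L)   # zero-count nodes are never materialized
  count_rec(tree, ch, rest_f, rest_v, rest_p)
}

#' Query a sample count from an AD-tree
#'
#' Exact equivalent of a direct row scan for the conjunctive query
#' "feature_j = value_j for all j". The query is internally re-sorted to the
#' tree's feature ordering; the empty query returns N. Dynamic trees may
#' expand nodes as a side effect.
#'
#' @param tree An `adtree`.
#' @param assignments Named list or vector: names are feature indices,
#'   values are the required (0-based) feature values.
#' @return The integer sample count (0 for combinations never observed).
#' @export
query_count <- function(tree, assignments) {
  if (length(assignments) == 0L) return(tree$root$count)
  feats <- as.integer(names(assignments))
  vals <- as.integer(unlist(assignments, use.names = FALSE))
  if (anyNA(feats)) stop("assignments must be named by feature index")
  if (anyDuplicated(feats)) stop("duplicate feature in query")
  if (any(feats < 1L | feats > tree$ds$M)) stop("feature index out of range")
  if (any(vals < 0L | vals >= tree$ds$arities[feats]))
    stop("query value outside feature arity")
  poss <- match(feats, tree$ordering)
  o <- order(poss)
  count_rec(tree, tree$root, feats[o], vals[o], poss[o])
}

#' Expand a dynamic AD-tree along a query branch
#'
#' Materializes exactly the nodes needed to answer the given conjunctive
#' query (including the sibling AD-nodes required to fix each Vary-node's
#' MCV); re-issuing the same query expands nothing further.
#'
#' @param tree A dynamic `adtree`.
#' @param assignments As in [query_count()].
#' @return The tree, invisibly (mutated in place).
#' @export
expand_dynamic <- function(tree, assignments) {
  if (tree$mode != "dynamic") stop("expand_dynamic requires a dynamic AD-tree")
  query_count(tree, assignments)
  invisible(tree)
}

# Dense joint-count vector (length prod(arities[feats])) for `feats`, which
# must already be sorted by tree ordering; `poss` are their ordering positions.
ctab_rec <- function(tree, node, feats, poss) {
  if (length(feats) == 0L) return(node$count)
  ar <- tree$ds$arities[feats]
  if (node$leaf) {
    sub <- tree$ds$values[node$rows, feats, drop = FALSE]
    if (length(node$rows) == 1L) sub <- matrix(sub, nrow = 1L)
    return(tabulate(encode_cells(sub, ar), nbins = prod(ar)))
  }
  f <- feats[1L]
  vn <- get_vary(tree, node, f, poss[1L])
  rest_f <- feats[-1L]; rest_p <- poss[-1L]
  nrest <- prod(ar[-1L])
  out <- numeric(prod(ar))
  mcv_rest <- ctab_rec(tree, node, rest_f, rest_p)   # marginal over f
  for (v in seq_len(ar[1L]) - 1L) {
    if (v == vn$mcv) next
    ch <- vn$children[[v + 1L]]
    if (is.null(ch)) next
    cell <- ctab_rec(tree, ch, rest_f, rest_p)
    out[v + 1L + ar[1L] * (seq_len(nrest) - 1L)] <- cell
    mcv_rest <- mcv_rest - cell
  }
  out[vn$mcv + 1L + ar[1L] * (seq_len(nrest) - 1L)] <- mcv_rest
  out
}

#' Assemble a contingency table from an AD-tree
#'
#' Recursively descends the tree, reconstructing MCV-elided branches and
#' scanning Leaf-Lists, to produce the exact joint table [count_joint()]
#' would build from the data directly (zero cells absent).
#'
#' @param tree An `adtree`.
#' @param features Non-empty feature-index vector (any order; the result
#'   preserves the requested order).
#' @return A [contingency_table()] with `total = N`.
#' @export
contingency_from_tree <- function(tree, features) {
  features <- as.integer(features)
  if (length(features) == 0L) stop("features must be non-empty")
  if (anyDuplicated(features)) stop("duplicate feature index")
  if (any(features < 1L | features > tree$ds$M))
    stop("feature index out of range")
  poss <- match(features, tree$ordering)
  o <- order(poss)
  sf <- features[o]; sp <- poss[o]
  ar_s <- tree$ds$arities[sf]
  dense <- ctab_rec(tree, tree$root, sf, sp)
  nz <- which(dense > 0)
  keys_s <- matrix(0L, length(nz), length(sf))
  rem <- nz - 1
  for (j in seq_along(sf)) {
    keys_s[, j] <- as.integer(rem %% ar_s[j])
    rem <- rem %/% ar_s[j]
  }
  # restore the requested feature order
  back <- match(features, sf)
  contingency_table(features, keys_s[, back, drop = FALSE],
                    as.integer(dense[nz]), tree$root$count,
                    tree$ds$arities[features])
}

#' Node-count summary of an AD-tree
#'
#' Entry counts are the memory metric used throughout (byte sizes are
#' implementation-dependent).
#'
#' @param tree An `adtree`.
#' @return Named integer vector: `ad_nodes`, `vary_nodes`, `leaf_lists`.
#' @export
adtree_node_counts <- function(tree) {
  c(ad_nodes = tree$n_adnodes, vary_nodes = tree$n_varynodes,
    leaf_lists = tree$n_leaflists)
}

#' Serialize a static AD-tree to JSON
#'
#' Records the ordering, LLT and node structure (including Leaf-List row
#' indices) so a static tree can be reloaded without the dataset. Dynamic
#' trees are in-memory only, since they need the dataset regardless.
#'
#' @param tree A static `adtree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
adtree_write_json <- function(tree, path) {
  if (tree$mode != "static") stop("only static AD-trees are serializable")
  ser_node <- function(node) {
    vl <- lapply(ls(node$vary), function(k) {
      vn <- get(k, envir = node$vary)
      list(feature = vn$feature, mcv = vn$mcv,
           children = lapply(vn$children, function(ch)
             if (is.null(ch)) NULL else ser_node(ch)))
    })
    list(count = node$count, leaf = node$leaf,
         rows = if (node$leaf) node$rows else NULL, vary = vl)
  }
  obj <- list(ordering = tree$ordering, llt_percent = tree$llt_percent,
              N = tree$ds$N, arities = tree$ds$arities,
              root = ser_node(tree$root))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
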