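# Shared fixtures and independent oracles. Oracles here deliberately avoid
# the package's own code paths (row scans instead of tabulate-encoding, path
# enumeration instead of graph moralization, dense-array CMI instead of the
# entropy decomposition) so each test compares two independent routes.

# --- tiny canonical networks ------------------------------------------------

chain_bn <- function(p_a = 0.5, eps = 0.1) {
  # A -> B -> C, binary, with B and C strongly tied to their parent
  bayesian_network(
    nodes = c("A", "B", "C"), arities = c(2L, 2L, 2L),
    parents = list(A = character(0), B = "A", C = "B"),
    cpts = list(
      A = matrix(c(1 - p_a, p_a), 1),
      B = rbind(c(1 - eps, eps), c(eps, 1 - eps)),
      C = rbind(c(1 - eps, eps), c(eps, 1 - eps))))
}

collider_bn <- function(eps = 0.1) {
  # A -> C <- B; C is (noisy) XOR of A and B so both edges are strong
  xor_rows <- rbind(c(1 - eps, eps), c(eps, 1 - eps),
                    c(eps, 1 - eps), c(1 - eps, eps))
  bayesian_network(
    nodes = c("A", "B", "C"), arities = c(2L, 2L, 2L),
    parents = list(A = character(0), B = character(0), C = c("A", "B")),
    cpts = list(A = matrix(c(0.5, 0.5), 1), B = matrix(c(0.5, 0.5), 1),
                C = xor_rows))
}

# Five binary nodes with strong CPTs: X1 -> X3 <- X2, X3 -> X4, X1 -> X5.
# Blanket(X1) = {X3, X2, X5}; blanket(X3) = {X1, X2, X4}; used for
# finite-sample recovery where edges must be detectable at moderate n.
# The collider is noisy-OR (not XOR): each parent must stay marginally
# dependent on the child, or the faithfulness assumption constraint-based
# discovery needs would be violated.
strong5_bn <- function(eps = 0.1) {
  noisy_or <- rbind(c(0.9, 0.1), c(0.3, 0.7), c(0.3, 0.7), c(0.05, 0.95))
  flip <- rbind(c(1 - eps, eps), c(eps, 1 - eps))
  bayesian_network(
    nodes = paste0("X", 1:5), arities = rep(2L, 5),
    parents = list(X1 = character(0), X2 = character(0), X3 = c("X1", "X2"),
                   X4 = "X3", X5 = "X1"),
    cpts = list(X1 = matrix(c(0.5, 0.5), 1), X2 = matrix(c(0.5, 0.5), 1),
                X3 = noisy_or, X4 = flip, X5 = flip))
}

# --- counting oracles -------------------------------------------------------

# Row-scan count of samples matching feats = vals (both vectors), no encoding.
scan_count <- function(ds, feats, vals) {
  keep <- rep(TRUE, ds$N)
  for (j in seq_along(feats))
    keep <- keep & ds$values[, feats[j]] == vals[j]
  sum(keep)
}

# Independent contingency oracle: per-row paste keys, tallied with table().
scan_ctab <- function(ds, feats) {
  key <- apply(ds$values[, feats, drop = FALSE], 1, paste, collapse = "|")
  tab <- table(key)
  out <- lapply(names(tab), function(k)
    as.integer(strsplit(k, "|", fixed = TRUE)[[1]]))
  list(keys = do.call(rbind, out), counts = as.integer(tab))
}

# Compare a package ctab against the scan oracle, order-independently.
expect_ctab_matches_scan <- function(ct, ds, feats) {
  oracle <- scan_ctab(ds, feats)
  ck <- apply(ct$keys, 1, paste, collapse = "|")
  ok <- apply(oracle$keys, 1, paste, collapse = "|")
  expect_setequal(ck, ok)
  expect_equal(ct$counts[order(ck)], oracle$counts[order(ok)])
  expect_equal(sum(ct$counts), ds$N)
}

# --- d-separation oracle by path enumeration --------------------------------

# Enumerate all undirected simple paths x..y and apply the blocking rules
# directly (chain/fork blocked iff mid in z; collider blocked iff neither mid
# nor any descendant of mid is in z). Exponential; fine for <= 7 nodes.
dsep_paths <- function(bn, x, y, z) {
  edges <- list()
  for (v in bn$nodes) for (p in bn$parents[[v]])
    edges[[length(edges) + 1L]] <- c(p, v)
  nbr <- function(v) unique(unlist(lapply(edges, function(e)
    if (e[1] == v) e[2] else if (e[2] == v) e[1] else NULL)))
  desc <- function(v) {
    out <- character(0); frontier <- v
    while (length(frontier)) {
      ch <- unique(unlist(lapply(frontier, function(u)
        bn$nodes[vapply(bn$nodes, function(w) u %in% bn$parents[[w]],
                        logical(1))])))
      ch <- setdiff(ch, out)
      out <- c(out, ch); frontier <- ch
    }
    out
  }
  is_parent <- function(a, b) a %in% bn$parents[[b]]   # a -> b
  active_path <- function(path) {
    if (length(path) == 2L) return(TRUE)        # direct edge is never blocked
    for (i in 2:(length(path) - 1L)) {
      a <- path[i - 1L]; m <- path[i]; b <- path[i + 1L]
      if (is_parent(a, m) && is_parent(b, m)) { # collider at m
        if (!(m %in% z) && !any(desc(m) %in% z)) return(FALSE)
      } else {                                  # chain or fork
        if (m %in% z) return(FALSE)
      }
    }
    TRUE
  }
  found_active <- FALSE
  dfs <- function(path) {
    if (found_active) return()
    v <- path[length(path)]
    if (v == y) { if (active_path(path)) found_active <<- TRUE; return() }
    for (w in setdiff(nbr(v), path)) dfs(c(path, w))
  }
  dfs(x)
  !found_active
}

# --- direct CMI oracle (dense arrays, no entropy decomposition) -------------

cmi_direct <- function(ds, x, y, z) {
  N <- ds$N
  zkey <- if (length(z)) apply(ds$values[, z, drop = FALSE], 1, paste,
                               collapse = "|") else rep("", N)
  tot <- 0
  for (zk in unique(zkey)) {
    idx <- zkey == zk
    nz <- sum(idx)
    t_xy <- table(ds$values[idx, x], ds$values[idx, y])
    p_xy <- t_xy / nz
    p_x <- rowSums(p_xy); p_y <- colSums(p_xy)
    for (i in seq_len(nrow(p_xy))) for (j in seq_len(ncol(p_xy))) {
      if (p_xy[i, j] > 0)
        tot <- tot + (nz / N) * p_xy[i, j] *
          log(p_xy[i, j] / (p_x[i] * p_y[j]))
    }
  }
  unname(tot)
}

# Independent subset enumerator (recursive, no combn) for the reuse-factor
# enumeration so the oracle does not share code with the package.
subsets_of_size_oracle <- function(v, k) {
  if (k == 0) return(list(integer(0)))
  if (length(v) < k) return(list())
  with_first <- lapply(subsets_of_size_oracle(v[-1], k - 1),
                       function(s) c(v[1], s))
  c(with_first, subsets_of_size_oracle(v[-1], k))
}

# --- misc -------------------------------------------------------------------

# Named-list query helper for query_count: q(feat1, val1, feat2, val2, ...)
adq <- function(...) {
  a <- c(...)
  stats::setNames(as.list(as.integer(a[seq(2, length(a), 2)])),
                  as.character(as.integer(a[seq(1, length(a), 2)])))
}

random_ds <- function(n, arities, seed) {
  set.seed(seed)
  m <- length(arities)
  vals <- sapply(seq_len(m), function(j)
    sample.int(arities[j], n, replace = TRUE) - 1L)
  discrete_dataset(matrix(as.integer(vals), n, m), arities = arities)
}
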