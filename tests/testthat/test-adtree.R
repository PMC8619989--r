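# AD-trees: construction, MCV elision, Leaf-Lists, query and assembly
# exactness against brute-force row scans.

test_that("hand-built single-feature tree elides the most common value", {
  ds <- discrete_dataset(matrix(c(rep(0L, 3), rep(1L, 5)), ncol = 1))
  tr <- build_static_adtree(ds, llt_percent = 0)
  expect_equal(tr$root$count, 8L)
  vn <- get("1", envir = tr$root$vary)
  expect_equal(vn$mcv, 1L)                      # value 1 has count 5: elided
  expect_null(vn$children[[2]])
  expect_equal(vn$children[[1]]$count, 3L)      # value 0 materialized
  # queries recover both, the elided one by reconstruction
  expect_equal(query_count(tr, adq(1, 0)), 3L)
  expect_equal(query_count(tr, adq(1, 1)), 5L)
})

test_that("MCV ties break toward the smallest value index", {
  ds <- discrete_dataset(matrix(c(0L, 0L, 1L, 1L, 2L), ncol = 1))
  tr <- build_static_adtree(ds)
  vn <- get("1", envir = tr$root$vary)
  expect_equal(vn$mcv, 0L)
})

test_that("leaf-list threshold is strict and llt = 0 disables leaf-lists", {
  ds <- random_ds(200, c(2L, 3L, 2L), seed = 21)
  t0 <- build_static_adtree(ds, llt_percent = 0)
  expect_equal(unname(adtree_node_counts(t0)["leaf_lists"]), 0L)
  t10 <- build_static_adtree(ds, llt_percent = 10)   # threshold: count < 20
  expect_gt(unname(adtree_node_counts(t10)["leaf_lists"]), 0L)
  # rebuild determinism: identical structure stats and query answers
  t10b <- build_static_adtree(ds, llt_percent = 10)
  expect_identical(adtree_node_counts(t10), adtree_node_counts(t10b))
  expect_equal(query_count(t10, adq(1, 0, 2, 2)),
               query_count(t10b, adq(1, 0, 2, 2)))
})

test_that("every query equals a brute-force row scan (all llt, both modes)", {
  ds <- random_ds(200, c(2L, 3L, 2L, 3L), seed = 22)
  combos <- c(lapply(1:4, function(f) list(f)),
              utils::combn(4, 2, simplify = FALSE))
  for (llt in c(0, 5, 10)) {
    st <- build_static_adtree(ds, llt_percent = llt)
    dy <- build_dynamic_adtree(ds, llt_percent = llt)
    expect_equal(query_count(st, list()), ds$N)   # empty query is N
    for (fs in combos) {
      fs <- unlist(fs)
      grids <- expand.grid(lapply(ds$arities[fs], function(a) 0:(a - 1)))
      for (r in seq_len(nrow(grids))) {
        vals <- as.integer(grids[r, ])
        want <- scan_count(ds, fs, vals)
        q <- stats::setNames(as.list(vals), as.character(fs))
        expect_equal(query_count(st, q), want)
        expect_equal(query_count(dy, q), want)
      }
    }
  }
})

test_that("queries through elided branches equal parent minus siblings", {
  ds <- random_ds(150, c(3L, 2L), seed = 23)
  tr <- build_static_adtree(ds)
  vn <- get("1", envir = tr$root$vary)
  mcv <- vn$mcv
  others <- setdiff(0:2, mcv)
  recon <- query_count(tr, list()) -
    sum(vapply(others, function(v) query_count(tr, adq(1, v)), numeric(1)))
  expect_equal(query_count(tr, adq(1, mcv)), recon)
  expect_equal(recon, scan_count(ds, 1L, mcv))
})

test_that("sibling counts (including the reconstructed MCV) conserve totals", {
  ds <- random_ds(120, c(3L, 3L, 2L), seed = 24)
  tr <- build_static_adtree(ds)
  for (f in 1:3) {
    tot <- sum(vapply(0:(ds$arities[f] - 1), function(v)
      query_count(tr, adq(f, v)), numeric(1)))
    expect_equal(tot, ds$N)
  }
})

test_that("assembled contingency tables equal direct counting everywhere", {
  ds <- random_ds(500, c(2L, 3L, 2L, 4L), seed = 25)
  featsets <- list(1L, c(1L, 3L), c(2L, 4L), c(1L, 2L, 3L), c(4L, 2L, 1L))
  for (llt in c(0, 5, 10)) {
    st <- build_static_adtree(ds, llt_percent = llt)
    dy <- build_dynamic_adtree(ds, llt_percent = llt)
    for (fs in featsets) {
      want <- count_joint(ds, fs)
      for (tr in list(st, dy)) {
        got <- contingency_from_tree(tr, fs)
        expect_identical(got$features, want$features)
        kw <- apply(want$keys, 1, paste, collapse = ",")
        kg <- apply(got$keys, 1, paste, collapse = ",")
        expect_setequal(kg, kw)
        expect_equal(got$counts[order(kg)], want$counts[order(kw)])
      }
    }
  }
})

test_that("dynamic trees expand on demand, idempotently, and stay smaller", {
  ds <- random_ds(200, c(2L, 3L, 2L), seed = 26)
  dy <- build_dynamic_adtree(ds)
  expect_equal(unname(adtree_node_counts(dy)), c(1L, 0L, 0L))  # bare root
  q <- adq(1, 0, 2, 1)
  expand_dynamic(dy, q)
  after_first <- adtree_node_counts(dy)
  expect_gt(unname(after_first["vary_nodes"]), 0L)
  # hand trace: a Vary-node for feature 1 at the root, then one for feature 2
  # at every AD-node the descent (or MCV reconstruction) visits
  vn1 <- get("1", envir = dy$root$vary)
  nonelided <- sum(!vapply(vn1$children, is.null, logical(1)))
  expected_vary <- if (q[["1"]] == vn1$mcv) {
    1L + 1L + nonelided    # reconstruction recurses at the root and siblings
  } else {
    ch <- vn1$children[[q[["1"]] + 1L]]
    1L + as.integer(!is.null(ch))   # direct descent into the matching child
  }
  expect_equal(unname(after_first["vary_nodes"]), expected_vary)
  expand_dynamic(dy, q)                       # re-issue: no growth
  expect_identical(adtree_node_counts(dy), after_first)
  expect_error(expand_dynamic(build_static_adtree(ds), q), "dynamic")

  # after an exhaustive query set, dynamic answers equal static everywhere
  st <- build_static_adtree(ds)
  for (fs in list(1L, c(1L, 2L), c(2L, 3L), c(1L, 2L, 3L))) {
    grids <- expand.grid(lapply(ds$arities[fs], function(a) 0:(a - 1)))
    for (r in seq_len(nrow(grids))) {
      qq <- stats::setNames(as.list(as.integer(grids[r, ])),
                            as.character(fs))
      expect_equal(query_count(dy, qq), query_count(st, qq))
    }
  }
  cs <- adtree_node_counts(st); cd <- adtree_node_counts(dy)
  expect_lte(cd["ad_nodes"], cs["ad_nodes"])
  expect_lte(cd["vary_nodes"], cs["vary_nodes"])
})

test_that("trees honor a custom feature ordering and re-sort queries", {
  ds <- random_ds(100, c(2L, 3L, 2L), seed = 27)
  tr <- build_static_adtree(ds, ordering = c(3L, 1L, 2L))
  for (fs in list(c(1L, 2L), c(2L, 3L), c(1L, 2L, 3L))) {
    want <- count_joint(ds, fs)
    got <- contingency_from_tree(tr, fs)
    kw <- apply(want$keys, 1, paste, collapse = ",")
    kg <- apply(got$keys, 1, paste, collapse = ",")
    expect_setequal(kg, kw)
    expect_equal(got$counts[order(kg)], want$counts[order(kw)])
  }
  expect_equal(query_count(tr, adq(2, 1, 1, 0)),
               scan_count(ds, c(2L, 1L), c(1L, 0L)))
})

test_that("static trees serialize to JSON", {
  ds <- random_ds(50, c(2L, 2L), seed = 28)
  tr <- build_static_adtree(ds, llt_percent = 10)
  f <- withr::local_tempfile(fileext = ".json")
  adtree_write_json(tr, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$N, 50L)
  expect_equal(obj$root$count, 50L)
  expect_equal(obj$llt_percent, 10)
  expect_error(adtree_write_json(build_dynamic_adtree(ds), f), "static")
})
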