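# The entropy-decomposition engine: JHT, DoF cache, exactness, reuse.

test_that("joint entropy matches hand evaluations", {
  two <- contingency_table(1L, rbind(0L, 1L), c(5L, 5L), 10L, 2L)
  expect_equal(joint_entropy(two), log(2), tolerance = 1e-12)
  point <- contingency_table(1L, matrix(0L, 1, 1), 4L, 4L, 2L)
  expect_equal(joint_entropy(point), 0)
  three <- contingency_table(1L, rbind(0L, 1L, 2L), c(1L, 1L, 2L), 4L, 3L)
  expect_equal(joint_entropy(three), 0.25 * log(4) + 0.25 * log(4) +
                 0.5 * log(2), tolerance = 1e-12)
  expect_error(joint_entropy(contingency_table(1L, matrix(0L, 0, 1),
                                               integer(0), 0L, 2L)), "empty")
})

test_that("the four-term decomposition equals the direct CMI definition", {
  expect_equal(cmi_decomposed(0, 0, 0, 0), 0)
  for (seed in 1:8) {
    ds <- random_ds(90, c(2L, 3L, 2L), seed = 300 + seed)
    h <- function(s) joint_entropy(count_joint(ds, s))
    got <- cmi_decomposed(h(c(1, 3)), h(c(2, 3)), h(c(1, 2, 3)), h(3))
    expect_equal(got, cmi_direct(ds, 1, 2, 3L), tolerance = 1e-9)
    # unconditional case: H(Z) = 0 by convention
    got0 <- cmi_decomposed(h(1), h(2), h(c(1, 2)), 0)
    expect_equal(got0, cmi_direct(ds, 1, 2, integer(0)), tolerance = 1e-9)
  }
  # independence limit: empirical CMI of independent columns is near 0
  set.seed(41)
  ds <- random_ds(5000, c(2L, 2L), seed = 41)
  h <- function(s) joint_entropy(count_joint(ds, s))
  expect_lt(cmi_decomposed(h(1), h(2), h(c(1, 2)), 0), 0.002)
})

test_that("JHT lookups miss once, then hit, and keys are order-free", {
  ds <- random_ds(50, c(2L, 3L, 2L), seed = 1)
  jht <- new_jht()
  v1 <- get_or_compute_term(jht, ds, c(1L, 2L))
  expect_equal(jht$misses, 1L); expect_equal(jht$hits, 0L)
  v2 <- get_or_compute_term(jht, ds, c(2L, 1L))   # permuted query, same set
  expect_equal(jht$misses, 1L); expect_equal(jht$hits, 1L)
  expect_identical(v1, v2)
  expect_equal(length(ls(jht$entries)), 1L)
  # empty set: H() = 0, no cache traffic
  expect_equal(get_or_compute_term(jht, ds, integer(0)), 0)
  expect_equal(jht$hits + jht$misses, 2L)
  # stored value equals a from-scratch recomputation
  expect_equal(v1, joint_entropy(count_joint(ds, c(1, 2))), tolerance = 1e-12)
})

test_that("stored entropies respect the uniform upper bound", {
  for (seed in 1:5) {
    ds <- random_ds(40, c(2L, 3L, 4L), seed = 320 + seed)
    jht <- new_jht()
    for (s in list(1L, c(1L, 2L), c(2L, 3L), c(1L, 2L, 3L))) {
      h <- get_or_compute_term(jht, ds, s)
      expect_gte(h, 0)
      expect_lte(h, log(prod(ds$arities[s])) + 1e-9)
    }
  }
})

test_that("a term miss fills the DoF cache for all pairs given the rest", {
  ds <- random_ds(100, c(2L, 2L, 3L), seed = 2)
  jht <- new_jht(); dc <- new_dof_cache()
  get_or_compute_term(jht, ds, c(1L, 2L, 3L), dc)
  keys <- sort(ls(dc$entries))
  expect_setequal(keys, c("1,2|3", "1,3|2", "2,3|1"))
  # each cached value equals a from-scratch recomputation on the data
  ct <- count_joint(ds, c(1, 2, 3))
  expect_equal(get("1,2|3", envir = dc$entries),
               degrees_of_freedom(ct, 1, 2, 3))
  expect_equal(get("1,3|2", envir = dc$entries),
               degrees_of_freedom(ct, 1, 3, 2))
  expect_equal(get("2,3|1", envir = dc$entries),
               degrees_of_freedom(ct, 2, 3, 1))
})

test_that("dcMI G-tests equal the canonical backend exactly", {
  for (seed in 1:5) {
    m <- sample(3:6, 1)
    ds <- random_ds(150, sample(2:3, m, replace = TRUE), seed = 330 + seed)
    jht <- new_jht(); dc <- new_dof_cache()
    for (rep in 1:20) {
      xy <- sample(m, 2)
      rest <- setdiff(seq_len(m), xy)
      z <- rest[stats::runif(length(rest)) < 0.5]
      a <- g_test_dcmi(ds, xy[1], xy[2], z, jht, dc)
      ct <- count_joint(ds, sort(c(xy, z)))
      b <- ci_test_from_counts(ct, xy[1], xy[2], z)
      expect_equal(a$g, b$g, tolerance = 1e-9)
      expect_identical(a$dof, b$dof)
      expect_identical(a$independent, b$independent)
    }
  }
})

test_that("an unconditional dcMI test performs exactly three lookups", {
  ds <- random_ds(80, c(2L, 2L, 2L), seed = 3)
  jht <- new_jht(); dc <- new_dof_cache()
  g_test_dcmi(ds, 1, 2, integer(0), jht, dc)
  expect_equal(jht$hits + jht$misses, 3L)
  expect_setequal(ls(jht$entries), c("1", "2", "1,2"))
})

test_that("term reuse across a test sequence matches a hand trace", {
  ds <- random_ds(60, c(2L, 2L, 2L), seed = 4)
  jht <- new_jht(); dc <- new_dof_cache()
  g_test_dcmi(ds, 1, 2, integer(0), jht, dc)  # terms {1},{2},{1,2}
  g_test_dcmi(ds, 1, 3, 2L, jht, dc)          # {1,2}h,{2,3},{1,2,3},{2}h
  g_test_dcmi(ds, 2, 3, 1L, jht, dc)          # {1,2}h,{1,3},{1,2,3}h,{1}h
  expect_equal(jht$hits + jht$misses, 11L)
  expect_equal(jht$misses, 6L)                # distinct non-empty term sets
  expect_equal(jht$hits, 5L)
  expect_lt(jht$misses, 4 * 3)
  # DoF for the third test was pre-filled by the {1,2,3} miss in test two
  expect_true("2,3|1" %in% ls(dc$entries))
})

test_that("hit rate is hits over lookups, with an enumeration cross-check", {
  jht <- new_jht()
  jht$hits <- 97L; jht$misses <- 3L
  expect_equal(hit_rate(jht), 0.97)
  expect_error(hit_rate(new_jht()), "no lookups")
  fresh <- new_jht()
  get_or_compute_term(fresh, random_ds(10, c(2L, 2L), seed = 5), c(1L, 2L))
  expect_equal(hit_rate(fresh), 0)

  # exhaustive unconditional pair tests over 6 features: the rate must equal
  # 1 - distinct/lookups where both counts come from explicit enumeration
  ds <- random_ds(100, rep(2L, 6), seed = 6)
  jht <- new_jht(); dc <- new_dof_cache()
  lookups <- 0L
  seen <- character(0)
  for (pr in utils::combn(6, 2, simplify = FALSE)) {
    g_test_dcmi(ds, pr[1], pr[2], integer(0), jht, dc)
    lookups <- lookups + 3L
    seen <- union(seen, c(paste(pr[1]), paste(pr[2]),
                          paste(sort(pr), collapse = ",")))
  }
  expect_equal(hit_rate(jht), 1 - length(seen) / lookups)
})

test_that("the exhaustive reuse factor follows the combinatorial identity", {
  for (m in 4:8) {
    canonical <- 0
    terms <- new.env(parent = emptyenv())
    for (pr in utils::combn(m, 2, simplify = FALSE)) {
      rest <- setdiff(seq_len(m), pr)
      for (k in 0:length(rest)) for (z in utils::combn(rest, k,
                                                       simplify = FALSE)) {
        canonical <- canonical + 4   # P(xyz), P(xz), P(yz), P(z) per test
        for (s in list(c(pr[1], z), c(pr[2], z), c(pr, z), z))
          if (length(s)) assign(paste(sort(s), collapse = ","), TRUE,
                                envir = terms)
      }
    }
    distinct <- length(ls(terms))
    expect_equal(distinct, 2^m - 1)   # every non-empty subset arises
    expect_equal(canonical, m * (m - 1) * 2^(m - 1))
    expect_equal(canonical / distinct,
                 m * (m - 1) * 2^(m - 1) / (2^m - 1))
  }
  # the ratio approaches M(M-1)/2 as M grows
  ratio <- function(m) m * (m - 1) * 2^(m - 1) / (2^m - 1)
  expect_lt(abs(ratio(8) / (8 * 7 / 2) - 1), 0.01)
})

test_that("caches serialize to JSON and back without loss", {
  ds <- random_ds(70, c(2L, 3L), seed = 7)
  jht <- new_jht(); dc <- new_dof_cache()
  g_test_dcmi(ds, 1, 2, integer(0), jht, dc)
  jf <- withr::local_tempfile(fileext = ".json")
  df <- withr::local_tempfile(fileext = ".json")
  cache_write_json(jht, jf)
  cache_write_json(dc, df)
  jht2 <- cache_read_json(jf)
  dc2 <- cache_read_json(df)
  expect_equal(jht2$hits, jht$hits)
  expect_equal(jht2$misses, jht$misses)
  expect_setequal(ls(jht2$entries), ls(jht$entries))
  for (k in ls(jht$entries))
    expect_equal(get(k, envir = jht2$entries), get(k, envir = jht$entries))
  expect_setequal(ls(dc2$entries), ls(dc$entries))
  # a reloaded JHT keeps serving hits
  get_or_compute_term(jht2, ds, c(2L, 1L))
  expect_equal(jht2$hits, jht$hits + 1L)
})

test_that("sharing the JHT across runs strictly reduces misses", {
  bn <- strong5_bn()
  ds <- sample_network(bn, 1500, seed = 8)
  cfg <- ci_test_config(backend = "dcmi")
  shared <- ci_engine(ds, cfg)
  t1 <- data_tester(shared)
  find_mb(1, t1, ds$M)
  misses_before <- shared$jht$misses
  t2 <- data_tester(shared)
  find_mb(2, t2, ds$M)
  shared_second_misses <- shared$jht$misses - misses_before

  fresh <- ci_engine(ds, cfg)
  t3 <- data_tester(fresh)
  find_mb(2, t3, ds$M)
  expect_lt(shared_second_misses, fresh$jht$misses)
})
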