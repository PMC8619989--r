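# IPC-MB: recognition, symmetry, spouses, full blanket discovery.

test_that("recognition separates chain and collider structures correctly", {
  ch <- chain_bn()                      # A -> B -> C, indices 1,2,3
  t1 <- dsep_tester(ch)
  r <- recognize_pc(1L, c(2L, 3L), t1)
  expect_equal(r$pc, 2L)
  expect_equal(r$sepsets[["3"]], 2L)    # C separated from A by {B}

  co <- collider_bn()                   # A -> C <- B
  t2 <- dsep_tester(co)
  r2 <- recognize_pc(1L, c(2L, 3L), t2)
  expect_true(3L %in% r2$pc)            # the child C survives
  expect_equal(r2$sepsets[["2"]], integer(0))  # B removed unconditionally
})

test_that("recognition terminates without removals under full dependence", {
  # saturated dependence: every pair dependent given everything
  deny <- new.env(parent = emptyenv())
  deny$n_tests <- 0L
  deny$is_indep <- function(x, y, z) {
    deny$n_tests <- deny$n_tests + 1L
    FALSE
  }
  r <- recognize_pc(1L, c(2L, 3L), deny)
  expect_equal(r$pc, c(2L, 3L))
  expect_gt(deny$n_tests, 0L)
})

test_that("conditioning-set sizes submitted to the tester never decrease", {
  bn <- random_network(7, max_parents = 3, seed = 31)
  t <- dsep_tester(bn, record_trace = TRUE)
  recognize_pc(1L, 2:7, t)
  sizes <- vapply(t$trace, function(e) length(e$z), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("find_pc applies the symmetry check and is itself symmetric", {
  ch <- chain_bn()
  expect_equal(find_pc(2L, 3L, dsep_tester(ch))$pc, c(1L, 3L))
  expect_equal(find_pc(1L, 3L, dsep_tester(ch))$pc, 2L)

  for (seed in 1:6) {
    bn <- random_network(sample(5:7, 1), max_parents = 3, seed = 800 + seed)
    m <- length(bn$nodes)
    t <- dsep_tester(bn)
    pcs <- lapply(seq_len(m), function(i) find_pc(i, m, t)$pc)
    for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
      expect_equal(j %in% pcs[[i]], i %in% pcs[[j]])
    # with an oracle, PC equals true graph adjacency
    for (i in seq_len(m)) {
      truth <- true_markov_blanket(bn, bn$nodes[i])
      adj <- sort(match(c(truth$parents, truth$children), bn$nodes))
      expect_equal(pcs[[i]], adj,
                   info = sprintf("seed %d node %d", seed, i))
    }
  }
})

test_that("spouse discovery finds colliders and nothing else", {
  co <- collider_bn()
  t <- dsep_tester(co)
  fp <- find_pc(1L, 3L, t)
  expect_equal(fp$pc, 3L)
  sp <- find_spouses(1L, fp$pc, 3L, t, fp$sepsets)
  expect_equal(sp, 2L)

  ch <- chain_bn()
  t2 <- dsep_tester(ch)
  fp2 <- find_pc(2L, 3L, t2)
  expect_equal(find_spouses(2L, fp2$pc, 3L, t2, fp2$sepsets), integer(0))
})

test_that("full blanket discovery matches graph truth on canonical networks", {
  ch <- chain_bn()
  expect_equal(find_mb(2L, dsep_tester(ch), 3L)$mb, c(1L, 3L))
  expect_equal(find_mb(1L, dsep_tester(ch), 3L)$mb, 2L)
  co <- collider_bn()
  res <- find_mb(1L, dsep_tester(co), 3L)
  expect_equal(res$mb, c(2L, 3L))
  expect_equal(res$pc, 3L)
  expect_equal(res$sp, 2L)
  expect_gt(res$ci_tests_performed, 0L)
})

test_that("oracle blanket recovery is exact on random 6-8 node networks", {
  for (seed in 1:25) {
    m <- 6L + (seed %% 3L)
    bn <- random_network(m, max_parents = 3, seed = 900 + seed)
    t <- dsep_tester(bn)
    for (i in seq_len(m)) {
      truth <- sort(match(true_markov_blanket(bn, bn$nodes[i])$blanket,
                          bn$nodes))
      got <- find_mb(i, t, m)
      expect_equal(got$mb, truth,
                   info = sprintf("seed %d target %d", seed, i))
      expect_true(!(i %in% got$mb))
      expect_equal(got$mb, sort(union(got$pc, got$sp)))
      expect_equal(length(intersect(got$pc, got$sp)), 0L)
    }
  }
})

test_that("single-candidate and degenerate inputs behave", {
  bn <- bayesian_network("A", 2L, list(A = character(0)),
                         list(A = matrix(c(0.5, 0.5), 1)))
  res <- find_mb(1L, dsep_tester(bn), 1L)
  expect_equal(res$mb, integer(0))
  expect_equal(res$ci_tests_performed, 0L)
})

test_that("finite-sample recovery on a strong 5-node network (dcMI backend)", {
  bn <- strong5_bn()
  truth <- lapply(bn$nodes, function(v)
    sort(match(true_markov_blanket(bn, v)$blanket, bn$nodes)))
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    ds <- sample_network(bn, 20000, seed = 1000 + seed)
    engine <- ci_engine(ds, ci_test_config(backend = "dcmi"))
    target <- (seed - 1L) %% 5L + 1L
    res <- find_mb(target, data_tester(engine), 5L)
    total <- total + 1L
    if (identical(res$mb, truth[[target]])) hits <- hits + 1L
  }
  expect_gte(hits / total, 0.9)
})

test_that("the ipcmb() interface resolves names and reports structures", {
  bn <- strong5_bn()
  ds <- sample_network(bn, 5000, seed = 55)
  fit <- ipcmb(ds, target = "X3", backend = "dcmi")
  expect_s3_class(fit, "ipcmb")
  expect_equal(fit$target, "X3")
  expect_setequal(fit$blanket, c("X1", "X2", "X4"))
  expect_gt(fit$ci_tests, 0L)
  expect_true(fit$jht_hit_rate > 0 && fit$jht_hit_rate < 1)
  expect_output(print(fit), "blanket")
  expect_output(summary(fit), "spouses")

  # oracle mode straight from the network
  ofit <- ipcmb(bn, target = "X1")
  expect_setequal(ofit$blanket, c("X2", "X3", "X5"))

  # JSON record round-trip
  f <- withr::local_tempfile(fileext = ".json")
  write_mb_json(fit, f)
  rec <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rec$target, "X3")
  expect_setequal(rec$blanket, c("X1", "X2", "X4"))
})
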