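test_that("contingency tables tally joint memberships with consistent marginals", {
  t1 <- contingency_table(make_partition(c(0, 0, 1, 1)),
                          make_partition(c(0, 1, 0, 1)))
  expect_equal(unname(t1$counts), matrix(1, 2, 2))
  expect_equal(unname(t1$a), c(2, 2))
  expect_equal(unname(t1$b), c(2, 2))
  expect_identical(t1$n, 4L)

  p <- make_partition(c(0, 0, 1, 1))
  expect_equal(unname(contingency_table(p, p)$counts),
               matrix(c(2, 0, 0, 2), 2, 2))

  t3 <- contingency_table(make_partition(c(0, 0, 0, 1, 1, 2)),
                          make_partition(c(0, 0, 1, 1, 2, 2)))
  expect_equal(unname(t3$counts),
               matrix(c(2, 1, 0, 0, 1, 1, 0, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(unname(t3$a), c(3, 2, 1))
  expect_equal(unname(t3$b), c(2, 2, 2))
  expect_equal(sum(t3$counts), t3$n)

  expect_error(contingency_table(make_partition(c(0, 1)),
                                 make_partition(c(0, 1, 0))),
               "sample counts")
})

test_that("worked ARI values match the closed form and the pair oracle", {
  cross_x <- make_partition(c(0, 0, 1, 1))
  cross_y <- make_partition(c(0, 1, 0, 1))
  expect_equal(ari_from_table(contingency_table(cross_x, cross_y)), -0.5)
  expect_equal(ari_pair_oracle(cross_x, cross_y), -0.5)

  p3 <- make_partition(c(0, 0, 0, 1, 1, 2))
  p4 <- make_partition(c(0, 0, 1, 1, 2, 2))
  # (1 - 0.8) / (3.5 - 0.8)
  expect_equal(ari_from_table(contingency_table(p3, p4)), 0.2 / 2.7)
  expect_equal(ari_pair_oracle(p3, p4), 0.2 / 2.7)

  expect_equal(ari_from_table(contingency_table(p3, p3)), 1)
  expect_equal(ari_pair_oracle(p3, p3), 1)
})

test_that("closed-form ARI equals the brute-force oracle on every partition pair of 6 samples", {
  parts <- enumerate_set_partitions(6, 3)
  expect_length(parts, 122L)  # S(6,1) + S(6,2) + S(6,3)
  nondeg <- Filter(function(l) length(unique(l)) >= 2, parts)
  worst <- 0
  for (lp in parts) {
    p <- make_partition(lp)
    for (lq in parts) {
      q <- make_partition(lq)
      a1 <- ari_from_table(contingency_table(p, q))
      a2 <- ari_pair_oracle(p, q)
      worst <- max(worst, abs(a1 - a2))
      expect_true(a1 <= 1 + 1e-12)
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("ARI is symmetric, relabeling-invariant, and 1 on identical partitions", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(8:40, 1)
    p <- make_partition(sample(0:3, n, replace = TRUE))
    q <- make_partition(sample(0:2, n, replace = TRUE))
    if (p$degenerate || q$degenerate) next
    a_pq <- ari_from_table(contingency_table(p, q))
    expect_identical(a_pq, ari_from_table(contingency_table(q, p)))
    # permute q's cluster ids
    perm <- sample(seq_len(q$k)) - 1L
    q2 <- make_partition(perm[q$labels + 1L])
    expect_equal(ari_from_table(contingency_table(p, q2)), a_pq)
    expect_equal(ari_from_table(contingency_table(p, p)), 1)
  }
})

test_that("ARI has mean approximately 0 under random label shuffles", {
  set.seed(31)
  p <- make_partition(sample(0:3, 200, replace = TRUE))
  aris <- replicate(1000, {
    q <- make_partition(sample(p$labels))
    ari_from_table(contingency_table(p, q))
  })
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("batch plans cover the task stream within the memory budget", {
  pl <- plan_batches(100, 100, 1000)
  expect_equal(nrow(pl$boundaries), 10)
  expect_true(all(pl$boundaries[, "end"] - pl$boundaries[, "start"] == 10))

  pl2 <- plan_batches(7, 100, 300)
  expect_equal(pl2$boundaries[, "end"] - pl2$boundaries[, "start"], c(3, 3, 1))

  # budget below one task's footprint degrades to single-task batches
  pl3 <- plan_batches(5, 1000, 1)
  expect_equal(nrow(pl3$boundaries), 5)

  # conservation: contiguous, disjoint, covering
  for (pl in list(pl, pl2, pl3)) {
    b <- pl$boundaries
    expect_equal(unname(b[1, "start"]), 0)
    if (nrow(b) > 1)
      expect_equal(unname(b[-1, "start"]), unname(b[-nrow(b), "end"]))
  }
  expect_equal(nrow(plan_batches(0, 8, 64)$boundaries), 0)
  expect_error(plan_batches(10, 0, 100), ">= 1")
})

test_that("execute_tasks max-reduces deterministically with first-index tie-breaking", {
  ps <- lapply(list(stats::rnorm(40), stats::rnorm(40)), function(v)
    build_partition_set(feature_vector(v), 2:5))
  pairs <- matrix(c(1L, 2L), ncol = 2)

  res1 <- execute_tasks(ps, pairs, engine_config())
  # self pair: max 1 at the first combination
  self <- execute_tasks(list(ps[[1]], ps[[1]]), pairs, engine_config())
  expect_equal(self$max_ari, 1)
  expect_identical(self$argmax_x, 1L)
  expect_identical(self$argmax_y, 1L)

  # invariance to workers, budget, and backend
  for (cfg in list(engine_config(budget_bytes = 1),
                   engine_config(workers = 4),
                   engine_config(backend = "reference"),
                   engine_config(budget_bytes = 1, workers = 4,
                                 backend = "reference"))) {
    res2 <- execute_tasks(ps, pairs, cfg)
    expect_identical(res2$max_ari, res1$max_ari)
    expect_identical(res2$argmax_x, res1$argmax_x)
    expect_identical(res2$argmax_y, res1$argmax_y)
  }

  # raw maximum is not clamped at zero
  pneg <- list(
    structure(list(feature_id = "a",
                   partitions = list(make_partition(c(0, 0, 1, 1))),
                   n_effective = 4L), class = "ccc_partition_set"),
    structure(list(feature_id = "b",
                   partitions = list(make_partition(c(0, 1, 0, 1))),
                   n_effective = 4L), class = "ccc_partition_set"))
  expect_equal(execute_tasks(pneg, pairs, engine_config())$max_ari, -0.5)

  # empty partition set: degenerate, not computed
  pempty <- list(
    structure(list(feature_id = "a", partitions = list(), n_effective = 4L),
              class = "ccc_partition_set"),
    pneg[[2]])
  out <- execute_tasks(pempty, pairs, engine_config())
  expect_true(out$degenerate)
  expect_true(is.na(out$max_ari))
})

test_that("the two backends agree bit-for-bit on a random workload", {
  set.seed(5)
  ps <- lapply(1:4, function(i)
    build_partition_set(feature_vector(stats::rnorm(30)), 2:6))
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L))
  a <- execute_tasks(ps, pairs, engine_config(backend = "vectorized"))
  b <- execute_tasks(ps, pairs, engine_config(backend = "reference"))
  expect_identical(a$max_ari, b$max_ari)
  expect_identical(a$argmax_x, b$argmax_x)
})
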