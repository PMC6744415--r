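test_that("single-move deltas are reversible and match full recomputation", {
  for (s in 1:3) {
    G <- rand_graph(15, seed = s + 30)
    g <- rand_partition(G, B = 3, seed = s)
    sp <- flat_prior(G, 0.6)
    l0 <- rsbm_loglik(G, g, sp)$log_likelihood
    set.seed(s)
    for (rep in 1:30) {
      v <- sample(G$nodes, 1)
      b <- sample(seq_len(3)[-unclass(g)[v]], 1)
      d <- delta_log_likelihood(G, g, sp, node = v, new_block = b)
      g2v <- unclass(g); g2v[v] <- b
      g2 <- as_partition(g2v, B = 3)
      full <- rsbm_loglik(G, g2, sp)$log_likelihood - l0
      expect_equal(d, full, tolerance = 1e-9)
      # move back cancels exactly
      d_back <- delta_log_likelihood(G, g2, sp, node = v,
                                     new_block = unclass(g)[v])
      expect_lt(abs(d + d_back), 1e-8)
    }
  }
})

test_that("a move into an impossible configuration returns -Inf", {
  G <- multigraph(c("a", "b", "c"), c("b", "c", "a"))
  g <- as_partition(c(a = 1, b = 1, c = 1), B = 2)
  sp <- prior_spec("rsbm_pernode", f_pernode = c(a = 1, b = 0.5, c = 0.5))
  expect_identical(
    delta_log_likelihood(G, g, sp, node = "b", new_block = 2), -Inf)
})

test_that("greedy chains are monotone and deterministic given the seed", {
  G <- rand_graph(18, seed = 77)
  sp <- flat_prior(G, 0.6)
  tr <- mcmc_run(G, sp, B = 2, steps = 800, seed = 5, mode = "greedy",
                 record_every = 1)
  ll <- tr$records$log_likelihood
  expect_true(all(diff(ll) >= 0))
  expect_equal(tr$log_likelihood, max(ll))
  expect_equal(unclass(tr$final_partition), unclass(tr$best_partition),
               ignore_attr = TRUE)

  tr2 <- mcmc_run(G, sp, B = 2, steps = 800, seed = 5, mode = "greedy",
                  record_every = 1)
  expect_identical(tr$records, tr2$records)
  expect_identical(unclass(tr$partition), unclass(tr2$partition))
})

test_that("RSBM at f = 1/2 makes the same decisions as the DCSBM chain", {
  G <- rand_graph(16, seed = 9)
  half <- prior_spec("rsbm_pernode",
                     f_pernode = stats::setNames(rep(0.5, G$n), G$nodes))
  for (mode in c("greedy", "sample")) {
    t1 <- mcmc_run(G, half, B = 2, steps = 600, seed = 31, mode = mode)
    t2 <- mcmc_run(G, prior_spec("degree_corrected"), B = 2, steps = 600,
                   seed = 31, mode = mode)
    expect_identical(unclass(t1$partition), unclass(t2$partition))
    expect_equal(t1$acceptance_rate, t2$acceptance_rate)
    # recorded trajectories differ only by a partition-independent constant
    d1 <- diff(t1$records$log_likelihood)
    d2 <- diff(t2$records$log_likelihood)
    expect_equal(d1, d2, tolerance = 1e-8)
  }
})

test_that("chains never empty a block when forbidden", {
  G <- rand_graph(10, seed = 41)
  tr <- mcmc_run(G, flat_prior(G), B = 3, steps = 500, seed = 1,
                 mode = "sample")
  expect_equal(length(unique(unclass(tr$final_partition))), 3)
})

test_that("multi_restart with one restart equals a single chain", {
  G <- rand_graph(12, seed = 55)
  sp <- flat_prior(G, 0.6)
  mr <- multi_restart(G, sp, B = 2, restarts = 1, steps = 400, seed = 17)
  single <- mcmc_run(G, sp, B = 2, steps = 400, seed = 17)
  expect_identical(unclass(mr$traces[[1]]$partition), unclass(single$partition))
})

test_that("constraint groups keep forced co-assignments together", {
  # star + leaf cluster: leaves have degree one, so under the floor prior
  # they can never sit apart from the hub in a feasible partition
  G <- multigraph(c("h", "h", "h", "x", "x", "y"),
                  c("l1", "l2", "l3", "y", "h", "x"))
  sp <- prior_spec("rsbm_floor", f = 0.8)
  tr <- mcmc_run(G, sp, B = 2, steps = 300, seed = 2, mode = "sample")
  g <- unclass(tr$final_partition)
  expect_true(all(g[c("l1", "l2", "l3")] == g[["h"]]))
  expect_true(is.finite(tr$log_likelihood))
})

test_that("exhaustive enumeration matches direct brute force", {
  G <- rand_graph(8, seed = 66)
  sp <- flat_prior(G, 0.65)
  ex <- exhaustive_search(G, sp)
  expect_equal(rsbm_loglik(G, ex$partition, sp)$log_likelihood,
               ex$log_likelihood, tolerance = 1e-10)
  best <- -Inf
  for (code in 1:(2^(G$n - 1) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(G$n)]
    g <- as_partition(stats::setNames(bits + 1L, G$nodes), B = 2)
    best <- max(best, rsbm_loglik(G, g, sp)$log_likelihood)
  }
  expect_equal(ex$log_likelihood, best, tolerance = 1e-10)
})

test_that("MCMC is bounded by and reaches the exhaustive optimum on the benchmark", {
  b <- sample_dcsbm(seed = 23)
  sp <- prior_spec("rsbm_floor", f = 0.8)
  ex <- exhaustive_search(b$graph, sp)
  mr <- multi_restart(b$graph, sp, B = 2, restarts = 5, steps = 2000,
                      refine_steps = 300, refine_from = "best", seed = 3)
  best <- max(vapply(mr$traces, `[[`, 0, "log_likelihood"))
  expect_lte(best, ex$log_likelihood + 1e-9)
  expect_equal(best, ex$log_likelihood, tolerance = 1e-9)
})

test_that("f_sweep is reproducible and a length-one grid is a single run", {
  b <- sample_dcsbm(seed = 23)
  sw1 <- f_sweep(b$graph, 0.8, B = 2, steps = 600, seed = 12, refine_steps = 200)
  sw2 <- f_sweep(b$graph, 0.8, B = 2, steps = 600, seed = 12, refine_steps = 200)
  expect_identical(sw1$table, sw2$table)
  single <- mcmc_run(b$graph, prior_spec("rsbm_floor", f = 0.8), B = 2,
                     steps = 600, refine_steps = 200, seed = 12, mode = "sample")
  expect_identical(unclass(sw1$partitions[[1]]), unclass(single$partition))
  expect_error(f_sweep(b$graph, c(0.5, 0.3)), "increasing")
})
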