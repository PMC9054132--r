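# Division mechanics, viability, population dynamics and determinism.

test_that("division without mis-segregation clones the parent", {
  parent <- rep(2L, 46L)
  d <- divide_with_missegregation(parent, 0, 0)
  expect_identical(d$daughter_a, parent)
  expect_identical(d$daughter_b, parent)
  expect_identical(d$n_misseg_events, 0L)
})

test_that("division conserves material arm-wise over random parents and rates", {
  set.seed(21)
  for (i in 1:2000) {
    parent <- random_karyotype()
    d <- divide_with_missegregation(parent, runif(1, 0, 0.6), runif(1))
    expect_true(all(d$daughter_a + d$daughter_b == 2L * parent))
    expect_true(all(d$daughter_a >= 0L), info = "no negative copies")
  }
})

test_that("mis-segregation count is Binomial(copies, p): printed conversions and Monte Carlo", {
  # expected events per division = p x chromosome copies
  expect_equal(0.05 * 46, 2.3)
  expect_equal(0.02 * 92, 1.84)
  expect_equal(0.001 * 46, 0.046)
  set.seed(31)
  n <- 1e4
  dip <- vapply(seq_len(n), function(i)
    divide_with_missegregation(rep(2L, 46L), 0.05, 0)$n_misseg_events,
    integer(1))
  se <- sqrt(46 * 0.05 * 0.95 / n)
  expect_lt(abs(mean(dip) - 2.3), 3 * se)
  tet <- vapply(seq_len(n), function(i)
    divide_with_missegregation(rep(4L, 46L), 0.01, 0)$n_misseg_events,
    integer(1))
  # tetraploid at p = 0.01 matches diploid at p = 0.02: 0.92 events/division
  se_t <- sqrt(92 * 0.01 * 0.99 / n)
  expect_lt(abs(mean(tet) - 0.92), 3 * se_t)
})

test_that("breakage transfers a single arm; whole-chromosome events move both", {
  set.seed(41)
  # p_break = 1: every event is an arm-level reciprocal alteration
  arm_deltas <- replicate(500, {
    d <- divide_with_missegregation(rep(2L, 46L), 0.1, 1)
    delta <- abs(d$daughter_a - 2L)
    c(sum(delta), d$n_misseg_events, d$n_break_events)
  })
  expect_true(all(arm_deltas[3, ] == arm_deltas[2, ]))  # every event broke
  # p_break = 0: arms of a chromosome always move together
  for (i in 1:200) {
    d <- divide_with_missegregation(rep(2L, 46L), 0.2, 0)
    delta <- d$daughter_a - 2L
    expect_identical(delta[seq(1, 45, 2)], delta[seq(2, 46, 2)])
  }
})

test_that("viability bounds are nullisomy and more than six copies", {
  expect_true(check_viability(rep(2L, 46L)))
  k <- rep(2L, 46L); k[10L] <- 0L
  expect_false(check_viability(k))
  k <- rep(2L, 46L); k[10L] <- 7L
  expect_false(check_viability(k))
  expect_true(check_viability(rep(6L, 46L)))
  expect_false(check_viability(rep(2L, 46L), copy_min = 3L))
})

test_that("no living cell in any pseudo-Moran record violates viability bounds", {
  sim <- run_simulation(sim_params(p_misseg = 0.05, S = 2, n_steps = 25,
                                   pop_cap = 400, seed = 13))
  expect_true(all(sim$population >= 1L & sim$population <= 6L))
  expect_false(sim$extinct)
})

test_that("neutral no-CIN growth has per-step factor 1.5 below the cap", {
  finals <- vapply(1:5, function(s) {
    sim <- run_simulation(sim_params(
      p_misseg = 0, S = 0, selection_model = "neutral", n_steps = 1,
      n_founders = 200L, pop_cap = 10000L, seed = 100 + s))
    sim$records$n_end
  }, numeric(1))
  # E[N_1] = 1.5 x 200 = 300; SE of the 5-run mean = sqrt(200 * .25 / 5)
  expect_lt(abs(mean(finals) - 300), 4 * sqrt(200 * 0.25 / 5))
})

test_that("S = 0 gives division probability 1/2 regardless of karyotype", {
  sim <- run_simulation(sim_params(p_misseg = 0.05, S = 0, n_steps = 1,
                                   n_founders = 2000L, pop_cap = 10000L,
                                   seed = 5))
  frac <- sim$records$n_divisions / sim$records$n_after_limit
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("identical seed and parameters give identical trajectories", {
  p <- sim_params(p_misseg = 0.02, p_break = 0.5, S = 5, n_steps = 15,
                  pop_cap = 300, seed = 77)
  a <- run_simulation(p)
  b <- run_simulation(p)
  expect_identical(a$records, b$records)
  expect_identical(a$population, b$population)
})

test_that("zero mis-segregation leaves the population fully euploid", {
  sim <- run_simulation(sim_params(p_misseg = 0, S = 10, n_steps = 20,
                                   pop_cap = 500, seed = 3))
  expect_true(all(sim$population == 2L))
  sim4 <- run_simulation(sim_params(p_misseg = 0, founder_ploidy = 4L,
                                    n_steps = 5, pop_cap = 300, seed = 3))
  expect_true(all(sim4$population == 4L))
})

test_that("driver selection drifts ploidy upward where abundance selection does not", {
  pd <- sim_params(p_misseg = 0.022, S = 10, selection_model = "driver",
                   n_steps = 60, pop_cap = 600, seed = 19)
  pa <- sim_params(p_misseg = 0.022, S = 10, selection_model = "abundance",
                   n_steps = 60, pop_cap = 600, seed = 19)
  drv <- run_simulation(pd)
  abn <- run_simulation(pa)
  expect_gt(mean_ploidy(drv$population), 2.1)
  expect_gt(mean_ploidy(drv$population), mean_ploidy(abn$population))
  expect_lt(abs(mean_ploidy(abn$population) - 2), 0.25)
})

test_that("Wright-Fisher populations restart every step at n_founders", {
  sim <- run_simulation(sim_params(p_misseg = 0.01, S = 1,
                                   growth_model = "wright_fisher",
                                   n_founders = 300L, n_steps = 10,
                                   seed = 23))
  expect_true(all(sim$records$n_start == 300L))
  expect_true(all(sim$records$n_end == 300L))
  expect_equal(nrow(sim$population), 300L)
})

test_that("Wright-Fisher re-initiation preserves per-arm marginals in expectation", {
  set.seed(61)
  # survivors with a known arm-1 marginal; neutral, no CIN, so death is
  # uniform and the resampled marginal should match the founder one
  pop <- matrix(2L, nrow = 4000L, ncol = 46L)
  pop[, 1L] <- sample(c(1L, 2L, 3L), 4000L, replace = TRUE,
                      prob = c(0.2, 0.5, 0.3))
  state <- list(pop = pop, lineage = seq_len(4000L), next_id = 4001L,
                step = 0L)
  params <- sim_params(p_misseg = 0, S = 0, selection_model = "neutral",
                       growth_model = "wright_fisher", n_founders = 4000L)
  res <- cinabc:::step_wright_fisher(state, params, load_arm_scores())
  counts <- tabulate(res$state$pop[, 1L], nbins = 3L)
  pval <- stats::chisq.test(counts, p = c(0.2, 0.5, 0.3))$p.value
  expect_gt(pval, 0.001)
})

test_that("extinction is a flagged terminal record, not an error", {
  # copy_max = 1 kills every diploid founder at the first viability check
  p <- sim_params(p_misseg = 0, n_steps = 10, copy_min = 1L, copy_max = 1L,
                  seed = 2)
  sim <- run_simulation(p)
  expect_true(sim$extinct)
  expect_equal(nrow(sim$records), 1L)
  expect_true(sim$records$extinct[1L])
  expect_equal(nrow(sim$population), 0L)
})

test_that("sample_cells draws without replacement and reproducibly", {
  sim <- run_simulation(sim_params(p_misseg = 0.01, n_steps = 10,
                                   pop_cap = 500, seed = 8))
  n <- nrow(sim$population)
  all_cells <- sample_cells(sim, n)
  expect_equal(dim(all_cells), dim(sim$population))
  expect_error(sample_cells(sim, n + 1L), "cannot sample")
  set.seed(1); a <- sample_cells(sim, 10)
  set.seed(1); b <- sample_cells(sim, 10)
  expect_identical(a, b)
})

test_that("simulation snapshots store the census at the requested steps", {
  sim <- run_simulation(sim_params(p_misseg = 0.01, n_steps = 10,
                                   pop_cap = 500, seed = 8),
                        snapshot_steps = c(0L, 5L, 10L))
  expect_named(sim$snapshots, c("0", "5", "10"))
  expect_true(all(sim$snapshots[["0"]] == 2L))
  expect_identical(sim$snapshots[["10"]], sim$population)
})
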