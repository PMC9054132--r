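# Rejection-ABC machinery: acceptance quantile, standardization, model
# selection, sliding windows, sample-size analysis and the rate helpers.
# Unit tests run on a small synthetic statistics library (helper-oracles.R);
# simulator-backed recovery is exercised in the acceptance suite.

test_that("a grid of g points x r replicates x s snapshots yields g*r*s records", {
  grid <- expand.grid(p_misseg = c(0.01, 0.05), S = c(0, 10))
  base <- sim_params(n_founders = 30L, pop_cap = 120L,
                     selection_model = "neutral")
  lib <- build_prior_library(grid, replicates = 1L, snapshot_steps = 5L,
                            base_params = base, n_cells = 20L, seed = 9L)
  expect_equal(nrow(lib), 4L)
  expect_setequal(lib$p_misseg, c(0.01, 0.05))
  lib2 <- build_prior_library(grid, replicates = 2L,
                              snapshot_steps = c(3L, 5L),
                              base_params = base, n_cells = 20L, seed = 9L)
  expect_equal(nrow(lib2), 16L)
  # determinism: identical seed, identical library
  lib3 <- build_prior_library(grid, replicates = 1L, snapshot_steps = 5L,
                              base_params = base, n_cells = 20L, seed = 9L)
  expect_identical(lib, lib3)
})

test_that("prior libraries round-trip through delimited text", {
  lib <- fake_library(20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prior_library(lib, path)
  back <- read_prior_library(path)
  expect_equal(back$p_misseg, lib$p_misseg, tolerance = 1e-12)
  expect_equal(back$colless, lib$colless, tolerance = 1e-12)
})

test_that("tolerance 1 accepts the whole library and recovers prior means", {
  lib <- fake_library(60)
  obs <- stats_of_record(lib, 1)
  fit <- infer_cin(obs, lib, tolerance = 1)
  expect_equal(fit$n_accepted, 60L)
  expect_equal(unname(fit$estimates["p_misseg"]), mean(lib$p_misseg))
  expect_equal(unname(fit$estimates["S"]), mean(lib$S))
  expect_equal(unname(fit$se["S"]), sd(lib$S) / sqrt(60))
})

test_that("an observation equal to a library record self-matches at distance 0", {
  lib <- fake_library(50)
  obs <- stats_of_record(lib, 17)
  fit <- infer_cin(obs, lib, tolerance = 1 / 50)
  expect_equal(fit$n_accepted, 1L)
  expect_equal(fit$accepted$distance, 0)
  expect_equal(fit$accepted$p_misseg, lib$p_misseg[17])
  expect_equal(fit$accepted$S, lib$S[17])
})

test_that("shrinking the tolerance never increases the maximum accepted distance", {
  lib <- fake_library(80)
  obs <- stats_of_record(lib, 3)
  maxd <- vapply(c(1, 0.5, 0.2, 0.1, 0.05),
                 function(t) max(infer_cin(obs, lib, t)$accepted$distance),
                 numeric(1))
  expect_true(all(diff(maxd) <= 0))
})

test_that("records with missing statistics are excluded from distances", {
  lib <- fake_library(30)
  lib$mkv[5] <- NA
  obs <- stats_of_record(lib, 1)
  fit <- infer_cin(obs, lib, tolerance = 1)
  expect_equal(fit$n_library, 29L)
})

test_that("feature mismatch between observed and library is refused", {
  lib <- fake_library(30)
  obs <- stats_of_record(lib, 1)
  expect_error(infer_cin(obs, lib, features = c("aneuploidy", "nonsense")),
               "lack ABC feature")
  chrom_mat <- matrix(2L, 10, 23)
  attr(chrom_mat, "feature_level") <- "chromosome"
  expect_error(infer_cin(chrom_mat, lib), "feature-level mismatch")
})

test_that("posterior methods expose estimates, quantiles and accepted draws", {
  lib <- fake_library(60)
  fit <- infer_cin(stats_of_record(lib, 2), lib, tolerance = 0.2)
  expect_named(coef(fit), c("p_misseg", "S"))
  s <- summary(fit)
  expect_equal(s$n_accepted, 12L)
  expect_equal(unname(s$quantiles["p_misseg", "50%"]),
               unname(quantile(fit$accepted$p_misseg, 0.5)))
  expect_output(print(fit), "P_misseg")
})

test_that("model posterior probabilities sum to 1 with BF(neutral) = 1", {
  lib <- rbind(fake_library(40, seed = 1, models = "abundance"),
               fake_library(40, seed = 2, models = "neutral"),
               fake_library(40, seed = 3, models = "driver"))
  obs <- stats_of_record(lib, 10)
  ms <- model_selection(obs, lib, tolerance = 0.1)
  expect_equal(sum(ms$posterior_prob), 1, tolerance = 1e-9)
  expect_equal(ms$bayes_factor[["neutral"]], 1)
  expect_error(model_selection(obs, fake_library(20), tolerance = 0.1),
               "neutral")
})

test_that("an empty neutral share reports an infinite Bayes factor", {
  # libraries engineered so every accepted record is non-neutral: the
  # neutral block sits far away in feature space
  a <- fake_library(40, seed = 4, models = "abundance")
  n <- fake_library(40, seed = 5, models = "neutral")
  n$aneuploidy <- n$aneuploidy + 100
  lib <- rbind(a, n)
  ms <- model_selection(stats_of_record(a, 1), lib, tolerance = 0.05)
  expect_equal(ms$posterior_prob[["neutral"]], 0)
  expect_true(is.infinite(ms$bayes_factor[["abundance"]]))
  expect_true("abundance" %in% ms$substantial)
})

test_that("an observation drawn from one model's library favors that model", {
  a <- fake_library(60, seed = 6, models = "abundance")
  n <- fake_library(60, seed = 7, models = "neutral")
  n$colless <- n$colless + 3  # separate the models in feature space
  lib <- rbind(a, n)
  votes <- vapply(1:10, function(i) {
    ms <- model_selection(stats_of_record(a, i), lib, tolerance = 0.1)
    names(which.max(ms$posterior_prob))
  }, character(1))
  expect_equal(names(sort(table(votes), decreasing = TRUE))[1], "abundance")
})

test_that("sliding windows partition the step axis and flag posterior drift", {
  lib <- fake_library(400, seed = 8)
  obs <- stats_of_record(lib, 1)
  sw <- sliding_window_inference(obs, lib, tolerance = 0.2)
  expect_equal(nrow(sw$results), 10L)
  expect_equal(sw$results$window_start, seq(0, 90, 10))
  expect_equal(sw$results$window_end, seq(10, 100, 10))
  expect_gte(sw$stability, 0)
  # a library constant in theta gives identical posteriors in every window
  const <- lib
  const$p_misseg <- 0.02
  const$S <- 40
  swc <- sliding_window_inference(obs, const, tolerance = 0.2)
  expect_true(all(swc$results$p_misseg_mean == 0.02))
  expect_equal(swc$stability, 0)
  expect_error(sliding_window_inference(obs, lib[lib$step > 50, ],
                                        tolerance = 0.2),
               "no library records")
})

test_that("sample-size analysis returns zero SE for whole-population samples", {
  lib <- fake_library(60, seed = 10)
  pop <- diploid_pop(30)
  pop[1:10, 1] <- 3L  # some heterogeneity so stats are finite
  res <- sample_size_analysis(pop, sizes = nrow(pop), replicates = 3,
                              library = lib, truth = 0.02, tolerance = 0.2)
  expect_equal(res$se_p_misseg, 0)
  expect_error(sample_size_analysis(pop, 10, 2, lib, truth = 0),
               "positive")
  expect_error(sample_size_analysis(pop, 100, 2, lib, truth = 0.02),
               "exceeds")
})

test_that("error-incidence and rate-approximation helpers follow their formulas", {
  expect_equal(predicted_error_incidence(0, 46), 0)
  expect_equal(predicted_error_incidence(0.005, 46), 23)
  expect_equal(predicted_error_incidence(0.01, 92), 92)
  expect_equal(approximate_rate_from_frequency(0, 46), 0)
  expect_equal(round(approximate_rate_from_frequency(31.3, 46), 5), 0.0068)
  expect_error(approximate_rate_from_frequency(10, 0), ">= 1")
})
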