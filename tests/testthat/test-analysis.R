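test_that("responses just above and below the threshold split correctly", {
  m_hi <- detect_significant(boundary_tensor(2.34), baseline_agg = "frames",
                             baseline_scope = "trial")
  expect_true(all(m_hi$responded))
  m_lo <- detect_significant(boundary_tensor(2.32), baseline_agg = "frames",
                             baseline_scope = "trial")
  expect_false(any(m_lo$responded))
})

test_that("zero baseline variance flags the cell instead of dividing", {
  vals <- array(0, c(2, 1, 2, 21))
  vals[2, 1, , 1:20] <- rep(c(0.1, -0.1), 10)
  tens <- response_tensor(vals, 0.5, 21)
  m <- detect_significant(tens, baseline_agg = "frames")
  expect_equal(m$excluded_cells, "cell1")
  expect_true(all(is.na(m$responded[1, , ])))
  expect_false(any(is.na(m$responded[2, , ])))
})

test_that("reliability classes follow the more-than-half rule and partition", {
  tab <- table_from_counts(matrix(c(4, 3, 0, 6, 1), 5, 1), n_trials = 6)
  expect_equal(as.character(tab$class),
               c("reliable", "unreliable", "silent", "reliable", "unreliable"))
  # partition invariant on a generated tensor
  tens <- generate_responses(generator_config("fly", n_cells = 80), seed = 2)
  t2 <- classify_cells(detect_significant(tens))
  counts <- table(t2$odor, t2$class)
  expect_true(all(rowSums(counts) == 80))
})

test_that("toy population fractions match the schematic walkthrough", {
  mask <- toy_mask_5x4()
  tab <- classify_cells(mask)
  fr <- population_fractions(tab, classify_env <- local({
    m <- olfstoch:::mask_from_activity(mask + 0)
    m$responded <- mask
    m
  }))
  s <- fr$summary
  expect_equal(s$per_trial_mean[s$class == "unreliable"], 0.20)
  expect_equal(s$per_odor_mean[s$class == "unreliable"], 0.60)
  expect_equal(s$per_trial_mean[s$class == "reliable"], 0.30)  # 1.5 of 5
  expect_equal(s$per_odor_mean[s$class == "reliable"], 0.40)
})

test_that("all-silent input yields zero fractions", {
  resp <- array(FALSE, c(4, 2, 4))
  m <- olfstoch:::mask_from_activity(resp + 0)
  tab <- classify_cells(m)
  fr <- population_fractions(tab, m)
  expect_true(all(fr$summary$per_trial_mean == 0))
  expect_true(all(fr$summary$per_odor_mean == 0))
})

test_that("per-trial and per-odor fractions relate as the classes dictate", {
  tens <- generate_responses(generator_config("fly"), seed = 6)
  m <- detect_significant(tens)
  fr <- population_fractions(classify_cells(m), m)
  s <- fr$summary
  # reliable cells recur: per-odor close to per-trial
  expect_lt(abs(s$per_odor_mean[s$class == "reliable"] -
                s$per_trial_mean[s$class == "reliable"]),
            0.6 * s$per_odor_mean[s$class == "reliable"])
  # unreliable cells churn: per-odor well above per-trial
  expect_gt(s$per_odor_mean[s$class == "unreliable"],
            s$per_trial_mean[s$class == "unreliable"])
})

test_that("overlap reproduces the printed worked examples and its bounds", {
  tab <- table_from_counts(matrix(c(4, 2, 1, 3, 0, 2), 3, 2, byrow = TRUE),
                           n_trials = 6)
  ov <- pairwise_overlap(tab)
  expect_equal(ov$per_cell$overlap[1], 8 / 36)
  expect_equal(round(ov$per_cell$overlap[1], 2), 0.22)
  expect_equal(ov$per_cell$overlap[2], 1 / 12)
  expect_equal(ov$per_cell$overlap[3], 0)
  # bound: overlap <= min(p_A, p_B), equality iff the larger p is 1
  tens <- generate_responses(generator_config("fly", n_cells = 60), seed = 3)
  t2 <- classify_cells(detect_significant(tens))
  pc <- pairwise_overlap(t2)$per_cell
  expect_true(all(pc$overlap <= pmin(pc$p_i, pc$p_j) + 1e-12))
  eq <- abs(pc$overlap - pmin(pc$p_i, pc$p_j)) < 1e-12 & pc$overlap > 0
  expect_true(all(pmax(pc$p_i, pc$p_j)[eq] == 1))
})

test_that("gamma fitting is consistent and rejects degenerate input", {
  true <- c(shape = 0.64, scale = 0.42)
  err <- vapply(c(1e3, 1e5), function(n) {
    f <- fit_gamma(withr::with_seed(40 + n, rgamma(n, 0.64, scale = 0.42)))
    abs(f$shape - true["shape"]) / true["shape"]
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
  f_exp <- fit_gamma(withr::with_seed(41, rexp(5e4)))
  expect_equal(f_exp$shape, 1, tolerance = 0.05)
  expect_error(fit_gamma(rep(2, 100)), "identical")
  expect_error(fit_gamma(c(-1, rexp(20))), "positive")
  expect_error(fit_gamma(rexp(5)), "at least 10")
})

test_that("cumulative frequency curve is the sorted empirical CDF", {
  cf <- cumulative_frequency(c(3, 1, 2, 2))
  expect_equal(cf$value, c(1, 2, 3))
  expect_equal(cf$cum_freq, c(0.25, 0.75, 1))
})

test_that("odor similarity: identical odors correlate at one, independent near zero", {
  tens <- generate_responses(generator_config("custom", n_cells = 100,
                                              n_odors = 2), seed = 8)
  # make odor 2 a copy of odor 1
  tens$values[, 2, , ] <- tens$values[, 1, , ]
  m <- detect_significant(tens)
  sim <- odor_similarity(tens, m)
  expect_equal(sim$averaged_r, 1, tolerance = 1e-12)
  expect_equal(sim$label, "similar")

  ind <- generate_responses(generator_config("custom", n_cells = 200,
                                             n_odors = 2), seed = 9)
  m2 <- detect_significant(ind)
  sim2 <- odor_similarity(ind, m2)
  expect_lt(abs(sim2$averaged_r), 0.25)
})

test_that("trial-pair mean correlation does not exceed the averaged-vector one", {
  cfg <- generator_config("fly", n_cells = 150)
  for (s in 1:3) {
    pair <- generate_correlated_pair(cfg, 0.5, seed = 50 + s)
    sim <- odor_similarity(pair, detect_significant(pair))
    expect_lte(sim$trial_pair_r, sim$averaged_r + 0.02)
  }
})

test_that("class-restricted similarity orders reliable above unreliable for similar pairs", {
  cfg <- generator_config("fly", n_cells = 200)
  pair <- generate_correlated_pair(cfg, 0.6, seed = 61)
  m <- detect_significant(pair)
  tab <- classify_cells(m)
  r_rel <- class_restricted_similarity(NULL, m, tab, "reliable")
  r_unr <- class_restricted_similarity(NULL, m, tab, "unreliable")
  expect_gt(mean(r_rel$r), mean(r_unr$r))

  lo <- generate_correlated_pair(cfg, 0.05, seed = 62)
  m2 <- detect_significant(lo)
  t2 <- classify_cells(m2)
  both <- rbind(class_restricted_similarity(NULL, m2, t2, "reliable"),
                class_restricted_similarity(NULL, m2, t2, "unreliable"))
  expect_lt(max(abs(both$r)), 0.45)
})

test_that("percentile cosine similarity: identical odors give one, disjoint zero", {
  act <- array(0, c(8, 2, 3))
  act[1:4, 1, ] <- 1
  act[1:4, 2, ] <- 1
  m <- olfstoch:::mask_from_activity(act)
  tab <- classify_cells(m)
  ps <- percentile_similarity(NULL, m, tab)
  expect_true(all(abs(ps$cosine - 1) < 1e-12))

  act2 <- act
  act2[, 2, ] <- 0
  act2[5:8, 2, ] <- 1
  m2 <- olfstoch:::mask_from_activity(act2)
  ps2 <- percentile_similarity(NULL, m2, classify_cells(m2))
  expect_true(all(ps2$cosine == 0))
})

test_that("top-percentile cells of a similar pair overlap most", {
  cfg <- generator_config("fly", n_cells = 200)
  pair <- generate_correlated_pair(cfg, 0.6, seed = 63)
  m <- detect_significant(pair)
  tab <- classify_cells(m)
  nested <- percentile_similarity(NULL, m, tab)
  bands <- percentile_similarity(NULL, m, tab, bands = TRUE)
  expect_gte(nested$cosine[nested$percentile == 25],
             bands$cosine[bands$percentile == "75-100"])
})

test_that("selectivity bias matches the analytic and shuffle expectations", {
  # small worked case: N = 10, n_A = 4, n_B = 5, co-count 4 -> bias 2.0
  counts <- matrix(0, 10, 2)
  counts[1:4, 1] <- 1
  counts[c(1:4, 5), 2] <- 1
  tab <- table_from_counts(counts, n_trials = 6)
  sb <- selectivity_bias(tab, c(1, 2), 1)
  expect_equal(sb$bias, 2.0)
  expect_equal(sb$expected, 2.0)

  # shuffle oracle: expectation of the co-count under random membership
  set.seed(99)
  sims <- replicate(1e4, {
    a <- sample(10, 4); b <- sample(10, 5)
    length(intersect(a, b))
  })
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - sb$expected), 3 * se)

  expect_error(selectivity_bias(tab, c(1, 2), 6), "no cells")
})

test_that("CV and Fano factor use sample statistics", {
  act <- array(0, c(1, 1, 4))
  act[1, 1, 1:2] <- c(1, 3)
  m <- olfstoch:::mask_from_activity(act)
  vs <- variability_stats(NULL, m)
  expect_equal(vs$mean, 2)
  expect_equal(vs$cv, sqrt(2) / 2)
  expect_equal(vs$fano, 1)

  const <- array(0, c(1, 1, 4))
  const[1, 1, ] <- 2
  vs2 <- variability_stats(NULL, olfstoch:::mask_from_activity(const))
  expect_equal(vs2$cv, 0)
  expect_equal(vs2$fano, 0)

  # Poisson-like counts have Fano factor near one
  set.seed(5)
  pois <- array(rpois(400 * 12, 5) + 1e-9, c(400, 1, 12))
  vsp <- variability_stats(NULL, olfstoch:::mask_from_activity(pois))
  expect_equal(mean(vsp$fano), 1, tolerance = 0.1)
})

test_that("split-half frequency finds the configured response rate", {
  resp <- array(FALSE, c(1, 1, 6))
  resp[1, 1, 2] <- TRUE
  m <- olfstoch:::mask_from_activity(resp + 0)
  sh <- split_half_frequency(m)
  expect_equal(sh$second_half_frequency, 0)
  expect_equal(attr(sh, "null_frequency"), 1 / 3)

  # homogeneous p = 1/3 population: mean second-half frequency ~ 1/3
  set.seed(17)
  resp2 <- array(runif(3000 * 8) < 1 / 3, c(3000, 1, 8))
  sh2 <- split_half_frequency(olfstoch:::mask_from_activity(resp2 + 0))
  expect_equal(mean(sh2$second_half_frequency), 1 / 3, tolerance = 0.05)

  # fly-like population is a reliability mixture, not concentrated at 1/3
  tens <- generate_responses(generator_config("fly", n_cells = 400), seed = 18)
  sh3 <- split_half_frequency(detect_significant(tens))
  expect_gt(sd(sh3$second_half_frequency), sd(sh2$second_half_frequency))
})

test_that("responsive counts fall monotonically with the threshold", {
  tens <- generate_responses(generator_config("fly"), seed = 19)
  ts <- threshold_sensitivity(tens, c(1.64, 2.33, 3.1))
  expect_true(all(diff(ts$n_responsive) < 0))
  # the default threshold row matches the default pipeline
  m <- detect_significant(tens)
  tab <- classify_cells(m)
  expect_equal(ts$n_responsive[2], sum(tab$n_responses > 0))
  expect_error(threshold_sensitivity(tens, c(-1, 2)), "> 0")
})
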