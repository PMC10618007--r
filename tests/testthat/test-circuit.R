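test_that("circuit realization matches its parameter distributions", {
  params <- circuit_params(n_kc = 5000)
  circ <- build_circuit(params, seed = 1)
  expect_equal(mean(circ$claws), 8 * 0.85, tolerance = 0.02)
  expect_true(all(circ$claws >= 1))
  expect_true(all(circ$apl_syn >= 5 & circ$apl_syn <= 30))
  # same seed, same wiring
  circ2 <- build_circuit(params, seed = 1)
  expect_identical(circ$W, circ2$W)
  expect_identical(circ$apl_syn, circ2$apl_syn)
})

test_that("gain calibration hits its target and is monotone", {
  circ <- build_circuit(circuit_params(), seed = 2)
  panel <- odor_panel(6, 50, seed = 3)
  cal <- calibrate_apl_gain(circ, panel, 0.08)
  frac <- function(circuit, gain) {
    mean(apply(panel, 1, function(P)
      mean(olfstoch:::noiseless_activity(circuit, matrix(P, 1), gain) > 0)))
  }
  expect_lt(abs(frac(cal, cal$apl_gain) - 0.08), 0.005)
  # active fraction non-increasing in gain; gain 0 leaves the threshold-only
  # fraction (everything with positive drive)
  expect_gte(frac(cal, 0), frac(cal, cal$apl_gain))
  expect_gte(frac(cal, cal$apl_gain), frac(cal, 10 * cal$apl_gain))
  expect_equal(frac(cal, 0), 1)  # threshold 0: all cells have positive drive
  expect_lt(frac(cal, 1), 0.01)
})

test_that("noiseless runs are deterministic with only reliable cells", {
  circ <- calibrate_apl_gain(build_circuit(circuit_params(), seed = 4),
                             odor_panel(6, 50, seed = 5), 0.08)
  panel <- odor_panel(6, 50, seed = 5)
  act <- run_experiment(circ, panel, zero_noise(), n_trials = 4, seed = 6)
  # identical across trials
  expect_true(all(apply(act$activity, c(1, 2), function(v) length(unique(v))) == 1))
  tab <- classify_cells(activity_mask(act))
  expect_equal(sum(tab$class == "unreliable"), 0)
  ev <- evaluate_characteristics(act)
  expect_false(ev$pass)        # undefined ratio reported as failure
  expect_false(is.finite(ev$stats["ratio"]))
})

test_that("trial simulation is reproducible under a seed", {
  circ <- calibrate_apl_gain(build_circuit(circuit_params(), seed = 7),
                             odor_panel(6, 50, seed = 8), 0.08)
  panel <- odor_panel(6, 50, seed = 8)
  a1 <- run_experiment(circ, panel, noise_config(), seed = 9)
  a2 <- run_experiment(circ, panel, noise_config(), seed = 9)
  expect_identical(a1$activity, a2$activity)
})

test_that("convergent claws average synaptic noise; APL source noise is not averaged", {
  # feedforward drive: relative variance shrinks with claw count
  drive_relvar <- function(claw_n, seed) {
    circ <- build_circuit(circuit_params(n_kc = 200, claw_n = claw_n,
                                         claw_p = 1), seed = seed)
    circ$apl_gain <- 0  # no inhibition: activity = feedforward drive
    panel <- odor_panel(1, 50, seed = seed + 1)
    acts <- withr::with_seed(seed + 2, replicate(40,
      simulate_trial(circ, panel[1, ],
                     noise_config(0, 0.5, 0, 0, 0, 0))))
    mean(apply(acts, 1, var) / pmax(rowMeans(acts), 1e-12)^2)
  }
  expect_lt(drive_relvar(7, 11), 0.5 * drive_relvar(1, 11))

  # single- vs multi-synapse variants: per-synapse APL->KC noise averages
  # out over ~15-20 synapses only in the multi variant
  inh_var <- function(variant, sigma_locus) {
    params <- circuit_params(wta_variant = variant)
    circ <- calibrate_apl_gain(build_circuit(params, seed = 21),
                               odor_panel(6, 50, seed = 22), 0.08)
    panel <- odor_panel(6, 50, seed = 22)
    ns <- do.call(noise_config, as.list(sigma_locus))
    acts <- withr::with_seed(23, replicate(40,
      simulate_trial(circ, panel[1, ], ns)))
    mean(apply(acts, 1, var))
  }
  apl_kc_only <- c(0, 0, 0, 0, 0, 0.3)
  expect_lt(inh_var("multi", apl_kc_only), inh_var("single", apl_kc_only))
  # APL-source noise: no averaging advantage for the multi variant
  apl_only <- c(0, 0, 0, 0, 0.3, 0)
  ratio <- inh_var("multi", apl_only) / inh_var("single", apl_only)
  expect_gt(ratio, 0.5)
})

test_that("characteristic evaluation agrees with the direct analysis chain", {
  circ <- calibrate_apl_gain(build_circuit(circuit_params(), seed = 31),
                             odor_panel(6, 50, seed = 32), 0.08)
  panel <- odor_panel(6, 50, seed = 32)
  act <- run_experiment(circ, panel, noise_config(), seed = 33)
  ev <- evaluate_characteristics(act)
  m <- activity_mask(act)
  fr <- population_fractions(classify_cells(m), m)
  s <- fr$summary
  expect_equal(unname(ev$stats["reliable_per_trial"]),
               100 * s$per_trial_mean[s$class == "reliable"])
  expect_equal(unname(ev$stats["unreliable_per_odor"]),
               100 * s$per_odor_mean[s$class == "unreliable"])
})

test_that("toy activity reproduces the schematic characteristics", {
  act <- array(0, c(5, 1, 4))
  act[toy_mask_5x4()] <- 1
  ev <- evaluate_characteristics(structure(
    list(activity = act, labels = "odorA", n_trials = 4),
    class = "kc_activity"))
  expect_equal(unname(ev$stats["unreliable_per_trial"]), 20)
  expect_equal(unname(ev$stats["unreliable_per_odor"]), 60)
})

test_that("sweeps are deterministic and zero-noise configurations never pass", {
  grid <- data.frame(apl = c(0, 0.28), pn = c(0, 0.25), kc = c(0, 0.45),
                     pn_kc = c(0, 0.2), kc_apl = c(0, 0.2),
                     apl_kc = c(0, 0.2),
                     target_active_fraction = c(0.08, 0.08))
  sw <- parameter_sweep(grid, replicates = 2, seed = 41)
  sw2 <- parameter_sweep(grid, replicates = 2, seed = 41)
  expect_equal(sw, sw2)
  expect_true(all(!sw$pass[sw$config == 1]))       # no noise, no variability
  expect_true(all(is.na(sw$ratio[sw$config == 1]) |
                  !is.finite(sw$ratio[sw$config == 1])))
  # permissive targets pass everything that has unreliable cells
  lax <- parameter_sweep(grid[2, ], replicates = 1, seed = 42,
                         targets = characteristic_targets(tolerance = 0.99))
  expect_true(all(lax$pass))
})
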