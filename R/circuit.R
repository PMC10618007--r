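#' Circuit parameters for the PN-KC-APL rate model
#'
#' Connectivity statistics of the fly mushroom-body input layer: each of
#' `n_kc` Kenyon cells draws its claw count from Binomial(`claw_n`,
#' `claw_p`) (zero draws are redrawn so every KC keeps at least one input),
#' each claw connects to one of `n_pn_types` projection-neuron types, and
#' each claw's synaptic strength comes from Gamma(`strength_shape`,
#' `strength_scale`). Every KC exchanges the same number of synapses with
#' the APL neuron in both directions, drawn uniformly on
#' `apl_syn_range`; individual APL synapses have unit strength, so a KC's
#' total coupling is its synapse count.
#'
#' @param n_pn_types number of PN types (default 50).
#' @param n_kc number of Kenyon cells (default 150; use 2000 for
#'   full-mushroom-body runs).
#' @param claw_n,claw_p Binomial claw-count parameters (defaults 8, 0.85).
#' @param strength_shape,strength_scale PN-KC synapse strength Gamma
#'   (defaults 4, 4).
#' @param apl_syn_range integer range of APL synapse counts per KC
#'   (default 5 to 30, giving a mean near the anatomical 15-20).
#' @param kc_threshold rectification threshold `t` applied to feedforward
#'   KC drive (default 0, as used for parameter exploration).
#' @param wta_variant `"multi"` (default): every APL synapse carries
#'   independent noise; `"single"`: all synapses of a KC share one noise
#'   draw (equivalently, one composite synapse).
#' @param pn_type_weights optional sampling weights over PN types for claw
#'   assignment (default uniform).
#' @return A list of class `circuit_params`.
#' @export
circuit_params <- function(n_pn_types = 50L, n_kc = 150L,
                           claw_n = 8L, claw_p = 0.85,
                           strength_shape = 4, strength_scale = 4,
                           apl_syn_range = c(5L, 30L),
                           kc_threshold = 0,
                           wta_variant = c("multi", "single"),
                           pn_type_weights = NULL) {
  wta_variant <- match.arg(wta_variant)
  if (n_pn_types < 1 || n_kc < 1) stop("counts must be positive")
  if (!is.null(pn_type_weights) && length(pn_type_weights) != n_pn_types)
    stop("`pn_type_weights` must have one weight per PN type")
  structure(list(n_pn_types = as.integer(n_pn_types), n_kc = as.integer(n_kc),
                 claw_n = claw_n, claw_p = claw_p,
                 strength_shape = strength_shape,
                 strength_scale = strength_scale,
                 apl_syn_range = as.integer(apl_syn_range),
                 kc_threshold = kc_threshold,
                 wta_variant = wta_variant,
                 pn_type_weights = pn_type_weights),
            class = "circuit_params")
}

#' Multiplicative-noise configuration for the six circuit loci
#'
#' Every noisy quantity `x` becomes `x * (1 + eta)` with
#' `eta ~ N(0, sigma)`, drawn fresh each trial. The six loci are PN firing
#' rates, PN-KC synapses, KC rates, KC-APL synapses, the APL rate itself,
#' and APL-KC synapses. Defaults sit inside the physiologically motivated
#' bands: 0-50% for PN and KC rate noise (PN at mid-band, KC in the upper
#' part, reflecting the inverse KC/APL noise trade-off of the successful
#' model region), 15-25% for synaptic transmission (mid-band), and 0.28
#' for APL-source noise (the centre of the successful configurations).
#'
#' @param pn,pn_kc,kc,kc_apl,apl,apl_kc Gaussian SDs, each >= 0
#'   (explored range 0-1.5).
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(pn = 0.25, pn_kc = 0.20, kc = 0.45,
                         kc_apl = 0.20, apl = 0.28, apl_kc = 0.20) {
  sig <- c(pn = pn, pn_kc = pn_kc, kc = kc, kc_apl = kc_apl,
           apl = apl, apl_kc = apl_kc)
  if (any(sig < 0)) stop("noise SDs must be >= 0")
  structure(as.list(sig), class = "noise_config")
}

#' @rdname noise_config
#' @export
zero_noise <- function() noise_config(0, 0, 0, 0, 0, 0)

#' Realize a circuit from its parameter distributions
#'
#' @param params a [circuit_params()].
#' @param seed integer seed; same (params, seed) gives identical
#'   connectivity.
#' @return An object of class `circuit`: PN-to-KC weight matrix `W`
#'   (`n_pn_types` x `n_kc`), claw counts, per-KC APL synapse counts
#'   `apl_syn` (identical in both directions), the parameters, and an
#'   `apl_gain` slot filled by [calibrate_apl_gain()] (initially `NA`).
#' @export
build_circuit <- function(params = circuit_params(), seed) {
  stopifnot(inherits(params, "circuit_params"))
  with_seed_if(seed, {
    n_kc <- params$n_kc; n_pn <- params$n_pn_types
    claws <- stats::rbinom(n_kc, params$claw_n, params$claw_p)
    while (any(claws == 0))  # every KC keeps at least one input
      claws[claws == 0] <- stats::rbinom(sum(claws == 0), params$claw_n,
                                         params$claw_p)
    W <- matrix(0, n_pn, n_kc)
    for (i in seq_len(n_kc)) {
      types <- sample.int(n_pn, claws[i], replace = TRUE,
                          prob = params$pn_type_weights)
      strengths <- stats::rgamma(claws[i], shape = params$strength_shape,
                                 scale = params$strength_scale)
      for (k in seq_along(types))
        W[types[k], i] <- W[types[k], i] + strengths[k]
    }
    apl_syn <- sample(seq(params$apl_syn_range[1], params$apl_syn_range[2]),
                      n_kc, replace = TRUE)
    structure(list(W = W, claws = claws, apl_syn = apl_syn,
                   params = params, apl_gain = NA_real_,
                   target_active_fraction = NA_real_),
              class = "circuit")
  })
}

#' @export
print.circuit <- function(x, ...) {
  cat("<circuit> ", x$params$n_pn_types, " PN types -> ", x$params$n_kc,
      " KCs (", x$params$wta_variant, "-synapse WTA)\n", sep = "")
  cat("  mean claw count ", round(mean(x$claws), 2),
      ", mean APL synapses ", round(mean(x$apl_syn), 1), "\n", sep = "")
  cat("  APL gain: ", if (is.na(x$apl_gain)) "uncalibrated"
      else signif(x$apl_gain, 4), "\n", sep = "")
  invisible(x)
}

#' Exponentially distributed PN odor rates
#'
#' @param n_odors number of odors (default 6).
#' @param n_pn_types number of PN types (must match the circuit).
#' @param seed integer seed.
#' @param rate exponential rate parameter (default 1).
#' @return Matrix `n_odors` x `n_pn_types` of non-negative firing rates.
#' @export
odor_panel <- function(n_odors = 6L, n_pn_types = 50L, seed, rate = 1) {
  with_seed_if(seed,
    matrix(stats::rexp(n_odors * n_pn_types, rate), n_odors, n_pn_types))
}

# Noiseless single-odor KC activity for a given gain.
noiseless_activity <- function(circuit, pn_rates, gain) {
  ff <- pmax(as.vector(pn_rates %*% circuit$W) - circuit$params$kc_threshold, 0)
  apl <- sum(ff * circuit$apl_syn)
  pmax(ff - apl * circuit$apl_syn * gain, 0)
}

#' Calibrate the APL inhibition gain
#'
#' Finds the gain at which, without noise, the mean fraction of KCs left
#' active across the odor panel equals `target_active_fraction` (the top
#' 6-11% of cells in the experimentally matched regime). The active
#' fraction is non-increasing in gain, so the gain is found by root
#' bracketing; the achieved fraction must land within `tol` (0.5
#' percentage points) of the target.
#'
#' @param circuit a [build_circuit()] result.
#' @param panel an [odor_panel()] matrix.
#' @param target_active_fraction target noiseless active fraction in (0, 1).
#' @param tol accepted absolute deviation (default 0.005).
#' @return The circuit with `apl_gain` and `target_active_fraction` set.
#' @export
calibrate_apl_gain <- function(circuit, panel, target_active_fraction = 0.08,
                               tol = 0.005) {
  stopifnot(inherits(circuit, "circuit"))
  if (target_active_fraction <= 0 || target_active_fraction >= 1)
    stop("`target_active_fraction` must lie in (0, 1)")
  act_frac <- function(g)
    mean(apply(panel, 1, function(P)
      mean(noiseless_activity(circuit, matrix(P, 1), g) > 0)))
  f <- function(g) act_frac(g) - target_active_fraction
  if (f(0) < 0)
    stop("gain search does not bracket the target: even zero gain leaves ",
         "fewer cells active than requested (threshold too high?)")
  hi <- 1e-4
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e6) stop("gain search does not bracket the target")
  }
  gain <- stats::uniroot(f, c(0, hi), tol = .Machine$double.eps^0.5)$root
  achieved <- act_frac(gain)
  if (abs(achieved - target_active_fraction) > tol)
    stop(sprintf("calibration missed the target: achieved %.3f for target %.3f",
                 achieved, target_active_fraction))
  circuit$apl_gain <- gain
  circuit$target_active_fraction <- target_active_fraction
  circuit
}

#' Simulate one noisy trial of the WTA circuit
#'
#' One feedforward-inhibit-rectify pass: (1) PN rates and PN-KC synapses
#' receive multiplicative noise and feedforward KC drive is computed and
#' rectified at the KC threshold; (2) KC rate noise applies; (3) the APL
#' rate pools the noisy KC-APL synapses and receives its own source noise;
#' (4) APL inhibition, scaled by the calibrated gain and the noisy APL-KC
#' synapses, is subtracted and the result rectified at zero. In the
#' single-synapse variant a KC's APL synapses share one noise draw per
#' direction; in the multi-synapse variant each unit synapse draws
#' independently (for unit strengths the sum of n independent noisy
#' synapses equals `n * (1 + eta_bar)` with `sd(eta_bar) = sigma / sqrt(n)`,
#' which is how it is computed).
#'
#' @param circuit a calibrated circuit.
#' @param pn_rates numeric vector (or 1-row matrix) of PN rates for one
#'   odor.
#' @param noise a [noise_config()].
#' @param seed optional integer seed for this trial.
#' @return Numeric vector of KC activities; a KC is active if > 0.
#' @export
simulate_trial <- function(circuit, pn_rates, noise = noise_config(),
                           seed = NULL) {
  stopifnot(inherits(circuit, "circuit"), inherits(noise, "noise_config"))
  if (is.na(circuit$apl_gain)) stop("circuit must be calibrated first")
  with_seed_if(seed, {
    n_kc <- circuit$params$n_kc
    P <- as.numeric(pn_rates) * (1 + stats::rnorm(length(pn_rates), 0, noise$pn))
    W <- circuit$W
    if (noise$pn_kc > 0)
      W <- W * (1 + stats::rnorm(length(W), 0, noise$pn_kc))
    ff <- as.vector(P %*% W)
    ff <- ff * (1 + stats::rnorm(n_kc, 0, noise$kc))
    ff <- pmax(ff - circuit$params$kc_threshold, 0)

    multi <- circuit$params$wta_variant == "multi"
    eff_sd <- function(sigma)
      if (multi) sigma / sqrt(circuit$apl_syn) else rep(sigma, n_kc)
    s_kc_apl <- circuit$apl_syn * (1 + stats::rnorm(n_kc, 0, eff_sd(noise$kc_apl)))
    apl <- sum(ff * s_kc_apl) * (1 + stats::rnorm(1, 0, noise$apl))
    s_apl_kc <- circuit$apl_syn * (1 + stats::rnorm(n_kc, 0, eff_sd(noise$apl_kc)))
    pmax(ff - apl * s_apl_kc * circuit$apl_gain, 0)
  })
}

#' Run a multi-odor, multi-trial circuit experiment
#'
#' @param circuit a calibrated circuit.
#' @param panel an [odor_panel()] matrix.
#' @param noise a [noise_config()].
#' @param n_trials trials per odor (default 6).
#' @param seed integer seed for all trial noise.
#' @return An object of class `kc_activity`: numeric array `activity`
#'   (KC x odor x trial) plus metadata. Any positive activity counts as a
#'   significant response downstream; [classify_cells()] accepts the
#'   result's mask via [activity_mask()].
#' @export
run_experiment <- function(circuit, panel, noise = noise_config(),
                           n_trials = 6L, seed) {
  stopifnot(inherits(circuit, "circuit"))
  with_seed_if(seed, {
    n_kc <- circuit$params$n_kc
    n_odors <- nrow(panel)
    act <- array(0, c(n_kc, n_odors, n_trials))
    for (o in seq_len(n_odors))
      for (t in seq_len(n_trials))
        act[, o, t] <- simulate_trial(circuit, panel[o, ], noise)
    structure(list(activity = act,
                   labels = paste0("odor", seq_len(n_odors)),
                   noise = noise, n_trials = n_trials),
              class = "kc_activity")
  })
}

#' @export
print.kc_activity <- function(x, ...) {
  d <- dim(x$activity)
  cat("<kc_activity> ", d[1], " KCs x ", d[2], " odors x ", d[3],
      " trials; active fraction ", signif(mean(x$activity > 0), 3),
      "\n", sep = "")
  invisible(x)
}

#' @rdname run_experiment
#' @param x a `kc_activity` object.
#' @export
activity_mask <- function(x) {
  stopifnot(inherits(x, "kc_activity"))
  mask_from_activity(x$activity, labels = x$labels)
}

#' Experimental characteristics of the stochastic code
#'
#' The five statistics a plausible model configuration must reproduce:
#' per-trial reliable:unreliable ratio 0.72, reliable cells per trial
#' 5.3%, unreliable per trial 7.2%, reliable per odor 6.1%, unreliable per
#' odor 29% (percentages of all KCs).
#'
#' @param ratio,reliable_per_trial,unreliable_per_trial,reliable_per_odor,unreliable_per_odor
#'   target values.
#' @param tolerance relative tolerance applied to each statistic (default
#'   0.25).
#' @return A list of class `characteristic_targets`.
#' @export
characteristic_targets <- function(ratio = 0.72,
                                   reliable_per_trial = 5.3,
                                   unreliable_per_trial = 7.2,
                                   reliable_per_odor = 6.1,
                                   unreliable_per_odor = 29,
                                   tolerance = 0.25) {
  if (tolerance <= 0 || tolerance >= 1) stop("tolerance must lie in (0, 1)")
  structure(list(targets = c(ratio = ratio,
                             reliable_per_trial = reliable_per_trial,
                             unreliable_per_trial = unreliable_per_trial,
                             reliable_per_odor = reliable_per_odor,
                             unreliable_per_odor = unreliable_per_odor),
                 tolerance = tolerance),
            class = "characteristic_targets")
}

#' Score simulated activity against the stochastic-code characteristics
#'
#' Delegates to [classify_cells()] and [population_fractions()] and
#' compares the five statistics to [characteristic_targets()]. A run with
#' no unreliable cells has an undefined ratio and is reported as a failure
#' rather than an error.
#'
#' @param activity a `kc_activity` object (or a `significance_mask`).
#' @param targets a [characteristic_targets()] object.
#' @return A list of class `characteristic_eval`: named `stats` vector,
#'   per-statistic `within` flags, and overall `pass`.
#' @export
evaluate_characteristics <- function(activity, targets = characteristic_targets()) {
  mask <- if (inherits(activity, "kc_activity")) activity_mask(activity)
          else activity
  stopifnot(inherits(mask, "significance_mask"))
  tab <- classify_cells(mask)
  fr <- population_fractions(tab, mask, denominator = "all")
  s <- fr$summary
  g <- function(col, cl) 100 * s[[col]][s$class == cl]
  stats <- c(ratio = g("per_trial_mean", "reliable") /
               g("per_trial_mean", "unreliable"),
             reliable_per_trial = g("per_trial_mean", "reliable"),
             unreliable_per_trial = g("per_trial_mean", "unreliable"),
             reliable_per_odor = g("per_odor_mean", "reliable"),
             unreliable_per_odor = g("per_odor_mean", "unreliable"))
  tg <- targets$targets
  within <- is.finite(stats) & abs(stats - tg) <= targets$tolerance * tg
  structure(list(stats = stats, within = within, pass = all(within),
                 targets = targets),
            class = "characteristic_eval")
}

#' @export
print.characteristic_eval <- function(x, ...) {
  cat("<characteristic_eval> pass:", x$pass, "\n")
  tg <- x$targets$targets
  for (nm in names(x$stats))
    cat(sprintf("  %-22s %7.3f (target %6.2f) %s\n", nm, x$stats[nm], tg[nm],
                if (x$within[nm]) "ok" else "off"))
  invisible(x)
}

#' Sweep noise configurations and gain targets
#'
#' Runs every row of `grid` (columns: any subset of the six noise SDs plus
#' `target_active_fraction`) for `replicates` independently built and
#' calibrated circuits, scoring each run against the characteristic
#' targets. Unspecified noise loci take their values from `base_noise`.
#'
#' @param grid data frame of configurations.
#' @param params a [circuit_params()].
#' @param base_noise a [noise_config()] supplying non-swept loci.
#' @param n_odors,n_trials panel size per run (defaults 6, 6).
#' @param replicates circuits per configuration (default 3).
#' @param seed master seed; replicate r of every configuration uses
#'   `seed + r` for the circuit, panel and trial noise.
#' @param targets a [characteristic_targets()] object.
#' @return A data frame of class `sweep_result`: one row per
#'   (configuration, replicate) with the five statistics and a `pass`
#'   flag; `summary(x)` aggregates per configuration.
#' @export
parameter_sweep <- function(grid, params = circuit_params(),
                            base_noise = noise_config(),
                            n_odors = 6L, n_trials = 6L,
                            replicates = 3L, seed = 1L,
                            targets = characteristic_targets()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  noise_cols <- intersect(names(grid),
                          c("pn", "pn_kc", "kc", "kc_apl", "apl", "apl_kc"))
  rows <- list()
  for (r in seq_len(replicates)) {
    rseed <- as.integer(seed) + r
    circ <- build_circuit(params, seed = rseed)
    panel <- odor_panel(n_odors, params$n_pn_types, seed = rseed + 10000L)
    for (ci in seq_len(nrow(grid))) {
      ns <- base_noise
      for (cl in noise_cols) ns[[cl]] <- grid[[cl]][ci]
      tgt <- if ("target_active_fraction" %in% names(grid))
        grid$target_active_fraction[ci] else 0.08
      cal <- calibrate_apl_gain(circ, panel, tgt)
      act <- run_experiment(cal, panel, ns, n_trials,
                            seed = rseed + 20000L + ci)
      ev <- evaluate_characteristics(act, targets)
      rows[[length(rows) + 1L]] <- cbind(
        config = ci, grid[ci, , drop = FALSE], replicate = r,
        as.data.frame(as.list(ev$stats)), pass = ev$pass,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "targets") <- targets
  out
}

#' @export
summary.sweep_result <- function(object, ...) {
  stats_cols <- c("ratio", "reliable_per_trial", "unreliable_per_trial",
                  "reliable_per_odor", "unreliable_per_odor")
  cfgs <- split(as.data.frame(object), object$config)
  out <- do.call(rbind, lapply(cfgs, function(d) {
    m <- colMeans(d[stats_cols], na.rm = TRUE)
    cbind(d[1, setdiff(names(d), c(stats_cols, "replicate", "pass")),
            drop = FALSE],
          as.data.frame(as.list(m)),
          pass_fraction = mean(d$pass),
          row.names = NULL)
  }))
  tg <- attr(object, "targets")$targets
  dist <- sqrt(rowSums(scale(as.matrix(out[stats_cols]),
                             center = tg, scale = tg)^2))
  out$target_distance <- ifelse(is.finite(dist), dist, Inf)
  out[order(out$target_distance), ]
}
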