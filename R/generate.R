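#' Generate a synthetic response tensor
#'
#' Draws, for each (cell, odor), a latent reliability probability `p` from
#' the configured Gamma truncated to [0, 1] (rejection sampling) and a base
#' amplitude `G` from the response-size Gamma. On each trial the cell
#' responds with probability `p`; responding trials add an amplitude
#' `G * exp(b * (p - p_ref))` to every frame of the response window, so the
#' expected amplitude grows exponentially with reliability (`p_ref` is the
#' mean of the truncated reliability distribution, making the coupling
#' amplitude-neutral at an average cell). All frames additionally carry
#' i.i.d. Gaussian baseline noise with SD `baseline_sd`.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; the same (config, seed) pair yields a
#'   bitwise-identical tensor.
#' @return A [response_tensor()] whose `latent` field holds the matrices
#'   `p` (cell x odor reliability probabilities), `amp` (realized expected
#'   amplitudes) and `amp_base` (the raw response-Gamma draws).
#' @examples
#' cfg <- generator_config("fly", n_cells = 50)
#' tens <- generate_responses(cfg, seed = 1)
#' dim(tens)
#' @export
generate_responses <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  with_seed_if(seed, generate_responses_impl(config))
}

generate_responses_impl <- function(config, latent = NULL) {
  nc <- config$n_cells; no <- config$n_odors; nt <- config$n_trials
  nb <- config$n_baseline_frames; nr <- config$n_response_frames
  nf <- nb + nr
  rg <- config$reliability_gamma; ag <- config$response_gamma
  b <- config$amplitude_coupling

  if (is.null(latent)) {
    p <- matrix(rgamma_trunc01(nc * no, rg[1], rg[2]), nc, no)
    amp_base <- matrix(stats::rgamma(nc * no, shape = ag[1], scale = ag[2]),
                       nc, no)
  } else {
    p <- latent$p; amp_base <- latent$amp_base
  }
  p_ref <- trunc_gamma_mean(rg[1], rg[2])
  amp <- amp_base * exp(b * (p - p_ref))

  values <- array(stats::rnorm(nc * no * nt * nf, sd = config$baseline_sd),
                  c(nc, no, nt, nf))
  responds <- array(stats::runif(nc * no * nt) < rep(p, nt), c(nc, no, nt))
  resp_frames <- (nb + 1L):nf
  add <- outer(ifelse(responds, rep(amp, nt), 0),
               rep(1, nr))
  values[, , , resp_frames] <- values[, , , resp_frames, drop = FALSE] +
    array(add, c(nc, no, nt, nr))

  response_tensor(values, config$frame_duration, nb + 1L,
                  latent = list(p = p, amp = amp, amp_base = amp_base,
                                responds = responds))
}

#' Generate an odor pair with controlled representational similarity
#'
#' Builds a two-odor tensor whose trial-averaged population vectors have a
#' Pearson correlation close to `target_corr`. The latent reliability and
#' amplitude fields of the two odors are coupled through a Gaussian copula;
#' the copula correlation is calibrated by bisection against cheap
#' simulations of the measured correlation under the same cell and trial
#' counts. Because the copula couples cells monotonically across the whole
#' reliability continuum, the cells shared between similar odors are
#' predominantly the high-reliability ones, as observed in the recordings.
#'
#' @param config a [generator_config()]; its odor count is ignored (the
#'   result always has two odors).
#' @param target_corr target Pearson correlation of the trial-averaged
#'   population vectors, in [0, 1].
#' @param seed integer seed.
#' @param tol accepted deviation of the measured correlation (default 0.1).
#' @return A two-odor [response_tensor()]; the achieved correlation is in
#'   `attr(, "measured_corr")`.
#' @export
generate_correlated_pair <- function(config, target_corr, seed, tol = 0.1) {
  stopifnot(inherits(config, "generator_config"))
  if (target_corr < 0 || target_corr > 1)
    stop("`target_corr` must lie in [0, 1]")
  with_seed_if(seed, {
    rho <- calibrate_copula_rho(config, target_corr)
    # finite-population realizations scatter around the calibrated value;
    # keep the realization closest to target, stopping once within tolerance
    best <- NULL; best_mc <- Inf
    for (try in 1:8) {
      tens <- generate_pair_impl(config, rho)
      mc <- measured_pair_corr(tens)
      if (abs(mc - target_corr) < abs(best_mc - target_corr)) {
        best <- tens; best_mc <- mc
      }
      if (abs(best_mc - target_corr) <= tol) break
    }
    if (abs(best_mc - target_corr) > tol)
      stop(sprintf(paste0("target correlation %.2f unreachable with %d cells: ",
                          "best achieved %.2f (copula rho %.2f); increase ",
                          "n_cells or relax the target"),
                   target_corr, config$n_cells, best_mc, rho))
    attr(best, "measured_corr") <- best_mc
    attr(best, "copula_rho") <- rho
    best
  })
}

# Latent fields for a correlated pair: one standard-normal field per odor,
# correlated rho across odors, mapped through the inverse CDFs.
pair_latent <- function(config, rho) {
  nc <- config$n_cells
  rg <- config$reliability_gamma; ag <- config$response_gamma
  z0 <- stats::rnorm(nc); zr1 <- stats::rnorm(nc); zr2 <- stats::rnorm(nc)
  z1 <- rho * z0 + sqrt(1 - rho^2) * zr1
  z2 <- rho * z0 + sqrt(1 - rho^2) * zr2
  q01 <- function(z, shape, scale) {
    # quantile of the [0,1]-truncated Gamma
    pmax <- stats::pgamma(1, shape, scale = scale)
    stats::qgamma(stats::pnorm(z) * pmax, shape, scale = scale)
  }
  p <- cbind(q01(z1, rg[1], rg[2]), q01(z2, rg[1], rg[2]))
  # amplitudes ride on the same latent field: shared cells respond alike
  amp_base <- cbind(stats::qgamma(stats::pnorm(z1), ag[1], scale = ag[2]),
                    stats::qgamma(stats::pnorm(z2), ag[1], scale = ag[2]))
  list(p = p, amp_base = amp_base)
}

generate_pair_impl <- function(config, rho) {
  cfg2 <- config
  cfg2$n_odors <- 2L
  class(cfg2) <- class(config)
  generate_responses_impl(cfg2, latent = pair_latent(config, rho))
}

measured_pair_corr <- function(tens) {
  nb <- tens$odor_onset_frame - 1L
  nf <- dim(tens$values)[4]
  resp <- apply(tens$values[, , , (nb + 1L):nf, drop = FALSE], c(1, 2, 3), mean)
  stats::cor(rowMeans(resp[, 1, ]), rowMeans(resp[, 2, ]))
}

calibrate_copula_rho <- function(config, target_corr, n_probe = 3L) {
  probe <- function(rho) {
    mean(vapply(seq_len(n_probe), function(i) {
      measured_pair_corr(generate_pair_impl(config, rho))
    }, 0))
  }
  if (target_corr >= probe(1)) return(1)
  if (target_corr <= probe(0)) return(0)
  lo <- 0; hi <- 1
  for (i in 1:8) {
    mid <- (lo + hi) / 2
    if (probe(mid) < target_corr) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
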