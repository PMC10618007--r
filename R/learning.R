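#' KC-to-MBON synapse weights
#'
#' Each Kenyon cell projects to an approach-driving and an avoid-driving
#' mushroom-body output neuron. Both weights start equal; reinforcement
#' depresses one of them in proportion to the cell's response, with a floor
#' at zero (reward depresses the avoid synapse, punishment the approach
#' synapse).
#'
#' @param cells character vector of cell identifiers.
#' @param w0 initial weight (default 1).
#' @param delta learning rate (> 0; default 0.25, chosen so a typical
#'   reliable cell saturates within the normal 12-trial training).
#' @return A data frame of class `synapse_weights` with columns `cell`,
#'   `w_approach`, `w_avoid`; `delta` is carried as an attribute.
#' @export
synapse_weights <- function(cells, w0 = 1, delta = 0.25) {
  if (delta <= 0) stop("`delta` must be > 0")
  if (w0 < 0) stop("initial weight must be >= 0")
  out <- data.frame(cell = as.character(cells),
                    w_approach = w0, w_avoid = w0,
                    stringsAsFactors = FALSE)
  class(out) <- c("synapse_weights", "data.frame")
  attr(out, "delta") <- delta
  attr(out, "w0") <- w0
  out
}

#' Apply reinforcement-gated synaptic depression
#'
#' Sequentially applies `w(t) = max(w(t-1) - delta * r, 0)` per training
#' trial: reward trials depress the avoid weights, punishment trials the
#' approach weights, each by the learning rate times that trial's response
#' amplitude.
#'
#' @param weights a [synapse_weights()] object.
#' @param responses matrix of non-negative response amplitudes, one row per
#'   training trial and one column per cell (a vector is treated as one
#'   trial).
#' @param valence `"reward"` or `"punishment"`.
#' @return The updated `synapse_weights`.
#' @export
update_weights <- function(weights, responses, valence = c("reward", "punishment")) {
  stopifnot(inherits(weights, "synapse_weights"))
  valence <- match.arg(valence)
  if (is.vector(responses)) responses <- matrix(responses, nrow = 1)
  if (ncol(responses) != nrow(weights))
    stop("`responses` needs one column per cell")
  if (any(responses < 0)) stop("response amplitudes must be >= 0")
  delta <- attr(weights, "delta")
  col <- if (valence == "reward") "w_avoid" else "w_approach"
  w <- weights[[col]]
  for (t in seq_len(nrow(responses)))
    w <- pmax(w - delta * responses[t, ], 0)
  weights[[col]] <- w
  weights
}

#' Training regime configuration
#'
#' @param n_trials_normal trials of normal (initial) training (default 12).
#' @param n_trials_extended trials of extended training (default 100).
#' @param simplified_saturation if `TRUE`, training is approximated by
#'   saturating reliable-cell synapses to zero after normal training and
#'   additionally unreliable-cell synapses after extended training, instead
#'   of simulating trial-by-trial depression.
#' @return A list of class `training_config`.
#' @export
training_config <- function(n_trials_normal = 12L, n_trials_extended = 100L,
                            simplified_saturation = FALSE) {
  if (n_trials_normal <= 0 || n_trials_extended <= n_trials_normal)
    stop("need extended > normal > 0 training trials")
  structure(list(n_trials_normal = as.integer(n_trials_normal),
                 n_trials_extended = as.integer(n_trials_extended),
                 simplified_saturation = simplified_saturation),
            class = "training_config")
}

#' Train an odor association on a reliability table
#'
#' Odor A is paired with reward and odor B with punishment. In full mode
#' each cell's response on each training trial is resampled from its
#' response probability (amplitude = its mean significant response), and
#' the depression rule is applied trial by trial. In simplified-saturation
#' mode the weights of reliable-cell synapses are set to zero after normal
#' training, and those of unreliable-cell synapses additionally after
#' extended training (reward affecting avoid weights via odor A, punishment
#' affecting approach weights via odor B).
#'
#' @param table a [classify_cells()] result.
#' @param pair character or integer vector: `c(rewarded_odor, punished_odor)`.
#' @param config a [training_config()].
#' @param regime `"normal"` or `"extended"`.
#' @param weights optional starting [synapse_weights()] (defaults to fresh
#'   equal weights for all cells).
#' @param seed integer seed (full mode resamples responses).
#' @return The trained `synapse_weights`, with the regime and pair as
#'   attributes.
#' @export
train_association <- function(table, pair, config = training_config(),
                              regime = c("normal", "extended"),
                              weights = NULL, seed = NULL) {
  stopifnot(inherits(table, "reliability_table"))
  regime <- match.arg(regime)
  labels <- attr(table, "labels")
  if (is.numeric(pair)) pair <- labels[pair]
  if (!all(pair %in% labels)) stop("unknown odor in `pair`")
  a <- table[table$odor == pair[1], ]
  b <- table[table$odor == pair[2], ]
  if (is.null(weights)) weights <- synapse_weights(a$cell)
  n_trials <- if (regime == "normal") config$n_trials_normal
              else config$n_trials_extended

  if (config$simplified_saturation) {
    sat_a <- if (regime == "normal") a$class == "reliable"
             else a$class %in% c("reliable", "unreliable")
    sat_b <- if (regime == "normal") b$class == "reliable"
             else b$class %in% c("reliable", "unreliable")
    weights$w_avoid[sat_a] <- 0     # reward odor A
    weights$w_approach[sat_b] <- 0  # punish odor B
  } else {
    # mean amplitude of a significant response (expected response is
    # probability x amplitude, so divide the probability back out)
    amp_a <- ifelse(a$p_response > 0, a$expected_response / a$p_response, 0)
    amp_b <- ifelse(b$p_response > 0, b$expected_response / b$p_response, 0)
    weights <- with_seed_if(seed, {
      ra <- matrix(stats::rbinom(n_trials * nrow(a), 1, rep(a$p_response,
                                                            each = n_trials)),
                   n_trials) * rep(amp_a, each = n_trials)
      rb <- matrix(stats::rbinom(n_trials * nrow(b), 1, rep(b$p_response,
                                                            each = n_trials)),
                   n_trials) * rep(amp_b, each = n_trials)
      w <- update_weights(weights, ra, "reward")
      update_weights(w, rb, "punishment")
    })
  }
  attr(weights, "pair") <- pair
  attr(weights, "regime") <- regime
  weights
}

#' Per-cell discrimination contributions
#'
#' With odor A rewarded and odor B punished, a cell's contribution to
#' discriminating A from B on an A test trial is its response probability
#' for A times the difference of its output weights:
#' `D_x = p_x(A) * (w_approach - w_avoid)`; the population total is the sum
#' over cells. A cell responding to A in 2 of 6 trials with weights 2
#' (approach) and 4 (avoid) contributes (1/3)(2 - 4) = -2/3.
#'
#' @param weights trained [synapse_weights()] (pair attribute required, or
#'   pass `odor`).
#' @param table the [classify_cells()] result used in training.
#' @param odor the tested odor (defaults to the rewarded odor of the
#'   training pair).
#' @return An object of class `discrimination_report`: per-cell data frame
#'   (`cell`, `p_response`, `class`, `n_responses`, `D`), `total` (signed
#'   sum), `total_abs`, per-class signed and absolute sums, and the regime
#'   label.
#' @export
discrimination_score <- function(weights, table, odor = NULL) {
  stopifnot(inherits(weights, "synapse_weights"),
            inherits(table, "reliability_table"))
  if (is.null(odor)) odor <- attr(weights, "pair")[1]
  a <- table[table$odor == odor, ]
  stopifnot(nrow(a) == nrow(weights), all(a$cell == weights$cell))
  D <- a$p_response * (weights$w_approach - weights$w_avoid)
  per_cell <- data.frame(cell = a$cell, p_response = a$p_response,
                         n_responses = a$n_responses,
                         class = a$class, D = D, stringsAsFactors = FALSE)
  by_class <- do.call(rbind, lapply(levels(per_cell$class), function(cl) {
    sel <- per_cell$class == cl
    data.frame(class = cl, n_cells = sum(sel),
               D_signed = sum(D[sel]), D_abs = sum(abs(D[sel])))
  }))
  structure(list(per_cell = per_cell, total = sum(D), total_abs = sum(abs(D)),
                 by_class = by_class, odor = odor,
                 regime = attr(weights, "regime"),
                 pair = attr(weights, "pair")),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("<discrimination_report> odor ", x$odor,
      if (!is.null(x$regime)) paste0(" (", x$regime, " training)"), "\n",
      sep = "")
  cat("  total D = ", signif(x$total, 4), "; sum |D| = ",
      signif(x$total_abs, 4), "\n", sep = "")
  print(x$by_class)
  invisible(x)
}

#' Discrimination improvement by reliability class
#'
#' For each reliability level (response count 1..n_trials of the tested
#' odor), the change in summed absolute discrimination contribution from
#' normal to extended training.
#'
#' @param report_normal,report_extended [discrimination_score()] results
#'   for the two regimes on the same population.
#' @return A data frame with one row per reliability level:
#'   `n_responses`, `n_cells`, `d_normal`, `d_extended`, `improvement`.
#' @export
contribution_by_reliability <- function(report_normal, report_extended) {
  stopifnot(inherits(report_normal, "discrimination_report"),
            inherits(report_extended, "discrimination_report"))
  pn <- report_normal$per_cell
  pe <- report_extended$per_cell
  stopifnot(all(pn$cell == pe$cell))
  levels <- sort(unique(pn$n_responses[pn$n_responses > 0]))
  do.call(rbind, lapply(levels, function(k) {
    sel <- pn$n_responses == k
    data.frame(n_responses = k, n_cells = sum(sel),
               d_normal = sum(abs(pn$D[sel])),
               d_extended = sum(abs(pe$D[sel])),
               improvement = sum(abs(pe$D[sel])) - sum(abs(pn$D[sel])))
  }))
}
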