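#' Detect significant odor responses
#'
#' A cell-trial responds if its mean dF/F over the response window exceeds
#' the baseline mean by `threshold_sd` baseline standard deviations (default
#' 2.33, the one-sided Gaussian 1% point). Baseline statistics are computed
#' from means over non-overlapping sub-windows of the pre-odor period, each
#' as long as the response window, so that baseline and response summaries
#' have the same sampling variance; with `baseline_scope = "cell"` (default)
#' the sub-window means are pooled across all trials and odors of a cell,
#' with `"trial"` each trial uses only its own baseline. Setting
#' `baseline_agg = "frames"` reproduces the naive per-frame statistics
#' instead.
#'
#' @param tensor a [response_tensor()].
#' @param threshold_sd significance threshold in baseline SD units (> 0).
#' @param baseline_window,response_window frame index vectors; defaults are
#'   all pre-onset frames and all post-onset frames. They must not overlap.
#' @param baseline_scope `"cell"` (pool baseline across trials) or `"trial"`.
#' @param baseline_agg `"windows"` (default; see above) or `"frames"`.
#' @return An object of class `significance_mask`: logical array `responded`
#'   (cell x odor x trial; `NA` for cells excluded for zero baseline
#'   variance), numeric array `response_values` (baseline-subtracted response
#'   means), `baseline_stats`, `threshold_sd`, and `excluded_cells`.
#' @export
detect_significant <- function(tensor, threshold_sd = 2.33,
                               baseline_window = NULL, response_window = NULL,
                               baseline_scope = c("cell", "trial"),
                               baseline_agg = c("windows", "frames")) {
  stopifnot(inherits(tensor, "response_tensor"))
  baseline_scope <- match.arg(baseline_scope)
  baseline_agg <- match.arg(baseline_agg)
  if (threshold_sd <= 0) stop("`threshold_sd` must be > 0")
  d <- dim(tensor$values)
  onset <- tensor$odor_onset_frame
  if (is.null(baseline_window)) baseline_window <- seq_len(onset - 1L)
  if (is.null(response_window)) response_window <- onset:d[4]
  if (any(baseline_window < 1) || any(response_window > d[4]))
    stop("windows out of frame range")
  if (length(intersect(baseline_window, response_window)))
    stop("baseline and response windows overlap")

  resp_mean <- apply(tensor$values[, , , response_window, drop = FALSE],
                     c(1, 2, 3), mean)

  if (baseline_agg == "frames") {
    base_vals <- tensor$values[, , , baseline_window, drop = FALSE]
    nwin <- length(baseline_window)
  } else {
    m <- length(response_window)
    nwin <- length(baseline_window) %/% m
    if (nwin < 2)
      stop("baseline window too short: needs at least two sub-windows of ",
           "the response-window length")
    use <- baseline_window[seq_len(nwin * m)]
    bw <- tensor$values[, , , use, drop = FALSE]
    dim(bw) <- c(d[1], d[2], d[3], m, nwin)
    base_vals <- apply(bw, c(1, 2, 3, 5), mean)
  }

  if (baseline_scope == "cell") {
    bmat <- matrix(base_vals, nrow = d[1])  # cell x (odor*trial*win)
    bmean <- rowMeans(bmat)
    bsd <- apply(bmat, 1, stats::sd)
    bmean_full <- array(bmean, dim = d[1:3])
    bsd_full <- array(bsd, dim = d[1:3])
  } else {
    bmean_full <- apply(base_vals, c(1, 2, 3), mean)
    bsd_full <- apply(base_vals, c(1, 2, 3), stats::sd)
    bmean <- rowMeans(matrix(bmean_full, nrow = d[1]))
    bsd <- rowMeans(matrix(bsd_full, nrow = d[1]))
  }

  excluded <- which(apply(bsd_full == 0, 1, any))
  responded <- resp_mean > bmean_full + threshold_sd * bsd_full
  if (length(excluded)) responded[excluded, , ] <- NA

  structure(
    list(responded = responded,
         response_values = resp_mean - bmean_full,
         baseline_stats = data.frame(cell = tensor$cell_ids,
                                     mean = bmean, sd = bsd),
         threshold_sd = threshold_sd,
         baseline_scope = baseline_scope,
         n_baseline_values = nwin,
         labels = tensor$labels,
         cell_ids = tensor$cell_ids,
         excluded_cells = tensor$cell_ids[excluded]),
    class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  d <- dim(x$responded)
  cat("<significance_mask> ", d[1], " cells x ", d[2], " odors x ", d[3],
      " trials; threshold ", x$threshold_sd, " SD\n", sep = "")
  cat("  responded fraction: ",
      signif(mean(x$responded, na.rm = TRUE), 3), "\n", sep = "")
  if (length(x$excluded_cells))
    cat("  excluded (zero baseline variance): ",
        length(x$excluded_cells), " cells\n", sep = "")
  invisible(x)
}

# Build a significance-mask-shaped object from a plain activity array
# (e.g. simulated circuit activity where any positive rate is a response).
mask_from_activity <- function(activity, labels = NULL, cell_ids = NULL) {
  d <- dim(activity)
  if (is.null(labels)) labels <- paste0("odor", seq_len(d[2]))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(d[1]))
  structure(
    list(responded = activity > 0,
         response_values = activity,
         baseline_stats = data.frame(cell = cell_ids, mean = 0, sd = 0),
         threshold_sd = 0,
         labels = labels,
         cell_ids = cell_ids,
         excluded_cells = character(0)),
    class = "significance_mask")
}

#' Classify cells along the reliability continuum
#'
#' Per (cell, odor): *reliable* cells respond in more than half of the
#' trials, *unreliable* cells respond in at least one but at most half
#' (exactly half counts as unreliable), and *silent* cells never respond.
#' The expected response is the trial-mean of (response indicator x response
#' amplitude), i.e. response probability times mean significant amplitude.
#'
#' @param mask a `significance_mask` (or logical cell x odor x trial array).
#' @param response_values optional amplitude array when `mask` is an array.
#' @return A data frame of class `reliability_table` with one row per
#'   (cell, odor): `cell`, `odor`, `n_responses`, `n_trials`, `p_response`,
#'   `class`, `expected_response`.
#' @export
classify_cells <- function(mask, response_values = NULL) {
  if (is.array(mask) && is.logical(mask)) {
    vals <- if (is.null(response_values)) mask + 0 else response_values
    m <- mask_from_activity(vals)
    m$responded <- mask
    mask <- m
  }
  stopifnot(inherits(mask, "significance_mask"))
  d <- dim(mask$responded)
  if (d[3] < 2) stop("need at least 2 trials per odor")
  resp <- mask$responded
  resp[is.na(resp)] <- FALSE
  n_resp <- apply(resp, c(1, 2), sum)
  amp <- mask$response_values
  exp_resp <- apply(resp * amp, c(1, 2), sum) / d[3]
  cls <- ifelse(n_resp > d[3] / 2, "reliable",
                ifelse(n_resp >= 1, "unreliable", "silent"))
  out <- data.frame(
    cell = rep(mask$cell_ids, d[2]),
    odor = rep(mask$labels, each = d[1]),
    n_responses = as.vector(n_resp),
    n_trials = d[3],
    p_response = as.vector(n_resp) / d[3],
    class = factor(as.vector(cls), levels = c("reliable", "unreliable", "silent")),
    expected_response = as.vector(exp_resp),
    stringsAsFactors = FALSE)
  class(out) <- c("reliability_table", "data.frame")
  attr(out, "n_cells") <- d[1]
  attr(out, "labels") <- mask$labels
  out
}

#' @export
print.reliability_table <- function(x, ...) {
  cat("<reliability_table> ", attr(x, "n_cells"), " cells x ",
      length(attr(x, "labels")), " odors\n", sep = "")
  print(table(x$class))
  invisible(x)
}

#' Per-trial and per-odor reliable/unreliable population fractions
#'
#' The per-trial fraction of a class is the number of class members that
#' respond in a given trial divided by the denominator; the per-odor
#' fraction is the number of class members for that odor (over all trials)
#' divided by the denominator. The denominator is all imaged cells by
#' default, or only responsive cells.
#'
#' @param table a [classify_cells()] result.
#' @param mask the matching `significance_mask`.
#' @param denominator `"all"` cells or `"responsive"` cells.
#' @return A list of class `population_fractions`: `per_trial` (one row per
#'   odor-trial pair and class), `per_odor` (one row per odor and class),
#'   and `summary` (mean and SEM per class for both reductions; per-trial
#'   SEM is reported both over odor-trial pairs and over odor means).
#' @export
population_fractions <- function(table, mask, denominator = c("all", "responsive")) {
  stopifnot(inherits(table, "reliability_table"),
            inherits(mask, "significance_mask"))
  denominator <- match.arg(denominator)
  d <- dim(mask$responded)
  resp <- mask$responded
  resp[is.na(resp)] <- FALSE
  cls <- matrix(table$class, d[1], d[2])  # table rows are cell-major

  denom <- if (denominator == "all") d[1] else {
    resp_any <- apply(resp, 1, any)
    max(sum(resp_any), 1L)
  }

  per_trial <- do.call(rbind, lapply(seq_len(d[2]), function(o) {
    do.call(rbind, lapply(seq_len(d[3]), function(t) {
      data.frame(odor = mask$labels[o], trial = t,
                 class = c("reliable", "unreliable"),
                 fraction = c(sum(resp[, o, t] & cls[, o] == "reliable"),
                              sum(resp[, o, t] & cls[, o] == "unreliable")) / denom)
    }))
  }))
  per_odor <- do.call(rbind, lapply(seq_len(d[2]), function(o) {
    data.frame(odor = mask$labels[o],
               class = c("reliable", "unreliable"),
               fraction = c(sum(cls[, o] == "reliable"),
                            sum(cls[, o] == "unreliable")) / denom)
  }))

  sem <- function(v) stats::sd(v) / sqrt(length(v))
  summ <- do.call(rbind, lapply(c("reliable", "unreliable"), function(cl) {
    pt <- per_trial$fraction[per_trial$class == cl]
    pt_odor <- tapply(per_trial$fraction[per_trial$class == cl],
                      per_trial$odor[per_trial$class == cl], mean)
    po <- per_odor$fraction[per_odor$class == cl]
    data.frame(class = cl,
               per_trial_mean = mean(pt), per_trial_sem = sem(pt),
               per_trial_sem_odors = sem(as.vector(pt_odor)),
               per_odor_mean = mean(po), per_odor_sem = sem(po))
  }))

  structure(list(per_trial = per_trial, per_odor = per_odor, summary = summ,
                 denominator = denominator),
            class = "population_fractions")
}

#' @export
print.population_fractions <- function(x, ...) {
  cat("<population_fractions> denominator:", x$denominator, "cells\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s per trial %5.2f%% +/- %.2f, per odor %5.2f%% +/- %.2f\n",
                s$class[i], 100 * s$per_trial_mean[i], 100 * s$per_trial_sem[i],
                100 * s$per_odor_mean[i], 100 * s$per_odor_sem[i]))
  invisible(x)
}

#' Sensitivity of the response statistics to the significance threshold
#'
#' Re-runs detection, classification and population fractions at each
#' threshold. Responsive counts are non-increasing in the threshold.
#'
#' @param tensor a [response_tensor()].
#' @param thresholds vector of SD multipliers (> 0).
#' @param ... passed to [detect_significant()].
#' @return A data frame with one row per threshold: responsive cell count
#'   and mean per-trial/per-odor class fractions.
#' @export
threshold_sensitivity <- function(tensor, thresholds = c(1.64, 2.33, 3.1), ...) {
  if (any(thresholds <= 0)) stop("thresholds must be > 0")
  do.call(rbind, lapply(thresholds, function(th) {
    m <- detect_significant(tensor, threshold_sd = th, ...)
    tab <- classify_cells(m)
    fr <- population_fractions(tab, m)
    s <- fr$summary
    data.frame(threshold_sd = th,
               n_responsive = sum(tab$n_responses > 0),
               reliable_per_trial = s$per_trial_mean[s$class == "reliable"],
               unreliable_per_trial = s$per_trial_mean[s$class == "unreliable"],
               reliable_per_odor = s$per_odor_mean[s$class == "reliable"],
               unreliable_per_odor = s$per_odor_mean[s$class == "unreliable"])
  }))
}
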