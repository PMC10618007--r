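#' Odor-pair overlap scores
#'
#' The overlap of a cell for an odor pair is the probability that it
#' responds to both odors: the product of its two response probabilities
#' (reliability converted to probability by dividing by the trial count).
#' A cell responding to odor A in 4 of 6 trials and to odor B in 2 of 6
#' scores (4/6)*(2/6) = 8/36 = 0.22. Pair-level overlap is the mean over
#' cells; by default over cells responsive to at least one odor of the pair.
#'
#' @param table a [classify_cells()] result.
#' @param cells which cells enter the pair mean: responsive to either odor
#'   of the pair (default), responsive to any odor, or all cells.
#' @return An object of class `overlap_matrix`: `per_cell` (one row per
#'   cell and unordered odor pair, with the cell's reliability class for the
#'   first odor), and `pair_mean` (symmetric odor x odor matrix; diagonal
#'   holds mean squared response probability).
#' @export
pairwise_overlap <- function(table,
                             cells = c("responsive_pair", "responsive_any", "all")) {
  stopifnot(inherits(table, "reliability_table"))
  cells <- match.arg(cells)
  labels <- attr(table, "labels")
  nc <- attr(table, "n_cells")
  no <- length(labels)
  p <- matrix(table$p_response, nc, no)
  cls <- matrix(as.character(table$class), nc, no)
  resp_any <- rowSums(p > 0) > 0

  per_cell <- NULL
  pair_mean <- matrix(NA_real_, no, no, dimnames = list(labels, labels))
  diag(pair_mean) <- colMeans(p^2)
  rows <- list()
  for (i in seq_len(no - 1)) for (j in (i + 1):no) {
    ov <- p[, i] * p[, j]
    keep <- switch(cells,
                   responsive_pair = p[, i] > 0 | p[, j] > 0,
                   responsive_any = resp_any,
                   all = rep(TRUE, nc))
    pair_mean[i, j] <- pair_mean[j, i] <-
      if (any(keep)) mean(ov[keep]) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      cell = table$cell[seq_len(nc)], odor_i = labels[i], odor_j = labels[j],
      p_i = p[, i], p_j = p[, j], overlap = ov,
      class_i = cls[, i], stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  per_cell <- do.call(rbind, rows)
  structure(list(per_cell = per_cell, pair_mean = pair_mean, cells = cells),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("<overlap_matrix> mean overlap over", x$cells, "cells\n")
  print(signif(x$pair_mean, 3))
  invisible(x)
}

#' Selectivity bias within a reliability level
#'
#' Observed number of cells at a given reliability level for both odors of
#' a pair, divided by the expectation if level membership were assigned at
#' random: `n_A * n_B / N` for `n_A` and `n_B` level members per odor among
#' `N` cells. A ratio above 1 means cells of that level co-respond to both
#' odors more often than chance.
#'
#' @param table a [classify_cells()] result.
#' @param odor_pair character or integer vector of two odors.
#' @param reliability_level response count defining the level (1..n_trials),
#'   or `"reliable"`/`"unreliable"` for whole classes.
#' @return A one-row data frame: `n_A`, `n_B`, `co_count`, `expected`,
#'   `bias`.
#' @export
selectivity_bias <- function(table, odor_pair, reliability_level) {
  stopifnot(inherits(table, "reliability_table"))
  labels <- attr(table, "labels")
  if (is.numeric(odor_pair)) odor_pair <- labels[odor_pair]
  a <- table[table$odor == odor_pair[1], ]
  b <- table[table$odor == odor_pair[2], ]
  in_level <- function(x) {
    if (is.character(reliability_level) &&
        reliability_level %in% c("reliable", "unreliable"))
      as.character(x$class) == reliability_level
    else x$n_responses == reliability_level
  }
  mem_a <- in_level(a); mem_b <- in_level(b)
  n_a <- sum(mem_a); n_b <- sum(mem_b)
  N <- attr(table, "n_cells")
  if (n_a == 0 || n_b == 0)
    stop("no cells at this reliability level for one of the odors")
  expected <- n_a * n_b / N
  co <- sum(mem_a & mem_b)
  data.frame(odor_i = odor_pair[1], odor_j = odor_pair[2],
             level = as.character(reliability_level),
             n_A = n_a, n_B = n_b, co_count = co,
             expected = expected, bias = co / expected,
             stringsAsFactors = FALSE)
}
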