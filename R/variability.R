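#' Trial-to-trial variability of significant responses
#'
#' Per (cell, odor) with at least two significant responses: the
#' coefficient of variation (sample SD over mean) and the Fano factor
#' (sample variance over mean) of the significant response amplitudes.
#' Sample statistics use the n-1 denominator. Cell-odors whose mean
#' significant amplitude is not positive are dropped with a warning.
#'
#' @param tensor unused placeholder; may be `NULL`.
#' @param mask a [detect_significant()] result.
#' @param table optional [classify_cells()] result supplying reliability
#'   annotations (recomputed from the mask if missing).
#' @return A data frame with one row per qualifying (cell, odor):
#'   `cell`, `odor`, `n_responses`, `mean`, `cv`, `fano`.
#' @export
variability_stats <- function(tensor, mask, table = NULL) {
  stopifnot(inherits(mask, "significance_mask"))
  if (is.null(table)) table <- classify_cells(mask)
  resp <- mask$responded
  resp[is.na(resp)] <- FALSE
  amp <- mask$response_values
  d <- dim(resp)
  rows <- list()
  dropped <- 0L
  for (o in seq_len(d[2])) for (i in seq_len(d[1])) {
    sel <- resp[i, o, ]
    if (sum(sel) < 2) next
    a <- amp[i, o, sel]
    m <- mean(a)
    if (m <= 0) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      cell = mask$cell_ids[i], odor = mask$labels[o],
      n_responses = sum(sel), mean = m,
      cv = stats::sd(a) / m, fano = stats::var(a) / m,
      stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    warning(dropped, " cell-odors dropped: non-positive mean response")
  if (!length(rows))
    return(data.frame(cell = character(0), odor = character(0),
                      n_responses = integer(0), mean = numeric(0),
                      cv = numeric(0), fano = numeric(0)))
  do.call(rbind, rows)
}

#' Split-half response-frequency analysis
#'
#' Finds cells that respond exactly once in the first half of an odor's
#' trials and reports their response frequency in the remaining trials,
#' together with the null prediction for a memoryless cell whose single
#' first-half response was typical of its rate (1 / first-half trial
#' count).
#'
#' @param mask a [detect_significant()] result.
#' @return A data frame with one row per qualifying (cell, odor):
#'   `cell`, `odor`, `second_half_frequency`; the null prediction is in
#'   `attr(, "null_frequency")`.
#' @export
split_half_frequency <- function(mask) {
  stopifnot(inherits(mask, "significance_mask"))
  resp <- mask$responded
  resp[is.na(resp)] <- FALSE
  d <- dim(resp)
  if (d[3] < 4) stop("need at least 4 trials")
  n1 <- floor(d[3] / 2)
  first <- seq_len(n1); second <- (n1 + 1L):d[3]
  rows <- list()
  for (o in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (sum(resp[i, o, first]) != 1L) next
    rows[[length(rows) + 1L]] <- data.frame(
      cell = mask$cell_ids[i], odor = mask$labels[o],
      second_half_frequency = mean(resp[i, o, second]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(cell = character(0), odor = character(0),
                         second_half_frequency = numeric(0))
  attr(out, "null_frequency") <- 1 / n1
  out
}
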