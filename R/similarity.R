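#' Odor-pair representational similarity
#'
#' Computes, per unordered odor pair, two Pearson correlations between
#' population response vectors: the mean over all cross-odor trial pairs
#' with distinct trial indices (`trial_pair_r`; 30 pairs for 6 trials per
#' odor), and the correlation of the trial-averaged vectors (`averaged_r`).
#' Averaged-vector correlations run higher than trial-pair means because
#' averaging removes trial noise. Pairs are labelled similar when the
#' chosen correlation exceeds `similar_cutoff` and dissimilar when at or
#' below `dissimilar_cutoff` (0.15 by default; 0.18 is an accepted
#' alternative bound).
#'
#' @param tensor a [response_tensor()] (used only for shape checks; the
#'   response values come from `mask`). May be `NULL`.
#' @param mask a [detect_significant()] result.
#' @param similar_cutoff,dissimilar_cutoff correlation bounds for the
#'   labels.
#' @param label_on which correlation drives the labels: `"averaged"`
#'   (default) or `"trial_pair"`.
#' @return A data frame with one row per unordered pair: `odor_i`,
#'   `odor_j`, `trial_pair_r`, `averaged_r`, `label`.
#' @export
odor_similarity <- function(tensor, mask, similar_cutoff = 0.5,
                            dissimilar_cutoff = 0.15,
                            label_on = c("averaged", "trial_pair")) {
  stopifnot(inherits(mask, "significance_mask"))
  label_on <- match.arg(label_on)
  resp <- mask$response_values
  d <- dim(resp)
  if (d[3] < 2) stop("need at least 2 trials per odor")
  labels <- mask$labels
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance population vector excluded from correlation")
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  rows <- list()
  for (i in seq_len(d[2] - 1)) for (j in (i + 1):d[2]) {
    rs <- c()
    for (ta in seq_len(d[3])) for (tb in seq_len(d[3]))
      if (ta != tb) rs <- c(rs, safe_cor(resp[, i, ta], resp[, j, tb]))
    tp <- mean(rs, na.rm = TRUE)
    av <- safe_cor(rowMeans(resp[, i, , drop = FALSE], dims = 1),
                   rowMeans(resp[, j, , drop = FALSE], dims = 1))
    r <- if (label_on == "averaged") av else tp
    lab <- if (!is.na(r) && r > similar_cutoff) "similar"
           else if (!is.na(r) && r <= dissimilar_cutoff) "dissimilar"
           else "intermediate"
    rows[[length(rows) + 1L]] <- data.frame(
      odor_i = labels[i], odor_j = labels[j],
      trial_pair_r = tp, averaged_r = av, label = lab,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Odor similarity restricted to one reliability class
#'
#' For each ordered odor pair (A, B), correlates the trial-averaged
#' responses of only those cells belonging to `reference_class` for odor A
#' (a cell reliable for A may be unreliable or silent for B; it stays in).
#' One row is emitted per ordered pair, so (A, B) and (B, A) generally
#' differ.
#'
#' @param tensor unused placeholder for interface symmetry; may be `NULL`.
#' @param mask a [detect_significant()] result.
#' @param table the matching [classify_cells()] result.
#' @param reference_class `"reliable"`, `"unreliable"`, or `"responsive"`
#'   (any responding cell; reduces to the averaged-vector correlation of
#'   [odor_similarity()] restricted to responsive cells).
#' @return A data frame with one row per ordered pair: `odor_ref`,
#'   `odor_other`, `n_cells`, `r`. Pairs whose reference class is empty are
#'   skipped with a message.
#' @export
class_restricted_similarity <- function(tensor, mask, table,
                                        reference_class = c("reliable",
                                                            "unreliable",
                                                            "responsive")) {
  stopifnot(inherits(mask, "significance_mask"),
            inherits(table, "reliability_table"))
  reference_class <- match.arg(reference_class)
  resp <- mask$response_values
  d <- dim(resp)
  labels <- mask$labels
  cls <- matrix(as.character(table$class), d[1], d[2])
  rows <- list()
  for (i in seq_len(d[2])) for (j in seq_len(d[2])) {
    if (i == j) next
    keep <- if (reference_class == "responsive") cls[, i] != "silent"
            else cls[, i] == reference_class
    if (sum(keep) < 3) {
      message("pair (", labels[i], ", ", labels[j], ") skipped: fewer than 3 ",
              reference_class, " cells for ", labels[i])
      next
    }
    a <- rowMeans(resp[keep, i, , drop = FALSE], dims = 1)
    b <- rowMeans(resp[keep, j, , drop = FALSE], dims = 1)
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      odor_ref = labels[i], odor_other = labels[j],
      n_cells = sum(keep), r = r, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Cosine similarity of top-percentile responsive cells
#'
#' For each odor, responsive cells are ranked by expected response and the
#' top `p`% retained; for each odor pair and percentile the cosine
#' similarity of the trial-averaged response vectors is computed over the
#' union of the two odors' top sets. With `bands = TRUE` the disjoint
#' quartile bands (0-25, 25-50, 50-75, 75-100) are used instead of the
#' nested top sets.
#'
#' @param tensor unused placeholder; may be `NULL`.
#' @param mask a [detect_significant()] result.
#' @param table the matching [classify_cells()] result.
#' @param percentiles top percentages of responsive cells (default
#'   25, 50, 75, 100).
#' @param bands use disjoint quartile bands instead of nested top sets.
#' @return A data frame with one row per (odor pair, percentile):
#'   `odor_i`, `odor_j`, `percentile`, `n_cells`, `cosine`.
#' @export
percentile_similarity <- function(tensor, mask, table,
                                  percentiles = c(25, 50, 75, 100),
                                  bands = FALSE) {
  stopifnot(inherits(mask, "significance_mask"),
            inherits(table, "reliability_table"))
  resp <- mask$response_values
  d <- dim(resp)
  labels <- mask$labels
  nresp <- matrix(table$n_responses, d[1], d[2])
  eresp <- matrix(table$expected_response, d[1], d[2])
  avg <- rowMeans(resp, dims = 2)  # cell x odor

  top_set <- function(o, p_lo, p_hi) {
    responsive <- which(nresp[, o] > 0)
    if (!length(responsive)) stop("no responsive cells for odor ", labels[o])
    ord <- responsive[order(eresp[responsive, o], decreasing = TRUE)]
    n <- length(ord)
    lo <- floor(n * p_lo / 100) + 1L
    hi <- max(ceiling(n * p_hi / 100), lo)
    ord[lo:min(hi, n)]
  }
  cosine <- function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(0)
    sum(x * y) / (nx * ny)
  }
  specs <- if (bands) Map(c, c(0, 25, 50, 75), c(25, 50, 75, 100))
           else lapply(percentiles, function(p) c(0, p))
  rows <- list()
  for (i in seq_len(d[2] - 1)) for (j in (i + 1):d[2]) {
    for (sp in specs) {
      si <- top_set(i, sp[1], sp[2]); sj <- top_set(j, sp[1], sp[2])
      u <- union(si, sj)
      rows[[length(rows) + 1L]] <- data.frame(
        odor_i = labels[i], odor_j = labels[j],
        percentile = if (bands) paste0(sp[1], "-", sp[2]) else sp[2],
        n_cells = length(u),
        cosine = cosine(avg[u, i], avg[u, j]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
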