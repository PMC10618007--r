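#' Trial-resolved response tensor
#'
#' The exchange object between all pipeline stages: fractional-fluorescence
#' (dF/F) values indexed by (cell, odor, trial, frame), plus the frame-time
#' metadata needed to locate the pre-odor baseline and the response window.
#'
#' @param values 4-d numeric array, dimensions cell x odor x trial x frame.
#'   All values must be finite.
#' @param frame_duration length of one frame in seconds.
#' @param odor_onset_frame index of the first frame with odor present; must
#'   lie strictly inside the frame range.
#' @param labels optional odor identifiers (defaults to `odor1`, `odor2`, ...).
#' @param cell_ids optional cell identifiers.
#' @param latent optional list of latent generator fields (see
#'   [generate_responses()]); carried along for diagnostics only.
#'
#' @return An object of class `response_tensor`.
#' @seealso [generate_responses()], [detect_significant()],
#'   [write_tensor_csv()]
#' @export
response_tensor <- function(values, frame_duration, odor_onset_frame,
                            labels = NULL, cell_ids = NULL, latent = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("`values` must be a 4-d array (cell x odor x trial x frame)")
  if (!all(is.finite(values)))
    stop("response tensor contains non-finite values")
  d <- dim(values)
  if (any(d < 1L)) stop("all tensor dimensions must be positive")
  if (odor_onset_frame <= 1L || odor_onset_frame > d[4])
    stop("`odor_onset_frame` must lie strictly inside the frame range")
  if (frame_duration <= 0) stop("`frame_duration` must be positive")
  if (is.null(labels)) labels <- paste0("odor", seq_len(d[2]))
  if (length(labels) != d[2]) stop("`labels` length must equal the odor dimension")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(d[1]))
  structure(
    list(values = values,
         frame_duration = frame_duration,
         odor_onset_frame = as.integer(odor_onset_frame),
         labels = as.character(labels),
         cell_ids = as.character(cell_ids),
         latent = latent),
    class = "response_tensor")
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<response_tensor> ", d[1], " cells x ", d[2], " odors x ",
      d[3], " trials x ", d[4], " frames\n", sep = "")
  cat("  frame duration: ", x$frame_duration, " s; odor onset at frame ",
      x$odor_onset_frame, "\n", sep = "")
  cat("  odors: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.response_tensor <- function(object, ...) {
  d <- dim(object$values)
  cat("response tensor: ", paste(d, collapse = " x "),
      " (cell, odor, trial, frame)\n", sep = "")
  cat("dF/F range: [", signif(min(object$values), 3), ", ",
      signif(max(object$values), 3), "]\n", sep = "")
  cat("baseline period: frames 1-", object$odor_onset_frame - 1L,
      " (", (object$odor_onset_frame - 1L) * object$frame_duration, " s)\n",
      sep = "")
  invisible(object)
}

#' @export
dim.response_tensor <- function(x) dim(x$values)

#' Long-format view of a response tensor
#'
#' @param x a [response_tensor()].
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @return A data frame with columns `cell`, `odor`, `trial`, `frame`, `dF_F`.
#' @export
as.data.frame.response_tensor <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  d <- dim(x$values)
  out <- expand.grid(cell = x$cell_ids,
                     odor = x$labels,
                     trial = seq_len(d[3]),
                     frame = seq_len(d[4]),
                     KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$dF_F <- as.vector(x$values)
  out
}

#' Write / read a response tensor as long-format CSV
#'
#' The CSV carries one row per (cell, odor, trial, frame) plus a short header
#' of commented metadata lines, and round-trips losslessly through
#' [read_tensor_csv()].
#'
#' @param tensor a [response_tensor()].
#' @param path file path.
#' @return `write_tensor_csv()` returns `path` invisibly; `read_tensor_csv()`
#'   returns a [response_tensor()].
#' @export
write_tensor_csv <- function(tensor, path) {
  stopifnot(inherits(tensor, "response_tensor"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# frame_duration=", format(tensor$frame_duration, digits = 17)),
    paste0("# odor_onset_frame=", tensor$odor_onset_frame)), con)
  utils::write.csv(as.data.frame(tensor), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tensor_csv
#' @export
read_tensor_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (!all(startsWith(hdr, "# ")))
    stop("not a tensor CSV: metadata header lines missing")
  meta <- sub("^# ", "", hdr)
  frame_duration <- as.numeric(sub("frame_duration=", "", meta[1]))
  onset <- as.integer(sub("odor_onset_frame=", "", meta[2]))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cell", "odor", "trial", "frame", "dF_F")
  if (!all(need %in% names(df)))
    stop("tensor CSV must contain columns: ", paste(need, collapse = ", "))
  cells <- unique(df$cell)
  odors <- unique(df$odor)
  trials <- sort(unique(df$trial))
  frames <- sort(unique(df$frame))
  expected <- length(cells) * length(odors) * length(trials) * length(frames)
  if (nrow(df) != expected)
    stop("tensor CSV is incomplete: expected ", expected,
         " rows for a full (cell, odor, trial, frame) grid, found ", nrow(df))
  per_odor <- tapply(df$trial, df$odor, function(t) length(unique(t)))
  if (length(unique(per_odor)) != 1L)
    stop("trial counts differ across odors")
  idx <- cbind(match(df$cell, cells), match(df$odor, odors),
               match(df$trial, trials), match(df$frame, frames))
  values <- array(NA_real_,
                  c(length(cells), length(odors), length(trials), length(frames)))
  values[idx] <- df$dF_F
  if (anyNA(values)) stop("tensor CSV has missing (cell, odor, trial, frame) cells")
  response_tensor(values, frame_duration, onset,
                  labels = odors, cell_ids = cells)
}
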