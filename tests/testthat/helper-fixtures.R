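# Shared fixtures, all built in code.

# Five-cell, four-trial response pattern with 2 reliable cells (3/4 trials
# each), one 2/4 unreliable cell and two single-trial unreliable cells:
# per trial exactly 1 unreliable and on average 1.5 reliable cells respond.
toy_mask_5x4 <- function() {
  resp <- array(FALSE, c(5, 1, 4))
  resp[1, 1, 1:3] <- TRUE
  resp[2, 1, 2:4] <- TRUE
  resp[3, 1, 1:2] <- TRUE
  resp[4, 1, 3] <- TRUE
  resp[5, 1, 4] <- TRUE
  resp
}

# Tensor with a single controllable response value: baseline frames have
# sample mean 0 and sample sd exactly 1 (response window is one frame).
boundary_tensor <- function(response_value, n_trials = 2) {
  a <- sqrt(19 / 20)                       # 20 frames at +/- a: sd(n-1) = 1
  base <- rep(c(a, -a), 10)
  vals <- array(0, c(1, 1, n_trials, 21))
  for (t in seq_len(n_trials)) vals[1, 1, t, 1:20] <- base
  vals[1, 1, , 21] <- response_value
  response_tensor(vals, frame_duration = 0.5, odor_onset_frame = 21)
}

# A reliability table built directly from counts (cells x odors matrix) and
# optional amplitude matrix, bypassing detection.
table_from_counts <- function(counts, n_trials, amps = NULL) {
  resp <- array(FALSE, c(nrow(counts), ncol(counts), n_trials))
  for (i in seq_len(nrow(counts))) for (o in seq_len(ncol(counts)))
    if (counts[i, o] > 0) resp[i, o, seq_len(counts[i, o])] <- TRUE
  vals <- if (is.null(amps)) resp + 0 else {
    v <- array(0, dim(resp))
    for (t in seq_len(n_trials)) v[, , t] <- amps
    v * resp
  }
  classify_cells(resp, response_values = vals)
}
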