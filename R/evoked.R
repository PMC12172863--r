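# Epoch averaging and the gradiometer RMS time course.

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus baseline
#' interval \[-50, 0) ms (the stimulus sample itself is excluded). Idempotent.
#'
#' @param epochs A `sef_epochs`.
#' @return The epochs with zero-mean baselines.
#' @export
baseline_correct <- function(epochs) {
  bl <- which(epochs$times >= -50 & epochs$times < 0)
  if (length(bl) < 1 || min(epochs$times) > -50)
    stop("epochs lack the [-50, 0) ms baseline interval")
  m <- rowMeans(epochs$data[, , bl, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - as.vector(m)
  epochs
}

#' Average epochs into an evoked response
#'
#' @param epochs A `sef_epochs` (>= 1 epoch).
#' @return A `sef_evoked`: `data` (channels x samples), `times` (ms),
#'   `n_ave`, `ch_kind`.
#' @export
average_epochs <- function(epochs) {
  n <- dim(epochs$data)[1]
  if (is.na(n) || n < 1) stop("no epochs to average")
  structure(list(data = colMeans(epochs$data), times = epochs$times,
                 n_ave = n, ch_kind = epochs$ch_kind),
            class = "sef_evoked")
}

#' @export
print.sef_evoked <- function(x, ...) {
  cat(sprintf("sef_evoked: %d channels x %d samples, n_ave=%d\n",
              nrow(x$data), ncol(x$data), x$n_ave))
  invisible(x)
}

#' Per-sample RMS over a channel subset
#'
#' `sqrt((x_1^2 + ... + x_nchan^2) / nchan)` at each sample, over the masked
#' channels — the field-gradient RMS when the mask selects the 204 planar
#' gradiometers.
#'
#' @param evoked A `sef_evoked`.
#' @param channel_mask Logical or integer channel selector (>= 1 channel);
#'   default: all gradiometers.
#' @return Numeric vector, one RMS value per sample.
#' @export
rms_time_course <- function(evoked, channel_mask = NULL) {
  if (is.null(channel_mask)) channel_mask <- evoked$ch_kind == "grad"
  x <- evoked$data[channel_mask, , drop = FALSE]
  if (nrow(x) < 1) stop("`channel_mask` selects no channels")
  sqrt(colMeans(x^2))
}

#' Time of maximum gradiometer RMS
#'
#' Returns the time of the maximum gradiometer RMS within the closed window
#' (default 15–60 ms post-stimulus, where early somatosensory responses
#' localize to primary somatosensory cortex). Earliest sample wins ties.
#'
#' @param evoked A `sef_evoked`.
#' @param window Closed time window, ms.
#' @return Time in ms.
#' @export
pmax_time <- function(evoked, window = c(15, 60)) {
  sel <- which(evoked$times >= window[1] & evoked$times <= window[2])
  if (!length(sel)) stop("window outside the evoked time axis")
  r <- rms_time_course(evoked)
  evoked$times[sel[which.max(r[sel])]]
}
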