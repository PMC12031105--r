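#' Frequency band definitions
#'
#' The four canonical EEG bands used throughout: delta 1-3 Hz,
#' theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz.
#'
#' @return Named list of `c(low, high)` band edges in Hz.
#' @export
default_bands <- function() {
  list(
    delta = c(1, 3),
    theta = c(4, 8),
    alpha = c(8, 12),
    beta = c(12, 30)
  )
}

check_band <- function(band, fs) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    stop(sprintf(
      "band (%g, %g) Hz must satisfy 0 < low < high < Nyquist (%g)",
      band[1], band[2], fs / 2
    ))
  }
}

#' Resample a recording
#'
#' Anti-aliased polyphase resampling of every channel; only
#' downsampling (or the identity) is supported.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz, `<= rec$fs`.
#' @return The resampled [recording()] with metadata preserved.
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs > rec$fs) stop("upsampling not supported")
  if (target_fs == rec$fs) {
    return(rec)
  }
  # integer p/q (rates here are rational)
  scale <- 1000L
  p <- round(target_fs * scale)
  q <- round(rec$fs * scale)
  g <- gcd_int(p, q)
  p <- p %/% g
  q <- q %/% g
  n_out <- floor(ncol(rec$data) * target_fs / rec$fs)
  out <- t(apply(rec$data, 1L, function(x) {
    if (p == 1L) {
      # integer decimation: anti-aliased zero-phase (no group delay)
      signal::decimate(x, q)[seq_len(n_out)]
    } else {
      signal::resample(x, p, q)[seq_len(n_out)]
    }
  }))
  recording(out, fs = target_fs, channel_labels = rec$channel_labels,
    meta = rec$meta)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

zero_phase_filter <- function(filt, x) {
  signal::filtfilt(filt, x)
}

#' Broadband band-pass plus mains notch filtering
#'
#' Zero-phase Butterworth band-pass (default 1-75 Hz) followed by a
#' zero-phase Butterworth band-stop around the mains frequency
#' (default 49-51 Hz), applied per channel.
#'
#' @param rec A [recording()].
#' @param band Pass band `c(low, high)` in Hz.
#' @param notch Stop band `c(low, high)` in Hz, or `NULL` to skip.
#' @param order Butterworth order (applied forward-backward).
#' @return Filtered [recording()].
#' @export
filter_broadband <- function(rec, band = c(1, 75), notch = c(49, 51),
                             order = 4L) {
  check_band(band, rec$fs)
  bp <- signal::butter(order, band / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1L, function(x) zero_phase_filter(bp, x)))
  if (!is.null(notch)) {
    check_band(notch, rec$fs)
    bs <- signal::butter(order, notch / (rec$fs / 2), type = "stop")
    out <- t(apply(out, 1L, function(x) zero_phase_filter(bs, x)))
  }
  recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
    meta = rec$meta)
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean over channels from every channel,
#' so each output sample column sums to zero.
#'
#' @param rec A [recording()] with at least two channels.
#' @return Re-referenced [recording()].
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2L) stop("average reference requires >= 2 channels")
  out <- sweep(rec$data, 2L, colMeans(rec$data))
  recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
    meta = rec$meta)
}

#' Decompose a recording into frequency bands
#'
#' One zero-phase Butterworth band-pass copy of the recording per
#' band.
#'
#' @param rec A [recording()].
#' @param bands Named list of band edges as in [default_bands()].
#' @param order Butterworth order.
#' @return Named list of band-limited [recording()]s.
#' @export
band_decompose <- function(rec, bands = default_bands(), order = 4L) {
  lapply(bands, function(band) {
    check_band(band, rec$fs)
    bp <- signal::butter(order, band / (rec$fs / 2), type = "pass")
    out <- t(apply(rec$data, 1L, function(x) zero_phase_filter(bp, x)))
    recording(out, fs = rec$fs, channel_labels = rec$channel_labels,
      meta = rec$meta)
  })
}

#' Segment a recording into fixed-length epochs
#'
#' Splits the recording into non-overlapping windows of
#' `window_seconds`; a trailing partial window is discarded. Labels
#' and task tags are copied from the recording metadata.
#'
#' @param rec A [recording()].
#' @param window_seconds Epoch length in seconds.
#' @return An `epoch_set`: list with `epochs` (array
#'   n_epochs x channels x samples), `labels`, `task_tags`, `fs`,
#'   `channel_labels` and optional `band` tag.
#' @export
segment_epochs <- function(rec, window_seconds = 3) {
  ws <- round(window_seconds * rec$fs)
  n_ep <- floor(ncol(rec$data) / ws)
  if (n_ep < 1L) stop("recording shorter than one window")
  epochs <- array(0, dim = c(n_ep, nrow(rec$data), ws))
  for (e in seq_len(n_ep)) {
    epochs[e, , ] <- rec$data[, ((e - 1L) * ws + 1L):(e * ws)]
  }
  level <- rec$meta$level %||% NA_character_
  task <- rec$meta$task %||% NA_character_
  epoch_set(
    epochs = epochs,
    labels = rep(level, n_ep),
    task_tags = rep(task, n_ep),
    fs = rec$fs,
    channel_labels = rec$channel_labels
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Epoch set constructor
#'
#' @param epochs Array n_epochs x channels x samples.
#' @param labels Workload level per epoch.
#' @param task_tags Task name per epoch.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Montage labels.
#' @param band Optional band tag.
#' @export
epoch_set <- function(epochs, labels, task_tags, fs, channel_labels = NULL,
                      band = NULL) {
  stopifnot(length(dim(epochs)) == 3L)
  n_ep <- dim(epochs)[1]
  stopifnot(length(labels) == n_ep, length(task_tags) == n_ep)
  structure(
    list(
      epochs = epochs, labels = labels, task_tags = task_tags, fs = fs,
      channel_labels = channel_labels, band = band
    ),
    class = "epoch_set"
  )
}

#' Concatenate epoch sets
#' @param sets List of `epoch_set`s with identical channel/sample dims.
#' @export
bind_epoch_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  dims <- dim(sets[[1]]$epochs)[2:3]
  for (s in sets) stopifnot(all(dim(s$epochs)[2:3] == dims))
  total <- sum(vapply(sets, function(s) dim(s$epochs)[1], integer(1)))
  epochs <- array(0, dim = c(total, dims))
  at <- 1L
  for (s in sets) {
    k <- dim(s$epochs)[1]
    epochs[at:(at + k - 1L), , ] <- s$epochs
    at <- at + k
  }
  epoch_set(
    epochs = epochs,
    labels = unlist(lapply(sets, `[[`, "labels")),
    task_tags = unlist(lapply(sets, `[[`, "task_tags")),
    fs = sets[[1]]$fs,
    channel_labels = sets[[1]]$channel_labels,
    band = sets[[1]]$band
  )
}

#' Standard preprocessing chain
#'
#' Applies the full pipeline to one raw recording: resample to
#' `target_fs`, broadband + notch filter, common-average reference,
#' band decomposition, and 3-s segmentation of each band copy.
#' Externally cleaned data (artifact-removed) can be passed directly;
#' no artifact correction is attempted here.
#'
#' @param rec A raw [recording()].
#' @param target_fs Analysis sampling rate (Hz).
#' @param window_seconds Epoch length in seconds.
#' @param bands Band definition list.
#' @param broadband,notch Broadband filter edges; `NULL` notch skips.
#' @param rereference Apply common-average reference.
#' @return Named list of band `epoch_set`s, with the applied step
#'   order recorded in `attr(, "pipeline")`.
#' @export
preprocess_recording <- function(rec, target_fs = 200, window_seconds = 3,
                                 bands = default_bands(),
                                 broadband = c(1, 75), notch = c(49, 51),
                                 rereference = TRUE) {
  steps <- character()
  if (target_fs < rec$fs) {
    rec <- resample_recording(rec, target_fs)
    steps <- c(steps, sprintf("resample:%g", target_fs))
  }
  rec <- filter_broadband(rec, band = broadband, notch = notch)
  steps <- c(steps, "broadband+notch")
  if (rereference) {
    rec <- rereference_average(rec)
    steps <- c(steps, "average-reference")
  }
  per_band <- band_decompose(rec, bands)
  steps <- c(steps, "band-decompose")
  out <- lapply(names(per_band), function(b) {
    es <- segment_epochs(per_band[[b]], window_seconds)
    es$band <- b
    es
  })
  steps <- c(steps, sprintf("segment:%gs", window_seconds))
  out <- stats::setNames(out, names(per_band))
  attr(out, "pipeline") <- steps
  out
}
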