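#' Band-integrated power via segment-averaged periodograms
#'
#' FFT power spectral density with non-overlapping Hamming-windowed
#' segments (Welch with zero overlap), integrated over the requested
#' band: `sum(PSD[band bins]) * df`. One-sided density normalisation
#' `2 |X_k|^2 / (fs * sum(w^2))`, so a full-range integral recovers
#' the signal's mean square (Parseval) and an in-band sinusoid of
#' amplitude A yields approximately `A^2 / 2`.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param band `c(low, high)` in Hz; must be resolvable, i.e. contain
#'   at least one frequency bin and lie below Nyquist.
#' @param seg_seconds Segment length in seconds (default 1 s).
#' @return Band power in signal-units squared.
#' @export
psd_power <- function(x, fs, band, seg_seconds = 1) {
  nseg <- floor(seg_seconds * fs)
  if (length(x) < nseg) stop("signal shorter than one PSD segment")
  if (band[2] > fs / 2 || band[1] < 0 || band[1] >= band[2]) {
    stop("band outside resolvable frequencies")
  }
  k <- floor(length(x) / nseg)
  w <- hamming_window(nseg)
  wnorm <- fs * sum(w^2)
  nfreq <- floor(nseg / 2)
  acc <- numeric(nfreq + 1L)
  for (s in seq_len(k)) {
    seg <- x[((s - 1L) * nseg + 1L):(s * nseg)] * w
    spec <- abs(stats::fft(seg)[1:(nfreq + 1L)])^2
    acc <- acc + spec
  }
  psd <- acc / (k * wnorm)
  # one-sided doubling except DC and (for even nseg) Nyquist
  dbl <- rep(2, nfreq + 1L)
  dbl[1] <- 1
  if (nseg %% 2L == 0L) dbl[nfreq + 1L] <- 1
  psd <- psd * dbl
  freqs <- (0:nfreq) * fs / nseg
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("band contains no frequency bin at this resolution")
  df <- fs / nseg
  sum(psd[sel]) * df
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Differential entropy under a Gaussian model
#'
#' For a time series modelled as Gaussian with variance `s2`, the
#' differential entropy is `0.5 * log(2 * pi * e * s2)` nats; `s2` is
#' estimated by the sample variance of the epoch signal.
#'
#' @param x Numeric signal of length >= 2.
#' @return Differential entropy in nats.
#' @export
differential_entropy <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  s2 <- stats::var(x)
  if (s2 <= 0) stop("zero-variance signal has no finite differential entropy")
  0.5 * log(2 * pi * exp(1) * s2)
}

#' Node feature tensor: (PSD, DE) per epoch, band and channel
#'
#' For each epoch of each band-limited epoch set, computes the
#' band-integrated power and the differential entropy of every
#' channel.
#'
#' @param band_epochs Named list of band `epoch_set`s (one per band,
#'   same epochs in the same order), as from [preprocess_recording()].
#' @param bands Band edge list matching `names(band_epochs)`.
#' @param seg_seconds Welch segment length in seconds.
#' @return Array `n_epochs x n_bands x n_channels x 2` (PSD, DE), with
#'   dimnames on the band and feature axes.
#' @export
build_node_features <- function(band_epochs, bands = default_bands(),
                                seg_seconds = 1) {
  band_names <- names(bands)
  missing <- setdiff(band_names, names(band_epochs))
  if (length(missing)) {
    stop("missing band epoch sets: ", paste(missing, collapse = ", "))
  }
  first <- band_epochs[[band_names[1]]]
  n_ep <- dim(first$epochs)[1]
  n_ch <- dim(first$epochs)[2]
  out <- array(0, dim = c(n_ep, length(band_names), n_ch, 2L),
    dimnames = list(NULL, band_names, NULL, c("psd", "de")))
  for (b in seq_along(band_names)) {
    es <- band_epochs[[band_names[b]]]
    stopifnot(dim(es$epochs)[1] == n_ep, dim(es$epochs)[2] == n_ch)
    band <- bands[[band_names[b]]]
    for (e in seq_len(n_ep)) {
      for (ch in seq_len(n_ch)) {
        x <- es$epochs[e, ch, ]
        out[e, b, ch, 1L] <- psd_power(x, es$fs, band, seg_seconds)
        s2 <- stats::var(x)
        out[e, b, ch, 2L] <- if (s2 > 0) {
          0.5 * log(2 * pi * exp(1) * s2)
        } else {
          NA_real_
        }
      }
    }
  }
  if (anyNA(out)) stop("degenerate (constant) channel epoch encountered")
  out
}
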