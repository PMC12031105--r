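#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal, computed by the FFT half-spectrum
#' method: zero the negative frequencies, double the positive ones,
#' inverse-transform, take `Arg`. Meaningful for band-limited input
#' (use after [band_decompose()]).
#'
#' @param x Numeric band-limited signal.
#' @return Phase series in `(-pi, pi]`, same length as `x`.
#' @export
instantaneous_phase <- function(x) {
  if (stats::var(x) == 0) stop("constant signal has no instantaneous phase")
  Arg(analytic_signal(x))
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

wrap_phase <- function(d) atan2(sin(d), cos(d))

#' Phase locking value
#'
#' Magnitude of the time-averaged unit phasor of the phase
#' difference: `|mean(exp(1i * (phase_x - phase_y)))|`. 1 means
#' perfect phase synchrony; offset-invariant.
#'
#' @param phase_x,phase_y Phase series (radians) of equal length >= 2.
#' @return Value in \[0, 1\].
#' @export
plv <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) stop("phase series length mismatch")
  if (length(phase_x) < 2L) stop("need at least 2 samples")
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Phase lag index
#'
#' Absolute time-average of the sign of the phase difference wrapped
#' to `(-pi, pi]`, with `sign(0) = 0`. Insensitive to zero-lag
#' coupling; 1 when one signal consistently leads.
#'
#' @param phase_x,phase_y Phase series (radians) of equal length >= 2.
#' @return Value in \[0, 1\].
#' @export
pli <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) stop("phase series length mismatch")
  if (length(phase_x) < 2L) stop("need at least 2 samples")
  abs(mean(sign(wrap_phase(phase_x - phase_y))))
}

#' Pearson correlation between two signals
#'
#' @param x,y Numeric signals of equal length >= 2 with nonzero
#'   variance.
#' @return Pearson correlation in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("signal length mismatch")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero-variance signal in correlation")
  }
  stats::cor(x, y)
}

#' Histogram mutual information
#'
#' Plug-in estimate `I = H(X) + H(Y) - H(X, Y)` in bits, with
#' marginal and joint entropies from equal-width histograms over each
#' signal's observed range.
#'
#' @param x,y Numeric signals of equal length.
#' @param n_bins Number of equal-width bins per signal (>= 2).
#' @return Mutual information in bits (>= 0 up to floating error).
#' @export
mutual_information <- function(x, y, n_bins = 16L) {
  if (length(x) != length(y)) stop("signal length mismatch")
  if (n_bins < 2L) stop("need at least 2 bins")
  bx <- bin_index(x, n_bins)
  by <- bin_index(y, n_bins)
  if (is.null(bx) || is.null(by)) {
    warning("constant signal: mutual information undefined, returning 0")
    return(0)
  }
  n <- length(x)
  joint <- tabulate(bx + n_bins * (by - 1L), nbins = n_bins * n_bins) / n
  px <- tabulate(bx, nbins = n_bins) / n
  py <- tabulate(by, nbins = n_bins) / n
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  ent(px) + ent(py) - ent(joint)
}

bin_index <- function(x, n_bins) {
  r <- range(x)
  if (r[1] == r[2]) {
    return(NULL)
  }
  idx <- floor((x - r[1]) / (r[2] - r[1]) * n_bins) + 1L
  idx[idx > n_bins] <- n_bins
  as.integer(idx)
}

#' Connectivity matrices for a band epoch set
#'
#' One symmetric channels x channels matrix per epoch, with zero
#' diagonal, under the chosen estimator. PLV/PLI work on analytic
#' phases; PCC is stored as `|rho|` (the signed matrix is kept in
#' `attr(, "signed")`); MI uses equal-width histogram bins.
#'
#' @param es A band-limited `epoch_set` (>= 2 channels).
#' @param method One of `"plv"`, `"pli"`, `"pcc"`, `"mi"`.
#' @param n_bins Histogram bins for MI.
#' @param average_epochs If `TRUE`, return the single mean matrix over
#'   epochs instead of one per epoch.
#' @return List of `connectivity_matrix` objects (matrices with
#'   `method`, `band`, `epoch` attributes), or one such matrix if
#'   `average_epochs`.
#' @export
connectivity_matrix <- function(es, method = c("plv", "pli", "pcc", "mi"),
                                n_bins = 16L, average_epochs = FALSE) {
  method <- match.arg(method)
  n_ep <- dim(es$epochs)[1]
  n_ch <- dim(es$epochs)[2]
  if (n_ch < 2L) stop("connectivity needs >= 2 channels")
  mats <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    X <- es$epochs[e, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = n_ch)
    M <- switch(method,
      plv = plv_matrix(X),
      pli = pli_matrix(X),
      pcc = pcc_matrix(X),
      mi = mi_matrix(X, n_bins)
    )
    signed <- attr(M, "signed")
    diag(M) <- 0
    M <- (M + t(M)) / 2 # enforce exact symmetry against rounding
    attr(M, "method") <- method
    attr(M, "band") <- es$band
    attr(M, "epoch") <- e
    attr(M, "signed") <- signed
    class(M) <- c("connectivity_matrix", class(M))
    mats[[e]] <- M
  }
  if (average_epochs) {
    avg <- Reduce(`+`, lapply(mats, unclass)) / n_ep
    attr(avg, "method") <- method
    attr(avg, "band") <- es$band
    class(avg) <- c("connectivity_matrix", class(avg))
    return(avg)
  }
  mats
}

phase_matrix <- function(X) {
  t(apply(X, 1L, instantaneous_phase))
}

plv_matrix <- function(X) {
  P <- phase_matrix(X)
  U <- exp(1i * P)
  M <- Mod(U %*% Conj(t(U))) / ncol(P)
  M
}

pli_matrix <- function(X) {
  P <- phase_matrix(X)
  n_ch <- nrow(P)
  M <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_ch - 1L)) {
    d <- sweep(-P[(i + 1L):n_ch, , drop = FALSE], 2L, -P[i, ])
    v <- abs(rowMeans(sign(wrap_phase(d))))
    M[i, (i + 1L):n_ch] <- v
    M[(i + 1L):n_ch, i] <- v
  }
  M
}

pcc_matrix <- function(X) {
  R <- stats::cor(t(X))
  M <- abs(R)
  attr(M, "signed") <- R
  M
}

mi_matrix <- function(X, n_bins) {
  n_ch <- nrow(X)
  M <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_ch - 1L)) {
    for (j in (i + 1L):n_ch) {
      v <- mutual_information(X[i, ], X[j, ], n_bins)
      M[i, j] <- v
      M[j, i] <- v
    }
  }
  M
}
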