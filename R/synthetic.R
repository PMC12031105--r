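#' Session protocol for synthetic EEG generation
#'
#' Describes the acquisition protocol emulated by [generate_session()]:
#' a montage of `n_channels` electrodes recorded at `fs_acquisition`,
#' with `n_rounds` rounds of `tasks` x `levels` blocks of
#' `block_duration` seconds each.
#'
#' @param n_channels Number of EEG channels (>= 2).
#' @param fs_acquisition Acquisition sampling rate in Hz.
#' @param n_rounds Number of experimental rounds.
#' @param tasks Character vector of task paradigm names.
#' @param levels Character vector of workload level names, ordered
#'   low to high.
#' @param block_duration Duration of one task-level block in seconds.
#' @param seed Base integer seed; per-subject seeds are derived as
#'   `seed + subject_index`.
#'
#' @return An object of class `session_protocol`.
#' @export
session_protocol <- function(n_channels = 59L,
                             fs_acquisition = 1000,
                             n_rounds = 3L,
                             tasks = c("nback", "ma", "sternberg"),
                             levels = c("low", "medium", "high"),
                             block_duration = 120,
                             seed = 1L) {
  if (n_channels < 2L) stop("protocol requires at least 2 channels")
  if (block_duration <= 0) stop("block_duration must be positive")
  if (length(tasks) == 0L || length(levels) == 0L) {
    stop("tasks and levels must be non-empty")
  }
  structure(
    list(
      n_channels = as.integer(n_channels),
      fs_acquisition = fs_acquisition,
      n_rounds = as.integer(n_rounds),
      tasks = tasks,
      levels = levels,
      block_duration = block_duration,
      seed = as.integer(seed)
    ),
    class = "session_protocol"
  )
}

#' Band-specific coupling specification
#'
#' Ground-truth substrate for the connectivity estimators: a set of
#' channel pairs that share their oscillatory phase in one frequency
#' band, plus per-level oscillation amplitudes and a noise floor.
#'
#' @param band One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @param pairs A data.frame with columns `i`, `j` (1-based channel
#'   indices, `i != j`), `coupling` in \[0, 1\] (fraction of samples on
#'   which channel `j` copies channel `i`'s phase) and `lag` (phase
#'   lag in radians applied on coupled samples). May have zero rows.
#' @param amplitude_by_level Named numeric vector mapping workload
#'   level to the band oscillation amplitude (signal units, nominally
#'   microvolts).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   contributed by this band's generator (applied once per channel
#'   overall, see [generate_session()]).
#' @param freq Representative oscillation frequency in Hz; defaults to
#'   the band centre used throughout the package (delta 2, theta 6,
#'   alpha 10, beta 20).
#' @param phase_jitter Per-sample standard deviation (radians) of the
#'   phase-diffusion increment.
#'
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(band,
                          pairs = empty_pairs(),
                          amplitude_by_level = c(low = 10, medium = 10, high = 10),
                          noise_sd = 5,
                          freq = NULL,
                          phase_jitter = 0.1) {
  band <- match.arg(band, names(band_center_freqs()))
  if (is.null(freq)) freq <- band_center_freqs()[[band]]
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) > 0L) {
    stopifnot(all(c("i", "j", "coupling", "lag") %in% names(pairs)))
    if (any(pairs$i == pairs$j)) stop("coupled pair must join distinct channels")
    if (any(pairs$coupling < 0 | pairs$coupling > 1)) {
      stop("coupling strength must lie in [0, 1]")
    }
  }
  structure(
    list(
      band = band,
      pairs = pairs,
      amplitude_by_level = amplitude_by_level,
      noise_sd = noise_sd,
      freq = freq,
      phase_jitter = phase_jitter
    ),
    class = "coupling_spec"
  )
}

#' @rdname coupling_spec
#' @export
empty_pairs <- function() {
  data.frame(i = integer(), j = integer(), coupling = numeric(), lag = numeric())
}

band_center_freqs <- function() {
  c(delta = 2, theta = 6, alpha = 10, beta = 20)
}

#' Phase-diffusion oscillator
#'
#' Phase track advancing by `2*pi*freq/fs` per sample plus Gaussian
#' jitter, so the instantaneous phase is analytically known while the
#' signal is not perfectly periodic. The initial phase is uniform on
#' the circle: without it every oscillator would cold-start at phase
#' zero and uncoupled channel pairs would begin each block
#' phase-aligned, distorting low-coupling phase statistics.
#'
#' @keywords internal
phase_walk <- function(n, freq, fs, jitter) {
  inc <- 2 * pi * freq / fs + rnorm(n, sd = jitter)
  stats::runif(1, 0, 2 * pi) + cumsum(inc)
}

#' Generate one pair of phase-coupled oscillatory signals
#'
#' Channel `x` is a phase-diffusion sinusoid; channel `y` copies `x`'s
#' phase (offset by `phase_lag`) on a Bernoulli(`coupling`) subset of
#' samples and follows its own independent phase walk elsewhere, so
#' that the expected phase-locking value equals approximately
#' `coupling` and is exactly 1 at full coupling.
#'
#' @param freq Oscillation frequency in Hz, below Nyquist.
#' @param phase_lag Phase lag (radians) of `y` relative to `x` on
#'   coupled samples.
#' @param coupling Fraction of samples in \[0, 1\] on which the phase
#'   is shared.
#' @param duration Signal duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param noise_sd SD of additive Gaussian noise on both channels.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param amplitude Oscillation amplitude.
#' @param phase_jitter Phase-diffusion SD per sample (radians).
#'
#' @return A list with `x`, `y` (numeric signals), and the generating
#'   phase series `phase_x`, `phase_y` for oracle computations.
#' @export
generate_coupled_pair <- function(freq, phase_lag, coupling, duration, fs,
                                  noise_sd = 0, seed = 1L, amplitude = 1,
                                  phase_jitter = 0.1) {
  if (freq <= 0 || freq >= fs / 2) stop("freq must lie in (0, Nyquist)")
  n <- floor(duration * fs)
  if (n < 2L) stop("duration * fs must be at least 2 samples")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  set.seed(seed)
  phi_x <- phase_walk(n, freq, fs, phase_jitter)
  phi_own <- phase_walk(n, freq, fs, phase_jitter)
  shared <- if (coupling >= 1) {
    rep(TRUE, n)
  } else if (coupling <= 0) {
    rep(FALSE, n)
  } else {
    runif(n) < coupling
  }
  phi_y <- ifelse(shared, phi_x + phase_lag, phi_own)
  x <- amplitude * sin(phi_x) + rnorm(n, sd = noise_sd)
  y <- amplitude * sin(phi_y) + rnorm(n, sd = noise_sd)
  list(x = x, y = y, phase_x = phi_x, phase_y = phi_y, shared = shared)
}

#' Default per-(task, level) coupling specifications
#'
#' The default study conditions: workload level modulates the theta
#' band only — theta amplitude increases with level and a set of
#' fronto-central theta pairs couples more strongly with level — while
#' delta, alpha and beta carry level-invariant background structure.
#' The same structure is used for every task, so workload is in
#' principle transferable across tasks.
#'
#' @param protocol A [session_protocol()].
#' @return Named list (by task) of named lists (by level) of lists of
#'   [coupling_spec()] objects, one per band.
#' @export
default_coupling_specs <- function(protocol = session_protocol()) {
  nch <- protocol$n_channels
  lv <- protocol$levels
  stopifnot(nch >= 12L)
  # fronto-central pairs carrying the workload signal in theta
  theta_pairs_idx <- cbind(
    i = c(1L, 2L, 3L, 4L, 5L, 1L, 2L, 6L),
    j = c(7L, 8L, 9L, 10L, 11L, 12L, 9L, 10L)
  )
  theta_coupling_by_level <- stats::setNames(
    seq(0.2, 0.9, length.out = length(lv)), lv
  )
  theta_amp_by_level <- stats::setNames(
    seq(8, 16, length.out = length(lv)), lv
  )
  # level-invariant background coupling in the other bands
  bg_pairs <- function(offset) {
    data.frame(
      i = c(13L, 15L) + offset, j = c(14L, 16L) + offset,
      coupling = 0.5, lag = pi / 4
    )
  }
  specs_for_level <- function(level) {
    theta_pairs <- data.frame(
      i = theta_pairs_idx[, "i"], j = theta_pairs_idx[, "j"],
      coupling = theta_coupling_by_level[[level]], lag = pi / 4
    )
    list(
      delta = coupling_spec("delta", bg_pairs(0L),
        amplitude_by_level = stats::setNames(rep(12, length(lv)), lv)
      ),
      theta = coupling_spec("theta", theta_pairs,
        amplitude_by_level = theta_amp_by_level
      ),
      alpha = coupling_spec("alpha", bg_pairs(4L),
        amplitude_by_level = stats::setNames(rep(10, length(lv)), lv)
      ),
      beta = coupling_spec("beta", bg_pairs(8L),
        amplitude_by_level = stats::setNames(rep(6, length(lv)), lv)
      )
    )
  }
  out <- lapply(protocol$tasks, function(task) {
    stats::setNames(lapply(lv, specs_for_level), lv)
  })
  stats::setNames(out, protocol$tasks)
}

#' Generate a full synthetic recording session
#'
#' Produces `n_rounds * |tasks| * |levels|` recordings of
#' `block_duration` seconds each. Every channel is the sum over the
#' four bands of a band-limited phase-diffusion oscillation (phase
#' shared across coupled pairs per the coupling specs) plus white
#' Gaussian noise.
#'
#' @param protocol A [session_protocol()].
#' @param coupling_specs Per-(task, level) coupling specs as returned
#'   by [default_coupling_specs()]; a spec set must exist for every
#'   (task, level) combination.
#' @param subject Subject index (integer >= 1); the effective seed is
#'   `protocol$seed + subject`.
#' @param fs Generation sampling rate in Hz. Defaults to the
#'   protocol's acquisition rate; generating directly at the analysis
#'   rate (200 Hz) is supported and leaves all phase-coupling ground
#'   truth unchanged.
#'
#' @return A list of [recording()] objects.
#' @export
generate_session <- function(protocol = session_protocol(),
                             coupling_specs = default_coupling_specs(protocol),
                             subject = 1L,
                             fs = protocol$fs_acquisition) {
  for (task in protocol$tasks) {
    if (is.null(coupling_specs[[task]])) {
      stop("missing coupling specs for task: ", task)
    }
    for (level in protocol$levels) {
      if (is.null(coupling_specs[[task]][[level]])) {
        stop("missing coupling specs for (", task, ", ", level, ")")
      }
    }
  }
  set.seed(protocol$seed + as.integer(subject))
  nch <- protocol$n_channels
  n <- floor(protocol$block_duration * fs)
  labels <- sprintf("CH%02d", seq_len(nch))
  recs <- list()
  for (round in seq_len(protocol$n_rounds)) {
    for (task in protocol$tasks) {
      for (level in protocol$levels) {
        specs <- coupling_specs[[task]][[level]]
        data <- matrix(0, nrow = nch, ncol = n)
        noise_sd <- 0
        band_edges <- default_bands()
        for (spec in specs) {
          amp <- spec$amplitude_by_level[[level]]
          phases <- matrix(0, nrow = nch, ncol = n)
          for (ch in seq_len(nch)) {
            phases[ch, ] <- phase_walk(n, spec$freq, fs, spec$phase_jitter)
          }
          if (nrow(spec$pairs) > 0L) {
            for (p in seq_len(nrow(spec$pairs))) {
              i <- spec$pairs$i[p]
              j <- spec$pairs$j[p]
              c_frac <- spec$pairs$coupling[p]
              shared <- if (c_frac >= 1) {
                rep(TRUE, n)
              } else if (c_frac <= 0) {
                rep(FALSE, n)
              } else {
                runif(n) < c_frac
              }
              phases[j, shared] <- phases[i, shared] + spec$pairs$lag[p]
            }
          }
          comp <- amp * sin(phases)
          # confine each band component to its own band (zero-phase
          # Butterworth magnitude response) so phase-diffusion
          # spectral tails do not leak level-dependent power into
          # neighbouring bands
          edges <- band_edges[[spec$band]]
          if (!is.null(edges) && edges[2] < fs / 2) {
            comp <- band_confine(comp, edges, fs)
          }
          data <- data + comp
          noise_sd <- max(noise_sd, spec$noise_sd)
        }
        if (noise_sd > 0) {
          data <- data + matrix(rnorm(nch * n, sd = noise_sd), nrow = nch)
        }
        recs[[length(recs) + 1L]] <- recording(
          data = data, fs = fs, channel_labels = labels,
          meta = list(
            subject = as.integer(subject), task = task,
            level = level, round = round
          )
        )
      }
    }
  }
  recs
}

#' Zero-phase spectral band confinement
#'
#' Applies the squared magnitude response of an order-4 Butterworth
#' band-pass (the same magnitude filtfilt would apply) in the
#' frequency domain, to all channels at once. Zero phase by
#' construction; used by the generator to keep each band component's
#' power inside its own band.
#'
#' @param x Channels x samples matrix.
#' @param edges `c(low, high)` band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @keywords internal
band_confine <- function(x, edges, fs) {
  n <- ncol(x)
  bp <- signal::butter(4, edges / (fs / 2), type = "pass")
  w <- 2 * pi * (0:(n - 1)) / n
  z <- exp(-1i * w)
  h <- outer(z, seq_along(bp$b) - 1, `^`) %*% bp$b /
    (outer(z, seq_along(bp$a) - 1, `^`) %*% bp$a)
  gain <- Mod(h)^2
  spec <- stats::mvfft(t(x))
  spec <- spec * as.vector(gain)
  t(Re(stats::mvfft(spec, inverse = TRUE) / n))
}

#' Ground-truth binary adjacency implied by a coupling spec
#'
#' @param spec A [coupling_spec()].
#' @param n_channels Number of channels in the montage.
#' @param threshold Pairs with `coupling >= threshold` become edges.
#'
#' @return Symmetric binary matrix with zero diagonal.
#' @export
ground_truth_adjacency <- function(spec, n_channels, threshold = 0.5) {
  adj <- matrix(0L, n_channels, n_channels)
  if (nrow(spec$pairs) > 0L) {
    keep <- spec$pairs$coupling >= threshold
    for (p in which(keep)) {
      i <- spec$pairs$i[p]
      j <- spec$pairs$j[p]
      adj[i, j] <- 1L
      adj[j, i] <- 1L
    }
  }
  diag(adj) <- 0L
  adj
}
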