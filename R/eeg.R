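#' Trial-epoched multichannel time series
#'
#' Container for response-locked epochs: a channels x samples x trials
#' numeric array plus sampling rate and the time of response onset
#' relative to epoch start. Phase-locking and phase-amplitude measures
#' require at least two trials.
#'
#' @param data numeric array, channels x samples x trials.
#' @param fs sampling rate in Hz.
#' @param t0 response-onset time relative to epoch start, in seconds;
#'   analysis windows are specified relative to it.
#' @param channels optional channel labels.
#' @return object of class `trial_epochs`.
#' @export
trial_epochs <- function(data, fs, t0 = 0, channels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0)
  if (any(!is.finite(data))) stop("epoch data contains non-finite samples")
  if (t0 < 0 || t0 > dim(data)[2] / fs)
    stop("t0 must lie within the epoch")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[1]))
  stopifnot(length(channels) == dim(data)[1])
  structure(list(data = data, fs = fs, t0 = t0,
                 channels = as.character(channels)),
            class = "trial_epochs")
}

#' @export
print.trial_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Trial epochs: %d channels x %d samples x %d trials (fs = %g Hz, t0 = %g s)\n",
    d[1], d[2], d[3], x$fs, x$t0))
  invisible(x)
}

#' Frequency-band and analysis-window specification
#'
#' Defaults follow the standard EEG bands theta 4-7, alpha 8-12,
#' beta 13-30, gamma 31-100 Hz and a 25-75 ms post-response window. Band
#' membership of frequency-grid bins is half-open, `[f_lo, f_hi)`, as is
#' the time window, so bins are counted exactly once.
#'
#' @param bands named list of `c(f_lo, f_hi)` pairs in Hz, ordered from
#'   low to high, non-overlapping.
#' @param window `c(t1, t2)` in seconds relative to response onset.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(bands = list(theta = c(4, 7), alpha = c(8, 12),
                                   beta = c(13, 30), gamma = c(31, 100)),
                      window = c(0.025, 0.075)) {
  stopifnot(length(bands) >= 1L, !is.null(names(bands)),
            length(window) == 2L, window[1] < window[2])
  lo <- vapply(bands, `[`, 0, 1); hi <- vapply(bands, `[`, 0, 2)
  if (any(lo >= hi)) stop("each band needs f_lo < f_hi")
  if (is.unsorted(lo) || any(hi[-length(hi)] > lo[-1]))
    stop("bands must be ordered and non-overlapping")
  structure(list(bands = bands, window = window), class = "band_spec")
}

# --- RID-Rihaczek time-frequency distribution -------------------------------

# principal-value wrap of an angle to (-pi, pi]
wrap_angle <- function(x) Arg(exp(1i * x))

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Reduced-interference Rihaczek time-frequency distribution
#'
#' Complex energy distribution \eqn{C(t, f)} of a signal over a uniform
#' time-frequency grid. The plain Rihaczek distribution
#' \eqn{C(t,f) = z(t)\, Z^*(f)\, e^{-j 2\pi f t}} (with z the analytic
#' signal) is smoothed by a Choi-Williams kernel
#' \eqn{\exp(-(\theta\tau)^2/\sigma)} applied in the ambiguity plane,
#' which suppresses the oscillatory cross-terms of multicomponent signals
#' while leaving the axes (hence the marginals) untouched. Implementation
#' follows the ambiguity-function route: instantaneous autocorrelation
#' \eqn{R(t, \tau) = z(t) z^*(t - \tau)} (circular lags), DFT over t to
#' the ambiguity plane, kernel multiplication with doppler/lag wrapped to
#' normalized coordinates in [-1/2, 1/2), inverse DFT over t and DFT over
#' \eqn{\tau}. The time marginal of the unsmoothed distribution is the
#' instantaneous energy: \eqn{\sum_f C(t,f) = |z(t)|^2}.
#'
#' The number of frequency bins equals the number of samples, so a
#' one-second epoch yields a 1 Hz grid.
#'
#' @param x finite numeric (or complex) signal.
#' @param fs sampling rate in Hz.
#' @param sigma Choi-Williams kernel parameter (> 0); smaller values
#'   smooth more aggressively. Default 0.001.
#' @param kernel `"choi-williams"` or `"none"` (plain Rihaczek).
#' @return object of class `tfd`: list with `C` (time x frequency complex
#'   matrix), `times` (s), `freqs` (Hz), `fs`.
#' @export
rid_rihaczek <- function(x, fs, sigma = 0.001,
                         kernel = c("choi-williams", "none")) {
  kernel <- match.arg(kernel)
  if (any(!is.finite(x))) stop("signal contains non-finite samples")
  if (sigma <= 0) stop("kernel parameter sigma must be positive")
  n <- length(x)
  z <- if (is.complex(x)) x else analytic_signal(as.numeric(x))
  # instantaneous autocorrelation R[t, tau] = z(t) z*(t - tau), circular
  tt <- seq_len(n)
  lag_idx <- outer(tt, 0:(n - 1L), function(t, tau) ((t - tau - 1L) %% n) + 1L)
  R <- matrix(z, n, n) * Conj(z)[lag_idx]
  if (kernel == "choi-williams") {
    A <- stats::mvfft(R)                       # DFT over t -> ambiguity plane
    wrap <- function(m, n) ifelse(m < n / 2, m, m - n) / n
    theta <- wrap(0:(n - 1L), n)               # doppler, cycles/sample
    tau <- wrap(0:(n - 1L), n)                 # lag, fraction of epoch
    A <- A * exp(-outer(theta, tau)^2 / sigma)
    R <- stats::mvfft(A, inverse = TRUE) / n
  }
  C <- t(stats::mvfft(t(R))) / n               # DFT over tau -> frequency
  structure(list(C = C, times = (tt - 1L) / fs,
                 freqs = (0:(n - 1L)) * fs / n, fs = fs),
            class = "tfd")
}

band_bin_idx <- function(freqs, band) {
  which(freqs >= band[1] & freqs < band[2])
}

window_row_idx <- function(times, t0, window) {
  which(times >= t0 + window[1] & times < t0 + window[2])
}

#' Time-frequency phase difference between two channels
#'
#' \eqn{\phi_{uv}(t,f) = \arg[C_u C_v^* / (|C_u||C_v|)]}, the phase
#' difference of the two complex distributions at each grid point. Bins
#' where either magnitude vanishes have undefined phase and are returned
#' as `NA` (excluded from downstream averages).
#'
#' @param tfd_u,tfd_v `tfd` objects on identical grids.
#' @param tol magnitude threshold below which phase is masked.
#' @return time x frequency matrix of phases in (-pi, pi], with `NA` at
#'   masked bins.
#' @export
tf_phase_difference <- function(tfd_u, tfd_v, tol = 1e-12) {
  if (!isTRUE(all.equal(tfd_u$freqs, tfd_v$freqs)) ||
      !isTRUE(all.equal(tfd_u$times, tfd_v$times)))
    stop("time-frequency grids are not aligned")
  z <- tfd_u$C * Conj(tfd_v$C)
  phi <- Arg(z)
  phi[Mod(tfd_u$C) <= tol | Mod(tfd_v$C) <= tol] <- NA_real_
  phi
}

#' Phase locking value across trials
#'
#' \eqn{\mathrm{PLV}(t,f) = |\sum_k e^{j\phi^k(t,f)}| / K}: the
#' across-trial consistency of a phase difference, in [0, 1]. `NA` phases
#' (masked bins) are excluded and the divisor at each bin is the number
#' of valid trials there; bins valid in no trial are `NA`.
#'
#' @param phase_diffs list of K phase matrices (one per trial), or a
#'   3-d array with trials in the third dimension.
#' @return matrix of PLV values.
#' @export
plv <- function(phase_diffs) {
  if (is.array(phase_diffs) && length(dim(phase_diffs)) == 3L)
    phase_diffs <- lapply(seq_len(dim(phase_diffs)[3]),
                          function(k) phase_diffs[, , k])
  K <- length(phase_diffs)
  if (K < 2L) stop("at least two trials are required")
  S <- 0; V <- 0
  for (phi in phase_diffs) {
    ok <- !is.na(phi)
    e <- exp(1i * phi)
    e[!ok] <- 0
    S <- S + e
    V <- V + ok
  }
  out <- Mod(S) / V
  out[V == 0] <- NA_real_
  out
}

#' Intra-layer connectivity: band-averaged PLV
#'
#' Pairwise phase synchrony within one frequency band: the PLV at every
#' (t, f) bin of the analysis window x band grid, averaged over the grid,
#' \eqn{w_{uv} = \frac{1}{|W|}\frac{1}{|h|} \sum_{t \in W} \sum_{f \in h}
#' \mathrm{PLV}_{uv}(t, f)}. Symmetric, in [0, 1].
#'
#' @param epochs a `trial_epochs` object (K >= 2 trials).
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param window `c(t1, t2)` in seconds relative to response onset.
#' @param sigma RID kernel parameter.
#' @return symmetric channels x channels matrix with zero diagonal.
#' @export
intra_layer_weights <- function(epochs, band, window = c(0.025, 0.075),
                                sigma = 0.001) {
  st <- tfd_stack(epochs, sigma, bands = list(band), window = window)
  intra_weights_from_stack(st, 1L)
}

tfd_stack <- function(epochs, sigma, bands, window) {
  d <- dim(epochs$data)
  n <- d[2]
  freqs <- (0:(n - 1L)) * epochs$fs / n
  times <- (0:(n - 1L)) / epochs$fs
  rows <- window_row_idx(times, epochs$t0, window)
  if (!length(rows)) stop("analysis window contains no samples")
  bins <- lapply(bands, band_bin_idx, freqs = freqs)
  if (any(!lengths(bins))) stop("band contains no frequency bins")
  if (d[3] < 2L) stop("at least two trials are required")
  C <- vector("list", d[1])
  for (ch in seq_len(d[1])) {
    C[[ch]] <- lapply(seq_len(d[3]), function(k)
      rid_rihaczek(epochs$data[ch, , k], epochs$fs, sigma)$C[rows, ,
                                                            drop = FALSE])
  }
  list(C = C, rows = rows, bins = bins, n_channels = d[1], K = d[3],
       freqs = freqs)
}

intra_weights_from_stack <- function(st, b, tol = 1e-12) {
  cols <- st$bins[[b]]
  nc <- st$n_channels
  W <- matrix(0, nc, nc)
  for (u in seq_len(nc - 1L)) for (v in (u + 1L):nc) {
    S <- 0; V <- 0
    for (k in seq_len(st$K)) {
      z <- st$C[[u]][[k]][, cols, drop = FALSE] *
        Conj(st$C[[v]][[k]][, cols, drop = FALSE])
      mag <- Mod(z)
      ok <- mag > tol
      e <- z
      e[ok] <- e[ok] / mag[ok]
      e[!ok] <- 0
      S <- S + e
      V <- V + ok
    }
    p <- Mod(S)[V > 0] / V[V > 0]
    W[u, v] <- W[v, u] <- if (length(p)) mean(p) else 0
  }
  W
}

#' Band-limited amplitude envelope from a TFD
#'
#' Frequency-constrained time marginal: the complex distribution is
#' summed over the band's frequency bins (times the bin width) and the
#' magnitude taken, \eqn{a(t) = |\sum_{f \in [f_1, f_2)} C(t, f)\,
#' \Delta f|}. An envelope must be real and nonnegative; taking the
#' magnitude of the band-integrated complex marginal is this package's
#' reading of that constraint.
#'
#' @param tfd a `tfd` object.
#' @param band `c(f_lo, f_hi)` in Hz (half-open).
#' @return nonnegative numeric vector over time.
#' @export
amplitude_envelope <- function(tfd, band) {
  cols <- band_bin_idx(tfd$freqs, band)
  if (!length(cols)) stop("band contains no frequency bins")
  df <- tfd$fs / length(tfd$freqs)
  Mod(rowSums(tfd$C[, cols, drop = FALSE])) * df
}

#' Low-frequency phase series from a TFD
#'
#' \eqn{\phi(t) = \arg[C(t, f_p) / |C(t, f_p)|]} at the grid bin
#' containing \eqn{f_p}; bins with vanishing magnitude are masked `NA`.
#'
#' @param tfd a `tfd` object.
#' @param f_p frequency in Hz (mapped to its grid bin).
#' @param tol magnitude mask threshold.
#' @return numeric vector of phases over time with `NA` at masked points.
#' @export
low_freq_phase <- function(tfd, f_p, tol = 1e-12) {
  col <- which.min(abs(tfd$freqs - f_p))
  z <- tfd$C[, col]
  phi <- Arg(z)
  phi[Mod(z) <= tol] <- NA_real_
  phi
}

#' Direct phase-amplitude coupling (dPAC) across trials
#'
#' Distributes per-trial amplitudes along the unit vectors of the
#' per-trial low-frequency phases and measures the resultant length,
#' normalized so that the value lies in [0, 1] by the Cauchy-Schwarz
#' inequality:
#' \deqn{\mathrm{dPAC}(t) = \frac{1}{\sqrt{K}}
#'   \frac{|\sum_k a^k(t) e^{j\phi^k(t)}|}{\sqrt{\sum_k a^k(t)^2}}.}
#' Equality (dPAC = 1) holds iff amplitudes are constant multiples along
#' a common phase. Trials with masked (`NA`) phase at a time point are
#' excluded there, with K the number of valid trials; if all amplitudes
#' at a time point are zero the value is 0 by convention.
#'
#' @param amps K x T matrix of nonnegative amplitudes (trials x time).
#' @param phases K x T matrix of phases (radians), `NA` allowed.
#' @return numeric vector of length T with values in [0, 1].
#' @export
dpac <- function(amps, phases) {
  amps <- as.matrix(amps); phases <- as.matrix(phases)
  stopifnot(all(dim(amps) == dim(phases)), nrow(amps) >= 2L)
  ok <- !is.na(phases)
  e <- exp(1i * phases)
  e[!ok] <- 0
  a <- amps
  a[!ok] <- 0
  num <- Mod(colSums(a * e))
  den <- sqrt(colSums(a^2))
  kv <- colSums(ok)
  out <- numeric(ncol(a))
  pos <- den > 0 & kv > 0
  out[pos] <- num[pos] / (sqrt(kv[pos]) * den[pos])
  out
}

#' Inter-layer connectivity: band-averaged dPAC
#'
#' Phase-amplitude coupling between a low-frequency (phase) band h and a
#' high-frequency (amplitude) band k, averaged over the analysis window
#' and all (f_p, f_a) bin pairs:
#' \eqn{w_{uv}^{hk} = \frac{1}{|W|}\frac{1}{|h||k|} \sum_{t \in W}
#' \sum_{f_p \in h} \sum_{f_a \in k} \mathrm{dPAC}_{uv}(f_p, f_a, t)}.
#' Per-bin amplitudes are \eqn{|C(t, f_a)|} (one-bin band of the
#' frequency-constrained marginal); phases are taken at each \eqn{f_p}
#' bin. Because the multilayer network model is undirected, the two
#' directions (amplitude at u / phase at v, and vice versa) are combined
#' according to `direction`.
#'
#' @param epochs a `trial_epochs` object.
#' @param band_phase,band_amp `c(f_lo, f_hi)` Hz; the phase band should
#'   lie below the amplitude band for PAC semantics.
#' @param window analysis window, seconds relative to response onset.
#' @param sigma RID kernel parameter.
#' @param direction `"mean"` (default: average of both directions),
#'   `"max"`, or `"uv"` (amplitude at the row channel, phase at the
#'   column channel; asymmetric).
#' @return channels x channels matrix in [0, 1]; symmetric unless
#'   `direction = "uv"`.
#' @export
inter_layer_weights <- function(epochs, band_phase, band_amp,
                                window = c(0.025, 0.075), sigma = 0.001,
                                direction = c("mean", "max", "uv")) {
  direction <- match.arg(direction)
  if (band_phase[1] >= band_amp[1])
    warning("phase band does not lie below amplitude band")
  st <- tfd_stack(epochs, sigma, bands = list(band_phase, band_amp),
                  window = window)
  inter_weights_from_stack(st, 1L, 2L, direction)
}

# Directed dPAC block: D[u, v] = window/bin-averaged dPAC with amplitude
# taken at channel u (band b_amp) and phase at channel v (band b_phase).
inter_weights_from_stack <- function(st, b_phase, b_amp,
                                     direction = "mean", tol = 1e-12) {
  pcols <- st$bins[[b_phase]]; acols <- st$bins[[b_amp]]
  nc <- st$n_channels
  nt <- length(st$rows)
  amp <- lapply(seq_len(nc), function(u)
    lapply(seq_len(st$K), function(k)
      Mod(st$C[[u]][[k]][, acols, drop = FALSE])))
  pha <- lapply(seq_len(nc), function(v)
    lapply(seq_len(st$K), function(k) {
      z <- st$C[[v]][[k]][, pcols, drop = FALSE]
      ph <- Arg(z)
      ph[Mod(z) <= tol] <- NA_real_
      ph
    }))
  D <- matrix(0, nc, nc)
  # u == v is kept: same-electrode cross-band coupling is an inter-layer
  # edge between u^h and u^k, not a self-loop
  for (u in seq_len(nc)) for (v in seq_len(nc)) {
    acc <- 0
    for (fp in seq_along(pcols)) {
      # amplitude (K x nt x |k|) paired with the phase at bin fp (K x nt)
      num <- matrix(0 + 0i, nt, length(acols))
      den <- matrix(0, nt, length(acols))
      kv <- matrix(0, nt, length(acols))
      for (k in seq_len(st$K)) {
        ph <- pha[[v]][[k]][, fp]
        ok <- !is.na(ph)
        e <- exp(1i * ph)
        e[!ok] <- 0
        a <- amp[[u]][[k]]
        num <- num + a * e
        den <- den + a^2 * ok
        kv <- kv + ok
      }
      dp <- matrix(0, nt, length(acols))
      pos <- den > 0 & kv > 0
      dp[pos] <- Mod(num)[pos] / (sqrt(kv[pos]) * sqrt(den)[pos])
      acc <- acc + sum(dp) / length(dp)
    }
    D[u, v] <- acc / length(pcols)
  }
  switch(direction,
         mean = (D + t(D)) / 2,
         max = pmax(D, t(D)),
         uv = D)
}

#' Build a multi-frequency multilayer network from epochs
#'
#' Full network-construction pipeline: one RID-Rihaczek distribution per
#' channel and trial, PLV-based intra-layer weights for every band, and
#' dPAC-based inter-layer weights for every ordered low/high band pair,
#' all averaged over the analysis window. Intra- and inter-layer weights
#' are both normalized to [0, 1], so they live on a common scale. Layers
#' are the bands, in the order given; node ids are the channel labels.
#'
#' @param epochs a `trial_epochs` object.
#' @param bands a `band_spec` (bands and analysis window).
#' @param sigma RID kernel parameter.
#' @param pac_direction how the two dPAC directions are combined into one
#'   undirected weight: `"mean"` (default) or `"max"`.
#' @return a `multilayer_network` with one layer per band.
#' @export
build_eeg_network <- function(epochs, bands = band_spec(), sigma = 0.001,
                              pac_direction = c("mean", "max")) {
  pac_direction <- match.arg(pac_direction)
  stopifnot(inherits(epochs, "trial_epochs"), inherits(bands, "band_spec"))
  st <- tfd_stack(epochs, sigma, bands = bands$bands,
                  window = bands$window)
  L <- length(bands$bands)
  intra <- lapply(seq_len(L), function(b) intra_weights_from_stack(st, b))
  inter <- list()
  if (L > 1L) for (h in seq_len(L - 1L)) for (k in (h + 1L):L) {
    inter[[paste0(h, ":", k)]] <-
      inter_weights_from_stack(st, b_phase = h, b_amp = k,
                               direction = pac_direction)
  }
  multilayer_network(intra, inter, layers = names(bands$bands),
                     node_ids = epochs$channels)
}
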