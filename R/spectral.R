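#' Notch-filter and downsample a raw trace
#'
#' Applies a second-order IIR notch (zero-phase, via forward-backward
#' filtering) at each listed mains frequency, then decimates to `fs_out`
#' with anti-aliasing. With `fs_in == fs_out` and an empty notch list this is
#' the identity.
#'
#' @param x Numeric trace.
#' @param fs_in,fs_out Input and output sampling rates, Hz; `fs_in` must be
#'   an integer multiple of `fs_out`.
#' @param notch_freqs Frequencies to notch, Hz; all must lie below the output
#'   Nyquist rate.
#' @param Q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return Numeric trace at `fs_out`.
#' @examples
#' x <- sin(2 * pi * 12 * seq(0, 2, by = 1e-3))
#' y <- preprocess(x, 1000, notch_freqs = 50)
#' @export
preprocess <- function(x, fs_in, notch_freqs = c(50, 100, 150),
                       fs_out = fs_in, Q = 30) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (fs_in < fs_out) abort("fs_in must be at least fs_out")
  if (fs_in %% fs_out != 0) abort("fs_in must be an integer multiple of fs_out")
  if (length(notch_freqs) && any(notch_freqs >= fs_out / 2)) {
    abort("notch frequencies must lie below the output Nyquist rate")
  }
  for (f0 in notch_freqs) {
    co <- iir_notch(f0, fs_in, Q)
    x <- signal::filtfilt(signal::Arma(b = co$b, a = co$a), x)
  }
  q <- fs_in %/% fs_out
  while (q > 1) {
    step <- min(q, 10L)
    # keep per-stage decimation factors modest for filter stability
    while (q %% step != 0) step <- step - 1L
    x <- signal::decimate(x, step, ftype = "iir")
    q <- q %/% step
  }
  x
}

# biquad notch coefficients (audio-EQ cookbook form)
iir_notch <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Divide a trace by the RMS of its baseline segment
#'
#' The baseline (an intertrial-interval segment) defines the per-trial
#' amplitude scale: the raw trace is divided by the baseline root mean
#' square before spectral decomposition, so power is in baseline-RMS units.
#'
#' @param x Numeric trace (or matrix).
#' @param baseline Numeric baseline segment.
#' @return `x / rms(baseline)`.
#' @export
baseline_normalize <- function(x, baseline) {
  if (length(baseline) == 0L) abort("baseline is empty")
  r <- sqrt(mean(baseline^2))
  if (r == 0) abort("baseline is all zero: RMS division undefined")
  x / r
}

# truncated complex Morlet kernel, L1-normalised (unit passband gain)
morlet_kernel <- function(f, fs, n_cycles, trunc_sd = 2.5) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(trunc_sd * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sum(Mod(w))
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves the trace with a bank of complex Morlet wavelets (fixed number
#' of cycles across frequencies) and returns squared-magnitude power on a
#' frequency-by-time grid. Samples within half a wavelet of either edge are
#' flagged invalid per frequency (spectral leakage near the margin).
#'
#' @param x Numeric trace.
#' @param fs Sampling rate, Hz.
#' @param freqs Analysis frequencies, Hz (default 8-60 in 1-Hz steps).
#' @param n_cycles Wavelet width in cycles (constant across frequencies).
#' @param times_ms Optional time axis for the samples of `x`.
#' @return A `tfr_map`: `power` (n_freqs x n_times), `freqs`, `times_ms`,
#'   `fs`, `margin` (per-frequency count of invalid edge samples).
#' @examples
#' x <- sin(2 * pi * 12 * seq(0, 2, by = 1 / 500))
#' m <- morlet_tfr(x, 500, freqs = 8:20)
#' m$freqs[which.max(rowMeans(m$power))]  # 12
#' @export
morlet_tfr <- function(x, fs, freqs = 8:60, n_cycles = 7, times_ms = NULL) {
  stopifnot(length(freqs) >= 1, all(freqs > 0))
  if (max(freqs) >= fs / 2) abort("max frequency must be below Nyquist")
  n <- length(x)
  bank <- morlet_bank(n, fs, freqs, n_cycles)
  if (is.null(bank)) {
    abort("signal shorter than the widest wavelet")
  }
  if (is.null(times_ms)) times_ms <- (seq_len(n) - 1) / fs * 1000
  power <- morlet_power(x, bank)
  structure(
    list(power = power, freqs = freqs, times_ms = times_ms, fs = fs,
         n_cycles = n_cycles, margin = bank$margin),
    class = "tfr_map"
  )
}

# precomputed FFT bank; reused across trials for speed
morlet_bank <- function(n, fs, freqs, n_cycles, trunc_sd = 2.5) {
  kernels <- purrr::map(freqs, morlet_kernel, fs = fs, n_cycles = n_cycles,
                        trunc_sd = trunc_sd)
  margin <- map_int(kernels, function(k) (length(k) - 1L) %/% 2L)
  if (any(2L * margin + 1L > n)) return(NULL)
  nfft <- stats::nextn(n + max(lengths(kernels)), 2)
  kf <- purrr::map(kernels, function(k) {
    fft(c(k, rep(0, nfft - length(k))))
  })
  list(kf = kf, margin = margin, nfft = nfft, n = n, freqs = freqs)
}

morlet_power <- function(x, bank) {
  xf <- fft(c(x, rep(0, bank$nfft - bank$n)))
  out <- matrix(0, length(bank$kf), bank$n)
  for (i in seq_along(bank$kf)) {
    conv <- fft(xf * bank$kf[[i]], inverse = TRUE) / bank$nfft
    # centre of the kernel aligns with sample t after shifting by margin
    out[i, ] <- Mod(conv[bank$margin[i] + seq_len(bank$n)])^2
  }
  out
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf("<tfr_map: %d freqs (%g-%g Hz) x %d samples at %g Hz>\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times_ms), x$fs))
  invisible(x)
}

#' @describeIn morlet_tfr Long-tibble view (freq, time_ms, power, valid).
#' @exportS3Method generics::tidy
tidy.tfr_map <- function(x, ...) {
  n_t <- length(x$times_ms)
  valid <- t(vapply(seq_along(x$freqs), function(i) {
    v <- rep(TRUE, n_t)
    m <- x$margin[i]
    if (m > 0) v[c(seq_len(min(m, n_t)), seq.int(max(1L, n_t - m + 1L), n_t))] <- FALSE
    v
  }, logical(n_t)))
  tibble(
    freq = rep(x$freqs, times = n_t),
    time_ms = rep(x$times_ms, each = length(x$freqs)),
    power = as.vector(x$power),
    valid = as.vector(valid)
  )
}

#' Baseline-normalised TFR stack for a whole trial set
#'
#' Divides each trial by its own baseline RMS, then computes the Morlet
#' power map for every trial, sharing one wavelet FFT bank.
#'
#' @param lfp An [generate_trials()] `lfp_trials` object.
#' @param freqs,n_cycles See [morlet_tfr()].
#' @param normalize Divide each trial by its baseline RMS first?
#' @return A `tfr_stack`: `power` array (n_freqs x n_times x n_trials),
#'   `freqs`, `times_ms`, `fs`, `labels`, `margin`.
#' @export
tfr_trials <- function(lfp, freqs = 8:60, n_cycles = 7, normalize = TRUE) {
  stopifnot(inherits(lfp, "lfp_trials"))
  if (max(freqs) >= lfp$fs / 2) abort("max frequency must be below Nyquist")
  n <- ncol(lfp$trials)
  bank <- morlet_bank(n, lfp$fs, freqs, n_cycles)
  if (is.null(bank)) abort("signal shorter than the widest wavelet")
  n_trials <- nrow(lfp$trials)
  power <- array(0, c(length(freqs), n, n_trials))
  for (i in seq_len(n_trials)) {
    x <- lfp$trials[i, ]
    if (normalize) x <- baseline_normalize(x, lfp$baselines[i, ])
    power[, , i] <- morlet_power(x, bank)
  }
  structure(
    list(power = power, freqs = freqs, times_ms = lfp$times_ms, fs = lfp$fs,
         labels = lfp$labels, margin = bank$margin, n_cycles = n_cycles),
    class = "tfr_stack"
  )
}

#' @export
print.tfr_stack <- function(x, ...) {
  cat(sprintf("<tfr_stack: %d freqs x %d samples x %d trials>\n",
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3]))
  invisible(x)
}

#' Extract pre- and post-onset analysis windows from a TFR stack
#'
#' The permutation test compares fixed-length windows ending/starting at
#' sample onset (default 800 ms each, trimming the epoch's outer margins
#' where wavelet leakage is worst).
#'
#' @param stack A [tfr_trials()] `tfr_stack`.
#' @param pre_ms,post_ms Two-element windows in ms relative to onset;
#'   pre is `[pre_ms[1], pre_ms[2])`, post is `[post_ms[1], post_ms[2])`.
#' @param labels Optional label subset (e.g. `"hit"`).
#' @return List with `pre` and `post` arrays (n_freqs x n_window x n_trials),
#'   `freqs`, window time axes, and `labels`.
#' @export
tfr_windows <- function(stack, pre_ms = c(-800, 0), post_ms = c(0, 800),
                        labels = NULL) {
  stopifnot(inherits(stack, "tfr_stack"))
  keep <- if (is.null(labels)) rep(TRUE, length(stack$labels))
          else stack$labels %in% labels
  if (!any(keep)) abort("no trials with the requested labels")
  pre_i <- which(stack$times_ms >= pre_ms[1] & stack$times_ms < pre_ms[2])
  post_i <- which(stack$times_ms >= post_ms[1] & stack$times_ms < post_ms[2])
  if (length(pre_i) == 0L || length(post_i) == 0L) {
    abort("requested windows lie outside the epoch")
  }
  if (length(pre_i) != length(post_i)) {
    abort("pre and post windows must have equal length")
  }
  list(pre = stack$power[, pre_i, keep, drop = FALSE],
       post = stack$power[, post_i, keep, drop = FALSE],
       freqs = stack$freqs,
       pre_times_ms = stack$times_ms[pre_i],
       post_times_ms = stack$times_ms[post_i],
       labels = stack$labels[keep])
}
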