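#' Burst specification for synthetic LFP trials
#'
#' Describes the label-dependent oscillatory burst superimposed on background
#' noise after sample onset: a carrier drawn uniformly in `band`, an envelope
#' that is zero before onset, rises linearly to `peak_latency_ms`, then
#' decays exponentially with `decay_tau_ms`. Defaults emulate the reported
#' encoding phenomenology: a 10-15 Hz transient that is larger and decays
#' faster on hit than miss trials.
#'
#' @param band Carrier frequency band, Hz.
#' @param amplitude Named (hit, miss) burst amplitudes, in units of the
#'   background-noise RMS.
#' @param peak_latency_ms Named (hit, miss) envelope peak times, ms.
#' @param decay_tau_ms Named (hit, miss) post-peak exponential time
#'   constants, ms.
#' @return A `burst_spec` list.
#' @export
burst_spec <- function(band = c(10, 15),
                       amplitude = c(hit = 1.5, miss = 0.75),
                       peak_latency_ms = c(hit = 100, miss = 100),
                       decay_tau_ms = c(hit = 100, miss = 200)) {
  stopifnot(length(band) == 2, band[1] < band[2],
            all(amplitude >= 0), all(decay_tau_ms > 0),
            all(peak_latency_ms >= 0))
  for (nm in c("amplitude", "peak_latency_ms", "decay_tau_ms")) {
    v <- get(nm)
    if (!all(c("hit", "miss") %in% names(v))) {
      abort(sprintf("%s must be named with 'hit' and 'miss'", nm))
    }
  }
  structure(list(band = band, amplitude = amplitude,
                 peak_latency_ms = peak_latency_ms,
                 decay_tau_ms = decay_tau_ms, rise = "linear"),
            class = "burst_spec")
}

#' Background-noise specification
#'
#' @param amplitude RMS of the 1/f background component.
#' @param exponent Spectral exponent of the background (power ~ 1/f^exponent).
#' @param line_freqs Mains-interference frequencies, Hz.
#' @param line_amplitude Amplitude of each line component (0 disables).
#' @return A named list.
#' @export
noise_config <- function(amplitude = 1, exponent = 1,
                         line_freqs = c(50, 100, 150), line_amplitude = 0) {
  stopifnot(amplitude >= 0, line_amplitude >= 0)
  list(amplitude = amplitude, exponent = exponent, line_freqs = line_freqs,
       line_amplitude = line_amplitude)
}

# spectrally shaped (1/f^exponent in power) Gaussian noise, unit RMS
pink_noise <- function(n, exponent = 1) {
  if (n < 2) return(rnorm(n))
  w <- rnorm(n)
  if (exponent == 0) return(w)
  wf <- fft(w)
  f <- c(1, seq_len(n - 1))  # avoid DC blow-up
  f <- pmin(f, n - f + 1)    # symmetric positive frequency index
  shaped <- Re(fft(wf / f^(exponent / 2), inverse = TRUE)) / n
  shaped / sqrt(mean(shaped^2))
}

#' Generate labelled synthetic LFP trial epochs
#'
#' Each trial is 1/f background noise, optional mains-line components, and a
#' label-dependent post-onset burst (see [burst_spec()]). Baseline segments
#' (emulating intertrial-interval recordings) are noise-only and are used for
#' RMS normalization downstream. Default trial counts match the reported
#' completed hit/miss totals of the first animal (346 / 118).
#'
#' @param n_hit,n_miss Trial counts per label.
#' @param burst A [burst_spec()].
#' @param noise A [noise_config()].
#' @param fs Sampling rate, Hz; must be at least 2.5x the burst's upper band
#'   edge.
#' @param epoch_ms Two-element epoch extent around sample onset, ms.
#' @param baseline_ms Baseline segment duration, ms.
#' @return An `lfp_trials` object: `trials` (n_trials x n_samples matrix),
#'   `baselines`, `fs`, `times_ms`, `onset_index`, `labels`, and `truth`
#'   (the generator parameters, for tests).
#' @examples
#' x <- generate_trials(5, 5, fs = 250)
#' dim(x$trials)
#' @export
generate_trials <- function(n_hit = 346, n_miss = 118,
                            burst = burst_spec(), noise = noise_config(),
                            fs = 1000, epoch_ms = c(-1000, 1000),
                            baseline_ms = 1000) {
  stopifnot(n_hit >= 0, n_miss >= 0, n_hit + n_miss > 0,
            epoch_ms[1] < 0, epoch_ms[2] > 0)
  if (fs < 2.5 * burst$band[2]) {
    abort(sprintf("fs = %g Hz violates the 2.5x band-edge rule for %g Hz",
                  fs, burst$band[2]))
  }
  dt <- 1000 / fs
  times_ms <- seq(epoch_ms[1], epoch_ms[2], by = dt)
  n_t <- length(times_ms)
  n_b <- round(baseline_ms * fs / 1000)
  labels <- rep(c("hit", "miss"), c(n_hit, n_miss))
  n_trials <- length(labels)

  trials <- matrix(0, n_trials, n_t)
  baselines <- matrix(0, n_trials, n_b)
  t_sec <- times_ms / 1000

  for (i in seq_len(n_trials)) {
    lab <- labels[i]
    sig <- noise$amplitude * pink_noise(n_t, noise$exponent)
    base <- noise$amplitude * pink_noise(n_b, noise$exponent)
    if (noise$line_amplitude > 0) {
      for (f0 in noise$line_freqs) {
        if (f0 < fs / 2) {
          ph <- runif(1, 0, 2 * pi)
          sig <- sig + noise$line_amplitude * sin(2 * pi * f0 * t_sec + ph)
          base <- base + noise$line_amplitude *
            sin(2 * pi * f0 * seq_len(n_b) / fs + runif(1, 0, 2 * pi))
        }
      }
    }
    amp <- burst$amplitude[[lab]]
    if (amp > 0) {
      carrier <- runif(1, burst$band[1], burst$band[2])
      ph <- runif(1, 0, 2 * pi)
      pk <- burst$peak_latency_ms[[lab]]
      tau <- burst$decay_tau_ms[[lab]]
      env <- rep(0, n_t)
      rising <- times_ms >= 0 & times_ms <= pk
      env[rising] <- if (pk > 0) times_ms[rising] / pk else 1
      after <- times_ms > pk
      env[after] <- exp(-(times_ms[after] - pk) / tau)
      sig <- sig + amp * env * sin(2 * pi * carrier * t_sec + ph)
    }
    trials[i, ] <- sig
    baselines[i, ] <- base
  }

  structure(
    list(trials = trials, baselines = baselines, fs = fs,
         times_ms = times_ms, onset_index = which.min(abs(times_ms)),
         labels = labels,
         truth = list(burst = burst, noise = noise, n_hit = n_hit,
                      n_miss = n_miss)),
    class = "lfp_trials"
  )
}

#' @export
print.lfp_trials <- function(x, ...) {
  cat(sprintf("<lfp_trials: %d trials (%d hit, %d miss), fs %g Hz, %d samples>\n",
              nrow(x$trials), sum(x$labels == "hit"),
              sum(x$labels == "miss"), x$fs, ncol(x$trials)))
  invisible(x)
}

#' @describeIn generate_trials Long-tibble view (trial, label, time_ms, value).
#' @param x An `lfp_trials` object.
#' @param ... Ignored.
#' @exportS3Method generics::tidy
tidy.lfp_trials <- function(x, ...) {
  tibble(
    trial = rep(seq_len(nrow(x$trials)), each = ncol(x$trials)),
    label = rep(x$labels, each = ncol(x$trials)),
    time_ms = rep(x$times_ms, nrow(x$trials)),
    value = as.vector(t(x$trials))
  )
}
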