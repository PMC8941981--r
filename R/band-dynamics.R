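#' Label-wise band-average power timecourse
#'
#' Averages TFR power over the in-band frequency rows, then over trials
#' within each label, giving one power-versus-time curve per label.
#'
#' @param stack A [tfr_trials()] `tfr_stack` (or a single `tfr_map`).
#' @param band Two-element frequency band, Hz (inclusive).
#' @return Tibble with columns `label` (absent for a single map), `time_ms`,
#'   `power`.
#' @export
band_average <- function(stack, band) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  rows <- which(stack$freqs >= band[1] & stack$freqs <= band[2])
  if (length(rows) == 0L) abort("band contains no analysis frequencies")
  if (inherits(stack, "tfr_map")) {
    return(tibble(time_ms = stack$times_ms,
                  power = colMeans(stack$power[rows, , drop = FALSE])))
  }
  stopifnot(inherits(stack, "tfr_stack"))
  purrr::map(unique(stack$labels), function(lab) {
    p <- stack$power[rows, , stack$labels == lab, drop = FALSE]
    tibble(label = lab, time_ms = stack$times_ms,
           power = colMeans(apply(p, c(1, 2), mean)))
  }) |> list_rbind()
}

#' Peak latency of a power timecourse
#'
#' @param timecourse Tibble with `time_ms` and `power` columns (one label).
#' @param window_ms Two-element search window, ms (inclusive).
#' @return Time of the maximum within the window, ms; ties take the earliest.
#' @export
peak_latency <- function(timecourse, window_ms = c(0, 500)) {
  keep <- timecourse$time_ms >= window_ms[1] & timecourse$time_ms <= window_ms[2]
  if (!any(keep)) abort("search window lies outside the timecourse")
  tc <- timecourse[keep, ]
  tc$time_ms[which.max(tc$power)]
}

#' Per-frequency post-peak power gradients
#'
#' For each label and each integer analysis frequency in the band, fits an
#' ordinary least-squares line to trial-averaged power versus time over the
#' gradient window and reports the slope in (baseline-normalised) power
#' units per ms. The window must not overlap the wavelet-invalid margin of
#' the epoch.
#'
#' @param stack A [tfr_trials()] `tfr_stack`.
#' @param band Two-element frequency band, Hz.
#' @param window_ms Two-element fit window relative to onset, ms —
#'   conventionally the 150 ms following the band's post-onset peak.
#' @return Tibble with columns `label`, `freq`, `slope`.
#' @export
per_frequency_gradients <- function(stack, band, window_ms) {
  stopifnot(inherits(stack, "tfr_stack"), length(window_ms) == 2,
            window_ms[1] < window_ms[2])
  rows <- which(stack$freqs >= band[1] & stack$freqs <= band[2])
  if (length(rows) == 0L) abort("band contains no analysis frequencies")
  cols <- which(stack$times_ms >= window_ms[1] & stack$times_ms <= window_ms[2])
  if (length(cols) < 2L) abort("gradient window too short for a linear fit")
  n_t <- length(stack$times_ms)
  marg <- max(stack$margin[rows])
  if (min(cols) <= marg || max(cols) > n_t - marg) {
    abort("gradient window overlaps the wavelet-invalid margin")
  }
  t_ms <- stack$times_ms[cols]
  purrr::map(unique(stack$labels), function(lab) {
    p <- stack$power[rows, cols, stack$labels == lab, drop = FALSE]
    avg <- apply(p, c(1, 2), mean)  # freq x time, trial-averaged
    tibble(
      label = lab, freq = stack$freqs[rows],
      slope = apply(avg, 1, function(y) unname(coef(lm(y ~ t_ms))[2]))
    )
  }) |> list_rbind()
}

#' Paired t test
#'
#' Classical two-tailed paired t test on elementwise differences, used to
#' compare hit versus miss per-frequency gradients (six in-band frequencies
#' give 5 degrees of freedom). Identical vectors return t = 0, p = 1 with
#' the `degenerate` flag set; constant non-zero differences (infinite t) are
#' an error.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 4, 6))
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (d[1] == 0) {
      return(tibble(t = 0, df = length(d) - 1, p = 1, mean_diff = 0,
                    degenerate = TRUE))
    }
    abort("differences have zero variance but non-zero mean: t undefined")
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Choose a stimulation frequency from two subjects' significant bands
#'
#' The stimulation frequency is the midpoint of the intersection of the two
#' significant frequency bands (10-17 Hz and 8-15 Hz intersect in 10-15 Hz,
#' giving 12.5 Hz).
#'
#' @param band_a,band_b Two-element frequency bands, Hz.
#' @return Midpoint of the band intersection, Hz.
#' @examples
#' select_stim_frequency(c(10, 17), c(8, 15))  # 12.5
#' @export
select_stim_frequency <- function(band_a, band_b) {
  stopifnot(length(band_a) == 2, length(band_b) == 2)
  lo <- max(band_a[1], band_b[1])
  hi <- min(band_a[2], band_b[2])
  if (lo > hi) abort("bands do not overlap; no common frequency")
  (lo + hi) / 2
}

#' Significant post-onset frequency band of a permutation outcome
#'
#' The range of frequencies with at least one significantly *increased*
#' cell after onset — the band-identification step between the permutation
#' test and stimulation-frequency selection.
#'
#' @param pt A [permutation_test()] result computed on post-vs-pre windows.
#' @param freqs Frequency axis of the grid rows.
#' @return Two-element band (Hz), or `NULL` when nothing is significant.
#' @export
significant_band <- function(pt, freqs) {
  stopifnot(inherits(pt, "perm_test"), length(freqs) == nrow(pt$observed))
  up <- pt$observed > pt$upper
  rows <- which(apply(up, 1, any))
  if (length(rows) == 0L) return(NULL)
  range(freqs[rows])
}
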