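#' rTMS pulse trains
#'
#' A pulse train is the set of pulse-onset times delivered during one sample
#' presentation epoch. Two kinds are used: a `beta` train delivers pulses at a
#' fixed inter-pulse interval (six pulses every 80 ms gives 12.5 Hz over the
#' 480-ms sample epoch), and a `random` train delivers the same number of
#' pulses in randomly chosen, non-adjacent 30-ms bins of the epoch.
#'
#' @param epoch_ms Sample presentation duration in ms.
#' @param isi_ms Inter-pulse interval in ms (beta train).
#' @param n_pulses Number of pulses in the train.
#' @param first_offset_ms Offset of the first pulse from sample onset, ms.
#'
#' @return A `pulse_train` object: a list with `times_ms` (ordered onsets
#'   relative to sample onset), `epoch_ms`, and `kind`.
#'
#' @examples
#' beta_pulse_train(480, 80, 6)
#' set.seed(1)
#' random_pulse_train(480, 30, 6)
#' @export
beta_pulse_train <- function(epoch_ms = 480, isi_ms = 80, n_pulses = 6,
                             first_offset_ms = 0) {
  stopifnot(epoch_ms > 0, isi_ms > 0, n_pulses >= 1, first_offset_ms >= 0)
  last <- first_offset_ms + (n_pulses - 1) * isi_ms
  if (last >= epoch_ms) {
    abort(sprintf(
      "beta pulse train does not fit: last pulse at %g ms but epoch is [0, %g) ms",
      last, epoch_ms
    ))
  }
  new_pulse_train(first_offset_ms + isi_ms * (seq_len(n_pulses) - 1),
                  epoch_ms, "beta")
}

#' @rdname beta_pulse_train
#' @param bin_ms Width of the scheduling bins in ms (random train). The epoch
#'   is divided into `epoch_ms / bin_ms` bins; `n_pulses` bins are drawn
#'   uniformly from all subsets with no two adjacent bins, and each pulse is
#'   placed at the start of its bin.
#' @export
random_pulse_train <- function(epoch_ms = 480, bin_ms = 30, n_pulses = 6) {
  stopifnot(epoch_ms > 0, bin_ms > 0, n_pulses >= 1)
  if (epoch_ms %% bin_ms != 0) {
    abort("epoch_ms must be divisible by bin_ms")
  }
  n_bins <- epoch_ms %/% bin_ms
  sets <- nonadjacent_bin_sets(n_bins, n_pulses)
  if (nrow(sets) == 0L) {
    abort(sprintf(
      "cannot place %d non-adjacent pulses in %d bins (max %d)",
      n_pulses, n_bins, ceiling(n_bins / 2)
    ))
  }
  bins <- sets[sample.int(nrow(sets), 1L), ]
  new_pulse_train((bins - 1L) * bin_ms, epoch_ms, "random")
}

new_pulse_train <- function(times_ms, epoch_ms, kind) {
  structure(
    list(times_ms = as.numeric(times_ms), epoch_ms = as.numeric(epoch_ms),
         kind = kind),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train: %s, %d pulses in [0, %g) ms>\n",
              x$kind, length(x$times_ms), x$epoch_ms))
  cat(" times (ms):", paste(x$times_ms, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all valid non-adjacent bin subsets
#'
#' All `k`-subsets of `1..n_bins` in which no two chosen bins are adjacent.
#' Enumeration is exhaustive so that [random_pulse_train()] samples uniformly
#' over the full set of admissible schedules; for the task defaults
#' (16 bins, 6 pulses) there are 462 such subsets.
#'
#' @param n_bins Number of bins.
#' @param k Subset size.
#' @return Integer matrix, one valid subset per row (sorted within row).
#' @export
nonadjacent_bin_sets <- function(n_bins, k) {
  key <- sprintf("bins:%d:%d", n_bins, k)
  if (!is.null(the[[key]])) return(the[[key]])
  stopifnot(n_bins >= 1, k >= 1)
  if (k > ceiling(n_bins / 2)) {
    out <- matrix(integer(0), nrow = 0, ncol = k)
  } else {
    cand <- combn(n_bins, k)
    ok <- apply(cand, 2, function(s) all(diff(s) >= 2L))
    out <- t(cand[, ok, drop = FALSE])
  }
  the[[key]] <- out
  out
}

#' Choose which samples in a list are targeted with rTMS
#'
#' Draws uniformly from the enumerated set of all admissible target
#' configurations: `n_targets` of the `n_samples` list positions with at
#' least `min_between` non-stimulated samples between any two targeted ones
#' (a TMS safety constraint limiting sustained high-frequency stimulation).
#' For the task defaults (4 of 12, at least 2 between) there are 15 valid
#' configurations.
#'
#' @param n_samples Length of the sample list.
#' @param n_targets Number of targeted positions.
#' @param min_between Minimum number of non-stimulated samples between any
#'   two targeted positions.
#' @return Sorted integer vector of 0-based targeted positions.
#' @export
sample_target_schedule <- function(n_samples = 12, n_targets = 4,
                                   min_between = 2) {
  sets <- spaced_target_sets(n_samples, n_targets, min_between)
  if (nrow(sets) == 0L) {
    abort(sprintf(
      "no valid configuration: %d targets in %d samples with >= %d between",
      n_targets, n_samples, min_between
    ))
  }
  sets[sample.int(nrow(sets), 1L), ]
}

#' @rdname sample_target_schedule
#' @export
spaced_target_sets <- function(n_samples, n_targets, min_between) {
  key <- sprintf("targets:%d:%d:%d", n_samples, n_targets, min_between)
  if (!is.null(the[[key]])) return(the[[key]])
  stopifnot(n_samples >= 1, n_targets >= 1, min_between >= 0)
  if (n_targets > n_samples) {
    out <- matrix(integer(0), nrow = 0, ncol = n_targets)
  } else {
    cand <- combn(n_samples, n_targets) - 1L  # 0-based positions
    ok <- apply(cand, 2, function(s) all(diff(s) >= min_between + 1L))
    out <- t(cand[, ok, drop = FALSE])
  }
  the[[key]] <- out
  out
}
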