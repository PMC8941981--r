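#' Run configuration for the two experiment arms
#'
#' Bundles every stage parameter with defaults set to the study's values:
#' 8-60 Hz in 1-Hz steps, 800-ms pre/post windows, 10,000 permutations at a
#' two-tailed .05 level, 346 hit / 118 miss trials, 480-ms samples with
#' six-pulse trains (80-ms ISI; 30-ms random bins), 12-sample lists with 4
#' targets, 3 subsessions of 15 blocks, and 9 participants per stimulation
#' site. Every parameter is validated by the stage that consumes it; override
#' any of them for reduced-scale runs.
#'
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @param lfp Named list of overrides for the LFP arm.
#' @param behavior Named list of overrides for the behavioural arm.
#' @return A `run_config` list with `seed`, `lfp`, `behavior`.
#' @export
run_config <- function(seed = 1, lfp = list(), behavior = list()) {
  lfp_def <- list(
    n_hit = 346, n_miss = 118, fs = 1000, epoch_ms = c(-1000, 1000),
    burst = burst_spec(), noise = noise_config(),
    freqs = 8:60, n_cycles = 7,
    pre_ms = c(-800, 0), post_ms = c(0, 800),
    n_perm = 10000, alpha = 0.05, scheme = "pooled",
    band = NULL,               # NULL: take the significant band from the data
    peak_window_ms = c(0, 500), gradient_len_ms = 150
  )
  beh_def <- list(
    n_per_site = 9, sites = c("dlPFC", "vertex"),
    design = design_config(),
    R = 0.4, dprime = 1.85, criteria = c(2.0, 1.55, 1.175, 0.75, 0.3),
    delta_R_dlPFC = 0.15, delta_R_random = 0, delta_d = 0,
    spillover = 0, lapse = 0
  )
  bad <- setdiff(names(lfp), names(lfp_def))
  if (length(bad)) abort(paste("unknown lfp parameter(s):", paste(bad, collapse = ", ")))
  bad <- setdiff(names(behavior), names(beh_def))
  if (length(bad)) abort(paste("unknown behavior parameter(s):", paste(bad, collapse = ", ")))
  lfp_def[names(lfp)] <- lfp
  beh_def[names(behavior)] <- behavior
  structure(list(seed = as.integer(seed), lfp = lfp_def, behavior = beh_def),
            class = "run_config")
}

# deterministic per-stage substream, kept below 2^31
derive_seed <- function(seed, stage, k = 0L) {
  (as.integer(seed) * 7919L + match(stage, c("lfp", "behavior")) * 1299709L +
     as.integer(k) * 104729L) %% 2147483629L
}

#' Run the LFP arm end to end
#'
#' Generates labelled trials, baseline-RMS-normalises them, computes the
#' Morlet TFR stack, runs the max/min-statistic permutation test separately
#' on hit and miss trials (post vs pre windows), identifies the significant
#' post-onset band from the hit outcome, averages power in that band,
#' locates its peak, fits per-frequency post-peak gradients over the 150 ms
#' after the peak, and compares hit versus miss gradients with a paired t
#' test.
#'
#' @param config A [run_config()].
#' @param out Optional directory; when given, maps, masks, gradients and a
#'   run log (seed and parameter echo) are written there as CSV/JSON.
#' @return An `lfp_report` list: `band`, `peak_ms`, `gradients`,
#'   `gradient_test`, `perm` (hit/miss outcomes), `band_power`, `config`.
#' @export
run_lfp_arm <- function(config = run_config(), out = NULL) {
  stopifnot(inherits(config, "run_config"))
  p <- config$lfp
  set.seed(derive_seed(config$seed, "lfp"))

  lfp <- generate_trials(p$n_hit, p$n_miss, burst = p$burst, noise = p$noise,
                         fs = p$fs, epoch_ms = p$epoch_ms)
  stack <- tfr_trials(lfp, freqs = p$freqs, n_cycles = p$n_cycles)

  perm <- purrr::map(c(hit = "hit", miss = "miss"), function(lab) {
    if (!any(stack$labels == lab)) return(NULL)
    w <- tfr_windows(stack, p$pre_ms, p$post_ms, labels = lab)
    permutation_test(w$pre, w$post, n_perm = p$n_perm, alpha = p$alpha,
                     scheme = p$scheme)
  })

  band <- p$band
  if (is.null(band) && !is.null(perm$hit)) {
    band <- significant_band(perm$hit, p$freqs)
  }

  band_power <- NULL
  peak_ms <- NA_real_
  gradients <- NULL
  gradient_test <- NULL
  if (!is.null(band)) {
    band_power <- band_average(stack, band)
    hit_tc <- band_power[band_power$label == "hit", ]
    peak_ms <- peak_latency(hit_tc, p$peak_window_ms)
    gradients <- per_frequency_gradients(
      stack, band, window_ms = c(peak_ms, peak_ms + p$gradient_len_ms))
    if (all(c("hit", "miss") %in% gradients$label)) {
      gradient_test <- paired_t(
        gradients$slope[gradients$label == "hit"],
        gradients$slope[gradients$label == "miss"])
    }
  }

  report <- structure(
    list(band = band, peak_ms = peak_ms, gradients = gradients,
         gradient_test = gradient_test, perm = perm,
         band_power = band_power, config = config),
    class = "lfp_report"
  )
  if (!is.null(out)) write_lfp_report(report, out)
  report
}

write_lfp_report <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  jsonlite::write_json(
    list(seed = cfg$seed,
         lfp = cfg$lfp[setdiff(names(cfg$lfp), c("burst", "noise"))],
         burst = unclass(cfg$lfp$burst), noise = cfg$lfp$noise,
         band = report$band, peak_ms = report$peak_ms),
    file.path(out, "lfp_run_log.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  for (lab in names(report$perm)) {
    pt <- report$perm[[lab]]
    if (is.null(pt)) next
    utils::write.csv(tidy(pt, freqs = cfg$lfp$freqs),
                     file.path(out, sprintf("perm_%s.csv", lab)),
                     row.names = FALSE)
  }
  if (!is.null(report$gradients)) {
    utils::write.csv(report$gradients, file.path(out, "gradients.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$band_power)) {
    utils::write.csv(report$band_power, file.path(out, "band_power.csv"),
                     row.names = FALSE)
  }
  invisible(out)
}

#' Run the behavioural arm end to end
#'
#' Builds a session design and simulates DPSD responses for every
#' participant at both stimulation sites (the recollection decrement
#' `delta_R_dlPFC` applies to beta-targeted trials of dlPFC participants
#' only), then computes within-block (R+/R-/F+/F-), between-block (R, F per
#' condition) and hit-rate tables.
#'
#' @param config A [run_config()].
#' @param out Optional directory for tidy CSV exports (for external ANOVA)
#'   and a run log.
#' @return A `behavior_report` list: `records`, `within`, `between`,
#'   `hit_rates`, `config`.
#' @export
run_behavior_arm <- function(config = run_config(), out = NULL) {
  stopifnot(inherits(config, "run_config"))
  p <- config$behavior
  records <- purrr::map(seq_along(p$sites), function(si) {
    site <- p$sites[si]
    purrr::map(seq_len(p$n_per_site), function(i) {
      k <- (si - 1L) * p$n_per_site + i
      design <- build_session(p$design, seed = derive_seed(config$seed, "behavior", k))
      model <- participant_model(
        R = p$R, dprime = p$dprime, criteria = p$criteria,
        delta_R = if (site == "dlPFC") p$delta_R_dlPFC else 0,
        delta_R_random = if (site == "dlPFC") p$delta_R_random else 0,
        delta_d = if (site == "dlPFC") p$delta_d else 0,
        spillover = p$spillover, lapse = p$lapse, site = site
      )
      set.seed(derive_seed(config$seed, "behavior", 10000L + k))
      simulate_responses(model, design,
                         participant = sprintf("%s_%02d", site, i))
    }) |> list_rbind()
  }) |> list_rbind()

  within <- within_block_indices(records)
  between <- between_block_indices(records)
  hit_rates <- records |>
    filter(.data$trial_type == "match") |>
    group_by(.data$participant, .data$site, .data$condition) |>
    summarise(hit_rate = mean(.data$correct), n_match = n(), .groups = "drop")

  report <- structure(
    list(records = records, within = within, between = between,
         hit_rates = hit_rates, config = config),
    class = "behavior_report"
  )
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out, "records.csv"), row.names = FALSE)
    write_index_table(within, file.path(out, "within_block_indices.csv"))
    write_index_table(between, file.path(out, "between_block_indices.csv"))
    utils::write.csv(hit_rates, file.path(out, "hit_rates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           behavior = p[setdiff(names(p), "design")], design = p$design),
      file.path(out, "behavior_run_log.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  report
}

#' @export
print.lfp_report <- function(x, ...) {
  cat("<lfp_report>\n")
  if (is.null(x$band)) {
    cat(" no significant post-onset band\n")
  } else {
    cat(sprintf(" significant band: %g-%g Hz, peak at %g ms\n",
                x$band[1], x$band[2], x$peak_ms))
    if (!is.null(x$gradient_test)) {
      cat(sprintf(" hit vs miss gradient: t(%d) = %.3f, p = %.4g\n",
                  x$gradient_test$df, x$gradient_test$t, x$gradient_test$p))
    }
  }
  invisible(x)
}

#' @export
print.behavior_report <- function(x, ...) {
  cat("<behavior_report>\n")
  s <- x$within |>
    group_by(.data$site, .data$condition, .data$stratum) |>
    summarise(R = mean(.data$R), F = mean(.data$F), .groups = "drop")
  print(as.data.frame(s), digits = 3)
  invisible(x)
}
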