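#' Configuration for a stimulation session design
#'
#' Defaults reproduce the human rTMS experiment's structure: 3 subsessions of
#' 15 blocks (each stimulation condition 5 times per subsession, randomly
#' ordered), 12-sample encoding lists with 4 targeted samples separated by at
#' least 2 non-stimulated samples, 480-ms sample epochs, six-pulse trains
#' (80-ms inter-pulse interval for beta, non-adjacent 30-ms bins for random),
#' and 6 match + 6 nonmatch test trials per block — 540 test trials in all.
#'
#' @param n_subsessions,blocks_per_subsession Session structure.
#' @param conditions Stimulation conditions cycled within each subsession;
#'   `blocks_per_subsession` must be a multiple of their number.
#' @param n_samples Encoding-list length per block.
#' @param n_targets,min_between Target-schedule constraint (see
#'   [sample_target_schedule()]).
#' @param n_match,n_nonmatch Test-trial composition per block.
#' @param epoch_ms Sample presentation duration, ms.
#' @param pulse_isi_ms,n_pulses Beta-train inter-pulse interval and count.
#' @param bin_ms Random-train bin width, ms.
#' @param sample_isi_ms Inter-sample interval, ms (metadata only).
#' @return A named list of validated design parameters.
#' @export
design_config <- function(n_subsessions = 3, blocks_per_subsession = 15,
                          conditions = c("beta", "random", "none"),
                          n_samples = 12, n_targets = 4, min_between = 2,
                          n_match = 6, n_nonmatch = 6,
                          epoch_ms = 480, pulse_isi_ms = 80, n_pulses = 6,
                          bin_ms = 30, sample_isi_ms = 350) {
  cfg <- as.list(environment())
  stopifnot(n_subsessions >= 1, blocks_per_subsession >= 1,
            n_samples >= 1, n_match >= 0, n_nonmatch >= 0)
  if (blocks_per_subsession %% length(conditions) != 0) {
    abort("blocks_per_subsession must be a multiple of the number of conditions")
  }
  if (n_match > n_samples) {
    abort("n_match cannot exceed n_samples: every match test stimulus must have been a sample")
  }
  if (any(c("beta", "random") %in% conditions) &&
      nrow(spaced_target_sets(n_samples, n_targets, min_between)) == 0L) {
    abort("no valid target schedule exists for (n_samples, n_targets, min_between)")
  }
  cfg
}

#' Build a randomized session design
#'
#' Generates the full block/session structure of the recognition-memory rTMS
#' experiment: per subsession a random ordering of the stimulation conditions,
#' per block a fresh list of session-unique sample stimuli, a target schedule
#' and pulse trains for stimulated blocks, and a counterbalanced, shuffled
#' test phase (match trials drawn from that block's samples, nonmatch trials
#' using novel stimuli).
#'
#' @param config A [design_config()] list.
#' @param seed Optional integer seed for reproducibility; if supplied the
#'   global RNG is seeded, so identical seeds give identical designs.
#' @return A `session_design` object with elements `config`, `seed`,
#'   `blocks` (tibble: subsession, block, condition), `samples` (tibble:
#'   block, position, stimulus_id, targeted), `schedules` (per-block list of
#'   targeted positions and [beta_pulse_train()]/[random_pulse_train()]
#'   objects) and `trials` (tibble: block, condition, trial_index,
#'   stimulus_id, trial_type, targeted).
#' @examples
#' d <- build_session(seed = 42)
#' nrow(d$trials)  # 540
#' @export
build_session <- function(config = design_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- config$conditions
  per <- config$blocks_per_subsession / length(conds)
  n_blocks <- config$n_subsessions * config$blocks_per_subsession

  blocks <- purrr::map(seq_len(config$n_subsessions), function(ss) {
    tibble(subsession = ss,
           condition = sample(rep(conds, per)))
  }) |>
    list_rbind() |>
    mutate(block = row_number(), .before = 1)

  next_id <- 0L
  samples_l <- vector("list", n_blocks)
  sched_l <- vector("list", n_blocks)
  trials_l <- vector("list", n_blocks)

  for (b in seq_len(n_blocks)) {
    cond <- blocks$condition[b]
    sample_ids <- next_id + seq_len(config$n_samples)
    next_id <- next_id + config$n_samples

    if (cond %in% c("beta", "random")) {
      targets <- sample_target_schedule(config$n_samples, config$n_targets,
                                        config$min_between)
      trains <- purrr::map(targets, function(pos) {
        if (cond == "beta") {
          beta_pulse_train(config$epoch_ms, config$pulse_isi_ms,
                           config$n_pulses)
        } else {
          random_pulse_train(config$epoch_ms, config$bin_ms, config$n_pulses)
        }
      })
    } else {
      targets <- integer(0)
      trains <- list()
    }
    sched_l[[b]] <- list(condition = cond, targeted_samples = targets,
                         pulse_trains = trains)

    positions <- seq_len(config$n_samples) - 1L
    samples_l[[b]] <- tibble(
      block = b, position = positions, stimulus_id = sample_ids,
      targeted = positions %in% targets
    )

    match_pos <- sample(positions, config$n_match)
    nonmatch_ids <- next_id + seq_len(config$n_nonmatch)
    next_id <- next_id + config$n_nonmatch

    tt <- tibble(
      block = b, condition = cond,
      stimulus_id = c(sample_ids[match_pos + 1L], nonmatch_ids),
      trial_type = rep(c("match", "nonmatch"),
                       c(config$n_match, config$n_nonmatch)),
      targeted = c(match_pos %in% targets, rep(NA, config$n_nonmatch)),
      circle_side = sample(c("left", "right"),
                           config$n_match + config$n_nonmatch, replace = TRUE)
    )
    trials_l[[b]] <- tt[sample.int(nrow(tt)), ] |>
      mutate(trial_index = row_number(), .after = "condition")
  }

  structure(
    list(config = config, seed = seed, blocks = blocks,
         samples = list_rbind(samples_l), schedules = sched_l,
         trials = list_rbind(trials_l)),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf(
    "<session_design: %d subsessions x %d blocks, %d test trials, seed %s>\n",
    x$config$n_subsessions, x$config$blocks_per_subsession, nrow(x$trials),
    if (is.null(x$seed)) "unset" else x$seed
  ))
  invisible(x)
}

#' Test-trial table of a session design
#'
#' @param design A [build_session()] result.
#' @return Tibble with one row per test trial: block, condition, trial_index,
#'   stimulus_id, trial_type, targeted.
#' @export
session_trials <- function(design) {
  stopifnot(inherits(design, "session_design"))
  design$trials |>
    select("block", "condition", "trial_index", "stimulus_id", "trial_type",
           "targeted")
}

#' Serialize a session design to JSON
#'
#' @param design A `session_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(design, path) {
  stopifnot(inherits(design, "session_design"))
  x <- list(
    config = design$config,
    seed = design$seed,
    blocks = design$blocks,
    samples = design$samples,
    schedules = purrr::map(design$schedules, function(s) {
      list(condition = s$condition, targeted_samples = s$targeted_samples,
           pulse_trains = purrr::map(s$pulse_trains, unclass))
    }),
    trials = design$trials
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
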