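#' Generative dual-process observer model
#'
#' Parameterises a simulated participant under the dual-process
#' signal-detection (DPSD) account of recognition: a studied (match) item is
#' recollected with probability `R`, yielding a highest-confidence "old"
#' response; otherwise an old/new decision is read off a Gaussian familiarity
#' strength (mean `dprime`, SD 1 for targets; mean 0, SD 1 for lures) binned
#' by five ordered criteria. Stimulation effects are modelled as decrements
#' applied to trials whose sample was rTMS-targeted.
#'
#' @param R Baseline recollection probability, in `[0, 1]`.
#' @param dprime Baseline familiarity sensitivity (SD units).
#' @param criteria Five strictly decreasing criteria on the strength axis;
#'   `criteria[1]` is the strictest (highest) "old" threshold. The defaults
#'   (with `R` and `dprime`) are calibrated so the observer produces roughly
#'   85% overall accuracy with a ~12% false-alarm rate, the performance level
#'   typical of this task.
#' @param delta_R Recollection decrement on beta-targeted match trials.
#' @param delta_R_random Recollection decrement on random-targeted trials.
#' @param delta_d Familiarity decrement on beta-targeted trials.
#' @param spillover Fraction of the applicable recollection decrement applied
#'   to *untargeted* match trials of stimulated blocks (0 = targeted only).
#' @param lapse Probability that a response is replaced by a uniform draw
#'   over the six confidence levels.
#' @param site Stimulation site label carried into the records ("dlPFC" or
#'   "vertex"); metadata only — effects are whatever the deltas say.
#' @param recollect_levels Confidence levels over which a recollected
#'   response is spread (default `1`: always "absolutely certain old").
#' @return A `participant_model` list.
#' @export
participant_model <- function(R = 0.4, dprime = 1.85,
                              criteria = c(2.0, 1.55, 1.175, 0.75, 0.3),
                              delta_R = 0, delta_R_random = 0, delta_d = 0,
                              spillover = 0, lapse = 0, site = "dlPFC",
                              recollect_levels = 1L) {
  stopifnot(R >= 0, R <= 1, length(criteria) == 5,
            all(diff(criteria) < 0), lapse >= 0, lapse <= 1,
            spillover >= 0, spillover <= 1,
            all(recollect_levels %in% 1:6))
  structure(as.list(environment()), class = "participant_model")
}

#' Map an old/new decision and 1-3 confidence rating to a 6-point level
#'
#' Level 1 is "absolutely certain old" through level 6, "absolutely certain
#' new": an "old" decision with rating r maps to level `4 - r`, a "new"
#' decision to `3 + r`.
#'
#' @param decision Character vector, `"old"` or `"new"`.
#' @param rating Integer vector in 1..3 (1 somewhat, 3 absolutely confident).
#' @return Integer level(s) in 1..6.
#' @examples
#' confidence_to_level("old", 3)  # 1
#' confidence_to_level("new", 3)  # 6
#' @export
confidence_to_level <- function(decision, rating) {
  if (!all(decision %in% c("old", "new"))) abort("decision must be 'old' or 'new'")
  if (!all(rating %in% 1:3)) abort("rating must be an integer in 1..3")
  ifelse(decision == "old", 4L - as.integer(rating), 3L + as.integer(rating))
}

level_to_decision <- function(level) ifelse(level <= 3L, "old", "new")
level_to_rating <- function(level) ifelse(level <= 3L, 4L - level, level - 3L)

#' Simulate confidence-rated recognition responses for one participant
#'
#' Runs the DPSD generative process over every test trial of a session
#' design. Match trials are recollected with the trial's effective
#' recollection probability (baseline minus the applicable stimulation
#' decrement, clamped to `[0, 1]`); non-recollected match trials draw
#' strength from `Normal(dprime_eff, 1)` and nonmatch trials from
#' `Normal(0, 1)`, binned by the model criteria (strength above the strictest
#' criterion gives level 1, below the most liberal gives level 6; "old" iff
#' level <= 3).
#'
#' @param model A [participant_model()].
#' @param design A [build_session()] design.
#' @param participant Participant identifier carried into the records.
#' @return Tibble of response records: participant, site, condition, block,
#'   trial_index, trial_type, targeted, decision, rating, level, correct.
#' @examples
#' d <- build_session(seed = 1)
#' set.seed(2)
#' r <- simulate_responses(participant_model(R = 1), d)
#' all(r$level[r$trial_type == "match"] == 1)  # recollection saturates
#' @export
simulate_responses <- function(model, design, participant = "P01") {
  stopifnot(inherits(model, "participant_model"),
            inherits(design, "session_design"))
  tr <- design$trials
  n <- nrow(tr)
  is_match <- tr$trial_type == "match"
  targeted <- !is.na(tr$targeted) & tr$targeted

  delta <- rep(0, n)
  delta[tr$condition == "beta"] <- model$delta_R
  delta[tr$condition == "random"] <- model$delta_R_random
  frac <- ifelse(targeted, 1, ifelse(tr$condition == "none", 0, model$spillover))
  R_eff <- pmin(1, pmax(0, model$R - delta * frac))

  d_eff <- rep(model$dprime, n)
  d_eff[tr$condition == "beta" & targeted] <- model$dprime - model$delta_d

  # every trial draws the same number of random variates regardless of the
  # deltas, so one RNG stream yields aligned responses across effect sizes
  recollected <- is_match & (runif(n) < R_eff)
  mu <- ifelse(is_match, d_eff, 0)
  strength <- rnorm(n, mean = mu, sd = 1)
  level <- 1L + colSums(outer(model$criteria, strength, ">"))
  rec_lev <- sample(as.integer(model$recollect_levels), n, replace = TRUE)
  level[recollected] <- rec_lev[recollected]
  if (model$lapse > 0) {
    lapsed <- runif(n) < model$lapse
    level[lapsed] <- sample(1:6, n, replace = TRUE)[lapsed]
  }

  decision <- level_to_decision(level)
  tibble(
    participant = participant, site = model$site,
    condition = tr$condition, block = tr$block,
    trial_index = tr$trial_index, trial_type = tr$trial_type,
    targeted = tr$targeted, decision = decision,
    rating = level_to_rating(level), level = as.integer(level),
    correct = (is_match & decision == "old") | (!is_match & decision == "new")
  )
}
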