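#' Hit rate of match trials
#'
#' Proportion of match trials answered "old" (hits) among all match trials in
#' the supplied records. Nonmatch trials are never counted — they contain no
#' old stimuli — so filter the records to the stratum of interest first.
#'
#' @param records Response-record tibble (see [simulate_responses()]).
#' @return A single proportion in `[0, 1]`.
#' @examples
#' rec <- tibble::tibble(trial_type = c("match", "match", "match", "match"),
#'                       correct = c(TRUE, TRUE, TRUE, FALSE))
#' hit_rate(rec)  # 0.75
#' @export
hit_rate <- function(records) {
  m <- records[records$trial_type == "match", ]
  if (nrow(m) == 0L) abort("no match trials in the supplied stratum")
  mean(m$correct)
}

fit_stratum <- function(match_rec, nonmatch_rec) {
  roc <- build_roc(bind_rows(match_rec, nonmatch_rec))
  fit <- fit_dpsd(roc)
  tibble(R = fit$R, F = fit$F, hit_rate = hit_rate(match_rec),
         n_match = nrow(match_rec), n_nonmatch = nrow(nonmatch_rec),
         refit_applied = fit$refit_applied)
}

#' Within-block recollection and familiarity indices (R+/R-, F+/F-)
#'
#' For each participant and each stimulated condition (beta, random), fits
#' the DPSD model twice: once on match trials whose samples were
#' rTMS-targeted (the `+` stratum) and once on match trials whose samples
#' were not (`-`), each against the same false-alarm base — all nonmatch
#' trials of that condition's blocks (nonmatch trials have no
#' targeted/untargeted identity).
#'
#' @param records Response records for one or more participants.
#' @param conditions Stimulated conditions to analyse; the no-stimulation
#'   condition is rejected (it has no targeted stratum).
#' @return Tibble keyed by (participant, site, condition, stratum) with
#'   columns R, F, hit_rate, n_match, n_nonmatch, refit_applied. `stratum`
#'   is `"targeted"` or `"untargeted"`.
#' @export
within_block_indices <- function(records, conditions = c("beta", "random")) {
  if ("none" %in% conditions) {
    abort("the no-stimulation condition has no targeted stratum; within-block indices are undefined for it")
  }
  combos <- dplyr::distinct(records[records$condition %in% conditions, ],
                            .data$participant, .data$site, .data$condition)
  if (nrow(combos) == 0L) abort("no records in the requested conditions")
  purrr::pmap(combos, function(participant, site, condition) {
    rec <- records[records$participant == participant &
                     records$condition == condition, ]
    nonmatch <- rec[rec$trial_type == "nonmatch", ]
    purrr::map(c(TRUE, FALSE), function(tg) {
      m <- rec[rec$trial_type == "match" & !is.na(rec$targeted) &
                 rec$targeted == tg, ]
      if (nrow(m) == 0L) {
        abort(sprintf(
          "participant %s, condition %s: zero %s match trials",
          participant, condition, if (tg) "targeted" else "untargeted"
        ))
      }
      mutate(fit_stratum(m, nonmatch),
             participant = participant, site = site, condition = condition,
             stratum = if (tg) "targeted" else "untargeted",
             .before = 1)
    }) |> list_rbind()
  }) |>
    list_rbind()
}

#' Between-block recollection and familiarity indices per condition
#'
#' For each participant, fits the DPSD model once per stimulation condition.
#' Match-trial inclusion mirrors the between-block analysis design: for beta
#' and random blocks only match trials whose samples were targeted; for
#' no-stimulation blocks all match trials. The false-alarm base is each
#' condition's full set of nonmatch trials.
#'
#' @param records Response records; all three conditions must be present for
#'   every participant.
#' @return Tibble keyed by (participant, site, condition) with columns R, F,
#'   hit_rate, n_match, n_nonmatch, refit_applied.
#' @export
between_block_indices <- function(records) {
  conds <- c("beta", "random", "none")
  combos <- dplyr::distinct(records, .data$participant, .data$site)
  purrr::pmap(combos, function(participant, site) {
    rec <- records[records$participant == participant, ]
    missing <- setdiff(conds, unique(rec$condition))
    if (length(missing) > 0L) {
      abort(sprintf("participant %s: missing condition(s) %s",
                    participant, paste(missing, collapse = ", ")))
    }
    purrr::map(conds, function(cond) {
      rc <- rec[rec$condition == cond, ]
      m <- rc[rc$trial_type == "match", ]
      if (cond != "none") m <- m[!is.na(m$targeted) & m$targeted, ]
      if (nrow(m) == 0L) {
        abort(sprintf("participant %s, condition %s: empty match stratum",
                      participant, cond))
      }
      mutate(fit_stratum(m, rc[rc$trial_type == "nonmatch", ]),
             participant = participant, site = site, condition = cond,
             .before = 1)
    }) |> list_rbind()
  }) |>
    list_rbind()
}

#' Export an index table as a tidy long-format CSV
#'
#' Writes the (participant, site, condition and optionally stratum) index table in the
#' long format consumed by standard ANOVA software; the mixed / repeated
#' measures ANOVAs themselves are deliberately out of scope here.
#'
#' @param table An index tibble from [within_block_indices()] or
#'   [between_block_indices()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
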