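# shared fixtures, all built in code

# roc_points from raw coordinates (bypasses record counting)
make_roc <- function(fa, hit, n_target = 1000, n_lure = 1000) {
  structure(list(points = tibble::tibble(level = seq_along(fa), fa = fa,
                                         hit = hit),
                 n_target = n_target, n_lure = n_lure),
            class = "roc_points")
}

# noise-free ROC generated by the DPSD forward model
roc_from_truth <- function(R, F, crit = c(1.2, 0.6, 0, -0.6, -1.2)) {
  p <- dpsd_predict(R, F, crit)
  make_roc(p$fa, p$hit)
}

# direct generative draw of confidence levels (independent of the session
# machinery): threshold recollection + Gaussian familiarity, binned
gen_levels <- function(n, R, F, crit = c(1.2, 0.6, 0, -0.6, -1.2)) {
  lev_t <- ifelse(runif(n) < R, 1L,
                  1L + colSums(outer(crit, rnorm(n, F), ">")))
  lev_l <- 1L + colSums(outer(crit, rnorm(n), ">"))
  tibble::tibble(trial_type = rep(c("match", "nonmatch"), each = n),
                 level = as.integer(c(lev_t, lev_l)))
}

# simulate a cohort of participants on one shared session design
sim_cohort <- function(n = 9, design_seed = 1, site = "dlPFC", R = 0.4,
                       dprime = 1.85, delta_R = 0, delta_R_random = 0) {
  design <- build_session(seed = design_seed)
  purrr::map(seq_len(n), function(i) {
    m <- participant_model(R = R, dprime = dprime, delta_R = delta_R,
                           delta_R_random = delta_R_random, site = site)
    simulate_responses(m, design, participant = sprintf("%s_%02d", site, i))
  }) |> purrr::list_rbind()
}

# tfr_stack built directly from a power array (for arithmetic oracles)
make_stack <- function(power, freqs, times_ms, labels, margin = 0L) {
  structure(list(power = power, freqs = freqs, times_ms = times_ms,
                 fs = 1000, labels = labels,
                 margin = rep(as.integer(margin), length(freqs)),
                 n_cycles = 7),
            class = "tfr_stack")
}
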