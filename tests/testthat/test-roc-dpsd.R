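test_that("cumulative ROC points match hand-counted tallies", {
  rec <- tibble::tibble(
    trial_type = rep(c("match", "nonmatch"), each = 6),
    level = c(1, 1, 2, 3, 4, 6, 3, 4, 5, 6, 6, 6)
  )
  roc <- build_roc(rec)
  expect_equal(roc$points$fa, c(0, 0, 1 / 6, 2 / 6, 3 / 6))
  expect_equal(roc$points$hit, c(2 / 6, 3 / 6, 4 / 6, 5 / 6, 5 / 6))
  expect_equal(roc$n_target, 6)
  expect_equal(roc$n_lure, 6)

  # perfect separation and exchangeable distributions
  sep <- tibble::tibble(trial_type = rep(c("match", "nonmatch"), each = 4),
                        level = rep(c(1, 6), each = 4))
  expect_true(all(build_roc(sep)$points$hit == 1))
  expect_true(all(build_roc(sep)$points$fa == 0))
  same <- tibble::tibble(trial_type = rep(c("match", "nonmatch"), each = 6),
                         level = rep(1:6, 2))
  pts <- build_roc(same)$points
  expect_equal(pts$hit, pts$fa)

  expect_error(build_roc(rec[rec$trial_type == "match", ]), "0 nonmatch")
  # reversed-coding direction flag flips the cumulation
  rev_pts <- build_roc(rec, direction = "new_first")$points
  expect_equal(rev_pts$hit[1], mean(c(1, 1, 2, 3, 4, 6) >= 6))
})

test_that("dpsd_predict matches the normal-CDF closed form", {
  expect_equal(unlist(dpsd_predict(0, 0, 0)[, c("fa", "hit")]),
               c(fa = 0.5, hit = 0.5))
  expect_equal(dpsd_predict(1, 0.3, c(-2, 0, 2))$hit, rep(1, 3))
  p <- dpsd_predict(0.3, 1.0, 0)
  expect_equal(p$fa, 0.5)
  expect_equal(p$hit, 0.3 + 0.7 * pnorm(1))
  # vectorised criteria give monotone liberal-ward rates
  pp <- dpsd_predict(0.2, 0.8, c(1.5, 0.5, -0.5, -1.5))
  expect_true(all(diff(pp$fa) > 0))
  expect_true(all(diff(pp$hit) > 0))
  expect_error(dpsd_predict(1.2, 1, 0))
})

test_that("noise-free ROCs are recovered to high precision", {
  cases <- list(c(R = 0.3, F = 1.0), c(R = 0.6, F = 0.4),
                c(R = 0.5, F = 0))  # pure-threshold limit
  for (cs in cases) {
    fit <- fit_dpsd(roc_from_truth(cs["R"], cs["F"]))
    expect_lt(abs(fit$R - cs["R"]), 1e-3)
    expect_lt(abs(fit$F - cs["F"]), 1e-3)
    expect_lt(fit$sse, 1e-8)
    expect_false(fit$refit_applied)
  }
})

test_that("chance-level ROCs trigger the fix-R-to-zero refit rule", {
  crit <- c(1.2, 0.6, 0, -0.6, -1.2)
  diag_roc <- make_roc(pnorm(-crit), pnorm(-crit))
  fit <- fit_dpsd(diag_roc)
  expect_equal(fit$R, 0)
  expect_lt(abs(fit$F), 1e-3)
  # a below-chance ROC forces an initially negative R, then the refit
  below <- make_roc(pnorm(-crit), pnorm(-crit - 0.4))
  fit2 <- fit_dpsd(below)
  expect_true(fit2$refit_applied)
  expect_equal(fit2$R, 0)
})

test_that("fit is invariant to the order of the supplied points", {
  roc <- roc_from_truth(0.35, 0.9)
  shuffled <- roc
  set.seed(1)
  shuffled$points <- shuffled$points[sample.int(5), ]
  a <- fit_dpsd(roc)
  b <- fit_dpsd(shuffled)
  expect_equal(a$R, b$R, tolerance = 1e-8)
  expect_equal(a$F, b$F, tolerance = 1e-8)
})

test_that("optimum beats random admissible parameter draws and is monotone", {
  set.seed(6)
  rec <- gen_levels(400, 0.3, 1.2)
  roc <- build_roc(rec)
  fit <- fit_dpsd(roc)
  sse_at <- function(R, F, crit) {
    sum((roc$points$fa - pnorm(-crit))^2 +
          (roc$points$hit - (R + (1 - R) * pnorm(F - crit)))^2)
  }
  rand_sse <- replicate(100, {
    sse_at(runif(1), runif(1, 0, 3), sort(runif(5, -2, 2), decreasing = TRUE))
  })
  expect_lte(fit$sse, min(rand_sse))
  # fitted criteria are strictly decreasing; predicted curve is monotone
  expect_true(all(diff(fit$criteria) < 0))
  pred <- dpsd_predict(fit$R, fit$F, fit$criteria)
  expect_true(all(diff(pred$fa) >= 0))
  expect_true(all(diff(pred$hit) >= 0))
})

test_that("degenerate ROCs are flagged, and broom/ggplot methods work", {
  expect_warning(fit <- fit_dpsd(make_roc(rep(0.3, 5), rep(0.6, 5))),
                 "degenerate")
  expect_true(fit$degenerate)

  fit2 <- fit_dpsd(roc_from_truth(0.3, 1))
  td <- generics::tidy(fit2)
  expect_equal(td$term, c("R", "F", paste0("c", 1:5)))
  gl <- generics::glance(fit2)
  expect_equal(nrow(gl), 1)
  expect_s3_class(ggplot2::autoplot(fit2), "ggplot")
  expect_s3_class(ggplot2::autoplot(fit2$roc), "ggplot")
})
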