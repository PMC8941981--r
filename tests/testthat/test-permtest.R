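test_that("median-difference map matches a sort-based oracle", {
  pre_same <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  expect_equal(median_diff_map(pre_same, pre_same), matrix(0, 2, 3))

  pre_c <- array(1, c(2, 2, 3))
  post_c <- array(3, c(2, 2, 3))
  expect_equal(median_diff_map(pre_c, post_c), matrix(2, 2, 2))

  set.seed(51)
  pre <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  post <- array(rnorm(4 * 5 * 7), c(4, 5, 7))
  oracle <- apply(post, c(1, 2), function(v) sort(v)[4]) -
    apply(pre, c(1, 2), function(v) sort(v)[2])
  expect_equal(median_diff_map(pre, post), oracle)

  expect_error(median_diff_map(pre, array(0, c(3, 5, 3))), "shape")
})

test_that("exhaustive thresholds equal brute-force enumeration exactly", {
  set.seed(52)
  pre <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  post <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  pt <- permutation_test(pre, post, exhaustive = TRUE, alpha = 0.05)
  expect_equal(pt$n_perm, choose(8, 4))

  # independent enumeration: every 4-subset of the 8 segments as "post"
  S <- cbind(matrix(pre, 6, 4), matrix(post, 6, 4))
  splits <- combn(8, 4)
  ext <- apply(splits, 2, function(A) {
    B <- setdiff(1:8, A)
    d <- apply(S[, A, drop = FALSE], 1, median) -
      apply(S[, B, drop = FALSE], 1, median)
    c(max(d), min(d))
  })
  expect_equal(pt$upper, unname(quantile(ext[1, ], 0.975, type = 7)))
  expect_equal(pt$lower, unname(quantile(ext[2, ], 0.025, type = 7)))
  expect_equal(sort(pt$maxima), sort(ext[1, ]))

  # paired scheme: all 2^4 within-trial swap patterns
  ptp <- permutation_test(pre, post, scheme = "paired", exhaustive = TRUE)
  expect_equal(ptp$n_perm, 16)
  swaps <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  extp <- apply(swaps, 1, function(s) {
    A <- ifelse(s, 1:4, 5:8)
    B <- ifelse(s, 5:8, 1:4)
    d <- apply(S[, A, drop = FALSE], 1, median) -
      apply(S[, B, drop = FALSE], 1, median)
    c(max(d), min(d))
  })
  expect_equal(sort(ptp$maxima), sort(extp[1, ]))
})

test_that("the observed map is untouched by the permutation machinery", {
  set.seed(53)
  pre <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  post <- array(rnorm(3 * 4 * 6) + 0.5, c(3, 4, 6))
  pt <- permutation_test(pre, post, n_perm = 200)
  expect_equal(pt$observed, median_diff_map(pre, post))
  expect_identical(pt$sig, pt$observed > pt$upper | pt$observed < pt$lower)
})

test_that("thresholds widen monotonically as alpha shrinks, deterministically", {
  set.seed(54)
  pre <- array(rnorm(3 * 4 * 8), c(3, 4, 8))
  post <- array(rnorm(3 * 4 * 8), c(3, 4, 8))
  run <- function(alpha) {
    set.seed(99)
    permutation_test(pre, post, n_perm = 500, alpha = alpha)
  }
  loose <- run(0.10)
  strict <- run(0.01)
  expect_gte(strict$upper, loose$upper)
  expect_lte(strict$lower, loose$lower)
  expect_lte(strict$lower, strict$upper)
  expect_identical(run(0.05), run(0.05))
})

test_that("matrixwise mode yields coherent, wider thresholds", {
  set.seed(55)
  pre <- array(rnorm(3 * 4 * 8), c(3, 4, 8))
  post <- array(rnorm(3 * 4 * 8), c(3, 4, 8))
  set.seed(1)
  mw <- permutation_test(pre, post, n_perm = 300, matrixwise = TRUE)
  expect_length(mw$maxima, 12)  # one running max per cell
  expect_lte(mw$lower, mw$upper)
  expect_identical(mw$sig, mw$observed > mw$upper | mw$observed < mw$lower)
})

test_that("input contracts are enforced", {
  ok <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  expect_error(permutation_test(ok, ok, n_perm = 10), "at least 100")
  one <- array(rnorm(2 * 2), c(2, 2, 1))
  expect_error(permutation_test(one, one, n_perm = 200), "at least 2 trials")
  expect_error(permutation_test(ok, array(0, c(3, 2, 3)), n_perm = 200),
               "shape")
})

test_that("an injected post-onset burst is detected inside its support", {
  set.seed(56)
  hits <- 0
  for (i in 1:15) {
    lfp <- generate_trials(
      30, 0, burst = burst_spec(amplitude = c(hit = 1.5, miss = 0)))
    stack <- tfr_trials(lfp, freqs = 8:20)
    w <- tfr_windows(stack)
    keep <- seq(1, 800, by = 8)
    pt <- permutation_test(w$pre[, keep, ], w$post[, keep, ], n_perm = 500)
    in_band <- stack$freqs >= 10 & stack$freqs <= 15
    in_time <- w$post_times_ms[keep] <= 500
    hits <- hits + any(pt$sig[in_band, in_time])
  }
  expect_gte(hits, 13)  # ~90% detection
})
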