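test_that("band averaging reduces to hand-computed row means", {
  power <- array(0, c(3, 4, 2))
  power[, , 1] <- matrix(1:12, 3, 4)
  power[, , 2] <- matrix(13:24, 3, 4)
  stack <- make_stack(power, freqs = 10:12, times_ms = c(0, 10, 20, 30),
                      labels = c("hit", "hit"))
  # single-frequency band returns that row (trial-averaged)
  one <- band_average(stack, c(11, 11))
  expect_equal(one$power, (power[2, , 1] + power[2, , 2]) / 2)
  # full band: mean over rows then trials
  full <- band_average(stack, c(10, 12))
  expect_equal(full$power, colMeans((power[, , 1] + power[, , 2]) / 2))

  uni <- make_stack(array(7, c(3, 4, 1)), 10:12, c(0, 10, 20, 30), "hit")
  expect_true(all(band_average(uni, c(10, 12))$power == 7))
  expect_error(band_average(stack, c(40, 50)), "no analysis frequencies")
})

test_that("peak latency follows the earliest-maximum tie rule", {
  tc <- tibble::tibble(time_ms = seq(0, 100, by = 10),
                       power = c(0, 1, 3, 2, 3, 1, 0, 0, 0, 0, 0))
  expect_equal(peak_latency(tc, c(0, 100)), 20)  # earliest of the two maxima
  dec <- tibble::tibble(time_ms = 0:10, power = 10:0)
  expect_equal(peak_latency(dec, c(0, 10)), 0)
  expect_equal(peak_latency(dec, c(4, 10)), 4)   # window start for monotone
  expect_error(peak_latency(dec, c(50, 60)), "outside")
})

test_that("gradients recover noiseless lines to machine precision", {
  times <- seq(0, 400, by = 1)
  n_t <- length(times)
  power <- array(0, c(2, n_t, 1))
  power[1, , 1] <- 5 - 0.004 * times
  power[2, , 1] <- 2
  stack <- make_stack(power, freqs = c(10, 11), times_ms = times, labels = "hit")
  g <- per_frequency_gradients(stack, c(10, 11), c(100, 250))
  expect_equal(g$slope[g$freq == 10], -0.004, tolerance = 1e-12)
  expect_equal(g$slope[g$freq == 11], 0, tolerance = 1e-12)

  # windows inside the invalid margin are rejected
  stack$margin <- rep(150L, 2)
  expect_error(per_frequency_gradients(stack, c(10, 11), c(100, 250)),
               "margin")
})

test_that("noisy-line slopes are unbiased within their sampling error", {
  set.seed(61)
  times <- seq(100, 250, by = 1)
  est <- replicate(100, {
    y <- 5 - 0.004 * times + rnorm(length(times), sd = 0.2)
    power <- array(y, c(1, length(times), 1))
    stack <- make_stack(power, 12, times, "hit")
    per_frequency_gradients(stack, c(12, 12), c(100, 250))$slope
  })
  se_theory <- 0.2 / sqrt(sum((times - mean(times))^2))
  expect_lt(abs(mean(est) + 0.004), 3 * se_theory / sqrt(100))
})

test_that("paired t reproduces the textbook statistic and its edge cases", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 6)
  res <- paired_t(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_manual)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 2))
  expect_equal(res$mean_diff, -2)

  same <- paired_t(1:4, 1:4)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  six <- paired_t(rnorm(6), rnorm(6))
  expect_equal(six$df, 5)  # six in-band frequencies

  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(c(1, 1), c(1, 1) + 2), "zero variance")
})

test_that("stimulation frequency is the midpoint of the band intersection", {
  expect_equal(select_stim_frequency(c(10, 17), c(8, 15)), 12.5)
  expect_equal(select_stim_frequency(c(10, 16), c(10, 16)), 13)
  expect_equal(select_stim_frequency(c(8, 12), c(12, 20)), 12)
  expect_error(select_stim_frequency(c(8, 10), c(12, 20)), "overlap")
})

test_that("band-average-then-fit commutes with fit-then-average on linear input", {
  times <- seq(0, 300, by = 1)
  n_t <- length(times)
  slopes <- c(-0.002, -0.004, -0.006)
  power <- array(0, c(3, n_t, 1))
  for (i in 1:3) power[i, , 1] <- 4 + slopes[i] * times
  stack <- make_stack(power, 10:12, times, "hit")
  per_freq <- per_frequency_gradients(stack, c(10, 12), c(50, 200))
  avg_tc <- band_average(stack, c(10, 12))
  keep <- avg_tc$time_ms >= 50 & avg_tc$time_ms <= 200
  avg_slope <- unname(coef(lm(avg_tc$power[keep] ~ avg_tc$time_ms[keep]))[2])
  expect_equal(mean(per_freq$slope), avg_slope, tolerance = 1e-10)
})
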