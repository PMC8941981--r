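fft_band_power <- function(x, fs, f0, half_width = 1) {
  n <- length(x)
  sp <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(sp[f >= f0 - half_width & f <= f0 + half_width])
}

test_that("notch removes the line frequency and preserves the passband", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  line <- sin(2 * pi * 50 * t)
  y <- preprocess(line, fs, notch_freqs = 50)
  atten_db <- 10 * log10(fft_band_power(line, fs, 50) /
                           fft_band_power(y, fs, 50))
  expect_gt(atten_db, 20)

  sig <- sin(2 * pi * 12 * t)
  y2 <- preprocess(sig, fs, notch_freqs = 50)
  change_db <- abs(10 * log10(fft_band_power(y2, fs, 12) /
                                fft_band_power(sig, fs, 12)))
  expect_lt(change_db, 1)

  expect_equal(preprocess(sig, fs, notch_freqs = numeric(0)), sig)
  expect_error(preprocess(sig, fs, notch_freqs = 600), "Nyquist")
  expect_error(preprocess(sig, 1000, fs_out = 2000), "at least")
})

test_that("decimation resamples without distorting an in-band tone", {
  fs_in <- 5000
  t <- seq(0, 2, by = 1 / fs_in)
  sig <- sin(2 * pi * 12 * t)
  y <- preprocess(sig, fs_in, notch_freqs = numeric(0), fs_out = 1000)
  expect_equal(length(y), ceiling(length(sig) / 5))
  mid <- y[500:1500]
  expect_lt(abs(max(mid) - 1), 0.05)
  change_db <- abs(10 * log10(fft_band_power(y, 1000, 12) / length(y) /
                                (fft_band_power(sig, fs_in, 12) / length(sig))))
  expect_lt(change_db, 1)
})

test_that("baseline RMS division follows its closed forms", {
  sig <- rnorm(100)
  expect_equal(baseline_normalize(sig, rep(2, 50)), sig / 2)
  a <- 3
  t <- seq(0, 10, by = 1e-3)
  sine_base <- a * sin(2 * pi * 7 * t)
  expect_equal(baseline_normalize(sig, sine_base), sig / (a / sqrt(2)),
               tolerance = 1e-3)
  normalized <- baseline_normalize(sine_base, sine_base)
  expect_equal(sqrt(mean(normalized^2)), 1, tolerance = 1e-12)
  expect_error(baseline_normalize(sig, rep(0, 10)), "all zero")
  expect_error(baseline_normalize(sig, numeric(0)), "empty")
})

test_that("Morlet power localizes tones at their frequencies", {
  fs <- 500
  t <- seq(0, 3, by = 1 / fs)
  for (nc in c(5, 7)) {
    m <- morlet_tfr(sin(2 * pi * 12 * t), fs, freqs = 8:20, n_cycles = nc)
    expect_equal(m$freqs[which.max(rowMeans(m$power))], 12)
  }
  z <- morlet_tfr(rep(0, 800), fs, freqs = 8:20)
  expect_true(all(z$power == 0))

  two <- sin(2 * pi * 10 * t) + sin(2 * pi * 40 * t)
  m2 <- morlet_tfr(two, fs, freqs = 8:50)
  prof <- rowMeans(m2$power)
  lo <- m2$freqs[m2$freqs <= 25]
  hi <- m2$freqs[m2$freqs > 25]
  expect_equal(lo[which.max(prof[m2$freqs <= 25])], 10)
  expect_equal(hi[which.max(prof[m2$freqs > 25])], 40)

  expect_error(morlet_tfr(sin(2 * pi * 12 * t), fs, freqs = c(10, 300)),
               "Nyquist")
  expect_error(morlet_tfr(rnorm(20), 1000, freqs = 8:10), "shorter")
})

test_that("power scales quadratically with amplitude and is stationary for a sine", {
  fs <- 500
  t <- seq(0, 3, by = 1 / fs)
  x <- sin(2 * pi * 15 * t) + 0.3 * sin(2 * pi * 31 * t)
  m1 <- morlet_tfr(x, fs, freqs = 8:40)
  m2 <- morlet_tfr(2 * x, fs, freqs = 8:40)
  expect_equal(m2$power, 4 * m1$power, tolerance = 1e-10)

  # stationary in-band sine: valid-region band power constant within 5%
  row <- m1$power[m1$freqs == 15, ]
  marg <- m1$margin[m1$freqs == 15]
  valid <- row[(marg + 1):(length(row) - marg)]
  expect_lt((max(valid) - min(valid)) / mean(valid), 0.05)
})

test_that("default analysis grid covers 53 frequencies and 800-ms windows", {
  set.seed(45)
  lfp <- generate_trials(2, 2)
  stack <- tfr_trials(lfp)
  expect_equal(stack$freqs, 8:60)
  expect_length(stack$freqs, 53)
  w <- tfr_windows(stack)
  expect_equal(dim(w$pre)[2], 800)
  expect_equal(dim(w$post)[2], 800)
  expect_equal(range(w$pre_times_ms), c(-800, -1))
  expect_equal(range(w$post_times_ms), c(0, 799))
  expect_error(tfr_windows(stack, pre_ms = c(-3000, -2000)), "outside")
  expect_error(tfr_windows(stack, labels = "nope"), "labels")
})
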