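make_sine_epoch <- function(amplitude = 1, fs = 1000, freq = 10) {
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- ifelse(t >= 1, amplitude * sin(2 * pi * freq * t), 0)
  epoch(x, fs, stim_window = c(1, 2), baseline_window = c(0, 1))
}

test_that("a pure sinusoid over a silent baseline gives RMS = A / sqrt(2)", {
  for (a in c(1, 7.5)) {
    expect_equal(extract_magnitude(make_sine_epoch(a)), a / sqrt(2),
                 tolerance = 1e-10)
  }
})

test_that("identical signal statistics in both windows give magnitude 0", {
  set.seed(1)
  x <- rnorm(2000)
  ep <- epoch(c(x, x), 1000, stim_window = c(2, 4), baseline_window = c(0, 2))
  expect_equal(extract_magnitude(ep), 0)
})

test_that("magnitude is DC-invariant and gain-linear", {
  set.seed(2)
  x <- rnorm(4000, sd = 3)
  x[2001:4000] <- x[2001:4000] * 4
  base <- epoch(x, 1000, c(2, 4), c(0, 2))
  shifted <- epoch(x + 17.3, 1000, c(2, 4), c(0, 2))
  scaled <- epoch(x * 2.5, 1000, c(2, 4), c(0, 2))
  m <- extract_magnitude(base)
  expect_gt(m, 0)
  expect_equal(extract_magnitude(shifted), m, tolerance = 1e-12)
  expect_equal(extract_magnitude(scaled), 2.5 * m, tolerance = 1e-12)
})

test_that("white noise with larger stim sd recovers sigma_s - sigma_b", {
  set.seed(3)
  fs <- 1000
  n <- 50000
  x <- c(rnorm(n, sd = 2), rnorm(n, sd = 5))
  ep <- epoch(x, fs, stim_window = c(n / fs, 2 * n / fs),
              baseline_window = c(0, n / fs))
  expect_equal(extract_magnitude(ep), 3, tolerance = 0.05)
})

test_that("epoch constructor rejects invalid windows and rates", {
  x <- rnorm(1000)
  expect_error(epoch(x, 0, c(0.5, 1), c(0, 0.5)), "sampling_rate")
  expect_error(epoch(x, 1000, c(0.5, 2), c(0, 0.5)), "stim_window")
  expect_error(epoch(x, 1000, c(0.4, 1), c(0, 0.5)), "must not overlap")
  expect_error(epoch(x, 1000, c(0.5, 0.5), c(0, 0.5)), "stim_window")
})

test_that("build_series reorders shuffled presentations and flags gaps", {
  series <- tibble::tibble(site = "e1", stimulus = "s1", trial = 1:25,
                           magnitude = seq(100, 52, by = -2))
  man <- generate_epochs(series, sampling_rate = 2000, stim_window = c(0.25, 1.25),
                         baseline_window = c(0, 0.25), baseline_sd = 0, seed = 4)
  expect_false(all(man$trial == sort(man$trial)))  # genuinely shuffled
  built <- build_series(man)
  expect_equal(built$trial, 1:25)
  expect_equal(built$magnitude, series$magnitude, tolerance = 0.1)

  expect_error(build_series(man[-3, ]), "missing trials")
  dup <- dplyr::bind_rows(man, man[1, ])
  expect_error(build_series(dup), "duplicated trials")
})

test_that("epoch synthesis round-trips the source series through extraction", {
  series <- tibble::tibble(site = "e1", stimulus = "s1", trial = 1:25,
                           magnitude = 100 * (1 - 0.035 * (1:25 - 15.5)))
  man <- generate_epochs(series, sampling_rate = 5000,
                         stim_window = c(0.5, 1.5), baseline_window = c(0, 0.5),
                         baseline_sd = 5, seed = 11)
  built <- build_series(man)
  # per-trial agreement within the sampling noise floor, no systematic bias
  expect_lt(max(abs(built$magnitude - series$magnitude)), 5)
  expect_lt(abs(mean(built$magnitude - series$magnitude)), 1)
  # zero-magnitude series extracts to ~0
  silent <- tibble::tibble(trial = 1:25, magnitude = 0)
  man0 <- generate_epochs(silent, sampling_rate = 2000, baseline_sd = 5, seed = 2)
  built0 <- build_series(man0)
  expect_lt(max(built0$magnitude), 0.5)
})
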