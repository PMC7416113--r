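test_that("detrending removes slow drift and preserves fast structure", {
  rate <- 15.625
  t <- (0:(600 * rate - 1)) / rate
  # constant trace maps to ~0
  flat <- detrend(fluor_trace(rep(3.7, length(t)), rate))
  expect_lt(max(abs(flat$f)), 1e-9 * 3.7)
  # 0.01 Hz drift attenuated > 90% (interior, away from edge windows)
  slow <- detrend(fluor_trace(sin(2 * pi * 0.01 * t), rate))
  interior <- t > 100 & t < 500
  expect_lt(max(abs(slow$f[interior])), 0.1)
  # 2 Hz signal preserved within 10%
  fast <- detrend(fluor_trace(sin(2 * pi * 2 * t), rate))
  expect_equal(max(abs(fast$f[interior])), 1, tolerance = 0.1)
  expect_error(detrend(fluor_trace(rnorm(5), rate)),
               class = "chromarg_invalid_argument")
})

test_that("z-normalization standardizes the baseline window and flags degeneracy", {
  rate <- 15.625
  withr::with_seed(1, {
    tr <- fluor_trace(rnorm(200, mean = 5, sd = 3), rate)
  })
  zn <- znorm(tr)
  in_win <- zn$time_s >= 1 & zn$time_s < 6
  expect_equal(mean(zn$f[in_win]), 0, tolerance = 1e-12)
  expect_equal(sd(zn$f[in_win]), 1, tolerance = 1e-12)
  # affine invariance
  tr2 <- tr
  tr2$f <- 10 * tr$f - 4
  expect_equal(znorm(tr2)$f, zn$f, tolerance = 1e-9)
  # constant input flagged degenerate
  expect_warning(zd <- znorm(fluor_trace(rep(1, 200), rate)),
                 "degenerate")
  expect_true(isTRUE(attr(zd, "degenerate")))
  expect_true(all(zd$f == 0))
  expect_error(znorm(fluor_trace(rnorm(20), rate)),
               class = "chromarg_invalid_argument")
})

test_that("derivative resampling matches analytic derivatives on the 500 Hz clock", {
  rate <- 50
  t <- (0:(20 * rate - 1)) / rate
  # linear ramp of slope k -> constant derivative k
  ramp <- resample_derivative(fluor_trace(2.5 * t, rate))
  expect_equal(nrow(ramp), floor(20 * 500))
  expect_true(all(abs(ramp$deriv - 2.5) < 1e-9))
  # sinusoid: derivative ~ 2*pi*f*cos within 5% for f <= 2 Hz
  f <- 2
  sn <- resample_derivative(fluor_trace(sin(2 * pi * f * t), rate))
  expected <- 2 * pi * f * cos(2 * pi * f * sn$time_s)
  interior <- sn$time_s > 0.5 & sn$time_s < 19.5
  expect_lt(max(abs(sn$deriv - expected)[interior]) / (2 * pi * f), 0.05)
  # constant trace -> all zeros
  cst <- resample_derivative(fluor_trace(rep(2, 20 * rate), rate))
  expect_true(all(cst$deriv == 0))
  expect_error(resample_derivative(fluor_trace(rnorm(10), 1000)),
               class = "chromarg_invalid_argument")
})

test_that("event detection thresholds the derivative against baseline noise", {
  rate <- 500
  withr::with_seed(2, base_noise <- rnorm(10 * rate, sd = 1))
  dv <- tibble::tibble(time_s = (0:(10 * rate - 1)) / rate, deriv = base_noise)
  attr(dv, "rate") <- rate
  # all-subthreshold series
  dv0 <- dv
  dv0$deriv <- abs(dv0$deriv) * 0.1
  dv0$deriv[dv0$time_s >= 1 & dv0$time_s < 6] <- rep(c(-1, 1), length.out = sum(dv0$time_s >= 1 & dv0$time_s < 6))
  ev0 <- detect_events(dv0, threshold_sd = 5, noise_window = c(1, 6))
  expect_equal(nrow(ev0), 0L)
  # a single isolated spike only yields events at its suprathreshold samples:
  # baseline noise is skewed so its own samples stay below 0.7 SD
  dv1 <- dv
  dv1$deriv <- rep(0, nrow(dv1))
  in_win <- dv1$time_s >= 1 & dv1$time_s < 6
  dv1$deriv[in_win] <- 0.001
  dv1$deriv[which(in_win)[c(10, 500, 1000, 1500, 2000)]] <- -0.1
  spike_at <- which(dv1$time_s >= 8)[1:3]
  dv1$deriv[spike_at] <- c(5, 8, 4)
  ev1 <- detect_events(dv1, threshold_sd = 0.7, noise_window = c(1, 6))
  expect_setequal(ev1$time_s, dv1$time_s[spike_at])
  expect_equal(sort(ev1$weight), sort(c(5, 8, 4)))
  expect_true(all(ev1$weight > 0))
  expect_error(detect_events(dv, noise_window = c(100, 200)),
               class = "chromarg_invalid_argument")
})

test_that("triggered average obeys its defining sum, linearity, and edge dropping", {
  stim <- noise_stimulus(duration_s = 30, frame_rate = 6.4, seed = 9)
  lags <- lag_grid()
  # single event, weight 1: kernel equals the stimulus snippet around t1
  ev1 <- tibble::tibble(time_s = 12.34, weight = 1)
  raw1 <- triggered_average(ev1, stim)
  snippet <- stim_at(stim, 12.34 + lags)
  expect_equal(unname(raw1$kernels), unname(snippet))
  expect_equal(raw1$n_events, 1L)
  # equal weights equal the unweighted event-triggered average
  times <- c(5.1, 9.7, 14.2, 20.05)
  evw <- tibble::tibble(time_s = times, weight = rep(2.5, 4))
  raw_w <- triggered_average(evw, stim)
  manual <- Reduce(`+`, lapply(times, function(t) stim_at(stim, t + lags))) / 4
  expect_equal(unname(raw_w$kernels), unname(manual) * 2.5)
  # linearity: concatenated event series give the M-weighted mean of kernels
  ev_a <- tibble::tibble(time_s = c(4.2, 8.8), weight = c(1.5, 0.7))
  ev_b <- tibble::tibble(time_s = c(11.3, 16.6, 21.9), weight = c(2, 1, 0.3))
  k_a <- triggered_average(ev_a, stim)$kernels
  k_b <- triggered_average(ev_b, stim)$kernels
  k_ab <- triggered_average(dplyr::bind_rows(ev_a, ev_b), stim)$kernels
  expect_equal(k_ab, (2 * k_a + 3 * k_b) / 5, tolerance = 1e-12)
  # events whose lag window exits the stimulus are dropped, M decremented
  ev_edge <- tibble::tibble(time_s = c(0.5, 12), weight = c(1, 1))
  expect_equal(triggered_average(ev_edge, stim)$n_events, 1L)
  expect_error(triggered_average(tibble::tibble(time_s = 0.1, weight = 1), stim),
               class = "chromarg_no_events")
})

test_that("fast correlation path of the triggered average matches the direct sum", {
  stim <- noise_stimulus(duration_s = 40, frame_rate = 6.4, seed = 10)
  lags <- lag_grid()
  withr::with_seed(3, {
    times <- round(sort(runif(500, 1.5, 38)) * 500) / 500
    w <- rexp(500) + 0.5
  })
  ev <- tibble::tibble(time_s = times, weight = w)
  fast <- triggered_average(ev, stim)      # M > 200, on-clock: FFT path
  # direct-sum oracle
  keep <- times + lags[1] >= 0 & times + lags[649] < nrow(stim) / 6.4
  tt <- times[keep]; ww <- w[keep]
  vals <- stim_matrix(stim)
  idx <- floor(outer(tt, lags, `+`) * 6.4) + 1
  oracle <- sapply(1:4, function(ch) {
    s <- matrix(vals[cbind(as.vector(idx), ch)], nrow = length(tt))
    as.numeric(crossprod(ww, s)) / length(tt)
  })
  expect_equal(unname(fast$kernels), oracle, tolerance = 1e-10)
})

test_that("kernel normalization is a baseline z-score with scale invariance", {
  stim <- noise_stimulus(duration_s = 40, seed = 11)
  withr::with_seed(4, {
    ev <- tibble::tibble(time_s = sort(runif(80, 1.5, 38)), weight = rexp(80) + 0.5)
  })
  raw <- triggered_average(ev, stim)
  ks <- normalize_kernels(raw)
  for (ch in 1:4) {
    expect_lt(abs(mean(ks$kernels[1:25, ch])), 1e-9)
    expect_equal(sd(ks$kernels[1:25, ch]), 1, tolerance = 1e-9)
  }
  expect_true(all(ks$quality >= 0))
  # scaling the raw kernel by 3 leaves the normalized output unchanged
  raw3 <- raw
  raw3$kernels <- raw$kernels * 3
  ks3 <- normalize_kernels(raw3)
  expect_equal(ks3$kernels, ks$kernels, tolerance = 1e-12)
  expect_equal(ks3$quality, ks$quality, tolerance = 1e-12)
  # flat kernel: degenerate channel zeroed with quality 0
  raw0 <- raw
  raw0$kernels[, 2] <- 1
  ks0 <- normalize_kernels(raw0)
  expect_true(all(ks0$kernels[, 2] == 0))
  expect_equal(unname(ks0$quality[2]), 0)
  expect_true(is.na(ks0$polarity[2]))
})

test_that("chirp averaging upsamples, averages, and enforces the 2499 window", {
  rate <- 15.625
  n <- round(2.6 * rate)
  tr_a <- fluor_trace(sin(2 * pi * 1 * (0:(n - 1)) / rate), rate)
  # identical trials: mean equals any trial (up to interpolation)
  avg <- average_chirp(list(tr_a, tr_a, tr_a))
  expect_equal(nrow(avg), 2499L)
  expect_equal(attr(avg, "n_trials"), 3L)
  one <- average_chirp(list(tr_a))
  expect_equal(avg$mean_f, one$mean_f)
  # trials a and -a cancel
  tr_b <- tr_a
  tr_b$f <- -tr_a$f
  expect_true(all(abs(average_chirp(list(tr_a, tr_b))$mean_f) < 1e-12))
  expect_error(average_chirp(list()), class = "chromarg_invalid_argument")
})

test_that("the full estimation chain recovers planted kernels on a shared population", {
  fix <- shared_sim()
  kt <- fix$kernels
  # per-ROI Pearson r between estimated and planted kernels (connected channels)
  rs <- purrr::map_dbl(seq_len(nrow(kt)), function(i) {
    est <- kt$kernel_set[[i]]$kernels
    tru <- kt$true_kernels[[i]]
    on_ch <- which(colSums(abs(tru)) > 0)
    mean(vapply(on_ch, function(ch) cor(est[, ch], tru[, ch]), numeric(1)))
  })
  expect_gt(mean(rs), 0.75)   # desk-scale fixture (120 s, 12 ROIs)
  # polarity agreement on connected channels
  pol_ok <- purrr::map_dbl(seq_len(nrow(kt)), function(i) {
    est <- kt$kernel_set[[i]]
    tru <- kt$true_kernels[[i]]
    on_ch <- which(colSums(abs(tru)) > 0)
    truth_pol <- vapply(on_ch, function(ch) classify_polarity(tru[, ch]),
                        character(1))
    mean(est$polarity[on_ch] == truth_pol)
  })
  expect_gt(mean(pol_ok), 0.9)
  # zero-kernel control: no stimulus-locked structure, so the clustering
  # quality falls well below the responsive population's typical level
  zero <- ground_truth_roi(matrix(0, 649, 4))
  tr0 <- simulate_trace(zero, fix$stim, fix$cfg, seed = 555)
  ks0 <- estimate_kernels(tr0, fix$stim)
  expect_lt(max(ks0$quality_sd), median(kt$quality_sd_max))
})
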