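test_that("pitch tracking recovers known frequencies", {
  seg <- list(samples = tone_segment(200, n = 2646), rate = 8820)
  tr <- estimate_pitch_track(seg)
  expect_true(all(tr$voiced))
  expect_true(all(abs(tr$f0 - 200) < 1))

  # strictly periodic pulse-train-like vowel: r -> 1, HNR at the cap
  seg2 <- preprocess_recording(periodic_vowel())
  tr2 <- estimate_pitch_track(seg2)
  expect_true(all(abs(tr2$f0 - 126) < 1))
  expect_equal(unique(tr2$hnr), hnr_cap_db())

  expect_error(estimate_pitch_track(list(samples = rnorm(2646), rate = 8820)),
               "unvoiced")
})

test_that("HNR tracks a known harmonic-to-noise power ratio", {
  set.seed(7)
  n <- 26460
  t <- (0:(n - 1)) / 8820
  harm <- sin(2 * pi * 210 * t) + 0.5 * sin(2 * pi * 420 * t) +
    0.25 * sin(2 * pi * 630 * t)
  noise <- rnorm(n)
  noise <- noise * sqrt(mean(harm^2) / (10 * mean(noise^2)))  # 10:1 power
  tr <- estimate_pitch_track(list(samples = harm + noise, rate = 8820))
  expect_lt(abs(mean(tr$hnr[tr$voiced]) - 10), 1)
})

test_that("cycle marking recovers period and amplitude structure", {
  # ~8 ms period (125 Hz): 17-19 cycles in 150 ms, all near 8 ms
  rec <- synthesize_vowel(voice_spec(f0 = 125, jitter_rel = 0,
                                     shimmer_rel = 0, hnr_db = Inf,
                                     seed = 1))
  mk <- mark_cycles(preprocess_recording(rec))
  expect_gte(length(mk$T), 16)
  expect_lte(length(mk$T), 19)
  expect_true(all(abs(mk$T - 0.008) < 1 / 8820))
  # near-constant amplitude (the 8 ms period is a non-integer number of
  # samples, so cycle waveforms differ at the sampling-phase level)
  Amid <- mk$A[3:(length(mk$A) - 2)]
  expect_lt((max(Amid) - min(Amid)) / mean(Amid), 0.05)

  # integer-period vowel: the sampled cycles are identical, so the A_i are
  # exactly equal
  mk70 <- mark_cycles(preprocess_recording(periodic_vowel()))
  A70 <- mk70$A[3:(length(mk70$A) - 2)]
  expect_lt(max(A70) - min(A70), 1e-9)

  # alternating-period train 7.5 / 8.5 ms, built from the generator's pulse
  fs <- 44100
  Ts <- rep(c(0.0075, 0.0085), 100)
  starts <- cumsum(c(0, Ts))[1:200]
  tt <- (0:(fs * 1.5 - 1)) / fs
  ci <- findInterval(tt, starts)
  x <- bulbarvoice:::rosenberg_deriv((tt - starts[ci]) / 0.008)
  x <- bulbarvoice:::formant_filter(x, vowel_formants("a", "M"), fs)
  rec2 <- vowel_recording(x, fs)
  mk2 <- mark_cycles(standardize(decimate_signal(rec2, 5)))
  Tmid <- mk2$T[5:(length(mk2$T) - 5)]
  alt <- ifelse(Tmid > 0.008, 0.0085, 0.0075)
  expect_true(all(abs(Tmid - alt) < 1 / 8820))
  expect_equal(sort(unique(round(alt, 4))), c(0.0075, 0.0085))

  expect_error(mark_cycles(list(samples = tone_segment(100, n = 200),
                                rate = 8820)),
               "frame|cycles|unvoiced")
})

test_that("jitter measures match hand values and the literal oracle", {
  # alternating 7/9 ms
  Talt <- rep(c(7e-3, 9e-3), 5)
  j <- suppressWarnings(jitter_features(Talt))
  expect_equal(j$jitter_absolute, 2e-3, tolerance = 1e-12)
  expect_equal(j$jitter_relative, 25, tolerance = 1e-9)

  # constant period: all zero
  j0 <- jitter_features(rep(8e-3, 20))
  expect_true(all(abs(unlist(j0)) < 1e-12))

  # frozen oracle value for a small worked rap example
  T5 <- c(8, 8, 10, 8, 8) * 1e-3
  j5 <- suppressWarnings(jitter_features(T5))
  expect_equal(j5$jitter_rap, oracle_jitter(T5)$jitter_rap, tolerance = 1e-12)
  expect_equal(j5$jitter_rap, 10.58201058, tolerance = 1e-6)

  # vectorized implementation == literal loop transcription, random tables
  set.seed(42)
  for (rep in 1:20) {
    T <- 8e-3 * (1 + rnorm(sample(12:60, 1), 0, 0.03))
    expect_equal(unlist(suppressWarnings(jitter_features(T))),
                 unlist(oracle_jitter(T)), tolerance = 1e-12)
  }
  expect_error(jitter_features(0.008), "insufficient")
})

test_that("shimmer measures match hand values and the literal oracle", {
  Aalt <- rep(c(1, 2), 5)
  s <- suppressWarnings(shimmer_features(Aalt))
  expect_equal(s$shimmer_dB, 20 * log10(2), tolerance = 1e-12)
  expect_equal(s$shimmer_relative, 1 / 1.5 * 100, tolerance = 1e-9)

  s0 <- shimmer_features(rep(2, 20))
  expect_true(all(abs(unlist(s0)) < 1e-12))

  A5 <- c(1, 1, 1.2, 1, 1)
  s5 <- suppressWarnings(shimmer_features(A5))
  expect_equal(s5$shimmer_apq3, oracle_shimmer(A5)$shimmer_apq3,
               tolerance = 1e-12)
  expect_equal(s5$shimmer_apq3, 8.547008547, tolerance = 1e-6)

  set.seed(43)
  for (rep in 1:20) {
    A <- 1 + rnorm(sample(12:60, 1), 0, 0.05)
    expect_equal(unlist(suppressWarnings(shimmer_features(A))),
                 unlist(oracle_shimmer(A)), tolerance = 1e-12)
  }

  # the printed literal 3-term window variant stays available
  sl <- suppressWarnings(shimmer_features(A5, literal_window = TRUE))
  expect_false(isTRUE(all.equal(sl$shimmer_apq11, s5$shimmer_apq11)))
})

test_that("scale and gain invariances hold", {
  set.seed(44)
  T <- 8e-3 * (1 + rnorm(30, 0, 0.02))
  j1 <- jitter_features(T); j2 <- jitter_features(2 * T)
  expect_equal(j2$jitter_absolute, 2 * j1$jitter_absolute, tolerance = 1e-12)
  for (k in c("jitter_relative", "jitter_rap", "jitter_ppq5"))
    expect_equal(j2[[k]], j1[[k]], tolerance = 1e-12)

  A <- 1 + rnorm(30, 0, 0.05)
  s1 <- shimmer_features(A); s2 <- shimmer_features(7 * A)
  expect_equal(unlist(s1), unlist(s2), tolerance = 1e-12)
})

test_that("hnr_and_pitch_stats summarizes the track", {
  tr <- data.frame(time = 1:5 / 100, f0 = rep(150, 5), r = rep(0.5, 5),
                   hnr = 10 * log10(0.5 / 0.5), voiced = TRUE)
  st <- hnr_and_pitch_stats(tr)
  expect_equal(st$pitch_mean, 150)
  expect_equal(st$pitch_min, 150)
  expect_equal(st$pitch_max, 150)
  expect_equal(st$pitch_sd, 0)
  expect_equal(st$hnr_mean, 0)       # r = 0.5 -> 0 dB

  # gliding pitch 100 -> 110 Hz over 1 s
  t <- (0:8819) / 8820
  glide <- sin(2 * pi * (100 * t + 5 * t^2))
  st2 <- hnr_and_pitch_stats(
    estimate_pitch_track(list(samples = glide, rate = 8820)))
  expect_lt(abs(st2$pitch_min - 100), 1.5)
  expect_lt(abs(st2$pitch_max - 110), 1.5)
})

test_that("phonatory_features returns the 15 canonical values", {
  pf <- phonatory_features(preprocess_recording(
    synthesize_vowel(voice_spec(seed = 6))))
  expect_identical(names(pf), phonatory_feature_names())
  expect_true(all(is.finite(unlist(pf))))
  expect_true(all(unlist(pf) >= 0))
})
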