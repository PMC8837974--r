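# Shared fixtures, built in code (no binary test data).

# a clean tone segment at the pipeline's working rate
tone_segment <- function(freq = 440, n = 1323, rate = 8820, amp = 1) {
  amp * sin(2 * pi * freq * (0:(n - 1)) / rate)
}

# a strictly periodic synthetic vowel whose period divides the sample grid
# (350 samples at 44100 Hz, 70 after decimation), so the sampled sequence is
# exactly periodic
periodic_vowel <- function(seed = 1) {
  synthesize_vowel(voice_spec(f0 = 126, jitter_rel = 0, shimmer_rel = 0,
                              hnr_db = Inf, seed = seed))
}

# literal loop transcriptions of the jitter formulas (independent oracles)
oracle_jitter <- function(T) {
  N <- length(T)
  mT <- sum(T) / N
  s_abs <- 0
  for (i in 2:N) s_abs <- s_abs + abs(T[i] - T[i - 1])
  s_abs <- s_abs / (N - 1)
  s_rap <- 0
  for (i in 2:(N - 1))
    s_rap <- s_rap + abs(T[i] - (T[i - 1] + T[i] + T[i + 1]) / 3)
  s_rap <- s_rap / (N - 2)
  s_ppq5 <- 0
  for (i in 3:(N - 2))
    s_ppq5 <- s_ppq5 +
      abs(T[i] - (T[i - 2] + T[i - 1] + T[i] + T[i + 1] + T[i + 2]) / 5)
  s_ppq5 <- s_ppq5 / (N - 4)
  list(jitter_absolute = s_abs,
       jitter_relative = s_abs / mT * 100,
       jitter_rap = s_rap / mT * 100,
       jitter_ppq5 = s_ppq5 / mT * 100)
}

oracle_shimmer <- function(A) {
  N <- length(A)
  mA <- sum(A) / N
  s_db <- 0; s_rel <- 0
  for (i in 1:(N - 1)) {
    s_db <- s_db + abs(20 * log10(A[i + 1] / A[i]))
    s_rel <- s_rel + abs(A[i] - A[i + 1])
  }
  apq <- function(P) {
    h <- (P - 1) / 2
    if (N < P) return(NA_real_)
    s <- 0
    for (i in (h + 1):(N - h)) s <- s + abs(A[i] - mean(A[(i - h):(i + h)]))
    s / (N - P + 1) / mA * 100
  }
  list(shimmer_dB = s_db / (N - 1),
       shimmer_relative = s_rel / (N - 1) / mA * 100,
       shimmer_apq3 = apq(3), shimmer_apq5 = apq(5), shimmer_apq11 = apq(11))
}

# build a bv_marginals object directly (for entropy/IE/kurtosis unit tests)
make_marginals <- function(mt, mf, rate = 8820) {
  structure(list(mt = mt / sum(mt), mf = mf / sum(mf),
                 time = seq_along(mt) * 1e-3,
                 freq = (seq_along(mf) - 1) * rate / (2 * length(mf))),
            class = "bv_marginals")
}

# a synthetic feature table of two Gaussian groups (for selection/classify)
gaussian_table <- function(n_per_group = 30, p = 50, delta = 0, seed = 1,
                           groups = c("C", "B"), sex = "F") {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_group * p), n_per_group),
             matrix(rnorm(n_per_group * p, mean = delta), n_per_group))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(p))
  df$group <- rep(groups, each = n_per_group)
  df$sex <- sex
  df$subject_id <- sprintf("s%03d", seq_len(2 * n_per_group))
  df$vowel <- "a"
  df
}
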