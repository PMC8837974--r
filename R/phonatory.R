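#' Ceiling value of the HNR estimator in dB
#'
#' The HNR maps the normalized autocorrelation peak r(T0) through
#' 10 log10(r / (1 - r)), which diverges as r -> 1; r is therefore clipped at
#' 1 - 1e-6, giving this cap (~60 dB) for perfectly periodic signals.
#' @return The cap in dB.
#' @export
hnr_cap_db <- function() 10 * log10((1 - 1e-6) / 1e-6)

#' Estimate a pitch and HNR track
#'
#' Frame-wise fundamental-frequency estimation by the peak of the normalized
#' cross-correlation between a frame and its lagged copy (computed over the
#' overlapping region, so a strictly periodic signal attains r(T0) = 1
#' exactly). The peak location is refined by parabolic interpolation; frames
#' whose peak correlation falls below `voicing_threshold` are flagged
#' unvoiced. Per-frame HNR is `10 log10(r / (1 - r))` with r clipped to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param seg A `bv_segment` or any `bv_recording` (the estimator also runs on
#'   full phonations).
#' @param floor,ceiling Pitch search bounds in Hz (defaults 75 and 600).
#' @param step Frame step in s (default 0.010).
#' @param window Frame length in s; default `3 / floor`, long enough for
#'   three periods at the pitch floor.
#' @param voicing_threshold Minimum peak correlation for a voiced frame
#'   (default 0.45).
#' @return A data.frame of class `bv_pitchtrack` with columns `time`, `f0`
#'   (NA when unvoiced), `r` (peak correlation), `hnr` (dB) and `voiced`.
#' @export
estimate_pitch_track <- function(seg, floor = 75, ceiling = 600,
                                 step = 0.010, window = NULL,
                                 voicing_threshold = 0.45) {
  stopifnot(floor > 0, ceiling > floor)
  x <- seg$samples; fs <- seg$rate
  if (is.null(window)) window <- 3 / floor
  L <- round(window * fs)
  hop <- max(1L, round(step * fs))
  lag_min <- max(2L, as.integer(base::floor(fs / ceiling)))
  lag_max <- as.integer(base::ceiling(fs / floor))
  if (lag_max + 2L >= L)
    stop("frame too short for the pitch floor: need window > 1/floor + 2 samples")
  if (length(x) < L)
    stop("segment too short for one analysis frame (", length(x), " < ", L,
         " samples)")
  starts <- seq(1L, length(x) - L + 1L, by = hop)

  nfft <- 2^base::ceiling(log2(2L * L))
  res <- lapply(starts, function(s0) {
    fr <- x[s0:(s0 + L - 1L)]
    fr <- fr - mean(fr)
    # raw cross-products for all lags via FFT
    F <- stats::fft(c(fr, numeric(nfft - L)))
    rc <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / nfft
    cs <- cumsum(fr^2)
    tot <- cs[L]
    lags <- lag_min:min(lag_max, L - 2L)
    e1 <- cs[L - lags]                 # sum x[1:(L-tau)]^2
    e2 <- tot - cs[lags]               # sum x[(tau+1):L]^2
    den <- sqrt(pmax(e1 * e2, 1e-300))
    r <- rc[lags + 1L] / den
    # candidate periods are interior local maxima (edge peaks, e.g. formant
    # ringing piling up at the shortest allowed lag, are excluded); a small
    # per-octave cost favouring the higher-frequency candidate (as in Praat)
    # prevents locking onto the 2 T0 subharmonic peak of near-periodic
    # signals
    nl <- length(r)
    cand <- which(r >= c(-Inf, r[-nl]) & r >= c(r[-1], -Inf) &
                  seq_len(nl) > 1L & seq_len(nl) < nl)
    if (length(cand) == 0L) cand <- which.max(r)
    score <- r[cand] - 0.01 * log2(lags[cand] * floor / fs)
    k <- cand[which.max(score)]
    tau <- lags[k]; rp <- r[k]
    # parabolic refinement on the unit-lag grid
    if (k > 1L && k < length(r)) {
      y1 <- r[k - 1L]; y2 <- r[k]; y3 <- r[k + 1L]
      d2 <- y1 - 2 * y2 + y3
      if (d2 < 0) {
        delta <- 0.5 * (y1 - y3) / d2
        delta <- max(min(delta, 0.5), -0.5)
        tau <- tau + delta
        rp <- y2 - 0.25 * (y1 - y3) * delta
      }
    }
    c(tau = tau, r = rp)
  })
  tau <- vapply(res, `[[`, numeric(1), "tau")
  r <- pmin(pmax(vapply(res, `[[`, numeric(1), "r"), 1e-6), 1 - 1e-6)
  voiced <- r >= voicing_threshold
  if (!any(voiced))
    stop("unvoiced: no frame reached voicing threshold ", voicing_threshold,
         " (max r = ", signif(max(r), 3), ")")
  out <- data.frame(time = (starts - 1L + L / 2) / fs,
                    f0 = ifelse(voiced, fs / tau, NA_real_),
                    r = r,
                    hnr = 10 * log10(r / (1 - r)),
                    voiced = voiced)
  attr(out, "config") <- list(floor = floor, ceiling = ceiling, step = step,
                              window = window,
                              voicing_threshold = voicing_threshold,
                              rate = fs, cap_db = hnr_cap_db())
  class(out) <- c("bv_pitchtrack", "data.frame")
  out
}

#' Mark glottal cycles
#'
#' Pitch-guided peak picking: starting from the highest waveform peak, each
#' successive cycle peak is searched within `[0.8, 1.25]` periods of the
#' previous mark (the local period comes from the pitch track), walking both
#' forward and backward. Mark positions are refined to sub-sample precision
#' by parabolic interpolation. Cycle durations `T_i` are successive mark
#' differences; amplitudes `A_i` are the peak-to-peak range of the waveform
#' within each cycle.
#'
#' @param seg A `bv_segment` or `bv_recording`.
#' @param track Optional [estimate_pitch_track()] result (computed if NULL).
#' @param ... Passed to [estimate_pitch_track()] when `track` is NULL.
#' @return A list of class `bv_cyclemarks`: `marks` (positions in samples,
#'   fractional), `T` (durations in s), `A` (peak-to-peak amplitudes).
#' @export
mark_cycles <- function(seg, track = NULL, ...) {
  x <- seg$samples; fs <- seg$rate
  if (is.null(track)) track <- estimate_pitch_track(seg, ...)
  tv <- track$time[track$voiced]; fv <- track$f0[track$voiced]
  Tmed <- fs / stats::median(fv)             # global median period, samples
  period_at <- function(pos_s) {
    f <- if (length(tv) == 1L) fv else
      stats::approx(tv, fv, xout = pos_s, rule = 2)$y
    # clamp to half/double the median so a bad frame cannot derail the walk
    min(max(fs / f, 0.5 * Tmed), 2 * Tmed)
  }
  refine <- function(i) {
    if (i <= 1L || i >= length(x)) return(as.numeric(i))
    y1 <- x[i - 1L]; y2 <- x[i]; y3 <- x[i + 1L]
    d2 <- y1 - 2 * y2 + y3
    if (d2 >= 0) return(as.numeric(i))
    i + max(min(0.5 * (y1 - y3) / d2, 0.5), -0.5)
  }

  T0 <- period_at((length(x) / 2) / fs)
  # seed mark: highest peak in a central 2-period window
  c0 <- length(x) %/% 2L
  w0 <- max(1L, c0 - round(T0)):min(length(x), c0 + round(T0))
  seed <- w0[which.max(x[w0])]

  walk <- function(from, dir) {
    marks <- numeric(0)
    cur <- from
    repeat {
      # window guided by the pitch track (frame-averaged, hence robust to
      # single-cycle perturbations) rather than the previous measured period,
      # so one mislocated mark cannot cascade
      Tcur <- period_at(cur / fs)
      lo <- cur + dir * 0.8 * Tcur
      hi <- cur + dir * 1.25 * Tcur
      win <- sort(c(round(lo), round(hi)))
      if (win[1] < 1L || win[2] > length(x)) break
      idx <- win[1]:win[2]
      peak <- idx[which.max(x[idx])]
      cur <- refine(peak)
      marks <- c(marks, cur)
    }
    marks
  }
  marks <- c(rev(walk(seed, -1)), refine(seed), walk(seed, +1))
  if (length(marks) < 3L)
    stop("insufficient cycles: fewer than 2 complete cycles found")

  # waveform-matching refinement of the periods: the peak marks anchor each
  # cycle, but peak-picking can hop between formant-ringing lobes when the
  # perturbation is large; the period itself is measured as the lag that
  # maximizes the normalized cross-correlation between consecutive
  # cycle-length windows, with parabolic sub-sample refinement.
  hw_cc <- max(2L, round(0.35 * Tmed))
  s_lo <- max(2L, round(0.70 * Tmed)); s_hi <- round(1.40 * Tmed)
  cc_period <- function(anchor) {
    # constant window and lag grid (from the global median period): identical
    # cycles then yield bit-identical periods, keeping the zero-perturbation
    # identity exact
    hw <- hw_cc
    a0 <- round(anchor)
    i0 <- a0 - hw; i1 <- a0 + hw
    if (i0 < 1L || i1 + s_hi > length(x)) return(NA_real_)
    w0 <- x[i0:i1]; w0 <- w0 - mean(w0)
    n0 <- sqrt(sum(w0^2))
    if (n0 == 0) return(NA_real_)
    lags <- s_lo:s_hi
    r <- vapply(lags, function(s) {
      w1 <- x[(i0 + s):(i1 + s)]; w1 <- w1 - mean(w1)
      d <- n0 * sqrt(sum(w1^2))
      if (d == 0) return(-1)
      sum(w0 * w1) / d
    }, numeric(1))
    k <- which.max(r)
    s <- lags[k]
    if (k > 1L && k < length(r)) {
      d2 <- r[k - 1L] - 2 * r[k] + r[k + 1L]
      if (d2 < 0)
        s <- s + max(min(0.5 * (r[k - 1L] - r[k + 1L]) / d2, 0.5), -0.5)
    }
    s / fs
  }
  Ti <- vapply(marks[-length(marks)], cc_period, numeric(1))
  Ti[is.na(Ti)] <- diff(marks)[is.na(Ti)] / fs
  Ai <- vapply(seq_len(length(marks) - 1L), function(i) {
    i0 <- max(1L, floor(marks[i])); i1 <- min(length(x), floor(marks[i + 1L]))
    w <- x[i0:i1]
    max(w) - min(w)
  }, numeric(1))
  structure(list(marks = marks, T = Ti, A = Ai), class = "bv_cyclemarks")
}

#' Jitter measures from a cycle table
#'
#' Four period-perturbation measures over the cycle durations `T_i`:
#' absolute (mean absolute consecutive difference, in s), relative (the same
#' as a percentage of the mean period), rap (3-point relative average
#' perturbation) and ppq5 (5-point period perturbation quotient). The
#' moving-average quotients average over the valid centred windows.
#'
#' @param marks A `bv_cyclemarks` or a numeric vector of cycle durations (s).
#' @return Named list: `jitter_absolute` (s), `jitter_relative`,
#'   `jitter_rap`, `jitter_ppq5` (%); measures with too few cycles are NA
#'   with a warning.
#' @export
jitter_features <- function(marks) {
  T <- if (inherits(marks, "bv_cyclemarks")) marks$T else as.numeric(marks)
  N <- length(T)
  if (N < 2L) stop("insufficient cycles: jitter needs at least 2")
  mT <- mean(T)
  out <- list(jitter_absolute = mean(abs(diff(T))),
              jitter_relative = mean(abs(diff(T))) / mT * 100,
              jitter_rap = NA_real_, jitter_ppq5 = NA_real_)
  if (N >= 3L) {
    i <- 2:(N - 1)
    avg3 <- (T[i - 1] + T[i] + T[i + 1]) / 3
    out$jitter_rap <- mean(abs(T[i] - avg3)) / mT * 100
  } else warning("fewer than 3 cycles: jitter_rap is NA")
  if (N >= 5L) {
    i <- 3:(N - 2)
    avg5 <- (T[i - 2] + T[i - 1] + T[i] + T[i + 1] + T[i + 2]) / 5
    out$jitter_ppq5 <- mean(abs(T[i] - avg5)) / mT * 100
  } else warning("fewer than 5 cycles: jitter_ppq5 is NA")
  out
}

#' Shimmer measures from a cycle table
#'
#' Five amplitude-perturbation measures over the per-cycle peak-to-peak
#' amplitudes `A_i`: dB (mean absolute 20 log10 consecutive ratio), relative
#' (%), and the 3-, 5- and 11-point amplitude perturbation quotients. The
#' quotients use the standard P-point centred moving-average window; the
#' 3-term inner sum some sources print for every P is available with
#' `literal_window = TRUE`.
#'
#' @param marks A `bv_cyclemarks` or numeric vector of amplitudes.
#' @param literal_window Use a 3-point inner average (divided by P) for all
#'   apqP variants.
#' @return Named list: `shimmer_dB` (dB), `shimmer_relative`,
#'   `shimmer_apq3`, `shimmer_apq5`, `shimmer_apq11` (%).
#' @export
shimmer_features <- function(marks, literal_window = FALSE) {
  A <- if (inherits(marks, "bv_cyclemarks")) marks$A else as.numeric(marks)
  N <- length(A)
  if (N < 2L) stop("insufficient cycles: shimmer needs at least 2")
  if (any(A <= 0)) stop("non-positive cycle amplitude")
  mA <- mean(A)
  out <- list(shimmer_dB = mean(abs(20 * log10(A[-1] / A[-N]))),
              shimmer_relative = mean(abs(diff(A))) / mA * 100,
              shimmer_apq3 = NA_real_, shimmer_apq5 = NA_real_,
              shimmer_apq11 = NA_real_)
  apq <- function(P) {
    if (literal_window) {
      if (N < 3L) return(NA_real_)
      i <- 2:(N - 1)
      mean(abs(A[i] - (A[i - 1] + A[i] + A[i + 1]) / P)) / mA * 100
    } else {
      h <- (P - 1L) / 2L
      if (N < P) return(NA_real_)
      i <- (h + 1):(N - h)
      win <- vapply(i, function(j) mean(A[(j - h):(j + h)]), numeric(1))
      mean(abs(A[i] - win)) / mA * 100
    }
  }
  for (P in c(3L, 5L, 11L)) {
    v <- apq(P)
    if (is.na(v)) warning("fewer than ", P, " cycles: shimmer_apq", P, " is NA")
    out[[paste0("shimmer_apq", P)]] <- v
  }
  out
}

#' HNR and pitch statistics from a pitch track
#'
#' @param track A [estimate_pitch_track()] result.
#' @return Named list: `hnr_mean`, `hnr_sd` (dB), `pitch_mean`, `pitch_sd`,
#'   `pitch_min`, `pitch_max` (Hz), computed over voiced frames (`hnr_sd` and
#'   `pitch_sd` are 0 when only one frame is voiced).
#' @export
hnr_and_pitch_stats <- function(track) {
  v <- track$voiced
  if (!any(v)) stop("no voiced frames")
  f0 <- track$f0[v]; hnr <- track$hnr[v]
  list(hnr_mean = mean(hnr),
       hnr_sd = if (sum(v) > 1L) stats::sd(hnr) else 0,
       pitch_mean = mean(f0),
       pitch_sd = if (sum(v) > 1L) stats::sd(f0) else 0,
       pitch_min = min(f0),
       pitch_max = max(f0))
}

#' The 15 phonatory-subsystem features of a segment
#'
#' Runs the pitch tracker and cycle marker and assembles the full phonatory
#' feature set: 4 jitter, 5 shimmer, HNR mean/SD and 4 pitch statistics.
#'
#' @param seg A `bv_segment` (or any `bv_recording`).
#' @param floor,ceiling,voicing_threshold Passed to
#'   [estimate_pitch_track()].
#' @param literal_window Passed to [shimmer_features()].
#' @return Named list of exactly 15 numeric values, in the canonical column
#'   order: jitter_absolute, jitter_relative, jitter_rap, jitter_ppq5,
#'   shimmer_dB, shimmer_relative, shimmer_apq3, shimmer_apq5,
#'   shimmer_apq11, hnr_mean, hnr_sd, pitch_mean, pitch_sd, pitch_min,
#'   pitch_max.
#' @export
phonatory_features <- function(seg, floor = 75, ceiling = 600,
                               voicing_threshold = 0.45,
                               literal_window = FALSE) {
  track <- estimate_pitch_track(seg, floor = floor, ceiling = ceiling,
                                voicing_threshold = voicing_threshold)
  marks <- mark_cycles(seg, track)
  c(jitter_features(marks),
    shimmer_features(marks, literal_window = literal_window),
    hnr_and_pitch_stats(track))
}

#' Names of the 15 phonatory features
#' @return Character vector of length 15.
#' @export
phonatory_feature_names <- function() {
  c("jitter_absolute", "jitter_relative", "jitter_rap", "jitter_ppq5",
    "shimmer_dB", "shimmer_relative", "shimmer_apq3", "shimmer_apq5",
    "shimmer_apq11", "hnr_mean", "hnr_sd", "pitch_mean", "pitch_sd",
    "pitch_min", "pitch_max")
}
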