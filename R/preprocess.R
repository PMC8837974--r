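#' Construct a vowel recording object
#'
#' The basic container of the pipeline: raw audio samples plus the labels that
#' identify the speaker and utterance. Group labels follow the clinical coding
#' `C` (control), `B` (ALS with bulbar involvement), `NB` (ALS without); the
#' pooled ALS group `A` is the derived union of `B` and `NB` and is never
#' stored.
#'
#' @param samples Numeric vector of audio samples (mono).
#' @param rate Sampling rate in Hz.
#' @param subject_id,vowel,sex,group Optional labels; `vowel` must be one of
#'   a, e, i, o, u when given; `group` one of C, B, NB.
#' @return An object of class `bv_recording`.
#' @export
vowel_recording <- function(samples, rate, subject_id = NA_character_,
                            vowel = NA_character_, sex = NA_character_,
                            group = NA_character_) {
  stopifnot(is.numeric(samples), length(rate) == 1, rate > 0)
  if (!is.na(vowel)) stopifnot(vowel %in% c("a", "e", "i", "o", "u"))
  if (!is.na(group)) stopifnot(group %in% c("C", "B", "NB"))
  if (!is.na(sex)) stopifnot(sex %in% c("M", "F"))
  structure(list(samples = as.numeric(samples), rate = rate,
                 subject_id = subject_id, vowel = vowel, sex = sex,
                 group = group),
            class = "bv_recording")
}

#' @export
print.bv_recording <- function(x, ...) {
  cat(sprintf("<bv_recording> %d samples @ %g Hz (%.3f s)",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  if (!is.na(x$subject_id))
    cat(sprintf("  subject=%s vowel=%s sex=%s group=%s",
                x$subject_id, x$vowel, x$sex, x$group))
  cat("\n")
  invisible(x)
}

# Windowed-sinc low-pass FIR, unit DC gain. fc is in cycles/sample.
lowpass_fir <- function(fc, n_taps) {
  m <- (n_taps - 1) / 2
  k <- seq_len(n_taps) - 1 - m
  h <- 2 * fc * ifelse(k == 0, 1, sin(2 * pi * fc * k) / (2 * pi * fc * k))
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
  h <- h * w
  h / sum(h)
}

# Linear "same" convolution via FFT; the symmetric FIR makes it zero-phase
# once the group delay (n_taps-1)/2 is removed.
fir_filter_zerophase <- function(x, h) {
  n <- length(x); L <- length(h)
  nfft <- 2^ceiling(log2(n + L - 1))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(h, numeric(nfft - L))), inverse = TRUE)) / nfft
  d <- (L - 1) / 2
  y[(d + 1):(d + n)]
}

#' Decimate a recording by an integer factor
#'
#' Applies an anti-aliasing low-pass FIR (zero-phase windowed sinc, cutoff at
#' 0.8 of the new Nyquist frequency) before dropping samples, so that content
#' above the new Nyquist (4410 Hz when going from 44100 to 8820 Hz with the
#' default factor 5) is attenuated.
#'
#' @param rec A `bv_recording`.
#' @param factor Positive integer decimation factor; `rec$rate` must be
#'   divisible by it.
#' @return A `bv_recording` at rate `rec$rate / factor`.
#' @export
decimate_signal <- function(rec, factor = 5L) {
  stopifnot(inherits(rec, "bv_recording"))
  factor <- as.integer(factor)
  if (length(rec$samples) == 0) stop("empty signal")
  if (factor < 1L) stop("decimation factor must be >= 1")
  if (rec$rate %% factor != 0)
    stop("sampling rate ", rec$rate, " is not divisible by factor ", factor)
  if (factor == 1L) return(rec)
  fc <- 0.8 * (1 / (2 * factor))
  h <- lowpass_fir(fc, n_taps = 20L * factor + 1L)
  y <- fir_filter_zerophase(rec$samples, h)
  out <- rec
  out$samples <- y[seq(1, length(y), by = factor)]
  out$rate <- rec$rate / factor
  out
}

#' Standardize a recording by the z-score
#'
#' Subtracts the mean and divides by the standard deviation so the output has
#' mean 0 and SD 1. The population SD (divide by N) is the default: the whole
#' signal is treated as the population being standardized; the sample SD
#' (divide by N-1) is available for comparison.
#'
#' @param rec A `bv_recording`.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A standardized `bv_recording`.
#' @export
standardize <- function(rec, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(rec, "bv_recording"))
  x <- rec$samples
  n <- length(x)
  mu <- mean(x)
  s2 <- sum((x - mu)^2) / if (sd_type == "population") n else n - 1
  if (s2 <= 0) stop("degenerate input: constant signal has zero SD")
  out <- rec
  out$samples <- (x - mu) / sqrt(s2)
  out
}

#' Cut the central analysis segment
#'
#' Returns `round(duration * rate)` samples centred on the temporal midpoint
#' of the recording, as a half-open window `[c - floor(L/2), c - floor(L/2) + L)`
#' with `c = floor(N/2)` (0-based indices). No resampling takes place: the
#' output is a contiguous sub-sequence of the input.
#'
#' @param rec A `bv_recording` (normally already decimated and standardized).
#' @param duration Segment duration in seconds (default 0.150).
#' @return An object of class `bv_segment` carrying the samples, rate,
#'   duration, labels, and the 1-based start index as attribute `start`.
#' @export
cut_segment <- function(rec, duration = 0.150) {
  stopifnot(inherits(rec, "bv_recording"), duration > 0)
  n <- length(rec$samples)
  len <- round(duration * rec$rate)
  if (n < len)
    stop("recording (", n, " samples) shorter than segment (", len, ")")
  c0 <- n %/% 2L
  start <- c0 - len %/% 2L          # 0-based
  idx <- (start + 1L):(start + len)
  structure(list(samples = rec$samples[idx], rate = rec$rate,
                 duration = duration, subject_id = rec$subject_id,
                 vowel = rec$vowel, sex = rec$sex, group = rec$group),
            start = start + 1L, class = c("bv_segment", "bv_recording"))
}

#' Standard preprocessing: decimate, z-score, cut
#'
#' The pipeline order is fixed: decimation first, then z-scoring of the whole
#' decimated recording, then the central 150 ms cut, so the cut is always
#' taken from a unit-SD signal.
#'
#' @param rec A `bv_recording` (typically 44100 Hz, 3-4 s).
#' @param factor Decimation factor (default 5, giving 8820 Hz).
#' @param duration Segment duration in s (default 0.150).
#' @param sd_type SD convention for [standardize()].
#' @return A `bv_segment`.
#' @export
preprocess_recording <- function(rec, factor = 5L, duration = 0.150,
                                 sd_type = "population") {
  cut_segment(standardize(decimate_signal(rec, factor), sd_type), duration)
}
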