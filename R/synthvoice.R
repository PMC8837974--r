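# Evaluate an expression with a local RNG seed, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Formant presets for the five Spanish vowels
#'
#' First two formants follow published adult Spanish vowel averages; F3/F4 are
#' generic. Female centre frequencies are scaled by 1.17 (shorter vocal
#' tract). Bandwidths increase with formant number.
#'
#' @param vowel One of a, e, i, o, u.
#' @param sex `"M"` or `"F"`.
#' @return A matrix with columns `freq` and `bw` (Hz), one row per formant.
#' @export
vowel_formants <- function(vowel = c("a", "e", "i", "o", "u"),
                           sex = c("M", "F")) {
  vowel <- match.arg(vowel); sex <- match.arg(sex)
  f <- switch(vowel,
    a = c(700, 1200, 2600, 3300),
    e = c(450, 1950, 2550, 3300),
    i = c(300, 2300, 2950, 3400),
    o = c(450,  880, 2600, 3300),
    u = c(325,  700, 2530, 3300))
  if (sex == "F") f <- pmin(f * 1.17, 4200)
  cbind(freq = f, bw = c(80, 90, 120, 150))
}

#' Specification of a synthetic sustained vowel
#'
#' @param f0 Mean fundamental frequency (Hz).
#' @param jitter_rel Target cycle-to-cycle relative period perturbation, in %.
#'   Per-cycle deviations are i.i.d. Gaussian with SD scaled so that the
#'   expected relative-jitter estimate (mean absolute consecutive difference
#'   over mean period) equals this value.
#' @param shimmer_rel Target relative amplitude perturbation, in % (same
#'   Gaussian calibration on per-cycle amplitudes).
#' @param hnr_db Target harmonics-to-noise ratio in dB (`Inf` = noise free).
#' @param vowel,sex Select the formant preset (see [vowel_formants()]).
#' @param formants Optional matrix overriding the preset.
#' @param voice_type 1 = periodic voice with clear harmonics; 2 adds an f0/2
#'   subharmonic (alternate-cycle amplitude modulation) and a slow amplitude
#'   modulation, emulating voices with strong modulations/subharmonics.
#' @param tilt_db Extra spectral tilt in dB/octave applied above 1500 Hz
#'   (negative = high-band attenuation, emulating attenuated harmonics).
#' @param f0_drift_pct RMS of a slow (~0.8 Hz) sinusoidal drift of the
#'   period, in % (long-range pitch variability, separate from jitter).
#' @param duration Duration in s.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed; synthesis is deterministic given the spec.
#' @return An object of class `bv_voicespec`.
#' @export
voice_spec <- function(f0 = 120, jitter_rel = 0.5, shimmer_rel = 2.5,
                       hnr_db = 25, vowel = "a", sex = "M", formants = NULL,
                       voice_type = 1, tilt_db = 0, f0_drift_pct = 0,
                       duration = 3, rate = 44100, seed = 1) {
  stopifnot(f0 > 0, jitter_rel >= 0, shimmer_rel >= 0, duration > 0,
            rate > 0, voice_type %in% c(1, 2))
  if (is.null(formants)) formants <- vowel_formants(vowel, sex)
  structure(list(f0 = f0, jitter_rel = jitter_rel, shimmer_rel = shimmer_rel,
                 hnr_db = hnr_db, vowel = vowel, sex = sex,
                 formants = formants, voice_type = voice_type,
                 tilt_db = tilt_db, f0_drift_pct = f0_drift_pct,
                 duration = duration, rate = rate, seed = seed),
            class = "bv_voicespec")
}

# Derivative of a Rosenberg glottal flow pulse at phase phi in [0,1);
# opening 0..op, closing op..op+cl, closed elsewhere. The closure
# discontinuity makes the source rich in harmonics. The phase landmarks are
# deliberately not round fractions: for integer-period signals, landmarks
# like 0.40/0.56 coincide with sample phases and float round-off then
# assigns the boundary sample inconsistently across cycles, breaking exact
# periodicity of the sampled waveform.
rosenberg_deriv <- function(phi, op = 0.413, cl = 0.153) {
  y <- numeric(length(phi))
  i <- phi < op
  y[i] <- 0.5 * pi / op * sin(pi * phi[i] / op)
  j <- phi >= op & phi < op + cl
  y[j] <- -pi / (2 * cl) * sin(pi * (phi[j] - op) / (2 * cl))
  y
}

# Cascade of second-order resonators (poles at r e^{+-i theta}), unit DC gain.
formant_filter <- function(x, formants, rate) {
  for (k in seq_len(nrow(formants))) {
    th <- 2 * pi * formants[k, "freq"] / rate
    r <- exp(-pi * formants[k, "bw"] / rate)
    b0 <- 1 - 2 * r * cos(th) + r^2
    x <- as.numeric(stats::filter(b0 * x, c(2 * r * cos(th), -r^2),
                                  method = "recursive"))
  }
  x
}

# dB/octave tilt above f_ref, applied in the frequency domain.
apply_tilt <- function(x, tilt_db, rate, f_ref = 1500) {
  if (tilt_db == 0) return(x)
  n <- length(x)
  f <- (0:(n - 1)) / n * rate
  f <- pmin(f, rate - f)                       # fold to two-sided magnitude
  g <- rep(1, n)
  hi <- f > f_ref
  g[hi] <- 10^(tilt_db * log2(f[hi] / f_ref) / 20)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

#' Synthesize a sustained vowel with known ground truth
#'
#' Source-filter synthesis: a differentiated Rosenberg glottal pulse train
#' with per-cycle period `T_i = T0 (1 + eps_i)` and amplitude
#' `A_i = 1 + eta_i`, filtered by the vowel's formant resonators, with white
#' noise (filtered by the same resonators) added at the exact target
#' harmonics-to-noise power ratio. The pulse phase is evaluated in continuous
#' time, so the injected jitter is not quantized to the sampling grid.
#'
#' @param spec A [voice_spec()].
#' @return A `bv_recording` with attribute `ground_truth`: a list holding the
#'   true cycle table (`cycles`: start time, period `T`, source amplitude
#'   `A_src`, peak-to-peak amplitude of the clean output `A_out`), the
#'   separate `harmonic` and `noise` components, the achieved HNR in dB, and
#'   the jitter/shimmer values of Eq.-style estimators applied to the true
#'   cycle table (`jitter_rel_true`, `shimmer_rel_true`).
#' @export
synthesize_vowel <- function(spec) {
  stopifnot(inherits(spec, "bv_voicespec"))
  with_local_seed(spec$seed, {
    fs <- spec$rate
    T0 <- 1 / spec$f0
    n_cycles <- ceiling(spec$duration / T0) + 3L

    # calibration: for i.i.d. Gaussian eps with SD s, E|eps_i - eps_{i-1}|
    # = 2 s / sqrt(pi); choose s so that value equals the requested %.
    s_j <- (spec$jitter_rel / 100) * sqrt(pi) / 2
    s_h <- (spec$shimmer_rel / 100) * sqrt(pi) / 2
    eps <- pmax(pmin(stats::rnorm(n_cycles, 0, max(s_j, 1e-12)), 3.5 * s_j), -3.5 * s_j)
    eta <- pmax(pmin(stats::rnorm(n_cycles, 0, max(s_h, 1e-12)), 3.5 * s_h), -3.5 * s_h)
    if (spec$jitter_rel == 0) eps[] <- 0
    if (spec$shimmer_rel == 0) eta[] <- 0

    drift <- if (spec$f0_drift_pct > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      sqrt(2) * spec$f0_drift_pct / 100 *
        sin(2 * pi * 0.8 * (0:(n_cycles - 1)) * T0 + ph)
    } else numeric(n_cycles)

    Ti <- T0 * (1 + eps + drift)
    Ai <- 1 + eta
    if (spec$voice_type == 2)
      Ai <- Ai * (1 + 0.25 * (-1)^(seq_len(n_cycles)))

    starts <- cumsum(c(0, Ti[-n_cycles]))
    n <- round(spec$duration * fs)
    t <- (0:(n - 1)) / fs
    ci <- findInterval(t, starts)
    # pulse shape tied to the mean period T0, not the instantaneous one:
    # a period-scaled pulse shifts the waveform landmark within each cycle
    # by ~0.5 dT, which would low-pass the injected jitter as seen by any
    # landmark-based period estimator
    phi <- (t - starts[ci]) / T0
    src <- Ai[ci] * rosenberg_deriv(phi)

    harm <- formant_filter(src, spec$formants, fs)
    harm <- apply_tilt(harm, spec$tilt_db, fs)
    if (spec$voice_type == 2)
      harm <- harm * (1 + 0.2 * sin(2 * pi * 2.5 * t))

    noise <- numeric(n)
    if (is.finite(spec$hnr_db)) {
      raw <- formant_filter(stats::rnorm(n), spec$formants, fs)
      Ph <- mean(harm^2)
      gain <- sqrt(Ph / (mean(raw^2) * 10^(spec$hnr_db / 10)))
      noise <- gain * raw
    }
    x <- harm + noise

    # true cycle table: complete cycles inside the signal, skipping the
    # formant-filter startup transient (first 50 ms) so the table reflects
    # steady-state phonation; windows use round() so that exactly periodic
    # boundaries land on identical sample indices
    t_skip <- min(0.05, 0.2 * spec$duration)
    keep <- which(starts + Ti <= spec$duration & starts >= t_skip)
    A_out <- vapply(keep, function(i) {
      i0 <- round(starts[i] * fs) + 1L
      i1 <- min(round((starts[i] + Ti[i]) * fs), n)
      w <- harm[i0:i1]
      max(w) - min(w)
    }, numeric(1))
    cycles <- data.frame(start = starts[keep], T = Ti[keep],
                         A_src = Ai[keep], A_out = A_out)

    gt <- list(
      cycles = cycles,
      harmonic = harm, noise = noise,
      hnr_achieved_db = if (is.finite(spec$hnr_db))
        10 * log10(mean(harm^2) / mean(noise^2)) else Inf,
      jitter_rel_true = if (nrow(cycles) > 1)
        mean(abs(diff(cycles$T))) / mean(cycles$T) * 100 else 0,
      shimmer_rel_true = if (nrow(cycles) > 1)
        mean(abs(diff(cycles$A_out))) / mean(cycles$A_out) * 100 else 0,
      spec = spec)

    rec <- vowel_recording(x, fs, vowel = spec$vowel, sex = spec$sex)
    attr(rec, "ground_truth") <- gt
    rec
  })
}

# Severity model: one latent severity s in [0,1] drives all the knobs that
# bulbar involvement affects. Baselines are healthy sustained-phonation
# values; the multipliers put s = 1 well into the pathological range
# (jitter > 1.04%, shimmer > 3.81% are conventional pathology thresholds).
severity_params <- function(s, base) {
  list(jitter = base$jitter * (1 + 6.0 * s),
       shimmer = base$shimmer * (1 + 3.5 * s),
       hnr = base$hnr - 13 * s,
       tilt = -8 * s,
       drift = base$drift * (1 + 3 * s),
       voice_type = if (s >= 0.7) 2 else 1)
}

#' Generate a synthetic single-sex cohort of sustained vowels
#'
#' Emulates a three-group clinical cohort: `C` (healthy controls) and most
#' `NB` subjects are drawn from a healthy parameter distribution; `B`
#' subjects carry latent severity in `[0.5, 1]` (elevated jitter/shimmer,
#' lowered HNR, attenuated high harmonics, subharmonics at high severity).
#' A fixed fraction (30%, at least one) of `NB` subjects are "lookalikes"
#' with severity in `[0.4, 0.8]`, emulating patients whose bulbar involvement
#' has not (yet) been diagnosed; this makes B vs NB intrinsically harder than
#' C vs B, as observed clinically.
#'
#' @param n_per_group Subjects per group (C, B, NB).
#' @param sex `"M"` or `"F"` (cohorts are single-sex; sexes are always
#'   analyzed separately downstream).
#' @param seed Integer seed; the cohort is deterministic given it.
#' @param duration,rate Passed to [voice_spec()].
#' @param out_dir Optional directory: writes one WAV per (subject, vowel),
#'   `metadata.csv` (subject_id, sex, group, vowel, path) and
#'   `ground_truth.csv`.
#' @return A list with `recordings` (list of `bv_recording`, each with its
#'   `ground_truth` attribute), `metadata` (data.frame) and `truth`
#'   (data.frame of true per-recording parameters).
#' @export
make_cohort <- function(n_per_group = 10, sex = c("F", "M"), seed = 1,
                        duration = 3, rate = 44100, out_dir = NULL) {
  sex <- match.arg(sex)
  stopifnot(n_per_group >= 1)
  vowels <- c("a", "e", "i", "o", "u")
  with_local_seed(seed, {
    groups <- rep(c("C", "B", "NB"), each = n_per_group)
    n_subj <- length(groups)
    ids <- sprintf("S%03d", seq_len(n_subj))

    n_look <- max(1L, ceiling(0.3 * n_per_group))
    sev <- numeric(n_subj)
    sev[groups == "B"] <- stats::runif(n_per_group, 0.5, 1)
    nb_idx <- which(groups == "NB")
    sev[nb_idx[seq_len(n_look)]] <- stats::runif(n_look, 0.4, 0.8)

    f0 <- stats::rnorm(n_subj, if (sex == "M") 118 else 208,
                       if (sex == "M") 12 else 18)
    # healthy baselines with per-subject biological variation
    base <- lapply(seq_len(n_subj), function(i)
      list(jitter = 0.4 * exp(stats::rnorm(1, 0, 0.2)),
           shimmer = 2.5 * exp(stats::rnorm(1, 0, 0.2)),
           hnr = 23 + stats::rnorm(1, 0, 1.5),
           drift = 0.15 * exp(stats::rnorm(1, 0, 0.2))))
    vseed <- sample.int(2^30, n_subj * length(vowels))

    recordings <- vector("list", n_subj * length(vowels))
    meta <- truth <- vector("list", n_subj * length(vowels))
    k <- 0L
    for (i in seq_len(n_subj)) {
      p <- severity_params(sev[i], base[[i]])
      for (v in vowels) {
        k <- k + 1L
        sp <- voice_spec(f0 = f0[i], jitter_rel = p$jitter,
                         shimmer_rel = p$shimmer, hnr_db = p$hnr,
                         vowel = v, sex = sex, voice_type = p$voice_type,
                         tilt_db = p$tilt, f0_drift_pct = p$drift,
                         duration = duration, rate = rate, seed = vseed[k])
        rec <- synthesize_vowel(sp)
        rec$subject_id <- ids[i]; rec$group <- groups[i]
        recordings[[k]] <- rec
        meta[[k]] <- data.frame(subject_id = ids[i], sex = sex,
                                group = groups[i], vowel = v,
                                path = NA_character_)
        truth[[k]] <- data.frame(subject_id = ids[i], group = groups[i],
                                 vowel = v, severity = sev[i], f0 = f0[i],
                                 jitter_rel = p$jitter, shimmer_rel = p$shimmer,
                                 hnr_db = p$hnr, tilt_db = p$tilt,
                                 voice_type = p$voice_type)
      }
    }
    meta <- do.call(rbind, meta)
    truth <- do.call(rbind, truth)

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_along(recordings)) {
        rec <- recordings[[k]]
        p <- file.path(out_dir, sprintf("%s_%s.wav", rec$subject_id, rec$vowel))
        # peak-normalize for WAV range; downstream z-scoring removes gain anyway
        write_wav(rec$samples / max(abs(rec$samples)) * 0.9, rec$rate, p)
        meta$path[k] <- p
      }
      utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                       row.names = FALSE)
      utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE)
    }
    list(recordings = recordings, metadata = meta, truth = truth)
  })
}
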