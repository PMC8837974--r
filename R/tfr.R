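# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Instantaneous-autocorrelation (lag x time) matrix of a (complex) signal:
# row for signed lag mu holds x[t+mu] * Conj(x[t-mu]), zero where out of
# range. Rows are arranged in FFT order: mu = 0..taumax, then -taumax..-1,
# so a column FFT yields the Wigner distribution with frequency bins
# f_k = k * rate / (2 * n_freq), k = 0..n_freq-1, covering [0, rate/2).
lag_matrix <- function(xa, n_freq, lag_window = c("hann", "rect")) {
  lag_window <- match.arg(lag_window)
  n <- length(xa)
  taumax <- n_freq %/% 2L - 1L
  # tapering the truncated lag window (standard for a discrete pseudo-WD)
  # replaces the Dirichlet sidelobes of the rectangular cutoff -- which leak
  # ~15% of a tone's mass across the whole axis -- by negligible ones
  w <- if (lag_window == "hann")
    0.5 * (1 + cos(pi * (0:taumax) / (taumax + 1L))) else rep(1, taumax + 1L)
  V <- matrix(0 + 0i, nrow = n_freq, ncol = n)
  t_all <- seq_len(n)
  for (m in 0:taumax) {
    ok <- t_all + m <= n & t_all - m >= 1L
    v <- rep(0 + 0i, n)
    v[ok] <- w[m + 1L] * xa[t_all[ok] + m] * Conj(xa[t_all[ok] - m])
    V[m + 1L, ] <- v
    if (m > 0L) V[n_freq - m + 1L, ] <- Conj(v)
  }
  V
}

new_tfr_grid <- function(values, rate, times, normalized, meta = list()) {
  structure(list(values = values,
                 freq = (seq_len(nrow(values)) - 1) * rate / (2 * nrow(values)),
                 time = times, rate = rate, normalized = normalized,
                 meta = meta),
            class = "bv_tfr_grid")
}

#' @export
print.bv_tfr_grid <- function(x, ...) {
  cat(sprintf("<bv_tfr_grid> %d freq x %d time bins, df=%.2f Hz, %s\n",
              nrow(x$values), ncol(x$values), x$freq[2] - x$freq[1],
              if (x$normalized) "unit mass" else "unnormalized"))
  invisible(x)
}

#' Discrete Wigner distribution of a segment
#'
#' Computes the discrete (pseudo-)Wigner distribution
#' `W(t, f) = sum_mu x(t+mu) x*(t-mu) exp(-j 4 pi f mu / rate)` on a
#' frequency lattice of `n_freq` bins covering `[0, rate/2)` and a time
#' lattice decimated by `time_step`. By default the analytic signal is used,
#' which suppresses the interference between positive and negative
#' frequencies of a real signal (the literal real-signal distribution is
#' available with `use_analytic = FALSE`). The imaginary residue of the lag
#' FFT (conjugate-symmetric by construction) is discarded.
#'
#' @param seg A `bv_segment`/`bv_recording`, or a numeric vector with `rate`.
#' @param use_analytic Apply the Hilbert transform first (default TRUE).
#' @param n_freq Number of frequency bins (default 660, ~6.7 Hz bins at
#'   8820 Hz).
#' @param time_step Keep every `time_step`-th sample of the time lattice
#'   (default 4, ~0.45 ms).
#' @param rate Sampling rate, required when `seg` is a bare numeric vector.
#' @param lag_window `"hann"` (default) tapers the truncated lag window,
#'   suppressing the Dirichlet sidelobes the rectangular cutoff would leak
#'   across the frequency axis; `"rect"` gives the plain truncated
#'   definition.
#' @return A `bv_tfr_grid` (unnormalized). The full-resolution lag matrix is
#'   kept in `meta$lagmat` so that [choi_williams()] can smooth at full time
#'   resolution before decimating.
#' @export
wigner_distribution <- function(seg, use_analytic = TRUE, n_freq = 660L,
                                time_step = 4L, rate = NULL,
                                lag_window = c("hann", "rect")) {
  if (is.numeric(seg)) {
    stopifnot(!is.null(rate))
    seg <- list(samples = seg, rate = rate)
  }
  x <- seg$samples
  n <- length(x)
  if (n < 64L) stop("segment too short for a time-frequency analysis (< 64)")
  n_freq <- as.integer(n_freq); time_step <- as.integer(time_step)
  xa <- if (use_analytic) analytic_signal(x) else as.complex(x)
  V <- lag_matrix(xa, n_freq, lag_window)
  keep <- seq(1L, n, by = time_step)
  W <- Re(stats::mvfft(V[, keep, drop = FALSE]))
  new_tfr_grid(W, seg$rate, times = (keep - 1) / seg$rate, normalized = FALSE,
               meta = list(lagmat = V, time_step = time_step,
                           use_analytic = use_analytic, n = n))
}

#' Choi-Williams smoothing of a Wigner distribution
#'
#' Multiplies the ambiguity function (doppler theta x lag mu domain) by the
#' exponential kernel `exp(-(theta * mu)^2 / sigma)` (theta in rad/sample, mu
#' in samples), which passes the auto-terms living near the axes and
#' attenuates oscillating cross-terms, then transforms back and normalizes to
#' unit total mass (CWDN). When the grid carries its full-resolution lag
#' matrix (the [wigner_distribution()] output does) the smoothing is applied
#' at full time resolution before the time lattice is decimated; otherwise
#' the grid itself is smoothed via a 2-D FFT.
#'
#' @param wd A `bv_tfr_grid` from [wigner_distribution()].
#' @param sigma Kernel parameter, > 0; larger = less smoothing
#'   (`sigma -> Inf` recovers the normalized Wigner distribution).
#' @return A unit-mass `bv_tfr_grid` (the CWDN).
#' @export
choi_williams <- function(wd, sigma = 1) {
  stopifnot(inherits(wd, "bv_tfr_grid"), sigma > 0)
  if (!is.null(wd$meta$lagmat)) {
    V <- wd$meta$lagmat
    M <- nrow(V); n <- ncol(V)
    taumax <- M %/% 2L - 1L
    mu <- c(0:taumax, 0, -(taumax:1))          # signed lag per row
    jj <- seq_len(n) - 1L
    theta <- 2 * pi * ifelse(jj > n / 2, jj - n, jj) / n   # rad/sample
    # FFT each row over time -> doppler, apply kernel, back
    A <- t(stats::mvfft(t(V)))
    A <- A * exp(-outer(mu^2, theta^2) / sigma)
    Vs <- t(stats::mvfft(t(A), inverse = TRUE)) / n
    keep <- seq(1L, n, by = wd$meta$time_step)
    W <- Re(stats::mvfft(Vs[, keep, drop = FALSE]))
  } else {
    W0 <- wd$values
    M <- nrow(W0); n <- ncol(W0)
    taumax <- M %/% 2L - 1L
    mu <- c(0:taumax, 0, -(taumax:1))
    jj <- seq_len(n) - 1L
    theta <- 2 * pi * ifelse(jj > n / 2, jj - n, jj) / n
    V <- stats::mvfft(W0, inverse = TRUE) / M          # freq -> lag
    A <- t(stats::mvfft(t(V)))                          # time -> doppler
    A <- A * exp(-outer(mu^2, theta^2) / sigma)
    Vs <- t(stats::mvfft(t(A), inverse = TRUE)) / n
    W <- Re(stats::mvfft(Vs))
  }
  tot <- sum(W)
  if (!is.finite(tot) || tot == 0) stop("degenerate distribution: zero mass")
  out <- new_tfr_grid(W / tot, wd$rate, wd$time, normalized = TRUE,
                      meta = list(sigma = sigma,
                                  time_step = wd$meta$time_step))
  out
}

#' Normalized Choi-Williams distribution of a segment
#'
#' Convenience wrapper: [wigner_distribution()] then [choi_williams()].
#' @inheritParams wigner_distribution
#' @inheritParams choi_williams
#' @return A unit-mass `bv_tfr_grid`.
#' @export
cwdn <- function(seg, sigma = 1, use_analytic = TRUE, n_freq = 660L,
                 time_step = 4L, rate = NULL) {
  choi_williams(wigner_distribution(seg, use_analytic, n_freq, time_step,
                                    rate), sigma)
}

#' Marginal densities of a normalized distribution
#'
#' `mt` (instantaneous power) is the column sum over frequency, `mf`
#' (spectral energy density) the row sum over time. Small negative values
#' (down to `-1e-6` of the maximum) left by the smoothing are clipped to
#' zero; larger negatives raise a warning before clipping. Each marginal is
#' renormalized to unit sum.
#'
#' @param grid A unit-mass `bv_tfr_grid`.
#' @param neg_floor Relative negativity considered benign (fraction of the
#'   marginal's maximum, default 0.05): truncating the lag window of a
#'   discrete Wigner distribution leaves sidelobes of a few percent of the
#'   peak, which are clipped silently; anything more negative indicates a
#'   genuinely ill-behaved grid and raises a warning.
#' @return A list of class `bv_marginals`: `mt`, `mf`, `time`, `freq`.
#' @export
tfr_marginals <- function(grid, neg_floor = 0.05) {
  stopifnot(inherits(grid, "bv_tfr_grid"))
  if (!grid$normalized) stop("marginals require a normalized grid; see cwdn()")
  clipfix <- function(v, what) {
    floor_ok <- -neg_floor * max(abs(v))
    if (any(v < floor_ok))
      warning("large negative values in ", what,
              " marginal (min ", signif(min(v), 3), "); clipped")
    v[v < 0] <- 0
    s <- sum(v)
    if (s <= 0) stop("degenerate ", what, " marginal: zero mass")
    v / s
  }
  structure(list(mt = clipfix(colSums(grid$values), "time"),
                 mf = clipfix(rowSums(grid$values), "frequency"),
                 time = grid$time, freq = grid$freq),
            class = "bv_marginals")
}

#' Interference-free joint density pD(f, t)
#'
#' Outer product of the frequency and time marginals. Valid as a joint
#' density when the marginals are (near-)independent, which the joint
#' time-frequency moments check; by construction it is non-negative
#' everywhere, sums to one, and is rank 1.
#'
#' @param m A `bv_marginals`.
#' @return A list of class `bv_density_grid`: `pD` (freq x time matrix),
#'   `freq`, `time`.
#' @export
joint_density <- function(m) {
  stopifnot(inherits(m, "bv_marginals"))
  structure(list(pD = outer(m$mf, m$mt), freq = m$freq, time = m$time),
            class = "bv_density_grid")
}

#' Joint time-frequency moments
#'
#' Central standardized joint moments
#' `E[((f - mu_f)/sd_f)^n * ((t - mu_t)/sd_t)^m]` of the grid mass, with `n`
#' the frequency and `m` the time order. Values at or near zero indicate
#' statistical independence of the marginals. Raw (non-central,
#' non-standardized, in bin units) moments are available with
#' `standardized = FALSE`.
#'
#' @param grid A unit-mass `bv_tfr_grid` (or a `bv_density_grid`).
#' @param orders List of `c(n, m)` pairs; default (1,1), (7,7), (15,15).
#' @param standardized Use central standardized moments (default TRUE).
#' @return Named numeric vector (`t1f1`, `t7f7`, ... following the orders).
#' @export
joint_moments <- function(grid, orders = list(c(1, 1), c(7, 7), c(15, 15)),
                          standardized = TRUE) {
  W <- if (inherits(grid, "bv_density_grid")) grid$pD else grid$values
  # negatives left by the smoothing would make the axis variances ill-defined
  # (they can cancel the positive mass); clip as in the marginal policy
  W[W < 0] <- 0
  s <- sum(W)
  if (!is.finite(s) || s == 0) stop("degenerate grid: zero mass")
  W <- W / s
  f <- seq_len(nrow(W)); t <- seq_len(ncol(W))
  mf <- rowSums(W); mt <- colSums(W)
  mu_f <- sum(f * mf); mu_t <- sum(t * mt)
  var_f <- sum((f - mu_f)^2 * mf); var_t <- sum((t - mu_t)^2 * mt)
  if (standardized && (var_f <= 0 || var_t <= 0))
    stop("degenerate grid: zero variance along an axis")
  zf <- if (standardized) (f - mu_f) / sqrt(var_f) else f
  zt <- if (standardized) (t - mu_t) / sqrt(var_t) else t
  out <- vapply(orders, function(o) {
    n <- o[1]; m <- o[2]
    as.numeric(t(zf^n) %*% W %*% (zt^m))
  }, numeric(1))
  names(out) <- vapply(orders, function(o)
    sprintf("t%df%d", o[2], o[1]), character(1))
  out
}
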