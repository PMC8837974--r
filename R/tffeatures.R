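#' The 7-band partition of the 0-4410 Hz spectrum
#'
#' Bands (Hz): 0-80, 80-250, 250-550, 550-900, 900-1500, 1500-3000,
#' 3000-4410; half-open to the right except the last. Chosen to resolve the
#' f0 region, the first formants and the high harmonics whose attenuation
#' accompanies bulbar involvement.
#'
#' @param edges Numeric vector of 8 increasing band edges in Hz.
#' @return Object of class `bv_bands` (the edges, with band labels).
#' @export
band_scheme <- function(edges = c(0, 80, 250, 550, 900, 1500, 3000, 4410)) {
  stopifnot(length(edges) == 8, !is.unsorted(edges, strictly = TRUE))
  structure(edges, class = "bv_bands")
}

# row indices of each band for a frequency axis
band_rows <- function(freq, bands) {
  b <- findInterval(freq, bands, rightmost.closed = TRUE)
  lapply(1:7, function(k) which(b == k))
}

pd_matrix <- function(pD) {
  if (inherits(pD, "bv_density_grid")) pD
  else stop("expected a bv_density_grid (see joint_density())")
}

#' Band energies and their time profiles
#'
#' Integrates pD over each band's frequency rows, giving the instantaneous
#' spectral energy profile `E_b(t)`; the reported feature per band is the
#' time-aggregated energy (the band's share of total mass), so the 7 values
#' sum to one.
#'
#' @param pD A `bv_density_grid`.
#' @param bands A [band_scheme()].
#' @return List: `values` (named `E_Bn1`..`E_Bn7`), `profile` (7 x time
#'   matrix of `E_b(t)`).
#' @export
band_energy <- function(pD, bands = band_scheme()) {
  g <- pd_matrix(pD)
  rows <- band_rows(g$freq, bands)
  prof <- do.call(rbind, lapply(rows, function(r)
    colSums(g$pD[r, , drop = FALSE])))
  v <- rowSums(prof)
  names(v) <- paste0("E_Bn", 1:7)
  list(values = v, profile = prof)
}

#' Per-band instantaneous frequency peak
#'
#' For each band and time bin, the frequency of maximum pD within the band
#' (ties broken toward the lower frequency); the reported feature is the
#' energy-weighted time average, which stabilizes the estimate where the
#' band's instantaneous mass is tiny.
#'
#' @inheritParams band_energy
#' @return Named vector `f_Cres1`..`f_Cres7` (Hz); a zero-mass band is NA
#'   with a warning.
#' @export
band_freq_peak <- function(pD, bands = band_scheme()) {
  g <- pd_matrix(pD)
  rows <- band_rows(g$freq, bands)
  v <- vapply(seq_along(rows), function(b) {
    r <- rows[[b]]
    sub <- g$pD[r, , drop = FALSE]
    E <- colSums(sub)
    if (sum(E) <= 0) {
      warning("zero-mass band ", b, ": f_Cres is NA")
      return(NA_real_)
    }
    fpk <- g$freq[r][apply(sub, 2, which.max)]
    sum(fpk * E) / sum(E)
  }, numeric(1))
  names(v) <- paste0("f_Cres", 1:7)
  v
}

#' Per-band average instantaneous frequency (band centroid)
#'
#' Centroid frequency of pD within the band at each time bin, reported as
#' the energy-weighted time average.
#'
#' @inheritParams band_energy
#' @return Named vector `f_Med1`..`f_Med7` (Hz); zero-mass band is NA.
#' @export
band_freq_mean <- function(pD, bands = band_scheme()) {
  g <- pd_matrix(pD)
  rows <- band_rows(g$freq, bands)
  v <- vapply(seq_along(rows), function(b) {
    r <- rows[[b]]
    sub <- g$pD[r, , drop = FALSE]
    E <- sum(sub)
    if (E <= 0) {
      warning("zero-mass band ", b, ": f_Med is NA")
      return(NA_real_)
    }
    # energy-weighted time average of the per-time centroid collapses to the
    # band-restricted frequency centroid
    sum(g$freq[r] * rowSums(sub)) / E
  }, numeric(1))
  names(v) <- paste0("f_Med", 1:7)
  v
}

#' Shannon entropies of the marginals
#'
#' Instantaneous (`H_t`) and spectral (`H_f`) information entropies of the
#' discrete marginal densities, in bits, with `0 log 0 := 0`; the joint
#' entropy is their sum by definition (the joint density is the product of
#' the marginals).
#'
#' @param m A `bv_marginals`.
#' @return Named vector `H_t`, `H_f`, `H_tf` (bits).
#' @export
tf_entropies <- function(m) {
  stopifnot(inherits(m, "bv_marginals"))
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  ht <- H(m$mt); hf <- H(m$mf)
  c(H_t = ht, H_f = hf, H_tf = ht + hf)
}

#' Per-band spectral information
#'
#' Pointwise spectral information `IE(f) = -log2(mf(f))`, summarized per band
#' as the mean over the band's bins with positive mass (zero-mass bins carry
#' no information and are excluded).
#'
#' @param m A `bv_marginals` (its `mf` is used).
#' @param bands A [band_scheme()].
#' @return Named vector `IE_Bn1`..`IE_Bn7` (bits); all-zero band is NA.
#' @export
spectral_information <- function(m, bands = band_scheme()) {
  stopifnot(inherits(m, "bv_marginals"))
  rows <- band_rows(m$freq, bands)
  v <- vapply(seq_along(rows), function(b) {
    p <- m$mf[rows[[b]]]
    p <- p[p > 0]
    if (length(p) == 0) {
      warning("all-zero band ", b, ": IE_Bn is NA")
      return(NA_real_)
    }
    mean(-log2(p))
  }, numeric(1))
  names(v) <- paste0("IE_Bn", 1:7)
  v
}

#' Kurtosis of the time marginal
#'
#' Fourth standardized central moment of the instantaneous-power marginal
#' `mt(t)` (3 for a Gaussian-shaped profile, 1.8 for uniform, 1 for a
#' two-point mass).
#'
#' @param m A `bv_marginals`.
#' @return Scalar `K`.
#' @export
kurtosis_feature <- function(m) {
  stopifnot(inherits(m, "bv_marginals"))
  t <- seq_along(m$mt)
  mu <- sum(t * m$mt)
  v <- sum((t - mu)^2 * m$mt)
  if (v <= 0) stop("degenerate time marginal: zero variance")
  c(K = sum(((t - mu) / sqrt(v))^4 * m$mt))
}

#' Names of the 35 time-frequency features
#' @return Character vector of length 35, in canonical column order.
#' @export
tf_feature_names <- function() {
  c(paste0("E_Bn", 1:7), paste0("f_Cres", 1:7), paste0("f_Med", 1:7),
    "H_t", "H_f", "H_tf", paste0("IE_Bn", 1:7), "K", "t1f1", "t7f7", "t15f15")
}

#' The 35 time-frequency features of a segment
#'
#' Runs the full Cohen-class pipeline on the segment (analytic signal,
#' Wigner distribution, Choi-Williams smoothing, normalization, marginals,
#' interference-free joint density) and computes: 7 band energies, 7 band
#' frequency peaks, 7 band centroids, 3 entropies, 7 band spectral
#' informations, kurtosis, and the joint moments t1f1, t7f7, t15f15.
#'
#' @param seg A `bv_segment` (or numeric vector with `rate`).
#' @param sigma Choi-Williams kernel parameter (default 1).
#' @param bands A [band_scheme()].
#' @param use_analytic,n_freq,time_step Passed to [wigner_distribution()].
#' @param rate Required if `seg` is a bare numeric vector.
#' @return Named numeric vector of exactly 35 values (see
#'   [tf_feature_names()]).
#' @export
extract_tf_features <- function(seg, sigma = 1, bands = band_scheme(),
                                use_analytic = TRUE, n_freq = 660L,
                                time_step = 4L, rate = NULL) {
  grid <- cwdn(seg, sigma = sigma, use_analytic = use_analytic,
               n_freq = n_freq, time_step = time_step, rate = rate)
  m <- tfr_marginals(grid)
  pD <- joint_density(m)
  out <- c(band_energy(pD, bands)$values,
           band_freq_peak(pD, bands),
           band_freq_mean(pD, bands),
           tf_entropies(m),
           spectral_information(m, bands),
           kurtosis_feature(m),
           joint_moments(grid))
  stopifnot(identical(names(out), tf_feature_names()))
  out
}
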