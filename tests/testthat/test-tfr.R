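test_that("FFT-path Wigner distribution equals the direct definition", {
  set.seed(10)
  x <- rnorm(128)
  wd <- wigner_distribution(x, rate = 8820, time_step = 1, n_freq = 64,
                            lag_window = "rect")
  xa <- bulbarvoice:::analytic_signal(x)
  M <- 64L; taumax <- M %/% 2L - 1L
  # literal transcription: W[k,t] = sum_mu x(t+mu) x*(t-mu) e^{-2i pi k mu / M}
  mu <- -taumax:taumax
  direct <- matrix(0, M, 128)
  for (t in 1:128) {
    ok <- t + mu >= 1 & t + mu <= 128 & t - mu >= 1 & t - mu <= 128
    v <- xa[t + mu[ok]] * Conj(xa[t - mu[ok]])
    for (k in 0:(M - 1))
      direct[k + 1, t] <- Re(sum(v * exp(-2i * pi * k * mu[ok] / M)))
  }
  expect_lt(max(abs(direct - wd$values)), 1e-9)
})

test_that("impulse and tone concentrate where they should", {
  xi <- numeric(256); xi[100] <- 1
  wdi <- wigner_distribution(xi, rate = 8820, use_analytic = FALSE,
                             time_step = 1, n_freq = 128)
  mass <- colSums(abs(wdi$values))
  expect_equal(which.max(mass), 100L)
  expect_gt(mass[100] / (sum(mass) - mass[100] + 1e-300), 1e6)
  expect_lt(diff(range(wdi$values[, 100])), 1e-9)     # flat in frequency

  wd <- wigner_distribution(tone_segment(440), rate = 8820)
  cw <- choi_williams(wd, 1)
  m <- suppressWarnings(tfr_marginals(cw))
  expect_lt(abs(m$freq[which.max(m$mf)] - 440), m$freq[2] + 1e-9)
  expect_lt(stats::sd(m$mt) / mean(m$mt), 1e-6)        # flat time marginal
})

test_that("Choi-Williams: sigma -> Inf limit, unit mass, cross-term kill", {
  x2 <- tone_segment(400) + tone_segment(1200)
  wd <- wigner_distribution(x2, rate = 8820, time_step = 1)
  cwI <- choi_williams(wd, 1e12)
  expect_lt(max(abs(cwI$values - wd$values / sum(wd$values))), 1e-6)

  cw <- choi_williams(wd, 1)
  expect_equal(sum(cw$values), 1, tolerance = 1e-9)

  wn <- wd$values / sum(wd$values)
  mid <- which(abs(wd$freq - 800) < 40)
  ridge_before <- sum(abs(wn[mid, ]))
  ridge_after <- sum(abs(cw$values[mid, ]))
  expect_gt(ridge_before / ridge_after, 10)

  # auto-term peaks move less than one bin
  for (f0 in c(400, 1200)) {
    sel <- which(abs(wd$freq - f0) < 60)
    expect_equal(which.max(rowSums(wn[sel, ])),
                 which.max(rowSums(cw$values[sel, ])))
  }

  # roughness decreases monotonically as sigma decreases
  tv <- function(M) sum(abs(diff(M))) + sum(abs(t(diff(t(M)))))
  tvs <- vapply(c(100, 10, 1, 0.1),
                function(s) tv(choi_williams(wd, s)$values), numeric(1))
  expect_true(all(diff(tvs) < 0))
})

test_that("energy bookkeeping: WD mass proportional to segment energy", {
  # zero-mean, odd length: the analytic signal has exactly twice the energy,
  # and the lag-FFT sums to n_freq times the analytic power per column
  set.seed(12)
  ratios <- vapply(1:5, function(i) {
    x <- rnorm(601); x <- x - mean(x)
    wd <- wigner_distribution(x, rate = 8820, time_step = 1, n_freq = 128)
    sum(wd$values) / sum(x^2)
  }, numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-6)
  expect_equal(mean(ratios), 2 * 128, tolerance = 1e-6)
})

test_that("marginals are clipped, renormalized densities", {
  cw <- cwdn(tone_segment(440), rate = 8820)
  m <- suppressWarnings(tfr_marginals(cw))
  expect_equal(sum(m$mt), 1, tolerance = 1e-12)
  expect_equal(sum(m$mf), 1, tolerance = 1e-12)
  expect_true(all(m$mt >= 0) && all(m$mf >= 0))

  # amplitude-ramped tone: mt tracks the squared envelope
  n <- 1323
  env <- seq(0.2, 1, length.out = n)
  cw2 <- cwdn(env * tone_segment(440), rate = 8820)
  m2 <- suppressWarnings(tfr_marginals(cw2))
  keep <- seq(1, n, by = 4)
  inner <- 20:(length(keep) - 20)       # edges distorted by finite support
  expect_gt(cor(m2$mt[inner], env[keep][inner]^2, method = "spearman"), 0.95)
})

test_that("joint density is an outer product with exact marginals", {
  mt <- runif(31); mf <- runif(17)
  m <- make_marginals(mt, mf)
  pD <- joint_density(m)
  expect_true(all(pD$pD >= 0))
  expect_equal(sum(pD$pD), 1, tolerance = 1e-12)
  expect_equal(rowSums(pD$pD), m$mf, tolerance = 1e-12)
  expect_equal(colSums(pD$pD), m$mt, tolerance = 1e-12)
  expect_equal(qr(pD$pD)$rank, 1L)

  # uniform x uniform: every cell 1/(n m)
  pu <- joint_density(make_marginals(rep(1, 8), rep(1, 4)))
  expect_true(all(abs(pu$pD - 1 / 32) < 1e-15))

  # delta x delta: single unit cell
  dm <- make_marginals(c(0, 0, 1, 0), c(0, 1, 0))
  pd <- joint_density(dm)
  expect_equal(pd$pD[2, 3], 1)
  expect_equal(sum(pd$pD != 0), 1L)
})

test_that("joint moments: independence, correlation, degeneracy", {
  # separable grid -> zero covariance, exactly
  mt <- runif(40); mf <- runif(25)
  pD <- joint_density(make_marginals(mt, mf))
  expect_lt(abs(joint_moments(pD, orders = list(c(1, 1)))[["t1f1"]]), 1e-12)

  # perfectly correlated two-point mass -> t1f1 = 1
  g <- structure(list(values = diag(c(0.5, 0.5)), normalized = TRUE),
                 class = "bv_tfr_grid")
  expect_equal(joint_moments(g, orders = list(c(1, 1)))[["t1f1"]], 1)

  # requested default orders and names
  mm <- joint_moments(cwdn(tone_segment(500), rate = 8820))
  expect_identical(names(mm), c("t1f1", "t7f7", "t15f15"))

  # zero variance along an axis errors
  g2 <- structure(list(values = matrix(c(1, 0, 0, 0), 2), normalized = TRUE),
                  class = "bv_tfr_grid")
  expect_error(joint_moments(g2), "degenerate")

  # raw moments available behind the flag
  raw <- joint_moments(pD, orders = list(c(1, 1)), standardized = FALSE)
  expect_gt(raw[["t1f1"]], 1)          # bin-index units, not centred
})
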