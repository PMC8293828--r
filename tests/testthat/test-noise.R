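test_that("noise generation is deterministic and site streams are stable", {
  ta <- seq(0, 100, by = 2)
  b <- study_bath()
  n2a <- generate_noise(modes_for(2, b), 2, ta, seed = 9)
  n2b <- generate_noise(modes_for(2, b), 2, ta, seed = 9)
  expect_identical(n2a$z, n2b$z)
  expect_false(identical(n2a$z, generate_noise(modes_for(2, b), 2, ta, 10)$z))
  # adding a site must not perturb the streams of existing sites
  n3 <- generate_noise(modes_for(3, b), 3, ta, seed = 9)
  expect_identical(n3$z[, 1:2], n2a$z)
})

test_that("empirical two-time statistics match the bath correlation function", {
  md <- decompose_correlation(study_bath())
  ta <- seq(0, 150, by = 2)
  n_real <- 1200
  Z <- vapply(seq_len(n_real),
              function(i) generate_noise(md, 1, ta, seed = 40000 + i)$z[, 1],
              complex(length(ta)))
  al <- correlation_function(md, ta)
  for (lag in c(0L, 25L, 50L)) {       # 0, 50, 100 fs
    prod <- Z[1L + lag, ] * Conj(Z[1L, ])
    dev <- mean(prod) - al[1L + lag]
    se_re <- stats::sd(Re(prod)) / sqrt(n_real)
    se_im <- stats::sd(Im(prod)) / sqrt(n_real)
    expect_lt(abs(Re(dev)), 4 * se_re)
    if (se_im > 0) expect_lt(abs(Im(dev)), 4 * se_im)
  }
  # pseudo-correlation E[z z] vanishes
  pp <- Z[26L, ] * Z[1L, ]
  expect_lt(abs(mean(Re(pp))), 4 * stats::sd(Re(pp)) / sqrt(n_real))
  expect_lt(abs(mean(Im(pp))), 4 * stats::sd(Im(pp)) / sqrt(n_real))
  # mean of the process itself is zero
  expect_lt(abs(mean(Re(Z))), 4 * stats::sd(Re(Z)) / sqrt(length(Z)))
})

test_that("noise on different sites is independent", {
  md <- modes_for(2, study_bath())
  ta <- seq(0, 100, by = 2)
  n_real <- 800
  cross <- vapply(seq_len(n_real), function(i) {
    z <- generate_noise(md, 2, ta, seed = 70000 + i)$z
    mean(z[, 1] * Conj(z[, 2]))
  }, complex(1))
  expect_lt(abs(mean(Re(cross))), 4 * stats::sd(Re(cross)) / sqrt(n_real))
  expect_lt(abs(mean(Im(cross))), 4 * stats::sd(Im(cross)) / sqrt(n_real))
})

test_that("interpolation follows the linear midpoint rule with range checks", {
  md <- decompose_correlation(study_bath())
  ta <- seq(0, 50, by = 2)
  nz <- generate_noise(md, 1, ta, seed = 3)
  expect_identical(noise_at(nz, 1, 10), nz$z[6, 1])
  expect_equal(noise_at(nz, 1, 11), (nz$z[6, 1] + nz$z[7, 1]) / 2)
  expect_identical(noise_at(nz, 1, 50), nz$z[26, 1])
  expect_error(noise_at(nz, 1, 50.5), "outside")
  expect_error(noise_at(nz, 1, -1), "outside")
})

test_that("the correction mode smooths the noise spectrum above gamma_mark", {
  pair <- decompose_correlation(study_bath())
  bare <- pair[1]
  hbar <- hops_constants()$hbar
  M <- 8192; dt <- 1
  j <- 0:(M - 1); tj <- ifelse(j <= M / 2, j * dt, (j - M) * dt)
  Sp <- Re(stats::fft(correlation_function(pair, tj)))
  Sn <- Re(stats::fft(correlation_function(bare, tj)))
  om <- 2 * pi * ifelse(j <= M / 2, j, j - M) / (M * dt) * hbar
  hi <- abs(om) > 500 & abs(om) < 2500
  expect_lt(mean(abs(Sp[hi])), 0.6 * mean(abs(Sn[hi])))
  # the corrected pair is a valid process, the bare mode is not
  expect_gt(min(Sp), 0)
  expect_lt(min(Sn), 0)
  ta <- seq(0, 100, by = 2)
  expect_error(generate_noise(bare, 1, ta, seed = 1), "positive semidefinite")
  expect_silent(generate_noise(bare, 1, ta, seed = 1, neg_tol = 2))
})
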