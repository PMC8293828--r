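test_that("compiled and reference evaluators agree for every variant", {
  sys <- dimer()
  md <- modes_for(2)
  fm <- adhops:::flatten_modes(md)
  basis <- triangular_basis(4, 3, fm$markovian)
  st <- random_state(basis, 2, seed = 5)
  z <- complex(real = stats::rnorm(2), imaginary = stats::rnorm(2)) * 80
  for (v in c("linear", "nonlinear", "normalized"))
    for (term in c(FALSE, TRUE)) {
      ctx <- adhops:::eom_context(sys, fm, basis, v, term)
      a <- adhops:::eval_derivative(ctx, st$psi, st$xi, Conj(z), use_cpp = TRUE)
      b <- adhops:::eval_derivative(ctx, st$psi, st$xi, Conj(z), use_cpp = FALSE)
      expect_equal(a$dpsi, b$dpsi, tolerance = 1e-13)
      expect_equal(a$dxi, b$dxi, tolerance = 1e-13)
    }
})

test_that("the linear equation is linear and reduces to phase evolution", {
  # single site, no coupling, zero noise: physical derivative -i eps/hbar psi
  eps <- 120
  sys1 <- hops_system(matrix(eps, 1, 1))
  m1 <- list(exponential_mode(100, 50, 1))
  basis <- triangular_basis(1, 2)
  psi <- matrix(c(1, 0, 0) + 0i, 3, 1)
  st <- hops_state(psi, 0 + 0i)
  d <- linear_derivative(st, sys1, basis, m1, z_t = 0 + 0i)
  expect_equal(d$psi[1, 1], -1i * eps / hops_constants()$hbar,
               tolerance = 1e-12)
  # the hierarchy is sourced by down-flux from the physical slice, while the
  # deeper auxiliary (no occupied neighbor) receives nothing
  expect_equal(d$psi[3, 1], 0 + 0i)
  # linearity in the state array
  sys <- dimer(); md <- modes_for(2); fm <- adhops:::flatten_modes(md)
  b4 <- triangular_basis(4, 3, fm$markovian)
  ctx <- adhops:::eom_context(sys, fm, b4, "linear", FALSE)
  s1 <- random_state(b4, 2, 1); s2 <- random_state(b4, 2, 2)
  z <- c(30 + 10i, -20 + 5i)
  d1 <- adhops:::eval_derivative(ctx, s1$psi, s1$xi * 0, Conj(z))$dpsi
  d2 <- adhops:::eval_derivative(ctx, s2$psi, s2$xi * 0, Conj(z))$dpsi
  d12 <- adhops:::eval_derivative(ctx, s1$psi + (2 - 1i) * s2$psi,
                                  s1$xi * 0, Conj(z))$dpsi
  expect_equal(d12, d1 + (2 - 1i) * d2, tolerance = 1e-12)
})

test_that("memory drift sources vanish for unpopulated sites", {
  sys <- build_chain(2, 0)
  md <- modes_for(2)
  cfg <- hops_config(sys, study_bath(), variant = "nonlinear", k_max = 4,
                     dt = 2, t_max = 100, start_site = 1)
  tr <- integrate_trajectory(cfg, seed = 6)
  # site 2 never populated (V = 0): its modes accumulate no drift
  fm <- cfg$fm
  expect_equal(tr$xi[fm$site == 2], c(0 + 0i, 0 + 0i))
  expect_true(all(Mod(tr$xi[fm$site == 1]) > 0))
})

test_that("nonlinear derivative rejects a zero-norm physical slice", {
  sys <- dimer(); md <- modes_for(2); fm <- adhops:::flatten_modes(md)
  basis <- triangular_basis(4, 2, fm$markovian)
  psi <- matrix(0 + 0i, nrow(basis$K), 2)
  st <- hops_state(psi, rep(0 + 0i, 4))
  expect_error(nonlinear_derivative(st, sys, basis, md, c(0 + 0i, 0 + 0i)),
               "zero norm")
})

test_that("normalized equation pins the physical norm step by step", {
  cfg <- hops_config(dimer(), study_bath(), variant = "normalized",
                     k_max = 6, dt = 1, t_max = 1)
  tr <- integrate_trajectory(cfg, seed = 13)
  expect_lt(abs(tr$norm[2] - 1), 1e-8)
})

test_that("normalized trajectory equals the post-normalized non-linear one", {
  sys <- dimer()
  cfgN <- hops_config(sys, study_bath(), variant = "normalized", k_max = 6,
                      dt = 1, t_max = 300)
  cfgU <- hops_config(sys, study_bath(), variant = "nonlinear", k_max = 6,
                      dt = 1, t_max = 300)
  nz <- generate_noise(cfgN$modes, 2, seq(0, 300, by = 1), seed = 5)
  trN <- integrate_trajectory(cfgN, 5, noise = nz)
  trU <- integrate_trajectory(cfgU, 5, noise = nz)
  expect_lt(max(Mod(trN$psi0 - trU$psi0)), 1e-4)
  # the raw non-linear physical norm drifts far from one meanwhile
  expect_gt(max(trU$norm), 10)
})

test_that("k-dependent prefactor keeps auxiliary norms bounded in depth", {
  sys1 <- hops_system(matrix(0, 1, 1))
  m1 <- decompose_correlation(study_bath(), 1)[1]  # bare mode, no correction
  nz <- generate_noise(m1, 1, seq(0, 200, 2), seed = 3, neg_tol = 2)
  cfgN <- hops_config(sys1, m1, variant = "normalized", k_max = 10, dt = 2,
                      t_max = 200, store_aux = TRUE)
  cfgU <- hops_config(sys1, m1, variant = "nonlinear", k_max = 10, dt = 2,
                      t_max = 200, store_aux = TRUE)
  trN <- integrate_trajectory(cfgN, 3, noise = nz)
  trU <- integrate_trajectory(cfgU, 3, noise = nz)
  mxN <- apply(sqrt(trN$aux_norm2), 2, max)
  mxU <- apply(sqrt(trU$aux_norm2), 2, max)
  # rescaled auxiliaries stay O(1) at every depth
  expect_lt(max(mxN), 2)
  # unrescaled auxiliaries diverge with depth (|g|/gamma > 1)
  expect_true(all(diff(log(mxU)) > 0))
  expect_gt(mxU[11] / mxU[2], 1e6)
})

test_that("terminator closure recovers limits and converged agreement", {
  sys <- dimer()
  # contribution shrinks as gamma grows at fixed g/gamma
  eff <- vapply(c(50, 800), function(gam) {
    md <- list(exponential_mode(40 * gam, gam, 1),
               exponential_mode(40 * gam, gam, 2))
    cfgOn <- hops_config(sys, md, variant = "normalized", k_max = 3, dt = 1,
                         t_max = 150, terminator = TRUE)
    cfgOff <- hops_config(sys, md, variant = "normalized", k_max = 3, dt = 1,
                          t_max = 150)
    nz <- generate_noise(md, 2, seq(0, 150, 1), seed = 8)
    max(abs(integrate_trajectory(cfgOn, 8, noise = nz)$pops -
              integrate_trajectory(cfgOff, 8, noise = nz)$pops))
  }, numeric(1))
  expect_lt(eff[2], eff[1] / 10)
  # negligible once the hierarchy is converged in k_max
  cfgOn <- hops_config(sys, study_bath(), variant = "normalized", k_max = 8,
                       dt = 2, t_max = 300, terminator = TRUE)
  cfgOff <- hops_config(sys, study_bath(), variant = "normalized", k_max = 8,
                        dt = 2, t_max = 300)
  nz <- generate_noise(cfgOn$modes, 2, seq(0, 300, 2), seed = 8)
  expect_lt(max(abs(integrate_trajectory(cfgOn, 8, noise = nz)$pops -
                      integrate_trajectory(cfgOff, 8, noise = nz)$pops)),
            1e-3)
  # closure values act on the mode's own site only
  md <- modes_for(2); fm <- adhops:::flatten_modes(md)
  basis <- triangular_basis(4, 2, fm$markovian)
  st <- random_state(basis, 2, seed = 2)
  cl <- apply_terminator(st, basis, md)
  expect_gt(length(cl), 0)
  for (e in cl) {
    off_site <- setdiff(1:2, fm$site[e$mode])
    expect_equal(e$value[off_site], 0 + 0i)
  }
})
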