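test_that("candidate flux equals the brute-force excluded derivative", {
  sys <- dimer()
  md <- modes_for(2)
  fm <- adhops:::flatten_modes(md)
  full <- triangular_basis(4, 2, fm$markovian)
  keep <- c(1, 2, 3, 5)
  red <- adhops:::new_hierarchy_basis(full$K[keep, , drop = FALSE], 4, 2,
                                      fm$markovian)
  st <- random_state(red, 2, seed = 4)
  cand <- full$K[-keep, , drop = FALSE]
  fb <- flux_up_bounds(st, sys, md, red, cand)
  # brute force: embed, evaluate the full-basis derivative, read off the
  # rows of the candidates that were excluded
  psi_full <- matrix(0 + 0i, nrow(full$K), 2)
  psi_full[match(red$keys, full$keys), ] <- st$psi
  ctx <- adhops:::eom_context(sys, fm, full, "normalized", FALSE)
  D <- adhops:::eval_derivative(ctx, psi_full, st$xi, c(0 + 0i, 0 + 0i),
                                apply_gamma = FALSE)$dpsi
  bf <- rowSums(Mod(D[-keep, , drop = FALSE])^2)
  expect_equal(fb, bf, tolerance = 1e-12)
  # bounds scale quadratically with amplitude and never go negative
  st2 <- st; st2$psi <- 2 * st2$psi; st2$psi[1, ] <- st$psi[1, ]
  fb2 <- flux_up_bounds(st2, sys, md, red, cand)
  expect_true(all(fb2 >= fb - 1e-14))
  expect_true(all(fb >= 0))
})

test_that("candidates reachable only through empty sites receive zero flux", {
  sys <- dimer(0)
  md <- modes_for(2)
  fm <- adhops:::flatten_modes(md)
  red <- adhops:::new_hierarchy_basis(matrix(0L, 1, 4), 4, 2, fm$markovian)
  psi <- matrix(c(1, 0) + 0i, 1, 2)  # all amplitude on site 1
  st <- hops_state(psi, rep(0 + 0i, 4))
  cand <- diag(1L, 4)  # the four first-order auxiliaries
  fb <- flux_up_bounds(st, sys, md, red, cand)
  expect_true(all(fb[fm$site == 2] == 0))
  expect_true(all(fb[fm$site == 1] > 0))
})

test_that("delta = 0 reverts to the full basis, huge delta freezes transport", {
  sys <- build_chain(3, 50)
  md <- modes_for(3)
  fm <- adhops:::flatten_modes(md)
  basis <- adhops:::new_hierarchy_basis(matrix(0L, 1, 6), 6, 4, fm$markovian)
  psi <- matrix(0 + 0i, 1, 1); psi[1, 1] <- 1
  st <- hops_state(psi, rep(0 + 0i, 6))
  ab0 <- build_adaptive_basis(st, sys, md, basis, sites = 2L, k_max = 4,
                              delta = 0)
  expect_equal(nrow(ab0$basis$K), nrow(triangular_basis(6, 4, fm$markovian)$K))
  expect_equal(ab0$sites, 1:3)
  # delta so large that only the occupied elements survive: no transport
  cfg <- hops_config(build_chain(5, 50), study_bath(), variant = "adaptive",
                     k_max = 10, delta = 10, dt = 2, t_max = 200)
  tr <- integrate_trajectory(cfg, 3)
  expect_equal(max(tr$n_aux), 1L)
  expect_equal(min(tr$pops[, 3]), 1)
  expect_error(build_adaptive_basis(st, sys, md, basis, 2L, 4, delta = -1),
               "non-negative")
})

test_that("the adaptive basis satisfies the derivative-error bound", {
  delta <- 1e-4
  sys <- build_chain(3, 50)
  md <- modes_for(3)
  fm <- adhops:::flatten_modes(md)
  full <- triangular_basis(6, 4, fm$markovian)
  ctxF <- adhops:::eom_context(sys, fm, full, "normalized", FALSE)
  cfg <- hops_config(sys, study_bath(), variant = "adaptive", k_max = 4,
                     delta = delta, dt = 2, t_max = 300)
  nz <- generate_noise(md, 3, seq(0, 300, 2), seed = 42)
  basis <- adhops:::new_hierarchy_basis(matrix(0L, 1, 6), 6, 4, fm$markovian)
  sites <- cfg$start_site
  state <- initial_state(cfg, basis, sites)
  worst <- 0; sizes <- integer(0)
  for (step in 1:150) {
    t0 <- (step - 1) * 2
    zrow <- adhops:::noise_row_at(nz, t0)
    ab <- build_adaptive_basis(state, sys, md, basis, sites, 4, delta,
                               znorm = max(Mod(zrow[sites])))
    state <- rebase_state(state, basis, sites, ab$basis, ab$sites)
    basis <- ab$basis; sites <- ab$sites
    # adaptive members always form a subset of the full triangular basis
    expect_true(all(basis$keys %in% full$keys))
    expect_equal(basis$K[1, ], rep(0L, 6))
    ctx <- adhops:::eom_context(sys, fm, basis, "normalized", FALSE, sites)
    if (step %% 3 == 0) {
      Da <- adhops:::eval_derivative(ctx, state$psi, state$xi, Conj(zrow),
                                     apply_gamma = FALSE)$dpsi
      pf <- matrix(0 + 0i, nrow(full$K), 3)
      pf[match(basis$keys, full$keys), sites] <- state$psi
      Df <- adhops:::eval_derivative(ctxF, pf, state$xi, Conj(zrow),
                                     apply_gamma = FALSE)$dpsi
      Da_emb <- matrix(0 + 0i, nrow(full$K), 3)
      Da_emb[match(basis$keys, full$keys), sites] <- Da
      worst <- max(worst, sqrt(sum(Mod(Df - Da_emb)^2)))
    }
    z1 <- Conj(zrow)
    zh <- Conj(adhops:::noise_row_at(nz, t0 + 1))
    z2 <- Conj(adhops:::noise_row_at(nz, t0 + 2))
    state <- adhops:::rk4_step(ctx, state, z1, zh, z2, 2)
    sizes <- c(sizes, nrow(basis$K))
  }
  expect_lte(worst, delta)
  expect_lt(min(sizes), nrow(full$K))  # reduced at least while flux is local
})

test_that("rebasing carries amplitudes by identity and pads with zeros", {
  md <- modes_for(2)
  fm <- adhops:::flatten_modes(md)
  b1 <- triangular_basis(4, 2, fm$markovian)
  st <- random_state(b1, 2, seed = 7)
  same <- rebase_state(st, b1, 1:2, b1, 1:2)
  expect_equal(same$psi, st$psi)
  # grow by one: new slot zero
  grown <- triangular_basis(4, 3, fm$markovian)
  st_g <- rebase_state(st, b1, 1:2, grown, 1:2)
  new_rows <- !(grown$keys %in% b1$keys)
  expect_true(all(st_g$psi[new_rows, ] == 0))
  expect_equal(st_g$psi[match(b1$keys, grown$keys), ], st$psi)
  # round-trip drop and re-add of a zero-amplitude member is the identity
  st0 <- st; st0$psi[nrow(st0$psi), ] <- 0
  red <- adhops:::new_hierarchy_basis(
    b1$K[-nrow(b1$K), , drop = FALSE], 4, 2, fm$markovian)
  back <- rebase_state(rebase_state(st0, b1, 1:2, red, 1:2), red, 1:2, b1, 1:2)
  expect_equal(back$psi, st0$psi)
  # the physical index must be present
  nophys <- adhops:::new_hierarchy_basis(
    b1$K[-1, , drop = FALSE], 4, 2, fm$markovian)
  expect_error(rebase_state(st, b1, 1:2, nophys, 1:2), "physical")
})

test_that("hierarchy occupation tracks the populated site", {
  sys <- build_chain(5, 10)
  cfg <- hops_config(sys, study_bath(), variant = "normalized", k_max = 6,
                     dt = 2, t_max = 600, store_aux = TRUE)
  tr <- integrate_trajectory(cfg, 11)
  k2 <- integer(10); k2[3] <- 1L  # first-order auxiliary of site 2's slow mode
  occ2 <- aux_occupation_map(tr, matrix(k2, 1))
  expect_gt(stats::cor(occ2[, 1], tr$pops[, 2]), 0.3)
})
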