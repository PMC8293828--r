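# Time-derivative evaluators for the HOPS family of equations of motion.
#
# All variants share the structure
#   d psi^(k)/dt = (-i H/hbar - k.gamma/hbar + sum_n L_n z*_{n,t}/hbar) psi^(k)
#                  + sum_n k_n c_n L_n psi^(k - e_n)
#                  - sum_n u_n (L_n^dag - shift) psi^(k + e_n)
# with L_n the site projectors. The three variants differ in the flux
# coefficients, the effective noise, and a scalar normalization correction:
#
# linear:      c_n = g_n/hbar, u_n = 1/hbar, raw noise, no shift.
# nonlinear:   as linear, but noise is shifted by the memory drift xi_n and
#              the up-flux operator by the expectation <L_n^dag>.
# normalized:  the non-linear equation after rescaling each auxiliary by the
#              k-dependent prefactor prod_n (gamma_n/g_n)^{k_n} (which keeps
#              auxiliary norms bounded in depth) and subtracting a scalar
#              Gamma_t chosen so the physical norm derivative is exactly zero:
#              c_n = gamma_n/hbar, u_n = g_n/(gamma_n hbar).

#' HOPS state
#'
#' Wave functions over a hierarchy basis plus per-mode noise-memory
#' accumulators.
#'
#' @param psi complex matrix, auxiliaries (rows, physical first) x sites
#' @param xi complex vector of per-mode memory accumulators
#' @param time current time (fs)
#' @return object of class `hops_state`
#' @export
hops_state <- function(psi, xi, time = 0) {
  structure(list(psi = psi, xi = xi, time = time), class = "hops_state")
}

# ---- evaluation context -----------------------------------------------------

# Precomputes everything that depends only on (system, modes, basis, variant):
# neighbor tables, flux coefficients, damping, terminator closures, and the
# reduced -iH/hbar block over the active sites.
eom_context <- function(sys, fm, basis, variant, terminator = FALSE,
                        sites = seq_len(sys$n_sites)) {
  stopifnot(variant %in% c("linear", "nonlinear", "normalized"))
  nb <- build_neighbor_tables(basis)
  K <- basis$K
  n_modes <- ncol(K)
  damp <- as.vector(K %*% fm$gamma) / .hbar
  if (variant == "normalized") {
    cdown <- K * matrix(fm$gamma, nrow(K), n_modes, byrow = TRUE) / .hbar
    cup <- fm$g / (fm$gamma * .hbar)
  } else {
    cdown <- K * matrix(fm$g, nrow(K), n_modes, byrow = TRUE) / .hbar
    cup <- rep(1 / .hbar, n_modes) + 0i
  }
  mode_col <- match(fm$site, sites, nomatch = 0L)
  # terminator closures only on the true triangular boundary of the
  # non-Markovian hierarchy (never as a stand-in for adaptively absent aux)
  tcoef <- matrix(0 + 0i, nrow(K), n_modes)
  if (terminator) {
    depth_nm <- as.vector(K[, !fm$markovian, drop = FALSE] %*%
                            rep(1L, sum(!fm$markovian)))
    at_edge <- depth_nm == basis$k_max
    kg <- as.vector(K %*% fm$gamma)
    for (m in which(!fm$markovian)) {
      rows <- which(nb$up[, m] == 0L & at_edge)
      if (!length(rows)) next
      num <- if (variant == "normalized") fm$gamma[m] else fm$g[m]
      tcoef[rows, m] <- (K[rows, m] + 1) * num / (kg[rows] + fm$gamma[m])
    }
  }
  list(sys = sys, fm = fm, basis = basis, variant = variant,
       terminator = terminator, sites = sites,
       M = -1i * sys$H[sites, sites, drop = FALSE] / .hbar,
       damp = damp, cdown = cdown, cup = cup, mode_col = mode_col,
       up = nb$up, down = nb$down, tcoef = tcoef,
       n_aux = nrow(K), n_act = length(sites))
}

# site-projector expectations from the physical slice, over active sites
physical_expectations <- function(psi, variant) {
  p0 <- psi[1L, ]
  nrm2 <- sum(Mod(p0)^2)
  if (variant != "linear" && nrm2 <= 0)
    stop("physical wave function has zero norm; expectation <L^dag> undefined")
  if (nrm2 <= 0) rep(0, length(p0)) else Mod(p0)^2 / nrm2
}

# Evaluate the time derivative on the context's basis.
#   psi:  n_aux x n_act complex matrix
#   xi:   per-mode memory accumulators (all modes, global indexing)
#   zconj: Conj(z_t) for every site of the system (cm^-1)
# Returns list(dpsi, dxi, gamma_t).
eval_derivative <- function(ctx, psi, xi, zconj, apply_gamma = TRUE,
                            use_cpp = TRUE) {
  fm <- ctx$fm
  variant <- ctx$variant
  if (variant == "linear") {
    expL_site <- rep(0, ctx$n_act)
    expL_mode <- rep(0 + 0i, length(fm$g))
    zt <- zconj[ctx$sites] / .hbar
    shift <- FALSE
  } else {
    expL_site <- physical_expectations(psi, variant)
    expL_mode <- rep(0 + 0i, length(fm$g))
    act <- ctx$mode_col > 0L
    expL_mode[act] <- expL_site[ctx$mode_col[act]]
    # effective noise: z* + sum of memory accumulators of the site's modes
    zts <- zconj[ctx$sites]
    for (m in which(act)) zts[ctx$mode_col[m]] <- zts[ctx$mode_col[m]] + xi[m]
    zt <- zts / .hbar
    shift <- TRUE
  }
  D <- if (use_cpp) {
    hops_deriv_core(psi, ctx$M, ctx$damp, zt, ctx$up, ctx$down, ctx$cdown,
                    ctx$cup, ctx$mode_col, expL_mode, shift, ctx$tcoef,
                    ctx$terminator)
  } else {
    deriv_reference(ctx, psi, zt, expL_mode, shift)
  }
  gamma_t <- 0
  if (variant == "normalized") {
    gamma_t <- Re(sum(Conj(psi[1L, ]) * D[1L, ]))
    if (apply_gamma) D <- D - gamma_t * psi
  }
  dxi <- if (variant == "linear") rep(0 + 0i, length(xi)) else
    (-Conj(fm$gamma) * xi + Conj(fm$g) * expL_mode) / .hbar
  list(dpsi = D, dxi = dxi, gamma_t = gamma_t)
}

# Plain-R reference evaluator with the same contract as hops_deriv_core;
# deliberately written as explicit loops so the two routes are independent.
deriv_reference <- function(ctx, psi, zt, expL_mode, shift) {
  n_aux <- nrow(psi); n_act <- ncol(psi)
  D <- matrix(0 + 0i, n_aux, n_act)
  for (i in seq_len(n_aux)) {
    D[i, ] <- as.vector(ctx$M %*% psi[i, ]) - ctx$damp[i] * psi[i, ] +
      zt * psi[i, ]
    for (m in seq_along(ctx$fm$g)) {
      s <- ctx$mode_col[m]
      if (s == 0L) next
      idn <- ctx$down[i, m]
      if (idn > 0L) D[i, s] <- D[i, s] + ctx$cdown[i, m] * psi[idn, s]
      iup <- ctx$up[i, m]
      if (iup > 0L) {
        D[i, s] <- D[i, s] - ctx$cup[m] * psi[iup, s]
        if (shift) D[i, ] <- D[i, ] + ctx$cup[m] * expL_mode[m] * psi[iup, ]
      } else if (ctx$terminator && ctx$tcoef[i, m] != 0) {
        sh <- if (shift) expL_mode[m] else 0 + 0i
        D[i, s] <- D[i, s] - ctx$cup[m] * ctx$tcoef[i, m] * (1 - sh) * psi[i, s]
      }
    }
  }
  D
}

# ---- exported derivative wrappers ------------------------------------------

eom_wrapper <- function(state, sys, basis, modes, z_t, variant,
                        terminator = FALSE) {
  fm <- flatten_modes(modes)
  ctx <- eom_context(sys, fm, basis, variant, terminator)
  stopifnot(nrow(state$psi) == nrow(basis$K),
            ncol(state$psi) == sys$n_sites)
  d <- eval_derivative(ctx, state$psi, state$xi, Conj(z_t))
  hops_state(d$dpsi, d$dxi, state$time)
}

#' Linear HOPS time derivative
#'
#' Derivative of all auxiliary wave functions under the linear HOPS equation:
#' phase evolution and per-auxiliary damping, multiplicative driving by the
#' raw conjugate noise, down-flux k_n g_n L_n / hbar from below and up-flux
#' -L_n / hbar from above (absent neighbors contribute zero).
#'
#' @param state a [hops_state()] whose `psi` spans the full state space
#' @param sys a [hops_system()]
#' @param basis a [triangular_basis()] consistent with `state`
#' @param modes list of [exponential_mode()]s
#' @param z_t per-site complex noise values at the current time
#' @param terminator apply the boundary closure at the truncation edge
#' @return a `hops_state` holding the derivatives
#' @export
linear_derivative <- function(state, sys, basis, modes, z_t,
                              terminator = FALSE)
  eom_wrapper(state, sys, basis, modes, z_t, "linear", terminator)

#' Non-linear HOPS time derivative
#'
#' As [linear_derivative()], but the noise is shifted by the memory drift
#' xi_n (whose own derivative, (-gamma_n* xi_n + g_n* <L_n>)/hbar, is returned
#' in the `xi` slot) and the up-flux operator becomes (L_n - <L_n>), with the
#' expectation taken in the normalized physical slice.
#'
#' @inheritParams linear_derivative
#' @export
nonlinear_derivative <- function(state, sys, basis, modes, z_t,
                                 terminator = FALSE)
  eom_wrapper(state, sys, basis, modes, z_t, "nonlinear", terminator)

#' Normalized non-linear HOPS time derivative
#'
#' The non-linear equation expressed in auxiliaries rescaled by the
#' k-dependent prefactor prod_n (gamma_n/g_n)^{k_n}, which keeps auxiliary
#' norms bounded with depth, plus a scalar correction Gamma_t (attribute
#' `"gamma_t"`) chosen so the physical-norm derivative vanishes identically.
#'
#' @inheritParams linear_derivative
#' @export
normalized_derivative <- function(state, sys, basis, modes, z_t,
                                  terminator = FALSE) {
  fm <- flatten_modes(modes)
  ctx <- eom_context(sys, fm, basis, "normalized", terminator)
  d <- eval_derivative(ctx, state$psi, state$xi, Conj(z_t))
  out <- hops_state(d$dpsi, d$dxi, state$time)
  attr(out, "gamma_t") <- d$gamma_t
  out
}

#' Terminator closure values
#'
#' For every auxiliary on the triangular boundary, the static closure that
#' replaces its absent up-neighbors: psi^(k + e_n) is approximated by
#' (k_n + 1) g_n / (k.gamma + gamma_n) L_n psi^(k) (with g_n replaced by
#' gamma_n in the rescaled, normalized convention), valid when the auxiliary
#' damping is much faster than the system frequencies. With k_max = 0 and a
#' single environment per site this closure turns HOPS into Markovian quantum
#' state diffusion.
#'
#' @param state a [hops_state()]
#' @param basis a [triangular_basis()]
#' @param modes list of [exponential_mode()]s
#' @param variant equation variant the closure is expressed in
#' @return list of entries `aux` (row), `mode`, and closure wave function
#'   `value`
#' @export
apply_terminator <- function(state, basis, modes,
                             variant = c("normalized", "nonlinear", "linear")) {
  variant <- match.arg(variant)
  fm <- flatten_modes(modes)
  n_sites <- ncol(state$psi)
  sys <- hops_system(diag(0, n_sites))
  ctx <- eom_context(sys, fm, basis, variant, terminator = TRUE)
  out <- list()
  for (m in seq_along(fm$g)) {
    rows <- which(ctx$tcoef[, m] != 0)
    for (i in rows) {
      v <- rep(0 + 0i, n_sites)
      v[fm$site[m]] <- ctx$tcoef[i, m] * state$psi[i, fm$site[m]]
      out[[length(out) + 1L]] <- list(aux = i, mode = m, value = v)
    }
  }
  out
}
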