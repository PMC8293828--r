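# Independent cross-check integrators. These deliberately do not share the
# HOPS equation-of-motion code: the hierarchical density-matrix oracle
# couples auxiliary density operators (not wave functions) and is integrated
# with a multistep ODE solver rather than the package's Runge-Kutta stepper,
# so agreement between the two routes checks the stochastic unraveling, the
# noise generation and the integrator at once.

#' Closed-form pure-dephasing coherence decay
#'
#' For two uncoupled, degenerate sites with a bath on site 1 only, the
#' intersite coherence evolves as rho_12(t) = rho_12(0) exp(-Phi(t)) with
#' Phi(t) = (1/hbar^2) int_0^t ds int_0^s ds' alpha(s'). For a sum of
#' exponentials alpha(t) = sum_j g_j exp(-gamma_j t / hbar) the double
#' integral has the closed form
#' sum_j g_j ((hbar/gamma_j) t - (hbar/gamma_j)^2 (1 - exp(-gamma_j t/hbar))).
#'
#' @param modes list of [exponential_mode()]s of the site-1 bath
#' @param t_axis times (fs, >= 0)
#' @return complex vector of coherence decay factors exp(-Phi(t))
#' @export
dephasing_oracle <- function(modes, t_axis) {
  fm <- flatten_modes(modes)
  phi <- vapply(t_axis, function(t) {
    sum(fm$g * ((.hbar / fm$gamma) * t -
                  (.hbar / fm$gamma)^2 * (1 - exp(-fm$gamma * t / .hbar))))
  }, complex(1)) / .hbar^2
  exp(-phi)
}

#' Dense hierarchical density-matrix oracle
#'
#' Deterministic integration of the hierarchically-coupled density-matrix
#' equations with the same exponential bath decomposition and the same
#' triangular/Markovian truncation as the stochastic hierarchy, for small
#' systems only. In the unscaled convention the auxiliary density operators
#' rho^(k) obey
#' d rho^(k)/dt = -(i/hbar)\[H, rho^(k)\] - (k.gamma/hbar) rho^(k)
#'   - (i/hbar) sum_m \[L_m, rho^(k+e_m)\]
#'   - (i/hbar) sum_m k_m (g_m L_m rho^(k-e_m) - g_m* rho^(k-e_m) L_m);
#' internally the auxiliaries are rescaled by sqrt(prod k_m! |g_m|^{k_m}) so
#' that deep hierarchies stay well conditioned (the physical k = 0 element is
#' unaffected).
#'
#' @param sys a [hops_system()] with at most `max_sites` sites
#' @param modes list of [exponential_mode()]s
#' @param k_max triangular truncation depth
#' @param t_axis output times (fs)
#' @param rho0 initial reduced density matrix (defaults to a pure state on
#'   the middle site)
#' @param max_sites size cap for the dense integration (default 3)
#' @return complex array time x site x site of reduced density matrices
#' @export
heom_oracle <- function(sys, modes, k_max, t_axis, rho0 = NULL,
                        max_sites = 3L) {
  if (sys$n_sites > max_sites)
    stop("dense hierarchical oracle is restricted to small systems")
  fm <- flatten_modes(modes)
  basis <- triangular_basis(length(fm$g), k_max, fm$markovian)
  nb <- build_neighbor_tables(basis)
  K <- basis$K
  n <- sys$n_sites
  n_aux <- nrow(K)
  if (is.null(rho0)) {
    rho0 <- matrix(0 + 0i, n, n)
    mid <- (n + 1L) %/% 2L
    rho0[mid, mid] <- 1
  }
  H <- sys$H
  damp <- as.vector(K %*% fm$gamma) / .hbar
  y0 <- rep(0 + 0i, n_aux * n * n)
  y0[seq_len(n * n)] <- as.vector(rho0)
  deriv <- function(t, y, parms) {
    rho <- array(y, c(n, n, n_aux))
    d <- array(0 + 0i, c(n, n, n_aux))
    for (a in seq_len(n_aux)) {
      r <- rho[, , a]
      d[, , a] <- -1i / .hbar * (H %*% r - r %*% H) - damp[a] * r
      for (m in seq_along(fm$g)) {
        s <- fm$site[m]
        iu <- nb$up[a, m]
        if (iu > 0L) {
          ru <- rho[, , iu]
          com <- matrix(0 + 0i, n, n)
          com[s, ] <- ru[s, ]
          com[, s] <- com[, s] - ru[, s]
          cu <- sqrt((K[a, m] + 1) * Mod(fm$g[m]))
          d[, , a] <- d[, , a] - 1i / .hbar * cu * com
        }
        idn <- nb$down[a, m]
        if (idn > 0L) {
          rd <- rho[, , idn]
          term <- matrix(0 + 0i, n, n)
          term[s, ] <- fm$g[m] * rd[s, ]
          term[, s] <- term[, s] - Conj(fm$g[m]) * rd[, s]
          cd <- sqrt(K[a, m] / Mod(fm$g[m]))
          d[, , a] <- d[, , a] - 1i / .hbar * cd * term
        }
      }
    }
    list(as.vector(d))
  }
  sol <- deSolve::zvode(y0, t_axis, deriv, parms = NULL,
                        atol = 1e-10, rtol = 1e-10)
  out <- array(0 + 0i, c(length(t_axis), n, n))
  for (ti in seq_along(t_axis))
    out[ti, , ] <- matrix(sol[ti, 1L + seq_len(n * n)], n, n)
  out
}

#' Pure-dephasing Lindblad integration
#'
#' Markovian reference dynamics: d rho/dt = -(i/hbar)\[H, rho\] +
#' sum_n Gamma_n (L_n rho L_n - (L_n rho + rho L_n)/2) with site projectors
#' L_n. The Markov-limit dephasing rate of an exponential bath mode is
#' Gamma = 2 Re(g) / (gamma hbar).
#'
#' @param sys a [hops_system()]
#' @param rates per-site dephasing rates Gamma_n (fs^-1)
#' @param rho0 initial density matrix
#' @param t_axis output times (fs)
#' @return complex array time x site x site
#' @export
lindblad_oracle <- function(sys, rates, rho0, t_axis) {
  n <- sys$n_sites
  stopifnot(length(rates) == n)
  H <- sys$H
  deriv <- function(t, y, parms) {
    r <- matrix(y, n, n)
    d <- -1i / .hbar * (H %*% r - r %*% H)
    # site-projector dissipator: damps off-diagonal elements only
    for (a in seq_len(n)) for (b in seq_len(n)) if (a != b)
      d[a, b] <- d[a, b] - (rates[a] + rates[b]) / 2 * r[a, b]
    list(as.vector(d))
  }
  sol <- deSolve::zvode(as.vector(rho0) + 0i, t_axis, deriv, parms = NULL,
                        atol = 1e-10, rtol = 1e-10)
  out <- array(0 + 0i, c(length(t_axis), n, n))
  for (ti in seq_along(t_axis))
    out[ti, , ] <- matrix(sol[ti, 1L + seq_len(n * n)], n, n)
  out
}
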