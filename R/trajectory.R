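#' Run configuration for HOPS trajectories
#'
#' Bundles the electronic system, the per-site bath, the equation-of-motion
#' variant, hierarchy and adaptivity parameters, and the integration grid.
#'
#' @param system a [hops_system()] (or use `n_sites`/`V` to build a chain)
#' @param bath a [drude_lorentz_bath()] applied to every site, or a list of
#'   [exponential_mode()]s for full control over the decomposition
#' @param variant one of `"normalized"` (default), `"nonlinear"`, `"linear"`,
#'   `"adaptive"` (normalized equation with per-step basis adaptation)
#' @param k_max triangular truncation depth
#' @param delta derivative-error bound for the adaptive variant
#' @param dt integrator step (fs), default 2
#' @param t_max final time (fs)
#' @param start_site initially excited site; default the middle of the chain
#' @param psi0 optional initial physical wave function over all sites
#'   (normalized internally); overrides `start_site` localization
#' @param terminator apply the boundary closure at the truncation edge
#' @param delta_split fraction of the squared error budget assigned to the
#'   auxiliary basis (remainder to the state basis)
#' @param store_every store every m-th step (default 1)
#' @param store_aux record the squared norms of all auxiliaries over time
#'   (fixed-basis variants only)
#' @return object of class `hops_config`
#' @export
hops_config <- function(system, bath, variant = c("normalized", "nonlinear",
                                                  "linear", "adaptive"),
                        k_max = 10L, delta = 0, dt = 2, t_max = 400,
                        start_site = NULL, terminator = FALSE,
                        delta_split = 0.5, store_every = 1L,
                        store_aux = FALSE, psi0 = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(system, "hops_system"), dt > 0, t_max >= dt, delta >= 0,
            k_max >= 0)
  modes <- if (inherits(bath, "drude_lorentz_bath"))
    chain_modes(system$n_sites, bath)
  else if (inherits(bath, "exponential_mode")) list(bath)
  else bath
  fm <- flatten_modes(modes)
  stopifnot(all(fm$site >= 1L), all(fm$site <= system$n_sites))
  if (is.null(start_site)) start_site <- (system$n_sites + 1L) %/% 2L
  if (start_site < 1L || start_site > system$n_sites)
    stop("start_site out of range")
  if (!is.null(psi0)) {
    stopifnot(length(psi0) == system$n_sites)
    psi0 <- as.complex(psi0) / sqrt(sum(Mod(psi0)^2))
    start_site <- which.max(Mod(psi0))
  }
  if (variant == "adaptive" && delta < 0) stop("adaptive variant needs delta >= 0")
  structure(list(system = system, modes = modes, fm = fm, variant = variant,
                 k_max = as.integer(k_max), delta = delta, dt = dt,
                 t_max = t_max, start_site = as.integer(start_site),
                 terminator = terminator, delta_split = delta_split,
                 store_every = as.integer(store_every),
                 store_aux = store_aux, psi0 = psi0),
            class = "hops_config")
}

#' @export
print.hops_config <- function(x, ...) {
  cat(sprintf("HOPS run: %d sites, %d modes, variant = %s, k_max = %d%s, dt = %g fs, t_max = %g fs\n",
              x$system$n_sites, length(x$fm$g), x$variant, x$k_max,
              if (x$variant == "adaptive") sprintf(", delta = %g", x$delta) else "",
              x$dt, x$t_max))
  invisible(x)
}

#' Initial HOPS state
#'
#' The physical wave function localized on the configured start site, all
#' auxiliaries and memory accumulators zero: without a source term the
#' hierarchy carries no amplitude at t = 0.
#'
#' @param config a [hops_config()]
#' @param basis hierarchy basis to allocate over (defaults to the full
#'   triangular basis of the configuration)
#' @param sites active site set (defaults to all sites)
#' @return a [hops_state()]
#' @export
initial_state <- function(config, basis = NULL, sites = NULL) {
  if (is.null(basis))
    basis <- triangular_basis(length(config$fm$g), config$k_max,
                              config$fm$markovian)
  if (is.null(sites)) sites <- seq_len(config$system$n_sites)
  psi <- matrix(0 + 0i, nrow(basis$K), length(sites))
  if (!is.null(config$psi0)) {
    col <- match(which(Mod(config$psi0) > 0), sites)
    if (anyNA(col)) stop("initial amplitude outside the active site set")
    psi[1L, col] <- config$psi0[Mod(config$psi0) > 0]
  } else {
    col <- match(config$start_site, sites)
    if (is.na(col)) stop("start site is not in the active site set")
    psi[1L, col] <- 1 + 0i
  }
  hops_state(psi, rep(0 + 0i, length(config$fm$g)), 0)
}

#' Integrate a single stochastic HOPS trajectory
#'
#' Classical fixed-step fourth-order Runge-Kutta integration of the chosen
#' equation variant, with the noise interpolated linearly at half steps. For
#' the adaptive variant the reduced basis is rebuilt from the state before
#' every step and the state rebased onto it. The result is deterministic
#' given (config, seed).
#'
#' @param config a [hops_config()]
#' @param seed integer trajectory seed (drives the noise)
#' @param noise optional pre-generated [generate_noise()] object (for
#'   shared-noise comparisons); must cover the integration grid
#' @return object of class `hops_trajectory`: time axis `t`, normalized
#'   physical wave function series `psi0` (time x site), physical norm series
#'   `norm`, site populations `pops`, basis-size series `n_aux` / `n_states`,
#'   optional auxiliary norm series `aux_norm2`, final memory accumulators
#'   `xi`, and the seed.
#' @export
integrate_trajectory <- function(config, seed, noise = NULL) {
  sys <- config$system
  fm <- config$fm
  n_steps <- floor(config$t_max / config$dt + 1e-9)
  t_axis <- seq(0, by = config$dt, length.out = n_steps + 1L)
  if (is.null(noise))
    noise <- generate_noise(config$modes, sys$n_sites, t_axis, seed)
  adaptive <- config$variant == "adaptive"
  variant <- if (adaptive) "normalized" else config$variant

  if (adaptive) {
    sites <- config$start_site
    basis <- new_hierarchy_basis(
      matrix(0L, 1L, length(fm$g)), length(fm$g), config$k_max, fm$markovian)
    state <- initial_state(config, basis, sites)
  } else {
    sites <- seq_len(sys$n_sites)
    basis <- triangular_basis(length(fm$g), config$k_max, fm$markovian)
    state <- initial_state(config, basis, sites)
    ctx <- eom_context(sys, fm, basis, variant, config$terminator, sites)
  }

  keep <- seq(0L, n_steps, by = config$store_every)
  n_keep <- length(keep)
  psi0 <- matrix(0 + 0i, n_keep, sys$n_sites)
  norms <- numeric(n_keep)
  n_aux <- integer(n_keep); n_states <- integer(n_keep)
  aux_norm2 <- if (config$store_aux && !adaptive)
    matrix(0, n_keep, nrow(basis$K)) else NULL
  k_idx <- 1L

  record <- function(step) {
    p0 <- state$psi[1L, ]
    nrm <- sqrt(sum(Mod(p0)^2))
    full <- rep(0 + 0i, sys$n_sites)
    full[sites] <- if (nrm > 0) p0 / nrm else p0
    psi0[k_idx, ] <<- full
    norms[k_idx] <<- nrm
    n_aux[k_idx] <<- nrow(state$psi)
    n_states[k_idx] <<- length(sites)
    if (!is.null(aux_norm2)) aux_norm2[k_idx, ] <<- rowSums(Mod(state$psi)^2)
    k_idx <<- k_idx + 1L
  }
  record(0L)

  for (step in seq_len(n_steps)) {
    t0 <- t_axis[step]
    if (adaptive) {
      zrow <- noise_row_at(noise, t0)
      ab <- build_adaptive_basis(state, sys, config$modes, basis, sites,
                                 config$k_max, config$delta,
                                 config$delta_split,
                                 znorm = max(Mod(zrow[sites]), 0))
      unchanged <- step > 1L && identical(ab$sites, sites) &&
        length(ab$basis$codes) == length(basis$codes) &&
        all(ab$basis$codes == basis$codes)
      if (!unchanged) {
        state <- rebase_state(state, basis, sites, ab$basis, ab$sites)
        basis <- ab$basis; sites <- ab$sites
        ctx <- eom_context(sys, fm, basis, variant, config$terminator, sites)
      }
    }
    z1 <- Conj(noise_row_at(noise, t0))
    zh <- Conj(noise_row_at(noise, t0 + config$dt / 2))
    z2 <- Conj(noise_row_at(noise, t0 + config$dt))
    state <- rk4_step(ctx, state, z1, zh, z2, config$dt)
    if (anyNA(state$psi) || any(is.infinite(Re(state$psi))) ||
        any(is.infinite(Im(state$psi))))
      stop(sprintf(
        "trajectory diverged (NaN/Inf in wave function) at t = %g fs [variant %s, seed %s]",
        t0 + config$dt, config$variant, format(seed)))
    if (step %in% keep) record(step)
  }

  structure(list(t = t_axis[keep + 1L], psi0 = psi0, norm = norms,
                 pops = Mod(psi0)^2, n_aux = n_aux, n_states = n_states,
                 aux_norm2 = aux_norm2,
                 basis_keys = if (!adaptive) basis$keys else NULL,
                 xi = state$xi, seed = seed, config = config),
            class = "hops_trajectory")
}

rk4_step <- function(ctx, state, z1, zh, z2, dt) {
  y <- state
  d1 <- eval_derivative(ctx, y$psi, y$xi, z1)
  d2 <- eval_derivative(ctx, y$psi + dt / 2 * d1$dpsi, y$xi + dt / 2 * d1$dxi, zh)
  d3 <- eval_derivative(ctx, y$psi + dt / 2 * d2$dpsi, y$xi + dt / 2 * d2$dxi, zh)
  d4 <- eval_derivative(ctx, y$psi + dt * d3$dpsi, y$xi + dt * d3$dxi, z2)
  hops_state(
    y$psi + dt / 6 * (d1$dpsi + 2 * d2$dpsi + 2 * d3$dpsi + d4$dpsi),
    y$xi + dt / 6 * (d1$dxi + 2 * d2$dxi + 2 * d3$dxi + d4$dxi),
    y$time + dt)
}

#' @export
print.hops_trajectory <- function(x, ...) {
  cat(sprintf("HOPS trajectory: %d stored times to %g fs, mean aux basis %.1f, mean state basis %.1f\n",
              length(x$t), max(x$t), mean(x$n_aux), mean(x$n_states)))
  invisible(x)
}
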