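#' Run an ensemble of HOPS trajectories
#'
#' Trajectories are statistically independent (seeds `master_seed + i - 1`)
#' and can be executed in parallel; results are identical for any worker
#' count. The reduced density matrix is the ensemble mean of physical-slice
#' projectors: normalized projectors for the non-linear equations, raw
#' (norm-weighted) projectors renormalized by their average trace for the
#' linear equation.
#'
#' @param config a [hops_config()]
#' @param n_traj number of trajectories
#' @param master_seed integer; trajectory i uses seed `master_seed + i - 1`
#' @param workers parallel worker processes (forked; default 1)
#' @param n_boot bootstrap resamples for population standard errors
#' @return object of class `hops_ensemble`: time axis `t`, density matrix
#'   array `rho` (time x site x site), population matrix `pops` with
#'   bootstrap standard errors `pops_se`, per-trajectory time-averaged basis
#'   sizes `aux_size` / `state_size`, seeds, `n_traj`.
#' @export
run_ensemble <- function(config, n_traj, master_seed, workers = 1L,
                         n_boot = 200L) {
  seeds <- master_seed + seq_len(n_traj) - 1L
  run1 <- function(s) integrate_trajectory(config, s)
  trajs <- if (workers > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(seeds, run1, mc.cores = workers)
  } else lapply(seeds, run1)
  bad <- vapply(trajs, inherits, logical(1), "try-error")
  if (any(bad))
    stop("trajectory failures for seeds: ", paste(seeds[bad], collapse = ", "))
  assemble_ensemble(trajs, config, n_boot, master_seed)
}

assemble_ensemble <- function(trajs, config, n_boot, master_seed) {
  n <- config$system$n_sites
  nt <- length(trajs[[1L]]$t)
  linear <- config$variant == "linear"
  rho <- array(0 + 0i, c(nt, n, n))
  w_tot <- if (linear) numeric(nt) else length(trajs)
  pop_arr <- array(0, c(length(trajs), nt, n))
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    w <- if (linear) tr$norm^2 else rep(1, nt)
    for (ti in seq_len(nt)) {
      v <- tr$psi0[ti, ]
      rho[ti, , ] <- rho[ti, , ] + w[ti] * (v %o% Conj(v))
    }
    if (linear) w_tot <- w_tot + w
    pop_arr[i, , ] <- Mod(tr$psi0)^2 * w
  }
  rho <- rho / if (linear) array(rep(w_tot, n * n), c(nt, n, n)) else w_tot
  pops <- matrix(0, nt, n)
  for (s in seq_len(n)) pops[, s] <- Re(rho[, s, s])
  # seeded bootstrap over trajectories
  set.seed((master_seed * 31 + 7) %% 2147483629)
  nT <- length(trajs)
  pm <- matrix(pop_arr, nrow = nT)  # trajectories x (time*site)
  wv <- if (linear) {
    wl <- vapply(trajs, function(tr) tr$norm^2, numeric(nt))
    t(wl)  # trajectories x time
  } else NULL
  boot <- matrix(0, n_boot, ncol(pm))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nT, nT, replace = TRUE)
    if (linear) {
      num <- colSums(pm[idx, , drop = FALSE])
      den <- rep(colSums(wv[idx, , drop = FALSE]), n)
      boot[b, ] <- num / den
    } else boot[b, ] <- colMeans(pm[idx, , drop = FALSE])
  }
  pops_se <- matrix(apply(boot, 2, stats::sd), nt, n)
  structure(list(
    t = trajs[[1L]]$t, rho = rho, pops = pops, pops_se = pops_se,
    aux_size = vapply(trajs, function(tr) mean(tr$n_aux), numeric(1)),
    state_size = vapply(trajs, function(tr) mean(tr$n_states), numeric(1)),
    n_traj = length(trajs), seeds = vapply(trajs, `[[`, numeric(1), "seed"),
    config = config), class = "hops_ensemble")
}

#' @export
print.hops_ensemble <- function(x, ...) {
  cat(sprintf("HOPS ensemble: %d trajectories, %d sites, t up to %g fs\n",
              x$n_traj, ncol(x$pops), max(x$t)))
  cat(sprintf("  mean aux basis %.1f, mean state basis %.1f\n",
              mean(x$aux_size), mean(x$state_size)))
  invisible(x)
}

#' Mean adaptive error between two shared-noise ensembles
#'
#' Mean absolute site-population difference between an adaptive and a full
#' calculation run with identical seeds (shared noise), averaged over all
#' time points and sites. Shared-noise pairing removes the leading-order
#' statistical error, leaving the truncation error of the adaptive basis.
#' Per-site means are attached as attribute `"per_site"`.
#'
#' @param adhops,hops two [run_ensemble()] results on identical time axes
#' @return scalar mean absolute population error
#' @export
adaptive_error <- function(adhops, hops) {
  if (length(adhops$t) != length(hops$t) ||
      max(abs(adhops$t - hops$t)) > 1e-9)
    stop("ensembles have mismatched time axes")
  d <- abs(adhops$pops - hops$pops)
  structure(mean(d), per_site = colMeans(d))
}
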