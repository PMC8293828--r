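# Adaptive basis construction (adHOPS).
#
# At each time point a reduced auxiliary basis and a reduced state (site)
# basis are chosen so that the Euclidean norm of the time-derivative error
# committed by the truncation stays below the user threshold delta. The
# error budget is split in quadrature between the two bases
# (delta_aux^2 + delta_state^2 <= delta^2). Selection is greedy: every
# candidate exclusion is scored by an upper bound on the squared derivative
# flux it would absorb, candidates are sorted by ascending score, and the
# largest prefix whose cumulative score fits the budget is excluded.
#
# Because the hierarchy couples only nearest-neighbor auxiliaries and the
# system-bath coupling is a site projection, flux towards an absent
# auxiliary can only originate from currently occupied neighbors with
# amplitude on the associated site, so the candidate pool is the current
# basis plus its one-step neighborhood and the cost of basis construction
# scales with the occupied basis, not with the aggregate size.

#' Derivative flux received by candidate auxiliaries
#'
#' For each candidate auxiliary outside the current set, computes the squared
#' Euclidean norm of the time-derivative contribution it would receive from
#' the current members under the normalized non-linear flux coefficients
#' (down-flux (k_n+1) gamma_n / hbar through L_n, up-flux g_n/(gamma_n hbar)
#' through (L_n - <L_n>)). Candidates reachable only through sites without
#' amplitude receive a bound of zero.
#'
#' @param state a [hops_state()] over the current basis
#' @param sys a [hops_system()]
#' @param modes list of [exponential_mode()]s
#' @param basis current [triangular_basis()] (the occupied auxiliary set)
#' @param candidates integer matrix of candidate index vectors (rows)
#' @param sites active site indices (columns of `state$psi`)
#' @return numeric vector of squared flux norms, one per candidate row
#' @export
flux_up_bounds <- function(state, sys, modes, basis, candidates,
                           sites = seq_len(sys$n_sites)) {
  fm <- flatten_modes(modes)
  psi <- state$psi
  expL <- physical_expectations(psi, "normalized")
  mode_col <- match(fm$site, sites, nomatch = 0L)
  nrm2 <- rowSums(Mod(psi)^2)
  out <- numeric(nrow(candidates))
  for (ci in seq_len(nrow(candidates))) {
    kc <- candidates[ci, ]
    v <- rep(0 + 0i, length(sites))
    for (m in seq_along(fm$g)) {
      s <- mode_col[m]
      if (s == 0L) next
      # flux from below: kc - e_m present and with amplitude on site(m)
      if (kc[m] > 0L) {
        kd <- kc; kd[m] <- kd[m] - 1L
        src <- match(aux_key(kd), basis$keys)
        if (!is.na(src))
          v[s] <- v[s] + kc[m] * fm$gamma[m] / .hbar * psi[src, s]
      }
      # flux from above through the shifted projector
      ku <- kc; ku[m] <- ku[m] + 1L
      src <- match(aux_key(ku), basis$keys)
      if (!is.na(src)) {
        cu <- fm$g[m] / (fm$gamma[m] * .hbar)
        v <- v + cu * expL[s] * psi[src, ]
        v[s] <- v[s] - cu * psi[src, s]
      }
    }
    out[ci] <- sum(Mod(v)^2)
  }
  out
}

# ---- greedy basis construction ---------------------------------------------

#' Build the adaptive auxiliary and state basis for the current state
#'
#' Scores every member of the current basis and of its one-step neighborhood
#' (within the triangular and Markovian-mode constraints) by an upper bound
#' on the derivative flux that would be lost were it excluded, then greedily
#' excludes the lowest-scoring prefix whose cumulative squared flux stays
#' within the error budget. The physical wave function, and every site
#' carrying physical amplitude above numerical zero, are always retained.
#' With `delta = 0` the full triangular basis and all sites are returned, so
#' the adaptive scheme reverts smoothly to a plain HOPS calculation.
#'
#' @param state a [hops_state()] over (`basis`, `sites`)
#' @param sys a [hops_system()]
#' @param modes list of [exponential_mode()]s
#' @param basis current [triangular_basis()]
#' @param sites current active site indices
#' @param k_max full triangular truncation depth
#' @param delta derivative-error bound (>= 0)
#' @param delta_split fraction of the squared budget given to the auxiliary
#'   basis (default 0.5: equal split in quadrature)
#' @param znorm optional magnitude of the current effective noise (cm^-1),
#'   tightening the retention guard for occupied members
#' @return object of class `adaptive_basis`: list(`basis`, `sites`,
#'   `delta_aux`, `delta_state`)
#' @export
build_adaptive_basis <- function(state, sys, modes, basis, sites, k_max,
                                 delta, delta_split = 0.5, znorm = 0) {
  if (delta < 0) stop("delta must be non-negative")
  fm <- flatten_modes(modes)
  n_modes <- length(fm$g)
  if (delta == 0) {
    return(structure(list(
      basis = triangular_basis(n_modes, k_max, fm$markovian),
      sites = seq_len(sys$n_sites), delta_aux = 0, delta_state = 0),
      class = "adaptive_basis"))
  }
  delta_aux <- sqrt(delta_split) * delta
  delta_state <- sqrt(1 - delta_split) * delta
  psi <- state$psi
  K <- basis$K
  expL <- physical_expectations(psi, "normalized")
  mode_col <- match(fm$site, sites, nomatch = 0L)
  absg <- Mod(fm$gamma) / .hbar
  abscup <- Mod(fm$g / (fm$gamma * .hbar))
  hnorm <- max(rowSums(abs(sys$H))) / .hbar

  nrm <- sqrt(rowSums(Mod(psi)^2))
  amp_tol <- 1e-13 * max(nrm, 1e-300)
  has_mark <- if (any(fm$markovian))
    rowSums(K[, fm$markovian, drop = FALSE]) > 0L else rep(FALSE, nrow(K))
  depth_nm <- rowSums(K[, !fm$markovian, drop = FALSE])

  # --- candidate generation with flux-norm accumulation ---
  codes_acc <- list(); fnorm_acc <- list(); newK <- list()
  for (m in seq_len(n_modes)) {
    s <- mode_col[m]
    if (s == 0L) next
    # up-candidates: sourced by amplitude on site(m), within truncation
    ok <- Mod(psi[, s]) > amp_tol
    ok <- ok & if (fm$markovian[m]) (depth_nm == 0L & !has_mark) else
      (!has_mark & depth_nm < k_max)
    src <- which(ok)
    if (length(src)) {
      Ku <- K[src, , drop = FALSE]; Ku[, m] <- Ku[, m] + 1L
      i <- length(newK) + 1L
      codes_acc[[i]] <- fast_keys(Ku, basis$B)
      fnorm_acc[[i]] <- Ku[, m] * absg[m] * Mod(psi[src, s])
      newK[[i]] <- Ku
    }
    # down-candidates: receive the shifted up-flux from their parent
    src <- which(K[, m] > 0L & nrm > amp_tol)
    if (length(src)) {
      Kd <- K[src, , drop = FALSE]; Kd[, m] <- Kd[, m] - 1L
      upn2 <- pmax(0, Mod(psi[src, s])^2 * (1 - 2 * expL[s]) +
                     expL[s]^2 * nrm[src]^2)
      i <- length(newK) + 1L
      codes_acc[[i]] <- fast_keys(Kd, basis$B)
      fnorm_acc[[i]] <- abscup[m] * sqrt(upn2)
      newK[[i]] <- Kd
    }
  }

  # --- pool assembly: occupied members plus generated neighbors ---
  pool_codes <- basis$codes
  pool_K <- K
  if (length(newK)) {
    codes_acc <- unlist(codes_acc)
    fnorm_acc <- unlist(fnorm_acc)
    cand_K <- do.call(rbind, newK)
    extra <- !(codes_acc %in% pool_codes) & !duplicated(codes_acc)
    if (any(extra)) {
      pool_codes <- c(pool_codes, codes_acc[extra])
      pool_K <- rbind(pool_K, cand_K[extra, , drop = FALSE])
    }
  }
  f_in <- numeric(length(pool_codes))
  if (length(newK)) {
    grp <- match(codes_acc, pool_codes)
    agg <- rowsum(fnorm_acc, grp)
    f_in[as.integer(rownames(agg))] <- agg[, 1L]
  }
  # retention guard for occupied members: bound on their own derivative norm
  rate <- Mod(as.vector(K %*% fm$gamma)) / .hbar + hnorm + znorm / .hbar +
    as.vector(K %*% (absg * (mode_col > 0L))) +
    sum(abscup[mode_col > 0L])
  f_amp <- c(nrm * rate, numeric(length(pool_codes) - nrow(K)))
  f <- (f_in + f_amp)^2
  f[1L] <- Inf  # physical wave function (row 1 of the current basis)

  keep_aux <- greedy_retain(f, delta_aux^2)
  Knew <- pool_K[keep_aux, , drop = FALSE]
  Knew <- Knew[graded_lex_order(Knew), , drop = FALSE]

  # --- state basis ---
  coupled <- which(colSums(abs(sys$H[sites, , drop = FALSE])) > 0 |
                     seq_len(sys$n_sites) %in% sites)
  pool_sites <- sort(unique(c(sites, coupled)))
  Hpool <- sys$H[pool_sites, sites, drop = FALSE] / .hbar
  Hoff <- Hpool
  # own-column coupling is not flux between sites
  for (j in seq_along(pool_sites)) {
    jj <- match(pool_sites[j], sites)
    if (!is.na(jj)) Hoff[j, jj] <- 0
  }
  Min <- psi %*% t(Hoff)
  f_site_in <- sqrt(colSums(Mod(Min)^2))
  amp_site <- sqrt(colSums(Mod(psi)^2))[match(pool_sites, sites)]
  amp_site[is.na(amp_site)] <- 0
  rate_s <- hnorm + znorm / .hbar + max(Mod(as.vector(K %*% fm$gamma))) / .hbar +
    k_max * max(absg) + max(abscup)
  f_site <- (f_site_in + amp_site * rate_s)^2
  p0 <- Mod(psi[1L, ])^2
  occupied_phys <- pool_sites %in% sites[p0 > 1e-12]
  f_site[occupied_phys] <- Inf
  keep_sites <- greedy_retain(f_site, delta_state^2)
  sites_new <- sort(pool_sites[keep_sites])

  structure(list(
    basis = new_hierarchy_basis(Knew, n_modes, k_max, fm$markovian),
    sites = sites_new, delta_aux = delta_aux, delta_state = delta_state),
    class = "adaptive_basis")
}

# logical keep-vector: exclude the largest ascending-score prefix whose
# cumulative score stays within the squared budget (stable order: ties keep
# their original graded-lex position)
greedy_retain <- function(f, budget2) {
  ord <- order(f)
  cum <- cumsum(f[ord])
  n_drop <- sum(cum <= budget2 + 1e-300)
  keep <- rep(TRUE, length(f))
  if (n_drop > 0) keep[ord[seq_len(n_drop)]] <- FALSE
  keep
}

#' @export
print.adaptive_basis <- function(x, ...) {
  cat(sprintf("adaptive basis: %d auxiliaries, %d sites (delta_aux = %.2g, delta_state = %.2g)\n",
              nrow(x$basis$K), length(x$sites), x$delta_aux, x$delta_state))
  invisible(x)
}

#' Carry a state onto a new basis
#'
#' Amplitudes are transferred by auxiliary-index and site identity; members
#' new to the basis start at zero and amplitudes of dropped members are
#' discarded (their derivative flux was bounded during basis construction).
#' The physical slice is renormalized after any discard.
#'
#' @param state a [hops_state()] over (`old_basis`, `old_sites`)
#' @param old_basis,new_basis [triangular_basis()] objects
#' @param old_sites,new_sites active site index vectors
#' @param renormalize rescale the physical slice to unit norm after the
#'   transfer (appropriate for the normalized equation of motion, where any
#'   discarded physical amplitude is a bounded truncation error)
#' @return a [hops_state()] over the new basis
#' @export
rebase_state <- function(state, old_basis, old_sites, new_basis, new_sites,
                         renormalize = TRUE) {
  pos <- if (identical(new_basis$B, old_basis$B))
    match(new_basis$codes, old_basis$codes)
  else match(new_basis$keys, old_basis$keys)
  if (is.na(pos[1L]) || any(new_basis$K[1L, ] != 0L))
    stop("new basis must contain the physical (zero) index first")
  scol <- match(new_sites, old_sites)
  psi <- matrix(0 + 0i, nrow(new_basis$K), length(new_sites))
  ok_r <- !is.na(pos); ok_c <- !is.na(scol)
  psi[ok_r, ok_c] <- state$psi[pos[ok_r], scol[ok_c], drop = FALSE]
  if (renormalize) {
    n0 <- sqrt(sum(Mod(psi[1L, ])^2))
    if (n0 > 0) psi[1L, ] <- psi[1L, ] / n0
  }
  hops_state(psi, state$xi, state$time)
}
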