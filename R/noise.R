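# Correlated complex Gaussian noise for HOPS trajectories.
#
# The stochastic processes z_{n,t} driving each site must satisfy
#   E[z] = 0,  E[z_t z_s] = 0,  E[z_t z*_s] = alpha_n(t - s),
# with independent processes on different sites. They are realised by
# spectral filtering of white complex Gaussian noise on a circulant
# embedding of the target correlation function: the Hermitian extension of
# alpha is wrapped onto a periodic grid (long enough that the wrap-around
# tail is negligible), its DFT gives the power spectrum, and filtering white
# noise with the root of that spectrum yields a stationary process with
# exactly the wrapped correlation and identically zero pseudo-correlation.

# Per-site stream seed: a fixed affine map of (master seed, site) so that
# adding sites to a system never perturbs the noise seen by existing sites.
site_stream_seed <- function(seed, site) {
  (as.double(seed) * 7919 + as.double(site) * 104729) %% 2147483629
}

#' Generate correlated complex Gaussian noise for all sites
#'
#' @param modes list of [exponential_mode()]s; the modes attached to each
#'   site jointly define that site's correlation function. Noise is generated
#'   from the total decomposed correlation (slow + Markovian mode) so that its
#'   imaginary part is continuous through t = 0.
#' @param n_sites number of sites (sites without modes get zero noise)
#' @param t_axis uniform time grid (fs) starting at 0
#' @param seed integer master seed; site streams are derived from it
#' @param neg_tol relative tolerance on negative eigenvalues of the embedded
#'   spectrum: values above `-neg_tol * max(S)` are clipped to zero, anything
#'   more negative is an error naming the offending site (the requested
#'   correlation function then admits no complex Gaussian process).
#' @return object of class `noise_trajectory`: `t_axis`, complex matrix `z`
#'   (time x site), `seed`.
#' @export
generate_noise <- function(modes, n_sites, t_axis, seed, neg_tol = 1e-6) {
  fm <- flatten_modes(modes)
  nt <- length(t_axis)
  stopifnot(nt >= 2L)
  dt <- t_axis[2] - t_axis[1]
  if (max(abs(diff(t_axis) - dt)) > 1e-9 * dt) stop("t_axis must be uniform")
  # periodic grid: doubled horizon plus room for the slowest mode to decay
  tail_fs <- 8 * .hbar / min(Re(fm$gamma))
  M <- 2^ceiling(log2(max(2 * nt, (2 * t_axis[nt] + tail_fs) / dt)))
  j <- 0:(M - 1)
  tj <- ifelse(j <= M / 2, j * dt, (j - M) * dt)
  z <- matrix(0 + 0i, nt, n_sites)
  for (s in seq_len(n_sites)) {
    on_site <- which(fm$site == s)
    if (!length(on_site)) next
    site_modes <- lapply(on_site, function(i)
      exponential_mode(fm$g[i], fm$gamma[i], s, fm$markovian[i]))
    cj <- correlation_function(site_modes, tj)
    S <- Re(stats::fft(cj))
    if (min(S) < -neg_tol * max(S))
      stop(sprintf(paste0(
        "embedded noise spectrum for site %d is not positive semidefinite ",
        "(min S = %.3g of max %.3g); the supplied mode set does not define a ",
        "valid complex Gaussian process"), s, min(S), max(S)))
    S[S < 0] <- 0
    set.seed(site_stream_seed(seed, s))
    w <- complex(real = stats::rnorm(M), imaginary = stats::rnorm(M)) / sqrt(2)
    zfull <- stats::fft(sqrt(S) * w, inverse = TRUE) / sqrt(M)
    z[, s] <- zfull[seq_len(nt)]
  }
  structure(list(t_axis = t_axis, z = z, seed = seed),
            class = "noise_trajectory")
}

#' Noise value at an arbitrary time
#'
#' Linear interpolation between grid points, as needed at Runge-Kutta
#' half-steps. Times outside the stored grid are an error.
#'
#' @param traj a [generate_noise()] result
#' @param site site index
#' @param t time (fs)
#' @return complex noise value
#' @export
noise_at <- function(traj, site, t) {
  ta <- traj$t_axis
  if (t < ta[1] - 1e-9 || t > ta[length(ta)] + 1e-9)
    stop(sprintf("t = %g fs is outside the stored noise grid", t))
  noise_row_at(traj, t)[site]
}

# Internal: interpolated noise across all sites at once (complex vector).
noise_row_at <- function(traj, t) {
  ta <- traj$t_axis
  dt <- ta[2] - ta[1]
  x <- (t - ta[1]) / dt
  i0 <- min(floor(x), length(ta) - 1)
  w <- x - i0
  if (w < 1e-12) traj$z[i0 + 1, ]
  else (1 - w) * traj$z[i0 + 1, ] + w * traj$z[i0 + 2, ]
}
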