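#' Site populations of an ensemble
#'
#' Diagonal of the reduced density matrix over time. Populations lie in
#' [0, 1] and sum to one at every time.
#'
#' @param result a [run_ensemble()] result
#' @return numeric matrix, time x site
#' @export
populations <- function(result) {
  stopifnot(inherits(result, "hops_ensemble"))
  result$pops
}

#' Mean-squared displacement of the exciton
#'
#' MSD(t) = sum_n P_n(t) ((n - start) l_0)^2 for a chain with spacing l_0.
#'
#' @param pops population matrix (time x site)
#' @param start_site initially excited site
#' @param spacing molecular spacing l_0 (default 1)
#' @return numeric MSD series (units of l_0^2)
#' @export
msd <- function(pops, start_site, spacing = 1) {
  d2 <- ((seq_len(ncol(pops)) - start_site) * spacing)^2
  as.vector(pops %*% d2)
}

#' Diffusion coefficient from a linear MSD fit
#'
#' Least-squares slope of the MSD over a fit window, converted to a
#' diffusion coefficient with the one-dimensional convention MSD = 2 D t
#' (`msd_factor = 2`; set 1 for the MSD = D t convention). The default
#' window is the second half of the series, past the initial ballistic
#' transient. A large relative fit residual flags a window where the MSD is
#' not linear (e.g. still ballistic).
#'
#' @param msd_series MSD values (l_0^2)
#' @param t time axis (fs)
#' @param window indices of the fit window (default: second half)
#' @param msd_factor proportionality between MSD and D t (default 2)
#' @return object of class `diffusion_fit`: `D` (l_0^2 / fs), `slope`,
#'   `residual` (RMS residual / RMS fitted value), `window`, `ballistic`
#'   flag (residual above 5 percent)
#' @export
diffusion_coefficient <- function(msd_series, t, window = NULL,
                                  msd_factor = 2) {
  stopifnot(length(msd_series) == length(t))
  if (is.null(window))
    window <- seq(ceiling(length(t) / 2), length(t))
  if (length(window) < 2L) stop("fit window must contain at least 2 points")
  fit <- stats::lm.fit(cbind(1, t[window]), msd_series[window])
  slope <- fit$coefficients[2L]
  scale <- sqrt(mean(fit$fitted.values^2))
  residual <- if (scale > 0) sqrt(mean(fit$residuals^2)) / scale else 0
  structure(list(D = unname(slope) / msd_factor, slope = unname(slope),
                 residual = residual, window = window,
                 ballistic = residual > 0.05,
                 msd = msd_series, t = t),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion fit: D = %.4g l0^2/fs (MSD = %g D t), rel. residual %.2g%s\n",
              x$D, x$slope / x$D, x$residual,
              if (x$ballistic) " [non-linear window]" else ""))
  invisible(x)
}

#' Auxiliary occupation map of a single trajectory
#'
#' Time series of the squared norms of selected auxiliary wave functions,
#' labeled by their index vectors. Requires a trajectory run with
#' `store_aux = TRUE` (fixed-basis variants). In a localized trajectory the
#' auxiliaries attached to a site's thermal environment are occupied only
#' while that site itself is populated.
#'
#' @param traj a [integrate_trajectory()] result with auxiliary capture
#' @param aux_keys character keys (comma-separated index vectors) or an
#'   integer matrix of index vectors selecting auxiliaries
#' @return numeric matrix time x selected auxiliary, with key column names
#' @export
aux_occupation_map <- function(traj, aux_keys) {
  if (is.null(traj$aux_norm2))
    stop("trajectory was run without auxiliary capture (store_aux = TRUE)")
  if (is.matrix(aux_keys)) aux_keys <- row_keys(aux_keys)
  pos <- match(aux_keys, traj$basis_keys)
  if (anyNA(pos))
    stop("auxiliaries not captured: ", paste(aux_keys[is.na(pos)], collapse = "; "))
  out <- traj$aux_norm2[, pos, drop = FALSE]
  colnames(out) <- aux_keys
  out
}
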