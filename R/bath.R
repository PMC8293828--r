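#' Drude-Lorentz bath description
#'
#' An overdamped vibrational environment attached to one site, characterised
#' by its reorganization energy `lambda`, relaxation rate `gamma`, temperature
#' and the decay rate `gamma_mark` of the Markovian short-time correction mode
#' that restores continuity of the imaginary part of the bath correlation
#' function at t = 0.
#'
#' The high-temperature exponential decomposition of the correlation function
#' is only valid for `gamma / (k_B T) < 1`; a warning is emitted when the
#' supplied parameters violate this condition.
#'
#' @param lambda reorganization energy (cm^-1), > 0
#' @param gamma bath relaxation rate (cm^-1), > 0
#' @param temperature temperature (K), > 0
#' @param gamma_mark decay rate of the Markovian correction mode (cm^-1);
#'   must exceed `gamma`. Default 500 cm^-1.
#' @return Object of class `drude_lorentz_bath`.
#' @examples
#' drude_lorentz_bath(lambda = 50, gamma = 50, temperature = 295)
#' @export
drude_lorentz_bath <- function(lambda, gamma, temperature, gamma_mark = 500) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0,
            is.numeric(gamma), length(gamma) == 1L, gamma > 0,
            is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  if (gamma_mark <= gamma)
    stop("gamma_mark must exceed gamma (the correction mode must decay faster than the bath)")
  if (gamma / (.kB * temperature) >= 1)
    warning(sprintf(
      "gamma/(k_B T) = %.3g >= 1: the high-temperature exponential decomposition is unreliable",
      gamma / (.kB * temperature)))
  structure(list(lambda = lambda, gamma = gamma, temperature = temperature,
                 gamma_mark = gamma_mark),
            class = "drude_lorentz_bath")
}

#' @export
print.drude_lorentz_bath <- function(x, ...) {
  cat(sprintf(
    "Drude-Lorentz bath: lambda = %g cm-1, gamma = %g cm-1, T = %g K, gamma_mark = %g cm-1\n",
    x$lambda, x$gamma, x$temperature, x$gamma_mark))
  invisible(x)
}

#' Drude-Lorentz spectral density
#'
#' Evaluates J(omega) = 2 lambda gamma omega / (omega^2 + gamma^2), an odd
#' function of frequency.
#'
#' @param bath a [drude_lorentz_bath()]
#' @param omega frequency (cm^-1); may be any real vector
#' @return spectral density values (cm^-1)
#' @examples
#' b <- drude_lorentz_bath(50, 50, 295)
#' spectral_density(b, 50)   # lambda at the peak omega = gamma
#' @export
spectral_density <- function(bath, omega) {
  stopifnot(inherits(bath, "drude_lorentz_bath"))
  2 * bath$lambda * bath$gamma * omega / (omega^2 + bath$gamma^2)
}

#' Single exponential mode of a bath correlation function
#'
#' One term g * exp(-gamma t / hbar) of the correlation-function expansion,
#' tagged by the site whose environment it belongs to and by whether it plays
#' the fast Markovian-correction role (kept only at first order in the
#' hierarchy).
#'
#' @param g complex prefactor (cm^-2)
#' @param gamma decay rate (cm^-1); the real part must be positive
#' @param site 1-based site index
#' @param markovian logical role flag
#' @return object of class `exponential_mode`
#' @export
exponential_mode <- function(g, gamma, site, markovian = FALSE) {
  g <- as.complex(g); gamma <- as.complex(gamma)
  stopifnot(length(g) == 1L, length(gamma) == 1L, length(site) == 1L)
  if (Re(gamma) <= 0) stop("Re(gamma) must be positive: every mode must decay")
  structure(list(g = g, gamma = gamma, site = as.integer(site),
                 markovian = isTRUE(markovian)),
            class = "exponential_mode")
}

#' Exponential decomposition of a Drude-Lorentz correlation function
#'
#' At high temperature the Drude-Lorentz correlation function is a single
#' exponential with prefactor g = 2 lambda k_B T - i lambda gamma. Its
#' imaginary part is discontinuous at t = 0 (the correlation function must
#' satisfy alpha(-t) = alpha(t)*), which injects unphysically high-frequency
#' content into the driving noise. The decomposition returned here therefore
#' pairs the slow mode with a fast "Markovian" mode of prefactor
#' -i Im(g) = +i lambda gamma decaying at `gamma_mark`, so that the total
#' correlation function has zero imaginary part at t = 0 and relaxes back to
#' the bare exponential on the timescale hbar / gamma_mark.
#'
#' @param bath a [drude_lorentz_bath()]
#' @param site site index the modes are attached to (default 1)
#' @return list of two [exponential_mode()]s: the slow mode and the Markovian
#'   correction mode.
#' @examples
#' decompose_correlation(drude_lorentz_bath(50, 50, 295))
#' @export
decompose_correlation <- function(bath, site = 1L) {
  stopifnot(inherits(bath, "drude_lorentz_bath"))
  g0 <- complex(real = 2 * bath$lambda * .kB * bath$temperature,
                imaginary = -bath$lambda * bath$gamma)
  list(
    exponential_mode(g0, bath$gamma, site, markovian = FALSE),
    exponential_mode(complex(real = 0, imaginary = -Im(g0)), bath$gamma_mark,
                     site, markovian = TRUE)
  )
}

#' Bath correlation function from exponential modes
#'
#' Evaluates alpha(t) = sum_i g_i exp(-gamma_i t / hbar) for t >= 0 and
#' extends it to negative times by the symmetry alpha(-t) = alpha(t)*.
#'
#' @param modes list of [exponential_mode()]s (their site tags are ignored)
#' @param t times (fs), any sign
#' @return complex vector of correlation values (cm^-2)
#' @export
correlation_function <- function(modes, t) {
  if (inherits(modes, "exponential_mode")) modes <- list(modes)
  pos <- rep(0 + 0i, length(t))
  for (m in modes) pos <- pos + m$g * exp(-m$gamma * abs(t) / .hbar)
  ifelse(t >= 0, pos, Conj(pos))
}

# Internal: collect per-site mode lists into a flat data structure used by the
# equation-of-motion code. Returns list with complex vectors g, gamma, integer
# site, logical markovian.
flatten_modes <- function(modes) {
  if (inherits(modes, "exponential_mode")) modes <- list(modes)
  stopifnot(length(modes) >= 1L,
            all(vapply(modes, inherits, logical(1), "exponential_mode")))
  list(
    g = vapply(modes, function(m) m$g, complex(1)),
    gamma = vapply(modes, function(m) m$gamma, complex(1)),
    site = vapply(modes, function(m) m$site, integer(1)),
    markovian = vapply(modes, function(m) m$markovian, logical(1))
  )
}

# Internal: build the full mode list for a system where every site carries the
# same Drude-Lorentz bath (the homogeneous-chain setting).
chain_modes <- function(n_sites, bath) {
  unlist(lapply(seq_len(n_sites), function(s) decompose_correlation(bath, s)),
         recursive = FALSE)
}
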