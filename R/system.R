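#' Electronic system model
#'
#' A Frenkel exciton Hamiltonian: site energies on the diagonal and
#' electronic couplings off the diagonal, in cm^-1. The system-bath coupling
#' operator of each site is implicitly the site projector |n><n|, which is
#' what permits the locality arguments behind the adaptive basis.
#'
#' @param hamiltonian Hermitian numeric/complex matrix (cm^-1)
#' @param spacing intersite spacing l_0 (arbitrary length unit, default 1)
#' @return object of class `hops_system`
#' @export
hops_system <- function(hamiltonian, spacing = 1) {
  H <- as.matrix(hamiltonian)
  if (max(abs(H - Conj(t(H)))) > 1e-12 * max(1, max(abs(H))))
    stop("hamiltonian must be Hermitian")
  structure(list(H = H, n_sites = nrow(H), spacing = spacing),
            class = "hops_system")
}

#' @export
print.hops_system <- function(x, ...) {
  cat(sprintf("exciton system: %d sites, max |coupling| = %g cm-1\n",
              x$n_sites, max(abs(x$H - diag(diag(x$H))))))
  invisible(x)
}

#' Linear chain system
#'
#' Tridiagonal Frenkel Hamiltonian for a homogeneous chain with
#' nearest-neighbor coupling `V` and uniform site energy.
#'
#' @param n_sites number of sites (>= 1)
#' @param V nearest-neighbor electronic coupling (cm^-1)
#' @param energy uniform site energy (cm^-1, default 0)
#' @param spacing molecular spacing l_0 (default 1)
#' @return a [hops_system()]
#' @examples
#' build_chain(5, V = 50)
#' @export
build_chain <- function(n_sites, V, energy = 0, spacing = 1) {
  stopifnot(n_sites >= 1L)
  H <- diag(energy, n_sites)
  if (n_sites > 1) {
    idx <- seq_len(n_sites - 1)
    H[cbind(idx, idx + 1)] <- V
    H[cbind(idx + 1, idx)] <- V
  }
  hops_system(H, spacing)
}
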