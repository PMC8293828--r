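# Shared fixtures: the homogeneous study bath and small chain systems.
# All test inputs are built programmatically; no external data.

study_bath <- function(gamma_mark = 500)
  drude_lorentz_bath(lambda = 50, gamma = 50, temperature = 295,
                     gamma_mark = gamma_mark)

dimer <- function(V = 50) build_chain(2, V)

# modes of a homogeneous chain (slow + Markovian pair per site)
modes_for <- function(n_sites, bath = study_bath())
  adhops:::chain_modes(n_sites, bath)

# a reproducible random HOPS state over a basis (physical slice normalized)
random_state <- function(basis, n_sites, seed = 1) {
  set.seed(seed)
  n_aux <- nrow(basis$K)
  psi <- matrix(complex(real = stats::rnorm(n_aux * n_sites),
                        imaginary = stats::rnorm(n_aux * n_sites)),
                n_aux, n_sites)
  psi[1, ] <- psi[1, ] / sqrt(sum(Mod(psi[1, ])^2))
  n_modes <- basis$n_modes
  hops_state(psi, complex(real = stats::rnorm(n_modes),
                          imaginary = stats::rnorm(n_modes)) * 0.1)
}

# run n trajectories serially and return the list (for bootstrap statistics
# on derived quantities such as coherences)
run_trajectories <- function(config, n, master_seed)
  lapply(master_seed + seq_len(n) - 1, function(s)
    integrate_trajectory(config, s))
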