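---
title: "Adaptive hierarchy of pure states: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive hierarchy of pure states: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhops)
```

## The physical model

`adhops` simulates the motion of a Frenkel exciton — a molecular electronic
excitation hopping between coupled pigments — in contact with the thermal
vibrations of each molecule. The electronic system is a Hermitian matrix
$H$ of site energies and couplings $V$ (all energies in cm$^{-1}$, times in
fs, connected by $\hbar = 5308.837$ cm$^{-1}$fs). Every site $n$ carries an
independent overdamped environment described by a Drude–Lorentz spectral
density

$$J_n(\omega) = \frac{2\lambda_n\gamma_n\omega}{\omega^2+\gamma_n^2},$$

with reorganization energy $\lambda_n$ and relaxation rate $\gamma_n$, and
couples to the system through the site projector $L_n=|n\rangle\langle n|$.
At high temperature ($\gamma_n < k_BT$) the bath correlation function is a
single decaying exponential $\alpha_n(t)=g_n e^{-\gamma_n t/\hbar}$ with
$g_n = 2\lambda_n k_B T - i\lambda_n\gamma_n$. The package defaults follow
the intermediate-coupling regime typical of photosynthetic pigment–protein
complexes: $\lambda=\gamma=50$ cm$^{-1}$, $T=295$ K, $V$ of a few tens of
cm$^{-1}$, where neither Förster nor Redfield perturbation theory applies.

### Short-time correction

The symmetry $\alpha(-t)=\alpha(t)^*$ makes the imaginary part of the bare
exponential discontinuous at $t=0$, which would put unbounded high-frequency
content into the driving noise. `decompose_correlation()` therefore returns
a *pair* of modes: the slow mode above plus a fast "Markovian" mode
$-i\,\mathrm{Im}(g_n)e^{-\gamma_{\rm mark}t/\hbar}$ that cancels the
imaginary part at $t=0$ and relaxes to the bare correlation on the scale
$\hbar/\gamma_{\rm mark}$. The default $\gamma_{\rm mark}=500$ cm$^{-1}$
(about 10 fs) is fast compared to all dynamical scales of the default
parameter set; for very strong coupling ($V\simeq250$ cm$^{-1}$) a larger
value is appropriate. Quantitatively the correction is a *relative*
perturbation of the total correlation that decays at rate
$(\gamma_{\rm mark}-\gamma)/\hbar$ against the decaying bare term, so
agreement with the bare correlation function at the $10^{-6}$ level is
reached around $t\approx150$ fs for the default parameters, not after a few
multiples of $\hbar/\gamma_{\rm mark}$.

Markovian modes participate in the noise, the memory drift, and first-order
hierarchy flux, but are excluded from deeper hierarchy levels: they enter
the auxiliary basis only as first-order singletons. With this bookkeeping
the five-site reference basis at $k_{\max}=10$ holds
$\binom{15}{5}+5=3008$ members.

## The stochastic hierarchy

The reduced density matrix is unraveled into stochastic pure states driven
by complex Gaussian noises $z_{n,t}$ with $\mathbb E[z_{n,t}z^*_{n,s}] =
\alpha_n(t-s)$ and $\mathbb E[z_{n,t}z_{n,s}]=0$. The functional derivative
of the underlying non-Markovian quantum state diffusion equation is unrolled
into auxiliary wave functions $\psi^{(\vec k)}$ indexed by non-negative
integer vectors over the bath modes. All three equation variants share the
structure

$$\partial_t\psi^{(\vec k)} =
\Big(-\tfrac{i}{\hbar}H - \tfrac{\vec k\cdot\vec\gamma}{\hbar}
 + \sum_n L_n \tfrac{\tilde z^*_{n,t}}{\hbar}\Big)\psi^{(\vec k)}
 + \sum_n k_n c_n L_n \psi^{(\vec k - e_n)}
 - \sum_n u_n (L_n - \langle L_n\rangle_t)\,\psi^{(\vec k + e_n)},$$

with variant-specific coefficients:

* **linear**: $c_n = g_n/\hbar$, $u_n = 1/\hbar$, raw noise, no expectation
  shift. Exact on average but with heavy-tailed trajectory norms, hence slow
  ensemble convergence.
* **nonlinear**: the noise acquires the memory drift
  $\dot\xi_n = (-\gamma_n^*\xi_n + g_n^*\langle L_n\rangle_t)/\hbar$ and the
  up-flux operator is shifted by $\langle L_n\rangle_t$ (expectations in the
  normalized physical slice).
* **normalized**: the non-linear equation after rescaling each auxiliary by
  $\prod_n(\gamma_n/g_n)^{k_n}$ and subtracting a scalar $\Gamma_t$ fixed
  operationally by requiring the physical-norm derivative to vanish. The
  prefactor makes down-flux $k_n\gamma_n/\hbar$ and up-flux
  $g_n/(\gamma_n\hbar)$, so auxiliary magnitudes stay $O(1)$ at every depth
  — the property the adaptive error bounds rely on. The multimode prefactor
  is the per-mode product of the single-mode rule; its correctness is
  checked numerically by the change-of-variables test (a normalized
  trajectory must equal the post-normalized non-linear trajectory on shared
  noise, and does to $\sim10^{-6}$).

The hierarchy is truncated triangularly at depth $k_{\max}$ (the full basis
has $\binom{n_{\rm modes}+k_{\max}}{k_{\max}}$ members — more than
$10^{23}$ for a thousand-pigment chain at $k_{\max}=10$, which is the
scaling problem the adaptive basis removes). An optional static terminator
closes the boundary with
$\psi^{(\vec k+e_n)} \approx \frac{(k_n+1)g_n}{\vec k\cdot\vec\gamma+\gamma_n}
L_n\psi^{(\vec k)}$; with $k_{\max}=0$ and a single environment per site this
reduces the propagator to Markovian quantum state diffusion.

## Noise generation

The paper-level theory only prescribes the two-time statistics, so the
generator is defined by its invariants rather than by a particular
algorithm. We use circulant spectral filtering: the Hermitian extension of
$\alpha$ is wrapped onto a periodic grid at the integrator step (doubled
horizon plus eight bare-mode lifetimes of padding), its DFT gives the
embedded spectrum $S_k \ge 0$, and $z = \mathrm{IFFT}(\sqrt{S}\,w)$ with
white complex Gaussian $w$ reproduces the wrapped correlation exactly and a
vanishing pseudo-correlation by construction. Negative embedded eigenvalues
beyond a small tolerance abort generation with the offending site named:
they mean the requested correlation admits *no* complex Gaussian process.
This is not hypothetical — the bare high-temperature Drude–Lorentz
correlation itself is not positive semidefinite (its spectrum turns negative
above $2k_BT$), which is precisely why the Markovian correction mode is
generated jointly with the slow mode. Per-site streams derive from a fixed
affine map of (master seed, site index), so enlarging a chain never perturbs
the noise on existing sites — the property that makes shared-noise
HOPS/adHOPS comparisons exact. Noise at Runge–Kutta half-steps is linearly
interpolated.

## Adaptive basis construction

At every step, before integrating, the package rebuilds a reduced auxiliary
basis and a reduced site basis such that the Euclidean norm of the
time-derivative error committed by the truncation stays below $\delta$
(split in quadrature, by default equally, between the two bases; the split
is a configuration knob). The flux-bound equations are the package's own
construction, specified operationally by two testable contracts: per
candidate, the score must upper-bound (and in the all-sources-retained case
equal) the squared derivative flux the candidate would receive; globally,
the derivative computed on the adaptive basis must stay within $\delta$ of
the full-basis derivative evaluated on the embedded state (the normalization
correction $\Gamma_t$ is excluded from this bound, as its effect is higher
order). Both contracts are verified by brute force on small systems in the
test suite.

Selection is greedy: candidates (current members plus their one-step
neighborhood; flux can only enter through occupied sites because the
coupling operators are site projectors) are sorted by ascending squared
flux, and the largest prefix whose cumulative sum fits the budget is
excluded. Occupied members additionally carry a retention guard proportional
to their amplitude times a bound on their total derivative rate, so
amplitude is only discarded within budget. Ties keep graded-lexicographic
order, making runs platform-reproducible. The physical wave function and
all sites holding physical amplitude above numerical zero ($|\psi_{0,s}|^2 >
10^{-12}$) are always retained; after a rebase the physical slice is
renormalized. With $\delta=0$ the full triangular basis is returned and
adHOPS reverts to HOPS exactly (trajectory-wise to machine precision).

Because the bound constrains the *derivative*, state-level errors accumulate
at most linearly in time: population deviations of order $\delta\,t$ are
expected and observed (e.g. $5\times10^{-4}$ over 300 fs at
$\delta=10^{-6}$). $\delta$ is therefore a convergence parameter on the same
footing as $k_{\max}$, and the shared-noise mean absolute population error
of the five-site reference system falls below $10^{-2}$ at
$\delta=10^{-3}$ with a median time-averaged auxiliary basis of order
$10^2$ — about 2% of the 3008-member full basis — while chains of 5–30
sites show basis sizes that plateau once the chain exceeds the exciton's
dynamic footprint.

## Numerical choices

* **Integrator**: fixed-step classical RK4, default `dt = 2` fs, gated by
  shared-noise self-convergence tests (population changes $\sim2\times
  10^{-2}$ per halving at 2 fs; the piecewise-linear noise limits pathwise
  order, but paired comparisons share the integrator error and ensemble
  observables are well converged). Norm-critical demonstrations use
  `dt = 0.5` fs, where the physical norm stays within $10^{-6}$ of unity
  over a picosecond.
* **Divergence guard**: linear-variant trajectory norms can genuinely
  diverge in rare realizations; any NaN/Inf aborts with the time, variant
  and seed named rather than silently dropping the trajectory.
* **Degenerate inputs**: a localized initial condition starts with an empty
  hierarchy (auxiliaries have no source until amplitude appears); a
  zero-norm physical slice makes the non-linear expectation undefined and is
  an error; `gamma_mark <= gamma` is rejected; `gamma/(k_B T) >= 1` warns
  that the high-temperature decomposition is unreliable.
* **Density matrices**: normalized/non-linear ensembles average normalized
  projectors (trace exactly one); the linear ensemble averages raw
  projectors and renormalizes by the ensemble-average norm. Statistical
  errors are seeded bootstrap (200 resamples) over trajectories.
* **Observables**: MSD uses the one-dimensional convention
  $\mathrm{MSD}=2Dt$ (configurable factor), fit over the second half of the
  time window by default, with a relative-residual diagnostic that flags
  windows still in the ballistic transient.

## Problem sizes used in the checks

The full study-scale ensembles ($10^4$ trajectories, $10^3$-pigment chains)
are deliberately out of desk scale. The automated checks run: 150
shared-noise pairs (test suite) or 80 pairs (acceptance script) of the
five-site chain at $k_{\max}=10$ over 400 fs; six trajectories per chain
length for the 5–30-site plateau at $k_{\max}=4$ (the long-chain comparison
fixes the start site and reuses seeds, so — per-site noise streams being
stable under chain growth — any basis-size difference between chain lengths
would be a genuine loss of size invariance rather than sampling noise); $10^3$ dimer trajectories
against the dense hierarchy oracle; and a six-trajectory, 21-site
diffusion demonstration at $V=50$ cm$^{-1}$. Because the adaptive-error
metric is paired by shared noise, it is systematic rather than statistical
and small ensembles measure it faithfully.

## Independent cross-checks

Three oracles, none sharing propagation code with the stochastic hierarchy,
anchor correctness: a dense hierarchically-coupled density-matrix integrator
(same bath decomposition and truncation, scaled auxiliary density operators,
`deSolve::zvode`); the closed-form independent-boson dephasing factor
$\exp(-\hbar^{-2}\int_0^t\!\!\int_0^s\alpha)$, itself verified against
direct double quadrature; and a Lindblad pure-dephasing integrator for the
Markovian limit. One subtlety: with the Markovian mode truncated at first
order, both the stochastic hierarchy and the density-matrix oracle share a
small systematic deviation ($\sim7\times10^{-3}$ for the default bath) from
the *exact* independent-boson decay — a property of the truncated model, not
of either implementation. The closed-form comparison therefore treats both
decomposition modes at full hierarchy order.

## What the synthetic systems do and do not probe

All test systems are homogeneous linear chains with identical Drude–Lorentz
environments, the setting of the original study. Passing tests demonstrate
correct bath statistics, formally exact propagation at converged
$(k_{\max},\delta,dt)$, locality-driven basis compression and
size-invariance on such chains. They do not probe static energetic disorder,
structured (underdamped or vibronic) spectral densities, low-temperature
baths where the single-exponential decomposition fails, non-projector
system-bath coupling, or long-range couplings — all outside the current
model family, and the first three are natural extension points.

## Known limitations

* The high-temperature decomposition restricts validity to
  $\gamma < k_BT$ (about 200 cm$^{-1}$ at room temperature); no Matsubara
  correction terms are implemented.
* The terminator is implemented for real-rate (overdamped) modes only and
  is applied only at the true triangular boundary, never as a stand-in for
  adaptively absent members.
* The adaptive machinery presumes the normalized equation (bounded
  auxiliary norms); adaptivity on the raw linear equation is intentionally
  unsupported.
* Single-trajectory pathwise accuracy is second order in `dt` because the
  stored noise is linearly interpolated; ensemble observables and paired
  comparisons are insensitive to this at the default step.
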