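---
title: "Sample-based quantum diagonalization for supramolecular binding energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-based quantum diagonalization for supramolecular binding energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqdbinder)
```

## The problem

Noncovalent interactions — hydrogen bonds, dispersion — are weak: a water
dimer binds by about 5 kcal/mol, a methane dimer by half a kcal/mol.
Resolving them requires solving the electronic Schrödinger equation to a
small fraction of a kcal/mol within a consistent model.  The supramolecular
approach computes a binding energy as a difference of two dimer energies,

$$E_\mathrm{binding} = E_{AB}^\mathrm{bound} - E_{AB}^\mathrm{unbound},$$

where the "unbound" reference is the same dimer with the monomers displaced
far apart (48.000 Å here, far beyond any interaction length).  Using the
dimer twice, rather than subtracting monomer energies, keeps the active
space — the subset of electrons and orbitals treated exactly — identical in
both calculations, which is what makes active-space energy differences
meaningful.

Within an active space of $M$ spatial orbitals the Hamiltonian is

$$\hat H = E_0 + \sum_{pr\sigma} h_{pr}\, a^\dagger_{p\sigma} a_{r\sigma}
 + \frac12 \sum_{prqs\sigma\tau} (pr|qs)\,
 a^\dagger_{p\sigma} a^\dagger_{q\tau} a_{s\tau} a_{r\sigma},$$

with $E_0$ collecting nuclear repulsion and inactive-orbital contributions
and $(pr|qs)$ the chemist-notation two-electron integrals.  The package
reads and writes this object in the standard FCIDUMP text format
(`read_fcidump()`, `write_fcidump()`); producing the integrals from a
geometry is an integration boundary (`prepare_active_space()`) delegated to
an external electronic-structure engine.

## Sample-based quantum diagonalization

Exact diagonalization over all
$d = \binom{M}{N_\alpha}\binom{M}{N_\beta}$ determinants (CASCI) grows
combinatorially — already $245{,}025$ determinants for a (16e,12o) space.
SQD replaces the full space with a subspace *spanned by configurations
sampled from an approximate ground state*:

1. prepare an ansatz state $|\Psi\rangle$ approximating the ground state;
2. measure it in the computational basis, collecting a multiset
   $\tilde\chi$ of occupation bitstrings $x \in \{0,1\}^{2M}$ with
   probabilities $|\langle x|\Psi\rangle|^2$ (on ideal hardware);
3. restore broken symmetries in the samples (below), draw $K$ batches
   $\tilde\chi_b$, and build from each a determinant subspace $S(b)$;
4. diagonalize the projected Hamiltonian
   $\hat H_{S(b)} = \hat P_{S(b)} \hat H \hat P_{S(b)}$ for its lowest
   eigenpair $(E(b), |\psi(b)\rangle)$ with a Davidson iteration;
5. report $\min_b E(b)$, and iterate.

Because the result is a Rayleigh quotient in a subspace, every reported
energy is variational: it can only approach the CASCI energy from above,
and it equals it once the sampled subspace spans the ground state's
support.

`sqd()` is the package's central fitting function; it returns a classed
object with `print()`, `summary()`, `coef()` and `plot()` methods, the last
showing the per-iteration minimum batch energy.

### Batch subspaces are Cartesian products

A batch contributes not just its sampled determinants but the product
$S(b) = A \times B$ of its unique $\alpha$ half-strings with its unique
$\beta$ half-strings (`build_subspace()`).  This closure is why $10^4$
samples can span a $2.5\cdot 10^5$-determinant space: $495$ distinct
strings per spin sector suffice for the full (16e,12o) space, and in
practice the production-scale subspace dimension saturates at the full CAS
dimension.  The per-spin string structure is also what the solver exploits
to keep coefficient vectors organized ($\alpha$-major matrix layout).

## The truncated LUCJ ansatz

The ansatz is a truncated local unitary cluster Jastrow form applied to the
restricted Hartree-Fock determinant,

$$|\Psi\rangle = e^{-\hat K_2}\, e^{\hat K_1}\, e^{i\hat J_1}\,
e^{-\hat K_1}\, |x_\mathrm{RHF}\rangle,$$

where $\hat K_\mu$ are one-body orbital-rotation generators and $\hat J_1$
is a density-density ("Jastrow") operator, diagonal in the computational
basis, so $e^{i\hat J_1}$ is a phase per determinant.  On quantum hardware
the Jastrow layer requires qubit adjacency; the locality mask
(`lucj_mask(M, "line_heavyhex")`) zeroes couplings between spin-orbitals
not adjacent on a heavy-hex layout (same-spin neighbours $|p-r|\le 1$,
opposite-spin only $p = r$).  The `"dense"` mask keeps all couplings.

Parameters come from closed-shell CCSD doubles amplitudes
(`lucj_from_ccsd()`).  Writing the doubles operator with the spin-summed
singlet excitations $\hat E_\mu = \sum_{ia} X^\mu_{ia} \hat E_{ai}$ built
from the eigenpairs $(\lambda_\mu, X^\mu)$ of the $(ia)\times(jb)$
amplitude matrix, the anti-Hermitian doubles generator factorizes exactly
as

$$\hat T_2 - \hat T_2^\dagger = \sum_\mu \left[\,
 i\tfrac{\lambda_\mu}{2}\hat Q_{\mu+}^2
 - i\tfrac{\lambda_\mu}{2}\hat Q_{\mu-}^2 \right],
\qquad \hat Q_{\mu\pm} = \hat A_\mu \pm \hat B_\mu,$$

with $\hat A = (\hat E + \hat E^\dagger)/2$ and
$\hat B = (\hat E - \hat E^\dagger)/2i$ Hermitian one-body operators.  Each
$e^{i\theta \hat Q^2}$ is a rotated Jastrow factor: diagonalizing
$Q = U D U^\dagger$ gives $e^{\hat K} e^{i\hat J} e^{-\hat K}$ with
$\hat K = \log U$ and $J_{p\sigma,r\tau} = \theta\, d_p d_r$.  The
truncation keeps the dominant eigenpair's first factor in full
($K_1, J_1$) and only the orbital rotation of its conjugate factor
($K_2$) — the printed four-factor form.  This identity is verified in the
test suite against dense operator matrices built by an independent
brute-force oracle.

Two consequences of this construction are worth stating plainly:

* **The rotation generators are complex anti-Hermitian.**  $\hat B$ has
  imaginary matrix elements, so $Q_\pm$ are complex Hermitian and
  $K = \log U$ is complex.  A purely real rotation cannot reproduce real
  doubles amplitudes at first order (a real Jastrow phase produces purely
  imaginary doubles), so the package stores complex generators and keeps
  complex amplitudes end to end; sampling uses $|c_x|^2$.
* **The truncated state has limited support.**  The retained rotations
  pair each occupied direction with a single virtual direction, so the
  four-factor state reaches only $2^{n_\mathrm{occ}}$ occupation strings
  per spin sector.  An ideal-device run sampling this state cannot span a
  generic ground state; coverage is restored by the combination of device
  noise and configuration recovery, which scatters and then repairs
  configurations.  This is a property of the literal 1.5-layer truncation,
  not an implementation artifact, and it is why the package's exactness
  checks on ideal sampling use a reference state with full support, while
  noisy-pipeline checks use the LUCJ ansatz.

Singles amplitudes are not used in the initialization.  `apply_lucj()`
evaluates the state exactly as a CI vector: orbital rotations act per spin
sector through series exponentials of the one-body generator in the
string basis (particle number is conserved structurally), and the Jastrow
phase is $\theta(x) = x^\top J x$ with the diagonal counted once
($\hat n^2 = \hat n$).  No further variational optimization of the
parameters is performed.

## The synthetic device and configuration recovery

Real hardware returns samples from a distribution
$\tilde p(x) \ne |\langle x|\Psi\rangle|^2$; its defining signature for
this workflow is **broken particle number**.  The package emulates exactly
that and nothing else: `corrupt()` flips every bit of every shot
independently with probability $\varepsilon$ (`noise_model(epsilon)`,
default 0.01).  Correlated errors, readout matrices and error-mitigation
schemes of real devices are deliberately out of scope; $\varepsilon$ is a
package choice, not a measured device property.

Self-consistent configuration recovery (`recovery_loop()`) then:

1. initializes occupation estimates $n_{p\sigma}$ from the samples that
   already have correct particle number (`init_occupations()`);
2. repairs every shot sector by sector: electrons are added on empty
   orbitals with probability $\propto n_{p\sigma}$ or removed from
   occupied ones with probability $\propto 1 - n_{p\sigma}$, one at a time
   without replacement, until the counts are exact
   (`recover_configuration()`); a correct sector is never touched, and a
   zero-weight candidate set falls back to a uniform choice;
3. draws $K$ batches of `batch_size` shots with replacement from the
   recovered pool (`make_batches()`), diagonalizes each batch subspace,
   and takes $\min_b E(b)$;
4. updates $n_{p\sigma}$ as the uniform average of
   $\langle\psi(b)|\hat n_{p\sigma}|\psi(b)\rangle$ over the $K$ batch
   ground states, and repeats until the fixed step count or until
   $|\Delta \min_b E(b)| <$ `energy_tol`.

The exact redistribution law used by hardware-facing implementations is
not printed in the sources this package follows; the
proportional-to-occupancy scheme above preserves the stated intent and is
exactly testable (completion frequencies match the weights in a
multinomial check).  Batches are drawn with replacement rather than by
partitioning, matching "K subsets" without assuming disjointness; the
occupation average over batches is uniform, not energy-weighted.  Raw
shots are re-recovered from scratch at every iteration with the current
estimate.

## Variance and zero-variance extrapolation

For each batch state the Hamiltonian variance
$\Delta H = \langle\psi|\hat H^2|\psi\rangle - \langle\psi|\hat H|\psi\rangle^2$
is computed with the *unprojected* Hamiltonian action (`variance()`): the
package enumerates the full particle-number sector (entries beyond double
excitations of the subspace vanish identically), so $\Delta H$ is exact,
zero at a CASCI eigenstate and positive otherwise.  Near convergence the
subspace energy is linear in the variance, so regressing $E$ on
$x = \Delta H / E^2$ over a ladder of increasing batch sizes and reading
the intercept estimates the zero-variance (exact) energy at reduced cost.
`extrapolate_energy()` fits ordinary least squares — the sources state no
weighting — and reports the intercept's standard error as the error
estimate; production ladders use three or four points (e.g. batch sizes
$9{\cdot}10^3, 11{\cdot}10^3, 14{\cdot}10^3$, chosen to spread the
variance values evenly).  Both the bound and the unbound energies are
extrapolated with identical batch-size ladders when the protocol is used
for binding energies.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `shots` | measurement samples | $200{\cdot}10^3$ (water), $300{\cdot}10^3$ (large methane space) | production run settings shipped in `inst/extdata/` |
| `epsilon` | per-bit flip probability | 0.01 | a plausible effective rate; the only noise knob |
| `K` | batches per iteration | 10 (4 for the largest space) | production settings |
| `batch_size` | shots per batch | $10{\cdot}10^3$ / $20{\cdot}10^3$ / $8.5{\cdot}10^3$ | production settings per system |
| `iterations` | recovery steps | 10 (5 for the largest space) | production settings; `energy_tol = 10^{-6}$ Ha adds an early stop |
| Davidson `tol` | residual 2-norm | $10^{-8}$ Ha | standard robust threshold; the sources name only "Davidson" |
| `max_subspace` | Davidson restart size | 25 vectors | standard restart setting |

## Numerical choices

* **Phase convention.**  Spin-orbitals are ordered $\alpha$ block
  (ascending orbital) then $\beta$ block; determinants are built by
  applying creation operators in descending position order.  All
  Slater-Condon signs follow, and the whole convention is pinned by an
  entrywise comparison against a brute-force second-quantization oracle.
* **Davidson.**  Diagonal preconditioning with a $10^{-8}$ floor on the
  denominator, restart at 25 trial vectors from the current Ritz vector,
  start vector on the lowest-diagonal determinant; subspaces of dimension
  $\le 32$ go straight to dense diagonalization.  Non-convergence raises a
  diagnostic error carrying the best residual.  The ground-state sign is
  fixed by making the largest-magnitude coefficient positive.
* **Exponentials.**  Orbital rotations use scaling-and-squaring series
  exponentials of the string-basis one-body matrices, truncated at a
  $10^{-16}$ term norm.
* **Degenerate inputs.**  Recovery candidate sets with all-zero weights
  fall back to uniform selection; variances within $-10^{-10}$ of zero are
  clipped to zero and more negative values raise an error; extrapolation
  with coincident abscissae raises a degenerate-design error (stderr is
  exactly zero only for collinear points).
* **Capacity guards.**  Dense Hamiltonian blocks and full-sector
  enumerations are bounded by configurable budgets
  (`options(sqdbinder.max_dense, sqdbinder.max_cas)`); exceeding them
  raises a capacity error naming the offending dimension rather than
  exhausting memory.

## What the synthetic generators emulate

`random_hamiltonian()` draws symmetric $h$ and 8-fold-symmetric Gaussian
`eri` — valid, reproducible instances that exercise every solver contract
but have no electronic structure.  `toy_dimer_hamiltonian(distance)` is a
(4e,4o) two-monomer model with net-neutral monomers: inter-monomer
electron-electron repulsion, electron-core attraction and core-core
repulsion cancel at the monopole level, exponentially decaying
inter-monomer hopping provides attraction, and a steep short-range wall
provides repulsion.  Its binding curve has the qualitative anatomy of a
dimer dissociation scan (repulsive wall, minimum of about $-0.7$ kcal/mol
near 2.5 length units, flat tail at 48), which lets the full
bound/unbound pipeline run against a cheap full-CI reference.
`mp2_like_t2()` supplies first-order doubles amplitudes from the
Hamiltonian's own mean field (`canonical_orbitals()` provides the
canonicalization), standing in for an external coupled-cluster engine.

What these generators do *not* emulate: real basis sets and AVAS orbital
selection, dynamical correlation outside the active space, correlated
device noise, and the $10^7$–$10^8$-determinant subspace sizes of
production runs.  Passing tests therefore demonstrate the correctness of
the algorithmic machinery and its statistical behaviour at desk scale, not
chemical accuracy for real dimers; reproducing published water/methane
numbers additionally requires the deposited equilibrium geometries, an
aug-cc-pVQZ integral engine and CCSD amplitudes, plus production-scale
computing.

Test and demonstration problem sizes are chosen to keep full
configuration-interaction references cheap: $M = 4$–$6$ orbitals
($d \le 400$ determinants), $10^4$–$2\cdot 10^4$ shots, ladders of six
nested subspaces for extrapolation checks.  At these sizes the recovery
loop saturates the full determinant space within a few iterations —
mirroring, at toy scale, the saturation seen in production (16e,12o)
runs.

## Known limitations

* The PES generator translates monomers rigidly along the anchor axis;
  whether production scans relaxed monomer geometries is not documented in
  the sources this package follows, so rigid translation is the stated
  assumption.
* Only particle number is recovered; spin symmetry ($\hat S^2$) is not
  purified.
* The Davidson solver operates on dense subspace matrices, which caps
  practical subspace dimensions at a few thousand determinants; the
  production-scale string-driven sparse path is out of scope.
* t1 amplitudes are ignored in the ansatz initialization; a final orbital
  rotation absorbing them could be added without changing the interfaces.
* Excited states, CSF bases and perturbative corrections are out of scope.
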