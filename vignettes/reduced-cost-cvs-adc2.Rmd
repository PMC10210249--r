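---
title: "Reduced-cost CVS-ADC(2) for K-edge excitations: models, choices, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-cost CVS-ADC(2): methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The physical problem and the model

K-edge absorption promotes a 1s electron of a light element into virtual
or Rydberg levels.  `rcadc` computes such states for closed-shell molecules
with strict CVS-ADC(2): the second-order algebraic-diagrammatic
construction restricted by the core–valence separation, in which every
singles configuration carries an active-core hole `I` and every doubles
configuration exactly one active-core hole.  The CVS restriction is
realised purely as an excitation-space restriction — no additional
integrals are zeroed — and the test-suite's explicit-matrix oracle applies
the identical restriction, so the two routes are comparable to machine
precision.

Because the strict-ADC(2) doubles–doubles block is diagonal at zeroth
order, the doubles can be folded into the singles problem, giving a
nonlinear ("effective Jacobian") eigenvalue equation whose operator depends
on the excitation energy.  The solver never materialises the doubles
tensor: for each trial vector the doubles coefficients are formed on the
fly from density-fitted three-center integrals and contracted immediately.

### Spin adaptation by singlet embedding

Internally all correlated tensors are spin-orbital objects.  A spatial
singlet singles vector enters as `r/sqrt(2)` on both spin components; every
contraction commutes with total spin, so the sigma vector stays in the
singlet space and is mapped back exactly.  This gives rigorously
spin-adapted singlet equations without hand-derived singlet doubles
couplings — the component most prone to transcription errors — at the cost
of a factor ~2 in tensor dimensions, which is irrelevant at the problem
sizes this package targets (double-zeta bases, up to ~30 correlated
orbitals).

### Verification strategy

Three independent oracles guard the working equations:

1. **Perturbation-order consistency.**  For a Hamiltonian `h + s·W` with a
   self-consistent reference, ADC(2) excitation energies of singly-excited
   states must agree with full CI through second order in the fluctuation
   potential; the deviation must decay as `s^3`.  A determinant-space FCI
   (`fci_oracle()`) verifies exactly this (observed decay ratios ≈ 8 when
   `s` doubles).  This test fixes every sign and factor of the
   second-order singles block and of the singles–doubles coupling; with the
   amplitude convention `t = ⟨ij||ab⟩/(ε_i+ε_j−ε_a−ε_b)` the static
   second-order blocks enter with a minus sign and the amplitude-dressed
   non-diagonal term with a plus.
2. **Folding equivalence.**  The explicit singles+doubles secular matrix
   (`dense_adc2_matrix()`), built from the same integrals by an independent
   code path, must have the folded solver's energies among its eigenvalues
   to 1e-8 Hartree.
3. **Exact limits.**  Closed-form two-level (one occupied, one virtual)
   MP2 and singlet CIS expressions are reproduced to machine precision on a
   loss-free factorisation of the dense integrals, and the transition
   density is compared term by term against an exact fermionic-algebra
   evaluation of `<0|a+_p a_q|n>` on the correlated model states (the
   occupied–occupied block requires orthogonalising the excited state
   against the ground state; the residual is cubic in the amplitudes).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `eps_naf` | 0.1 au | NAF truncation on singular values of `J` |
| `eps_vno` | 7.5e-5 | VNO truncation on density eigenvalue magnitude |
| metric cutoff | 1e-10 | two-center Coulomb eigenvalue floor |
| `e_tol`, `r_tol` | 1e-6 Ha, 1e-5 | solver convergence (energy, residual) |
| SCF convergence | 1e-9 | orbital-gradient norm |

The defaults of the two truncation thresholds are the conservative
production values of the reduced-cost scheme; they are meant to keep the
compression error an order of magnitude below the method's intrinsic error
(~2–3 eV for K-edges).

**NAF threshold convention.**  The eigenvalues of `W = JᵀJ` are the squares
of the singular values of the unfolded three-center tensor; `eps_naf`
thresholds the *singular values* (au), which is what makes the discarded
Frobenius weight of `J` equal the square root of the dropped eigenvalue
sum — an identity the suite asserts.  Both NAF truncations (global, and
per-state in the reduced virtual space) use the same threshold.

**VNO construction.**  The per-state density is the equal-weight average of
the unrelaxed MP2 virtual–virtual density and the unrelaxed CVS-CIS(D)
density (CIS outer product plus the quadratic doubles term evaluated at the
CVS-CIS energy; second-order singles dressings of the density are omitted —
their effect is bounded by the zero-threshold limit test and the benchmark
statistics).  Ranking is by eigenvalue magnitude because the CIS(D) part
can be slightly indefinite.  After truncation the retained span is
semicanonicalised (the virtual–virtual Fock is re-diagonalised) so that all
orbital-energy denominators remain valid; this is what makes the
`eps → 0` limit recover canonical energies to numerical precision, which
the suite asserts on every fixture.  The occupied space is never truncated.

**Frozen cores.**  1s orbitals of second-row atoms other than the probed
element are frozen by default — in the MP2 amplitudes and in the doubles
space alike (configurable via `frozen_policy`).

**Solver.**  Modified Davidson: the effective Jacobian is re-evaluated at
the current energy every cycle (the ω-independent part is cached per
subspace vector, so only the doubles fold is recomputed), the energy is
updated from the selected Ritz value, roots are homed by maximal overlap
with the CVS-CIS guess (a warning is emitted below overlap 0.5 — such
states are exactly the ones for which CIS-based natural orbitals can be
poor), the preconditioner is the orbital-energy difference `ε_a − ε_I − ω`,
and on subspace overflow the restart vector is DIIS-extrapolated from the
residual history (depth 6).  States are solved one at a time, each in its
own reduced subspace in reduced mode.

## The integral and reference backend

AO integrals (overlap, kinetic, nuclear attraction, dipole, two-, three-
and four-center Coulomb) are evaluated with the McMurchie–Davidson scheme
for contracted Cartesian shells up to `l = 3`; the restricted Hartree–Fock
reference uses exact four-center integrals with DIIS.  Built-in basis sets
are STO-3G (minimal-basis oracles) and 6-31G (production double-zeta);
the backend is validated against closed-form primitive integrals and
published total energies (e.g. H2/STO-3G at 1.4 bohr, −1.116714 Hartree).
The auxiliary basis (`"autoaux"`) is generated per atom from the orbital
basis: candidate exponents are sums of primitive-exponent pairs, thinned to
an even-tempered progression (ratio 2.2), with angular momenta up to twice
the atomic maximum (at least `l_max + 1`).  Fitting quality at fixture
scale: reconstructed ERIs to ~3e-4 Hartree, CVS-CIS energies to < 2 meV —
well below the compression errors being studied.  The SCF deliberately
avoids density fitting so that the fitting basis is a property of the
correlation treatment only.

## The fixture suite and what the tests do (and do not) show

Fixtures are seven gas-phase molecules at experimental geometries (H2O,
NH3, CO, HF, CH4, C2H4, H2CO).  The benchmark harness
(`kedge_benchmark()`) runs the three lowest K-edge states of every
second-row element present — C, N, O edges, plus the F edge of hydrogen
fluoride so that molecule contributes states — in canonical and reduced
mode at 6-31G, and reports the canonical-vs-reduced mean absolute energy
deviation and mean relative oscillator-strength deviation (f > 0.015).
Problem sizes (24 states, ≤ 26 AOs) were chosen so the full suite runs in
well under a minute on one CPU.

Two honest limitations of desk scale:

* At a compact double-zeta basis **every** virtual natural orbital is
  important — observed retention is 100% at the default `eps_vno` (the
  density's eigenvalue floor on these systems is ~1e-4).  The VNO
  machinery is therefore exercised by the zero-threshold limit, by the
  coarse grid point `eps_vno = 7.5e-4` (where truncation does bite and the
  error responds monotonically), and by the bookkeeping tests — but the
  production-scale regime in which ~half the virtuals drop only develops
  in triple-zeta-plus-diffuse spaces that are out of scope here.  The
  reduced-vs-canonical deviations measured by the suite are consequently
  dominated by the NAF compression.
* Absolute excitation energies carry the well-known CVS-ADC(2)
  overestimation plus a small-basis blue shift (O K-edge of water: 538.3 eV
  at 6-31G vs 534 eV experimentally); no relativistic correction is
  applied.  All shipped statistics are reduced-vs-canonical differences, in
  which these systematic shifts cancel.

**Degenerate pairs.**  Exactly degenerate K-edge pairs arise from angular
momentum (e.g. the 1s→π* pair of CO), and the suite asserts their
degeneracy to < 1e-5 eV.  The two states of ethene's equivalent carbons are
*not* exactly degenerate: the 1σ_g/1σ_u core combinations split by core
hopping (~0.1 eV experimentally; 0.01–0.02 eV at these bases), so the suite
asserts that pair at its physical scale.  The error statistics offer an
optional degenerate-partner exclusion (1e-3 eV window), mirroring common
benchmarking practice; the shipped headline statistics keep all states.

## Oscillator strengths

Dipole-length gauge, `f = (2/3) ω |μ|²`, from the transition density
through the orders consistent with strict ADC(2): CIS term, MP2-amplitude
dressing of the virtual–occupied block, and the occupied–occupied /
virtual–virtual terms bilinear in ground-state amplitudes and the state's
doubles coefficients.  Second-order contributions that would require
second-order ground-state amplitudes are omitted (they belong to ADC(3)
consistency).  Gauge-origin independence for neutral molecules and
rotational invariance of summed degenerate-pair intensities are asserted to
1e-8.  Only ground→excited moments are implemented; state-to-state moments
between two core-excited states are out of scope.

## Degenerate and pathological inputs

Open-shell molecules, basis sets without virtuals, CVS selectors that match
nothing (or a virtual), unnormalised CIS inputs, energies that hit a
doubles-denominator pole, thresholds that empty the virtual space, and
non-convergent SCF/Davidson iterations all fail with explicit errors naming
the stage and, where meaningful, the offending orbital or configuration.
Root collapse (two states converging onto one vector, overlap > 0.95) is
detected and refused rather than silently double-counting a state.
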