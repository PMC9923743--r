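---
title: "Diabatic excited-state dynamics with diabatmd: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diabatic excited-state dynamics with diabatmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`diabatmd` propagates classical nuclei on electronic surfaces defined by
single Slater determinants: the ground state from ordinary
restricted/unrestricted Hartree–Fock, and excited states from ΔSCF — the
same SCF equations converged onto a non-Aufbau stationary point.  This
vignette is the package's own account of the models it implements, the
parameters that matter, and the places where the design was genuinely
open and a choice had to be made.

## Electronic models

Two integral providers share one contract (overlap, core Hamiltonian,
two-electron tensor in chemists' notation, electronic dipole matrices,
nuclear repulsion):

* **s-type Gaussian backend.**  Contracted s-primitives with closed-form
  overlap, kinetic, nuclear-attraction and repulsion integrals via the
  Boys functions F0/F1.  This path exists to exercise the full
  SCF/ΔSCF/embedding machinery against textbook systems (H2, HeH+, H4)
  where an independently coded oracle is feasible; chemical realism is
  not its job.

* **Pariser–Parr–Pople (PPP) π-electron model.**  One basis function per
  π site; identity overlap; hopping `t(r) = t0·exp(−(r−r0)/λ)` (smooth in
  the geometry, hence analytic forces); on-site Hubbard repulsion `U`;
  two-center repulsion from the Ohno interpolation
  `γ(r) = Ū/sqrt(1+(Ūr)²)` with `Ū` the pair average — finite at contact,
  Coulombic at long range.  Electron–core and core–core interactions use
  the same Ohno form with a separate per-atom *core hardness* (default
  0.8 hartree), so that atoms without basis functions (the toy's mobile
  proton) interact smoothly with the π system.  Because the Ohno forms
  are finite at the origin while the hopping grows exponentially at short
  range, the bare model's global minimum would be fused sites; a
  Born–Mayer core wall `√(A_i A_j)·exp(−r/ρ)` (per-atom amplitudes,
  geometric mixing) restores physical minima.  This wall is the package's
  own addition to the standard PPP ingredients and is disabled by
  default (`repulsion_a = 0`) outside the dynamics fixtures.

Full configuration interaction over the Löwdin-orthonormalized orbitals
(`exact_diagonalization`) provides the *adiabatic* reference states
everywhere a test needs one; it is never used inside the propagated
method.

## ΔSCF: iMOM, STEP, and tracking

The excited determinant starts from a one-electron promotion of converged
ground-state orbitals.  Two collapse-avoidance strategies are
implemented:

* **iMOM** selects, at every cycle, the occupied orbitals with maximal
  projection `p_j = ‖C_refᵀ S c_j‖₂` onto a *fixed* reference occupied
  space (the initial guess, or the previous MD step's converged
  orbitals).  The 2-norm metric is invariant to rotations within the
  reference space; ties within 1e-8 resolve to the lower orbital energy
  and are logged.

* **STEP** raises the complement of the reference occupied space,
  `F' = F + η(S − S·C_ref·C_refᵀ·S)`, with the shift chosen automatically
  each cycle as (top reference-orbital energy − lowest eigenvalue) plus a
  margin (default 1 hartree), and fills `F'` by Aufbau.  With the
  projector built from the fixed reference — the literal reading of the
  method's description — a stationary point of the *unshifted* equations
  is only reached when the converged occupied span coincides with the
  reference span.  Where orbital relaxation leaves that span (e.g. the
  toy's strongly relaxed CT state, which is a saddle in orbital space),
  the commutator stalls at a finite value and the result is returned
  flagged as non-converged, never silently.  A variant that rebuilds the
  projector from the current iterate preserves stationary points but
  loses the anchoring and was observed to slide into the ground state;
  it was rejected.  iMOM is therefore the default for excited-state MD
  in this package.

Two further numerical decisions matter in practice.  First, near-saddle
excited states can enter the convergence window and then escape along
the unstable direction under DIIS noise; `scf_solve` therefore remembers
the best (lowest-commutator) iterate and returns it if the final cycles
escaped.  Second, along MD the commutator tolerance is 1e-6 (static
calculations use 1e-8): the resulting force error is at the 1e-6
hartree/bohr level of the force tests, while 1e-8 is unreachable for
marginally stable tracked states at thermally perturbed geometries.

Collapse is detected by projecting the converged occupied orbitals onto
the ground occupied space: all projections above 0.999 flag the result
as collapsed.  Along a trajectory the reference is always the previous
step's converged occupied orbitals, which keeps the state's character —
this is what makes the propagated surface quasidiabatic: in the
acceptance suite the tracked CT dipole varies continuously along a
100-point path across the LE/CT crossing while the FCI adiabatic
ordering swaps.

## Polarizable environment

Environment sites carry permanent charges, dipoles and traceless
Cartesian quadrupoles plus isotropic polarizabilities.  Induced dipoles
solve `(α⁻¹ − T)μ = E` by conjugate gradient with the diagonal (α)
preconditioner to a residual of 1e-10; `T` is Thole-damped with the
exponential smearing form (`u = r/(αᵢαⱼ)^{1/6}`, global factor
`a = 0.39`) and excludes same-group pairs (the fixture's "residue
analogs").  The QM density enters through Löwdin atomic charges; the
environment acts back on the electrons through exact charge-type
integrals in Gaussian mode and site potentials in PPP mode, with
permanent dipole/quadrupole and induced-dipole potentials coupled
through the same Löwdin representation.  This asymmetry (point charges
out, mixed representation in) is a deliberate desk-scale surrogate for
density-level coupling; the total energy is defined by the implemented
expression, and the analytic forces differentiate *it*, which is why the
finite-difference cross-checks close to 1e-6.  Because the induced
dipoles are re-converged (warm-started) inside every Fock build, the
environment response is self-consistent and state-specific: the toy's
CT state always has a strictly more negative polarization energy than
its ground state.

Polarization damping applies only to the mutual site–site interaction;
QM-to-site fields and induced-to-QM potentials are undamped.  There are
no cutoffs: all sums are direct, which is exact for the ≤ 10³-site
systems this package targets.

## Grassmann extrapolation

Idempotent one-particle densities of fixed trace live on a Grassmann
manifold.  `grassmann_log` maps a density to the tangent space at a
reference occupied set `C₀` via `L = (I − C₀C₀ᵀ)C(C₀ᵀC)⁻¹` and
`Γ = U·atan(Σ)·Vᵀ`; `grassmann_exp` inverts it with the cos/sin
geodesic formula, so every extrapolated density is idempotent with exact
integer trace — no purification step exists anywhere in the package.
Extrapolation coefficients minimize
`‖d_now − Σ c_k d_k‖² + λ‖c‖²` over Coulomb-matrix descriptors
(`M_IJ = Z_I Z_J/r_IJ`, diagonal `½Z^2.4`, unsorted because atom order is
stable along one trajectory), with `λ = 1e-10` to keep near-collinear
histories solvable.  Open shells extrapolate α and β densities
independently but share one coefficient set, since the descriptor is a
function of the geometry alone.  The history (default depth 6) keeps one
base point per window and resets, with a log message, when the newest
density's largest principal angle from the base point exceeds 1 rad.
On a 200-step toy trajectory the mean SCF iteration count orders
Grassmann < previous-density < core guess (2.65 / 4.05 / 5.42 for the
shipped seed).

## Dynamics

Velocity Verlet with the electronic state fully converged at every step;
0.5 fs default step.  The Bussi stochastic velocity-rescaling thermostat
uses the canonical-sampling formula with the χ² term drawn as a gamma
deviate and is exactly the identity in the τ→∞ limit.  Degrees of
freedom subtract 3 only for isolated, fully mobile molecular systems;
an external (harmonic) potential or frozen atoms keep all of them.
Analytic PPP forces assemble Hellmann–Feynman terms from dt/dr and
dγ/dr, core and Born–Mayer terms, and `q_a·E_env(r_a)` for the
embedding, with induced dipoles at their variational optimum (no
response terms needed); a finite-difference mode with state tracking at
displaced geometries cross-checks them and serves the Gaussian backend.
Checkpoints serialize the complete mutable state including the RNG
stream, so a restarted run is identical to an uninterrupted one to
machine precision.

## The PCET toy: what it emulates, and what it does not

`make_pcet_toy` builds a donor–bridge–acceptor π system that reproduces,
at five sites plus a mobile proton, the phenomenology of a
flavin-photoreceptor active site: a donor whose edge site carries an
anionic electron pair hydrogen-bonded to the proton (a phenolate-oxygen
analog), a high-lying bridge that mediates superexchange without holding
charge, an acceptor dimer whose π* receives the transferred electron,
and a polarizable multipole shell (default 18 sites in neutral
"residue" triples at ~14 bohr, far members frozen and depolarized beyond
16 bohr).  Two donor holes exist: the π-stack hole and the edge
(lone-pair) hole; the delivered CT excitation digs the edge hole,
because depleting the orbital the proton binds to is what releases it.
Delivered excitations are pinned to orbital indices resolved once at the
delivered geometry; the general Löwdin-weight selector machinery
(`"pi_donor"`-style labels with a 50% threshold and a 5% ambiguity
margin) remains available and tested, but index pinning keeps the
sudden-switch protocol deterministic when thermal motion reorders
near-degenerate levels.

Generation-time verification is part of the generator's contract: the
ground state must be closed-shell with fragment charges below 0.2 e, the
CT dipole at least twice the ground-state dipole, the CT-state force on
the proton directed donor→acceptor, and the FCI adiabatic LE/CT ordering
must flip inside the proton track.  A violated clause is an error, never
a silently bad fixture.  The acceptor on-site bias that positions the CT
state is a committed constant (−0.75 hartree): scan-based calibration
was tried and rejected because iMOM converges to different local SCF
solutions at nearby biases, which made scan-selected values land on
marginal states.  With the committed bias the adiabatic crossing sits
early on the track (~10–25%), consistent with the ultrafast transfers
the protocol produces.

The protocol (`run_pcet_cycle`) makes three choices worth stating.
First, both the photoexcitation and the recombination start from rest
(vertical events at a thermally sampled geometry): at this scale the
transfer exothermicities are a few hundred millihartree spread over a
handful of modes, and hot tails otherwise eject the proton into long
Coulomb orbits around the acceptor anion.  For the same reason the
thermostat coupling is tight (τ = 0.02 ps) in the protocol while the
package default stays 0.1 ps.  Second, charge recombination is
triggered a fixed delay (default 150 steps) after the forward-transfer
event — recombining much later lets the proton sink into a covalent
acceptor well from which the short-lived recombined state cannot recall
it.  Third, the back transfer is *manual*: the transferred α electron
of the final CT state is demoted into the donor edge orbital and the
resulting closed-shell-type determinant is tracked with iMOM
(`back_electron_transfer`).  Aufbau filling cannot prepare this state:
at the post-transfer geometry the global closed-shell minimum parks the
pair on the acceptor side and provides no driving force for the reverse
transfer, whereas the recombined donor-anion state — initially higher in
energy, as expected for a charge-separated closed shell — pulls the
proton home before it decays.

What the toy does **not** emulate: real electronic structure (the ΔSCF
machinery is functional-agnostic and exercised at the Hartree–Fock/PPP
level), force-field bonded and van der Waals terms, covalent QM/MM
boundaries (the fixtures have none), nuclear quantum effects (the proton
is classical, matching the classical-nuclei treatment throughout), and
ensemble statistics over many trajectories — the package runs single
representative trajectories, and the sampling loop in the acceptance
script (discard-and-resample on SCF halts) stands in for trajectory
ensembles.  Passing tests therefore demonstrate the *machinery* —
diabatic tracking, state-specific polarization, exact-physics
extrapolation, conservative dynamics, event detection — not quantitative
fidelity to any real photoreceptor.

## Problem sizes and tolerances used in the shipped tests

Unit and acceptance tests run H2/HeH+/H4 (2–4 Gaussian basis functions),
PPP systems of 2–5 sites, polarization shells of 20–100 sites, a
100-point crossing path, 200-step guess-comparison trajectories, one
2000-step NVE run, a 1e5-step thermostatted harmonic run, and the full
three-leg PCET cycle (100 + 1200 + 1200 steps at 0.5 fs).  SCF
convergence is 1e-8 on the commutator for static calculations and 1e-6
along MD; polarization residuals 1e-10; Grassmann idempotency is checked
at 1e-12.  Oracles are independent implementations (plain-loop damped
SCF, Fock-space exact diagonalization, dense polarization solves,
finite-difference forces), never calls into the code paths they check.

## Known limitations

STEP's fixed-reference projector cannot converge states whose orbital
relaxation leaves the reference span (flagged, not silent).  ΔSCF
determinants with a single spin flip are spin-contaminated
(⟨S²⟩ = 1 for the two-orbital open shell) and no purification is
applied.  The embedding couples the QM density as Löwdin point charges,
so penetration effects are absent.  Trajectory outcomes on the toy's CT
surface are stochastic under thermal initial conditions — by design the
reverse transfer is only guaranteed under the protocol's quenched,
fixed-delay recombination; other initial conditions may need resampling,
and the analysis layer treats halted trajectories as first-class,
reportable outcomes.
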