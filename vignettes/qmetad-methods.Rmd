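---
title: "Methods: a tight-binding engine for well-tempered metadynamics and free-energy decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a tight-binding engine for well-tempered metadynamics and free-energy decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

qmetad implements, at desk scale, the computational stack used to drive
enhanced-sampling molecular dynamics with a quantum-mechanical energy
engine: a third-order self-consistent-charge density-functional
tight-binding (DFTB3) model fed by Slater-Koster parameter tables, a
divide-and-conquer generalized symmetric eigensolver (the operation that
dominates the wall time of such simulations), NVT dynamics with a
Nose-Hoover thermostat, a well-tempered metadynamics (WT-MetaD) driver,
and the analysis layer that turns deposited hills into free-energy
surfaces and decomposes them into internal-energy and entropy terms.
This vignette records the models, the tunable parameters, the numerical
choices, and the limitations — in particular what the packaged synthetic
fixtures do and do not establish about behavior on real molecules.

## 1. The DFTB3 energy model

The total energy is

$$E = E_\mathrm{BS} + E_\gamma + E_\Gamma + E_\mathrm{rep}\;(+\,E_\mathrm{disp}),$$

with the band-structure term $E_\mathrm{BS}=\sum_i f_i\,
\langle\psi_i|H^0|\psi_i\rangle$, the second-order charge-fluctuation
term $E_\gamma=\tfrac12\sum_{AB}\Delta q_A\Delta q_B\,\gamma_{AB}$, the
third-order chemical-hardness correction
$E_\Gamma=\tfrac13\sum_{AB}\Delta q_A^2\Delta q_B\,\Gamma_{AB}$, and a
pairwise repulsive potential $E_\mathrm{rep}$ tabulated per element
pair.  $\Delta q_A$ is the net Mulliken charge in the electron-count
convention (positive = electron excess).  All engine internals are in
Hartree and Bohr; the MD layer converts once, at its boundary, to
kJ/mol, Angstrom, fs and amu (`qm_constants()` is the single source of
conversion factors).

Matrix elements of $H^0$ and of the overlap $S$ are strictly two-center:
the diagonal holds free-atom orbital energies, same-atom off-diagonal
blocks vanish, and inter-atomic blocks are obtained by Slater-Koster
rotation of the tabulated $ss\sigma$, $sp\sigma$, $pp\sigma$ and
$pp\pi$ channels with direction cosines.  Only s and p valence shells
are supported; this covers every packaged fixture (d shells, needed for
phosphorus or sulfur in production parameter sets, are out of scope, so
production systems containing them cannot be treated at full fidelity).

**Charge kernels.** We adopt the published DFTB3 forms: $\gamma$ is
the exponentially damped Coulomb interpolation with decay
$\tau = 16U/5$, equal to the Hubbard parameter $U$ on site and to $1/r$
asymptotically, with the optional hydrogen-pair short-range damping
$\exp(-((U_A+U_B)/2)^\zeta r^2)$ behind a switch (off by default — the
synthetic fixtures contain no hydrogen).  $\Gamma_{AB}=
\partial\gamma_{AB}/\partial q_A$ is chained through the Hubbard
derivative $U^d_A$.  Rather than transcribing the lengthy analytic
$\tau$-derivative, the $U_A$-derivative is evaluated by a 4-point
central difference.  The step is deliberately large, $h=10^{-2}U_A$:
the unequal-parameter closed form of $\gamma$ contains
$(\tau_a^2-\tau_b^2)^{-3}$ factors that cancel catastrophically when
the perturbed $\tau$ values nearly coincide, and a $10^{-4}$ step sits
exactly in that regime (we observed orientation-dependent noise at the
$10^{-3}$ level before widening the step; at $10^{-2}$ the evaluation
is well conditioned and the truncation error is $\sim10^{-8}$
relative).  On site, $\Gamma_{AA}=U^d_A$ exactly.

**SCC loop.** The charge-dependent Hamiltonian shift is applied per
atom pair as $S_{\mu\nu}(\epsilon_A+\epsilon_B)$ with the potential
$\epsilon_A=\sum_\xi \Delta q_\xi\,(\gamma_{A\xi}/2 + \Delta q_A
\Gamma_{A\xi}/3 + \Delta q_\xi \Gamma_{\xi A}/6)$, so all charges zero
reproduce $H^0$ exactly.  Orbitals are filled by zero-temperature
Aufbau (two electrons per spatial orbital) with optional Fermi
smearing; an exact degeneracy at the Fermi level without smearing is an
error that advises enabling it, rather than a silently arbitrary
occupation.  Charges are relaxed by simple linear mixing
($\alpha=0.2$ by default; Broyden-type accelerators are out of scope)
until $\max_A|\Delta q_A^\mathrm{out}-\Delta q_A^\mathrm{in}|$ drops
below `tol` ($10^{-8}$ e by default).

One caveat is worth stating plainly: the stopping rule bounds the
*residual* of the charge map, not the distance to the fixed point.  For
systems with a slowly contracting charge mode, a $10^{-8}$ residual can
leave an energy error orders of magnitude above $10^{-8}$ Ha (we
measured $10^{-4}$ Ha on a strongly polar triatomic).  Reproducibility
checks at the nano-Hartree level therefore run with `tol = 1e-12`, and
`dftb_energy()` exposes the tolerance.  Forces are central finite
differences of the total energy (step $10^{-3}$ Bohr, configurable) —
correctness over speed at desk scale — and geometry relaxation is
steepest descent with backtracking down to a maximum per-atom force of
0.04 eV/Å by default.

## 2. The eigensolver

Each SCC iteration solves the generalized symmetric-definite problem
$Ax=\lambda Bx$.  The reduction chain is Cholesky
($B=LL^\mathsf{T}$, $C=L^{-1}AL^{-\mathsf{T}}$; the factorization
itself is delegated to LAPACK via `chol()`), Householder
tridiagonalization with accumulated $Q$ and the off-diagonal normalized
non-negative, and a from-scratch divide-and-conquer tridiagonal solver:

* the matrix is torn at $m=\lfloor n/2\rfloor$ into two half blocks
  plus a rank-one coupling $\beta uu^\mathsf{T}$ (the sign of $\beta$
  is absorbed into $u$ so the rank-one weight is always positive);
* halves are solved recursively — closed form at $n\le2$, implicit-shift
  QL below the base size (default 32, configurable);
* the merge solves the secular equation
  $1+\rho\sum_i z_i^2/(d_i-\lambda)=0$ by safeguarded bisection **in the
  shifted variable** $\mu=\lambda-\sigma$, $\sigma$ the closer
  bracketing pole.  This matters: eigenvector components are
  $z_i/(d_i-\lambda)$, and computing $d_i-\lambda$ by subtraction loses
  all significant digits when a root sits within machine precision of a
  pole (tiny $|z_i|$).  The shifted solve returns the differences
  directly, keeping eigenvector residuals at the $10^{-13}$ level;
* deflation removes components with $|z_i|\le 10^{-14}\|T\|$ and merges
  near-degenerate $d_i$ by a Givens rotation; a modified Gram-Schmidt
  re-orthogonalization backstops the (rare) heavily deflated merges.

Eigenvectors are back-transformed to $x=L^{-\mathsf{T}}Qy$, which are
$B$-orthonormal by construction.  The independent oracle in the tests
is base R's `eigen(symmetric = TRUE)` (a different LAPACK code path) on
matrices reduced inline in the test code; agreement is at $10^{-10}$
relative over hundreds of random problems up to $n=128$.  Empirical
cost grows no worse than cubically, as expected for the dense
algorithm.  QR and RRR alternatives, GPU offload and sparse solvers are
out of scope.

## 3. Dynamics and the thermostat

`run_nvt()` integrates velocity Verlet with an optional single
Nose-Hoover thermostat in a symmetric splitting (quarter-step friction
updates around the velocity scaling, then the Verlet kick-drift-kick).
The coupling mass is $Q=N_f k_B T\tau^2$ with $\tau$ defaulting to
50 fs (common run protocols leave this unpinned; the choice is exposed
in the configuration).  The extended-system conserved
quantity is tracked and drifts below $10^{-3}$ relative over
$5\times10^4$ toy steps.

Two honest limitations of the *single* thermostat (chains are out of
scope by design):

* it is non-ergodic on integrable systems — a pure harmonic oscillator,
  or any 1-DOF toy.  Kinetic-energy statistics remain exact
  ($\langle T\rangle$ within 0.1% in our runs) but configurational
  distributions on such systems are not canonical.  Statistical tests
  of configurational observables therefore use chaotic anharmonic toys
  (the periodic double well; a quartic-coupled 2-D well);
* strong coupling distorts configurational sampling even on chaotic
  toys: at $\tau=5$ fs we measured $\langle V\rangle$ 2.4× the
  canonical value, at $\tau=20$–50 fs a few percent high, while
  $\tau\ge100$ fs agrees with quadrature to 2–3%.  Configurational
  averages in the test suite use $\tau=100$ fs; the default stays at
  50 fs, which is fine for the metadynamics runs themselves (the bias
  continually stirs the system).

## 4. Well-tempered metadynamics

The bias is a sum of Gaussians deposited every `pace` steps (default
500) at the instantaneous collective-variable (CV) values, with
per-deposit height damped by the accumulated bias:
$h = W_0\exp(-V_B/(k_BT\,\delta))$.  Two damping conventions are in
circulation: dividing the exponent by $\delta=\gamma$ (here called
"paper", as some papers print the tempering rule this way) and the
community-code convention dividing by $\delta=\gamma-1$ ("standard",
the PLUMED behavior).  Both are implemented behind `wt_convention`,
defaulting to the former.  The distinction is not cosmetic: the asymptotic bias with
damping $\delta$ satisfies $V_B\to-\tfrac{\delta}{\delta+1}F$, so the
sum-hills estimator $F=-\tfrac{\gamma}{\gamma-1}V_B$ is exact only for
the standard convention, and under the paper convention carries a
systematic factor $\gamma/(\gamma+1)\cdot\gamma/(\gamma-1)\approx1.01$
at $\gamma=10$ plus slower late-time convergence.  End-to-end recovery
checks therefore run the standard convention; at $2\times10^6$ steps
the paper convention recovers the same basin difference to within
0.1 kJ/mol, consistent with the factor above.

Hill widths are interpreted in radians ($\sigma=0.35$ by default) —
the natural unit for torsional CVs.  Gaussians use the minimum-image
periodic displacement per CV rather than an infinite image sum, exact
to better than $10^{-6}$ for $\sigma\le0.6$ rad.  Hills deposited on a
pace boundary enter the dynamics at the next force evaluation.  Full
runs are bit-reproducible from (seed, configuration); HILLS and COLVAR
files follow the PLUMED text dialect (time in ps in the files), so
community sum-hills tooling can read them for two-torsion runs.

Torsional CVs use the IUPAC sign convention (cis = 0, trans = $\pi$)
with analytic gradients validated against finite differences; the four
gradient rows sum to zero by construction.  CV-space walkers (identity
CVs, unit mass per dimension, 1 fs steps) run through a specialized
inner loop that transcribes the generic integrator arithmetic exactly
— the two paths agree to the last bit on toy systems, and the
specialization only buys speed.

## 5. Free-energy surfaces and their decomposition

`sum_hills()` evaluates the bias on bin centers of a uniform grid over
$(-\pi,\pi]^k$ (100 bins per CV by default; the protocol prints no grid
size) and applies $F=-\tfrac{\gamma}{\gamma-1}V_B$, shifted so the
minimum is zero.  Convergence is diagnosed as in the field: surfaces at
successive time checkpoints should agree up to a constant offset, and
`fes_time_series()` reports the offset-corrected maximum deviation.

The decomposition follows $\Delta A = \Delta U - T\Delta S$:
$\Delta U$ is the grid-local arithmetic mean of the instantaneous
potential energy over the frames falling in each bin (bins with fewer
than `min_count = 5` frames are masked), and the entropic term is the
bin-wise rearrangement $T\Delta S=\Delta U-\Delta A$, which makes the
identity hold to machine precision by construction wherever unmasked.
A note on signs: the entropic term reported here is
$T\Delta S=\Delta U-\Delta A$ (some community scripts report the
opposite sign, $\Delta A-\Delta U$; the decomposition equation above
is taken as normative).
Gaussian smoothing (wrapped, FFT-based, mean-preserving) exists for
presentation only and is never applied before quantitative analyses.

Basin free-energy differences are Boltzmann-weighted integrals
$\Delta F=-k_BT\ln(Z_A/Z_B)$ over stated intervals (default half-width
0.8 rad), not well-depth differences.  Minima of 2-D grids are bins
strictly below all 8 periodic neighbors and deeper than `depth_cut`
below the grid median.  Transition paths use a nudged elastic band on
the gridded surface: images on the minimum-image straight segment,
bilinear surface interpolation, the gradient component perpendicular to
a normalized central-difference tangent plus a tangential spring force
(10 kJ/mol/rad²), fixed endpoints, fixed-step descent (0.01 rad) to a
$10^{-5}$ rad displacement tolerance.  The simple tangent (not the
improved-tangent scheme) is a documented simplification; on the
constructed separable test surface with an analytic 12 kJ/mol saddle
the recovered barrier is within 0.06 kJ/mol.

## 6. Synthetic data: what it emulates and what it does not

Two generators make the stack testable without any external download.

**Synthetic Slater-Koster tables** (`make_synthetic_sk()`): smooth
exponentially decaying H/S channels for fictitious s-shell elements X
and Y and the s,p element Z, with on-site energies, Hubbard parameters
and third-order derivatives of realistic magnitude (a few tenths of a
Hartree, $U^d<0$), a purely short-range quadratic repulsive spline
$a(r-r_c)^2$ written in the standard spline-block encoding, and overlap
amplitudes small enough that assembled $S$ matrices stay positive
definite on the packaged geometries.  The channel identity
$ss\sigma(A,B)=ss\sigma(B,A)$ (and likewise $pp$) is enforced —
only the $sp$ channel is directional — because the assembled matrices
must be symmetric.  Tables round-trip through the dftb.org-style text
dialect at 15 significant digits.  In this s/p-restricted dialect the
`Ud` column of the homonuclear on-site line carries the third-order
Hubbard derivative (the d-shell Hubbard it would otherwise hold is
meaningless without d shells), which keeps the derivative
file-persistent; production parameter sets distribute it separately.

What passing tests on these fixtures shows: the Slater-Koster rotation,
SCC algebra, energy bookkeeping and eigensolver are correct, since
rotational invariance, closed-shell closed forms and charge sums probe
exactly that machinery.  What it does not show: chemical accuracy for
any real element, transferability of parameters, or behavior of d-shell
chemistry.  The fixture "chemistry" is deliberately aggressive (large
charge transfer), which stress-tests the SCC loop; real 3ob-class
parameters are tamer.

**Toy landscapes** (`double_well_1d()`, `double_well_2d()`): periodic
closed-form potentials whose free energy is known exactly (for one CV,
$F=V$ up to a constant; basin differences by $10^4$-point quadrature).
The 1-D default — barrier 10 kJ/mol, asymmetry 5 kJ/mol, wells exactly
at $\mp\pi/2$ — is the end-to-end study condition: barriers of
$\sim4\,k_BT$ at 300 K, crossing times of tens of ps, recoverable to
0.5 kJ/mol in a $5\times10^5$-step run.  The 2-D default surface is
Ramachandran-like (two dominant wells, saddles, a diagonal coupling);
its tilt terms mix sine and cosine deliberately, because an all-sine
family possesses an exact discrete symmetry
$(\phi,\psi)\to(-\pi-\phi,\pi-\psi)$ that produces degenerate minima in
adjacent grid bins and makes strict-inequality minima detection
ill-posed.  A Metropolis sampler with wrapped proposals provides an
independent Boltzmann oracle.  What the toys do not emulate: the
coupling between CV motion and orthogonal degrees of freedom of a real
molecule, force-field noise in the internal-energy surfaces, and CV
gradients of real dihedrals (those are tested separately on the
molecular fixtures).

**Molecular fixtures**: a 22-atom alanine dipeptide and a 77-atom
remdesivir conformer, generated once with standard cheminformatics
tooling (ETKDG embedding + MMFF cleanup) and stored as plain-text XYZ
— synthetic stand-ins for the PDB-derived structures of production
work, carrying documented $\phi/\psi$ dihedral quadruples (for
remdesivir, the two phosphoramidate scaffold torsions about P–N and
P–O(ester) — a documented choice among the scaffold's rotatable
bonds).

## 7. Problem sizes and reproducing the full-scale numbers

The test suite and the acceptance script use: random eigenproblems up
to $n=128$ (hundreds of instances), $5\times10^5$-step WT-MetaD runs
(0.5 ns at 1 fs) on the 1-D double well for three seeds, 100 ps
thermostat runs, and 40–100-bin analysis grids — sizes chosen so the
full stack exercises in minutes on one CPU while every assertion stays
at its stated tolerance.

The production-scale pathway is documented but deliberately not part of
the automated checks: with user-supplied 3ob-3-1 parameter tables
(plus their Hubbard derivatives), a prepared remdesivir geometry, d
shells for phosphorus (out of scope here), and a $\sim$10 ns WT-MetaD
run, the 1-D basin free-energy differences along the two scaffold
torsions are expected near −6.92 and −3.80 kJ/mol.  That computation is
cluster-scale and stochastic; nothing at desk scale stands in for it,
and the package does not pretend otherwise.

## 8. Known limitations

* s/p valence only; no periodic boundary conditions, k-points, spin
  polarization or analytic forces.
* Dispersion is a generic damped-$C_6$ hook with user coefficients, not
  a full D3 parameterization (no coordination-number dependence, no
  three-body term).
* Single Nose-Hoover thermostat (see §3); no Langevin or NPT.
* Linear SCC mixing only; strongly polar systems may need small mixing
  or smearing, and SCC multistability is possible for extreme charge
  transfer (warm starts select the branch).
* Minimum-image Gaussians limit hill widths to $\sigma\lesssim0.6$ rad.
* NEB uses the simple central-difference tangent and reports the
  barrier from bilinear interpolation of the grid, so its resolution is
  bounded by the grid spacing.
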