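---
title: "Coarse-grained cofactor parametrization: models, conventions and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained cofactor parametrization: models, conventions and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgparam)
```

# Scope

`cgparam` implements the workflow used to build Martini 3 coarse-grained
(CG) models of the photosynthetic cofactors — beta-carotene, violaxanthin,
neoxanthin, lutein, plastoquinone/plastoquinol, chlorophylls A and B, heme —
plus the derived pheophytin A model and the 4-bead oxygen-evolving (CaMn4O5)
cluster. It covers:

* atom-to-bead mapping and center-of-mass projection of atomistic ensembles;
* Boltzmann-inversion fitting of harmonic bonded terms, with constraint
  substitution for sharp distributions and a distribution-matching
  refinement step;
* GROMACS-dialect ITP topology emission and parsing;
* Bennett-acceptance-ratio (BAR) free energies over lambda windows,
  composed into water/octanol transfer free energies and log P;
* membrane/protein validation analyses: electron density profiles along
  the bilayer normal, Kabsch superposition with RMSD/RMSF, and
  Shrake-Rupley solvent-accessible surface area (SASA).

Running an MD engine is out of scope: every stage consumes and produces
plain files (mappings, coordinate trajectories, per-window energy tables,
ITPs), so engine steps can be interleaved externally. The nonbonded
interaction matrix belongs to the force-field release and is not emitted;
only bead *type names* are.

# The models

## Mapping and projection

A mapping assigns every heavy atom (united-atom convention, implicit
hydrogens folded into mass and electron count) to one CG bead; 2–6 heavy
atoms per regular bead, 2–4 for small (S) and 1–3 for tiny (T) beads, with
monatomic metal ions (Mg to TQ3p, Fe to SQ3p) mapped 1:1 whatever the size
class. Aromatic ring systems may *doubly map* atoms — an atom shared by two
beads — to preserve symmetry; the chlorophyll fixtures share the four
methine-bridge carbons between adjacent ring beads.

Bead positions are the **center of mass** of the mapped atoms
(`project_frame()`), the physically meaningful choice for united-atom
references; center of geometry is available behind a switch. A
doubly-mapped atom contributes its full mass to each host bead; for
electron bookkeeping (`electrons_per_bead()`) its electrons are instead
split 50/50, so the per-bead totals always sum to the molecular electron
count.

Emitted bead masses are the Martini 3 size-class defaults (72/54/36 amu);
the summed atomic masses remain on the mapping for projection.

## Boltzmann inversion

For a harmonic bond the Boltzmann marginal is Gaussian, so a single pass
inverts the moments: `b0 = mean`, `k = RT / sd^2` with
R = 0.0083145 kJ mol^-1 K^-1. Angles use the Martini cosine-harmonic form
(GROMACS funct 2), inverted in **cosine space**: `theta0 =
acos(mean(cos))`, `k = RT / var(cos)`. Impropers are harmonic in the plane
angle (funct 2), fitted with a circular mean and radian variance. No
Jacobian (r^2 or sin theta) correction is applied: moments are taken on
raw samples, and in cosine space the cosine-harmonic density is exactly
Gaussian, which makes the moment inversion self-consistent.

A known limitation follows from the bounded domain of cos(theta): a *soft*
angle near its boundary (e.g. theta0 = 150 deg with k = 100 kJ/mol at
298 K, sigma_cos = 0.157) has ~20% of its nominal Gaussian mass beyond
cos = -1, so moment inversion on physically realizable angle samples is
biased for such terms. The synthetic round-trip oracle therefore samples
directly in cosine space (the estimator's conjugate model); for stiff
angles, where the boundary is many sigma away, the distinction is
immaterial.

Distributions with `sd < 0.005` nm (configurable) are emitted as
**constraints** rather than bonds — the sharp ring-network distances of
the chlorophyll, heme and plastoquinone-head fixtures fall below this
threshold, chain bonds sit well above it. Force constants are always
capped (25,000 kJ mol^-1 nm^-2 for bonds by default) and the cap is
logged, so no emitted parameter is unstable.

`refine_term()` implements one step of the iterative matching loop:
`k' = k * (sd_observed / sd_target)^2` with the equilibrium shifted by the
mean mismatch, clamped to the cap. The update is a contraction on the
width mismatch and a fixed point at match; since a freshly inverted
harmonic model already reproduces a harmonic target, the loop's value is
for *non-harmonic* references, where it converges in a few iterations
(tested with a 50% mis-initialized force constant). The loop never runs an
MD engine — the caller supplies the `observed` ensemble. Bimodal
distributions (two histogram maxima separated by a >= 20% dip) are
flagged and fitted on the pooled samples; tabulated potentials are
deliberately not implemented.

## Topologies and the special cases

`write_itp()`/`read_itp()` form a round-trip identity on the GROMACS
dialect: `[moleculetype]` (nrexcl = 1, the Martini convention),
`[atoms]`, `[bonds]` (funct 1), `[constraints]` (funct 1), `[angles]`
(funct 2), `[dihedrals]` (funct 2, impropers). Equilibria print with 6
decimals, force constants with 2.

* **Pheophytin A** (`derive_pheophytin()`): remove the TQ3p magnesium bead
  with index re-packing, zero every charge, convert every constraint to a
  bond with k = 50,000 kJ mol^-1 nm^-2 (ring stability), drop terms that
  referenced the removed bead. Chlorophyll A's 23 beads become 22.
* **OEX cluster** (`build_oex()`): 4 beads, all 6 pairwise bonds at
  k = 10,000 kJ mol^-1 nm^-2, equilibria from the supplied (mapped
  structure) coordinates. The cluster's 2+ charge is ambiguous between
  per-cluster and per-bead conventions; the default distributes +0.5 e per
  bead (total +2), `charge_mode = "per_bead"` selects the alternative.
* **Restraints** (`build_restraints()`): harmonic cofactor-protein bonds
  with equilibria measured from a supplied structure; k defaults to
  1000 kJ mol^-1 nm^-2 (magnesium-protein chlorophyll restraints,
  pheophytin), 300 kJ mol^-1 nm^-2 being the convention for generic
  cofactor elastic bonds. Which protein bead coordinates each magnesium is
  input, not inferred.

## Free energies and log P

`bar_pair()` solves Bennett's self-consistency equation by bracketing,
Brent's method and a Newton polish (per-sample residual < 1e-12), with the
standard asymptotic variance estimate. Both sample sets use the same
energy-difference convention, `dU = U_next - U_this`, evaluated in the two
neighboring ensembles; `bar_chain()` sums adjacent pairs with quadrature
errors. Decoupling direction: `dG_X/vac` is the free energy of switching
the solute-solvent interactions *off* in solvent X, so a molecule that
prefers octanol has `dG_W/Oct = dG_W/vac - dG_Oct/vac < 0` and a positive

`log P = -dG_W/Oct / (R T ln 10)`.

The synthetic oracle (`gen_crooks_work()`) draws forward work from
`N(dF + beta sigma^2/2, sigma^2)` and reverse from
`N(dF - beta sigma^2/2, sigma^2)`; this pair satisfies the Crooks
fluctuation relation exactly, so BAR's estimand *is* the programmed `dF` —
the estimator is validated against an exact analytic truth, plus an
independent grid/bisection solve of the same equation. A trapezoidal TI
helper is included as a cross-check when derivative columns exist.

## Validation analyses

* **Electron density** (`electron_density_profile()`): bead z positions
  wrapped into the box, re-centered per frame on the membrane selection's
  mean z, histogrammed with per-bead electron weights and averaged over
  frames. "Normalized" means unit maximum per selection (the choice used
  for plotted membrane profiles); the raw electrons/nm profile is kept and
  integrates exactly to the selection's electron count. Leaflet
  symmetrization is off by default — asymmetric two-headed xanthophyll
  profiles are physically meaningful. Molecules are not made whole across
  the boundary; bead-level profiles do not need it.
* **RMSD/RMSF** (`kabsch_superpose()`, `rmsf()`): SVD-based optimal rigid
  superposition with reflection guard; RMSF about the realigned
  time-average, in Angstrom. Note that superposition absorbs 6 rigid-body
  degrees of freedom, so for N sites with isotropic jitter sigma the
  expected RMSF is `sqrt(3) sigma * sqrt(1 - 6/(3N))`; validation
  ensembles use N = 100 so the closed form `sqrt(3) sigma` holds to ~1%.
* **SASA** (`sasa()`): Shrake-Rupley with a 960-point Fibonacci lattice
  and a 0.14 nm probe. CG bead radii default to half the Martini 3
  size-class sigma (0.264/0.230/0.191 nm); united-atom radii use standard
  van der Waals values with carbon at 0.20 nm. Both tables are arguments,
  not constants. Points landing exactly on a coincident neighbor's sphere
  are owned by the lower site index, so fully overlapping sites count one
  surface. Only the *sign* of the CG-vs-atomistic difference is treated as
  checkable — CG surfaces are systematically smaller — because the printed
  percentage differences depend on radii and reference conformers that are
  not part of this artifact.

# Synthetic data: what it emulates and what it does not

All test inputs are generated in code, seed-deterministically.

* `gen_internal_samples()` draws single internal coordinates from the
  exact marginal of the corresponding harmonic form (bond: Gaussian in r;
  angle: Gaussian in cos theta, unbounded; improper: Gaussian in xi). It
  is the conjugate-model oracle for the fitters: round-trips recover
  (b0 = 0.35 nm, k = 5000 kJ mol^-1 nm^-2) and (theta0 = 150 deg,
  k = 100 kJ mol^-1) within (0.1%, 5%) at 1e5 samples.
* `gen_harmonic_ensemble()` is a sweep Metropolis sampler over the full
  bonded potential, run as many independent walkers started at the
  idealized geometry, with per-bead proposal scales initialized from the
  local stiffness and auto-tuned to 30–50% acceptance during burn-in
  (defaults: 250 walkers, 300 burn sweeps, samples every 10 sweeps —
  spacing chosen beyond the sweep-level autocorrelation of soft modes).
  Its single-bond marginal reproduces `sigma = sqrt(RT/k)` within 2%.
* In a *cross-braced* network (the chlorophyll/heme ring scaffolds carry
  deliberately redundant bonds for rigidity) the marginal width of a bond
  is narrower than its per-term `sqrt(RT/k)` — a property of coupled
  harmonic systems, and the very reason iterative refinement exists in CG
  parametrization. Closure is therefore validated in two parts: (i)
  *projection closure* — building pseudo-atoms around sampled bead frames
  and projecting back must reproduce the bead-ensemble widths within 3%
  for every shipped cofactor (it is exact by construction of
  `place_atoms()`, whose per-bead mass-center correction cancels atomic
  jitter; doubly-mapped atoms sit at host midpoints, jitter-free); and
  (ii) *analytic recovery* on acyclic (bridge) bonds, where the per-term
  marginal is well-posed, to 3%.
* `gen_crooks_work()` / `gen_crooks_series()` provide the exact-estimand
  BAR harness described above.
* `gen_toy_bilayer()` builds Gaussian leaflets (head beads about
  +-1.8 nm, a DPPC-like leaflet offset; tails about the midplane) with
  cofactor beads either head-anchored or midplane-dwelling, reproducing
  the qualitative membrane-profile shapes: co-localized head peaks for
  polar-headed xanthophylls, a single central peak for the apolar case.

What passing these tests shows — and what it does not: the estimators,
the bookkeeping and the file formats are correct against exact synthetic
truths. The generators match *target statistics*, not force-field
energetics: no claim is made that they reproduce GROMOS conformational
ensembles, solvent structure, or the sampled work distributions of real
alchemical runs. Reproducing the published log P values or membrane
density profiles requires an MD engine and the external force-field
release, both out of scope.

# The shipped fixtures

The mapping files under `inst/extdata/mappings/` encode the eight cofactor
fragmentations plus the chlorophyll B (bead 15 SN4a, formyl substituent)
and plastoquinol (TN3a -> TN6 head beads) variants. The bead counts, bead
types, charges and bonded-term totals are the reference values: 10 beads /
11 bonds / 8 angles for beta-carotene, violaxanthin and lutein; 11/12/9
for neoxanthin; 13/13/12 for plastoquinone/ol; 23 beads, 44 bonds, 22
angles, 15 impropers for the chlorophylls (with the four methine-bridge
carbons doubly mapped — their exact identity is not documented anywhere we
could trace, so the symmetric bridge positions were chosen); 19 beads and
net charge -2 for heme (Fe at +0.4, four TN6q at -0.1, two deprotonated
Q5n propionates at -1). The *atom-level* tables inside each bead are a
synthetic, formula-accurate united-atom reconstruction (each file says so
in its header): element counts, masses and electron totals match the
molecular formulas, but per-atom assignments within a bead are plausible
rather than traced, and tests lock only the authoritative totals.

Idealized geometries (`idealized_coordinates()`) come from a deterministic
stress embedding of the bead graph (bonded pairs pulled to size-class
contact distances, non-bonded pairs pushed apart below 0.3 nm), driven by
an internal linear-congruential generator and rounded to 1e-5 nm — pure
arithmetic, so emitted preliminary ITPs are byte-stable across platforms.

# Numerical choices and degenerate inputs

* Temperatures default to 298 K for fitting and 300 K for log P.
* Histogram binning is Freedman-Diaconis and affects only reporting and
  overlap scores; every fit uses raw samples.
* `compare_distributions()` rebins both sample sets onto 100 common bins;
  the overlap coefficient is symmetric, in [0, 1], 1 only for identical
  histograms, 0 (with a warning) for disjoint supports.
* Zero-length bond vectors and collinear superposition selections are
  errors, not NaNs; a zero-width bond distribution directs the caller to
  the constraint path; BAR refuses non-overlapping sample sets with a
  diagnostic rather than returning an unconstrained root.
* Problem sizes in the test-suite and acceptance script (1,200–5,000
  ensemble frames per cofactor, 1e4 work samples per BAR side, 1e5
  round-trip samples, 150–800 analysis frames) were chosen so every
  statistical tolerance sits several standard errors away from its
  expected value while the whole suite stays lightweight.

# Known limitations

* Mappings are human-authored; there is no automatic fragmentation from a
  chemical graph, matching how such models are actually built.
* No proper-torsion fitting (the shipped cofactors use none) and no
  iterative Boltzmann inversion against radial distribution functions.
* The refinement stopping rule (overlap >= 0.9 by default in the CLI
  workflow) is this artifact's own convention; published work reports
  only a qualitative "satisfactory match".
* Soft angles near the cosine boundary are biased under moment inversion
  (see above); a maximum-likelihood fitter for truncated densities would
  be the remedy if such terms ever mattered for these molecules (they are
  all stiff or far from the boundary here).
* MBAR across all windows is not implemented; BAR on adjacent pairs
  matches the established tooling's behavior.
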