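---
title: "Weighted multistate ensemble analysis with spanflex: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted multistate ensemble analysis with spanflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanflex)
```

# The problem

Bispecific T cell engagers (TcEs) crosslink a T cell surface antigen
(typically CD3ε) with a tumor antigen (here Her2 serves as the model), and
their potency depends on geometric properties of the ternary
antigen–TcE–antigen assembly that no single static structure captures: the
spacing between the two paratopes, the spacing between the points that
would anchor the two antigen ectodomains to their respective membranes (a
proxy for the intermembrane gap, to be compared against the ~13 nm "close
contact" span of CD2–CD58 and TCR–pMHC pairs), and the conformational
flexibility of the whole assembly. Solution SAXS constrains these
quantities through *multistate models*: sets of rigid conformations with
fractional weights whose mixed scattering jointly fits one experimental
curve. spanflex takes such weighted ensembles and computes the derived
geometry, flexibility, and scattering statistics, and quantifies the
corresponding membrane-interface observables (colocalization and
normalized signal levels) in two-channel images. A synthetic-data module
generates articulated bead-model ensembles, mixture SAXS curves and
synapse images with exact ground truth, so that every stage of the
pipeline is testable without any external data.

# Weighted ensembles and their statistics

The unit of analysis is a `weighted_ensemble`: states (atom tables in
Ångström) plus weights normalized to sum to 1. Every scalar measured per
state (a spacing, a tilt, a radius of gyration) becomes a
`weighted_distribution` carrying the state weights.

**Weighted quantiles.** Medians and quartiles of weighted distributions
use midpoint plot positions: sorted values sit at cumulative weight minus
half their own weight, quantiles are linearly interpolated between the
straddling values and clamped at the extremes. Two equal-weight values 1
and 3 therefore have median 2, and a single value is every quantile of
itself. This estimator is symmetric, exact under weight renormalization,
and invariant to splitting any state into duplicates with halved weights.

**Units.** Coordinates are kept in Å internally (the PDB's native unit);
all reported spacings and flexibilities are converted to nm at the
reporting boundary, and angles are reported in degrees.

# Geometry

**Superposition.** States are aligned by the least-squares (Kabsch/SVD)
fit of the annotated `reference` selection onto the same selection in
state 1 — the first row of the weight table, a deterministic and
order-documented choice (a weighted mean structure would change under
state permutation while the fit target should not; order invariance is
guaranteed for all order-free statistics and checked in the tests).
Collinear or sub-3-atom references are rejected as rank-deficient.

**Landmarks.** "Tip of the heavy-chain CDR3 loop" and "C-terminal anchor"
are realized as centroids of user-annotated selections; the annotation
makes the atom set explicit because the landmark, not the atom rule, is
the scientific content. Defaults in the synthetic template follow common
practice: a single Cα for a paratope tip, the last three ordered Cα for a
membrane anchor (three residues damp terminal disorder). Both
centroid-to-centroid and single-atom distances are therefore available
through the same mechanism.

**Tilt angles.** A domain's orientation relative to the antigen–binder
axis is the acute angle between the domain's longest principal axis (the
largest-eigenvalue eigenvector of the covariance of its atom positions)
and the axis-head→axis-tail unit vector. Principal axes are sign-ambiguous,
so angles fold into [0°, 90°]. The principal axis was chosen because it is
parameter-free and reproducible; a domain-specific vector (for instance an
Ig-domain pseudo-twofold axis) would need per-domain conventions. When the
top two covariance eigenvalues agree within 1% the axis is ill-defined:
those states are flagged (`degenerate` attribute) and a warning is raised
rather than silently reporting a noise-driven angle.

# Flexibility metrics

All flexibility metrics operate on the aligned ensemble and are reported
per domain plus a whole-molecule row, since either convention may be
wanted and the two answer different questions.

- **Rg**: mass-weighted radius of gyration per state (unknown elements
  fall back to the carbon mass with a warning), reported as a weighted
  distribution in nm.
- **CoM flexibility** (`com_flexibility`): weighted RMS deviation of the
  domain's mass-weighted center of mass about its weighted mean position,
  `sqrt(sum_i w_i |c_i - cbar|^2)`. RMS (not mean absolute deviation) was
  chosen because it composes analytically: two equal-weight states
  displaced by `d` give exactly `d/2`.
- **Rotational flexibility** (`rotational_flexibility`): per state the
  domain orientation is extracted by Kabsch superposition of its centered
  atoms onto state 1; the weighted mean orientation is the principal
  eigenvector of the weighted quaternion outer-product matrix; the metric
  is the weighted RMS rotation angle about that mean, with the quaternion
  double cover resolved to [0°, 180°]. Two equal-weight states rotated by
  ±θ give exactly θ. One genuine degeneracy exists: at exactly ±90° the
  two orientations are antipodal (orthogonal quaternions) and the mean
  orientation is mathematically ill-defined; dispersions that extreme
  should not be summarized by a single mean orientation anyway.
- **Effective disorder** (`effective_disorder`): the exact product
  CoM flexibility × rotational flexibility (nm·degrees). This follows the
  literal combined-disorder definition used in the field's reports; since
  the same reports use the words "Shannon entropy" for it, the package
  also provides the true entropy of the state weights
  (`weight_entropy`, −Σ wᵢ ln wᵢ in nats) under an unambiguous name, and
  never conflates the two.

# Coarse-grained SAXS

**Debye engine.** `debye_profile` evaluates
`I(q) = Σᵢⱼ sin(q dᵢⱼ)/(q dᵢⱼ)` over Cα beads (or all atoms) with uniform
unit form factors, `sinc(0) := 1`, so `I(0) = n²`. There is deliberately
no atomic form factor, excluded-volume or hydration-layer term: the
package's claims are comparative (rigid vs flexible, mixture composition
recovery), not absolute-intensity parity with full atomistic predictors,
and a uniform-bead Debye engine keeps every result reproducible from the
formula above. Profiles are exactly invariant under rigid motion of the
state.

**Guinier fit.** Linear fit of ln I against q² on the largest low-q
window satisfying q·Rg ≤ 1.3 (the standard validity rule), found by
iterating fit → recompute window from the fitted Rg until stable, starting
from the lowest 8 points; the window must keep at least 5 points and a
non-negative slope is an error (no Guinier regime). On the Debye profile
of a uniformly filled ball the fitted Rg lands within 2% of the model's
Rg (analytically `sqrt(3/5) R` for the continuum ball).

**Dimensionless Kratky.** `x = qRg`, `y = x² I(q)/I(0)`. An exact
Guinier curve peaks at `(sqrt(3), 3/e)` — the globular signature — and a
flat profile gives `y = x²`, the flexible limit. A caveat discovered while
validating on the generator: a *fully extended* multi-domain molecule is
rod-like, and rods also show elevated dimensionless Kratky amplitude, so
"low hinge angle vs high hinge angle" does not isolate flexibility in this
representation. The flexibility contrast the tests assert is the standard
one: a heterogeneous multi-domain ensemble keeps elevated amplitude past
the peak, while a rigid globular particle of comparable size decays.

**Chi.** `chi = sqrt( (1/M) Σ ((I_e − c·I_m)/σ)² )` with the scale `c`
solved in closed form; the model is linearly interpolated onto the
experimental grid and only overlapping points count. The 1/M convention is
declared because only relative comparisons are meaningful here. Chi is
invariant to rescaling the model. Experimental curves without an
uncertainty column get σ = 0.03·I by default (configurable), since chi is
undefined without uncertainties.

**Multistate selection.** `select_multistate` enumerates every subset of
the candidate pool up to `n_max` (≤ 5) states, restricted to pools of at
most 50 profiles — an exhaustive, deterministic, desk-scale analogue of
multistate SAXS fitting. Per subset the objective
`Σ((I_e − c Σ w_k I_k)/σ)²` with `w ≥ 0`, `Σw = 1` factorizes exactly
through `v = c·w`, so one nonnegative least-squares solve (an authored
Lawson–Hanson active-set solver) is the exact minimizer; the scale is
`Σv` and the weights `v/Σv`. Ties break deterministically toward smaller
subsets, then lexicographic label order, and the best chi is non-increasing
in the allowed ensemble size.

**Mixture identifiability.** Two-state weight recovery at 3% Gaussian
noise is only well-conditioned when the two component profiles are
shape-distinct and the curve is densely sampled. The validated recovery
scenario therefore mixes a fully extended conformer with a strongly bent
one (0.7/0.3), uses a beamline-like grid of 2000 points over
q = 0.005–0.45 Å⁻¹, and fills the pool with bent decoys; under those
conditions the true pair is selected and both weights land within 0.05
across independent noise realizations. With sparse grids (~100–500
points) or pools containing intermediate-compactness decoys the weights
are genuinely ill-identified at that noise level — a property of the
physics, not of the solver.

# Synapse image quantification

Per-contact quantification mirrors per-point violin plots: footprints are
segmented on a chosen channel (Otsu or fixed threshold), connected
components at least `min_area_um2` (default 1 µm²) become cells, and each
cell yields one row: Pearson correlation of the two channels over the
footprint pixels, background-subtracted mean levels, and area. A
correlation is reported as an error — never silently as 0 — when a channel
is constant within the mask, and masks need at least 10 pixels.

Background is the image minus all footprints dilated by 2 µm (configurable),
excluding the halo of spilled signal around each contact. Normalized
levels divide the background-subtracted mean by a reference scale, defined
as the per-batch median of the same quantity over an explicitly declared
reference condition; because any global gain multiplies both numerator and
reference, normalized levels are gain-invariant. The reference condition
is a required, explicit analysis choice — the package does not guess it.

No deconvolution, flat-field or bleed-through correction is applied, and
synapse phenotype classification is out of scope.

# The synthetic-data generator

`articulated_template` describes a chain of rigid bead domains — rods
(thin deterministic helices, never exactly collinear so rigid-body fits
stay well-posed) and blobs (deterministic Fibonacci-spiral ball fillings)
— linked by joints with a hinge half-angle κ and a twist half-range, with
landmark roles mapped onto beads. The TcE-like preset has four domains
(antigen blob, binder rod, Fc-like blob, second binder rod; radii
2–2.5 nm), three joints defaulting to 30°, and spans up to ~17 nm fully
extended, so anchor spacings fall in the 12–17 nm range where the
close-contact comparison lives.

`sample_conformations` draws each state by sampling per-joint hinge angles
uniformly in [−κ, κ] and twists in the twist range, rigid-propagating
domains down the chain. When the per-call κ override is given it sets
*both* the hinge half-angle and the twist half-range, so κ = 0 yields
bit-identical states (the rigid limit) and the flexibility ordering is
monotone in κ. Weights are uniform by default ("no information"
ensembles) or symmetric-Dirichlet to exercise the weighted statistics.
Everything is reproducible bit-exactly from (template, n, κ, seed), and
the caller's RNG stream is never disturbed.

Sampled coordinates are quantized to 0.001 Å — the PDB ATOM record's
native precision — as the generator's final step, so the recorded ground
truth, the written multi-model PDB and the re-read ensemble agree exactly
and the write→read→measure round trip is lossless by construction.

What the generator does *not* emulate: linker energetics or sterics
(domains may clash), side chains, atomic form factors, realistic q-dependent
beamline noise, structured image background, or optical blur. Passing
tests therefore demonstrate the correctness and internal consistency of
the estimators on articulated rigid-body data — not predictive accuracy on
experimental ensembles.

`simulate_saxs_experiment` mixes per-component Debye profiles by fraction
and adds Gaussian noise with σ(q) = noise_fraction·I(q), writing that σ
into the uncertainty column so the true mixture has chi ≈ 1 by
construction; a noiseless simulation carries a nominal 1% σ column so chi
remains finite and scale fitting stays well-posed. `synth_synapse_image`
plants non-overlapping circular contacts in three channels (a uniform
`ref` footprint channel for segmentation plus the two quantified channels)
with colocalized, segregated (complementary azimuthal domains) or excluded
(channel B depleted where A is enriched) patterns, and Poisson photon
noise at a photon scale set by the requested peak SNR.

# Problem sizes and runtimes

The shipped tests run the geometry and flexibility oracles on 200-state
ensembles, the κ-monotonicity checks on 100-state ensembles over 20 seeds,
SAXS analytics on 800-bead ball models and 2000-point grids, and imaging
checks on 256–512 px images with 6–12 contacts — sizes chosen so the whole
suite completes in about two minutes on one CPU while still exercising
every estimator well inside its asymptotic regime.

# Known limitations

- The Debye engine is comparative, not an absolute-intensity predictor;
  chi values are meaningful only relative to one another.
- Exhaustive subset selection is limited to pools of 50; larger pools
  must be pruned upstream.
- Rotational flexibility assumes matched domain atom counts across states
  (rigid-body states), and its mean orientation degenerates for antipodal
  (±90°) two-state ensembles.
- Tilt angles use the longest principal axis; near-spherical domains are
  flagged rather than measured.
- mmCIF input, chain/domain inference from sequence, P(r) inversion,
  hydration-layer modeling and synapse phenotype classification are out
  of scope.
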