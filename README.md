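# spanflex

Weighted multistate-ensemble geometry, coarse-grained SAXS analysis and
synapse-image quantification for bispecific T cell engagers (TcEs) and
other articulated multi-domain molecules.

## What it is for

A TcE crosslinks CD3ε on a T cell with a tumor antigen (e.g. Her2), and
its potency tracks geometric properties of the ternary antigen–TcE–antigen
assembly in solution: the spacing between the two paratopes, the spacing
between the membrane-anchor points of the two antigen ectodomains (a proxy
for the intermembrane gap, judged against the ~13 nm "close contact" span
of CD2–CD58), and the flexibility of the assembly. Solution SAXS
constrains these through multistate models — sets of conformations with
fractional weights `w_i` whose mixed scattering fits one experimental
curve. spanflex is for the structural bioinformatician analyzing such
ensembles, end to end:

- **Ensemble I/O** — multistate ensembles from PDB files or one
  multi-model PDB plus a state-weight table; YAML annotations naming the
  landmark selections (paratope tips, anchors, superposition reference,
  tilt axis, domains); 3-column SAXS curves; CSV reports.
- **Geometry** — Kabsch superposition on a reference subcomplex; weighted
  spacing distributions `d_i = |c(A)_i − c(B)_i|` with weighted medians
  and quartiles; domain tilt-angle distributions about the antigen–binder
  axis.
- **Flexibility** — weighted Rg distributions; per-domain CoM flexibility
  `sqrt(Σ w_i |c_i − c̄|²)`; rotational flexibility (weighted RMS rotation
  angle about the quaternion-mean orientation); their product, the
  effective disorder, plus the Shannon entropy `−Σ w_i ln w_i` of the
  weights.
- **SAXS** — Debye profiles `I(q) = Σ_ij sin(q d_ij)/(q d_ij)` on Cα
  beads; iterative Guinier fits (q·Rg ≤ 1.3); dimensionless Kratky curves
  `(qRg)² I(q)/I(0)`; chi goodness of fit with closed-form scaling;
  exhaustive small-pool multistate selection with nonnegative weight
  fitting.
- **Imaging** — footprint segmentation, per-contact Pearson
  colocalization, background-subtracted and reference-normalized signal
  levels for two-channel membrane-interface images (TIFF).
- **Synthetic data** — articulated bead-model ensembles, SAXS mixtures and
  synapse images with exact ground truth, so the whole pipeline is
  testable offline.

## Worked example

Generate a 100-state TcE-like ensemble at hinge flexibility κ = 30°,
measure the anchor-to-anchor spacing, and compute the flexibility report:

```r
library(spanflex)
tm  <- tce_template()
sim <- sample_conformations(tm, n_states = 100, seed = 1, kappa = 30)

summary(spacing_distribution(sim$ensemble, sim$annotation,
                             "anchor_1", "anchor_2"))
#>    min     q1 median     q3    max
#>   14.6   15.9   16.1   16.3   16.4        # nm

aligned <- superpose_states(sim$ensemble, sim$annotation)$ensemble
flexibility_report(aligned, sim$annotation)
#> flexibility report
#>  Rg (nm):
#>    min     q1 median     q3    max
#> 4.7936 4.9545 4.9862 5.0288 5.0657
#>  per-domain:
#>            domain com_flex_nm rot_flex_deg effective_disorder
#>          antigen1     0.02628         7.13             0.1874
#>           binder1     0.08761        20.12             1.7630
#>                fc     1.11496        32.99            36.7863
#>           binder2     2.80653        39.96           112.1409
#>  (whole molecule)     0.70634        17.55            12.3992
#>  weight entropy: 4.6052 nats
```

The anchor spacing distribution is read against the ~13 nm close-contact
threshold; the per-domain rows show how translational (nm) and rotational
(degrees) disorder accumulate toward the distal binder.

Recover a known 0.7/0.3 two-state mixture from a noisy (3%) simulated
SAXS curve against a 10-profile candidate pool:

```r
q   <- seq(0.005, 0.45, length.out = 2000)
mix <- simulate_saxs_experiment(tm,
  list(list(fraction = 0.7, kappa = 0), list(fraction = 0.3, kappa = 120)),
  q, noise_fraction = 0.03, seed = 1)
pool <- lapply(mix$states, debye_profile, q_grid = q)
names(pool) <- names(mix$components)
# ... add decoy conformer profiles, then:
select_multistate(pool, mix$experiment, n_max = 2)
#> multistate fit: best N = 2, chi = 1.038
#>   component_1          w = 0.6817
#>   component_2          w = 0.3183
```

Chi ≈ 1 means the fit explains the curve to within its uncertainties, and
the fitted weights recover the planted 0.7/0.3 composition.

Quantify a synthetic two-channel synapse image with segregated domains:

```r
si <- synth_synapse_image("segregated", n_cells = 5, snr = 15, seed = 1)
quantify_synapses(si$image, "A", "B", mask_channel = "ref", min_area_um2 = 2)
#>   cell pearson_r area_um2 level_A level_B
#> 1    1    -0.269     4.93    11.3    11.4
#> 2    2    -0.275     6.27    11.6    11.7
#> 3    3    -0.275    12.04    11.5    11.6
#> 4    4    -0.272     9.63    11.6    11.5
#> 5    5    -0.274    11.67    11.5    11.5
```

Negative per-contact Pearson r reflects the planted segregation of the
two channels; a colocalized pattern gives r close to +1.

A thin command-line front end over the same functions lives at
`inst/cli/spanflex.R` (subcommands `measure`, `flex`, `kratky`,
`fit-ensemble`, `coloc`, `simulate`).

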