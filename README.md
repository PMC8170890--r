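# helixkin

Coarse-grained kinetic models of helix–coil folding in blocked
polyalanine peptides.

`helixkin` is an R package for analyzing how short model helices
(Ac-(Ala)\_n-NH\_2, n ≈ 5–21) fold, starting from conformational
trajectories. It targets the standard analysis chain of peptide-folding
simulation studies: helicity metrics, relaxation-time analysis,
two-state thermodynamics, microstate Markov models, and kinetic
coarse-graining, together with a fully controlled synthetic generator
so that every estimator can be validated against exact ground truth.

## What it computes

**Helicity metrics.** Conformations are built from backbone dihedrals
by internal-coordinate chain extension. Helix content is measured two
ways: by the α-helical hydrogen bonds (C=O of residue *i* to N–H of
residue *i*+4, formed when the O…N distance is below 3.6 Å; the acetyl
and amide caps participate, giving *n* − 2 possible bonds), and by the
backbone dihedrals (a residue is helical when (φ, ψ) lies within 20°
of (−62°, −41°)).

**Two-state thermodynamics.** With helix fraction *f* at temperature
*T*, the folding free energy is

    ΔG = −RT ln( f / (1 − f) )

and the folding/unfolding rates follow the two-state decomposition
k_f = f/τ₂, k_u = (1 − f)/τ₂, where τ₂ = 1/(k_f + k_u) is the global
relaxation time obtained from biexponential fits to autocorrelation
functions of global features (RMSD from helix, radius of gyration,
hydrogen-bond count).

**Kinetic models.** Microstates come from CA-RMSD leader clustering;
the trajectory is discretized by transition-based core assignment
(core radii calibrated so the model's slowest implied timescale
matches τ₂ from the trajectory); a rate matrix **K** is estimated from
transition counts. PCCA+ lumps the microstates into N metastable
aggregates and an optimal reduced rate matrix **R** is fitted by
propagator matching under generator and detailed-balance constraints.
Aggregates are classified as helix / coil / intermediates, with
committor probabilities, lifetimes −1/R_ii, per-set free energies,
hydrogen-bond heat maps P(HBi, NHB) and neighbor-bond correlation
profiles describing the folding pathways.

**Synthetic ground truth.** A cooperative Zimm–Bragg chain
(propagation weight *s*, nucleation penalty *σ*) with single-flip
Metropolis kinetics generates per-residue helical indicator
trajectories, rendered to 3D coordinates. Its equilibrium is exactly
solvable by transfer matrix, so estimator output can be compared
against closed-form oracles.

## Worked example

```r
library(helixkin)

# simulate a cooperative helix-coil chain and fit a two-state model
sim <- helix_coil_simulate(8, s = 1.4618, sigma = 0.01,
                           t_total = 2000, dt = 0.5, seed = 42)
print(sim)
#> Helix-coil simulation: n = 8, s = 1.462, sigma = 0.01, 4001 frames (dt = 0.5 ns)
#>   sampled helicity 0.513 (transfer-matrix oracle 0.400)

traj <- render_helix_coil(sim)
fit <- fit_helix_kinetics(traj, cluster_radius = 2.5, n_states = 2)
print(fit)
#> Helix-folding kinetic model for ALA8
#>   N_c = 16 microstates -> N = 2 aggregate states
#>   tau2 (trajectory ACF) = 7.895 ns; slowest model time = 8.255 ns
#>   helix fraction f = 0.714, k_f = 0.0994 1/ns, k_u = 0.03972 1/ns
#>   folding free energy dG = -0.547 kcal/mol at 300 K

round(coef(fit), 4)
#>     k_f     k_u    tau2       f delta_g
#>  0.0994  0.0397  7.1880  0.7145 -0.5469
```

The fitted object reports: the relaxation time measured directly from
the trajectory ACF (7.9 ns) against the slowest implied timescale of
the microstate rate matrix (8.3 ns, matched by core-radius
calibration); the helix-aggregate population f; and the two-state
rates and folding free energy from the reduced 2×2 rate matrix. In
this realization the sampled helicity (0.513) sits above the infinite-
time transfer-matrix value (0.400), and the fitted ΔG is negative
accordingly — the helix macrostate of this cooperative chain includes
partly folded configurations, not just the mean per-residue helicity.

Structural metrics work standalone:

```r
spec <- peptide_spec(21)
helix <- build_conformation(spec, ideal_dihedrals(spec, "helix"))
count_helical_hbonds(helix)
#> [1] 19

free_energy_slope(data.frame(n = c(5, 8, 15, 21),
  delta_g = c(1.66, 1.77, 0.49, -0.69)))$slope
#> [1] -0.157        # kcal/mol per residue
```

`run_pipeline(analysis_config(...))` executes the whole chain from a
configuration (or YAML file) and writes an artifact bundle — feature
tables, cluster/core assignments, kinetic matrices, reduced model,
aggregate classification, committors, representative structures (PDB)
and a manifest — deterministically for a fixed seed.

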