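---
title: "Coarse-grained kinetics of helix-coil folding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained kinetics of helix-coil folding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixkin)
```

This vignette documents the models behind `helixkin`, the numerical
choices made where several defensible options existed, and what the
package's synthetic validation does and does not demonstrate about
real trajectory data.

## The system and its metrics

The package models blocked polyalanine peptides, Ac-(Ala)$_n$-NH$_2$.
Blocking matters for the bookkeeping: the acetyl carbonyl can accept
and the terminal amide nitrogen can donate an $i \to i+4$ hydrogen
bond, so an $n$-residue chain supports $n-2$ helical hydrogen bonds
(3, 6, 13 and 19 for $n$ = 5, 8, 15, 21) and all $n$ residues have
complete $(\varphi, \psi)$ pairs.

Two helicity measures are implemented, and they deliberately probe
different things:

* **HB** — a hydrogen bond at position $i$ is formed when the O…N
  distance is below 3.6 Å. A single sharp cutoff is used, with no
  hysteresis or angular term: the indicator must be reproducible from
  coordinates alone, and the O…N criterion makes the placement of the
  amide hydrogens irrelevant (either terminal NH$_2$ hydrogen may face
  the acceptor).
* **PP** — a residue is helical when $\varphi$ and $\psi$ are both
  within 20° of $(-62°, -41°)$.

Conformations are built from internal coordinates by chain extension
(NeRF placement) with standard peptide geometry: N–CA 1.458 Å,
CA–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å, N–H 1.010 Å; angles
N–CA–C 111.0°, CA–C–N 116.2°, C–N–CA 121.7°; trans peptide bonds.
Building an ideal helix with these values places every O…N contact at
3.19 Å — comfortably inside the 3.6 Å cutoff but not near-degenerate
with it — and re-measuring dihedrals from built coordinates returns
the inputs to ~10⁻¹³ degrees, so the 0.5° round-trip tolerance in the
tests is loose by design, not by necessity. For the "extended"
reference state the package uses $(-140°, 150°)$, a generic
β-region value. CB atoms are built (standard tetrahedral geometry)
but excluded from RMSD, which is CA-only; the radius of gyration is
unweighted over heavy atoms — for an alanine homopeptide, mass
weighting would change it negligibly.

## Relaxation times

Global relaxation is measured from autocorrelation functions of
per-frame features (CA RMSD from the ideal helix by default). The ACF
estimator is the biased one (normalizing by the full frame count),
which trades a small systematic underestimate at large lags for much
lower variance — the standard choice when the tail is fed to a fit.
The ACF is fitted to $a_1 e^{-t/\tau_{fast}} + a_2 e^{-t/\tau_{slow}}$
by Levenberg–Marquardt least squares over a deterministic multi-start
grid of timescale pairs (six logarithmically spaced decades, all
ordered pairs), with ties broken by residual and then by the smaller
$\tau_{slow}$, so the fit is reproducible without randomness.

Two guards keep the reported global time meaningful:

* the fit window ends at the first crossing of 0.02 — beyond that the
  biased estimator's tail is mostly noise;
* timescales are bounded above by ten times the fit window, and a
  component with amplitude below 0.05 is not eligible to be reported
  as $\tau_{slow}$. Without these, white-noise tails are occasionally
  fitted as a near-zero-amplitude component with an enormous
  timescale, which would silently corrupt everything downstream that
  consumes $\tau_2$.

On telegraph (two-state jump) signals with rates $k_1, k_2$, whose
exact ACF is $e^{-(k_1+k_2)t}$, the fitted $\tau_{slow}$ recovers
$1/(k_1+k_2)$ within the sampling tolerance of the test suite.

## Two-state thermodynamics

With helix fraction $f$ at temperature $T$ (300 K throughout, with
$R$ = 1.9872×10⁻³ kcal/(mol K)),

$$\Delta G = -RT \ln \frac{f}{1-f}, \qquad
  k_f = f/\tau_2, \qquad k_u = (1-f)/\tau_2 .$$

The rate decomposition is the unique one satisfying both two-state
identities $k_f + k_u = 1/\tau_2$ and $k_f/k_u = f/(1-f)$; the
algebraic round trip $f \to (k_f, k_u) \to f$ is exact and tested to
machine precision. The per-residue stability increment is
$\Delta G/\Delta n = \Delta H/\Delta n - T\,\Delta S/\Delta n$, and
the length trend of $\Delta G$ is summarized by an ordinary
least-squares slope.

## Microstate kinetic models

**Clustering.** Microstates are defined by single-pass leader
(threshold) clustering in frame order under CA RMSD with Kabsch
superposition: a frame farther than the radius from every existing
center founds a new cluster; final assignments are nearest-center.
This is deterministic, order-respecting, and its centers are real
frames, which downstream stages reuse as representative structures.

**Core discretization.** Transition counting uses microstate *cores*:
a frame is labeled only within the core radius $R_c$ of a center;
frames in transit inherit the last visited core (frames before the
first entry are back-filled from it). This suppresses fast recrossing
at cluster boundaries, which otherwise contaminates the slow spectrum.
$R_c$ is calibrated on a small grid so that the model's slowest
implied timescale matches the ACF-derived $\tau_2$; the achieved
timescale typically grows with $R_c$, but on sampled data this
monotonicity can fail, so violations warn rather than abort.

**Rate matrix.** Counts are symmetrized, $(C + C^\top)/2$, enforcing
detailed balance (the trajectories are sampled at equilibrium, and a
real spectrum is needed by everything downstream), and the generator
is estimated as $K = (T - I)/\tau_{lag}$ on the largest connected
state set. This linearization slightly biases timescales that are not
much longer than the lag — the matrix logarithm would remove the bias
but introduces branch and negative-rate pathologies — so implied
timescales can also be read from the transition matrix as
$-\tau_{lag}/\ln\lambda$, which is what the recovery tests use.

## Coarse-graining

**PCCA+.** Metastable aggregates come from the simplex structure of
the top-$N$ right eigenvectors of the reversible generator.
Determinism is pinned down explicitly: eigenvectors are sorted by
eigenvalue, sign-fixed (first element positive), and simplex vertices
are selected by the standard farthest-point rule with lowest-index
tie-breaks. Memberships are clipped to $[0,1]$ and row-normalized;
crisp assignments take the row argmax.

**Optimal reduced rate matrix.** The reduced $N \times N$ generator
$R$ minimizes, over a set of lag times, the stationary-weighted squared
deviation between the population-aggregated full propagator
$A\,e^{Kt}\,B$ and the reduced propagator $e^{Rt}$. Design choices:

* optimization is over the logarithms of the symmetric exchange
  fluxes $F_{IJ} = \Pi_I R_{IJ}$, which gives positivity and detailed
  balance for free and pins the aggregate populations to the lumped
  stationary distribution;
* the lag set defaults to $\{1, 2, 5, 10, 20, 50\}$ times the shortest
  mean residence time of the full model, covering both the fast
  intra-aggregate plateau and the slow exchange regime;
* initialization is the naive lumped generator
  $R^0_{IJ} = \sum_{i \in I, j \in J} \pi_i K_{ij} / \Pi_I$, which is
  already exact for lumpable systems.

On an exactly lumpable two-block generator the fit returns the
analytic lumped rates to 10⁻⁶; on a 9-state metastable chain the two
slowest reduced relaxation times reproduce the full spectrum within a
few percent (the suite enforces 30%). When reduced times deviate from
the full model by more than 50% — the signature of an inconsistent
high-resolution discretization — the model is flagged with a warning
rather than rejected, since the object is still useful for diagnosis.

**Classification.** The helix aggregate is the one whose
representative structure (center of the most populated member cluster,
lowest index on ties) lies closest to the ideal helix, with the formed
hydrogen-bond count breaking ties; the coil is the set with the most
member clusters among the remainder — the coil basin is always the
structurally broadest — and anything left is an intermediate. Under
this rule the helix and coil criteria cannot select the same set; the
degenerate-model error can only arise with fewer than two aggregates.

**Pathways.** Committors solve $K q = 0$ on the interior with $q = 1$
on the helix and $q = 0$ on the coil microstates (residuals are
checked to 10⁻⁸; on 1-D chains $q$ is provably monotone and the tests
verify this). Transition-state candidates are interior states with
$q$ in a window (default $[0.4, 0.6]$), ranked by $|q - 0.5|$; an
empty result is legitimate — very short chains need not resolve
transition-state-like microstates. Helix initiation statistics come
from the NHB = 1 row of the heat map $P(\mathrm{HB}_i, \mathrm{NHB})$,
with a terminal-versus-interior contrast statistic; heat-map rows with
no frames are reported as missing, never as zero.

## The synthetic generator

The generator is a Zimm–Bragg chain: configuration weight
$s^{h} \sigma^{\text{segments}}$ with propagation weight $s$ and
nucleation penalty $\sigma$, equilibrium solved exactly by transfer
matrix. Kinetics are continuous-time single-residue flips with
Metropolis rates at attempt frequency $\nu$ (default 1/ns), which
satisfy detailed balance with respect to the Zimm–Bragg measure; the
initial configuration is drawn exactly from equilibrium by
forward-filtering backward-sampling, so trajectories are stationary
from the first frame. Rendering maps helical residues to
$(-62°, -41°)$ with 3° Gaussian jitter and coil residues to an
equal-weight mixture of extended $(-140°, 150°)$ and PPII
$(-75°, 150°)$ basins with 10° jitter — enough noise to be
non-trivial for RMSD clustering while keeping the dihedral helicity
window (±20°) essentially error-free. Turn-like coil conformers are
deliberately omitted so the equilibrium oracle stays exact.

The packaged parameter preset ($s = 1.2395$, $\sigma = 0.004854$) was
calibrated once, against the transfer matrix, to reproduce the
qualitative length trend of the study system — mean helicity ≈ 6% at
$n = 5$ rising to ≈ 60% at $n = 21$; it is a statistical emulation
target, not a force-field claim. The validation suite additionally
uses a cooperative $n = 8$ setting ($s = 1.4618$, $\sigma = 0.01$,
mean helicity 40%), whose strong nucleation penalty produces the
two-state-like kinetics the estimators are meant to resolve.

## What the validation shows — and what it does not

The end-to-end test simulates the $n = 8$ cooperative chain (6 µs at
0.5 ns sampling), renders it to coordinates, and pushes it through
featurization, clustering (radius 2.5 Å, giving $N_c \approx 20$
microstates), core calibration, rate estimation, PCCA+ and the ODR
fit with $N = 2$. The recovered folding free energy is compared with
exact ground truth obtained by enumerating the generator's full
master equation over all $2^8$ configurations and lumping it at its
kinetic barrier; the suite requires agreement within 0.3 kcal/mol. A caution this exercise makes explicit: for a
nucleation-limited chain the kinetic helix macrostate includes partly
folded configurations, so its population is *not* the mean per-residue
helicity — two-state $\Delta G$ values from content-based and from
kinetic definitions of "helix" answer different questions.

Problem sizes throughout the suite (10⁵–10⁶ jump-process samples,
10³–10⁴ rendered frames, $n \le 21$ builders) were chosen as the
smallest at which the statistical tolerances above are comfortably
resolved. What passing does not show: the generator has no solvent,
no turns, no helix-turn-helix motifs, and its coil is memoryless
between frames, so real-trajectory phenomena — multiple intermediates,
slow non-Markovian memory, force-field-dependent helicities — are
outside what these tests can certify. The package's estimators are
validated as estimators; their scientific output on real data is only
as good as the trajectories fed to them.

## Known limitations

* The generator estimate $K = (T-I)/\tau_{lag}$ biases timescales of
  order the lag; use transition-matrix implied timescales when that
  matters.
* ODR fits use crisp memberships; fuzzy-membership reduction is not
  implemented.
* Committors are computed on the microstate rate matrix, not the
  reduced model, and assume a connected interior.
* The moving-block bootstrap behind the hydrogen-bond population
  confidence intervals uses a block of ten times the estimated
  relaxation time of the total bond count; severely undersampled
  trajectories will understate the intervals like any bootstrap.
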