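---
title: "Chain flexibility and lipid-droplet partitioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain flexibility and lipid-droplet partitioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ldflex)
```

# The scientific question

Lipid droplets (LDs) are phase-separated organelles: a neutral-lipid core of
triacylglycerols (TAGs) wrapped in a phospholipid monolayer. A lipophilic
molecule approaching an LD from the cytosol crosses two boundaries — the
water-to-phospholipid interface (Interface I) and the phospholipid-to-TAG
interface (Interface II). `ldflex` implements a desk-scale computational
pipeline for studying how the *chain flexibility* of the migrating molecule
decides what happens at Interface II: a worm-like flexible chain (a squalene
analog) threads through the monolayer tails and dissolves in the TAG core,
while a rod-like rigid chain (a carotenoid analog) stalls at the
phospholipid-TAG boundary and accumulates at the surface. The corresponding
cell-scale prediction — flexible products scale with total LD **volume**,
rigid products with net LD **surface area** — is handled by the morphometry
module on per-cell droplet statistics.

The package has two halves that meet in the storage-scaling analysis:

1. a coarse-grained (CG) bead-spring simulator of the monolayer/TAG slab with
   Langevin dynamics, collective variables, well-tempered multiwalker
   metadynamics, and steered constant-force pulls for friction estimation;
2. tidy morphometry of per-cell LD measurements (sphere geometry, percent
   changes, rank-correlation storage-scaling classification) plus
   seed-deterministic synthetic-data generators for every input the pipeline
   consumes.

# The coarse-grained model

## Reduced units and mapping

Everything runs in reduced Lennard-Jones units: bead diameter
$\sigma = 1$, bead mass $m = 1$, well depth $\epsilon = 1$, $k_B = 1$, so the
reduced temperature $T = 1$ plays the role of 300 K. One physical anchor maps
lengths: the rigid solute's contour length (6.79 $\sigma$ with the default
8-bead chain) is identified with 2.4 nm, the end-to-end length of a rod-like
carotenoid, giving $\sigma \approx 0.35$ nm; `unit_map()` exposes the
conversion. The energy scale follows from the temperature anchor
($\epsilon = k_B \cdot 300\,\mathrm{K} \approx 0.60$ kcal/mol). This is an
illustrative mapping, not a parameterization: no all-atom force field stands
behind the beads, and none of the all-atom observables (barrier heights in
kcal/mol, nanosecond time scales) should be read off quantitatively.

## Molecules

* **Phospholipid**: one polar head bead and two semi-flexible apolar tails
  (default 4 beads each; bond $k = 100$, $r_0 = 0.97\sigma$; bending
  $k_\theta = 5$ toward straight). The paired tails align roughly in
  parallel in an assembled monolayer.
* **TAG**: an apolar hub carrying three floppy tails ($k_\theta = 2$), so a
  TAG melt is polymer-melt-like with intertwined chains; all beads apolar.
* **Solutes**: linear chains with declared end beads.
  The *flexible* chain uses weak bending ($k_\theta = 1$) and torsion
  ($k_\phi = 0.04$): its end-to-end distance $R_{ee}$ fluctuates over a broad
  range (relative SD well above 10%). The *rigid* chain uses stiff bonds
  ($k_b = 1000$), bending $k_\theta = 200$ and torsion $k_\phi = 2$ — at
  least 50 times the flexible stiffness term for term — and holds $R_{ee}$
  at the contour length within about 1% relative SD. Stiff bonds matter as
  much as stiff angles here: with $k_b = 100$ the longitudinal bond noise
  alone contributes ~4% relative SD, which would blur the rigid/flexible
  contrast. Rigid chains also use a *wider* bead ($\sigma_R = 1.3$): a
  conjugated, ring-bearing rod-like lipid is genuinely thicker in cross
  section than a thin isoprenoid chain, and that bulk is part of why rods
  pay more drag in a packed melt. The flexible chain keeps $\sigma = 1$.
  `rigid_polar` adds polar terminal beads (a hydroxylated-carotenoid
  analog); it is off the default path because the effect of the terminal
  hydroxyls on monolayer trapping is an open question in the underlying
  biology.

## Interactions

Nonbonded pairs use Lorentz-Berthelot combination with two deliberate
asymmetries that encode the hydrophobic physics:

* polar-apolar cross pairs are scaled by 0.3 **and** truncated at the LJ
  minimum (WCA, repulsive-only). Head groups and solvent are therefore
  expelled from the oil phase rather than weakly dissolved in it; without
  this the heads slowly mix into the TAG core in implicit-solvent runs.
* phospholipid tail beads carry $\epsilon = 0.6$ versus 1.0 for TAG beads.
  An apolar solute thus sees an enthalpic funnel: solvent (penalized) →
  monolayer tails (cohesion 0.6) → TAG core (cohesion 1.0). This is the CG
  statement that the ordered tail brush is a poorer solvent environment
  than the isotropic melt.

Attractive pairs are truncated and shifted at $2.0\sigma$ (a compromise
between capturing the cohesive well and neighbor-list cost at desk scale);
WCA pairs end at $2^{1/6}\sigma$.

Torsion terms use the cosine form $k(1 + \cos(n\phi - \phi_0))$. Because the
torsion angle is ill-conditioned for near-collinear chains (its gradient
diverges as the flanking angles straighten), the term is tapered smoothly to
zero inside ~10 degrees of collinearity (smoothstep on $\sin^2\theta$ of the
flanking angles). Away from the taper band forces are exact negative
gradients of the energy, which is what the finite-difference property tests
assert; inside the band the taper keeps forces bounded at the cost of a
small, thermostat-absorbed non-conservative correction. For the rigid rod
the torsions are effectively dormant (the rod lives inside the taper band)
and its rigidity is carried by the bond and angle terms.

## Solvent: explicit beads or an implicit solvophobic field

The spec-level solvent model is a single polar bead (attractive to itself
and heads, WCA toward all apolar beads). The default desk configuration
instead runs **implicit** solvent: a Langevin bath above the monolayers plus
a smooth solvophobic field — apolar beads pay an energy `eps = 4`
(in $k_BT$) per bead, switched on over $w = 0.5\sigma$ above the upper (and
below the lower) head plane. The field is the implicit-solvent stand-in for
the hydrophobic driving force that expels lipophilic molecules from water
and captures them at Interface I; it acts on phospholipid tails too, which
stabilizes the monolayer. Soft reflective walls ($k = 10$) bound the slab in
z. Because the TAG core relaxes toward its equilibrium density during
thermalization and the monolayers ride on it, `calibrate_slab_references()`
re-anchors the field and walls to the relaxed head planes before production
— a stale reference would leave a penalty-free gap above the monolayer.

## Integration

BAOAB Langevin splitting at `dt = 0.005`, single-threaded, with a
counter-seeded RNG so every trajectory is bit-reproducible from its seed.
Center-of-mass momentum is removed every 1000 steps in thermostatted runs.
Nonbonded evaluation uses a Verlet neighbor list (skin $0.45\sigma$) built
by cell binning and rebuilt on a max-displacement criterion; between
rebuilds positions evolve unwrapped and each pair carries its frozen
periodic-image shift, which is what makes intramolecular distances
(end-to-end vectors) exact even for chains longer than half the box.

# Collective variables

For a tracked solute the engine streams:

* **migration depth z**: mass-weighted solute COM z minus the instantaneous
  mean head-bead z of the proximal leaflet (recomputed every frame — the
  monolayer breathes). Negative is into the LD core. The proximal-leaflet
  choice (rather than averaging both leaflets) is a documented convention.
* **end-to-end distance** $R_{ee}$ and its z-component $z_{ee}$, measured
  along the contiguous chain so periodic wrapping never folds the vector.
* **conformation order** $\mu = |z_{ee}| / R_{ee} \in [0, 1]$. The absolute
  value makes $\mu$ invariant under head-to-tail relabeling of a symmetric
  chain; the 2D free-energy landscapes are displayed on this $[0,1]$ range.
* **orientation angle** $\theta = \arccos\mu$ in degrees.

# Metadynamics

Well-tempered metadynamics over (z, $\mu$) or any subset: every `pace`
steps a Gaussian hill of height
$\omega_0 e^{-V(s)/(k_B T(\gamma_{wt} - 1))}$ is deposited, so heights decay
at revisited centers and the estimator
$F(s) = -\frac{\gamma_{wt}}{\gamma_{wt} - 1} V(s)$ converges. Defaults
($\omega_0 = 0.5\,k_BT$, $\sigma_z = 0.25$, $\sigma_\mu = 0.05$,
pace 500, $\gamma_{wt} = 10$, grid $120 \times 60$ over
$z \in [-8, 4]$, $\mu \in [0, 1]$) are desk-slab choices: the source study
reports the method (six replica walkers, well-tempered) but none of the hill
parameters, so these are tuned for the CG system and documented here, not
inherited. The bias is kept on a grid (values plus analytic gradients,
updated locally per hill, truncated at $6\sigma$) and interpolated
bilinearly for the bias force; the gridded values agree with direct
Gaussian summation to better than $10^{-6}$, which is a standing test.
Bias forces reach the beads by the chain rule: the z gradient is spread
mass-weighted over the solute beads (the moving head-plane reference is
deliberately not differentiated), and the $\mu$ gradient acts on the two
end beads. Reflective containment walls in CV space catch excursions past
the grid edge and are logged.

Multiwalker runs execute walkers sequentially in sync intervals; each
interval's new hills are merged time-ordered and the merged grid is
broadcast, so the final surface is invariant to walker ordering. Whether
walkers should share bias continuously or at intervals is not prescribed by
the source method description; interval sync is the documented choice here.

Barriers are extracted by a minimax-path estimate (rising-threshold flood
fill between basins) minus the basin minimum. The calibration route for the
whole stack is the analytic overdamped double well
$U(x) = h[(x/a)^2 - 1]^2$ with $h = 4\,k_BT$: the recovered barrier is
within 10% of $h$ across seeds, and a separable 2D well projects onto
marginals consistent with 1D runs (Boltzmann-weighted marginalization).

# Steered pulls and friction

In a neat TAG melt (60 molecules at desk scale, fully periodic, standing in
for the reference 745-molecule layer) a constant force is applied to the
solute COM, mass-weighted over its beads, and increased stepwise per
interval until the COM displacement along the pull fits a line with
$R^2 \ge 0.98$ after discarding the first 25% of the interval and moves at
least the minimum displacement. The friction coefficient is
$\zeta = F/(m v)$ with $v$ the fitted drift velocity. $\zeta$ is reported
positive: with $v$ measured along the force the minus sign of the
force-balance form is a convention, not physics. The estimator is validated
against a free bead in a Langevin bath, where $v = F/(m\gamma_L)$ exactly;
during melt pulls the bath's $\gamma_L$ is set to 0.1, an order of magnitude
below the measured melt friction, so the thermostat does not mask the medium.

The flexibility contrast in the melt is probed at moderate force in a
denser melt (bead density 0.9) with the drift velocity averaged over three
orthogonal pull directions per melt realization; at strong driving a rigid
rod aligns with the pull and gliding along its own axis hides the
free-volume penalty, and single-direction estimates are noisy because the
drift over one interval is comparable to the diffusive wander. The package
asserts the *ordering* (median $\zeta_{rigid} > \zeta_{flexible}$, one-sided
signed-rank test on seed-paired melts), not the all-atom factor of two,
which is outside what this CG resolution can promise. With same-size beads
for both solutes the ordering is genuinely marginal in a generic
bead-spring melt — monomeric friction dominates and is identical by
construction; the rod's wider beads (its real cross-section) are what carry
the penalty.

# The migration experiment

`migration_run()` packages the unrestrained-migration analog: assemble the
slab, thermalize, recalibrate references, insert the solute flat in the
cytosol region $2\sigma$ above the upper head plane, and integrate with CV
streaming. The reported `final_depth` is the median migration depth over the
last tenth of the run, and `interface_boundary()` reports the
phospholipid-TAG boundary as the mean depth of the terminal phospholipid
tail beads of the upper leaflet. The expected phenotype, asserted across
seeds: the flexible chain's final depth lies below the boundary (it crosses
Interface II into the core) while the rigid rod's sits at or above it
(trapped at the boundary). Two honest caveats: at desk scale the TAG core
(~6 $\sigma$ thick in the test configuration) is *thinner than the rod is
long*, so the rod's trapping is partly geometric confinement on top of the
packing/entropy argument; and run lengths are far below anything resembling
the 500-ns all-atom regime, so only the ordering of outcomes — not rates or
depths in physical units — carries meaning.

# Morphometry and storage scaling

Droplets are treated as spheres. With per-cell diameters the per-cell total
volume is $\sum_i \frac{\pi}{6} d_i^3$ and net surface $\sum_i \pi d_i^2$,
averaged over cells; with only summary rows (count $N$, mean diameter
$D_{avg}$) the mean-diameter approximation $N \frac{\pi}{6} D_{avg}^3$ /
$N \pi D_{avg}^2$ is used and flagged, because $E[d^3] \ge E[d]^3$ makes it
an underestimate for dispersed populations — this is exactly why a
recomputed total volume from printed summary values can undershoot a
printed per-cell volume by a few percent. Percent changes are reported
exactly, with a display-style rounding helper (nearest 10% above 1000%,
nearest 1% below) mirroring how such numbers are usually quoted.

Storage scaling across strains uses Spearman rank correlation of a lipid's
titers with total volume and with net surface area, classifying
volume-scaled / surface-scaled when the correlations differ by more than a
0.1 margin and indeterminate otherwise (or with fewer than 3 strains). With
3-6 strains a rank statistic is the honest choice; the margin guards
against calling a winner on ties. Uncertainty for n-of-6-cells statistics
comes from a seed-deterministic percentile bootstrap.

# Synthetic data

Per-cell droplet populations are modeled as Poisson counts (over-dispersion
available via a negative-binomial switch, off by default) and lognormal
diameters (default geometric SD 1.25): LD size distributions are
right-skewed and strictly positive, and a single per-strain lognormal is
assumed because the within/between-cell variance split is not reported
anywhere usable. Strain presets: wild type λ = 23, median 0.20 µm; a
large-droplet strain λ = 16, median 0.33 µm; a many-droplet strain
λ = 51.67, median 0.20 µm. Titer replicates are Gaussians truncated at
zero around the printed 144-h means (squalene 0.43 / 13.93 mg/L;
zeaxanthin 1.27 / 2.16 / 2.85 mg/L), three replicates per condition; the
many-droplet strain's squalene titer is not printed as a number, so the
preset carries a synthetic intermediate (1.00 mg/L) consistent with the
reported ordering and flags it as synthetic. The round-trip property —
morphometry on generated tables recovers the generating count mean and
diameter median within 5% at 200 cells — is a standing test. What passing
these tests does *not* show: anything about segmentation error, optical
resolution limits on ~0.2-µm droplets, or real biological covariance
between droplet count and size; the generator emulates the statistical
shape of the measurements, not the microscope.

# Problem sizes and numerical choices

Test-scale systems are deliberately small: a mini slab of 32 phospholipids
per leaflet with 3-bead tails over a 36-TAG core (~800 beads), 60-TAG melts
for pulls, 4.5x10^4-step migration runs, 4x10^5-step toy-metadynamics
runs.
The full-size desk preset (64 phospholipids per leaflet, 140 TAGs — the
reference composition scaled by four) remains available through
`desk_config()`. Degenerate inputs are handled explicitly: zero-hill biases
refuse FES reconstruction, zero-force pulls refuse drift detection,
R_ee = 0 refuses the conformation order, empty leaflets refuse depth
references, diverging integrations abort with the offending step. Ties in
the storage-scaling classification fall to "indeterminate" by construction.

# Known limitations

* The CG force field is designed, not derived: bead counts, stiffnesses and
  the 0.6/1.0 tail/TAG cohesion split are modeling choices that produce the
  qualitative flexibility physics; none of the all-atom numbers (the ~12
  and ~9 kcal/mol Interface-II barriers, the >12 kcal/mol Interface-I drop,
  the exact twofold friction ratio) are reproduced or asserted at this
  scale, and the package states this rather than pretending otherwise.
* Implicit-solvent capture dynamics are faster and cruder than explicit
  hydration; the explicit-solvent switch exists but costs ~40% more beads.
* The monolayer at desk scale is a loose brush (2.4 sigma^2 per lipid), not
  a tension-controlled membrane; there is no barostat by design.
* Friction estimates at strong driving are shear-thinned and
  orientation-biased; only the low-force protocol supports the
  rigid-vs-flexible ordering claim.
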