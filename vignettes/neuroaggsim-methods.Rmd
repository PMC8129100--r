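---
title: "Modelling neuron-astrocyte aggregation and sorting in confined 3D cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neuron-astrocyte aggregation and sorting in confined 3D cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroaggsim)
```

## The biological problem

Dissociated cortical neurons and astrocytes seeded densely into a confined
channel (a PDMS slit on a poly-D-lysine substrate) self-assemble over days
into a contracted three-dimensional culture with two striking features:
periodic neuron-dense clusters along the channel axis, and an
astrocyte-rich superficial sheath reminiscent of a glial scar. `neuroaggsim`
implements a phenomenological point-cell model of this process together
with the morphometric and activity-analysis procedures used to quantify
such cultures, and seeded synthetic-data generators so that every analysis
path is testable without microscope or electrode data.

## The aggregation model

Each cell is a point in 3D. Between two cells at Euclidean distance $d$ a
type-weighted attraction and a type-independent repulsion act along the
line joining them, each a single exponential parameterised by its strength
and the distance at which it has decayed to 1% of that strength:

$$ a(d) = A\,0.01^{d/\tau_a}, \qquad r(d) = R\,0.01^{d/\tau_r}. $$

The attraction felt by cell $i$ from cell $j$ is scaled by a constant
$AS_{ij}$ that depends on the ordered type pair (neuron-neuron,
neuron-astrocyte, astrocyte-neuron, astrocyte-astrocyte): the differential
adhesion that drives sorting. Substrate adhesion uses the same form
($S$, $\tau_s$) toward fixed random anchor points on the floor, and a
constant gravity displacement $g$ acts downward. With
$\tau_a > \tau_r$ and $R > A_{\mathrm{eff}}$ the pairwise net force
vanishes at a single *force equilibrium point*

$$ d^\ast = \frac{\ln(R/A_{\mathrm{eff}})}{\ln(0.01)\,
            (1/\tau_a - 1/\tau_r)}, $$

which sets the characteristic cell-to-cell spacing of the aggregated
culture; `equilibrium_distance()` and `repulsion_for_equilibrium()` are
exact inverses of each other, a property the test suite checks against a
brute-force sign-change scan of the force curve.

Movement is overdamped: each step every cell is displaced by $k\,F$, where
$F$ sums all pairwise and anchor forces, plus $-g$ in $z$. The movement
freedom $k(t)$ falls logistically from 1 toward 0
(`movement_freedom()`), reaching $1/2$ at the stiffening delay — a
phenomenological stand-in for maturation-driven tissue stiffening that
freezes the culture near the end of the run. Two published parameter sets
are shipped as presets (`force_preset("initial")` /
`force_preset("optimized")`); they differ only in $\tau_r$ (140 vs
200 um) and neither is re-fit here.

```{r presets}
force_preset("optimized")
equilibrium_distance(1, 320, 2.27, 200)
```

### Numerical choices

* The printed per-axis force expressions are not rotation-invariant (their
  exponent diverges for one sign of the coordinate difference), so the
  decay is applied to the Euclidean 3D distance and directed along the
  unit vector between the two points. We compared the plausible per-axis
  readings empirically: both collapse the culture into a single vertical
  column, unlike any published morphology, while the isotropic reading
  reproduces clustering, contraction, and sorting.
* One simulation step is one unit of simulation time; no extra $\Delta t$
  multiplies the force, and the displacement rule is applied literally.
  An optional bounded migration speed (`max_displacement`, um/step;
  default 0 = unbounded) is available because the literal rule lets
  condensed aggregates exchange cells violently (summed forces in the
  hundreds, per-step jumps of tens of um). We evaluated the bound at one
  cell radius and below: it calms the within-aggregate churn but changes
  neither cluster counts nor any sorting or contraction trend, while
  degrading the equilibrium-sweep linearity at reduced scale, so the
  literal rule remains the default.
* Pairs beyond the distance where the decay falls under $10^{-4}$ of its
  maximum (two length constants) are skipped via an x-sorted sliding
  window; inside the run loop the exponentials come from a
  piecewise-linear table on a 0.05 um grid (relative error $<10^{-6}$).
  `net_force()` applies no cutoff and exact exponentials, and the suite
  checks it against a brute-force R oracle.
* Coincident cells receive the full repulsion along a seeded-random unit
  vector (attraction and adhesion contribute nothing there), so
  coincident points separate instead of producing NaNs.
* Boundaries clamp: per-axis onto the slit walls, radial projection onto
  the disk wall, and $z \ge 0$. The top is open.
* Replicate seeds in `sweep_simulations()` are `base_seed + replicate - 1`,
  recorded per row in the output table.

### What the dynamics do and do not reproduce

Clusters nucleate quickly from the seeding noise, then the chain of
clusters coalesces from its ends: interior clusters feel balanced pulls
from both neighbours, while end clusters drift inward until they merge.
The stiffening freeze stops this coarsening, so the final cluster count
is kinetic, set by the competition between end-drift and the freeze. In
our full-scale slit runs the culture passes through a many-cluster state
and freezes with somewhat fewer, larger clusters than the original study
reports, and strongly-sorted states are cleaner (superficial ratios near
0 or 1) than the graded published values — both consequences of that
kinetics. Contraction, the linear growth of the CCDP peak with the
configured equilibrium point, the differential-adhesion sorting
directions, and the force-vs-sorting correlation structure are
reproduced; absolute cluster counts are reported as measured.

## Morphometrics

* **CCDP** (`ccdp()`, `cluster_ccdp()`): the probability-normalised 5-um
  histogram of pairwise neuron distances; within clusters, distances are
  planar and only between neurons sharing a 10-um z-slab, mirroring how
  confocal stacks are analysed. The profile peak is the centre of the
  maximal bin (ties toward the smaller distance, matching the published
  bin-centre values).
* **Cluster segmentation** (`segment_clusters()`): 10-um x-bins, 3-bin
  moving average, culture extent from a 5%-of-maximum occupancy
  threshold, boundaries at local count minima. Because raw strict minima
  fragment dense clusters through shot noise, a boundary must additionally
  dip at least 20% of the maximum bin count below its flanking peaks
  (a standard prominence rule; the original edge threshold and smoothing
  are unpublished).
* **Contraction** (`contraction()`): relative shortening of the robust
  x-extent (0.5th-99.5th percentile of all cell x-coordinates — the
  whole-aggregate length, as contraction is read from whole-culture
  images; the robust quantiles keep single stragglers from defining it);
  `normalized_contraction()` divides by a reference condition's mean.
* **Depth profile** (`depth_profile()`): depth is measured from the local
  aggregate surface (maximum cell z over a 10-um (x,y) column and its
  eight neighbours). The two sorting scalars are the astrocyte fraction
  in the top 10 um and the maximum per-bin fraction in a reference
  window 10-50 um below the surface (matching how deep layers are read
  from stained stacks, e.g. 15-25 um); deep bins need at least 10 cells
  to enter that maximum so that near-empty bins cannot dominate it, and
  the window keeps the underside of a fully-enveloping shell from
  counting as interior.
* **Force-morphology screen** (`force_morphology_correlation()`):
  zero-lag Pearson correlations between each type-pair attraction column
  and the superficial astrocyte ratio across sweep configurations.

## Image analysis

ROI directionality binarises a patch at gray value 55, autocorrelates it
(`xcorr2d()`, the full zero-padded shift-product surface), thresholds the
surface at 70% of its own maximum, and measures the central connected
blob: the major axis is the farthest edge-point pair, the minor axis the
shortest edge-to-edge chord through the major axis' midpoint, and the ROI
counts as directional only when the axis ratio reaches 2 and the major
axis 5 px. The nucleus pipeline mirrors the stated cuboid-ROI algorithm:
3D 6-connected components touching the lateral border are suppressed,
each z-plane is eroded with a 3x3 cross and outlined, and the farthest
3D outline-voxel pair gives the axis (XY angle) while the outline z-range
gives the height. Angles live in (-90, 90] with the culture long axis at
0 and counter-clockwise positive; the default pixel pitch is 0.25 um
(40x40 px per 10-um ROI) since the original magnification's pixel size is
not printed. Nuclei whose two planar principal spreads differ by less
than 20% are flagged `low_anisotropy`: their angle is reported but
unstable by symmetry.

## Activity analysis

The calcium path is: asymmetric-least-squares baseline
(`asls_baseline()`, second-difference penalty; defaults
$\lambda = 10^7$, $p = 0.01$, 10 iterations — the cited algorithm's
usual range, as the original parameters are unpublished), then
$\Delta F/F = (R - F_0)/F_0$, then thresholding at 3 robust standard
deviations (1.4826 x MAD) about the series median. The median centring
matters: the asymmetric baseline tracks the lower noise envelope, leaving
a small positive offset that a zero-centred threshold would misread as
continuous activity. Burst metrics are run length x frame interval,
maximum $\Delta F/F$, and the trapezoidal integral. Note that a pure 3-sigma
rule statistically admits isolated single-frame noise crossings
(about 0.1% of frames); real bursts last tens of seconds, so downstream
summaries are insensitive to them.

The LFP path band-passes 100-3000 Hz and notches 60 Hz and harmonics
(4th/2nd-order Butterworth, forward-backward), picks the channel
threshold as the standard deviation of the minimum-variance 100-ms
window (`silent_threshold()`, replacing the original manual selection),
and registers an initiation when the trace stays above threshold for a
full 10 ms, re-arming only after it falls below. Channel delays pair
nearest initiations within 5 s (network bursts are tens of seconds
apart); exact ties count as neither centre- nor edge-leading and are
excluded from the centre-leading fraction.

## Synthetic data

`make_cell_field()`, `make_fiber_image()`, `make_nucleus_stack()`,
`make_ca_trace()` and `make_lfp_pair()` generate every analysis input
with known ground truth and bit-reproducible seeding. Their defaults
follow the published study conditions: 0.2 astrocyte fraction, 10-um
shell thickness, 14-66 s burst durations, 0.2 s frames, 6 kHz LFP
sampling. They emulate the *geometry and statistics* the analyses consume
— hard-core spacing, layered astrocyte fractions, plateau bursts on a
drifting baseline, shared burst envelopes with channel leads — not cell
biology: there is no biophysical calcium or field-potential forward
model, fibers are straight segments, and nuclei are perfect ellipsoids.
Passing parameter-recovery tests therefore demonstrates that the
analysis chain is correct on inputs with the published statistics, not
that it is robust to every imaging artefact of real data.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the slit at reduced lengths
(600-2000 um at the published density, one seed per configuration point)
and the disks at 400-1300 um diameter with density halved for the two
largest; the full 4000-um culture is simulated once for the cluster-count
check. These sizes keep every emergent behaviour (clustering, sorting,
contraction trends, ring formation) while remaining desk-scale; all of
them can be raised through `simulation_config()` without touching any
other code.

## Known limitations

* Point cells: no cell shapes, processes, ECM field, division or death.
* The integrator is the literal printed rule; its vigorous pre-freeze
  dynamics make absolute cluster counts kinetics-dependent (see above),
  while trends across parameters are stable.
* Depth profiling ignores lateral faces when computing the superficial
  scalars; for long slit cultures these are a negligible cell fraction.
* The 24-configuration screen reconstructs the unprinted force table as
  the 24 permutations of {1.0, 0.9, 0.8, 0.7} over the four type pairs.
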