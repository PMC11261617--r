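---
title: "Multipoint shape reconstruction from exchangeable-probe FRET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipoint shape reconstruction from exchangeable-probe FRET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretshape)
```

## The measurement this package models

A molecule of interest carries two to four short ssDNA docking strands at
positions whose mutual geometry is unknown. Dye-labeled imager oligos in
solution hybridize transiently to the docking strands; each imager carries
either a donor or an acceptor fluorophore, and both compete for the same
sites. Whenever exactly one donor and one acceptor imager are bound, the
donor is excited and transfers energy to the acceptor with efficiency

$$E = \frac{1}{1 + (r/R_0)^6},$$

where $r$ is the dye separation and $R_0$ the Förster radius (about 5.4 nm
for a Cy3–Cy5-like pair). Because imagers exchange stochastically, every
site pair is eventually sampled in a single recording, and the histogram of
per-event apparent efficiencies $I_A/(I_A+I_D)$ develops one peak per
resolvable distance, plus a dominant peak at $E = 0$ from donor-only
binding. The pipeline turns that histogram into distances and the distances
into 3D coordinates for up to four labeled points — with no prior knowledge
of the structure.

## Exchange kinetics and assay design

Each site is modeled as an independent continuous-time Markov chain:

* empty → bound by species $s$ at rate $k_{\mathrm{on}} c_s$,
* bound by $s$ → empty at rate $1/\tau_s$.

Event times are simulated exactly (Gillespie) and discretized to camera
frames by majority occupancy, which avoids aliasing events shorter than one
frame; the minimum resolvable event is one frame. Sites are kinetically
independent — no steric coupling between neighboring docks is modeled. The
long-run probability that a site is bound by species $s$ is the
competitive-binding steady state

$$p_s = \frac{k_{\mathrm{on}} c_s \tau_s}{1 + \sum_{s'} k_{\mathrm{on}} c_{s'} \tau_{s'}},$$

which the simulator reproduces within Monte Carlo error
(`occupancy_steady_state()` gives the closed form).

Defaults: $k_{\mathrm{on}} = 10^{-3}\,\mathrm{nM^{-1}s^{-1}}$ (typical
short-oligo hybridization; the association constant is rarely reported for
specific imagers and is configurable), frame time 0.1 s so that a 1 s dwell
spans about ten frames, donor dwell 1.0 s as measured for 8 nt imagers.

A design point worth knowing: the frame-level single-pair probability for
$n$ iid sites is, for three sites, $6\,p_D\,p_A\,p_E$, which at a *fixed
total bound fraction* is maximized by an even donor/acceptor split. The
practical benefit of acceptor excess with longer acceptor dwell arises in
the sparse-binding regime, where occupancies are far below saturation and
lengthening the acceptor dwell adds bound-acceptor probability that a
donor-limited design could not otherwise reach; it also raises the fraction
of donor events that are FRET events rather than donor-only. The simulated
comparisons in the test suite are run in that sparse regime.

## Trace synthesis and its noise model

Synthetic traces translate the per-frame site occupancy into two channel
intensities. Frames with exactly one donor at site $i$ and one acceptor at
site $j$ emit at the pair efficiency $E_{ij}$ of the Förster model applied
to the effective dye distance; donor-bound frames without an acceptor emit
at $E = 0$; the rare frames with several imagers use the multi-acceptor
transfer formula $E = \sum_j k_{ij}/(1 + \sum_j k_{ij})$ with
$k_{ij} = (R_0/r_{ij})^6$, averaged over bound donors. Frames without a
bound donor carry only background: the acceptor is not directly excited, so
acceptor-only frames are dark. Total emission while a donor is bound is
constant in expectation; per-channel noise is additive Gaussian
(`channel_sd`, default 110 a.u. on a 1000 a.u. total — chosen so that a
typical ten-frame event averages to an efficiency SD of about 0.05, the
peak width scale seen in experimental histograms), with background noise
(default 30 a.u.) in dark frames.

Deliberately not modeled: photobleaching, blinking, triplet states,
spectral crosstalk and gamma corrections (the modeled quantity is the
*apparent* efficiency), dye-orientation ($\kappa^2$) effects, and
site-to-site binding interference. Passing tests on these synthetics
therefore validate the inference machinery under idealized photophysics,
not robustness to every artifact of real recordings.

The effective dye position is the site coordinate pushed radially outward
from the centroid by the linker length (`linker_expand()`), the same
convention used when fitting reconstructions to reference structures.

## Event detection and per-event efficiency

Binding events are contiguous runs where the total intensity $I_D + I_A$
exceeds baseline $+\,k\cdot$SD ($k = 3$). The baseline is a quantile of the
total intensity (default the median, a robust background center while
bound frames are in the minority) and the noise SD is the MAD of the whole
trace; estimating the SD from the dimmest frames alone would be
truncation-biased and set the threshold far too low. Runs separated by at
most `gap_frames` (default 1) are merged and runs shorter than
`min_frames` (default 3) are dropped.

Two further steps reflect how exchangeable-probe data actually behave:

* **Change-point splitting** (`split_delta`, default 0.2): a run during
  which the bound pair changes — an acceptor joining a bound donor
  mid-dwell, or one acceptor replacing another — shows a step in the
  per-frame efficiency. Recursive binary segmentation at the maximal mean
  difference recovers the pure-state episodes. This is deliberately not a
  hidden-Markov analysis; it is the minimal segmentation that keeps
  mixed-state averages out of the histogram.
* **Internal-SD quality filter** (`max_internal_sd`, default 0.2): events
  whose within-event efficiency SD is far above the per-frame noise level
  are residual mixtures and are discarded, standard practice in
  single-molecule event curation.

The per-event efficiency is the *mean of per-frame ratios*
$\langle I_A/(I_A+I_D)\rangle$, clipped to $[0,1]$, not the ratio of
channel means; the two differ under noise and the per-frame average is the
quantity histogrammed here. Frames with non-positive total intensity are
excluded. Event detection is invariant to a common offset on both channels
because baseline and SD are re-estimated from the shifted trace.

## Peak fitting

Per-event efficiencies are fit with an EM-estimated Gaussian mixture of
$k = 1 \dots k_{\max}$ free components plus a donor-only anchor. $k$ is
selected by BIC. Two modeling details matter:

* The donor-only anchor is **half-normal at zero, with two scales**.
  Clipping puts roughly half of the donor-only events exactly at 0 and
  folds the rest; and because the event-averaged noise scales as
  $1/\sqrt{n_{\mathrm{frames}}}$, the pile has no single width. Two
  mean-zero half-normal scales (SD capped at 0.12) absorb it; they are
  reported as one zero peak with the combined weight — the donor-only
  fraction of all events.
* Free components whose mean falls below `min_peak_E` (default 0.1) are
  counted into the donor-only population: below $E = 0.1$ the Förster
  transform leaves the usable range ($r > 1.44\,R_0$, where
  $\mathrm{d}r/\mathrm{d}E$ explodes) and such components cannot be
  distinguished from the zero pile's tail. Components closer than one
  average SD are merged (one population that EM modeled at two noise
  scales), and components carrying less than 2% of the non-zero weight are
  discarded as splinters. High-efficiency events are retained — real peaks
  above 0.9 occur.

Initialization is deterministic (quantile-based), so refitting permuted
events gives identical peaks; seeded jitter restarts guard against local
optima. Per-peak SEM is $\mathrm{SD}/\sqrt{n}$ with $n$ the
responsibility-weighted event count — a choice, since hard assignment
would give slightly different $n$.

## From peaks to distances

Each non-zero peak mean converts through the inverse Förster relation
$r = R_0 (1/E - 1)^{1/6}$; the peak SEM propagates to a distance SD by the
delta method. The uncertainty is reported but not used to weight the
embedding — no weighting scheme is adopted here, and the violation
residual treats all edges equally.

$n$ labeled points have $m = n(n-1)/2$ pairwise distances: the triangular
numbers 1, 3, 6. If fewer peaks than $m$ are resolved, some peaks must be
degenerate; `degenerate_expansions()` enumerates every assignment of
positive multiplicities summing to $m$ (for example $(2,2,2)$ for a
D2-symmetric tetramer whose opposite-edge pairs coincide) and the
reconstruction tries them all.

## Geometric reconstruction

Six labels on the edges of $K_4$ can be arranged in $6! = 720$ ways, but
vertex relabelings ($|S_4| = 24$) produce congruent quadrangles, leaving
$720/24 = 30$ dissimilar candidates for six distinct lengths (fewer under
repetition; the count is verified against brute-force orbit enumeration).
Each assignment is embedded by sequential trilateration with
Cayley–Menger-style feasibility checks on the squared offsets; exact
embeddings get violation residual 0. Unrealizable assignments are embedded
by minimizing the squared edge-length violation
$\sum_{i<j} (\lVert x_i - x_j\rVert - d_{ij})^2$ from a classical-scaling
start with seeded random restarts (BFGS with the analytic gradient). The
reported residual is the RMS edge-length change — "changes the least" is
interpreted in the least-squares sense, matching the embedding objective;
an L1 variant would penalize single large violations differently, and RMS
was chosen as the convention here.

Three numerical choices worth stating:

* **Screening fast path.** When at least one assignment embeds exactly,
  unrealizable assignments cannot win; they are ranked by the cheap
  classical-scaling residual (an upper bound on their attainable minimum)
  instead of running the optimizer for each. The full restart budget is
  spent only when no exact embedding exists.
* **Ties are real, not numerical.** Realizability is an open condition:
  the edge multiset of a generic tetrahedron often admits *several*
  exactly embeddable assignments. Distance data alone cannot distinguish
  them, so all shapes within `tie_tol` (1e-6 nm) of the best residual are
  returned, lexicographically smallest canonical form first, and the
  generator is provably among them for exact inputs. Downstream analyses
  should treat the tie set, not only the first element, as the answer.
* **Canonical frame and chirality.** Shapes are reported with vertex 1 at
  the origin, vertex 2 on $+x$, vertex 3 in the $y \ge 0$ half-plane and
  vertex 4 at $z \ge 0$. The $z$-flip removes the mirror ambiguity that
  distances fundamentally cannot resolve; a shape and its enantiomer share
  one canonical representative.

Triangles are trivial: three lengths determine at most one dissimilar
triangle. If the triangle inequality fails, the least-change layout is
collinear, obtained in closed form by shifting the longest edge and the two
shorter ones by a common amount $t = (c - a - b)/3$, giving residual
$|t|$ — verified against a grid-search oracle.

## Averaging, bootstrap and reference fitting

Per-molecule shapes are aligned by generalized Procrustes analysis —
translation and rotation only, reflection allowed by default (chirality is
unobservable), no scaling (absolute size is measured) — iterated to a mean
shape. Positional uncertainty comes from bootstrapping molecules:
resampling with replacement, re-averaging each replicate (per-molecule
reconstructions are cached), aligning the replicate means, and reporting
per-vertex SDs (the root of the summed coordinate variances).

Fitting to a reference structure (e.g. crystallographic coordinates read
from PDB via `read_reference_pdb()`) expands each reference point radially
from the centroid by the mean dye linker length before rigid-body
superposition; when the vertex correspondence is unknown all permutations
are searched. The default linker of 1.8 nm is a realistic average for
dye-DNA conjugates on proteins.

## Helix calibration

Reconstructions of triangles whose docking strands sit at known base-pair
offsets along one dsDNA edge constrain both $R_0$ and the linker length:
the attachment point of base pair $b$ sits at
$((r_h + L)\cos\theta_b, (r_h + L)\sin\theta_b, b\,\delta)$ with
$\theta_b = 2\pi b/T + \phi$, rise $\delta = 0.34$ nm/bp, $T = 10.5$
bp/turn, helix radius $r_h = 1.0$ nm — standard B-DNA values.
`helix_calibrate()` fits $(R_0, L)$ (optionally $\phi$) by
Levenberg–Marquardt least squares between helix-model distances and
FRET-derived distances. With all points on a single helix the phase is a
global rotation and drops out of every distance, so it is held fixed by
default — fitting it would add an unidentifiable flat direction. The
under-determination guard requires more distances than free parameters.

## Shape classification

Shapes are encoded rotation-, translation- and reflection-invariantly as
the sorted pairwise distances plus their sum and, for triangles, the Heron
area. For three points the sorted edge triple is a complete congruence
invariant; for four points sorted distances are near-complete (rare
non-congruent configurations share them — a documented limitation).
Absolute size is retained deliberately: it is informative. A
gradient-boosted tree ensemble (shallow depth 3, 100 rounds) is trained on
a stratified 70/30 *molecule-level* split, and the row-normalized confusion
matrix is computed on held-out molecules only, so no event- or
molecule-level leakage can inflate the accuracy.

## Problem sizes and what the tests show

The synthetic experiments in the test suite use 60–100 molecules recorded
for 240–360 s at 10 frames/s with donor 50 nM ($\tau$ = 1 s) and acceptor
10 nM ($\tau$ = 8–12 s), giving a few thousand events per condition — the
scale at which three-peak and four-peak histograms stabilize. Distance
geometry properties are exercised on 1000 random tetrads; peak recovery on
20 seeded draws of 1000 events at means 0.34/0.49/0.67 with SD 0.05. These
sizes are the package's validation design points. Quantities that depend
on unreleased experimental recordings — a specific held-out classification
accuracy, bootstrap spreads in ångströms, experimental peak positions —
are represented by these property-based checks and by the qualitative peak
structure of the synthetic pipelines (three peaks for a three-site
construct, three doubly degenerate peaks for a D2 tetramer, four peaks
with a triply degenerate expansion for the quadrangle), not by numeric
reproduction.

## Known limitations

* At most four labeled sites; $n \ge 5$ embedding is out of scope.
* Apparent efficiencies only: no gamma/crosstalk corrections, so absolute
  distances inherit any such experimental bias unless $R_0$ is calibrated
  (which `helix_calibrate()` addresses).
* Event segmentation is change-point-based, not a full kinetic model;
  extremely short pair episodes (under `min_frames`) are unrecoverable.
* Mixture fitting assumes Gaussian peaks; strongly skewed peaks (e.g. near
  the $E$ range limits under heavy clipping) are handled only through the
  zero anchor.
* Degenerate-peak expansion makes reconstruction ambiguity explicit (ties)
  rather than resolving it; additional information — e.g. iterative
  probing — is needed to pick among exactly tied structures.
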