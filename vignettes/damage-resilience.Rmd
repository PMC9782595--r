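---
title: "From calcium traces to damage resilience: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From calcium traces to damage resilience: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroresil)
```

`neuroresil` analyses how in vitro neuronal networks respond to physical
damage. The pipeline runs from per-ROI calcium fluorescence to binarized
activity, network bursts, transfer-entropy effective connectivity, graph
metrics, and two damage protocols: sequential targeted attack versus random
failure on aggregated cultures, and a diametral scalpel cut with staged
recovery on homogeneous cultures. Because recordings of real cultures are
not publicly deposited, the package ships a synthetic culture simulator that
stands in for the microscope; this vignette explains every model choice, its
assumptions, and what the synthetic results do and do not show about real
preparations.

## The two culture types

**Aggregated cultures** are ensembles of ~100 compact neuronal islands in a
6 mm well. Each island is one ROI/node. Islands wire as a directed
stochastic block model: dense, strong couplings within a module
(`p_within = 0.7`, weights U(0.5, 1)) and sparse inter-module coupling that
funnels through one *gateway* island per module with strong bundle weights
(U(0.8, 1.6)). The gateway construction reflects how inter-island axon
bundles follow a few spatial paths, and it gives the network genuinely
central nodes — the objects a centrality attack is supposed to find.
`p_between` is the nominal cross-pair edge probability; the generator
concentrates the same expected number of cross edges on gateway pairs.

**Homogeneous cultures** are uniform monolayers on a PDMS disc (3 mm
radius) bonded to glass, imaged over a 7.1 mm field and discretized on a
40 × 40 ROI grid; tiles outside the circular field mask are dropped, which
leaves about 1300 ROIs. Geometry labels each ROI `disc`, `contour` (the
outermost disc ring of one tile width — neurons on the PDMS walls, which a
scalpel cannot reach) or `surroundings` (the glass population). Couplings
are short-range (1.7 tiles, the 8-neighbourhood, 0.30 mm at the standard
grid). The disc height `h` controls disc–surroundings interaction: full
coupling at `h <= 0.7` mm, linear attenuation in between, and exactly zero
at `h >= 3` mm — the three experimental preparations. Contour couplings are
attenuated (factor 0.4) because the wall population is thin.

## Spontaneous activity: a cascade model

Dynamics are deliberately not biophysical. Only burst-level statistics
matter downstream, so activity is a seeded branching process:

* spontaneous initiations arrive as a Poisson process with total rate
  `init_rate` over the intact network (0.4/s aggregated, 0.15/s
  homogeneous), shared uniformly over live nodes;
* a spiking node recruits each structural out-neighbour with probability
  `min(1, weight * trans_scale)` after a uniform 5–25 ms delay;
* a node fires at most once per cascade and is refractory for 100 ms,
  which terminates reverberation.

With the default calibration, homogeneous cascades percolate the whole
lattice (burst participation ≥ 0.9 of live ROIs, network-wide
synchronization), while aggregated cascades engage a module partially and
sometimes jump through gateways, giving mean burst participation in the
0.10–0.20 band — the regime described for modular island cultures. The
transmission delays are at the scale of one camera frame (20 ms at
50 frames/s) so that propagation order is visible to the connectivity
stage; sub-frame delays would collapse every cascade into a single frame
and no direction could be inferred at all.

## Calcium imaging model

Each spike adds a difference-of-exponentials transient (rise 0.1 s, decay
1.0 s — a GCaMP6s-like slow indicator) with 20 %ΔF/F peak amplitude;
transients sum and saturate at 300 %. Raw fluorescence is
`F0 * (1 + ΔF/F / 100)` plus white Gaussian noise (sd 2 % of baseline),
sampled at 50 frames/s. These are configuration values, not claims about
any specific indicator batch.

## Signal layer

The baseline `F0` is the 10th percentile of each ROI's raw trace
(optionally computed per window and medianed, for drifting recordings);
ΔF/F is the standard `100 * (F - F0) / F0`. Binarization uses a Schmitt
trigger: on at `high`, off below `low`, initial state off. Default
thresholds are noise-scaled — 6 σ and 1 σ, where σ is a robust noise
estimate (MAD of the first-differenced trace, rescaled). Two constraints
fix these multiples. First, the on-threshold must sit far enough above
noise that isolated frames never fire: at 50 fps × 10³ ROIs even a
10⁻³/frame false rate swamps burst chaining. Second, the *hysteresis gap*
must be ~5 σ wide: the indicator decays slowly through the gap after every
burst, and once a ROI switches off a re-onset only requires noise to jump
the gap, so a 2–3 σ gap generates spurious "echo" bursts on every decay
tail. Both thresholds remain user-settable.

## Bursts and activity

Event onsets (first frame of each 0→1 transition) are pooled across ROIs
and chained whenever consecutive onsets are closer than 0.2 s; a chain
recruiting at least `min_fraction` of live ROIs is a network burst
(defaults: 0.5 homogeneous, 0.1 aggregated — the "substantial group"
thresholds, exposed in the configuration since no canonical values exist).
The chaining window is an order of magnitude above the frame period, so a
cascading burst is never split, yet two orders below typical inter-burst
intervals, so distinct bursts are never merged. Network activity is
`A = 1 / mean(IBI)` with IBI the onset-to-onset intervals; the activity
ratio `Φ = A_after / A_before` quantifies damage response. For
synchronously bursting subpopulations (the cut experiment), activity is
reported as per-region burst counts instead, with the participation
denominator restricted to the region.

## Effective connectivity

Directed connectivity is inferred with a generalized transfer entropy on
binary trains: a plug-in joint-histogram estimator of
`TE(I→J) = Σ p log2[ p(j_{t+1} | j_past, i_word) / p(j_{t+1} | j_past) ]`
with Markov order 2 and *instant feedback* — the source word is shifted
forward one bin to include the predicted bin itself, which captures
same-frame propagation when cascades are faster than the frame clock. No
bias correction is applied; significance is handled entirely by the joint
z-score: for each ordered pair the null sample is the pair's whole TE
column (inputs to J) and row (outputs of I), the pair's own value counted
once (a flag removes it), and `z = (TE - mean) / sd` of that sample.
Connections with `z >= 1` form the directed, unweighted effective network.

The network-inference wrapper feeds the estimator *onset* trains rather
than raw Schmitt envelopes. The envelopes of a slow indicator last seconds
and overlap by chance between unrelated ROIs, and at the permissive
`z >= 1` working point those chance overlaps materialize as spurious
connections that mask structural effects; onset impulses almost never
coincide by chance at 20 ms resolution. The bare estimator keeps the
convention of consuming the bits as given, so estimator-level properties
(e.g. a lag-one copy of an i.i.d. source carrying exactly 1 bit) can be
verified directly. Removed ROIs are excluded from the estimate and from
every null sample. A zero-variance null yields z = 0 by convention, and
the variance computation explicitly snaps floating-point-zero variances to
zero so that z-scores are exactly invariant under rescaling all TE values.

## Graph metrics

Degrees, BFS shortest paths (the unweighted case of Dijkstra), unnormalized
directed betweenness, Louvain communities and Newman modularity follow the
standard definitions; shortest paths, betweenness and Louvain are delegated
to igraph and are cross-checked in the test suite against literal
independent implementations (Floyd–Warshall, exhaustive shortest-path
enumeration, a double-loop modularity). Global efficiency is the mean
inverse distance over ordered pairs (1/∞ = 0). Modularity is evaluated on
the symmetrized graph — the printed undirected form — with a directed
variant behind a flag. Louvain is made deterministic by seeding the sweep;
argmax selections (attack targets) break ties toward the lowest node id.

## Damage protocols

**Sequential attack (aggregated).** Each step records activity, infers the
effective network, computes pre-damage metrics, selects a target (highest
betweenness, highest degree, or uniformly random), removes it, records and
computes post-damage metrics, then applies homeostatic recovery to model
the 24 h between sessions. Removed nodes keep their matrix index with
zeroed couplings, so ROI identity is stable along the sequence. Because
global efficiency depends on network size, the step's deleted node is
excluded from *both* the pre- and post-damage computation (size-matched
node sets). A step with fewer than two bursts is flagged as activity
extinction and the sequence continues.

**Diametral cut (homogeneous).** The cut is a straight band of width
500 µm through the disc centre: disc ROIs inside the band are wounded
(removed), and every coupling involving a disc ROI whose segment crosses
the band is severed; wall and glass ROIs are untouched. Regions are then
`A`/`B` (the two disc halves, ~30 % of ROIs each), `wound`, `C` (contour,
~5 %) and `S` (surroundings, ~25 %). The timeline records before, just
after, and at 2 h, 6 h, 24 h and 3 days, emitting per-region burst counts
and region-interaction matrices (counts of effective connections between
regions, direction folded).

**Homeostatic recovery.** The between-stage rule is synaptic scaling plus
sprouting. Surviving pairs may sprout new couplings, with the candidate
pool weighted by the *product* of the endpoints' remaining input deficits
— regrowth concentrates where input was lost, i.e. at the wound flanks —
and with a range that stretches with cumulative regrowth: the base reach
is local (1.7 grid tiles for monolayers, 1 mm for island cultures) and
grows by a factor `1 + outgrowth`, so early recovery cannot bridge the
500 µm wound but near-complete regrowth can, as axons do over days. After
sprouting, each node's incoming weights are scaled so that a fraction
`strength` of its lost total input is restored; at strength 1 the input
sum returns exactly to its pre-damage value. Sprouting respects the PDMS
barrier: it never couples disc and glass when `h >= 3`. The staged
timeline applies cumulative strengths 0.2, 0.35, 0.6, 0.85 at 2 h, 6 h,
24 h, 3 d. The real biology gives no quantitative recovery rule, so this
schedule is a modeling choice: monotone, saturating below full recovery.
It reproduces the observed phenomenology: with coupled surroundings the
two halves functionally reconnect at late stages, while the wound itself
stays silent throughout.

## What the simulator does and does not emulate

It emulates: modular cascading bursts and whole-network synchronous
bursts; slow-indicator fluorescence at 50 fps with realistic
signal-to-noise; the disc/surroundings geometry with height-controlled
coupling; needle removal, the 500 µm scalpel cut, and activity rebound
after damage. It does not emulate: the transient minute-scale
drop-then-boost immediately after damage (only steady pre/post rates);
glial biology; development or ageing across the multi-day protocol beyond
the recovery rule; spatially correlated noise, photobleaching or movement
artefacts; neuron-level dynamics inside a ROI. Passing tests therefore
show that the *analysis chain* behaves correctly and that its directional
conclusions hold under the stated burst phenomenology — not that any
specific biological parameter value has been validated.

## Numerical conventions and degenerate inputs

Frames and ROI ids are 1-based (R convention); times in seconds are
`(frame - 1) / fps`; the ROI grid is row-major from the top-left, origin
at the field centre; angles from the +x axis. A constant (degenerate)
target train has TE 0 by construction; graphs with no edges make
modularity undefined (signalled) and global efficiency 0; fewer than two
bursts make `A` undefined (signalled) and IBI empty with a warning.
Every stochastic stage draws its seed from the master seed through a fixed
integer splitting rule (`derive_seed`), so entire pipeline runs are pure
functions of their configuration.

## Problem sizes in the shipped checks

The test-suite and acceptance-script runs use desk-scale instances chosen
so the full suite completes in minutes on one core: aggregated cultures of
40–100 islands with recordings of 3–10 simulated minutes, homogeneous
grids of 12–16 tiles per side for the cut timelines (the geometry scales
with the tile, so the default 40 × 40 grid behaves identically, only
slower), and 10 replicate seeds for every stochastic claim. The
acceptance script's pipeline target uses the 60-island, 4-module, 15-min
configuration.

## Known limitations

* At the permissive `z >= 1` working point, a few percent of inferred
  connections between genuinely independent populations can survive
  thresholding when recordings contain few bursts; inter-region
  interaction counts should be read on recordings with dozens of bursts.
* The gateway construction makes inter-module routing depend on single
  islands. That is the intended regime for targeted-attack experiments,
  but Erdős–Rényi-style diffuse inter-module wiring (obtainable by
  generating with many modules and rewiring weights) will show weaker
  attack/failure contrasts.
* Transfer entropy is bivariate; shared drive from a third population is
  not conditioned away, matching the reference method but inflating
  within-burst cliques.
* File formats are plain text (CSV/TSV/JSON/YAML/GraphML); traces of very
  long recordings are large on disk.
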