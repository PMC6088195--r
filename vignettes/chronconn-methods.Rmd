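---
title: "Methods: static and dynamic connectivity reliability with chronconn"
author: "chronconn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: static and dynamic connectivity reliability with chronconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Resting-state electrophysiological recordings can be summarized as functional
connectivity graphs (FCGs): weighted networks whose nodes are brain regions
(ROIs) and whose edges quantify the statistical coupling of their band-limited
activity. Before network summaries of such data can serve as biomarkers, one
must know how *reliable* they are: if the same subjects are scanned twice,
how well do their network metrics agree? `chronconn` implements a complete
source-space pipeline for this question, at two temporal scales:

* a **static** branch — one FCG per recording, filtered statistically and
  topologically, summarized by nodal graph metrics and compared across
  recordings by a diffusion-based graph distance;
* a **dynamic** branch — a sliding-window sequence of FCGs reduced to a small
  set of recurring network configurations ("functional connectivity
  microstates") whose temporal evolution is summarized by chronnectomic
  statistics: the transition rate (TR), the occupancy time of each state (OC)
  and the transition-probability matrix of the associated first-order Markov
  chain.

Reliability of any per-subject quantity is the Pearson correlation between
the cohort's session-1 and session-2 values (`testRetest()`,
`nodalReliability()`); a Spearman switch exists for monotone but nonlinear
agreement.

Because no public two-session MEG cohort accompanies this implementation, the
package ships a first-class synthetic cohort generator with planted ground
truth, so that every stage — estimators, filters, metrics, microstates,
chronnectomics, reliability — can be validated end to end against known
answers. All tests and the acceptance script run on such planted data.

# Connectivity estimators

Both estimators operate on band-limited signals; the eight canonical bands
(delta 0.5–4 Hz through gamma2 55–90 Hz) are in `defaultBands()`. Band
limitation uses a 4th-order Butterworth filter applied forward and backward
(`signal::filtfilt`), i.e. zero-phase: phase-based coupling estimates must
not inherit filter phase distortion. Instantaneous phase and envelope come
from the analytic signal, computed by the standard frequency-domain
construction (positive frequencies doubled, negative zeroed).

**Imaginary phase-locking value.** For phase series $\varphi_k, \varphi_l$,

$$\mathrm{iPLV} = \frac{1}{T}\,\Bigl|\,\mathrm{Im}\sum_{t=1}^{T}
e^{i(\varphi_k(t)-\varphi_l(t))}\Bigr| \in [0,1].$$

Taking only the imaginary part suppresses zero-lag coupling, the signature of
volume conduction / field spread; a constant lag $\Delta$ yields
$|\sin\Delta|$ exactly.

**Orthogonalized envelope correlation.** Amplitude coupling is measured after
pairwise leakage correction: each band-limited signal is regressed on the
other, the residual's envelope is correlated with the partner's envelope, and
the two directed values are averaged (`corenv()`). A signal that is an exact
scalar multiple of the other gives exactly 0. Envelopes are smoothed with a
0.5-s moving average (roughly a 2-Hz low-pass) before correlation — the
conventional range for envelope-correlation analyses. This width is a
compromise we fixed after examining both sides of the trade-off: much longer
smoothing inflates the null distribution of the estimator (fewer effective
samples), much shorter smoothing lets the carrier's own fast amplitude
fluctuations dilute slow envelope coupling. It is exposed as
`smooth_samples` and can be disabled.

# Static and dynamic graphs

`staticFCG()` evaluates all ROI pairs over the whole recording.
`dynamicFCG()` re-estimates the graph in sliding windows whose width and
step are given either in samples or in *cycles* of the band via
`windowSpec()`; the reference frequency for "one cycle" is configurable
(`bandCycleFreq()`), defaulting to the arithmetic band centre, because no
single convention reproduces all published window counts. Phases and
envelopes are computed once from the full-length analytic signal and sliced
per window, avoiding per-window filter edge effects; a single window covering
the recording therefore reproduces the static graph.

`optimizeWindow()` implements the width/step selection principle used in
this literature: run the full dynamic pipeline per grid point and maximize
the test-retest reliability of the transition rate. The default grid is
widths 1–10 cycles in 0.5 steps by steps 0.1–2 cycles in 0.1 steps (380
evaluations); because each evaluation re-runs clustering, desk-scale use
passes a subsampled grid, and a mocked objective is supported for testing
the selection logic itself.

# Statistical filtering

Edge significance is assessed against **single-cut surrogates**: the
recording is cut once at a random point near its midpoint (within
`cut_halfwidth` seconds, default 10) and the two blocks are exchanged. This
preserves the sample multiset and almost all autocorrelation structure while
destroying the cross-signal alignment. The one-sided p-value of an edge is
the fraction of surrogate coupling values at least as large as the observed
one; Benjamini–Hochberg FDR at `q = 0.01` (via `stats::p.adjust`) is applied
within each graph snapshot, and non-significant edges are zeroed.

Two implementation notes:

* A block exchange is a circular rotation, and the analytic transform
  commutes with circular rotation up to edge effects. For iPLV the package
  therefore evaluates *all* surrogate cuts of an edge at once through the
  circular cross-correlation of the two unit phasor series (three FFTs per
  edge), instead of re-filtering every rotated series. `surrogateSeries()`
  still provides the literal rotated series for direct use.
* Following the design that the surrogate scheme is applied to the
  *full-length* series once per recording and reused across windows, the
  per-window test is liberal: short-window estimates exceed full-length
  nulls, so dynamic snapshots retain most edges and the subsequent
  topological filter does the effective per-window selection. The
  calibration property (uniform p-values, FDR control) holds exactly at the
  static level, where observed and null statistics share the same sample
  size; the test suite verifies this.

For the envelope estimator the test is one-sided on the *signed* value
(large positive coupling = significant); this choice is recorded in the
filter output metadata.

# Topological filtering: orthogonal spanning trees

`omst()` filters a weighted graph by iteratively extracting edge-disjoint
maximum-weight spanning trees (minimum spanning trees on distances $1/w$,
via `igraph::mst`; equal weights are broken by stable edge order, so the
result is deterministic). After each round $r$ the cumulative selection is
scored by

$$J_r = \mathrm{GE}_r - \mathrm{Cost}_r,$$

where $\mathrm{GE}$ is the global efficiency of the selection (inverse
shortest-path distances on $1/w$) and $\mathrm{Cost}$ is the selected
fraction of total edge weight. The returned network is the cumulative prefix
of rounds maximizing $J$: connected by construction, spanning-tree-sparse at
minimum, denser when additional trees buy more efficiency than they cost.
The test suite checks the selection against an exhaustive oracle on small
complete graphs and the first round against an independent Kruskal
implementation.

# Graph metrics and graph distances

`nodalMetrics()` computes, on the filtered nonnegative graphs, nodal and
global efficiency, local efficiency over first-neighbor subgraphs, and
strength, all with the $1/w$ distance map. `passageProbability()` implements
the shortest-path arrival probability of a random walk: with transition
matrix $P$ (row-normalized weights) and $B_j$ equal to $P$ with column $j$
zeroed,

$$\pi_{ij} = 1 - \sum_v\bigl[B_j^{\,\varphi_{ij}}\bigr]_{iv},$$

where $\varphi_{ij}$ is the *hop count* of the weighted shortest path (ties
broken toward fewer hops, keeping $B_j^{\varphi}$ a plain matrix power).
Although this quantity is sometimes labelled a "mean first passage time",
the formula yields a probability, and the package names it accordingly.

`gdd()` compares two graphs through their Laplacian heat kernels,

$$d^2(G_1,G_2) = \max_{t>0}\;\bigl\|e^{-tL_1}-e^{-tL_2}\bigr\|_F^2,$$

with the exponentials evaluated spectrally and $t$ searched on 60 log-spaced
points in $[10^{-3}, 10]$ refined by golden-section/`optimize` — the
two-node closed form $\sup_t (1-e^{-2t})^2 = 1$ anchors the grid's adequacy.
The subject-by-session distance matrix is embedded in 2D by classical MDS
(`stats::cmdscale`) with stress-1 reported; classical MDS is deterministic,
which matters for the package's reproducibility contract.

# Microstates and chronnectomics

Each filtered dynamic snapshot is summarized by the ascending eigenvalues of
its Laplacian $L = D - A$ (`eigenFeatures()`): a permutation-invariant
spectral signature whose dimension is the ROI count rather than the edge
count, sidestepping the dimensionality problem of vectorized graphs.
Features are used unstandardized — post-OMST eigenvalues share a common
scale — with a standardization switch available upstream of the clustering
call.

Spectra pooled across subjects (per band and session, as the study design
requires) are quantized by the **neural gas** algorithm
(`neuralGasFit()`): for each presented sample all $k$ prototypes are ranked
by distance and moved toward it with factor
$\varepsilon(t)\,e^{-\mathrm{rank}/\lambda(t)}$, with $\lambda: 10 \to
0.01$ and $\varepsilon: 0.5 \to 0.005$ decaying exponentially over 50
epochs — the classical defaults scaled to desk problems, all exposed via
`params`. After the annealed run a deterministic centroid (Lloyd) polish
moves each prototype to the mean of its assigned rows, relocating any
prototype left without members to the worst-reconstructed row; this standard
finishing step never increases the reconstruction error, makes exactly
representable configurations exact, and repairs the occasional dead unit of
the raw gas solution (it can be disabled with `params$polish = FALSE`). The
fit is deterministic under its seed. The state count is the
smallest $k$ whose relative reconstruction error

$$E = 100\,\frac{\|X-\hat X\|_F}{\|X\|_F} \quad (\hat X:\ \text{rows
replaced by assigned prototypes})$$

falls below 4% (`selectK()`), with the whole $E$-vs-$k$ curve returned for
plateau inspection.

Codebooks are fitted per session; to compare per-state quantities across
sessions, `matchCodebooks()` finds the state permutation minimizing total
prototype distance (exhaustive, $k \le 8$). From the per-recording symbol
sequence, `transitionRate()` is the fraction of consecutive windows that
change state, `occupancy()` the fraction of windows per state, and
`transitionMatrixOf()` the row-normalized pair-count matrix.
`prototypeTopologies()` averages the graph slices of each state, and
`aggregateNetworks()` collapses ROI graphs into a
network-of-networks matrix (e.g. DMN/FPN/occipital/sensorimotor/
cingulo-opercular) with collection-wide max normalization
(`normalizeAggregates()`); the ROI-to-network partition is supplied by the
user as a two-column table, since no canonical mapping ships with the
package.

# The synthetic cohort generator

`generateCohort()` emulates the study design the pipeline targets: a cohort
scanned twice, band-limited ROI time series, piecewise-stationary coupling
switching between a small number of planted network states according to a
subject-specific first-order Markov chain. Defaults mirror a realistic
acquisition (40 subjects, 2 sessions, 300 s at 600 Hz, 90 ROIs, 8 bands,
2 states); tests use smaller, explicitly stated configurations.

Design choices that matter for interpretation:

* **States are spectrally separable by construction.** Laplacian spectra are
  permutation-invariant, so two states that merely relabel the same topology
  are indistinguishable; and a state whose strong edges admit several
  alternative spanning trees produces unstable OMST selections and smeared
  spectra. The default templates therefore couple all ROIs into the *same*
  star topology while the planted hub–leaf lag shrinks from $\pi/2$ (edge
  weight 1) toward $\pi/6$ (weight 0.5) across states: each snapshot has a
  unique strong spanning tree, leaf–leaf lags are zero (suppressed by iPLV),
  and states differ cleanly in spectrum. Arbitrary templates (any
  antisymmetric lag matrix plus an envelope-correlation matrix) can be
  supplied instead.
* **Phase coupling is exact.** Followers are built from the driver's
  analytic signal rotated by the planted lag, plus white noise
  (`noise_sd`, default 0.1), so the planted lag is the true instantaneous
  phase difference.
* **Carriers.** ROI carriers keep the *phase* dynamics of band-filtered
  white noise but are amplitude-normalized; planted slow log-normal
  modulators (cutoff $\min(0.2, f_{low}/4)$ Hz, log-sd 0.4) then constitute
  the signal's envelope. With raw filtered-noise carriers the carrier's own
  Rayleigh-like envelope fluctuations (bandwidth-fast, ~4 Hz in the alpha
  band) dominate any slow planted coupling and envelope correlations cannot
  be recovered at realistic recording lengths; normalizing the carrier makes
  the planted envelope the measurable one while keeping realistic phase
  behavior.
* **State switching is window-aligned.** The Markov chain advances on a
  fixed segment grid (`segment_samples`), so analyses windowed at the same
  width and step have unambiguous planted labels and assignment accuracy is
  well defined.
* **Sessions.** Session 2 uses the subject's transition matrix perturbed by
  additive noise of scale `session_jitter` (rows re-normalized), with fresh
  chain and noise seeds. `session_jitter = 0` replays session 1's sub-seeds
  exactly — the two sessions are bit-identical recordings, giving the exact
  $r = 1$ end-member of the reliability scale.
* **Between-subject spread.** `defaultSubjectTP()` sweeps each subject's
  persistence level over 0.5–0.95 (driving transition-rate spread) and a
  bounded persistence asymmetry between states (driving occupancy spread);
  with symmetric chains every subject would occupy all states equally and
  occupancy reliability would be a correlation of pure noise.
* **Seeding.** One master seed expands to per-subject/session/band/ROI
  sub-seeds through a counter-based mixing scheme, so any sub-stream is
  reproducible in isolation and generation order is irrelevant.

What the generator does *not* emulate: 1/f background spectra, volume
conduction and leakage between ROIs (couplings are planted directly at the
source level), artifacts, inter-individual anatomy, or graded
within-state fluctuations. Passing tests on this data therefore demonstrate
the correctness and calibration of the pipeline's machinery — not that any
particular real dataset will show reliable chronnectomics.

# Problem sizes and numerical conventions

The test suite and acceptance script use desk-scale configurations chosen as
the package's reference conditions: planted-recovery cohorts of 10 subjects
x 2 sessions x 200 two-second windows (fs 80 Hz, 12 ROIs, alpha band,
persistence swept 0.5–0.95, session jitter 0.02, noise 0.1), surrogate
budgets of 100–200 draws (the conventional 1000 remains selectable), and
oracle comparisons on graphs of up to 10 nodes. Two-second windows (about 20
cycles at the alpha centre) keep the per-window estimator noise small enough
that the two planted states reconstruct with E below 2%; shorter windows
degrade E gracefully without harming assignment accuracy.

Other conventions, in one place: distances are $1/w$ everywhere a shortest
path is taken; disconnected pairs contribute zero efficiency; the OMST
cost denominator is the total weight of the unfiltered graph; surrogate
p-values use the plain proportion with ties counted against the observed
value; FDR is applied per snapshot across its $n(n-1)/2$ edges; MST ties
follow stable edge order; neural-gas presentation order is drawn per epoch
under the fit seed; reconstruction error is reported in percent; statically
filtered snapshots that lose connectivity fall back to the unfiltered
snapshot for tree extraction (the trees need a connected support).

# Known limitations

* The per-window statistical test inherits the liberal full-length-null
  design described above; interpret dynamic edge "significance" accordingly.
* Passage probabilities require a connected graph and are computed per
  target via dense matrix powers — adequate for post-OMST graphs at
  atlas scale, not for very large networks.
* `matchCodebooks()` is exhaustive over state permutations and limited to
  $k \le 8$.
* The graph diffusion distance is a pseudo-metric here: nonnegativity,
  symmetry and identity are guaranteed and tested; the triangle inequality
  is not asserted.
* On-disk interchange uses delimited text plus JSON sidecars; very large
  cohorts are better kept in memory or regenerated from seeds.
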