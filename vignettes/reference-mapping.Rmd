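---
title: "Reference templates for unsupervised bone-marrow immunophenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference templates for unsupervised bone-marrow immunophenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowSOM)
```

## The model

Multiparameter flow cytometry measures, for every cell, light scatter and
ten or more fluorescence intensities. Classical analysis gates subsets on
two-dimensional projections (CD45/SSC above all), one pair of markers at a
time; the thresholds are manual, and rare or transitional subsets are easy
to miss. `marrowSOM` instead quantizes the full measurement space: events
from a cohort of normal bone-marrow donors are merged and summarized by a
self-organizing map whose 100 codebook vectors ("nodes") tile the occupied
region of the 11-dimensional space spanned by the panel's ten fluorescence
channels plus side scatter. A minimum spanning tree over the codebook
vectors provides the canonical two-dimensional display, on which adjacent
nodes are immunophenotypically similar, so hematopoietic maturation appears
as connected branches (granulocytic, monocytic, lymphoid, erythroid/
progenitor).

The central object is the **frozen reference template**: the trained
codebook, the exact per-channel scaling statistics of the training data,
the MST and its layout, per-node summary statistics, per-marker phenotype
bin edges, and one node-occupancy row per normal donor. Freezing is what
makes the approach clinically interpretable: every patient sample is
compensated, transformed and scaled with the *reference's* parameters and
assigned to the *reference's* nodes, so "node 15" denotes the same cell
phenotype in every sample ever mapped, and a patient's occupancy vector is
directly comparable to the normal ranges. Mapping never modifies the
template.

Abnormality is read out per node. For occupancy $p_k$, normal mean
$\mu_k$ and standard deviation $\sigma_k$,
$z_k = (p_k - \mu_k)/\sigma_k$; excess (blast-like) nodes have large
positive $z_k$, and maturation loss appears as near-zero occupancy of nodes
that are substantial in every normal donor. The total excess burden — the
percentage of events in excess-flagged nodes — is the package's
measurable-residual-disease style summary.

## Preprocessing

* **Compensation.** Standard spillover correction,
  $\text{true} = \text{observed} \cdot S^{-1}$, applied to the
  fluorescence block when the panel declares a spillover matrix $S$ (rows =
  source stain, columns = detector). A singular $S$ is an error, not a
  warning.
* **Transform.** `asinh(x / cofactor)` on fluorescence (default cofactor
  150, the conventional choice for 5-decade digital flow data) and on side
  scatter with cofactor 10,000 so SSC's dynamic range lands on the same
  scale as the fluorescences. Logicle/biexponential transforms are out of
  scope by design — arcsinh is monotone, exactly invertible, and has one
  parameter. Forward scatter and time are never transformed and never
  clustered (a flag can admit FSC).
* **Scaling.** Per-channel median and standard deviation of the merged
  training data (median for robustness to the heavy tails of rare-positive
  channels), spread floored at $10^{-6}$. These statistics are frozen into
  the template; patient samples reuse them verbatim. An 11-of-13-channel
  panel therefore clusters in exactly 11 standardized dimensions.

## SOM training and the node-allocation problem

Training is batch Kohonen: codebook initialized by seeded random sampling
of events; each epoch assigns all events to their best-matching unit (BMU,
Euclidean; ties to the lowest node id) and replaces each codebook vector
with the Gaussian-neighborhood-weighted mean of assigned events. The
neighborhood acts on the rectangular grid with Chebyshev distance; its
radius shrinks linearly from half the grid diagonal to **zero** over 10
epochs. Batch mode makes training deterministic given the seed and
independent of event order.

Ending at radius zero (rather than one) is deliberate. A Gaussian
neighborhood of radius 1 keeps each node coupled to its eight grid
neighbors with weight $e^{-1/2} \approx 0.61$, which visibly smooths the
codebook: nodes cannot specialize, and rare subsets (a fraction of a
percent of events) never obtain a node of their own even when they are many
standard deviations away from everything else. The zero-radius limit makes
the final epochs plain quantization (Lloyd) steps.

Lloyd steps alone, however, inherit the quantizer's local optimum: on
marrow-like data both batch SOM and k-means reproducibly leave a handful of
nodes idle in low-density interstitial positions while two well-separated
rare populations share a single node. The package therefore appends 10
zero-radius *refinement* epochs with **utility reallocation** (in the
spirit of enhanced-LBG codebook repair): the node whose removal costs least
(its events fall back to their second-best unit; an empty node costs
nothing) is relocated into the highest-distortion cluster, seeded at
whichever of 24 candidate members — spread over the upper half of the
within-cluster distance distribution — realizes the largest exact decrease
in summed squared error. A move is applied only when that exact gain
exceeds the exact cost, so the quantization error is non-increasing
throughout, and the whole procedure remains deterministic. The candidate
search matters: the single farthest member of a bimodal cluster is usually
a stray outlier whose capture gains almost nothing, whereas a candidate
inside the secondary mode splits the cluster properly. With repair in
place, each of the three CD34/CD38 progenitor compartments (roughly 0.5-1 %
of events each) reliably acquires dedicated nodes across training seeds.

The MST is the exact minimum spanning tree of the complete Euclidean graph
over codebook vectors (via igraph); the layout is a seeded
Fruchterman-Reingold embedding, stored in the template so every later
display uses identical coordinates. Average-linkage metaclustering of the
codebook is available as an aid to node review, not a substitute for it.

## Node annotation

Each node's phenotype is summarized as a neg/lo/pos/hi level per marker: by
default the merged transformed intensity distribution of each marker is cut
at its 20th/50th/80th percentiles and the node's median falls into a bin.
Quantile edges are the right default for markers whose merged distribution
is genuinely spread out (CD45, SSC), but for markers dominated by a
negative mode — CD34 is the canonical case, with ~98 % of marrow events
negative — the 80th percentile still sits inside the negative mode and
cannot separate dim from bright. Rule sets may therefore carry absolute bin
edges per marker; the bundled progenitor rules use CD34 edges (0.8, 2.2,
3.8) and CD38 edges (0.8, 2.0, 3.8) on the arcsinh scale. Labeling is
declarative: a rule's clauses must all match (a `pos` clause accepts pos or
hi), every matching label is kept in priority order, multiple matches are
reported, and the whole step is a pure function of template statistics and
rules, hence exactly reproducible. Nodes sharing a label are grouped for
display by their connected components on the MST.

## Comparison thresholds

All thresholds are package defaults, configurable per call and printed in
every report.

| parameter | default | units | rationale |
|---|---|---|---|
| `zHi` | 3.5 | z units | Family-wise control across 100 nodes: per-node one-sided normal rate ≈ 2.3e-4, i.e. ~0.02 expected false node flags per normal sample. A per-node z of 3 looks conventional but flags some node in roughly a quarter of perfectly normal samples once 100 nodes are tested. |
| `minFold` | 2 | fold | Excess must also be at least twice the normal mean (with pseudocount). Guards against z-score fragility: with ~19 donors the per-node sd estimate has ~17 % sampling error, and an unluckily low estimate would otherwise flag the same node in many normal samples. Genuine blast excess over a near-empty node is orders of magnitude above 2-fold. |
| `minExcess` | 5e-4 | fraction | Ignores sub-0.05 % occupancy blips. |
| `minDeficitBase` | 5e-3 | fraction | Deficit is only meaningful for nodes filled in normals. |
| `deficitFraction` | 0.2 | fraction of mean | A five-fold drop of a normally substantial node. |
| sd floor | 1/(merged events) | fraction | Keeps z finite (and very large) for nodes empty in all normals — the MRD-relevant case. |

The per-node sds are additionally moderated by empirical-Bayes shrinkage
toward a log-mean-occupancy variance trend (`limma::squeezeVar`) before
flooring — the standard few-replicates variance remedy; `moderate = FALSE`
recovers the raw cohort sds. The log2 fold-change column uses pseudocount
1/(patient event count). Excess burden is reported as percent of **all**
analyzed events, which is the denominator the occupancy fractions already
use; whether a laboratory would prefer a CD45-gated denominator is a
pre-filter question (`referenceConfig(preFilter = ...)`), not a reporting
one.

## The synthetic marrow generator

No public dataset accompanies this problem, so validation rests on a
simulator whose defaults define the study conditions: 19 donors of 10,000
events for a reference, four 10-color panels (two myeloid, two lymphoid),
and 16-22 populations per panel — granulocytes and their maturation stages,
monocytes including the CD14dim CD16+ nonclassical subset, T/B/NK cells,
hematogones, eosinophils, basophils, plasma cells, plasmacytoid dendritic
cells, and the three CD34/CD38 progenitor compartments. Populations are
Gaussian in arcsinh space with hand-authored means encoding the qualitative
marker patterns of each subset (these numbers are fixtures, not
measurements); events are inverse-transformed to the raw scale and pushed
through the panel's synthetic spillover so that the standard pipeline must
undo it. The population of origin travels with each event as a ground-truth
label — in memory and in CSV exports, never in a measurement channel — so
tests can score node purity exactly.

Inter-donor variation is Dirichlet on the population frequencies. The
default concentration (5000) yields frequency CVs of about 1.5 % for
granulocytes, 4-7 % for lymphoid subsets and 15-35 % for the rarest
populations — the variability expected of a harmonized acquisition
protocol, and the calibration under which the default thresholds leave
normal samples unflagged. That coupling is intrinsic and worth stating
plainly: detecting a 0.5 %-absolute blast excess at z = 3.5 presupposes
that the blast-region nodes' normal occupancy varies by clearly less than
that across donors. A laboratory with wilder inter-donor variation must
either raise thresholds or enlarge its normal cohort.

Normal marrow also contains a rare population (0.10 % here, "Ber3") with
the immunophenotype of the AML blast spike-ins (CD34+ CD117+ HLA-DR+ with
aberrant CD7), so the blast region of measurement space is near-empty but
not void in normals — its nodes carry roughly 0.12-0.15 % of normal events.
Spiked samples replace a random event fraction with blast draws, so the
recovered excess burden is structurally the spike fraction plus that small
baseline.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: staining batch effects and per-donor
intensity shifts, debris/doublets, non-Gaussian population shapes and
maturation continua (real CD34/CD38 progenitors blend into one another;
simulated ones are distinct modes), autofluorescence, and acquisition-time
drift. The package's algorithms do not depend on these simplifications,
but threshold defaults would need local re-calibration on real cohorts.

## Numerical choices and degenerate inputs

* Distances use the $\|x\|^2 + \|c\|^2 - 2 x \cdot c$ expansion (clamped at
  zero) in blocks of 50,000 events; BMU ties break to the lowest node id.
* Duplicate codebook vectors yield zero-weight MST edges, not a
  disconnected graph; coincident layout points are separated by a
  deterministic nudge.
* Constant channels are floored (spread $10^{-6}$) with a warning and map
  to zero after scaling.
* Empty nodes report count 0 and undefined (NA) medians/levels; they are
  excluded from rule matching.
* Serialized templates are written at full double precision
  (`%.17g`), so save/load round-trips exactly and rebuilding with the same
  inputs and seed is byte-identical; provenance records sample ids, seed
  and package version, never timestamps.
* All randomness (simulation, initialization, layout) flows from explicit
  seeds through a restore-on-exit RNG guard, so library calls never disturb
  the caller's RNG state.

## Problem sizes

Default validation scale is the study scale: a 19 x 10,000-event reference
(about half a minute on one core), with unit tests on 6 x 2,000-event
references and spike-in/specificity loops of 40 single samples of 10,000
events. Exhaustive oracles (all labelled spanning trees via Pruefer
sequences, brute-force BMU search) run at n ≤ 6 nodes and ≤ 50 events where
exhaustion is exact and fast.

## Known limitations

* One template per panel; no cross-panel node alignment.
* No batch-effect correction across normal donors and no automated
  outlier-donor rejection; a contaminated normal cohort widens the ranges
  silently.
* Rectangular grid only (hexagonal topology not implemented); online SOM
  updates not implemented — batch only.
* The excess/deficit read-out is per sample; longitudinal modeling across
  timepoints is out of scope.
* Thresholds are calibrated for ~100-node maps and ~19-donor cohorts; very
  different grids or cohort sizes call for re-derived defaults.
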