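---
title: "Methods: simulating and reconstructing the otic commitment network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reconstructing the otic commitment network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otognet)
```

## The problem

Commitment of cranial ectoderm to the inner-ear lineage proceeds through a
sequence of transcriptional states: posterior pre-placodal (PPR) progenitors
become otic-epibranchial progenitors (OEPs) under FGF signalling, and OEPs
mature into a committed otic placode over roughly a dozen somite stages
(ss). The regulatory logic of this process is probed by partial knockdown
of single transcription factors followed by panel-scale read-outs of
downstream genes. `otognet` implements the computational route from those
read-outs — plus staged transcriptome tables — to a signed, stage-annotated
gene regulatory network, and pairs it with a synthetic-data generator whose
ground truth makes every stage of the pipeline testable.

## The generative model

### Network topology

`generate_network()` draws a tiered hierarchy (default 3 tiers over 30
genes, tier sizes proportional to depth). Two kinds of non-input genes
exist, mirroring the two regulatory roles seen in early otic development:

* **activated targets** receive one essential activating parent from a
  strictly lower tier — guaranteeing reachability from the tier-1 inputs —
  plus extra activators (Poisson-distributed, calibrated so the expected
  mean in-degree equals `edges_per_gene`, default 2);
* **repressed targets** (probability `repressor_fraction`, default 0.1)
  model intrinsically expressed alternative-fate genes that the network
  clears: they carry exactly one repressive input and no activators.

Parents come from strictly lower tiers so that every true edge originates
from a tier-1/2 regulator and is therefore observable in a full tier-1/2
knockdown screen; the designated two-gene mutual-activation feedback pair
in tier 2 (default 1 pair, after the mutual maintenance of otic identity
factors) is the only same-tier structure. Repressed targets regulate
nothing: a gene silenced by an active repressor cannot transmit information,
so edges out of it would be unidentifiable in principle.

Multi-input targets integrate activators through an AND gate (product of
activities). An OR (max) gate is available via `or_gate_fraction` but
defaults to 0: the documented integration logic in this system is AND-type
(a committed-state gene requiring both posterior-PPR input and the FGF
mediator), and OR-redundant inputs are invisible to single-knockdown
screens — knocking one redundant parent leaves the max unchanged — so
enabling them reduces recall by construction, not through any failure of
the inference.

### Activity propagation

`propagate_activities()` evaluates per-stage activities in `[0, 1]`:
`a(target) = gate(activators) * (1 - max(repressors))`, gated by a
stage-of-onset schedule (tier *k* genes switch on at stage *k*). A
knocked-down regulator's own activity is multiplied by `1 - efficiency`
(default 0.8 — morpholino knockdown is partial) before propagation. Acyclic
models are evaluated exactly in one topological pass; models containing
feedback components use damped fixed-point iteration (damping 1/2,
tolerance 1e-8, maximum 500 iterations, started from the fully-on state),
with a named error on non-convergence. Fixed points of the damped map
coincide with fixed points of the gate map, and the small designated cycles
converge geometrically.

### Read-out models

* **Counts** (`simulate_counts()`): mean `μ = baseline_mean ·
  amplitude^activity` (defaults 200 and 4, anchoring inactive genes below
  the empirical expressed-count cut-off of 300); negative-binomial noise
  with `variance = μ + α μ²` (`dispersion` α, default 0.05; α = 0 gives
  Poisson); per-sample log-normal size factors (sd 0.15) so normalization
  is non-trivial but benign. An expectation mode (`exact = TRUE`) returns
  the noise-free means for closed-form round trips.
* **Background transcripts.** Both the stage series and the knockdown
  panels carry stable background genes (100 and 60 by default) at constant
  levels. This is not a convenience: median-of-ratios normalization is only
  defined when most genes are unchanged. A real transcriptome is dominated
  by stable genes, and the real probe panel contained markers of many
  lineages precisely so most probes stay flat; a panel consisting solely of
  network genes would let a hub knockdown shift the median and absorb its
  own signal.
* **qPCR** (`simulate_qpcr()`): `Ct = ct_intercept − log2(μ) + N(0,
  ct_noise_sd)` (defaults 34 and 0.25 cycles), technical triplicates within
  biological duplicates; reference transcripts are held at constant
  abundance.
* **ISH** (`simulate_ish()`): per gene, `affected ~ Binomial(n_embryos,
  p)` with `p = 0.05 + 0.95·(2·logistic(s·|d|) − 1)`, where `d` is the
  log2 effect on the mean and `s = ish_sensitivity` (default 1.5, chosen so
  the canonical knockdown effect of |d| ≈ 1.6 is detected in most embryos).
  The 0.05 floor encodes background scoring noise: control morpholinos show
  no effect, but scoring is not noise-free.

Every simulated artifact is a pure function of the configuration and its
seed: each draw uses a stream seed derived from the master seed and a salt
naming the assay, condition and design, so identical calls are
byte-identical and distinct conditions are independent.

## The inference pipeline

### Enrichment and expression

Size factors are median-of-ratios (the factor of a sample is the median
over always-positive genes of its count over the gene's geometric mean).
Fold changes use a pseudocount of 1 on the normalized count scale (bounded
FC for silent genes). Expressed = RPKM > 4 and normalized count > 300, both
strict; the count filter is applied to the otic samples only (whether the
reference was filtered too is not documented; the choice is exposed).
Enriched = expressed and FC > 1.5, strict.

For unreplicated two-sample comparisons, `blind_variance_test()` pools the
two samples as pseudo-replicates, fits `v(m) = m + αm²` by least squares of
`(pairwise variance − m)` on `m²` (α floored at 0), and tests each gene's
two normalized counts against a common mean. Because true differences
inflate the fitted variance, the test is deliberately conservative — few
genes pass `p_adj < 0.1`, which is why the candidate gene lists in this
design are driven by the fold-change filter, with significance reported
alongside.

### Clustering

Stage fold-change profiles (relative to the earliest-stage reference) are
row-standardized (`n − 1` denominator; zero-variance rows flagged, not
standardized), clustered with `hclust` (default Euclidean/complete — the
defaults of the heatmap tool this analysis style descends from; both
configurable), and cut into a user-chosen k (no automatic selection; the
source analyses chose 5 for transcription factors and 6 for all genes).
Cluster labels are renumbered by the stage at which the cluster mean
trajectory peaks, ties broken by the alphabetically first member, making
labels reproducible and row-order invariant. Genes downregulated at the
first transition can be excluded from the clustering input (flag, default
on, matching the source analysis); genes with no baseline fold change are
excluded with a warning upstream.

### Perturbation calling and integration

The panel test normalizes all samples together, filters to mean normalized
count > 300 *before* testing (so BH runs over tested genes only — the
expressed subset; correcting over the whole panel instead is configurable),
moment-estimates gene dispersions from pooled within-condition variances,
shrinks them 50/50 toward a parametric trend `v = m + αm²` fitted across
the panel, and applies a Wald test to the log2 fold change with a
delta-method standard error. The p-value uses a **t reference with
`n1 + n2 − 2` degrees of freedom**: with triplicates, plug-in dispersions
make the usual normal reference badly anti-conservative, and the null
property of the screen (almost no false calls on a zero-edge network) is
part of the module's contract. Calls require mean count > 300,
|log2FC| > log2(1.2) and BH-adjusted p < 0.1, all strict.

qPCR: technical replicates are averaged first; `ΔCt = Ct_gene −
mean(Ct_refs)` per biological replicate; `ΔΔCt = mean ΔCt(kd) − mean
ΔCt(control)`; `FC = 2^(−ΔΔCt)`; two-tailed Student's t (pooled variance)
on the ΔCt values; calls at FC ≥ 1.5 or ≤ 1/1.5 with p < 0.05. Adding a
constant to every Ct cancels exactly. ISH scoring is reduced to a numeric
rule induced from the reported fractions: ≥ 4 embryos and a strict majority
affected.

Integration: if all present modalities agree, that is the call; if ISH
detected a change, ISH wins (conflicts flagged) — spatially resolved
evidence takes precedence; otherwise any two modalities agreeing on the
same result (including "no change") carry the call; otherwise the pair is
unresolved. A single-modality result stands on its own. "Reduced after
knockdown" maps to *activated*, "enhanced" to *repressed*.

### Assembly

Activated/repressed calls become signed edges. The parsimony rule assumes
the most parsimonious pathway: an activating edge implied by a longer
activating chain is withdrawn from the displayed graph. It is implemented
as a transitive reduction of the activation subgraph after condensing
strongly connected components: intra-component edges are always kept (there
is no principled basis to drop edges inside a feedback loop), and when a
component-to-component link is kept, all parallel original edges between
those components are kept. Repressive edges are never removed — the
parsimony argument concerns activation chains only. Withdrawn edges are
flagged, never deleted, so the feed-forward ambiguity report can cite them:
every triple A→B, A→T, B→T with concordant signs on the shortcuts is listed
as unresolvable (linear chain vs feed-forward loop) from knockdown data
alone. A target with two or more activating inputs that the displayed graph
cannot serialize is annotated as an AND-gate candidate.

Curated literature edges are merged by union; a curated *direct* flag marks
the highest-confidence tier, and on sign disagreement the curated sign wins
with the conflict logged — a stated convention (the source does not document
how such conflicts were resolved), not an inference.

### Recovery scoring

Precision and recall are over directed edges ignoring sign; sign accuracy
over matched edges. A withdrawn edge that matches a truth edge still counts
as correct (the reduction withdrew it only as redundant); displayed edges
that exist only as indirect chains are false positives. The irreducible
false-positive classes under the default conditions are mixed-sign two-step
chains (an activating step into a repressor produces a repressive shortcut
the parsimony rule may not remove) and parallel links into feedback
components (kept by the component rule).

## Problem sizes and numerical choices

The validation suite runs at the generator's default study conditions:
30 genes, 3 tiers, dispersion 0.05, knockdown efficiency 0.8, amplitude 4,
3 replicates, full tier-1/2 screens over 10 seeds for recovery; 200
zero-edge screens for the null; 2,000 genes for blind-test calibration;
all DAGs on ≤ 5 nodes (enumerated as edge subsets of the complete DAG in
topological order — both the implementation and the greedy-deletion oracle
are label-equivariant, so this covers every DAG up to relabelling) for the
parsimony oracle. Tolerances: activity fixed points 1e-8; z-score moments
1e-9; closed-form round trips 1e-9; hypergeometric tails 1e-10;
normalization ratio identities 1e-12.

## What passing tests do and do not show

The generator emulates tiered signed regulation, partial knockdowns with
downstream propagation, NB count noise with sample-specific size factors,
log2-linked Ct values and per-embryo binomial ISH scores. It does not
emulate spatial expression patterns, cell-type mixtures in dissected
tissue, probe-specific hybridization biases, morpholino off-target
effects, or stage mis-staging; recovery of the simulated truth therefore
validates the pipeline's logic and calibration, not the biological
completeness of any real network. Indirect-vs-direct disambiguation is
bounded in principle: without cis-regulatory information, a feed-forward
loop and a linear chain are indistinguishable, which is why the package
reports ambiguity triples instead of resolving them.
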