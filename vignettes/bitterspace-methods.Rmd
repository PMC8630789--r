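---
title: "Methods: scaffold decomposition and chemical-space profiling of TAS2R agonists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaffold decomposition and chemical-space profiling of TAS2R agonists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitterspace)
```

## Scope and model

Humans perceive bitterness through a family of 25 G protein-coupled bitter
taste receptors (TAS2Rs). A compound is an *agonist* of a subtype if it
activates that receptor in vitro. `bitterspace` characterizes a curated
compound–receptor activation table along four axes:

1. **Scaffold decomposition.** Each molecule is reduced to its
   Bemis–Murcko framework — the union of ring systems and the acyclic
   linkers connecting them — and the framework is expanded into its
   *scaffold network*, the set of all sub-frameworks reachable by deleting
   terminal ring systems in every order. Per-receptor unique-scaffold
   counts and the scaffold-per-compound ratio quantify the chemical
   complexity of an agonist set: ratios above one mean structurally
   complex ligands, below one mean scaffold sharing.
2. **Promiscuity profiling.** The receptor promiscuity index is the
   fraction of the dataset's compounds activating a receptor; the scaffold
   promiscuity index divides a receptor's unique-scaffold count by an
   explicit reference scaffold total. Compound promiscuity is the number
   of receptors a compound activates, binned as 1, 2, 3, 4, 5+.
3. **Flow aggregation.** Activations are aggregated into a tripartite
   alluvial graph, receptor → chemical superclass → promiscuity bin.
4. **Chemical space.** Public 166-key MACCS structural fingerprints feed a
   from-scratch exact-gradient t-SNE that embeds the library in 2-D.

All statistics are *dataset-relative*: the same compound can legitimately
carry different promiscuity counts in the full collection and in a subset
restricted to compounds tested against every receptor. Every function
therefore takes an explicit `activity_dataset`, and the receptor universe
is pinned to the 25 human TAS2Rs regardless of which columns an input file
contains, so index denominators never drift.

## Scaffold machinery

The framework is computed by iterated leaf pruning of the heavy-atom graph
(yielding ring systems plus linkers) followed by re-attachment of
exocyclic atoms that are double- or triple-bonded to a retained atom, such
as ring carbonyl oxygens. This matches the original framework definition,
in which such atoms are part of the ring system's chemistry. Acyclic
molecules have an empty framework; the operation is idempotent.

Two representational choices matter:

* **Scaffold identity is 2-D.** Charges and stereochemistry are stripped
  inside the scaffold layer before canonical comparison; element,
  aromaticity and bond order are kept. Canonical strings come from
  OpenBabel's canonical SMILES writer.
* **Fused, bridged and spiro rings are one ring system.** Ring systems
  are connected components over ring bonds (bonds on a cycle, i.e.
  non-bridges of the graph). Deleting one ring of a fused pair would
  leave an invalid fragment, so ring systems are deleted as units.

The scaffold network is defined over *all* deletion orders of terminal
ring systems. Because any cycle of ring systems through linkers would
itself be a ring (and hence a single ring system), the quotient graph of
ring systems is always a tree; the network therefore equals the set of
frameworks induced by connected subsets of ring systems, which gives an
order-independent, testable definition. The test suite checks the
recursive-deletion implementation against an independent brute-force
enumerator over all `2^k - 1` ring-system subsets on randomly assembled
molecules with up to four ring systems.

The decomposition tool used to produce the published per-receptor scaffold
counts is proprietary and its enumeration rule is undocumented, so exact
agreement on every compound cannot be assumed. On the flagship example it
does agree: amarogentin's four ring systems (iridoid bicycle, pyranose,
and two phenyls) form a chain with 10 connected subchains, of which the
two lone phenyls collapse to one benzene under canonical deduplication —
9 unique scaffolds, the published count for its receptor. The package
nonetheless treats the published table's *counts* as inputs for ratio
arithmetic rather than a reproduction target.

Rounding follows the display conventions of the summary table:
scaffold-per-compound ratios are rounded half-up to 2 decimals, median
molecular weights (mean of the central pair for even sets) half-up to
integers. Note the reference value printed for amarogentin, 586: the
computed average molecular weight of its structure (C29H30O13) is
586.55 g/mol, so the printed figure corresponds to the integer part rather
than half-up rounding; comparisons against it are made at ±1 g/mol.

## Promiscuity and flows

The scaffold promiscuity index takes its denominator as an argument
because the published convention divides unique-scaffold counts of the
all-tested subset by the scaffold total of the *full* food set (133); an
implicit denominator would silently change when subsetting.

The flow graph uses two accounting conventions at once, by design:
receptor → superclass edges count (compound, receptor) activation pairs —
a compound genuinely flows into each receptor it activates — while
superclass → bin edges count each compound once. The two layer totals
therefore differ; both are recorded in the graph metadata and each is
conserved within its own layer pair. Layer orderings are deterministic:
receptors by descending promiscuity index, superclasses by descending
compound count, bins ascending, all ties broken by name.

The bin boundary is configurable with default 5 ("5+"), chosen so that a
five-receptor agonist such as caffeine counts as promiscuous, which is the
consistent reading of the published grouping (the narrative's "more than
five" conflicts with its own example compounds).

Counts of zero receptors are a typed error in `promiscuity_bin()`:
agonist datasets contain only agonists, and a zero count indicates an
upstream data problem rather than a bin.

## Fingerprints and chemical space

Fingerprints are the public 166-key MACCS structural keys, shipped as a
SMARTS dictionary with per-key minimum match counts and evaluated by
SMARTS matching; three keys that are not single SMARTS patterns (isotope;
more than one aromatic ring; more than one fragment) are computed from the
molecular graph. On reference molecules the resulting bit sets coincide
with an independent toolkit implementation of the same public keys.

Distances between fingerprints default to Euclidean on the raw bits (the
square root of the Hamming distance), matching what a generic
numeric-column embedding tool would compute; Jaccard (1 − Tanimoto) is
available as an option. No column standardization is applied.

The t-SNE implementation follows the original formulation: per-point
Gaussian bandwidths are bisected until the conditional distribution's
entropy matches `log(perplexity)` (tolerance 1e-6, with a
nearest-neighbor fallback when the bandwidth collapses at perplexity → 1);
probabilities are symmetrized and normalized; the 2-D map minimizes
KL(P‖Q) under a Student-t kernel with early exaggeration (factor 12 for
250 iterations), a 0.5 → 0.8 momentum schedule, learning rate 200, and
adaptive per-parameter gains. The gradient is the exact O(n²) expression:
at the library sizes this package targets (n ≈ 100–250) the Barnes–Hut
approximation buys nothing, while the exact gradient is directly testable
against the cost function. A `theta` parameter is accepted for
configuration compatibility and recorded in outputs, but unused.

Determinism and equivariance are engineered explicitly: initial
coordinates are Gaussian at the conventional 1e-4 scale, drawn per point
from a hash of (seed, compound id), and points are processed in sorted-id
order internally. Reruns are bit-identical, and permuting input rows
permutes output rows exactly — floating-point summation order would
otherwise leak through hundreds of gradient iterations.

Default perplexity is 30 (reported in all outputs); iterations default to
5000. The feasibility rule `perplexity < (n − 1)/3` is enforced at the
dataset entry point; for very small inputs the perplexity is clamped to
the feasible value (never below 1) with a warning rather than failing,
so the pipeline remains runnable on toy tables. Note that a dataset
containing duplicated structures bounds the reachable entropy of *other*
rows from below by log 2, so perplexities below 2 are only meaningful for
duplicate-free inputs.

The published embedding used a specific long integer seed in a different
code path; coordinate-level reproduction of the published plot is not a
goal. What is validated instead: final KL within 20% of an independent
reference implementation on a fixed 50-point input, KL non-increasing
after the exaggeration phase, and recovery of three well-separated
synthetic fingerprint clusters (Rand index ≥ 0.9 against ground truth
after k-means on the embedding) — the testable restatement of the claim
that compounds of the same class map to the same region.

## Synthetic data: what it emulates, what it does not

The generator produces libraries with exactly known ground truth.
Compounds are assembled from ring-system templates (possibly 2–3 chained
by single bonds) decorated with 0–3 acyclic substituents at free-valence
positions; because substituents are constrained acyclic and joins are
single bonds, the true framework of every molecule is the assembled
template chain itself, recorded before decoration. Superclass labels
follow a configurable template → label rule over the nine superclass
names observed in food bitterant collections, with an "Unclassified"
fallback that superclass analyses exclude (mirroring the handful of
unclassifiable compounds in real collections).

Activation is Bernoulli per (compound, receptor). Defaults are the study
conditions of the curated food collection: 133 compounds, the 17
receptors that carry at least one food agonist, and per-receptor
activation probabilities equal to the published agonist counts divided by
133 — giving a mean compound promiscuity near 2, with most compounds
activating one or two receptors. A promiscuous-type compound (probability
0.1 by default) has all its activation rates multiplied by 3 (capped at
1), creating the long tail observed in real data. All-zero rows are
resampled, because agonist datasets contain only agonists; the resample
count is recorded so the effective (zero-truncated) distribution is
documented, and tests compare against the zero-truncated binomial
expectation.

What the generator does **not** emulate: chemically realistic bitterants
(no QSAR plausibility), correlated activation across receptors, the
true scaffold-size distribution of natural products, or
structure–activity coupling (activation is independent of the molecule).
Passing tests on synthetic data therefore validate the *statistical
machinery* — index recovery, conservation identities, scaffold
enumeration, embedding behavior — not any biological claim about real
TAS2R pharmacology.

## Problem sizes and numerical tolerances

The test and acceptance workloads use: 1000 random molecules for the
scaffold-network/brute-force equivalence, 1000 single-template molecules
for framework recovery, n = 1000 activation draws for
parameter-recovery (rank correlation ≥ 0.9 over 10 well-separated rates),
a fixed 50-point input for the reference-KL comparison (within 20%), and
n = 133 for the full-pipeline smoke runs. Bandwidth search tolerance is
1e-6 in entropy; probability matrices are floored at 1e-18 inside KL and
gradient computations; all acceptance-facing rounding uses half-up.

## Known limitations

* OpenBabel aborts a batch conversion at the first invalid SMILES, so
  validation is per molecule; large-scale canonicalization batches retry
  stragglers individually.
* The aromatic-ring count behind MACCS key 125 counts 5–7-membered
  all-aromatic rings, which covers the chemistry in scope but not exotic
  aromatic macrocycles.
* Scaffold networks grow with the number of ring systems (tree-connected
  subsets); molecules with many ring systems are tractable here because
  food bitterants rarely exceed four or five.
* The promiscuity statistics treat the input activation table as
  authoritative; conflicting literature reports must be resolved upstream.
  Receptor lists are reported as given even when they reference receptors
  absent from a summary table built on another subset.
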