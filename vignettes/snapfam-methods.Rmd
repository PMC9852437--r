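---
title: "Annotating molecular networking subnetworks by compound family: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating molecular networking subnetworks by compound family: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MS² molecular networking groups tandem mass spectra into a graph whose
connected components ("subnetworks") tend to contain structurally related
analytes. Identifying *which* compound family a subnetwork contains usually
requires reference MS² spectra, which exist for only a small minority of
known natural products. `snapfam` annotates subnetworks using **only the MS¹
parent masses** and a structure reference database, exploiting a statistical
property of natural-product chemical space: while a single molecular formula
is compatible with many unrelated structures, a *set* of formulae that
co-occur in one subnetwork is highly diagnostic for a single compound
family. The package quantifies exactly this property on any reference
database (`formulaCounts()`, `familyTupleOccurrence()`,
`distributionSummary()`), and builds the annotation pipeline on top of it.

## The annotation model

For one subnetwork with parent masses $m_1,\dots,m_n$:

1. **Binning.** Masses are sorted and greedily binned into *compound
   groups*: a new group opens whenever the next mass deviates from the
   current group's representative by more than the ppm window. The
   representative is the group **minimum** — the lowest mass is a
   deterministic choice and favours the monoisotopic peak when isotope
   features co-occur. Coverage is later counted over compound *groups*, not
   raw masses, because binning exists precisely to collapse redundant
   features of one analyte; the alternative (counting raw masses) would let
   a duplicated feature count twice.

2. **Candidate retrieval.** Each representative mass $m$ is searched against
   the database through a panel of singly charged positive adducts. A record
   with neutral monoisotopic mass $M$ matches under adduct $a$ iff

   $$\left|\frac{m - (M + \delta_a)}{M + \delta_a}\right| \times 10^6 \le
   \text{ppm}.$$

   The default shifts are cation masses (electron mass included):
   $\delta_{[M+H]^+} = +1.007276$, $\delta_{[M+Na]^+} = +22.989218$,
   $\delta_{[M-H_2O+H]^+} = -17.003289$ Da. The ppm error is reported
   relative to the **theoretical** adduct m/z; the alternative convention
   (observed denominator) differs by under $10^{-4}$ ppm inside a 10 ppm
   window, so the choice is documented rather than consequential. One record
   may match under several adducts; it still counts once per group for
   coverage.

3. **Clustering.** Candidates from *all* groups are pooled (deduplicated by
   id) into one similarity network: Morgan fingerprints (radius 2, hashed to
   2048 bits), Sørensen–Dice scoring, and an edge iff the score is **at or
   above** the cutoff (closed threshold, so the printed cutoff 0.71 is
   attainable exactly). Compound families are the connected components,
   singletons included.

4. **Filtering and ranking.** Families with fewer than `minFamilySize`
   (default 3) members are removed. Survivors are ranked by the number of
   compound groups their members explain — **coverage, not size**, because
   large families of isobaric regio- and stereoisomers would otherwise
   dominate. Ties break by family size, then mean pairwise member
   similarity, then smallest member id; the tie-break chain beyond coverage
   is this package's own convention, chosen to be deterministic and to
   prefer the more coherent family. Finally, results graphs exceeding 2000
   nodes or 10,000 edges are flagged `graph_too_large` (and their family
   list cleared) instead of being silently dropped, so database-driven false
   negatives remain auditable.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `ppmWindow` | 10 ppm | binning and query tolerance; matches a typical high-resolution instrument |
| `adducts` | `[M+H]+`, `[M+Na]+`, `[M-H2O+H]+` | user-extensible panel of +1 species |
| `cutoff` | 0.71 | candidate clustering (0.75 for database-wide family precomputation) |
| `minFamilySize` | 3 | families of ≤ 2 members are discarded |
| `minGnpsClusterSize` / `maxGnpsClusterSize` | 3 / 5000 | subnetwork size filter when splitting a network |
| `maxNodeCount` / `maxEdgeCount` | 2000 / 10,000 | results-graph size limits |
| `fpMethod`, `fpRadius`, `metric` | morgan, 2, dice | clustering configuration |

The two cutoffs are not arbitrary: 0.71 is the value selected by the
benchmark procedure below for candidate clustering, and 0.75 is the
database-family convention used by the formula statistics.

## Fingerprints and similarity

Fingerprinting runs through OpenBabel (via its command-line interface, with
`ChemmineR` handling SDF structures for atom pairs):

* **Morgan** — OpenBabel's circular ECFP fingerprints; radius $r$ maps to
  diameter $2r$ (supported radii 1–5, i.e. ECFP2–ECFP10; the default and
  benchmark-selected radius is 2). The native 4096-bit vector is folded to
  2048 bits, the dominant community default for hashed circular
  fingerprints.
* **MACCS** — the 166 structural keys.
* **atom pair** — atom-pair descriptors hashed into 2048 bits (the folding
  is modular on the descriptor integers; a reference-set-based folding would
  tie results to an external descriptor dictionary).

Scoring is Dice $2|A\cap B|/(|A|+|B|)$ or Tanimoto $|A\cap B|/|A\cup B|$;
Dice ≥ Tanimoto always. Two empty bit sets score 0 under both metrics (the
convention of the major cheminformatics toolkits); the corner case cannot
arise for parseable multi-atom structures. Stereochemistry is not encoded by
any of the three fingerprint types, so isobaric stereoisomers co-cluster by
construction — acceptable here, since family-level annotation is the goal.
Salts/solvents are not stripped: curated natural-product databases store
parent structures. Different toolkits hash circular environments
differently, so database-wide family *counts* can shift by a small amount
across toolkits even though the clustering behaviour is equivalent; exact
bit-level reproduction of another tool's family census is not a goal.

## Selecting the clustering method (benchmark module)

Given a reference MS² network over compounds of known structure,
`sweepMethods()` computes, for each fingerprint/metric configuration and
each cutoff in a grid (default 0.01–1.00 by 0.01):

* `tp_pct` — the percentage of MS-network edges also created by the
  structural network;
* `tn_pct` — the percentage of MS-network **non-edges** also excluded.

The non-edge denominator keeps a "0.5% false positives" ceiling meaningful
on sparse networks (an all-pairs denominator would make any false-positive
rate vanish as networks grow). `selectClusteringMethod()` takes, per
configuration, the smallest cutoff whose `tn_pct` reaches the floor
(default 99.5%), then picks the configuration with the highest `tp_pct`
there. False edges merge unrelated families and distort the network far
more than missing edges fragment it — hence a hard false-edge ceiling
rather than, say, a Youden-style trade-off. Nodes present on only one side
are dropped pairwise (MS networks omit unclustered spectra); several MS
nodes mapping to one structure should be collapsed to one node keyed by
compound id before the comparison.

## The synthetic fixture generator

`generateReferenceFixture()` emulates the scaffold-centric structure of
natural-product chemical space: each seeded family is one of ~20
natural-product-like scaffold templates (flavonoids, quinones, indole
diketopiperazines, macrolactones, a steroid, a cyclopeptide, ...) decorated
at three peripheral sites with small substituents (methyl, hydroxyl,
methoxy, halogens, acetyl, acetoxy). Members are accepted greedily, in
seeded random order, under two verified constraints: every within-family
Morgan r=2/Dice similarity is at or above the clustering cutoff (the family
is a clique, hence a connected component), and every cross-family
similarity stays below it. Decoys come from a curated list of structurally
diverse metabolites, each sitting below the cutoff against every scaffold
family and against each other. Formulae and masses are computed from the
structures; subnetwork masses are emitted through the adduct panel with
uniform ppm jitter (jitter is uniform in ppm, not Da, mimicking how
instrument mass accuracy is specified). Defaults: 3 families × 6 members,
30 decoys, adduct mix 60/20/20 across the panel, 5 ppm noise against a
10 ppm window.

What the fixtures do **not** emulate: isotopologues, multiply charged or
negative-mode species, in-source fragments beyond the modelled water loss,
chimeric features, retention-time structure, and the long-tailed similarity
continuum of real databases (real compound families are not cliques and
real decoys are not guaranteed to sit below the cutoff). Passing the
end-to-end tests therefore demonstrates that the pipeline recovers planted
structure under controlled conditions — not that any particular real
subnetwork will be annotated correctly.

## Numerical and degenerate-input choices

* Binning is a single greedy pass over sorted masses; the window is
  evaluated against the group's first (lowest) member, so group width never
  exceeds the window in ppm terms relative to the representative.
* Mass queries use a sorted-mass index with an interval search per adduct;
  results are returned sorted by absolute ppm error with id/adduct as
  deterministic tie-breaks.
* Structures that OpenBabel cannot parse are *skipped and counted* at
  database load (an error only if the majority of a dump fails, to catch
  format mix-ups), skipped with a warning during network building, and a
  hard error only when a single structure is explicitly fingerprinted.
* Family ids (`CF0001`, ...) are assigned by the lexicographically smallest
  member id, making family extraction order-independent.
* An empty query result, an empty family list after filtering, and an
  oversized results graph are distinct, explicit statuses
  (`no_candidates`, `all_families_filtered`, `graph_too_large`), never
  silent empties.
* Fingerprints are memoised per session keyed by (method, radius, SMILES);
  the cache affects timing only.

## Problem sizes used by the test-suite and acceptance script

The shipped checks run entirely on generated fixtures: reference databases
of ~50 records (3×6 family members + 30 decoys), 100 seeded end-to-end
runs for the recovery-rate estimate (with a ≥95% pass line), a ten-fold
decoy excess for the stability check, 1000 random bit-vector pairs for the
Dice/Tanimoto dominance property, and brute-force oracle comparisons on
databases and networks of ≤ 200 compounds. Full-database integration checks
(the published census numbers for the pinned NPAtlas v2020_06 dump, the
trichostatin worked example, and the NIH Round-1 benchmark selection)
require externally downloaded inputs and run only when those files are
supplied under `tests/testthat/integration/`.

## Known limitations

* Only singly charged positive adducts are modelled; the panel is
  user-extensible but the charge is fixed at +1.
* Annotation quality is bounded by database coverage: a subnetwork whose
  family is absent from the reference database can at best return
  `no_candidates`, and with very large databases the results-graph size
  filter converts some would-be annotations into explicit
  `graph_too_large` refusals.
* COCONUT dumps carry no usable organism taxonomy, so taxonomy filtering is
  restricted to NPAtlas-style and fixture databases.
* Morgan radii above 5 are not available from the underlying fingerprinter.
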