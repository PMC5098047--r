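---
title: "Function-potential scoring of PTM hotspots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function-potential scoring of PTM hotspots: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the unit of
analysis, each feature's definition and the choices behind it, the scoring
model and its training procedure, the downstream statistics, what the
synthetic generators do and do not emulate, and the numerical conventions
that make everything deterministic.

## The unit of analysis: modified alignment positions

A protein family's experimentally observed PTM sites are projected onto
the columns of its multiple sequence alignment. A column holding at least
one observation is a *modified alignment position* (MAP). Pooling across
the family is the central move: a site phosphorylated in yeast and
acetylated in human at the same column is one piece of evolutionary
evidence, not two unrelated observations. A MAP is labeled
*known-function* when any of its observations has experimentally
demonstrated biological function; the number of independent literature
sources behind that call (the known-function source count, KFSC) is kept
as a confidence measure, binned 1, 2, 3, 4, 5–10, 11+.

Conventions: native positions and alignment columns are 1-based;
intervals are closed. A PTM's residue must match the canonical sequence at
its stated position or the row is rejected (with a per-row reason) during
ingestion; putative sites flagged in the input are dropped outright.

## The six features

* **PTM count (PC)** — observations projected onto the column. The single
  strongest feature, but useless at PC = 1 (most of any real dataset), by
  construction: all values tie.
* **Conservation** — the fraction of members whose residue at the column
  matches *any* amino-acid identity observed modified there, gaps counted
  in the denominator. The fraction-of-matching-members definition was
  chosen because it is deterministic, bounded in (0, 1], and reduces to
  plain fractional identity when a single modified identity exists. Other
  conservation scores (entropy-based, substitution-matrix-based) would be
  defensible; this one is the simplest that respects the "union of
  modified identities" semantics.
* **SASA** — per-residue solvent accessible surface area from an in-house
  Shrake–Rupley implementation (below), averaged over qualifying chains,
  then averaged over the MAP's member observations with values. Residues
  unresolved in every structure but predicted disordered (tendency > 0.5)
  receive the protein's maximal observed per-residue SASA — disordered
  tails are maximally exposed even though no crystal shows them; residues
  unresolved and predicted ordered receive no value at all, because
  inventing exposure for a structured-but-uncaptured residue would be
  wrong in both directions. The mean-across-chains / max-for-fallback
  aggregation is a design choice; both are configurable sites in the code.
* **PPI residence** — a residue is at an interface when any of its heavy
  atoms lies within 5 Å (configurable) of a heavy atom of a different
  chain in the same structure. At MAP level this becomes the fraction of
  structurally covered members flagged, 0 when nothing is covered. A
  geometric contact criterion replaces database lookups; 5 Å heavy-atom
  contact is the standard cutoff in interface analysis.
* **NC / NKC** — neighbor count and neighbor known count within ±2
  alignment columns, never counting the MAP's own column. The window is
  configurable with the ±2 default.

Missing SASA enters the model as 0. This keeps the feature vector dense;
the alternative (imputation or a coverage indicator feature) would change
the model's dimensionality, and rank-based evaluation is insensitive to
the choice at realistic coverage.

## Structure ingestion and quality filters

Only x-ray-style ATOM records of the 20 standard residues are used, first
model only, alternate locations resolved per atom by highest occupancy
then alphabetical altloc code. Chains qualify when (i) strictly more than
50 residues are resolved and (ii) the resolved residues map cleanly onto
the canonical sequence. The mapping splits resolved residues into blocks
of consecutive residue numbers and requires each block to occur verbatim
in the canonical sequence, left to right (greedy first occurrence). Any
internal insertion or deletion — the signature of a chimeric or
engineered construct — rejects the whole chain as "noncanonical". Greedy
matching can in principle reject a chain a scored alignment would rescue,
but it is deterministic and errs toward exclusion, which is the right
direction for a quality filter.

## Shrake–Rupley SASA

Each atom is surrounded by 960 quasi-uniform test points (golden-section
spiral) on its solvent-expanded sphere (van der Waals radius + 1.4 Å
probe); points inside any neighbor's expanded sphere are buried; the
accessible area is the exposed fraction times 4π(r + p)². Per-atom areas
sum per residue. Radii: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 Å;
unknown elements fall back to 1.70 Å with a warning.

Two numerical details matter. First, each atom's point sphere is oriented
by a local frame built from the directions to its nearest and nearest
non-collinear neighbors. The frame co-rotates with the molecule, so SASA
is invariant under rigid motion to floating-point precision — with a
lab-fixed point set it would only be invariant to ~1%. Degenerate
collinear clusters fall back to an arbitrary completion, where burial is
axially symmetric anyway. Second, convergence: at 960 points the
chain-total SASA is within 1% of the 3840-point value, individual
residues within ~5%; downstream use is rank- and feature-based, so this
is ample. Absolute values from coarse-grained calculators (e.g.
POPS-style) differ systematically; the model consumes whatever calculator
is configured, and comparisons should never mix calculators.

## The scoring model

Single-feature baselines are maximum-likelihood univariate logistic
regressions (complete separation triggers a small-ridge refit; constant
features get an intercept-only fit). The integrated model is a fully
connected 6–3–1 network: inputs standardized on the training partition,
tanh hidden layer, logistic output. Training minimizes cross-entropy plus
an L2 penalty of 1e-3 on the weights, by full-batch BFGS (analytic
gradients, up to 500 iterations) from a seed-controlled uniform
initialization in [−0.5, 0.5]/√6. A random 33% holdback is scored by the
trained model for validation; the partition is redrawn (≤ 10 times) if
either class is missing from either side. Identical seeds give
bit-identical parameters. Three hidden nodes are the fixed topology;
architecture search is out of scope.

Evaluation is by ROC–AUC computed as the rank statistic (probability a
random positive outscores a random negative, ties ½) — exactly the
pairwise concordance, as the test suite verifies by brute force. Model
AUCs on the same samples are compared with a chi-square statistic
(AUC₁ − AUC₂)²/Var(diff) on 1 degree of freedom, the variance from paired
DeLong placement covariances (cross-checked against pROC). Class
imbalance (~6% positives) is left unweighted. The PTM-count-threshold
sweep restricts the scored set to MAPs with PC ≤ t and recomputes each
model's AUC on the restriction — no retraining — so at t = 1 a PC-only
model is exactly 0.5 (all values tie) while the integrated model keeps
whatever signal the other five features carry. KFSC-stratified AUC takes,
for each bin, that bin's known MAPs as positives against all unknown MAPs.

A note on seed stability: the training seed also redraws the holdback
partition, so validation AUCs across seeds differ by partition sampling
noise (≈ 0.01 at n = 20,000 with 6% positives) on top of any training
instability. The stability test therefore compares two retrained models
on the common full fixture, isolating the training contribution (< 0.02).

## Hotspots, enrichment and variants

The hotspot threshold is the largest observed score t such that at least
90% of MAPs with KFSC ≥ 11 score ≥ t — the empirical lower-decile with
conservative (lower-value) interpolation, so the coverage contract holds
exactly on every dataset. At least 10 such MAPs are required; otherwise
the caller must supply a threshold explicitly. On the real-scale data the
published value of this construction is 0.196; the package reports its
derived value alongside that default rather than asserting it, because
the threshold is a property of the score distribution, not a constant.

Enrichment of a subset above threshold t is observed / expected with
expected = |subset| · P(score ≥ t): the fixed-margin (hypergeometric-mean)
expectation under random subset placement. It is exactly 1 when the
subset is everything, ≈ 1 for score-independent subsets, and ≈ 10 for a
subset confined to the top decile at the decile threshold.

Clinical missense variants join MAPs by projecting the variant's native
position through its protein's alignment row. A match is Type-1 when that
exact (protein, position) carries an observed PTM in the MAP, Type-2
otherwise; the classes partition all matches. Variants of
other/uncertain significance are retained in joins but excluded from
pathogenic/benign enrichment, which pools pathogenic with
likely_pathogenic and benign with likely_benign. Only exact column
matches count as coincident; near-misses are simply dropped (reported in
the drop table), not annexed to neighboring hotspots.

## PTM-type coincidence

MAPs with ≥ 2 distinct PTM types form the coincident subset. Every
unordered type pair within a MAP increments that pair's edge; a node's
occurrence is the number of coincident MAPs containing the type. The
*relative edge count*, count(a,b)/(occ(a)+occ(b)), removes the bias
toward abundant types (any display scaling is cosmetic; analysis uses the
raw ratio). Edges are *typical* when the two types can modify a common
residue under the packaged chemistry table (phospho S/T/Y; Ub/SUMO/NEDD/
acetyl K; methyl K/R; citrulline R; N-glyco N; O-glyco S/T; hydroxy P/K;
nitrosyl/disulfide/palmitoyl/prenyl/glutathionyl C; myristoyl G; Gla E) —
user-overridable, and unknown types are an error rather than a silent
guess. Outlier edges per typicality group are Tukey upper-fence flags
(> Q3 + 1.5·IQR, quartiles by linear interpolation; groups under 4 values
are undefined). Disorder stratification pools member-residue disorder
tendencies per type-count class (2, 3, 4, 5+) and reports the ordered
fraction (tendency ≤ 0.5).

## What the synthetic generators emulate

Every input format has a seeded generator; all randomness flows from one
seed through per-family hashed substreams, so adding families never
perturbs existing ones, and identical configurations are byte-identical.

* Families: a root sequence with i.i.d. substitutions (rate 0.15) per
  member and column-wise gaps (rate 0.06), so each member's canonical
  sequence is its ungapped row by construction. PTMs land only on
  residues chemically compatible with their type; type frequencies follow
  the empirical dominance of phosphorylation (~61%), ubiquitination and
  acetylation.
* Labels: known-function is Bernoulli with logit linear in the six
  features. The default intercept (−6.2) and coefficients (PC 0.55, SASA
  0.014, cons 1.8, PPI 0.9, NC 0.15, NKC 0.7) were fixed once to give the
  ~6% positive rate and a Bayes AUC near 0.8 — the regime of curated PTM
  datasets. KFSC for positives is truncated-geometric on 1..68 with mean
  rising in the linear predictor, reproducing the monotone
  confidence–score relationship.
* Structures: idealized α-helical backbones (rise 1.5 Å, 100°/residue)
  over a contiguous covered subrange, optionally with a docked second
  chain at 4 Å to create interfaces; unresolved residues exercise the
  disorder fallback. Disorder tracks are smoothed noise elevated toward
  both termini.
* Variants: pathogenic variants are placed on MAP columns with weight
  exp(bias · z-score), a quarter of them exactly on observed PTM sites
  (Type-1), the rest on unmodified members of the same column (Type-2,
  the ~1:3 regime); benign variants go half uniformly over residues and
  half onto MAP columns with the inverse weight, emulating the
  concentration of tolerated variation at unconstrained positions.

What they do *not* emulate: real phylogenetic correlation (substitutions
are i.i.d.), realistic fold geometry (helices only — SASA values are
internally consistent but not protein-like in distribution), curation
artifacts, or family-size/PTM-density heterogeneity beyond the configured
ranges. A passing suite therefore demonstrates that the machinery is
correct and the statistical contracts hold under known generative truth —
not that any particular biological effect size will be observed on real
data.

## Problem sizes and runtime choices

The test and acceptance workloads were sized for a laptop-class single
core: model-recovery fixtures at n = 20,000 MAPs (where the holdback AUC
estimates carry ≈ 0.01 standard error), enrichment calibration at
n = 10,000, demo pipelines at 8–10 families (~300–400 MAPs) with 240
sphere points for SASA (960 is the analysis default), and ROC oracles at
≤ 200 samples × 100 replicates. The full suite runs in a few minutes; the
acceptance script in about one.

## Known limitations

* Conservation is interpretation-dependent (see above); entropy-style
  scores may rank differently at polymorphic columns.
* One canonical sequence per protein identifier; isoforms must be given
  distinct identifiers upstream.
* The chimera filter's greedy block matching can reject repeat-rich
  chains that a scored alignment would place.
* The network is intentionally small; with many fewer than ~200 MAPs the
  trainer refuses to run, and with very few positives the holdback AUC is
  noisy.
* mmCIF, NMR structures and external database retrieval are out of scope.
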