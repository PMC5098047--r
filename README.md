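# saphire

Structure-aware function-potential scoring of post-translational
modification (PTM) hotspots.

Mass spectrometry now detects PTM sites far faster than they can be tested
for biological function: only a few percent of curated eukaryotic PTMs have
experimentally demonstrated effects. `saphire` prioritizes them. It pools
PTM observations across a protein family by projecting every site onto its
multiple-sequence-alignment column — a **modified alignment position
(MAP)** — and asks how likely the modifications at that column are to
matter biologically. The package is aimed at proteomics and structural
bioinformatics groups who have family alignments, PTM tables and crystal
structures, and want a ranked list of candidate regulatory sites.

## The model

Each MAP is described by six features:

| feature | meaning |
|---|---|
| `ptm_count` (PC) | number of PTM observations projected onto the column |
| `sasa` | mean solvent accessible surface area of the modified residues (Å², Shrake–Rupley, probe 1.4 Å), with a disorder fallback for unresolved residues |
| `conservation` | fraction of family members whose residue at the column matches a modified identity (gaps count in the denominator) |
| `ppi` | fraction of structurally covered members whose residue sits at a protein–protein interface (heavy-atom contact < 5 Å to another chain) |
| `nc` | neighbor count: other MAPs within ±2 alignment columns |
| `nkc` | neighbor known count: those neighbors with known function |

A MAP is labeled known-function (y = 1) when at least one of its
observations has experimentally demonstrated function. The score is a
fully connected 6–3–1 network

&nbsp;&nbsp;&nbsp;&nbsp;p(x) = σ( W₂ᵀ tanh(W₁ᵀ x̃ + b₁) + b₂ ),&nbsp; x̃ = (x − μ)/s,

trained by BFGS on L2-penalized cross-entropy with a random 33% holdback
for validation, evaluated by ROC–AUC (rank statistic, ties ½), and
compared between models with a paired DeLong chi-square test. MAPs scoring
at or above a threshold derived from the high-confidence score
distribution (the largest score retaining ≥ 90% of MAPs with 11+
known-function sources) are called **function-potential hotspots**.
Downstream analyses: enrichment of subsets above score thresholds versus
random chance, PTM-type coincidence networks with typical/atypical edge
chemistry and Tukey-fence outliers, and clinical missense-variant
coincidence (Type-1: the variant is itself an observed PTM site; Type-2:
it aligns to a modified column of another family member).

All six input formats (aligned FASTA, PTM/disorder/variant TSVs, PDB
coordinates, chain→protein map) have seeded synthetic generators, so the
whole pipeline runs and is tested without any external database.

## Worked example

```r
library(saphire)
demo <- run_demo(seed = 42, n_families = 10)   # simulate + full pipeline
demo$result
#> saphire_result: 357 MAPs, 23 known-function; validation AUC 0.852;
#>   threshold 0.196 -> 26 hotspots
demo$result$enrichment_known
#>   threshold observed  expected     ratio
#> 1     0.100       16 3.4789916  4.599034
#> 2     0.196       11 1.6750700  6.566890
#> 3     0.350        7 0.6442577 10.865217
#> 4     0.500        5 0.3865546 12.934783
demo$result$network
#> coincidence_network: 7 nodes, 9 edges, 20/357 mixed-type MAPs
```

Ten simulated families give 357 MAPs, 23 of them known-function. The
network's holdback AUC is 0.852: on held-out MAPs a random known-function
position outscores a random unknown one 85% of the time. The enrichment
table shows known-function MAPs concentrated 4.6- to 12.9-fold above
chance as the score threshold rises — the signature of a useful ranking.
(The demo's high-KFSC subset is too small to derive a threshold, so the
default 0.196 is used.) With real data, replace the simulated inputs with
`read_alignment()`, `read_ptm_table()`, `read_structure()`,
`read_disorder_table()` and `read_variant_table()`, then call
`run_pipeline()`; `inst/scripts/saphire` wraps the same stages as a
command line (`saphire demo|simulate|all`).

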