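# smdiv

Surveying the diversity of secondary-metabolite biosynthetic genes —
non-ribosomal peptide synthetase (NRPS) and polyketide synthase (PKS)
domains — in rhizosphere amplicon sequencing data.

Soil and rhizosphere bacteria encode much of their chemical repertoire
(antibiotics, siderophores, surfactants) in NRPS and PKS gene clusters.
Amplifying fragments of their catalytic domains (adenylation for NRPS;
ketosynthase, methyl-malonyl-CoA transferase and acyl carrier protein for
PKS) with degenerate primers turns a soil DNA extract into a sequence
survey of that repertoire. `smdiv` is an R package for the full in-silico
side of such a survey, built for a design with multiple sampling sites,
plant vegetation stages and biological replicates:

- **Degenerate primers**: IUPAC expansion and degeneracy, mismatch-tolerant
  matching on both strands, in-silico amplicon extraction, primer-anchored
  reference-set construction (`expand_degenerate`, `match_primer`,
  `extract_amplicons`, `build_reference_db`). The survey's three primer
  pairs ship in `primer_pairs()`.
- **Read prep** (454-style): rolling-window quality truncation, barcode
  demultiplexing with primer clipping, exact dereplication with singleton
  removal, abundance-skew two-parent chimera flagging, common-length
  trimming.
- **Clustering**: global-alignment identity, greedy centroid (UCLUST-style)
  clustering at any thresholds, OTU tables with per-sample counts,
  representative picking, query-vs-reference shared-cluster accounting.
- **Diversity**: bias-corrected Chao1, iterated rarefaction, coverage, and
  the effective-species community-overlap model
  `(α/γ − 1/N) / (1 − 1/N)` on per-site vs pooled richness.
- **Sharing**: replicate-consistency filtering (present in ≥2 of 3
  biological replicates) and exact Venn region counts across sites and
  stages at several identity thresholds.
- **Phylogeny**: neighbor-joining trees of cluster representatives on
  identity distances, annotated Newick output.
- **Statistics**: Bray-Curtis + NMDS with Shepard diagnostics;
  per-OTU negative-binomial GLMs with likelihood-ratio tests, a summed
  multivariate statistic and bootstrap (residual-resampling) p-values;
  Spearman correlation of differentially abundant marker vs SM-gene OTUs
  with genus-abundance and taxon-pairing filters.
- **Functional assignment**: six-frame translation, local protein
  alignment with BLAST-style bitscores/E-values, and the pass rule
  identity ≥ 70 % aa, alignment ≥ 200 aa (AD) / 100 aa (others),
  E ≤ 1e-25.
- **Synthetic communities**: `community_spec()` / `simulate_community()`
  generate amplicon reads with known family structure, controlled
  between-site overlap, stage effects, 454-like errors and chimeras, plus
  a truth table — every stage above is testable offline against ground
  truth.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()`/`plot_*()` companions.

## Worked example

```r
library(smdiv)

spec <- community_spec(n_families_per_site = 20, reads_per_sample = 150,
                       between_site_overlap = 0.3, error_rate = 0.01,
                       chimera_rate = 0.03, seed = 42)
cfg <- pipeline_config(outdir = "smdiv_demo", spec = spec, seed = 42)
res <- run_pipeline(cfg)

res$cluster_counts
#> # A tibble: 4 × 2
#>   threshold clusters
#>       <dbl>    <int>
#> 1      0.75       29
#> 2      0.85       29
#> 3      0.9        29
#> 4      0.97       37

res$diversity$overlap_pct
#> [1] 39

glance(res$differential)
#> # A tibble: 2 × 6
#>   factor  stat p_boot n_otu n_otu_excluded n_boot
#>   <chr>  <dbl>  <dbl> <int>          <int>  <dbl>
#> 1 site   447.   0.005    37              0    199
#> 2 stage   69.3  0.02     37              0    199
```

Reading: the generator plants 36 distinct gene families across the three
sites; 29 of them survive singleton removal at this modest depth (150
reads/sample) and are recovered as exactly one cluster each at thresholds
up to the build divergence — extra clusters appear only at 97%, where
within-family lineages split. The overlap percentage is the
effective-species overlap among sites computed from per-site and pooled
Chao1 richness (above the planted 30% here because shallow sampling
censors rare site-specific families more than shared ones). Both site and
stage significantly structure OTU composition; the stage signal is the
planted 4-fold shift in 20% of families, and `p_boot = 0.005` is the
smallest value attainable with 199 bootstrap resamples.

Per-stage outputs (OTU tables, sharing reports, Newick tree, assignment
tables, a record-count manifest) are written under `outdir`; identical
config + seed reproduces them byte for byte.

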