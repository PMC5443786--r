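---
title: "Methods: surveying NRPS/PKS domain diversity in rhizosphere amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying NRPS/PKS domain diversity in rhizosphere amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdiv)
options(smdiv.verbose = FALSE)
```

## The scientific problem

Soil bacteria — above all Actinobacteria and Firmicutes — synthesize
secondary metabolites (antibiotics, siderophores, surfactants, toxins)
through two families of giant modular enzymes: non-ribosomal peptide
synthetases (NRPS) and polyketide synthases (PKS). The diversity of the
genes encoding their catalytic domains is a proxy for the chemical
diversity a community can produce. A practical way to survey that
diversity is to amplify short fragments of those domains directly from
community DNA with degenerate primers — the adenylation (AD) domain of
NRPS, and the ketosynthase (KS), methyl-malonyl-CoA transferase
(met-mal-CoA) and acyl carrier protein (ACP) domains of PKS — sequence the
amplicons, and analyze the resulting mixture of gene variants per sample.

`smdiv` implements that analysis end to end for a rhizosphere survey
design: three sampling sites (`P1`, `P2`, `P3`), two vegetation stages
(`emergence`, `senescence`), three biological replicates each. Every
stage of the pipeline is a plain function over tibbles, so the pieces can
be used separately or chained through `run_pipeline()`.

## Degenerate-primer arithmetic and in-silico PCR

Primers are IUPAC strings; `degeneracy()` is the product of per-position
degeneracies and `expand_degenerate()` materializes the variant set (the
bundled ACP forward primer expands to $4^5 \cdot 2^6 = 65{,}536$
oligos). Matching (`match_primer()`) is ungapped: a mismatch is a target
base outside the primer position's allowed set; minus-strand hits are
searched on the reverse complement and reported in forward coordinates.
`extract_amplicons()` pairs forward hits with reverse-complemented
reverse-primer hits, reports every candidate span (flagging templates
with multiple hits) and re-orients output 5'→3' with respect to the
forward primer. Amplicons *include* the primers, matching the advertised
amplicon sizes (~200 bp ACP, ~700 bp AD, ~1200–1400 bp KS).

`build_reference_db()` mirrors the construction of a primer-anchored
reference set from a larger sequence collection: a candidate is kept only
when each primer matches with ungapped identity ≥ 0.90 *over the full
primer length* (identity $= 1 - \text{mismatches}/\text{primer length}$);
retained candidates are trimmed to the amplicon region and dereplicated
exactly. Full-primer-length ungapped matching stands in for an external
aligner: the filter quantity (per-primer identity) is the same, the
machinery is self-contained. Indel-tolerant primer matching is
deliberately out of scope.

## Read preparation

The prep order is fixed: `quality_filter()` → `demultiplex()` →
`dereplicate()` → `flag_chimeras()` → `trim_to_common_length()`. Total
read mass is non-increasing at every stage, and each stage logs its
input/output counts (suppress with `options(smdiv.verbose = FALSE)`).

**Quality truncation** uses a trailing window (default 50 bp, mean PHRED
cutoff 20): the read is cut just before the start of the first window
whose mean falls below the cutoff; reads shorter than one window after
truncation are dropped. Reads containing any ambiguous (non-ACGT) call
are removed — the strictest reading of "ambiguous calls removed", chosen
so that downstream exact dereplication is well defined; the log makes the
removals auditable.

**Dereplication** is exact-sequence, pooled across samples but with
per-sample counts retained (a `samples` list-column), so OTU tables keep
sample resolution. Uniques below `min_size = 2` (singletons) are dropped.

**Chimera flagging** is a deliberate simplification of abundance-skew
de-novo detection, keeping two ideas: candidate parents must be at least
`abundance_skew = 1.9` times as abundant as the query, and a chimera must
look like a two-parent crossover. For each breakpoint the prefix is
compared (ungapped, left-anchored) and the suffix (right-anchored)
against all candidate parents; the query is flagged when some *distinct*
parent pair beats the best single-parent model by `min_crossover_gain`
(default 0.05) on both segments. The single-parent null includes the best
parent's min(prefix, suffix) identity at the same breakpoint — without
this, a read that differs from an abundant parent by one homopolymer
indel looks exactly like a chimera of two sibling lineages and the
false-positive rate is catastrophic. Known limitation: chimeras that
themselves carry indel errors can defeat the ungapped anchoring, so
recall degrades with rising indel error rates; the accuracy bounds the
tests enforce (recall ≥ 0.9, FPR ≤ 0.05) are demonstrated on error-free
chimeric reads with 2× abundance skew, not on arbitrary error regimes.

## Clustering and shared-cluster accounting

`pairwise_identity()` is global (Needleman–Wunsch) alignment identity:
match +1, mismatch −1, first gap column −2, each extension −1; identity =
matching columns / alignment columns with terminal-gap columns excluded
(amplicons are length-trimmed, but reference fragments may overhang).
Internal gaps count as non-matching columns.

`greedy_cluster()` is single-pass centroid clustering in the UCLUST
style: sequences sorted by (size desc, length desc, id asc); each joins
the *first* centroid, in creation order, with identity ≥ threshold, else
seeds a new centroid. The order dependence is intrinsic to this family of
algorithms, which is why the sort key is fixed and documented. Two exact
shortcuts keep it fast without changing results: gapless alignments need
no traceback (identity = matches/columns), and since alignment columns ≥
matches + mismatches, the ratio matches/(matches+mismatches) is an upper
bound on identity — a pair whose bound is already below the threshold can
be rejected without traceback.

`shared_with_reference()` pools a query set and a reference set, clusters
at each threshold, and partitions clusters into query-only,
reference-only and shared (≥1 member from each side); the three counts
always partition the total, and cluster counts are non-increasing as the
threshold drops.

## Richness and the alpha/gamma overlap model

`chao1()` uses the bias-corrected estimator
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (defined even when no doubletons are
present; the classic $F_1^2/2F_2$ form is behind a flag). Coverage is
reported both as the raw ratio observed/Chao1 and as a half-up-rounded
percentage; base R's banker's rounding would disagree with conventionally
printed tables on .5 boundaries. `rarefy_curve()` subsamples without
replacement, by default 10 iterations per depth, and reports mean
observed richness and Chao1.

Community overlap among $N$ sites uses effective species numbers:
$$\mathrm{overlap} = \frac{\alpha/\gamma - 1/N}{1 - 1/N},$$
with $\alpha$ the mean per-site richness and $\gamma$ the pooled
richness, clipped to $[0,1]$: 1 when all communities are identical,
0 when they are disjoint ($\alpha/\gamma = 1/N$). The package computes it
on Chao1 richness (observed-OTU richness is reported alongside). A pooled
estimate below the largest per-site estimate is estimator noise and
warns rather than errors.

## The synthetic community generator

`community_spec()` fixes the study conditions: 3 sites × 2 stages × 3
replicates, 5% aggregate per-base error (the pyrosequencing regime the
pipeline is built for) with half of the errors realized as
single-base indels inside homopolymer runs of length ≥ 3 (a caricature of
454 chemistry sufficient to exercise dereplication and clustering, not a
flowgram model), lognormal family abundances (meanlog 0, sdlog 1 — the
survey literature gives no abundance model, so a standard skewed choice
is exposed as a parameter), 50 families per site, 300 reads per sample by
default (desk-scale; per-sample depth targets are not part of the study
conditions), and amplicons of 200 bp carrying exact concretized primer
sites (one concretization per family, as a real template would).

Families are diversified on a star phylogeny: each family is an ancestral
random core mutated independently into 3 lineages at per-base rate
$(1-t)/4$ for build threshold $t$ (default 0.95), which keeps
within-family identity above $t$ and between-family identity near the
random floor. If $t - \text{margin}$ does not clear the estimated floor
(shared primers + ~55% alignment identity of random DNA), generation
refuses rather than emit unrecoverable families.

**Overlap calibration.** The generator guarantees two things at once:
`round(overlap × n_families_per_site)` families are shared by *all*
sites, and the alpha/gamma statistic on true per-site family counts
equals the requested overlap. With only all-shared and private families
these conflict — per-site richness $n$, all-shared count $on$ gives
$\gamma = n(3-2o)$ and a statistic of $o/(3-2o)$, not $o$. The package
therefore adds families shared by exactly two sites: with target
$\gamma^* = Nn/(1+(N-1)o)$ and per-site pair-participation $b$,
$\gamma = a + Nb/2 + N(n-a-b)$ yields
$b = \tfrac{2}{N}\,(a + N(n-a) - \gamma^*)$, which is feasible
($b \ge 0$, $a+b \le n$) for all $o \in [0,1]$. Pair-shared families are
distributed cyclically over site pairs; integer rounding keeps recovery
within ±0.02 at 50 families per site.

Stage effects multiply a `stage_shift` fraction of families (default
20%) by `1/stage_factor` (default 4) at senescence — declining abundance
with plant age, the direction the pipeline's differential test is
benchmarked against. Chimeras join two distinct same-sample parents at a
uniform interior breakpoint (≥30 bp from either end). Every read has
exactly one truth row; a fixed seed makes all outputs byte-identical.

What the generator does *not* emulate — realistic phylogenetic structure,
codon-aware evolution, correlated quality/error profiles, chimera
formation biased toward conserved regions — bounds what green tests mean:
they certify the pipeline's algebra and its behavior under the stated
error caricature, not performance on arbitrary real 454 data.

## Phylogeny of representatives

Representatives (cluster centroids, annotated with size and majority
site/stage) are related by neighbor joining on pairwise-identity
distances ($d = 1 - \text{identity}$). Identity distances replace an
external multiple alignment; they keep the contract self-contained, and
`neighbor_joining()` accepts any externally computed distance matrix for
users who prefer their own MSA-based distances. NJ on additive matrices
reconstructs the generating tree exactly; negative branch estimates —
a known NJ artifact on non-additive input — are clamped to zero and
logged. Newick leaf labels carry `id|site|stage|origin` with structural
characters replaced by `_` so output round-trips through any Newick
reader.

## Ordination and differential abundance

Bray–Curtis dissimilarity ($\sum|x_i-y_i| / \sum(x_i+y_i)$) feeds NMDS
(`vegan`'s engine, 20 seeded random starts, $k = 2$) on the 97%-identity
OTU table; the Shepard correlation between input dissimilarities and
ordination distances diagnoses fit quality alongside the stress.

Differential abundance uses, per OTU, a negative-binomial log-linear
model with per-OTU dispersion estimated by maximum likelihood. Each
factor (site, stage) is tested by a likelihood-ratio test against the
model with that factor dropped, and a community-level statistic sums the
per-OTU LRTs — the multivariate-GLM idea, rebuilt here with simulation
calibration rather than any claim of matching an external package's
internals. Inference is by residual resampling: randomized PIT residuals
of the null model are permuted across samples (one permutation shared by
all OTUs, preserving between-OTU association) and mapped back through the
null NB quantile function; $p = (1 + \#\{T^* \ge T\})/(B+1)$ with
$B = 999$ by default. This scheme preserves the NB mean–variance relation
under the null. The test suite verifies type-I error in $[0.01, 0.10]$ at
nominal 0.05 over 200 null repetitions (199 bootstraps each) and that
planted 4-fold effects rank to the top (AUC > 0.8). Saturated one-factor
designs use closed-form group-mean fits; general designs use IRLS with a
profiled dispersion, cross-checked against `MASS::glm.nb`. Non-convergent
OTUs are flagged and excluded from the sum.

For linking marker (16S rRNA) and SM-gene communities,
`correlate_differential()` computes tie-corrected Spearman correlations
between differentially abundant OTUs of both tables, after (i) an
unadjusted bootstrap $p < 0.05$ filter — the survey convention for
"differentially abundant" is not recorded, so the cutoff is configurable
and Benjamini–Hochberg adjusted values are reported alongside; (ii) a
mean relative genus abundance filter (> 1%); and (iii) taxon-pairing
rules (Firmicutes markers against ACP genes; Actinobacteria, Firmicutes
and Proteobacteria against KS, met-mal-CoA and AD genes).

## Functional assignment

Queries (representatives clustered at 100% identity) are translated in
six frames and aligned locally (Smith–Waterman, BLOSUM62, gap open 11 /
extend 1) against a characterized-domain table. Bit scores use the
published Karlin–Altschul constants for this matrix
($\lambda = 0.267$, $K = 0.041$) and
$E = m\,n\,2^{-\text{bit}}$ over the fixture's total residue count — the
BLAST conventions, without claiming bit-for-bit equality with any
external tool. An assignment passes iff identity ≥ 70% at the amino-acid
level, alignment length ≥ 200 aa for AD (100 aa for KS, met-mal-CoA,
ACP), and $E \le 10^{-25}$; only the best hit per query (bitscore, then
identity, then domain id) is eligible — best-hit semantics chosen where
the convention was ambiguous. The bundled fixture (`domain_fixture()`) is
*synthetic*: deterministic random proteins labelled with real compound
names, shaped like a curated domain database so the rule logic is
testable offline; real analyses should supply a real database in the
same four-column format.

## Numerical and design choices, in brief

- Percentages mirrored from printed tables use half-up rounding; raw
  ratios are always retained. Published per-site coverage values that
  disagree with direct rounding by one point are reported, not asserted.
- Greedy clustering ties (equal size and length) break by id; Venn
  percentages use the replicate-filtered cluster total as denominator;
  site comparisons pool stages after replicate filtering.
- Singleton removal precedes chimera checking (the abundance-skew test
  needs dereplicated sizes); the reverse order is not supported.
- Seeds: every stochastic stage takes an explicit seed; the pipeline
  derives per-stage seeds from one global seed, all below $2^{31}$.
- Problem sizes in the test suite (tens of families, hundreds of reads
  per sample, 199–999 bootstraps) are desk-scale choices that keep the
  full validation loop interactive while leaving every algorithmic path
  exercised.

## Worked example

```{r example, eval = FALSE}
spec <- community_spec(n_families_per_site = 20, reads_per_sample = 150,
                       between_site_overlap = 0.3, error_rate = 0.01,
                       chimera_rate = 0.03, seed = 42)
cfg <- pipeline_config(outdir = "smdiv_demo", spec = spec, seed = 42)
res <- run_pipeline(cfg)

res$diversity$overlap_pct      # alpha/gamma overlap among the three sites
res$cluster_counts             # clusters per identity threshold
glance(res$differential)       # community-level site/stage tests
autoplot(res$ordination, res$metadata)
```

The published headline quantity the package can recompute exactly from
printed inputs — the effective-species overlap among the three Andean
sites from their per-site and pooled Chao1 richness — is reproduced by
`scripts/acceptance.R` (see the README).
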