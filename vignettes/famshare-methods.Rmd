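---
title: "famshare: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{famshare: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

famshare is a pipeline for asking, with family-structured gut-metagenome
cohorts, three linked questions: (i) how much of the variation in
microbial community composition and in within-species genetic composition
is explained by the family a person belongs to, relative to family role,
ethnicity, sex, age and region; (ii) which species populations are
*shared* within families, in the sense that the genetic variation of their
genomes is structured by family; and (iii) what selective pressure and
functional potential those shared genomes carry. This vignette documents
the models, the tunable parameters, the synthetic-data generator and the
numerical conventions, in that order. It states no empirical result that
the test suite does not itself compute.

## Statistical model

**Variance partitioning.** The central statistic is PERMANOVA on a
dissimilarity matrix: the matrix is Gower-centered
(`G = -1/2 J D^2 J`, `J = I - 11'/n`), the total sum of squares is
`trace(G)`, and a factor's sum of squares is the trace of its hat-matrix
projection of `G`. For several factors we report *marginal* effects:
`SS(full) - SS(model without the factor)`, so each factor controls for
all others. Significance uses the pseudo-F statistic with whole-sample
label permutation for single factors, and permutation of residuals under
the reduced model (Freedman-Lane) for marginal tests — raw-label
permutation would not respect "controlling for all other variables".
`p = (1 + #{F* >= F}) / (1 + n_perm)`, so `p >= 1/(n_perm + 1)` always.
Negative-eigenvalue contributions of non-Euclidean matrices are retained
in the SS accounting, matching common practice. The implementation is
checked in the tests against an independent sums-of-squared-distances
oracle and against `vegan::adonis2` (R², F and df agree to 1e-10).

A caveat worth knowing: in small cohorts a family-level covariate such as
ethnicity or region can absorb most of the family degrees of freedom
(families are nested in ethnicity-by-region combinations), so the
*marginal* family R² can be far below the single-factor family R². This
is the intended semantics of a marginal test, not a defect; with many
families relative to covariate combinations the effect fades.

**Community level.** Abundance is RPKM
(`count / ((length/1e3) * (total/1e6))`), alpha diversity is the Shannon
index with natural logarithm (the common ecology default; the base is an
argument), and the between-sample dissimilarity is Bray-Curtis
`sum|x - y| / sum(x + y)`. Within- versus between-family distances are
compared with a two-sided Wilcoxon rank-sum test (exact enumeration when
both sides have at most 10 values, normal approximation with continuity
and tie corrections otherwise; identical pooled values give p = 1).
Trends (child age versus child-parent distance; pair diversity versus
pair distance) use Spearman correlation with average ranks for ties, an
all-tied vector defined as rho = 0 with p = 1, exact permutation
enumeration for n <= 8 and the t approximation otherwise. "Parents" are
the father/mother roles of the same family; a child with a single
enrolled parent uses that single distance.

**Genome level.** ANI between two genomes is fragment-based: the query is
cut into non-overlapping 1 kb fragments, each fragment is placed on the
reference at the position winning the most shared 16-mer votes (leftmost
position on ties), and scored by *ungapped* percent identity; ANI is the
mean over mapped fragments and pairs with aligned fraction below
`min_af = 0.3` are reported as unrelated, not as a number. Ungapped
scoring is exact for the indel-free synthetic data model and keeps an
exact Hamming-identity oracle available; on real genomes with indels it
underestimates ANI, which is a documented limitation. Dereplication is
two-stage in the dRep style: single-linkage components at a coarse
k-mer-sketch ANI above the primary threshold, then greedy
complete-linkage subclusters at fragment ANI above the secondary
threshold, seeded in canonical quality order
(`completeness - 5 * contamination`, ties by longer genome then id), so
the result is independent of input order.

**Sharing inference.** Candidate populations are species with genomes
from at least 2 members of the same family in at least 30% of *all*
families (inclusive comparisons; the denominator includes singleton
families — the alternative was unstated in the source convention and
this choice is the conservative one). Each candidate's ANI distance
matrix is tested by single-factor PERMANOVA against the family of the
contributing sample (family is the only genome-level factor, so no
marginal test is needed); the population is flagged shared when
`R² > 0.5` and `p < 0.05`, both strict. Sharing events are counted per
within-family genome *pair* at or above the sharing ANI; family
prevalence counts distinct families with at least one such pair — the
pairwise convention is the one under which "times" can exceed
"families". Flagged matrices are projected by classical MDS (Torgerson
scaling) with a deterministic sign convention (largest-magnitude loading
positive per axis).

**Microdiversity.** Nucleotide diversity is
`pi = sum_sites (1 - sum_b f_b^2) / genome_length`. pN/pS uses NG86
equal-weight site counting (each codon position contributes the fraction
of its three possible changes that are synonymous; no
transition/transversion weighting — the simplest scheme with an
enumerable oracle) under the bacterial genetic code; every minor allele
at a polymorphic site is classified against the reference codon, with
minus-strand genes reverse-complemented first. Stop-gain changes count
as nonsynonymous; reference stop codons are counted with stop-to-stop
treated as synonymous, which preserves the `syn + nonsyn = 3` per-codon
conservation law. A gene with no synonymous change gets the `undefined`
sentinel rather than a pseudocount or infinity, because only ratios
around 1 are interpretable.

**Modules and networks.** Metabolic modules are flat ordered steps of
alternative KOs (AND across steps, OR within a step); coverage is the
fraction of satisfied steps and presence is `coverage >= 0.66`
(inclusive). The full KEGG boolean grammar is out of scope; the packaged
SCFA module file is an illustrative fixture, not a curated catalog.
Co-occurrence networks keep taxon pairs with `|rho| > 0.6` (strict),
`|rho| < 1` (strict) and `p < 0.05`. The upper bound is applied
literally, which excludes exactly monotone pairs; if it was only meant
to exclude self-correlation, pass `include_perfect = TRUE`. No
multiple-testing correction is applied by default (an optional
Benjamini-Hochberg flag exists), and the correlations are not
compositionality-aware (no SparCC-style correction) — a known caveat.

## Tunable parameters

| parameter | default | unit / meaning |
|---|---|---|
| `min_completeness` / `max_contamination` | 50 / 10 | percent; inclusive quality gate |
| `primary` / `secondary` | 0.90 / 0.95 | ANI fractions for dereplication (family-comparison preset; the species-binning preset uses 0.95/0.95) |
| `fragment_len`, `k`, `min_af` | 1000 bp, 16, 0.3 | ANI fragmentation, placement k-mer, aligned-fraction gate |
| `min_members`, `min_family_frac` | 2, 0.30 | candidate-population rule |
| `r2_threshold`, `p_threshold` | 0.5, 0.05 | sharing flag (strict) |
| `sharing_ani` | 99.5 | percent; one sharing event per within-family pair at/above it. No canonical published value exists: 99.5 sits between the ~95% species boundary and strain-identity thresholds. Treat as a convention and vary it. |
| `n_perm` | 999 | permutations (199 in the demo for speed) |
| `module_cutoff` | 0.66 | module coverage for presence |
| `rho_min`, `p_max` | 0.6, 0.05 | network band |
| `min_total`, `min_maf` | 5, 0.05 | SNV site filters for pi and pN/pS (the source tooling's filters are unstated; these are explicit package choices) |

## The synthetic cohort generator

The generator emulates the *statistical structure* the analysis assumes,
with planted ground truth, and its defaults mirror the study design the
pipeline targets: 25 families with 2-4 enrolled members
(father/mother/children, three ethnicities and regions at the family
level, children under 13), a few genome-resolved species plus a wider
abundance table, 2% within-species divergence of host strains from a
species ancestor, and 0.01% divergence between the two strains of a
planted transmission pair.

Concretely: one ancestral genome per species carries codon-aware gene
models tiling >= 50% of it (in-frame stops removed from the ancestor by
rejection; mutated descendants may regain premature stops, which pN/pS
simply counts as nonsynonymous). Each host's strain is the ancestor
mutated by independent per-site substitution — substitution only, no
indels, no recombination, so exact Hamming oracles exist for every ANI
claim. A planted transmission draws one donor strain for the family and
derives the first two members' strains from it at the transmission
divergence. Abundance is log-normal:
`exp(baseline_s + effect * u_{f,s} + eps)` with `u_{f,s}` a standard
normal family-by-taxon deviate, `effect = 1` and `eps ~ N(0, 0.5)` by
default — the simplest generative model with a tunable family R².
SNV profiles are drawn at fixed 50x depth; single-strain hosts get
polymorphism only through a residual heterogeneity rate (1e-4 per site)
with minor allele frequencies uniform on (0.1, 0.45), a stand-in for
within-host microdiversity. An optional `diversity_coupling` knob makes
high-diversity families also more internally similar (used to emulate the
diversity-versus-similarity trend).

What the generator does **not** emulate: read-level noise (no FASTQ, no
mapping errors), indels and rearrangements, horizontal transfer and
plasmid gain/loss, strain mixtures within a host, uneven genome
completeness, taxonomic mis-binning, and compositional closure of real
abundance data. A green test therefore establishes that the statistical
machinery recovers planted structure under its own model assumptions —
it does not establish performance on real metagenomes.

Everything is a deterministic function of the configuration seed: the
whole cohort, the written bundle, and the pipeline report are
byte-identical across reruns (the run manifest records the seed, every
threshold and input-file hashes, and deliberately no timestamps).

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive everywhere; strand `-` genes are
  reverse-complemented before codon lookup.
* N bases are legal; they are excluded from mutation, from ANI identity
  scoring, and codons containing N are skipped in site counting.
* Threshold comparisons are inclusive exactly where stated (>= 50,
  <= 10, >= 30%, >= 0.66, sharing ANI >=) and strict where stated
  (R² > 0.5, p < 0.05, 0.6 < |rho| < 1).
* Unrelated genome pairs enter distance matrices at the documented cap
  `1 - primary`, a bounded-matrix convention, not a measurement.
* A distance matrix in which all off-diagonal entries are equal carries
  no grouping signal: every relabeling gives pseudo-F = 1, so the
  permutation p is 1 and the sharing flag stays down. (The sample R² of
  such a matrix is `df_model / (n - 1)`, not 0 — the flag logic relies
  on the p-value in this degenerate case.)
* Perfectly aliased factors are reported with R² 0, an `aliased` flag
  and a warning, symmetrically for all members of an aliased set.
* Ties: Spearman uses average ranks; dereplication, ranking and MDS all
  carry explicit deterministic tie-breaks (documented at each function).

## Scaling of the acceptance suite

The acceptance criteria are property-based (the study's headline numbers
require its deposited cohort and are out of scope). Two criteria are run
scaled to their time budgets: the marginal-dominance check uses 1 kb
genomes (genomes are irrelevant to an abundance-level criterion), and
the sharing-recovery check uses 12 families x 2-4 members with 3 kb
genomes instead of 25 families with 20 kb genomes. The scaled design
preserves the statistical shape that matters — family degrees of freedom
about one third of the genome count, so the null family R² expectation
(~0.31) sits far below the 0.5 flag threshold while the planted
configuration sits above it. Thresholds, divergences (1e-4 versus 2e-2)
and acceptance bands are exactly as stated.

## Known limitations

Ungapped ANI and the no-indel assumption (above); one genome per sample
per population (the highest-quality one) rather than strain-mixture
deconvolution; sharing calls are associational — a family-structured ANI
matrix is consistent with transmission but also with shared environment
selecting identical strains; the SCFA module fixture is illustrative;
networks are neither compositionality-corrected nor multiplicity-
corrected by default.
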