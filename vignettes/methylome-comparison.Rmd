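---
title: "Comparing iPSC-derived and native methylomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing iPSC-derived and native methylomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Cells derived from induced pluripotent stem cells (iPSCs) are expected to
carry the methylome of their target tissue, but two classes of deviations
are common: errors made *at reprogramming* (CpG-island hypermethylation,
loss of imprinting, erosion of X inactivation) that are then inherited by
every derivative of that iPSC line, and errors made *during differentiation
or culture* (failure to demethylate or remethylate regions that distinguish
the target tissue, emergence of partially methylated domains). Telling these
apart requires comparing base-resolution WGBS methylomes across a panel of
cell states — fibroblast of origin, iPSC, the iPSC-derived tissue before and
after transplantation, cultured and native tissue — and a toolbox of
analyses that this package implements: methylome segmentation, feature-level
clustering, DMR calling with etiological classification, imprinting and XCI
classifiers, and non-CpG methylation profiling.

Because raw patient WGBS is not distributable, the package is organised
around a synthetic cohort whose generative model plants exactly the
structure each analysis is meant to detect. Every analysis is therefore
testable against a known truth; what that does and does not say about real
data is discussed at the end.

# Site model and conventions

A methylome is a *site table*: one row per cytosine occurrence with
`chrom`, 1-based `pos`, `strand`, trinucleotide `context` (`CG` or one of
the 12 CHN contexts), methylated and total read counts. Site methylation
level is `meth/total`. Two conventions are fixed package-wide:

* CG sites are emitted per strand and, for all mCG analyses, merged onto
  the plus-strand coordinate by summing counts (`merge_symmetric_cpg()`).
  Merging doubles effective depth at 10× per-strand coverage, which is what
  makes site-resolution segmentation workable; a toggle exists for
  dialects that already merge.
* Coverage filters follow standard practice for sparse WGBS: CG sites are
  usable when covered at least once, CH sites at least 10 times (mCH levels
  are ~100-fold lower, so they need the depth).
* The methylation level of a *feature* is the unweighted mean of its sites'
  levels, not the pooled-count ratio — deep sites do not dominate.
* Annotations are BED (0-based, half-open) on disk and `GRanges` in
  memory; site positions stay 1-based. Conversions live in one place.

# The synthetic study

`generate_genome()` builds three 10-Mb autosomes and a 5-Mb X with a CpG
background of one site per ~150 bp, CpG islands at 5× that density (60% of
promoters plus intergenic islands), LADs covering about a third of each
autosome, ~40 genes/Mb with a unique TSS each, 773 X-linked genes, a
50-interval iDMR catalogue, and planted truths: reprogramming-error CGIs
(25 shared by both patients plus 15 patient-specific, 12 of the shared ones
with hypomethylated 20-kb flanks), 6 iDMRs hypermethylated in both patients
plus 13 more in patient 2, 394 XCI-subject genes of which 45 escape in the
patient-1 lineage, and 87 differential regions with fixed per-state levels
and known etiology.

`simulate_cohort()` realizes the default 16-sample design. Counts are
binomial draws at Poisson per-strand depth (mean 10), through a symmetric
bisulfite non-conversion floor `obs = p(1 − e) + (1 − p)e` with e = 0.5%.
Cell states differ in:

* **PMDs**: fibroblasts depress all LADs by 0.35; iPSC/ESC retain a small
  residue (8% of LADs at 0.25 depth — reprogramming erases most but not all
  PMDs); iRPE/xRPE share a patient-specific 80% subset at 0.18 depth
  (PMDs persist after xenotransplantation); cRPE uses its own 60% subsets;
  nRPE has none.
* **Reprogramming memory**: iPSC, iRPE and xRPE of one patient carry
  identical CGI/iDMR/XCI error sets.
* **mCH**: near-zero in fibroblasts, CAG-skewed in pluripotent states,
  CAC-skewed and high in nRPE (CAC 15%, CAA/CAG/CAT/CTC 5%), half-restored
  in xRPE, and inversely coupled to expression rank within gene bodies.
* **Cell identity**: each state has 40 marker promoters unmethylated only
  in that state, and 60 RPE-signature promoters lowly methylated in all
  RPE states — this is what gives promoter-space clustering six separable
  states and an RPE-discriminating independent component.
* **X chromosome**: modeled as the aggregate of two alleles — XCI-subject
  TSS regions are at 33% in females (one methylated inactive allele) and
  5% in males; escaped genes drop to 2% in the reprogrammed female lineage.

Defaults that the study description does not pin down numerically (depth,
non-conversion, PMD depths/occupancies, marker-set sizes, mCH rates) were
chosen once at values typical for the respective assays and are documented
in `genome_config()`/`cell_state_params()`; they are not tuning knobs.

`simulate_expression()` draws per-gene log2 FPKM baselines (N(3, 1.5²)) and
applies three couplings: errored promoter CGIs repress (−2 log2 units),
methylated hyper-DMR neighbourhoods repress (−1.5), XCI escape derepresses
(+1, i.e. 2-fold).

# Segmentation and PMDs

`segment_methylome()` is least-squares binary segmentation on per-site mCG
levels: a split is accepted when it lowers the within-segment sum of squared
deviations by more than `penalty` (default 1.0, in squared level-fraction
units), with at least 20 sites per segment, per chromosome, breaking at
uncovered gaps > 100 kb. The default penalty is set well above the largest
spurious single-split gain expected from binomial noise at ~20× merged
depth over 10^5 sites (≈ σ²·2·ln n ≈ 0.2) and well below the gain from any
biologically meaningful step (a 10-kb, 30-point step at that depth gains
several units), so constant methylomes stay single-domain while CGIs,
marker promoters and PMD edges are resolved. Domain boundaries sit at
midpoints between flanking sites so domains tile each covered block, which
makes the base-wise arithmetic downstream (Venn partitions, Jaccard against
planted truth) well defined.

PMDs are the classical filter — strictly larger than 10 kb, strictly below
70% mean — applied to domains. Lineage classification is base-wise set
algebra: iRPE PMD bases inside fibroblast PMDs are *persistent* if also PMD
in iPSC, else *recurrent*; bases outside both fibroblast and pan-cRPE PMDs
(the union over the four cultured batches) are *specific*. PMD-prone
regions, used to mask clustering, are the union of fibroblast PMDs.

# Clustering and components

All three workflows cluster samples with Ward's method (`ward.D2` on
Euclidean distances; this is the algorithm that actually implements Ward's
criterion on distances). The raw workflow uses complete features (listwise
deletion — imputation would invent methylation where there is no coverage).

The ICA is a from-scratch FastICA (fixed-point iteration, logcosh contrast,
symmetric decorrelation, PCA whitening) because no ICA implementation is
available in the dependency set; it is validated in the test suite against
planted mixtures (source recovery |r| > 0.95, permutation equivariance,
reconstruction). The decomposition is `X ≈ S·A` with features × components
loadings `S` and components × samples mixing matrix `A`. Normalization is
fixed so thresholds are portable: source columns have unit variance, hence
loadings are in SD units and the conventional |loading| ≥ 5 contributor
cutoff means "5σ feature". Sample clustering uses the columns of `A` as-is:
with unit-variance sources the mixing rows carry each component's share of
signal, so strong components dominate the distances exactly as they do for
raw levels (row-standardizing `A` instead lets noise components swamp the
structure; we verified this degrades six-state recovery). The *common
component* — whose removal before component-based clustering is standard in
this workflow — is defined as the mixing row with the smallest coefficient
of variation across samples: a shared baseline loads every sample almost
equally. PCA uses the same S/A layout (SVD), so removal, contributor
extraction and discrimination tests apply uniformly. Group discrimination
uses exact two-sided Wilcoxon rank-sum tests on mixing weights; component
indices are run-specific, so components are identified by their
discrimination pattern, never by number.

# DMR calling

The caller works on the per-CpG difference between group mean levels,
restricted to CpGs covered in every sample of both groups and to autosomes
(sex mixtures would otherwise dominate). Candidates come from a recursive
maximum-subsegment search: within each segment, the contiguous run whose
sum of deviations from the segment mean is largest is located (Kadane-style
scan, so an isolated 30-CpG region is found even inside a 100,000-CpG flat
chromosome — a single least-squares split cannot do this, its gain decays
as Δ²m²/n); the run is recorded as a candidate if it has ≥ 10 CpGs and
|mean difference| ≥ 0.15, and the search recurses into the run and its
flanks. Every visited segment is also a candidate (a segment that *is*
exactly a differential region would otherwise contribute only its interior
noise runs), nearby same-sign candidates are also offered merged (recursion
boundaries can bisect a region), and nested survivors are resolved after
testing in favour of the best-supported segment (smallest q, most CpGs).

Each candidate is tested with a two-sided Wilcoxon signed-rank test on the
per-CpG paired group differences; BH q-values are computed across all
candidates; the emitted set must satisfy ≥ 20 CpGs, q < 0.01 and
|Δ| > 0.30, with direction *hyper* when group 1 exceeds group 2. The test
statistic is deliberately rank-based and paired — the per-CpG differences
are the natural exchangeable unit, and the |Δ| > 30% filter, not the
p-value, is what keeps regional low-amplitude structure (PMD-depth
differences, at ~18%) out of the DMR set.

Origin tracing is a fixed rule set on per-state means: if iPSC ≈ ESC
(|difference| ≤ 0.15, configurable), the error arose in differentiation —
hyper-DMRs methylated in iPSC are demethylation errors, hypo-DMRs
methylated in iPSC are maintenance errors, hypo-DMRs unmethylated in iPSC
are de novo errors; if iPSC ≠ ESC and the iPSC state is transmitted to iRPE
(same side of 0.5), it is a reprogramming error; anything else is
unclassified. Fate is *resolved-in-xRPE* when xenotransplantation moved the
region closer to the nRPE level by more than 0.10. The 0.15/0.5/0.10
constants quantify qualitative rules; they are arguments, and the planted
truth recovery in the acceptance suite is exact under the defaults.
k-means clusters (k = 5 for hyper, 2 for hypo) use `stats::kmeans` with 25
restarts under a fixed seed, relabelled by descending iPSC-state level so
cluster numbering is reproducible rather than arbitrary.

# Imprinting, XCI, non-CpG methylation

iDMR bands default to [0.25, 0.75] for "intermediate": symmetric about the
50% expected of a parent-of-origin mark at aggregate resolution. XCI calls
use group means over non-reprogrammed samples (male ≤ 10%, female 20–45%)
with callability requiring ≥ 5 covered CpGs per TSS region in every sample
used; escape requires ≤ 5% in *all* reprogrammed female samples (an
any-sample mode exists but is off — a single demethylated sample is culture
noise, not lineage-wide escape). These thresholds make the calls monotone:
tightening the female band can only remove candidates, a property the test
suite checks.

CH sites are never strand-merged (the context is strand-specific). The 12
CHN trinucleotides partition CH sites; CCG is reported as its own axis and
excluded from both CHG and CHH class means by default, because it overlaps
the CpG definition at an offset and standard pipelines disagree about its
class — a flag records the chosen dialect. Class means are site-weighted
means over member contexts, so the CHG class level equals the overall mCHG
level by construction. Context ranking breaks exact ties lexicographically
(logged in the ordering itself, deterministic).

Gene-set enrichment is classic per-term Fisher with the conventional
filters (terms annotating 10–500 genes; report at raw p < 0.01 with ≥ 3
annotated query genes). No graph-aware decorrelation of nested terms is
attempted — the synthetic annotations are flat — but BH-adjusted p-values
are exported alongside for users who want a stricter gate. The gene
universe defaults to feature-covered genes, since genes invisible to the
assay cannot be drawn.

# Problem sizes, determinism, degenerate inputs

The default study (three 10-Mb autosomes + 5-Mb X, 16 samples, ~0.84 M
site records per sample) runs end-to-end in minutes on one CPU; the test
suite uses a half-size genome for module tests and the full default for the
end-to-end contracts. All randomness flows from a single integer seed
through labelled child streams (`child_seed()`), so genomes, cohorts,
k-means and ICA are bit-reproducible and sub-simulations are independent of
call order. Degenerate inputs are handled explicitly: chromosomes with
fewer covered CpGs than a segment are skipped with a warning; features
without covered sites are missing, not zero; constant expression yields NA
correlations; iDMRs without coverage are `uncallable`; empty candidate sets
return empty, typed tables.

# What passing tests show — and what they do not

The generator reproduces the *statistical shape* the analyses assume:
binomial counts at realistic depth, site-density contrasts at CGIs,
block-structured PMDs, lineage-correlated error sets, aggregate-allele X
methylation. It does not emulate read-level artefacts (mapping bias,
M-bias, incomplete conversion clustered within reads), sequence-driven
context effects beyond the planted rates, fine-scale methylation autocorrelation
within domains, or biological heterogeneity between donors beyond the
planted differences. Recovery rates measured here are therefore upper
bounds for real data: they validate the *logic* (filters, classifiers,
counting, set algebra) and the *statistics* (power and FDR under the
declared noise model) of the implementation, not the wet-lab robustness of
the original assay. Real studies should also expect PMD boundaries to be
fuzzier than LAD-planted ones and ESC references to differ from iPSCs in
more ways than the single error class modeled here.
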