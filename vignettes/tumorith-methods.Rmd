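---
title: "Methods: multi-region immunogenomic ITH analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region immunogenomic ITH analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorith)
```

This vignette is the package's account of its methods: the models behind
each stage, the parameters that matter and why their defaults are what they
are, what the synthetic-cohort generator does and does not emulate, and the
numerical decisions a maintainer would want written down.

## The data and the problem

A multi-region tumor-sequencing study samples two or three spatially
separated regions from each resected tumor and asks how much of the tumor's
molecular portrait is shared across regions (truncal, early) versus
region-restricted (branching, late). The package takes per-region somatic
variant tables, allele-specific copy-number segments with per-region purity
and ploidy, class-I HLA genotypes with binned allele-specific copy
estimates, predicted neoantigen tables, TCR-β clonotype tables, and a
clinical table. All coordinates are 1-based inclusive; files are
tab-separated UTF-8 with `"."` for missing values; `"adjacent_lung"` is a
reserved region identifier for non-tumor repertoires.

## Variant QC and the FFPE rescue rule

FFPE fixation deaminates cytosine, producing artifact calls that are
non-recurrent, low-confidence (low log-odds score), low-VAF, and
overwhelmingly C>T|G>A. The filters therefore require tumor depth ≥ 20×,
germline depth ≥ 10×, tumor VAF ≥ 0.02, germline VAF < 0.01, ≥ 4
alt-supporting reads, population frequency < 0.01 in all three of the
ESP/1000-genomes/ExAC columns simultaneously (read conjunctively), and LOD
strictly greater than 18 at region level — far above a caller's default —
or 30 for merged tumor-level calls. All thresholds are strict in the
direction stated; boundary behavior is pinned by tests (LOD 18 fails,
18.0001 passes).

Because artifacts are non-recurrent, recurrence across regions certifies a
low-LOD call: a variant failing *only* the LOD rule is rescued when the
identical mutation (same chromosome, position, ref, alt — the gene symbol
is not consulted) passed with LOD ≥ 18 in another region of the same tumor.
Tumor-level calls reuse the same machinery with the LOD-30 threshold and
region-level passes as supporters. Rescue is monotone by construction: it
can only add variants, and never one failing a non-LOD rule. The
QC readout is the substitution spectrum by LOD stratum: a low-LOD stratum
enriched for C>T|G>A relative to the high-LOD stratum is the artifact
fingerprint.

Missing population frequencies are treated as 0 (absence of evidence of
commonness); a missing value in any other filtered field counts as a
violation of that rule, which is the conservative direction. Missing CADD
is treated as "not above 20" in the cancer-gene classifier for the same
reason.

## Trunk/branch/private and parsimony trees

Per tumor, passing variants form a binary mutation-by-region matrix. A
mutation is *trunk* iff present in every region, *private* iff in exactly
one, *branch* otherwise. Single-region tumors are all-trunk by convention
and flagged as excluded from ITH summaries — one cannot observe
heterogeneity in one sample. The pairwise mutational Jaccard index
(shared / union over region mutation sets) complements the trunk fraction
because it does not depend on the number of regions sequenced.

Phylogenies use Wagner parsimony on the binary matrix with an all-zero
germline ancestor: binary characters, reversals allowed, minimum total
changes. At two to three regions per tumor (the scale this package
targets), exhaustive search over rooted topologies is trivial, so the
implementation enumerates all of them (hard bound: 8 regions), scores each
with Fitch counting over unique presence patterns, and breaks ties by the
lexicographically smallest canonical topology encoding so results are
reproducible. Per-edge mutation counts come from the minimum-change
labeling that prefers the parental state at ambiguous nodes; the edge from
the germline root is the trunk, and on homoplasy-free matrices the
trunk-edge share equals the trunk fraction exactly (a tested invariant).
The test suite checks the implementation against an independent brute-force
oracle (phangorn's parsimony scores over all enumerated topologies) on
hundreds of random matrices.

## Cancer-cell fractions and clonal architecture

For merged tumor-level calls, read counts are summed per mutation across
regions (emulating calling on merged alignments) and the VAF recomputed;
log-odds scores are summed, since independent regions contribute
independent evidence. The cancer-cell fraction is

CCF = VAF · (purity·CN + (1 − purity)·2) / (purity · multiplicity),

the standard purity/copy-number adjustment under a diploid normal
background. Multiplicity defaults to 1; when the adjusted value exceeds 1
it is re-estimated as the rounded raw value capped by the major allele
count, which is common CCF practice. The raw value is kept alongside the
[0, 1]-clamped one.

Clonal architecture is a one-dimensional Gaussian mixture over CCFs with
the number of components chosen by BIC over 1..5. This is a deliberate,
documented simplification of Dirichlet-process clustering: at a few hundred
mutations per tumor in one dimension, BIC-selected mixtures recover the
same cluster structure at a fraction of the complexity, and the
clonal/subclonal decision rule is unchanged — mutations in the cluster with
the highest cellular prevalence (cluster mean) are clonal. Clustering runs
on the *raw* CCFs: clamping piles the clonal peak onto exactly 1.0,
destroying the variance structure the mixture needs. Fewer than five
mutations yield a flagged single-cluster fallback rather than a meaningless
fit.

## Gene-level copy number and LOH

Segments are projected onto a gene model; each (region, gene) gets the
segment-length-weighted mean log2 ratio, called gain above +0.6 and loss
below −0.6, both strictly — a mean of exactly 0.6 is neutral. A CNA
*event* is a (gene, direction) pair everywhere, which makes burden
(non-neutral gene count per region; direction-qualified union per tumor)
and the CNA Jaccard index mutually consistent. Oncogene gains must
additionally exceed the region's overall ploidy in integer copies, which
suppresses calling "gains" that merely track a polyploid genome. LOH
classes come from allele counts of the covering segment — A=2,B=0 is
copy-neutral LOH, A=1,B=0 is copy-loss LOH — and a gene spanning several
segments takes the class of the segment covering its midpoint, a
deterministic tiebreak for an edge case the containment-minded definition
leaves open. The packaged gene model is a ~1,000-gene synthetic fixture
(real cancer-gene and IFN-γ-pathway symbols at synthetic coordinates) so
tests need no annotation download; users supply their own model for real
data.

## Immune escape

Neoantigen candidates are kept as binders iff IC50 < 500 nM (strict).
Binders inherit their mutation's trunk/branch/private and clonal labels;
per-tumor fractions are over distinct binder-bearing mutations.
"Neoantigen-associated gene" means any gene with ≥ 1 binder-generating
mutation; the LOH-enrichment comparison contrasts, per sample and LOH
class, the LOH fraction among those genes versus mutated genes without
binders, paired across samples with a Wilcoxon signed-rank test.

The HLA-LOH caller consumes precomputed binned allele-specific copy
estimates (read-level machinery is out of scope) but applies the published
decision rule verbatim: an allele is lost iff the median binned copy number
is strictly below 0.5 *and* the allelic-imbalance p-value is below 0.01.
The imbalance test here is a two-sided rank-sum test between the two
alleles' bins — a deliberate choice, documented rather than asserted as
what read-level pipelines use (some use a paired t-test); with ≥ 10 bins
and genuine imbalance both reject comfortably. Calls from fewer than 5 bins
are flagged low-confidence. The default IFN-γ pathway set (IFNGR1, IFNGR2,
JAK1, JAK2, STAT1, IRF1, B2M, IFNG) is a reconstruction of the commonly
used panel and is overridable; analyses should not assume it matches any
specific study's exact list.

## TCR-β repertoire

Density is templates per input nucleated cell (the housekeeping-gene
estimate); richness is the count of unique rearrangements R; clonality is
1 − H/ln R with Shannon entropy H over productive frequencies renormalized
to sum to 1 (natural log, Pielou's convention), defined as 0 when R = 1.
Overlap uses the standard Jaccard index on rearrangement sets — the verbal
"shared over total" definition is read as |∩|/|∪|, consistent with the
index's name and range — the Morisita–Horn index on template counts (the
immunoSEQ convention for "Morisita index"), and the shared proportion of
the top-20 highest-frequency clonotypes with denominator 20 (or the
smaller repertoire's size when below 20) and frequency ties broken by
rearrangement string order. Clonotype identity is the nucleotide
rearrangement throughout — an assumption, since amino-acid collapsing is
also defensible. Tumor-versus-adjacent contrasts pair patients (tumor
regions averaged) under a Wilcoxon signed-rank test when ≥ 3 matched pairs
exist and otherwise fall back, with a report of the switch, to an unpaired
Mann–Whitney test.

## Mutational signatures

SNVs with a trinucleotide context string are counted into the fixed 96
pyrimidine-strand channels (purine contexts reverse-complemented). Refit is
deterministic forward selection: add the reference signature that most
reduces the L2 norm of the reconstruction residual, refit all selected
weights by nonnegative least squares, stop when the improvement falls below
1e-3, then zero weights under 0.06 and renormalize survivors to the
pre-cutoff mass. The stopping tolerance is applied on the residual *norm*:
on the squared scale a several-ten-percent admixture of a broad, flat-ish
signature improves the fit by less than 1e-3 and would never be selected.
The cutoff and tolerance are the defaults of the widely used refitting
package in this space and are exposed as arguments.

The packaged 96×30 reference is a **synthetic stand-in built in code**, not
the published catalog: column 4 is C>A-heavy (smoking-like), column 3 broad
and even (DSB-repair-defect-like), column 1 C>T-dominated, the rest
distinct smooth pseudo-random profiles. It gives the simulator and the
fitter a common, structurally faithful reference without shipping
third-party data; exposures from it are *not* comparable to published
signature numbers. Trinucleotide-frequency renormalization (exome versus
genome) is off by default because synthetic catalogs are generated directly
in channel space.

The trunk-versus-nontrunk contrast pools exposures across tumors per
compartment, ranks, keeps the top 5, renormalizes over them, and reports
each signature's share, plus a paired Wilcoxon test on per-tumor shares of
a named signature.

## Cohort statistics

Mann–Whitney comparisons use the exact distribution for combined n ≤ 20
without ties (verified against brute-force rank enumeration) and the
tie-corrected normal approximation otherwise. Spearman correlations use
average ranks with the t approximation. Chi-squared tests never apply a
continuity correction — with correction the published 2×2 patient-count
tables do not reproduce their printed p-values, without it they do to three
decimals. Median dichotomization sends values equal to the median to the
"low" group (deterministic, and consistent with "above median" defining
the high group); the positive rule splits at 0. Kaplan–Meier/log-rank and
Cox fits (Efron ties) delegate to the survival package; because a
univariate hazard ratio can be per-unit or per-SD and studies rarely say
which, callers choose the scaling of the covariate they pass, and the
acceptance script labels its HRs per SD.

## The synthetic cohort: what it emulates

`simulation_config()` defaults are the study conditions: 19 patients (13
with three regions, 5 with two, one single-region patient, who exercises
the exclusion paths), 200 mutations per tumor with trunk fraction 0.8,
tumor depth negative-binomial around 180× (germline 161×), purity 0.5–0.9,
truncal CCF 1.0 versus subclonal CCF 0.2–0.6 with binomial read noise at
multiplicity 1 and local copy number 2 (the transparent CCF regime),
trunk mutations drawn from a smoking-dominant signature mix versus a
DSB-repair-heavy nontrunk mix, ~15% artifact calls per true call (low-LOD,
low-VAF, C>T-biased) plus a 10% low-LOD rate on true multi-region calls to
exercise the rescue rule, HLA LOH in 9/19 tumors with the trunk:branch
split seen at cohort scale, and exponential proportional-hazards survival
with ~30% censoring.

Three generator choices encode biology the observables depend on. First, a
per-tumor log-normal multiplier (sdlog 0.6) scales all copy-number event
probabilities, reproducing the strong between-patient variation in CNA
burden and making IFN-γ-pathway loss ride the same instability — which is
what produces the positive loss-versus-burden correlation downstream.
Second, class-I presentation is skewed (an immunodominance profile over the
six alleles), and when a tumor undergoes HLA LOH it loses the allele
presenting the most binders — the immune-pressure story — which is why a
large share of binders ends up on lost alleles. Third, clone frequencies
are Zipf with exponent 0.45 for tumor regions (1.6× steeper and larger for
adjacent lung), with 12% of each region's clonotypes drawn from a
tumor-wide shared pool; under multinomial template sampling at 1,000
templates per 60,000 input cells this lands the observed density, richness,
clonality, pairwise Jaccard and shared-in-all-regions medians in the range
the assay produces on real tumors.

What it does **not** emulate: read-level data (no FASTQ/BAM), indel realism
beyond class labels, segmentation noise (segments are emitted directly from
gene states), subclonal copy-number evolution coupled to point mutations,
germline contamination beyond a zero germline VAF, V/J gene usage, or any
transcriptional readout. Passing tests on this cohort therefore demonstrate
that the *analysis chain* is correct and calibrated under the documented
generative model — not that the model captures every failure mode of real
FFPE exomes.

A no-noise mode (`noise = FALSE`) replaces every stochastic observation
with its expectation (fixed depths, expected alt counts, constant copy
bins, no artifacts); in this mode the full pipeline reproduces the planted
ground truth exactly, which the suite asserts label-for-label.

## Numerical and reproducibility choices

Everything is deterministic given the seed: the simulator threads a single
RNG stream, signature refitting and parsimony tie-breaks are deterministic,
and mixture initialization is hierarchical (not random). Result files
round-trip bit-exactly: doubles are serialized at 17 significant digits and
re-parsed with R's correctly rounded `strtod`, so two runs at the same seed
produce byte-identical tables and manifests (checked by MD5 in the
manifest). Degenerate inputs fail loudly and early: zero-margin
contingency tables, constant covariates in Cox fits, all-identical values
under a median split, single regions where pairwise quantities are
undefined.

Test problem sizes are chosen to make each check sharp but quick: the
parsimony oracle runs 200 random matrices on ≤ 4 regions; trunk-fraction
recovery uses a 20-tumor, 3-region, 200-mutation cohort (mean absolute
error < 0.05 against ground truth); signature recovery samples 2,000
mutations from a 70/30 mixture (weights recovered within ±0.05); survival
calibration uses 200 null replicates for log-rank uniformity and 100
replicates at n = 200 for Cox recovery; and the determinism check runs the
full pipeline twice on a six-patient cohort, byte-comparing the outputs —
determinism does not depend on cohort size.

## Known limitations

- The packaged signature reference and gene model are synthetic stand-ins;
  results on them are internally consistent but not comparable to numbers
  derived from the published catalogs or a genome-wide gene model (the
  default cohort's CNA burden, for instance, is on a 1,000-gene scale).
- Per-tumor nontrunk catalogs are small (tens of SNVs at the default
  trunk fraction), so broad signatures are under-attributed there; the
  pooled contrast is the more stable readout.
- At 19 patients, survival hazard ratios are noise-dominated; the package
  reports them because the machinery must be exercised, but their signs
  vary by seed, exactly as small-cohort estimates do.
- The exhaustive parsimony search is bounded at 8 regions; beyond that a
  heuristic search (not provided) would be needed.
- The clonal-architecture model is a single-sample 1-D mixture; it does not
  borrow strength across regions or model cluster assignments jointly.
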