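---
title: "Calling expressed SNVs from RNA-Seq: filters, confidence merging and benchmarking"
author: "esnvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling expressed SNVs from RNA-Seq: filters, confidence merging and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esnvkit)
```

## The problem

Substitutions observed in RNA-Seq reads — expressed single-nucleotide
variants, eSNVs — are a cheap by-product of transcriptome sequencing,
but a treacherous one. Coverage follows expression rather than a
capture design, spliced alignment scatters reads at exon junctions,
and each aligner makes its own mismatch- and gap-placement choices, so
a naive caller drowns true variants in alignment artifacts. `esnvkit`
implements a post-alignment strategy for non-directional paired-end
RNA-Seq: extract per-site read evidence produced by upstream callers
(samtools mpileup text or per-sample VCF fields), apply a battery of
coverage-dependent hard filters, and only promote a variant to high
confidence when it survives the battery under **two independent
aligners**. The surviving calls are annotated by table joins and
benchmarked against orthogonal truth (genotyping arrays or exome
sequencing).

Read alignment, duplicate marking, realignment/recalibration and the
pileup/VCF-producing callers themselves are out of scope: the package
consumes their downstream products.

## Per-site evidence

The unit of data is a `SiteEvidence` record: chromosome, 1-based
position, reference and alternate base, total read depth $t_i$,
alternate-allele depth $aa_i$, its forward/reverse strand split
$aa_i^+ / aa_i^-$, and optionally a read-position rank-sum score. The
mpileup parser applies the conventional base-quality screen (retain
Phred $> 13$; mapping quality is assumed screened upstream by the
pileup producer), handles the `^X $ +n/-n * < >` markers, derives
strand from the case of the base symbol, and emits one record per
alternate allele. Reads supporting neither the reference nor the
allele under consideration (including `N` calls) count toward $t_i$
but never toward $aa_i$; the `*` deletion placeholder counts toward
neither, since it carries no base call. Only substitutions are
emitted — indel evidence is consumed and discarded.

Three derived statistics feed the filters:

* allele fraction $\mathrm{Ratio}_i = aa_i / t_i$;
* strand-bias ratio $\mathrm{SBS}_i = \min(aa_i^+, aa_i^-) /
  \max(aa_i^+, aa_i^-)$ — 1 for balanced support, 0 for one-sided
  support;
* read-position rank-sum $Z$: a Mann–Whitney statistic comparing
  within-read offsets of alternate- versus reference-supporting bases,
  with midranks for ties and the tie-corrected variance
  $\sigma_U^2 = \frac{n_a n_r}{12}\left[(N+1) -
  \frac{\sum_j (t_j^3-t_j)}{N(N-1)}\right]$. Offsets are measured as
  the distance from the **nearer** read end
  (`min(cycle, readLen-1-cycle)`), because the artifact this score
  targets is alternate bases piling up at the 5′/3′ ends of reads;
  such sites score strongly negative. When either group is empty or
  all offsets tie, the score is missing. Precomputed upstream values
  (e.g. a VCF `ReadPosRankSum` INFO field) are accepted verbatim;
  different upstream implementations differ in their offset
  convention, so scores near the bounds may not agree exactly across
  tools.

## The hard-filter battery

Five criteria, all evaluated unconditionally so every verdict is fully
reportable:

| criterion        | requirement (defaults)                                      |
|------------------|-------------------------------------------------------------|
| total depth      | $t_i \ge 4$                                                  |
| alternate depth  | $aa_i \ge 4$ (single-cell preset: $\ge 2$)                   |
| allele fraction  | $> 0.1$ if $t_i < 100$; $> 0.05$ if $t_i \ge 100$            |
| strand bias      | $> 0.1$ if $t_i < 100$; $> 0.05$ if $t_i \ge 100$            |
| rank-sum         | $-8 < Z < 8$, missing passes                                 |

Numerical conventions worth stating precisely: the fraction and
strand-bias comparisons are strict (`>`), so a site at exactly the
threshold fails; the rank-sum bound is an open interval, so $Z = \pm 8$
fails; the depth minima are inclusive. The high-coverage regime uses
the laxer fraction threshold deliberately — with ample depth, a 5%
allele fraction can still be a real subclonal event in an impure
tumor. The regime boundary is unified at $t_i \ge 100$ for both the
fraction and the strand-bias filter; descriptions of the two filters
elsewhere place the boundary at "≥100" and ">100" respectively, and we
chose a single convention since the one-read boundary effect is
negligible. A missing rank-sum passes: upstream tools omit the score
at sites lacking reference or alternate reads, and rejecting every
such site would silently discard legitimate high-fraction variants.

Degenerate evidence ($t_i = 0$ or $aa_i = 0$) fails the corresponding
depth/fraction/strand criteria rather than erroring, so filter output
is total over its input.

The single-cell preset (`singleCellFilterConfig()`) differs from the
default in exactly one parameter — the alternate-depth minimum drops
to 2 — accommodating libraries sequenced to only ~10^5 reads per cell.

## Two-aligner confidence

Variants are matched across aligners exactly on (chrom, pos, ref,
alt); multi-allelic records are decomposed to biallelic keys before
merging, the conservative reading when no combination rule is
specified. Confidence is

* `CONF = 2`: passed the battery under **both** aligners;
* `CONF = 1`: supported only by the user-designated *preferred*
  aligner (typically the splice-aware one);
* `CONF = 0`: supported only by the other aligner.

A site called by both aligners but passing filters in only one counts
as single-aligner support — high confidence requires surviving the
filters twice — though the failing aligner's evidence is attached to
the merged record for reporting. Per-aligner depths are reported
side-by-side rather than averaged; inventing a combination rule would
add nothing and lose information. `concordanceSummary()` generalizes
the same support counting to 3- and 4-aligner comparisons.

## Annotation as table joins

The annotation stage is deliberately reduced to reproducible joins
against user-supplied tables, rather than wrapping any specific
annotation engine and its versioned databases: a gene-model interval
table (1-based TSV or 0-based half-open BED, declared explicitly)
drives region classification; a known-variant table gives the
known/novel flag; protein-domain intervals (pre-projected to genomic
coordinates) are overlap-joined; a SIFT-style tolerance score column
yields the deleteriousness flag (strictly $< 0.05$). When a position
overlaps several transcript features the single reported class follows
the fixed precedence `exonic > ncRNA > UTR5 > UTR3 > intronic >
upstream > downstream` (the widely used annotation convention; no
overlap means intergenic). Synonymy calling requires an optional
codon-context table — embedding a full transcript translator is out of
scope — and defaults to `unknown`/`noncoding` without it.

## Benchmarking protocol

Two truth kinds, with expression-aware gating applied before any
counting:

* **chip** (genotyping array): calls are restricted to positions the
  array assayed; the recall denominator is the set of array variants
  *expressed* in the RNA, defined as strictly more than 3
  alternate-allele supporting reads. An array hom-ref position that we
  call is a false positive.
* **wes** (exome mutation list): calls at positions with exome
  coverage below 4 reads are excluded from the precision denominator
  and reported separately (`nNoCoverage`) — the exome simply cannot
  adjudicate them; the recall denominator is the mutation list,
  gated to RNA-covered positions (total depth ≥ 1) when RNA evidence
  is supplied, the list being taken as already expression-gated
  otherwise.

Then precision $= TP/(TP+FP)$, recall $= TP/(TP+FN)$,
$F = 2PR/(P+R)$, with the conservation identities
$TP+FP = |\text{assayable calls}|$ and $TP+FN = |\text{expressed
truth}|$ asserted on every run. Percentages print half-up at one
decimal and table-style fractions at three decimals, matching the
granularity such results are reported at. The transition/transversion
ratio (`tstvRatio()`) and a 3×3 bulk-versus-cell zygosity concordance
matrix complete the report. Zygosity is called from the alternate
fraction with bounds 0.1/0.9; these bounds are a package choice
(aligned with the low-coverage fraction threshold) and are exposed as
parameters, not a literature constant.

## The synthetic-data generator

`simulateEsnvData()` is first-class, tested code: it defines the study
conditions under which the pipeline's recovery properties are
established. It plants `nSites` sites on a deterministic toy gene
model (coding genes with upstream/UTR5/exon–intron/UTR3/downstream
blocks plus ncRNA genes on four chromosomes), placing sites by a region
mixture that defaults to the composition reported for validated eSNV
sets (≈37% exonic, ≈38% UTR, ≈14% intronic, the rest ncRNA/flanks/
intergenic). Each site is either:

* **clean** — a true variant, het (60%, allele fraction ≈ 0.5) or
  hom-alt (fraction 0.99, i.e. ~1% sequencing error), depth uniform on
  10–200, drawn from the *passing region* of the default battery:
  "clean" means free of the artifact signatures the filters target, so
  draws are conditioned to clear every criterion;
* **strand-biased** — all alternate reads on one strand, otherwise
  het-like; fails exactly the strand-bias criterion;
* **end-clustered** — alternate read offsets in the outer 10% of a
  100 bp read, reference offsets uniform elsewhere; fails exactly the
  rank-sum bound. These are drawn at depths 120–200 with alternate
  counts clamped to ≥ 50 per group because the rank-sum magnitude is
  bounded by $\sqrt{3\,n_a n_r/(N+1)}$ — under complete separation the
  score only exceeds 8 with ≳45 reads per group, so an end-clustering
  artifact is mathematically invisible to this filter at low depth;
* **low-alt-depth** — 2–3 alternate reads at depths chosen so only
  the alternate-depth minimum fails.

Substitution types for true variants are transitions with probability
0.75 (expected ts/tv = 3, as observed for validated exonic eSNV sets);
artifacts draw near-uniformly (ts/tv ≈ 0.5). A known-variant table
covers 97% of planted variants, mirroring the known-SNP fraction
reported for tumor eSNV sets.

**Aligner concordance.** `alignerConcordance` is the probability that
the second aligner reports byte-identical evidence at a site; with the
complementary probability its evidence is *re-drawn independently from
the same planted truth* — the aligners disagree about depths and
strand splits, not about whether the site exists. Missed calls are
modelled separately by `alignerDropout` (default 0). This separation
is a design choice: discordant-but-consistent evidence and outright
dropout have very different effects on the confidence levels, and
conflating them would make clean-variant recovery a function of a
nuisance parameter.

The generator returns a ledger recording, per site, the planted class,
zygosity, region, the criterion it was designed to fail, and which
aligners observe it — every recovery/rejection test in the package is
a reconciliation against this ledger. The chip-style truth set carries
the planted variants, the artifact positions as hom-ref (a leaking
artifact scores as a false positive), and extra assayed hom-ref
positions.

**What passing these tests does and does not show.** The simulator
emulates marginal per-site read counts with independent sites and
single-signature artifacts. It does not emulate alignment itself:
correlated errors around splice junctions and repeats, reference bias,
allele-specific expression, RNA editing, PCR duplicates, or quality
miscalibration. Recovery of 100% of clean variants here demonstrates
the pipeline's *internal consistency* (filters reject exactly what
they target, merging conserves keys, scoring obeys its identities),
not field performance on real libraries, which is what the external
benchmark arithmetic targets.

## Problem sizes and numerical choices

The shipped test suite establishes the recovery properties at 10,000
planted sites (5% strand-biased, 5% end-clustered, 90% clean, aligner
concordance 0.95) — large enough that a 1% recovery shortfall would be
a ~30σ event — and validates the rank-sum implementation against a
brute-force pairwise-enumeration oracle on 1,000 random list pairs
(tolerance 10⁻⁹), plus exact permutation moments on tiny inputs.
Filter boundaries are exercised on a grid straddling every threshold
(depths 3/4, 99/100, fractions at and just above 0.05 and 0.1,
rank-sum at ±8). Ties in the rank-sum use midranks; variant keys are
ordered lexicographically by (chrom, pos, alt) for deterministic
output; all counts are integers end to end.

## Worked example

```{r example}
sim <- simulateEsnvData(simConfig(seed = 11, nSites = 500))
merged <- mergeCallSets(sim$callSets, preferred = "tophat2")
table(merged$conf)

calls <- merged[merged$conf == 2, c("chrom", "pos", "ref", "alt")]
evaluateCalls(calls, sim$truth, rnaEvidence = sim$callSets$tophat2)

ann <- annotateVariants(merged, sim$geneModel, sim$knownTable,
                        sim$domainTable, sim$scoreTable)
round(prop.table(table(ann$region)), 3)
tstvRatio(calls$ref, calls$alt)$ratio
```

## Known limitations

* Genotype likelihoods, VQSR-style soft filtering and somatic/germline
  decomposition are out of scope — the battery is deliberately a
  transparent hard-filter set.
* The rank-sum filter cannot reject end-clustering artifacts below
  ~90× depth (see the bound above); they are instead usually caught by
  the allele-fraction or strand filters when correlated with those
  signatures, but a pure low-depth end-clustering artifact passes.
* Annotation joins are exact-coordinate; no splice-site category, no
  liftover, no transcript-aware projection of domain coordinates.
* The merged record carries both aligners' depths; consumers that
  need a single depth must choose one.
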