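---
title: "Identifying causal mutations in haploid mutant genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying causal mutations in haploid mutant genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutfunnel)
```

## The problem

In a forward-genetics screen on a haploid organism, UV mutagenesis produces
strains with a phenotype of interest, and whole-genome resequencing of two or
more independently derived mutant strains is used to locate the causal gene.
Each resequenced genome yields tens of thousands of putative variants, almost
all of which are alignment artefacts, reference-genome errors, or neutral
background mutations. `mutfunnel` implements the candidate funnel that
reduces this haystack to a handful of candidates:

1. **Panel subtraction** — variants also called in a panel of independently
   sequenced sibling mutant lines are removed. Recurrent calls across
   unrelated lines are overwhelmingly reference errors or systematic
   artefacts, not strain-specific mutations.
2. **Quality filtering** — five predicates, applied jointly: site depth
   within ±50% of the genome mean (closed interval), mapping quality > 20,
   call quality > 50, alt-allele read fraction > 0.9, and at least one
   alt-supporting read on each sequencing strand. The four scalar thresholds
   are strict inequalities; the depth band is inclusive at both ends because
   a "±" band names its endpoints as part of the range.
3. **Effect annotation** — each surviving SNV is mapped onto strand-aware
   gene models (CDS / intron / 5' UTR / 3' UTR / intergenic) and CDS hits
   are classified at codon level (silent, missense, nonsense, plus
   start-loss and stop-loss for completeness).
4. **Cross-strain intersection** — genes with at least one CDS variant in
   *every* independent strain are the candidates. With two strains carrying
   independent causal alleles of the same gene, the intersection is
   typically a single gene.

The package also covers the downstream characterisation steps such a study
needs: Mendelian segregation testing, mutation–phenotype co-segregation,
expression gating and differential-expression set classification for
mutant-vs-wild-type transcriptomes, and transect-profile peak counting for
quantifying cytoskeletal bundles in fluorescence images.

## Why alt fraction ≈ 1 and a 1:1 ratio

The organism is haploid in the relevant generation: a true mutation should
be carried by essentially every read covering its site, so the alt-fraction
filter can demand > 0.9 where a diploid pipeline would centre on 0.5.
Likewise a cross segregating a single recessive locus among haploid progeny
gives a 1:1 mutant:wild-type ratio, tested here with a Yates-corrected
goodness-of-fit test.

## The synthetic-data generator

No raw sequencing data accompany the analysis, so the generator produces
every input with known ground truth. Its defaults define the study
conditions used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| genome | 2 Mb, 1 contig | desk-scale stand-in for a ~200 Mb genome |
| genes | 300, both strands | CDS occupies ~15% of the genome |
| CDS length | 300–1800 bp, 1–6 exons | segments split at non-codon boundaries so phase handling is exercised |
| background mutations | 30 per strain | desk-scale analogue of the ~100 real filtered mutations |
| transition fraction | 0.9 | UV spectra are transition-dominated; both observed causal lesions are transitions (T→C, G→A), but with only two observations a dominant-not-exclusive bias is the safer model |
| causal policy | one shared gene; missense + nonsense | mirrors the two independent alleles of the screen |
| mean depth | 33× | midpoint of the two strains' reported coverages (34×, 32×) |
| alt fraction (true) | Uniform(0.92, 1.0) | haploid; alt count is `ceiling(depth × f)` so the realised fraction never falls below the draw |
| panel | 14 lines, 500 shared false positives | false positives get alt fractions Uniform(0.3, 1.0) and identical keys in every line: the reference-error model, removable by subtraction regardless of quality |

Each generator is a pure function of its seed (sub-steps use fixed small
offsets of the configured seed so genome, mutations and panel draw from
independent streams).

**Depth truncation.** True-mutation depths are negative-binomial around the
mean (size = `mean_depth × depth_dispersion`) but truncated to
[0.65, 1.35] × mean. This emulates callable, well-covered sites — a real
caller never reports a variant at unusable depth — and makes planted
mutations sit inside the ±50% depth band, so recovery of the causal gene is
a property of the pipeline rather than a coin-flip on depth tails. Panel
false positives draw from the same depth model, which keeps the per-strain
mean depth (computed from the strain's own records when no explicit genome
mean is supplied) near the nominal 33×.

**Disjoint background.** With `ensure_disjoint_background` (the default), no
non-causal gene receives CDS background variants in more than one strain and
the causal gene receives none, making the causal gene the unique
cross-strain intersection by construction. Switching it off allows
coincidental shared genes, which is the realistic behaviour for larger
background loads.

**What the generator does not emulate:** read-level errors, alignment
artefacts, indels and structural variants (the UV screen's causal lesions
are SNVs and the pipeline parses but excludes indels), base-quality models,
linked-mutation clusters, and reference-error mechanisms beyond "identical
variant in every line". Passing tests therefore demonstrate the correctness
of the subtraction/filter/annotate/intersect logic under clean conditions,
not robustness to alignment pathology.

## Numerical and boundary decisions

* **Mean depth source** — the depth band is centred on the arithmetic mean
  of the strain's own variant-site depths unless `genome_mean_depth` is
  supplied; per-strain coverages differ, so a per-strain mean is the
  natural default. Filtering is idempotent and commutes with subtraction
  when the mean is held fixed in the configuration.
* **Panel matching** — exact (contig, pos, ref, alt) keys by default;
  position-only matching is available as an option since either convention
  is defensible for removing recurrent artefacts.
* **Variant frequency** — defined as alt reads / site depth (from
  AD/ADF/ADR, or DP4 in the pileup-caller dialect), the natural reading for
  haploid data.
* **Overlapping genes** — a variant is annotated against every overlapping
  gene (one record each) and counts as "in CDS" if any record is CDS;
  `locate_variant` reports the lexicographically first gene with an
  ambiguity flag.
* **CDS boundaries** — only positions strictly inside CDS segments are CDS;
  there is no splice-region class because the funnel counts coding-region
  hits only. UTR sides are resolved on the coding strand, so a minus-strand
  gene's 5' UTR lies genomically downstream of its CDS.
* **Yates correction** — clamped, `max(0, |O−E|−0.5)`, so a perfect fit
  yields exactly 0 rather than a spurious positive statistic; applied only
  at df = 1 by default (a flag forces it for more categories). The
  published statistic for the 16:22 family (0.4767) is *not* reproduced by
  this standard formula (which gives 0.6579, or 0.9474 uncorrected); the
  published (statistic, p) pair is internally consistent under the df = 1
  upper tail, and the package reports both rather than reverse-engineering
  the original calculator.
* **Expression gate** — the threshold is the 5th percentile of the TPMmean
  vector (zeros included), using the type-7 linear-interpolation quantile;
  "expressed" means strictly above the threshold. The percentile is
  computed over the pooled TPMmean vector by default (per-condition gating
  is available), since the gate is defined on per-gene means rather than
  per-sample values.
* **DE classes** — down iff log2FC ≤ −1 and padj ≤ 0.01; up iff log2FC ≥ 1
  and padj ≤ 0.01; all bounds inclusive as stated. Exclusive expression and
  silencing require the relevant condition's TPM mean to equal zero
  *exactly* — no tolerance — because "not expressed at all" is the
  biological claim being encoded.
* **DE engine** — negative-binomial model fitting is deliberately out of
  scope; the module consumes per-gene (log2FC, padj) from any fitter. A
  self-contained naive path (log2 ratio of mean TPM + 1 with
  label-permutation p-values, BH-adjusted) exists for demonstrations; TPM
  here is plain TPM from counts and lengths, not a length-scaled import
  from a pseudo-mapper.
* **Peak counting** — local maxima with topographic prominence ≥ 0.1 of the
  dynamic range, minimum separation 3 px, keeping the higher of two close
  peaks. The original quantification was manual and names no parameters;
  these defaults are recorded and every test pins them explicitly.
  Prominence is relative, so counting is invariant to affine intensity
  rescaling. Only 1-D transect counting is claimed: bundles perpendicular
  to the image plane are invisible to any line profile.
* **Minimal caller** — `call_site()` exists so the pipeline is runnable
  without an external caller at desk scale: majority non-reference base,
  depth and fraction thresholds, call quality = −10·log10 of the upper
  binomial tail of the alt count under a 1% error rate, ties broken
  deterministically A < C < G < T.

## Problem sizes in the tests

The test suite and the acceptance script run the full screen at the default
scale (2 Mb, 300 genes) over 20 generator seeds for recovery, 1000 random
variants for the filter-algebra properties, 500 random planted CDS variants
for the annotation oracle, 200 random vectors for the BH oracle, 2000
simulated n = 38 families for the size of the Yates test, and 50 mutation
seeds on a fixed genome for the CDS-fraction echo (the genome is fixed
because its CDS fraction is the comparator). These sizes keep the whole
suite around a minute while leaving the binomial tolerances meaningful.

## Known limitations

* Sensitivity to mis-specified gene models is untested: the generator's
  GFF3 is always internally consistent, and genes whose CDS length is not a
  multiple of 3 are excluded from annotation rather than rescued.
* The funnel assumes SNVs; a causal indel would be parsed but excluded.
* With panel subtraction keyed on exact alleles, a true mutation that
  coincides in position *and* allele with a panel artefact would be lost;
  the generator never creates this case, and on real data the position-only
  mode makes the behaviour explicit instead.
* The naive DE path inherits TPM's compositionality: a heavy global DE
  burden shifts apparent fold changes of unaffected genes. It is a
  demonstration route, not a substitute for a count-model fitter.
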