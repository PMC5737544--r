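---
title: "Mapping 3'-UTR regulatory elements from CRISPR tiling-deletion screens"
author: "utrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping 3'-UTR regulatory elements from CRISPR tiling-deletion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrscreen)
```

## The measurement model

A tiling-deletion screen introduces Cas9 cuts at every available SpCas9 site
of a 3'-UTR in a cell population, lets end-joining produce a spectrum of
small deletions, and then sequences the same amplicon twice: from genomic
DNA (which allele does each cell carry?) and from cDNA (how much mRNA does
each allele produce?). For a deletion allele $d$ observed $D_d$ times in the
DNA library and $R_d$ times in the RNA library, the count ratio

$$ r_d = \frac{R_d}{D_d} $$

is proportional to the steady-state mRNA output per cell carrying $d$.
Dividing by the *reference ratio* — the same RNA/DNA ratio over fragments
with no qualifying deletion — gives a normalized $r$ that is 1 for alleles
expressing like the intact UTR, above 1 when the deletion removed a
destabilizing (expression-limiting) element, and below 1 when it removed a
sequence required for full expression (for instance a transcription-
promoting element in the UTR DNA).

The per-nucleotide map asks, for every position $i$: among retained distinct
deletions, how do the $r$ values of deletions whose *deleted interval
contains* $i$ compare with the $r$ of all other deletions? We summarize the
at-position set by its median, attach a bootstrap percentile confidence
interval, and test the contrast with a two-sided Mann–Whitney U-test,
Bonferroni-corrected over the positions actually tested.

The key assumptions are: (i) each fragment derives from one molecule, so a
deletion seen on both mates of a pair is one observation; (ii) sequencing
and PCR treat alleles approximately evenly, so $r$ is comparable across
alleles; (iii) a deletion's effect is attributable to the bases it removes,
which is why "involving a position" means the position was deleted, not
merely adjacent to a junction.

## From alignments to distinct deletions

Deletion calling walks each alignment's CIGAR: M/=/X advance reference and
read, I and S advance the read only, D advances the reference only, and N is
treated as D (amplicon alignments should not be spliced, but aligners can
emit N; the length filters below then dispose of implausible gaps). H and P
are not supported and such records are discarded with a counted reason.

Four read-level filters, in this order, with their defaults:

* deletions of length 1–2 nt are removed from the read and the read kept —
  at typical error rates these are overwhelmingly sequencing/alignment
  artifacts, and dropping the read instead would discard its evidence for
  the reference allele;
* reads with more than one remaining deletion are discarded
  (`multi-deletion`) — a single end-joining event produces one gap, so these
  indicate chimeras or misalignment;
* a junction closer than 8 read bases to either read end is discarded
  (`edge-proximal`), because placement of an indel near a read end is
  unreliable;
* deletions of 30 nt or longer are discarded (`length->=30`); together with
  the 1–2 nt rule this restricts analysis to 3–29 nt alleles, the window in
  which a single-cut or short dual-cut repair product can be assigned
  confidently within a 150-nt read.

Mates are then reconciled per fragment: agreement (including one mate simply
not reaching the junction) yields one observation; a reference mate whose
aligned span contains the deleted interval, or two mates reporting different
deletions, is a `mate-conflict` and the fragment is discarded. A fragment
with no qualifying deletion is a reference fragment regardless of whether it
covers the whole UTR — uncovered regions are taken to harbor no deletion.
Because per-position statistics are computed over distinct deletions rather
than fragments, partial coverage of reference fragments does not bias the
map, only the (large) denominator of the reference ratio.

Distinct deletions are grouped by the aligner-reported (start, length) pair.
Deletions in repeats that an aligner could place at several equivalent
coordinates are grouped as reported; we deliberately do not re-normalize
alignments. Alleles observed only in RNA have no defined $r$ and are
excluded rather than treated as infinitely expressed.

## Abundance filter

A distinct deletion is retained only if it is frequent enough in *both*
libraries: count/total must exceed 6.5 per 10^7 reads in each library
(the boundary itself is eliminated). $r$ needs both a reliable numerator and
denominator, which is why the rule is applied per library; an alternative
`absolute` mode retains alleles with at least 8 RNA and 16 DNA fragments,
the equivalent absolute minima at full screen depth. The retained set is
further restricted to lengths 3–29 nt.

## Per-position statistics

* **Coverage rule.** A position is analyzed only when at least 4 retained
  distinct deletions involve it; with fewer, a median and a rank test are
  not meaningful. Positions where the at-position set would equal the whole
  deletion set (no "elsewhere" group) are likewise not analyzed.
* **Bootstrap.** The resampling unit is the distinct deletion, not the read:
  reads within an allele are not exchangeable draws of $r$. The interval is
  the 2.5/97.5 percentile of B medians of same-size resamples with
  replacement; the package default is B = 1000 (10000 for final maps is
  equally supported, at proportional cost), and B = 0 skips intervals when
  only p-values are needed. Degenerate sets (all values equal) collapse to a
  zero-width interval.
* **Test.** Two-sided Mann–Whitney, because elements of both signs are
  expected (destabilizing elements raise $r$ when deleted, expression-
  promoting sequences lower it). The p-value is exact by enumeration when
  the smaller group has at most 8 untied values — per-position groups are
  often tiny, where the normal approximation is poor — and otherwise uses
  the normal approximation with tie and continuity correction. Identical
  groups give p = 1.
* **Multiplicity.** Bonferroni over the family of *analyzed* positions:
  tests that were never performed are not part of the family. Adjacent
  significant positions are merged into intervals for BED output.

## The synthetic-data generator

The generator is the package's ground-truth instrument: it emulates an
AT-rich ~781-nt 3'-UTR (42% GC, which gives on the order of 64 SpCas9 sites
on a typical draw, with a canonical AATAAA signal planted 10–35 nt upstream
of the 3' end), Cas9 cuts 3 bp 5' of each NGG PAM, a deletion-length
spectrum with mode 5 nt truncated at 40 nt so that both the analyzable 3–29
window and the filtered tails are populated, dual-cut alleles spanning
nearby cut pairs, an intact-allele fraction of 0.3, 150-nt paired-end
fragments of Normal(300, 30) length, and substitution sequencing errors at
10^-3 per base. Default allele density (24 draws per cut before
deduplication) produces roughly a thousand distinct analyzable alleles over
the UTR — the saturation scale a full screen reaches. Library depths default
to 200,000 DNA and 112,500 RNA fragments, preserving the ~80:45 proportion
of a deep screen at desk scale.

Ground truth is an *effect profile*: intervals with multiplicative RNA
effects (multiplier 2 models removal of a destabilizing element; multiplier
0.5 removal of a transcription-promoting one) plus a baseline RNA/DNA ratio
of 0.5 for the intact allele. Each allele's expected RNA abundance is its
DNA frequency times the baseline times the product of multipliers of every
region its deletion overlaps.

Reads are emitted pre-aligned: a truth SAM (with D operations at the
allele's deletion for junction-spanning mates) alongside paired FASTQ, so
the pipeline is exercised end to end without an external aligner while the
FASTQ preserves the option of using one. For statistical calibration at
depths where emitting tens of millions of read records would add nothing,
`simulate_counts()` draws per-allele fragment counts directly
(multinomially) in the shape the quantification stage consumes; this path
assumes perfect fragment classification, which the read-level path verifies
separately.

What the generator does *not* model — and therefore what passing tests do
not demonstrate about real data: PCR amplification and GC bias, unequal
editing efficiency across sites, microhomology-biased end-joining spectra,
indel sequencing errors beyond an optional 1–2 nt injection mode used to
exercise that filter, base-quality variation, and reverse-transcription
artifacts. Real screens also leave low-complexity regions uncovered; the
generator reproduces coverage gaps only insofar as PAM sites are absent.

## Numerical and design choices at open points

* **Coordinates** are 0-based half-open throughout; BED output needs no
  shifting.
* **PolyA signal search**: the hexamer must lie entirely within 10–35 nt
  upstream of the cleavage site (the strictest reading of the window); with
  several candidates the 5'-most is chosen, keeping the distal guide cut as
  far from the signal as possible. When no canonical AATAAA is found the
  pipeline requires a user-supplied signal rather than predicting
  alternatives.
* **Guide design**: plain NGG enumeration with no uniqueness or synthesis
  filters; the dual pair maximizes the excised span subject to sparing the
  stop codon (antisense proximal guide, PAM inside the UTR) and the polyA
  signal (sense distal guide, PAM entirely 5' of the signal).
* **Pilot classes**: a deletion is classed with the element only if fully
  inside it, with the element-plus class only if it strictly contains the
  element, and as control only if disjoint; boundary-straddling deletions
  are excluded. "Most abundant" is by DNA count, since abundance of an
  allele in the population is a DNA property.
* **Determinism**: every stochastic step (generator, bootstrap) takes a
  seed, and a pipeline run writes a log from which any output can be
  reproduced byte for byte.

## Problem sizes used by the test suite

The package's statistical guarantees are checked at sizes chosen to make
the checks sharp yet quick: exact-test equivalence on 200 random small-group
instances against a full rank-enumeration oracle; bootstrap coverage on
1,000 simulated sets of 15 values (B = 1000); type-I error and family-wise
control on 100 seeded null screens of 10^5 fragments per library over 64 cut
sites; and sign-correct recovery of planted 20-nt elements (multipliers 2.0
and 0.5) in 20 seeded screens at the same depth. Planted elements are
centered on actual cut sites of the fixed synthetic UTR: a screen can only
interrogate bases that deletions reach, so planting where no guide cuts
would test nothing — the real-data analogue is that uncovered low-PAM
regions yield no calls.

## A short worked run

```{r example, eval = FALSE}
ref <- make_synthetic_utr(seed = 3)
guides <- enumerate_guides(ref)
prof <- effect_profile(
  data.frame(start = 560, end = 580, multiplier = 2),
  baseline_ratio = 0.5)
truth <- simulate_alleles(ref, guides, prof,
                          depths = c(dna = 3e4, rna = 17e3), seed = 1)
sim <- simulate_reads(truth, ref, tempfile("screen"))
cfg <- read_run_config(seed = 1)
res <- run_pipeline(cfg, ref = ref, dna_sam = sim$dna_sam,
                    rna_sam = sim$rna_sam, out_dir = tempfile("out"))
res$map$significant_intervals
plot_position_map(res$map)
```

## Known limitations

Overlapping deletions make neighboring positions statistically dependent;
the map is a marginal, not a deconvolved, picture, and a strong element
spills significance into flanking bases covered by the same alleles. The
Mann–Whitney "elsewhere" group contains all other deletions, so a UTR
dominated by large-effect regions shifts the comparison baseline. Bonferroni
over positions is conservative under this dependence. Finally, $r$ compares
steady-state RNA only: separating transcriptional from post-transcriptional
mechanisms requires the companion 4sU pulse (new transcription) and
pulse-chase (decay) assay statistics, which this package computes from
replicate tables but which need their own experiments.
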