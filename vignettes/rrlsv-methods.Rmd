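---
title: "Detecting structural variants from paired-end reduced representation libraries"
author: "rrlsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structural variants from paired-end reduced representation libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrlsv)
```

## The method

`rrlsv` implements structural-variant (SV) discovery by paired-end mapping
(PEM) of *reduced representation libraries* (RRLs). Instead of sequencing a
whole genome, an RRL sequences a size-selected slice of a restriction
digest: genomic DNA (here, pooled DNA from 25 individuals per population)
is cut with a blunt 4-cutter (AluI, motif AGCT, cutting between the G and
the C), fragments of a narrow length window (150--200 bp, or 125--200 bp)
are excised from a gel, and both ends of each fragment are sequenced with
short reads (36 bp, trimmed to 32 bp).

Because every sequenced molecule is a restriction fragment of known length
range, the *outer span* of a read pair mapped back to the reference -- the
distance from the leftmost mapped base of one mate to the rightmost mapped
base of the other -- is tightly constrained. A pair whose span or
orientation is inconsistent with the library is a *discordant pair* and is
evidence for a rearrangement between the sampled genome and the reference:

* span too **long** (> 220 bp): the sample carries a **deletion** relative
  to the reference inside the fragment;
* span too **short** (< 100 bp): the sample carries an **insertion**;
* **non-convergent orientation**: the fragment straddles an **inversion
  breakpoint**.

Discordant pairs of one class are clustered by single linkage: two pairs
join a cluster when their left-mate intervals overlap *and* their
right-mate intervals overlap. A cluster has a support count $n$, a
consensus span (median of member spans), and a mean mapping quality over
all member mates (`aamq`). Pairs implying an SV larger than 100 kb are
discarded before clustering, and inter-chromosomal pairs are excluded.

## The discrimination rule

Gel size selection is imperfect: a small fraction of molecules outside the
excised window leaks through (migration artifacts). A leaked, perfectly
reference-concordant fragment of, say, 300 bp produces a small discordant
cluster indistinguishable in kind from a true deletion -- but its span
deviates only modestly from the 220 bp threshold and its support is low,
because leakage is rare. True rearrangements at meaningful allele
frequency enjoy the full library coverage of their junction fragment.

The discrimination rule exploits this asymmetry. Writing the span-size
deviation as

$$d = \mathrm{span} - 220 \;\text{(deletions)}, \qquad
  d = 100 - \mathrm{span} \;\text{(insertions)},$$

a cluster is validated when

$$d \times n > 500 \quad (\text{strict}).$$

The deviation baseline is the concordance threshold (220 / 100 bp), not
the modal insert (~185 bp): the rule's published validity window starts
exactly at a span of 220 bp, which identifies the baseline unambiguously.

The rule was calibrated on deletion spans of 220--720 bp -- the range that
gel leakage can plausibly reach. `rrlsv` evaluates the rule for *every*
deletion cluster with span > 220 and reports a separate `rule_in_window`
flag (FALSE above 720 bp) instead of refusing to score large spans. Two
facts force this design: confirmed rearrangements exist just above the
window (a validated deletion predicted at span 868 with $n = 2$), so large
spans cannot be auto-failed; and independent confirmation above the window
was mixed (one single-pair 5.8 kb cluster confirmed, one 15-pair 19.6 kb
cluster not), so the flag marks them lower-confidence rather than
auto-passing silently. Insertion spans are meaningful between 32 bp (one
read length) and 100 bp; inversion-breakpoint clusters are outside the
rule (`not_applicable`).

Clusters are additionally screened by mapping quality: both footprint
sides must reach a mean mapping quality of 60 (stringent) or 35 (relaxed),
the two operating points used for the published call sets. The per-side
mean is the stricter reading of requiring "both ends" to map well.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `span_min`, `span_max` | 100, 220 bp | concordance window on the outer span |
| `rule_threshold` | 500 | strict lower bound on $d \times n$ |
| `del_valid_max` | 720 bp | upper end of the calibrated deletion window (confidence flag) |
| `ins_min` | 32 bp | smallest meaningful insertion span |
| `mapq_threshold` | 60 (alt. 35) | per-side mean mapping-quality floor |
| `max_sv_bp` | 100 kb | cluster size cap |
| `cluster_slop` | 0 bp | footprint overlap tolerance |
| `merge_overlap` | 0.5 | reciprocal overlap for cross-pool locus merging |
| `tag`, `trim_to`, `min_q` | "CT", 32, 20 | read qualification |

The restriction tag is the post-cut AluI half-site: every internal
fragment begins `CT` and ends `AG`, so both mates of a genuine RRL
fragment begin `CT`. Reads are trimmed to 32 bp and every base must reach
phred 20 ("l32q20"); a pair is rejected when either mate fails, the
stricter of the two possible readings of a paired filter.

Cross-pool merging (reciprocal overlap 0.5) and the footprint-overlap
tolerance (0 bp) are conventions chosen here -- the original analysis does
not state its criteria -- and both are configurable. Sharing partitions
(Venn cells over up to 6 pools) are computed over rule-validated calls
only, matching how the published breed-sharing analysis restricted itself
to rule-validated deletions.

## Mapping

Alignments normally enter as name-grouped SAM (`read_sam_pairs()`), with
the aligner's mapping qualities preserved and the outer span recomputed
from mate coordinates (TLEN is ignored). The original study's aligner is
not reimplemented; to keep the test bed self-contained the package
includes a deterministic toy mapper (`map_reads_unique()`): exact
dictionary matching on both strands, a half-read seed search for
one-mismatch placements, and a *unique best hit* requirement -- a read
maps only when exactly one locus attains the best mismatch count (0 or 1),
mirroring the unique-&le;1-mismatch constraint of the analysis. Its
mapping qualities are a package convention: 99 for a unique exact hit, 80
for a unique one-mismatch hit. Both values clear the stringent threshold
of 60, so synthetic clusters are screened the way real high-quality
clusters are.

## The synthetic study

`simulate_study()` builds the standard validation conditions as one
deterministic function of a seed:

* a 5-Mb i.i.d. genome (GC 0.42) whose AluI-site spacing is set to one
  site per 190 bp, so that 150--200 bp fragments cover ~9.6% of the
  genome -- the genome fraction the published in-silico digest of the real
  assembly yields (101 Mb of ~1.05 Gb). An unadjusted i.i.d. genome would
  give only ~6%.
* 60 deletions (50--5000 bp), 15 insertions (10--90 bp) and 5 inversions
  (200--2000 bp), placed uniformly with &ge; 2 kb separation, at pool
  allele frequency 1.0;
* sequencing at 20 pairs per selected fragment, 36-bp reads, per-base
  substitution error 0.001;
* per-base probability 0.004 of a low (phred < 20) quality score, which
  makes ~77% of pairs survive the l32q20 filter -- the qualified fraction
  observed in the real libraries;
* gel leakage: an out-of-window fragment molecule is accepted with
  probability $0.001 \times e^{-\Delta/100}$ where $\Delta$ is its
  distance in bp from the window. The exponential decay encodes the same
  physical premise as the rule's validity window: gel artifacts reach
  nearby sizes only. Leakage is per *molecule*, so a leaked fragment
  typically contributes one or two pairs -- exactly the small-deviation,
  low-support clusters the rule exists to absorb.

Each sampled molecule draws its haplotype by the local SV's allele
frequency (per-fragment draw; individual genotypes within the pool of 25
are not modelled beyond frequency, which is all the pooled design
observes).

### What the RRL design can and cannot see

An implanted SV is *detectable* only if the variant haplotype carries a
size-selected fragment whose end reads both map cleanly around the
junction. `detectability_mask()` formalises this: the junction must lie at
least one read length (32 bp) inside both fragment ends, and the
fragment's reference-projected span must fall in the discordant window for
its class (deletions: span $\in$ (220, 100000]; insertions: span $\in$
[32, 100), which mappable flanks tighten to an effective minimum of
$2 \times 32 = 64$ -- consistent with the smallest insertion span the real
screen confirmed, 64 bp). Under the default conditions only a few percent
of randomly placed SVs are detectable; this is a property of the RRL
design itself, not of the caller, and the end-to-end recovery checks are
therefore evaluated over the mask-positive subset.

### What passing tests do and do not show

The generator emulates the statistical structure the caller relies on
(fragment-length-constrained spans, restriction tags, leakage, errors,
pooling) but not repeat landscapes, PCR duplicates, base-composition bias
or reference assembly errors. Passing the synthetic recovery checks shows
the algorithmic chain is correct and calibrated to its own assumptions; on
real data, repeat-driven mismapping and assembly errors add false-positive
modes that the mapping-quality screen only partially removes.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally; BED/BEDPE output converts
  to 0-based half-open at the boundary only. A deletion with breakpoints
  $(l, r)$ removes bases $l{+}1..r$ and has length $r - l$; this is the
  convention under which every published breakpoint/size pair is
  internally consistent.
* Cluster span = median of member spans (robust to one outlier pair); the
  aggregation is not stated in the original analysis.
* The predicted interval is the inner interval between the footprints
  (`[left footprint end, right footprint start]`); when heavily
  overlapping mates make the inner edges cross (small insertion spans) the
  edges are ordered.
* Breakpoint resolution anchors the junction-spanning product by exact
  20-mer match at its ends and chooses the split minimising total
  mismatches; ties (junction microhomology) are broken toward the
  smallest coordinates, the usual left-alignment convention, which the
  original analysis does not state. Resolution fails below 95% identity
  (configurable), for products shorter than 40 bp, or when the product is
  not shorter than its reference extent (no deletion junction).
* Microhomology at breakpoints $(l, r)$ is the longest $k$ with
  `ref[l+1..l+k] == ref[r+1..r+k]` (deleted prefix equals post-junction
  prefix), searched up to 25 bp.
* Empty inputs flow through every stage: an empty FASTQ pair yields a
  zero-count QC report, a header-only VCF and an empty locus table.

## Problem sizes

The bundled checks run the full chain -- simulation, QC, mapping,
classification, clustering, rule screening, truth comparison -- on the
5-Mb single-pool study (~56k read pairs, under a minute), plus a
two-pool 0.3-Mb sharing scenario and ~1 Mb of digestion oracle
comparisons. These sizes were chosen so the whole suite exercises every
code path at meaningful depth while remaining quick to run routinely.

## Known limitations

* Inversion breakpoints are clustered and reported but not scored by the
  rule, and inversion intervals are not reconstructed (an RRL sees only
  the breakpoint-spanning fragments).
* Size estimates for unresolved calls are relative to the modal insert
  and inherit its spread; exact sizes come only from breakpoint
  resolution.
* The toy mapper is for synthetic data; real data should be aligned
  externally and ingested as SAM.
* Allele frequencies are not estimated from read counts; presence/absence
  across pools is what the pooled design supports (and even that is
  conservative: PCR follow-up in the original study found SVs more widely
  shared than sequencing predicted, because an RRL samples an SV only
  when restriction sites flank it in range).
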