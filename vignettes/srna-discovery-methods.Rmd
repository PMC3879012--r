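---
title: "Methods: sRNA discovery and stress-response profiling with sRNAstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sRNA discovery and stress-response profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAstress)
```

# Scope and model

sRNAstress implements a genome-scale procedure for discovering bacterial small
non-coding RNAs (sRNAs, roughly 50–500 nt) from mapped RNA-seq reads and for
characterizing how they respond to graded chemical stress. The search space is
the set of **interoperonic regions (IORs)** — maximal intervals of the contig
not covered by any operon span, with ORFs unassigned to an operon treated as
singleton operons so that all gene-covered DNA is excluded. Coordinates are
0-based half-open internally; GFF3 import/export converts to 1-based
inclusive, and BED is consumed natively. IORs are strandless, because the
counting model assumes an unstranded library protocol.

The calling procedure has three stages:

1. **Threshold call.** An IOR is *expressed* when its raw read count reaches
   `min_count` (default 50) in at least a quorum of libraries. The default
   quorum is a single library — the permissive reading that retains
   condition-specific sRNAs — and is configurable as a library fraction
   (`min_library_fraction`), since a stricter quorum is equally defensible.
   Raw, un-normalized counts are used here deliberately: the threshold is
   calibrated against the raw read-count distribution of annotated genes, not
   against normalized abundances.
2. **Prediction intersection.** An expressed IOR becomes a *candidate* when it
   overlaps (by at least 1 nt) an interval from a computational sRNA
   prediction track, supplied as BED. Predictions matching an already-known
   sRNA set are removed through an exclusion list, so only new candidates
   remain.
3. **UTR false-positive filter.** Coverage bleeding over from the
   untranslated ends of a neighboring gene's transcript can make an IOR look
   expressed. A candidate is eliminated (`fp_utr`) when the share of its
   pooled per-base coverage lying in the two `w`-nt flank windows (default
   50 nt) reaches `dominance` (default 0.8) *and* the neighbor ORF on the
   dominant side is itself expressed (count ≥ `neighbor_min`, default 50, in
   at least one library). Both conditions are required: a dominant flank next
   to a silent gene cannot be explained as UTR bleed-through and is retained.
   The original procedure this reimplements was manual visual curation; an
   explicit two-parameter rule replaces it so results are reproducible.
   IORs no longer than `w` cannot be assessed (the window is the whole IOR);
   they are retained and flagged for manual review.

Survivors are named `sCAC<n>` after the locus number of the nearest
downstream ORF (left neighbor for terminal IORs), with deterministic
`a`, `b`, … suffixes when several survivors share a reference ORF.

## Read counting

A read increments a feature when their overlap is at least
`min_overlap_frac` (default 0.5) of the read's length. The rule is symmetric,
standard, and makes double-counting impossible for disjoint features at
fractions above one half. Counting is unstranded throughout.

## Differential expression

Expression of the sRNA set (known + newly called) is compared pairwise — each
stress level against the unstressed control at the same time point — under a
negative binomial model with variance $\mu + \alpha\mu^2$:

* **Size factors** are median-of-ratios: factor $s_j$ is the median over
  features of $k_{fj}/\tilde k_f$, where $\tilde k_f$ is the feature's
  geometric mean across libraries (features with a zero anywhere are
  excluded; a per-library fallback over nonzero features handles the
  degenerate case).
* **The two-group test** models each group's count sum as a moment-matched
  negative binomial at the pooled per-unit mean and sums the conditional
  probabilities of all splits of the observed total that are no more likely
  than the observed one. Totals up to $10^4$ are enumerated exactly; larger
  totals use a normal approximation on the normalized difference. At
  $\alpha = 0$ the conditional distribution reduces exactly to a binomial.
* **Dispersion** is estimated per feature by method of moments, pooling
  within-group means and variances of normalized counts across replicated
  (condition × time) cells and solving $s^2 = \mu + \alpha\mu^2$, floored at
  `min_disp = 0.01`. A local-regression shrinkage estimator (as mature DE
  packages use) would be preferable at scale; the moment estimator is
  self-contained, well-defined, and adequate for replicated designs — this is
  a deliberate design simplification.
* **No multiple-testing correction by default**: significance is raw
  $p \le 0.05$, matching the convention of the analysis this package
  reimplements. Benjamini–Hochberg adjustment is available behind
  `fdr = TRUE`.

Note that for a conditional test, rescaling one library's counts together
with its size factor leaves normalized means exactly invariant but shifts
p-values slightly (the conditioning statistic changes); the suite checks
order-of-magnitude stability rather than exact invariance.

## Expression patterns

Per (stressor, dose, time) contrast the **ratio matrix** holds
$\log_2\!\frac{\bar n_\text{stress} + c}{\bar n_\text{control} + c}$ of mean
normalized counts with pseudocount $c = 1$ (zeros are common at sRNA scale).
Rows are clustered agglomeratively with Pearson correlation distance
($1 - r$; constant rows get distance 1 with a message) and average linkage,
cut at a user-chosen $k$ (default 4, the scale of cluster structure such
stress panels typically show). Distance, linkage and $k$ are configurable
because no single choice is canonical. **Percentile ranks** map each
feature's normalized count within a library to $100(r-1)/(n-1)$ with average
ties, giving the within-library abundance standing that complements the
ratio view.

## Sequence-level characterization

* **Rho-independent terminators** are found by enumerating all
  inverted-repeat placements with stem arms of 6–12 nt, loops of 3–10 nt, at
  most one unpaired stem position, and optional G·U wobble pairs, scoring
  `paired + 0.5·GC − mismatches + min(u_tail, 8)` where `u_tail` is the
  longest poly-U run starting within `tail_gap = 3` nt of the stem's 3' arm.
  This is a combinatorial detector, not a thermodynamic folder: no partition
  function or free energy is computed. The pairing-count score is fully
  enumerable, which makes the detector exactly testable against brute force;
  the cost is that marginal, energetically weak hairpins are scored the same
  as stable ones.
* **Hfq-binding classification** follows the canonical description of
  Hfq-associated sRNAs — a poly-U tail at the 3' end downstream of the
  terminator and a U-rich or AU-rich element upstream of it. The rule is:
  positive iff (a) a terminator exists with its 5' stem arm in the 3' half of
  the sRNA, (b) the 10 nt downstream of its stem contain at least 5 U, and
  (c) the 25 nt upstream of the stem have U fraction ≥ 0.40 or A+U fraction
  ≥ 0.70. Criteria are evaluated on the *top-scoring* 3'-half hit — the
  hairpin a terminator caller would report — so ablating the tail of the
  terminator reliably flips the call. All thresholds are explicit
  configuration values; they are this package's defaults for a rule that is
  usually stated only qualitatively. In a 29% GC genome the AU-rich
  criterion (c) is nearly always satisfiable by chance (random A+U fraction
  averages 0.71), so the discriminating work is done by (a) and (b) — worth
  remembering when interpreting positive calls on real low-GC genomes.
* **Promoter scanning** builds PSSMs as
  $\log_2\frac{(c_{bj}+q)/(n+4q)}{\pi_b}$ with pseudocount $q = 0.5$ and
  scans all two-box placements with a 15–19 nt spacer (a σ^A-like range),
  summing the −35 and −10 box scores. The shipped worked example is the
  σ^A consensus pair TTGACA/TATAAT.

T and U are equivalent on input everywhere.

# The synthetic-data generator

`simulate_genome()` and `simulate_counts()` define the study conditions the
package is validated under; they are tested code, not a fixture.

The genome is an i.i.d. nucleotide string at GC 0.29 (a low-GC clostridial
genome) of 120 kb by default, tiled by 48 operons of 1–5 ORFs (200–800 nt,
intra-operon gaps 25–60 nt). Internal inter-operon gaps host, in random
order: 20 true sRNAs (48–300 nt, the span of experimentally validated sizes,
centered with ≥ 100 nt margins), 5 "known" sRNAs (the analogue of a
previously predicted set, used as the exclusion list), 10 UTR-bleed decoys,
4 structural RNAs (rRNA/tRNA-like, baseline mean 20,000, so the read-category
partition has a realistic structural share), and empty gaps. Half of the true
and known sRNAs are built Hfq-positive by splicing in a terminator cassette:
a 25-nt upstream window of fixed 52% U / 72% A+U composition, an 8-bp GC stem,
a 4-nt A/G loop, and an 8-U tail. Two constructive details guarantee that
classification of the planted set is separable at the default thresholds,
rather than probably separable: the 4 nt abutting the stem are drawn from
{C, U} only (an A or G there can Watson–Crick- or wobble-pair against the
poly-U tail and extend the stem into a register that swallows the tail), and
Hfq-negative sRNA sequences have U-runs suppressed (no 10-nt window keeps
≥ 5 U) so the tail criterion cannot fire by chance.

The study design is 7 conditions — an unstressed control plus butanol at
30/60/90 mM and butyrate at 30/40/50 mM (low/medium/high) — sampled at 15,
30, 60 and 75 min, with 2 replicates and 50,000 reads per library by default:
a desk-scale replica of the original 84-library design (3 replicates) that
keeps the full pipeline under a minute. Counts are negative binomial with
mean $s_l\,\mu_f\,e_f(\text{condition}, t)\,\cdot d/50000$ and dispersion
$\alpha = 0.05$ (a modeling choice; the source data carry no dispersion
estimate), size factors log-normal around 1 (sd 0.1), and background
intergenic Poisson noise at 0.5% of depth so the count threshold is
meaningfully exercised. Stress effects are multiplicative and monotone in
dose — fold changes 1.5/2/4 for low/medium/high, direction per stressor drawn
from {−1, 0, +1} per sRNA (10% of ORFs also respond) — with a time ramp that
applies half the log-effect at 15 min and the full effect from 30 min,
emulating early-response kinetics.

Reads are realized as uniformly placed read-start intervals of 50 nt within
their feature. **Decoys are the exception**: their reads straddle the
operon/IOR boundary, with the read's overlap into the IOR uniform on
[25, 74] nt. This is the geometry of genuine UTR bleed-through — a transcript
running across the boundary — and it concentrates about 86% of the IOR-clipped
coverage in the 50-nt flank window. A naive "read starts uniform inside the
window" placement would leave only about half the covered bases inside the
window, below any sensible dominance threshold, i.e. it would simulate a
short intergenic transcript rather than UTR bleed. Decoy reads never extend
more than a read length beyond their window.

What the generator does **not** emulate: sequencing error and quality,
alignment ambiguity, strand information, rRNA depletion artifacts, operon
read-through transcription, condition-dependent library composition shifts,
or sRNAs antisense to ORFs. Passing the end-to-end recovery checks therefore
demonstrates that the calling logic, the filter and the classifiers do what
they claim under the stated statistical structure — not that their default
thresholds are optimal for any particular real genome.

# Numerical choices and degenerate inputs

* Exact NB enumeration up to total $10^4$, normal approximation beyond;
  all-zero features give $p = 1$; the observed-probability comparison uses a
  $1+10^{-8}$ slack against floating-point ties.
* Terminator hits are sorted by score, then leftmost position, then 3' end —
  a total, deterministic order.
* Clustering ties are handled by `stats::hclust`; with continuous ratio data
  exact ties are measure-zero, and cluster *partitions* (not labels) are
  permutation-invariant, which is what the suite asserts.
* Percentile ranks of a single feature are 100 by convention (with a
  message); all-equal counts rank 50.
* Overlapping operon spans are merged with a warning before IOR derivation;
  zero operons give one whole-contig IOR in terminal mode.
* The pipeline writes every table deterministically (fixed column order, no
  row names, no timestamps) and manifests MD5 hashes of all outputs, so a
  config + seed pair is reproducible byte for byte.

# Problem sizes used in validation

The shipped checks run at: 100 randomized fixtures per brute-force oracle
(reads ≤ 10⁴ per fixture, sequences ≤ 300 nt); null calibration with 2,000
features at 3 vs 3 replicates; power at 100 repeats of a 4-fold effect at
mean 200; and the default 56-library end-to-end design. These sizes were
chosen so the entire suite completes in a couple of minutes on one CPU while
keeping Monte-Carlo standard errors small relative to the tolerances tested
(e.g. 3 standard errors of the null rejection rate at $n = 2000$ is ±0.015).

# Known limitations

* The dispersion estimator has no shrinkage; at 2 replicates per cell,
  per-feature estimates are noisy and the floor does real work. For real
  data with few replicates, an established DE package's shrinkage estimator
  is the better tool; this package's value there is the calling/filtering
  front end and the sequence-level classifiers.
* The UTR filter sees pooled coverage; a condition-specific UTR extension
  co-occurring with a genuine condition-specific sRNA in the same IOR is not
  separable by this rule.
* The terminator score is not an energy model; it should be read as a
  screening statistic.
* Unstranded counting cannot distinguish an sRNA from an antisense transcript
  of a neighboring gene.
* Single-contig genomes are the primary path; multi-contig inputs are
  handled by running contigs independently.
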