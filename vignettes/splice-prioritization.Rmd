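---
title: "PSI quantification, candidate prioritization and regulator ranking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSI quantification, candidate prioritization and regulator ranking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceprio)
library(dplyr)
```

This vignette documents the models, conventions and design choices behind
`spliceprio` — what each stage computes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open.

## Coordinates and the event catalog

All internal coordinates are **0-based half-open**, so every interval length
is `end - start` with no off-by-one arithmetic; GTF input/output converts
from/to the 1-based inclusive convention at the boundary
(`read_gtf_models()`, `write_gtf()`).

`enumerate_events()` compares transcript structures pairwise within a gene
and classifies events into the five standard categories:

* **CASSETTE** — an internal exon of one transcript whose flanking exons are
  joined by a single junction in another, with no overlapping exon there.
  Inclusion evidence spans two junctions, exclusion evidence one.
* **MXE** — two non-overlapping internal exons sharing both flanking
  junction anchors and never co-present in any annotated transcript of the
  gene. Because the event record carries a single alternative interval, the
  upstream (smaller-start) exon is stored as `alt_segment` and its junctions
  as the inclusion set; the downstream exon's junctions are the exclusion
  set. This is a representation choice only — both exons are recoverable
  from the junction sets.
* **A5SS / A3SS** — two versions of one exon sharing one junction boundary;
  the category is strand-aware (the moving boundary is the donor on `+`,
  the acceptor on `-`). The alternative segment is the extension, the longer
  form's junction is the inclusion junction.
* **RI** — an intron of one transcript fully contained in an exon of
  another. Retention has **no junction evidence** (a retained intron
  produces no junction-spanning read on the inclusion form), so RI events
  carry an empty inclusion-junction set and are catalogued but not
  junction-quantifiable; `psi_matrix()` drops them with a warning. Exon-body
  read support, which could quantify RI, is out of scope.

Events found through multiple transcript pairs are merged on
(type, chrom, strand, alternative segment, exclusion junctions). The catalog
is annotation-driven; junctions present only in reads are not discovered.
The coding flag `in_cds` is true when the alternative segment overlaps a CDS
interval of a transcript that contains the segment inside an exon (an
inclusion-form transcript).

## Junction extraction and PSI

`extract_junctions()` walks CIGAR strings and emits one junction per `N`
operation; a junction needs at least `min_overhang` aligned bases
(default 6) on both sides within the read. Insertions and soft/hard clips
consume no reference; deletions consume reference but do not count as
aligned overhang. Minimal headerless SAM is accepted; only FLAG, RNAME, POS
and CIGAR are read.

PSI uses junction-count normalization. For inclusion reads \(I\) over
\(n_{inc}\) inclusion junctions (2 for a cassette exon) and exclusion reads
\(S\) over \(n_{exc}\):

\[
\bar I = I/n_{inc}, \qquad \bar S = S/n_{exc}, \qquad
\psi = \bar I / (\bar I + \bar S).
\]

Without the normalization, an inclusion isoform sampled at equal molarity
would contribute twice as many junction reads as the exclusion isoform and
PSI would be biased upward. PSI is `NA` when `I + S < min_total_reads`
(default 10 — the coverage rule needs a concrete number; it is configurable
everywhere it appears). Only junction-spanning reads count; reads internal
to the alternative exon are ignored. Junctions are matched on
(chrom, donor, acceptor), summing over strand: minimal single-end alignments
carry no transcription-strand information.

Expression is normalized to TPM with gene length defined as the union of
exonic bases over the gene's transcripts. The low-expression filter removes
genes with mean TPM strictly below the threshold (default 2; a gene at
exactly 2 is retained) and deliberately does **not** renormalize — columns
of a filtered table no longer sum to \(10^6\) unless `compute_tpm()` is
re-applied to the retained counts.

## The two screens

**Differential splicing** is a two-sided Wilcoxon rank-sum test per event on
the non-NA PSI values, with \(\Delta PSI\) = mean tumor − mean control. The
exact rank-sum distribution is used when both groups have at most 8 values
and the pooled values are tie-free; otherwise the normal approximation with
tie and continuity correction. Groups with fewer than 2 usable values yield
`NA`.

**Survival association** dichotomizes samples at the median PSI of each
event — ties, including the median itself, go to the low group, which makes
the split deterministic — and compares the two groups with the log-rank
test. The statistic is the standard one-degree-of-freedom
\((\sum_j O_{1j}-E_{1j})^2/\sum_j V_j\) with the hypergeometric variance at
each distinct event time, computed by an internal vectorized routine that is
cross-checked against `survival::survdiff` in the test suite. The p-value
is chi-square(1) asymptotic in large samples; when the number of group
assignments `choose(n, n_a)` is at most 20,000, `logrank_test()` instead
enumerates the statistic's full permutation distribution and reports the
exact tail probability. The chi-square approximation is known to be
unreliable at such sizes, and the exact mode costs little there; the
asymptotic p is always reported alongside (`p_chisq`). This exact
small-sample mode is the package's own choice of p-value; the screen at
cohort scale (tens of samples) always takes the chi-square path.

Median dichotomization + log-rank was chosen over likelihood-based
isoform-survival modeling: it is assumption-light, matches how PSI–survival
relationships are usually displayed (Kaplan–Meier curves by PSI group), and
is directly testable against a permutation oracle. Cox modeling and
competing risks are out of scope.

## The prioritization cascade

`apply_prioritization()` evaluates six exclusion criteria and three
shortlist rules per event; an event is retained iff **no** criterion fires
and **all** shortlist rules hold. The flags are computed independently, so
the retained set equals the intersection of the per-criterion survivor sets
and is monotone in the thresholds.

| flag | fires when | default |
|---|---|---|
| `c1_na_two_thirds` | PSI `NA` in ≥ 2/3 of all samples | 2/3 |
| `c2_small_inframe` | length divisible by 3 **and** < 5 amino acids (< 15 bp) | — |
| `c3_no_survival` | log-rank p ≥ α (or `NA`) | α = 0.05 |
| `c4_no_differential` | Wilcoxon p ≥ α (or `NA`) | α = 0.05 |
| `c5_control_na` | PSI `NA` in > 4 control samples | 4 |
| `c6_small_delta` | \|ΔPSI\| ≤ 0.1 (the boundary value fires) | 0.1 |

Shortlist: alternative-segment length within 30–300 bp inclusive, segment in
the coding region, and mean tumor PSI above mean control PSI (the
"tumor-high" direction; no magnitude cutoff beyond c6). Two wordings needed
interpretation: c2 is read as *in-frame and trivially small* (a fragment
that is a multiple of 3 nt affecting fewer than five amino acids), which
excludes only in-frame segments under 15 bp; and c6 treats ΔPSI as an
absolute value, since a sign requirement already enters through the
tumor-high shortlist rule. p-values are used nominally (α = 0.05), matching
how such screens are usually reported; `adjust = "BH"` switches both screens
to FDR-adjusted values.

## Regulators, motifs and TF sites

`correlate_regulators()` ranks candidate RBPs by the Pearson correlation
between a target event's per-sample PSI and regulator expression over
pairwise-complete samples (t-distribution p, sorted by p then |r|; fewer
than 3 complete pairs gives `NA`). `scan_motif()` reports **all**
overlapping exact occurrences of the motif (default `GGAA`) on the mRNA
sense strand — no IUPAC degeneracy — and `motif_summary()` reports the
percentage of scanned sequences with at least one hit, to one decimal.

`filter_tf_sites()` keeps ChIP sites whose strand-aware offset from the
target's TSS lies in the window −2500..+500 **inclusive** and whose score is
**strictly** above 50. The window bounds are inclusive ("between −2500 to
+500") while the score cut is strict ("over than 50"); both readings are
asserted by boundary tests. For minus-strand genes upstream means
numerically greater coordinates, so the offset is `tss - position`.
`rank_tf_candidates()` correlates each retained TF with the target gene in
every supplied expression cohort, ranks by worst-case p (ties by smallest
|r|), and flags TFs significant in **all** cohorts (intersection rule).

## The synthetic-data generator

`simulate_splice_study()` emulates a bulk tumor/control splicing cohort with
one cassette-exon event per event gene. Defaults are the study conditions,
chosen once:

* **Cohort shape**: 85 tumor / 10 control samples — so the "NA in ≥ 2/3 of
  samples" and "> 4 control NA" criteria operate at realistic proportions.
* **Baseline PSI**: Beta(2, 2) per event (clamped to [0.05, 0.95]), a broad
  mid-range distribution typical of variable cassette exons.
* **Biological variability**: per-sample Gaussian jitter with SD 0.08 around
  the event/group mean (final clamp [0.02, 0.98]). Real cohorts show
  continuous between-patient PSI variation; without it the median split of a
  survival-linked event would separate nothing but binomial noise.
* **Planted differential events**: 20 of 200 events get a +0.25 tumor shift.
* **Read depth**: total junction depth per event per sample
  `d ~ Poisson(100)`; inclusion reads `I ~ Binomial(d, 2π/(1+π))` — the
  two-junction inclusion form produces twice the junction reads per
  molecule — split evenly (binomially) between the two inclusion junctions.
  The PSI estimator's normalization exactly inverts this 2:1 weighting, so
  \(\hat\psi\) is consistent for π.
* **Survival**: `T ~ Exponential(h0 · exp(β(π − 0.5)))` with `h0 = 0.02`
  per month and β (log hazard ratio per unit PSI) defaulting to 4, driven by
  the true PSI of one flagship planted event. Centering at π = 0.5 makes β
  interpretable across the PSI range; with the 0.25 tumor shift the
  flagship's median-split groups sit near a log hazard ratio of 1, i.e. a
  strong prognostic splicing marker. Censoring is independent uniform on
  `(0, m)` with the horizon `m` solved numerically so the expected censored
  fraction matches `censoring_rate` (default 0.3) at the baseline hazard.
* **Regulators**: expression is an affine transform of
  `r·z(π) + sqrt(1−r²)·noise` for the planted regulator (default r = 0.8,
  anchored to the flagship event's standardized true PSI) and independent
  noise for the 30 decoys.
* **Motif**: `GGAA` planted at a random offset into a Bernoulli(0.352)
  fraction of alternative segments and rejection-excluded from the rest
  (sense strand; the genomic strand carries the reverse complement for
  minus-strand genes).
* **TF sites**: one planted TF whose promoter sites fall inside the window
  with scores above 50 and whose expression correlates with the target gene
  at r = 0.7 in both cohorts; decoys get random offsets/scores and
  independent expression.

The generator is a deterministic function of its configuration: the same
config and seed reproduce a byte-identical file bundle, and
`extract_junctions()` on the generated SAM reproduces the generator's
internal junction counts exactly. `truth_report()` compares pipeline output
against the recorded ground truth (PSI RMSE and 3-SE coverage, screen
sensitivity/specificity, planted regulator rank, recovered motif fraction).

**What it does not emulate** — and hence what passing tests do not show
about real data: sequencing error and quality, paired-end fragment geometry,
multi-mapping, GC or positional bias, isoform complexity beyond one cassette
event per gene, correlated events, batch effects, or non-exponential
hazards. Recovery results on this generator validate the estimators'
arithmetic and calibration, not robustness to alignment artifacts.

## Numerical choices and degenerate inputs

* PSI with `I = S = 0` (above no coverage threshold this cannot happen;
  below it) is `NA`, never `0/0`.
* Constant-PSI events produce a degenerate median split and `NA` log-rank p;
  all-censored groups likewise give `NA` rather than an error.
* Median-split ties go to the low group (deterministic).
* The exact log-rank p counts permutations with statistic
  `>= observed − 1e-12` to absorb floating-point ties.
* TPM requires a positive library rate sum per sample; a zero-total sample
  is an error naming the sample.
* `filter_low_expression()` on an empty table returns it unchanged.
* Events lacking any evidence row are excluded with
  `reason = "incomplete evidence"` rather than silently dropped.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated data at
sizes chosen to make the statistical assertions sharp but cheap: PSI
recovery on the default 200 × 95 cohort (19,000 cells, depth ~100);
null calibration on 50 independent null cohorts of 200 events; Wilcoxon
exactness by full enumeration at group sizes ≤ 8; log-rank versus a
100,000-shuffle permutation oracle at n ≤ 12; regulator and TF recovery
over 100 replicates each; the Beta-marginal Kolmogorov–Smirnov check on
1,500 baseline draws at its n-matched critical value; motif-scan equivalence
against a quadratic oracle on 1,000 random sequences.

## Known limitations

* The catalog covers the five classic local event types; alternative
  first/last exons, fusion transcripts and de-novo assembly are out of
  scope.
* RI events are catalogued but not quantified (no junction evidence for
  retention).
* A pooled SAM without per-sample labels quantifies as a single sample;
  per-sample junction tables (or one SAM per sample) are the intended
  multi-sample path.
* The Wilcoxon screen with a 10-sample control arm is mildly conservative
  (rank-test discreteness); measured null false-positive rates sit slightly
  below the nominal 0.05.
* No multiple-testing correction by default (nominal screening p-values,
  with an optional BH mode), so retained-candidate counts on real cohorts
  should be read as a shortlist, not as a controlled discovery set.
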