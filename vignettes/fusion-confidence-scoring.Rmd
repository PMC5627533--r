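---
title: "Rule-based confidence scoring of fusion gene candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based confidence scoring of fusion gene candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusescore)
library(dplyr)
```

## The problem

Fusion callers for paired-end RNA-seq (deFuse and its relatives) report a
putative fusion transcript wherever discordant read pairs and
junction-crossing reads can be assembled into a chimeric sequence. On real
tumour cohorts the large majority of these calls are mapping artifacts,
library-preparation chimeras, read-through transcription into a
neighbouring gene, or alternative splicing between adjacent genes — events
with little biological interest. Simple filters on read counts do not
separate true from false calls: a lowly expressed true fusion may have a
handful of supporting reads while a mapping artifact in a repeat-rich
region can have hundreds.

fusescore ranks candidates instead of hard-filtering them. Each candidate
starts from a **baseline of 10 score units**, and every feature rule that
fires adds its weight (almost all negative). The total,
$\min\!\big(10,\; 10 + \sum_i w_i\big)$, is classified as

* **high** confidence: $8 \le s \le 10$,
* **medium** confidence: $6.5 \le s \le 7.5$,
* **low** confidence: $s \le 6$.

Because every weight is an integer multiple of 0.5, no total can land
strictly inside $(6, 6.5)$ or $(7.5, 8)$: the three classes are exhaustive.
There is no floor — heavily penalized candidates can score well below zero.
The cap at 10 is a design choice of this package: strong read support can
push the raw sum above the baseline, and capping keeps the published class
definition ("between 8 and 10") exhaustive at the top.

## The scoring rules

| rule | weight | fires when |
|---|---|---|
| artifact list | −6 | gene pair on the recurrent-artifact blacklist |
| read-through / altsplice | −4 | caller flags the call as read-through transcription or alternative splicing between adjacent genes |
| adjacent only | −0.5 | partners are neighbouring genes, but no read-through/altsplice flag (adjacent-gene fusions are occasionally real) |
| intrachromosomal | −0.5 | both partners on one chromosome |
| breakpoint homology | −1 | ≥ 10 bases near the junction map equally well to both partners |
| repeat, middle bin | −0.5 | 80% up to 90% of spanning reads in repeat regions |
| repeat, high bin | −1 | more than 90% of spanning reads in repeat regions |
| no ORF | −1 | open reading frame not preserved |
| not exon boundary | −1.5 | splicing point not at an annotated exon edge |
| downstream 3′ break | −4 | break point downstream of the 3′ partner |
| all spans multimapped | −1.5 | every spanning read maps to more than one location |
| read support | −2.0 … +2.5 | always (tiered, below) |

The read-through/altsplice penalty and the adjacent-only penalty are
mutually exclusive by construction, as are the two repeat bins. The
repeat-proportion input is the *maximum* of the two partners' repeat
fractions; exactly 90% falls in the middle bin and only strictly more than
90% in the high bin. The `downstream_3prime_break` flag is consumed as an
input column, not recomputed from coordinates — deriving it would require
transcript models this tool deliberately does not consume.

### The read-support tier table

Read support always contributes a nonzero component between −2.0 and
+2.5: support always argues for or against a candidate. Candidates whose
spanning reads *all* multimap get −1.5 outright regardless of volume.
Otherwise, with $s$ split reads, $u$ uniquely mapping spanning reads and
$o$ the number of transcripts reported for the same gene pair in the
sample (splice-variant recurrence, a positive signal), the support index

$$ (s \ge 10) + (s \ge 50) + (u \ge 5) + (u \ge 15) + (o \ge 2) $$

maps through $(-2.0, -1.0, -0.5, +0.5, +1.5, +2.5)$. This tier table is a
declared design choice of this package: the method's published description
pins the component's range, sign structure and the all-multimapped value,
but not the individual cells, which appear only in supplementary material.
The default table is monotone in all three inputs, respects the published
bounds, and is fully configurable through `weight_config()` or a YAML file
for users who wish to substitute their own calibration. Candidates with no
spanning reads at all fall to the lowest tier rather than the
all-multimapped value — "all spanning reads multimapped" is vacuous at zero
reads.

The intrachromosomal penalty is unconditional by default;
`weight_config(intra_distance_cutoff = ...)` waives it for partners
further apart than the cutoff (in bases), for users who consider distal
intrachromosomal events as credible as translocations. No default cutoff
is shipped since any value would be a guess about the user's genome and
question.

```{r single}
score_candidate(fusion_candidate())                 # clean candidate
score_candidate(fusion_candidate(altsplice = TRUE)) # read-through/altsplice
```

## The artifact list

The same true fusion is rarely seen across multiple unrelated tumour
entities, so gene pairs recurrently called across entities are treated as
artifacts. The builder counts, for every pair, the number of *distinct
entity labels* with at least one sample containing the pair — multiple
samples, or multiple transcripts, within one entity count once, so one
large noisy cohort cannot promote a pair by itself. Pairs reaching the
recurrence threshold (default 3 entities, overridable) are blacklisted;
a user-supplied whitelist of verified fusions is removed even when
recurrent, protecting known drivers (KIAA1549--BRAF-like cases) that
genuinely recur across entities. Raising the threshold always yields a
subset, so the 3/4/5-entity lists are nested. Membership is by unordered,
case-folded gene pair: 5′/3′ orientation is deliberately ignored because
mapping artifacts are orientation-unstable and published lists rarely fix
an orientation.

```{r artifact}
cohort <- generate_cohort(cohort_params(), seed = 7)
dir <- tempfile(); invisible(write_cohort(cohort, dir))
manifest <- read_cohort_manifest(file.path(dir, "manifest.tsv"))
build_artifact_list(manifest, min_entities = 3)
```

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces multi-sample, multi-entity cohorts in the
caller's table dialect with per-row truth labels. Planted **true fusions**
follow the feature profile reported for validated fusions: split reads
uniform on [5, 200), spanning reads on [2, 50) with 80–100% mapping
uniquely, breakpoint homology below 10 bases, repeat proportion below 0.8,
reading frame and exon-boundary flags almost always set (97%), and an
enrichment (80%) of interchromosomal events. Planted **artifacts** are
read-through/altsplice rows, rows whose spanning reads all multimap, and
gene pairs planted across 2 to `n_entities` entities so that the
artifact-list builder has genuine recurrences (and sub-threshold decoys)
to find. **Ambiguous** rows sit exactly on decision boundaries (homology
exactly 10, repeat proportion exactly 0.8 or 0.9) for boundary testing.
Distributions are uniform or categorical within the described ranges —
the published evidence gives ranges, not distributions, and fitting
anything finer would be false precision.

The generator does not simulate reads, genomes, or a realistic
caller: coordinates are arbitrary, gene names are synthetic, and feature
values are drawn independently rather than from the correlated joint
distribution a real aligner induces. Passing tests on synthetic cohorts
therefore demonstrate that the *rules behave as specified* — separation of
planted classes, determinism, round-trips — not that the default weights
are optimal for any particular real dataset.

Default cohort sizes (12 samples, 5 entities, 5 true fusions, 10 flagged
artifacts, 2 boundary rows and 10 recurrent pairs per the defaults of
`cohort_params()`) are chosen so a full simulate → build → score →
evaluate round completes in seconds while every rule fires many times;
property tests run the scorer against an independent brute-force oracle
on 10,000 randomized records.

With the default weights and tier table, a read-through/altsplice row can
reach at most $10 - 4 + 2.5 = 8.5$, so the generator's guarantee that such
rows never classify high rests on it planting them with modest support
(under 50 split reads, occurrence 1, capping their support component at
+0.5 and their total at 6.5). Blacklisted pairs are bounded at
$10 - 6 + 2.5 = 6.5$ unconditionally.

## Evaluation

`recovery_rate()` reports the fraction of a validated-fusion list found
at or above a score threshold. Matching is by canonical gene pair, not
breakpoint — validated lists rarely carry exact coordinates — and a
validated pair with no scored row at all counts against recovery, so
fusions the caller never detected are not silently dropped from the
denominator. `threshold_sweep()` tabulates surviving candidates and
recovery across thresholds; both columns are non-increasing in the
threshold. The default report thresholds are 8 (high) and 6.5
(high + medium).

```{r evaluate}
scored <- score_fusions(bind_rows(cohort$tables),
                        build_artifact_list(manifest, 3))
threshold_sweep(cohort$truth, scored)
```

## Numerical and interface choices

* **Scores are exact.** All weights are half-integers, sums are exact in
  binary floating point, and scored tables serialize scores with one
  decimal place and re-read bit-identically. Output rows are ordered by
  total descending with ties broken by `cluster_id` ascending, so outputs
  diff cleanly.
* **Dialect insulation.** Tables are read through a column-alias mapping
  (`default_column_aliases()`) so genuine deFuse v0.6.x headers
  (`splitr_count`, `gene_chromosome1`, `exonboundaries`, two-sided
  `repeat_proportion1/2`, `probability`) resolve without renaming. Where a
  caller does not expose uniquely-mapping spanning reads, the reader falls
  back to `span_count` with a warning (optimistic: penalties from
  multimapping are then never triggered), or the user can bind a
  difference of two columns. The caller's own probability is carried
  through untouched and never used in scoring.
* **Validation is strict.** Counts must be non-negative with
  `unique_span_count <= span_count`, proportions in [0, 1], the
  interchromosomal flag must match chromosome equality (after stripping a
  `chr` prefix), and read-through implies adjacency; violations are
  reported with row indices rather than silently repaired.
* **Degenerate inputs.** Empty tables score to empty tables; an empty
  truth set is an error (a recovery rate over nothing is meaningless);
  `min_entities` below 1 is rejected.

## Known limitations

The weights are the published, manually curated values — this package
does not refit them, and offers no training facility beyond editing the
YAML configuration. Scoring consumes the caller's annotations (ORF, exon
boundary, homology, flags) as given and cannot rescue mis-annotated
input. The artifact-list builder is only as good as the cohort behind the
manifest: few entities, or entities that share a platform-specific
artifact spectrum, weaken the recurrence signal. No multi-caller support
beyond the alias mapping is attempted.
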