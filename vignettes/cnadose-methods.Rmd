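---
title: "Methods: copy-number segmentation, calling and dosage integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number segmentation, calling and dosage integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnadose)
```

## The data model

Everything in the package moves through three tabular objects:

* a **clone map** — one row per probe (BAC clone for copy number, cDNA
  clone for expression) with chromosome, arm, and 0-based half-open
  start/end coordinates; the midpoint is the single positional anchor
  used for all distance computations (symmetric and deterministic, since
  a "within 1 Mb" rule needs an anchor);
* a **ratio table** — probes × samples log2 ratios with `NA` for missing
  values, the same shape for aCGH (log2 tumour/reference) and expression
  (log2 relative abundance);
* per-stage result tibbles (segments, calls, events, correlation
  records, candidates) that chain with the pipe and have `tidy()` /
  `glance()` views.

All files are TSV with a header and `NA` as the missing token; the only
exception is the BED export of region catalogues, which is already
0-based half-open by definition. Any 1-based coordinate never enters the
package; an export in 1-based convention would be explicitly suffixed.

## Segmentation

`segment_cna()` treats chromosomes independently (no cross-chromosome
arcs; arms are *not* segmented separately — arm information is used only
by arm-level calling). Per sample and chromosome:

1. Missing probes are set aside; index arithmetic runs on the observed
   sequence and missing probes are restored afterwards. This keeps the
   change-point test well defined.
2. **Outlier shrinking** (`smooth_outliers()`): a probe deviating from
   the median of its ±k neighbours (excluding itself, k = 2) by more
   than z = 4 robust SDs (MAD × 1.4826 of the chromosome) is shrunk to
   that median ± z·SD for testing only. Single-probe spikes are almost
   always measurement artefacts on BAC arrays; shrinking prevents them
   from attracting spurious change points while the reported matrix
   keeps the original values.
3. **Circular binary segmentation** (`cbs_segment()`): among all arcs
   [i, j) of the circularized sequence, find the one maximizing the
   absolute two-sample t statistic between in-arc and out-of-arc values;
   assess it against `n_perm = 1000` permutations of the sequence
   (p = plain proportion of shuffled maxima ≥ observed; a (k+1)/(B+1)
   estimator is available via `pseudo_count`); split and recurse while
   p ≤ α = 0.01. Adjacent segments closer than `merge_tol` = 0.05 log2
   units are merged. All parameters are configurable.

**Statistic choice.** The scan uses the *pooled-variance* two-sample t.
An unequal-variance (Welch) form was tried first and rejected: with
per-group variance estimates, an arc of one or two mildly extreme probes
has a near-zero standard error and |t| of the order of 30, so the
maximal statistic is essentially always a short noise arc — in the
observed sequence and in every permutation alike — and genuine
breakpoints (|t| ≈ 20 at the scale below) are swamped; the procedure
loses essentially all power. Pooling scales every arc by the common
noise SD and restores the intended behaviour. The permutation reference
keeps the test exact under either statistic, so this is purely a power
repair.

**Numerical conventions.** Sums of squares are clamped at zero against
cancellation; a zero pooled SD yields t = ∞ when the means differ (the
noiseless-step case) and 0 otherwise; ties in |t| are broken by smaller
arc start, then shorter arc; each partition of the circle is enumerated
exactly once (arcs ending at the sequence end are complements of arcs
starting at 0 and are skipped), so floating-point noise cannot break
ties between two encodings of the same split. Sequences shorter than 4
probes are returned as a single segment, and `n_perm` below 100 is
refused.

**Determinism and early stopping.** Every significance test is seeded
from the master seed plus its genomic context (sample, chromosome, piece
offset and length) through a hash, and the permutation generator is
self-contained (it neither reads nor advances R's global RNG). Because
each test's reference distribution depends only on its own piece, a test
may stop early once the exceedance count already forces p > α without
affecting any other test; this is what makes segmenting a 62 × 2300
matrix cheap, since most chromosome pieces are null. It also gives the
monotonicity property that a smaller α can only prune the recursion
tree, never grow it.

**Smoothed output.** Probes take their segment mean; flagged outlier
probes keep their originally observed ratio; probes missing inside a
segment's span are imputed with the segment mean (`impute_missing()`,
idempotent); probes outside any segment — beyond the outermost observed
probe of a chromosome, or on an entirely missing chromosome — stay
missing and are listed.

## Calling

Calls are made on **raw** per-clone ratios; smoothed values are reserved
for the integration analysis (a flag on the pipeline allows calling on
smoothed values for sensitivity analysis). Thresholds are strict
inequalities with boundary values neutral; the gain/loss cut (±0.225 by
default) is `sd_multiplier` (3) times the mean per-profile SD of
normal-vs-normal reference hybridizations (`derive_thresholds()`), while
the amplification (0.8) and homozygous-deletion (−0.7) cuts are fixed
conventions set independently of array noise. For frequency summaries,
amp counts within gain and homdel within loss (amp > gain cut by
construction); the event catalogue reports amp runs both as their own
events and inside the enclosing gain runs. Recurrent regions are the
deterministic maximal intervals with a constant carrier set — a
transparent substitute for significance-based recurrence callers, which
are out of scope here.

## Integration

`map_expression_to_bac()` computes, for every expression clone, the
Pearson correlation (pairwise-complete, at least `min_n` = 10 shared
samples) against every BAC whose midpoint lies within 1 Mb, and keeps
the best; ties break by distance, then clone id. Selection happens
**once**, before permutation: shuffled replicates recompute r for the
already-chosen pairs. The alternative — re-selecting the best BAC under
every shuffle, which is more conservative because the null then includes
the selection maximum — is available via `reselect = TRUE`; the default
follows the view that the mapping is part of the study design, not of
the test statistic.

All records within one permutation replicate share the same label
shuffle. This preserves the dependence between clones (neighbouring
clones see the same copy-number segments), which is what makes the
Benjamini–Hochberg adjustment of the resulting p-values an honest FDR
control at the set level. p = 0 is reported as the plain proportion
permits; with B = 1000 the smallest non-zero p is 0.001, which is why
the selection cut operates on q rather than p. `bh_adjust()` implements
the step-up rule directly (sort, cummin of m·p/j from the top, clip at
1, restore order) and is cross-checked in the tests against both a
literal brute-force transcription and `stats::p.adjust`.

The binned diagonal analysis divides every chromosome arm into 20-Mb
bins and averages all pairwise expression × copy-number correlations for
every bin pair; a *cis* dosage effect appears as a positive diagonal
median against an off-diagonal median near zero. Probe rows with missing
entries are mean-imputed before this computation (a bin-mean is an
average over hundreds of pairs; per-pair complete-observation handling
would cost far more than the imputation bias is worth here). Arms
shorter than one bin form a single bin.

## Candidate nomination

`nominate_candidates()` applies the conjunction: passed the correlation
selection (r > 0.29, q < 0.01); |gains − losses| ≥ 5 at the mapped BAC
(counted from raw-ratio calls, per clone — the filter operates on the
clone list, not on gene roll-ups); and differential-expression direction
concordant with the imbalance sign. Discordant records (e.g. gained but
down-regulated) are excluded and reported. A gene is counted once, its
representative clone being the one with the largest r; genes whose
clones land in both classes are reported as conflicts rather than
collapsed. Clustering of candidate expression uses 1 − Pearson
correlation with average linkage (the classic Cluster/TreeView setting,
both configurable); with a single candidate clone, sample distances fall
back to Euclidean on that one profile, since a correlation over one
observation is undefined.

## The synthetic-data generator

The generator is the package's study-conditions definition, not a test
dial. It emulates:

* a BAC genome of 23 chromosomes × 100 clones at 1.5 Mb spacing
  (~2300 clones), arms split at a fixed centromere fraction (0.4) —
  real cytoband positions are deliberately out of scope for a synthetic
  genome;
* 62 tumour samples shared between copy number and expression;
* per-clone i.i.d. Gaussian noise. The paper trail for such arrays
  reports thresholds, not noise SDs, so the default SD (0.075 log2) is
  chosen so that the 3×SD rule lands on the conventional 0.225 cut —
  a modelling choice, stated as such;
* a catalogue of planted events echoing the gastric-cancer aberration
  spectrum (broad 5p/8q/20q-style gains and 4q/18q/21q-style losses at
  30–50% recurrence, focal 8q/20q amplicons at 10–17%, a focal 9p
  deletion), carriers drawn without replacement per event;
* background per-(sample, arm) gains and losses (probability 0.15 each,
  shift ±0.45 log2 ≈ a single-copy change at realistic tumour-cell
  content). These give *every* genomic region sample-to-sample
  copy-number variance — the substrate of the genome-wide diagonal
  dosage signal observed in real tumour cohorts, which focal events
  alone cannot produce;
* dosage-driven expression for a quarter of clones by default (matching
  the ~24% correlated fraction reported for matched aCGH/expression
  gastric-cancer data): expression = `dosage_effect` × true local
  copy-number value + noise, the source being the nearest BAC within
  1 Mb. With the default noise levels (expression SD 0.3) and the
  background-event variance, the implied true correlation for a dosage
  clone is ≈ 0.6 by the variance-component formula
  r = v/√((v+σ²ₑ)(v+σ²ₐ)), which the tests verify by simulation;
* DE labels `up`/`down` for dosage clones under recurrently directional
  regions (|mean shift| > 0.05 log2), plus 10% copy-number-independent
  DE clones; an optional admixture shrink compresses all shifts.

A truth channel (noiseless mean matrix, implied calls, breakpoints,
dosage flags, DE labels) flows out of every simulation, so parameter
recovery is assertable exactly.

What the generator does **not** emulate: dye bias, spatial artefacts,
GC waviness, probe-specific variance, correlated noise, and any real
clinical covariate structure (clinical labels are arbitrary grouping
factors). Tests passing on this generator therefore validate the
statistical machinery under its stated assumptions; they do not certify
performance on arrays whose artefacts violate them.

## Problem sizes and reproducibility

The test-suite and acceptance script use: threshold recovery on
3 × 2300-clone reference profiles; breakpoint recovery on 50 seeded
200-clone sequences (shifts ±0.5, noise SD 0.15, B = 1000) plus 50 flat
nulls; null calibration on 500 independent clone pairs at n = 62 with
B = 1000; FDR/sensitivity on 20 replicates of a 500-clone mixture with
10% dosage clones; the diagonal contrast on a 10-chromosome coupled and
decoupled pair; and a full-scale end-to-end run (62 × 2300 aCGH, 3000
expression clones, B = 1000) executed twice to confirm byte-identical
TSV outputs. Sizes are chosen to exercise each property at the scale it
is stated for while keeping a desk-scale runtime.

All randomness flows from explicit seeds: simulation stages derive
sub-seeds from the configuration seed and the stage name; segmentation
tests derive theirs from the master seed and the genomic context;
permutation p-values from the supplied seed. Identical inputs and seeds
give identical outputs to the byte, which is what the pipeline's stage
cache keys on.

## Known limitations

* Calls assume a roughly diploid baseline; ploidy and purity estimation
  are out of scope (an admixture shrink exists in the generator, not an
  inverse correction in the caller).
* Recurrence is catalogued deterministically, without a significance
  model for recurrent regions.
* Records stay at clone level; gene-level aggregation is a reporting
  roll-up only.
* The package performs no genome-build liftover: user-supplied maps for
  both platforms must share one assembly.
* Trans (off-diagonal) association discovery is intentionally absent.
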