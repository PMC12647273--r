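---
title: "Methods: screening lesion-suppressive lncRNAs with astrolnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening lesion-suppressive lncRNAs with astrolnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astrolnc)
```

## The screening model

`astrolnc` operationalizes a simple biological hypothesis: in a graded
lesion design, transcripts that *suppress* the lesion should be expressed
at high levels where the lesion is weak or absent and at low levels where
it is severe. The pipeline turns that hypothesis into five concrete,
individually testable stages. This vignette explains the statistical
choices in each stage, the parameters worth tuning, what the synthetic
generator does and does not emulate, and the known limitations.

The design assumed throughout is eight microarray samples: two replicates
at each of four lesion grades, encoded as an ordinal severity covariate
(control = 0, weak = 1, moderate = 2, severe = 3, `severity_of()`).

## Preprocessing

Four filters are applied in a fixed order; each is a pure function on the
probe set, and the pipeline records a telescoping report of counts.

* **Confidence** (`min_conf = 2`): a probe survives if *any* sample reaches
  the platform's top quantification-confidence score. The rule is a
  disjunction by construction — one reliable measurement justifies keeping
  the probe.
* **Biotype** (`keep = "lncRNA"`): exact, case-insensitive label match.
  Unknown labels are removed and summarized rather than silently passed.
* **Replicate outliers** (`k_sd = 1`, `require = "all"`): for every probe
  and every within-condition replicate pair, the absolute intensity
  difference is computed; pooling the differences across probes gives a
  per-comparison band `mean ± k_sd · sd`. With two samples per condition
  there is exactly one comparison per condition; the stated rule —
  disagreement across "all replicates" — is read as the *all* quantifier
  over comparisons, with `require = "any"` preserving the stricter
  alternative. Two numerical guards matter: a degenerate comparison with
  `sd = 0` flags nothing (otherwise toy data with identical replicates
  would lose every probe), and a condition with one sample is skipped with
  a warning.
* **Low expression** (`threshold = 100`, `mode = "any"`): the default is
  the literal reading — a probe is removed if *any* sample falls strictly
  below 100. Intensities exactly at 100 survive, and `mode = "all"`
  implements the laxer interpretation. Note the tension this creates for
  genuinely suppressed transcripts: their severe-sample intensities must
  still clear the floor, which constrains how strong a down-regulation the
  assay can report.

Z-score standardization then centers and scales each probe row:
$x_n = (I_n - \bar I)/\sigma$, with the population convention (divisor
$N$) for $\sigma$ since the source formula leaves it unqualified. The
choice is exposed (`sd_divisor`) and is provably cosmetic: switching to
$N-1$ rescales every row by the same constant and changes no downstream
ranking (asserted in the tests). Zero-variance rows cannot be standardized
and are removed with a message — never emitted as `NaN`.

## PCA selection

PCA is taken over probes as observations and samples as variables: eight
loadings per component (one per sample) and one score per probe, the only
orientation consistent with reporting per-sample loading bars and a
per-lncRNA score ranking. Because rows are already Z-scored, no further
centering is applied across samples; `run_pca()` eigendecomposes the
sample-by-sample second-moment matrix of the standardized rows. With all
components kept, `scores %*% loadings` reconstructs the input exactly
(the loading vectors are an orthonormal basis), which the tests assert to
1e-8.

The lesion-discriminating component is *selected*, not hard-coded: the
component whose loading vector has the largest absolute Spearman
correlation with severity wins (ties resolve to the lowest index, logged),
and its sign is fixed so that low-severity samples load positively. Under
that convention, probes suppressed by the lesion receive high scores.
Automating the choice keeps synthetic runs valid when variance ordering
differs from the original data, and recovers the manual "first component"
choice whenever its criteria hold. `select_top()` ranks probes by oriented
score with deterministic lexicographic tie-breaking.

Hierarchical clustering for display uses Euclidean distance and average
linkage (configurable); the linkage was not specified in the source
procedure, and average linkage is the conventional default for expression
heatmaps. One caveat discovered while validating the generator: with a
*linear* severity gradient the gaps between adjacent condition pairs are
equal, so which conditions merge first in the sample dendrogram is
noise-driven; the tests therefore assert replicate-pair adjacency (a
design-true invariant) rather than a particular two-block split.

## Consensus motifs

`column_consensus()` implements the positional-frequency rule: per
alignment column, count each nucleotide with T and U pooled; a unique
modal base at frequency ≥ `min_frac` becomes the consensus symbol; two or
more bases tying at the maximum display `+` — counted as *no* consensus
base even when above threshold; anything else is no consensus. The
threshold is inclusive at exactly `min_frac` (float-safe). Gaps count in
the denominator by default, matching consensus percentages computed over
all alignment rows; `count_gaps = FALSE` gives the occupancy-normalized
variant. `extract_runs()` then reports maximal runs of ≥ `min_run_length`
consensus bases, left to right, in 0-based half-open column coordinates,
with sequences rendered in the RNA alphabet.

The "complementary sequence" of a common sequence is its *reverse*
complement — every published sequence/complement pair satisfies the
reverse-complement relation, not the plain complement — and
`reverse_complement()` is an involution that preserves the input alphabet
(RNA or DNA).

Alignment construction itself is an external input: the original analysis
used Clustal Omega, and `read_alignment()` accepts aligned FASTA or
Clustal files. No aligner is implemented.

## Complement matching

For 11–15 nt motifs at ≥ 85% identity, at most two mismatches are allowed
and gapped alignment is meaningless, so a heuristic seed-based search is
replaced by an exhaustive ungapped Hamming scan (`scan_database()`, backed
by `Biostrings::vmatchPattern`): every full-length window of every
transcript is scored, identity = (L − mismatches)/L with the motif length
as denominator, and only the given (sense) strand is scanned, matching the
requirement that the match direction agree with the searched sequence.
The scan is deliberately *more* sensitive than a seed-based search at the
same threshold — a documented deviation in mechanism, not in criteria.
Windows overhanging transcript ends are not scored, and transcripts
shorter than the motif are skipped. Hits retain transcript detail;
summaries count genes, since one gene may have many transcripts.

Two post-filters mirror the original curation: descriptions containing
"PREDICTED" or "cDNA" are excluded (case-sensitive substring,
configurable), and gene symbols are intersected with a cortex-expression
whitelist (case-insensitive). The two filters commute, which the tests
assert on random hit sets.

## Enrichment

Contingency counts follow per-category annotation-total semantics: within
a category, PT is the number of background genes with at least one
annotation, PH those annotated to the term, LT the list genes with at
least one annotation, LH the list genes on the term. These semantics were
adopted because they reproduce every published fold value exactly from its
published integer counts (the prose definitions accompanying those tables
are circular). Fold enrichment is the exact ratio `(LH/LT)/(PH/PT)`.

The p-value is the one-sided hypergeometric upper tail; with
`ease = TRUE` (default) the observed hit count is first reduced by one,
floored at zero — the conservative EASE-score variant, never smaller than
the plain tail. FDR is Benjamini–Hochberg, computed within each category
(each category is one multiple-testing family, matching how the published
tables group their rows); the variant name is recorded in output headers
since the original analysis does not state which FDR procedure its server
applied. The significance filter keeps fold ≥ 2.0 *and* FDR ≤ 0.05, both
bounds inclusive, sorted by fold descending.

Published FDR values depended on a server-side annotation catalog that is
not reproduced here; the package reproduces the *procedure*, and its
value-level checks use the fold statistics, which are catalog-independent.

## The synthetic generator

`simulate_study()` emulates the eight-sample design with planted ground
truth at every stage:

* **Expression** (`simulate_expression`): suppressive-probe mean intensity
  is linear in severity, `base_intensity * (1 - delta * severity)` with
  `delta = effect_size * noise_sd`, so `effect_size` measures the per-step
  signal in noise units; all intensities carry multiplicative log-normal
  noise `exp(N(0, noise_sd))`. Defaults — `base_intensity = 20000`,
  `noise_sd = 0.25`, `effect_size = 1.25` (a 5-sigma step) — were chosen
  once so that severe-sample means (~1250) stay comfortably above the
  intensity-100 filter, as genuinely detected transcripts must. The linear
  (rather than geometric) decay matters: it places the weak-lesion samples
  *above* the row mean, producing the positive weak/control loadings the
  selection convention expects; a geometric decay is convex and pushes the
  weak samples below the mean. Disjoint fractions of background probes are
  planted to fail each of the four filters, so every filter's removal set
  is checkable. The raw-intensity distribution of the original arrays is
  not public; log-normal is a stand-in, not an inference.
* **Sequences** (`simulate_probe_sequences`): equal-length gapless
  sequences — an implicit trivial alignment — with each planted motif
  written into every suppressive probe at a fixed column, under an
  optional per-base corruption probability. The default planted motifs are
  two of the published common sequences (12 and 11 nt), exercising
  realistic motif lengths.
* **Transcript database** (`simulate_mrna_db`): per motif, target
  transcripts embed the motif's reverse complement (a configurable
  fraction with one mismatch, still above the 0.85 identity threshold);
  decoys are verified clean by exhaustive scan at generation time and
  resampled until no decoy matches any complement. A fraction of decoy
  headers are marked "PREDICTED"/"cDNA"; the whitelist covers a
  configurable fraction of target genes; the annotation catalog plants one
  term per motif (its target genes) among random background terms of 5–15
  genes.

All randomness flows from explicit seeds (sub-seeds derived from one
master seed), and regeneration with the same seed is byte-identical,
asserted by file hashing.

**Consensus threshold on synthetic alignments.** The 10% column threshold
presumes gapped alignments in which most columns have low occupancy, so
few columns reach 10% of *all rows*. A gapless synthetic alignment has
full occupancy everywhere: any column's modal base is at ≥ 25% by
pigeonhole, and the 10% rule would return the entire alignment as one run.
`run_synthetic_study()` therefore uses `min_frac = 0.90` — near-unanimity,
the faithful analogue of the original rule on full-occupancy columns —
while `run_pipeline()` keeps 0.10 as its default for externally aligned
input.

**What passing tests show, and what they do not.** The generator plants
clean block structure: motifs at identical columns, i.i.d. background
sequence, decoys certified clean, annotation terms that exactly cover
target gene sets. Passing the planted-recovery tests therefore
demonstrates that the *machinery* is correct — filters remove exactly what
they should, PCA ranks a 5-sigma monotone signal, consensus extraction
returns planted runs, scanning finds all embedded complements, enrichment
flags exactly the planted terms. It does not demonstrate performance on
real arrays, where probe effects correlate, alignments contain gaps and
paralogous near-motifs, and annotation terms overlap heavily.

## Problem sizes and runtime choices

The test suite and acceptance script run the full pipeline at the study
scale (1000 probes, 50 suppressive, 8 samples, ~330 transcripts), which
completes in a few seconds; unit tests use smaller instances (toy 8-column
matrices, 200–500 probes). Oracle-equivalence checks are exhaustive where
cheap — every hypergeometric contingency with PT ≤ 60, 200 random
consensus-symbol lists, 50 random scan instances — and the 20-seed null
calibration of the enrichment stage uses 800-gene backgrounds. At a
5-sigma planted effect the top-50 recovery is 90–98% across seeds (the
per-row standardization bounds oriented scores at $\sqrt 8$, so a few
background probes can always intrude by chance); the fixed-seed
end-to-end check asserts the ≥ 90% recovery the design targets, and the
scaled-down 500-probe configuration freezes its observed 84% rather than
pretending the small instance performs like the full one.

## Known limitations

* Counts from the original dataset (16,251 → 12,135 probes; 470 → 415
  mRNAs) are not reproducible without the deposited accession and the
  RefSeq snapshot its search ran against; the pipeline instead logs the
  equivalent funnel so a user with the data can compare.
* The replicate-outlier rule's original replicate structure ("all three
  replicates" in an eight-sample, two-per-condition design) is ambiguous;
  both quantifier readings are implemented, neither asserted as original.
* No gapped or scored alignment, no RNA secondary-structure or binding
  thermodynamics, no annotation-catalog reproduction, no GEO download.
* The component selector assumes severity varies across samples; constant
  severity is an error by design.
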