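---
title: "Diagnostic characters in whole-plastome alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic characters in whole-plastome alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcscan)
library(dplyr)
```

## The problem

Super-barcoding identifies plant species from complete chloroplast genome
(plastome) sequences rather than short barcode loci. Within a genus
alignment, a **molecular diagnostic character (MDC)** — a "pure diagnostic
site" — is an alignment column at which every specimen of a query species
carries a character state that no specimen of any other species in the
genus carries. Species without a single MDC anywhere in the plastome
cannot be identified by this method at all, and the share of such species
varies enormously between genera. `mdcscan` implements the full analysis:
plastome preprocessing, the column scan, event classification, per-genus
diversity summaries, and the statistical models that relate those
summaries to sampling effort, sequence identity and habitat.

## The diagnostic-site rule

Each alignment cell denotes a *state set*: a subset of `{A, C, G, T, -}`.
IUPAC ambiguity codes expand to their canonical sets (`R = {A,G}` and so
on), `-` is the literal gap state, and `N`/`?` are missing data under the
default policy. A column is diagnostic for the query species when:

1. every non-missing query specimen carries the *identical* state set
   (so `{R, R}` is monomorphic but `{R, A}` is polymorphic, the strictest
   reading of the query-polymorphism exclusion);
2. that set is disjoint from the union of all non-missing reference state
   sets; and
3. at least one non-missing specimen exists on each side (columns missing
   on a whole side are skipped and counted, not errors).

Internally state sets are 5-bit masks, so the scan is a handful of
vectorised min/max/bit-or operations per species rather than a per-cell
loop; the test suite pins the scanner to a deliberately naive per-column
oracle on hundreds of random alignments.

### Missing-data policy

The default (`missing = "ignore"`) lets `N`/`?` specimens contribute
nothing at a column: one low-quality genome cannot erase another species'
diagnostic characters. The alternative `missing = "strict"` expands `N`
to `{A, C, G, T}`, which is the conservative reading (an unknown base
might be anything) but makes a single all-`N` region of one reference
genome delete every site in its span. Both policies are exposed because
diagnostic-character software differs here and the choice is consequential;
the package treats "ignore" as the analysis default. Terminal gap runs are
ordinary gap states by default, with `mask_terminal_gaps = TRUE` available
because leading/trailing gaps are often alignment end-trim artifacts
rather than biological deletions.

## Variation events

Maximal runs of consecutive diagnostic columns are merged into **events**:
single-column events keep their site category (substitution, deletion,
insertion, or mixed when gap and nucleotide states co-occur across the two
sides), and runs of two or more columns become `multi_substitution`,
`multi_deletion`, `multi_insertion`, or `multi_mixed` when the run is
heterogeneous or contains a mixed site. The MDC *count* of a species is
its number of diagnostic columns — sites, not events — matching the
magnitudes (hundreds to thousands per species) that whole-plastome studies
report; events are a derived layer and both are in the output tables.
Event lengths always sum to the site count, and events are maximal (the
flanking columns are never diagnostic), which the suite checks as an
invariant.

## Inverted-repeat handling

Plastomes are quadripartite: LSC–IRb–SSC–IRa, with IRa the reverse
complement of IRb. One IR copy is removed before cross-species comparison
so repeat-region mutations are not counted twice. Detection is a
seed-and-extend scan of the sequence against its own reverse complement:
a pair of inverted arms lies on a single anti-diagonal (position *i* of
one arm pairs with position *D − i* of the other), exact 16-mer seeds
nominate diagonals, and the longest matching run on each diagonal is
extended outward. A mismatch is crossed only when the next 8 positions all
match — scattered mismatches inside a near-identical repeat are absorbed,
while chance complementarity in flanking sequence (one base in four
matches by chance) is not — and the total mismatch fraction must stay
within `max_mismatch_frac` (default 0.02). Defaults: `min_ir_length`
1000 bp (real plastome IRs are 20–25 kb; validation toys scale down and
pass a smaller threshold explicitly). Ties between equally long pairs go
to the smallest start coordinate.

For `circular = TRUE` the scan runs on the doubled sequence and the
annotation is reported on a rotated frame with canonical LSC–IRb–SSC–IRa
order (the rotation is recorded in `offset`); detection is then rotation
invariant. Linear inputs are annotated in input order, with any residue
after IRa reported as an `lsc_tail` region. By default exactly one copy
(IRa) is removed — observed per-genus alignment lengths in whole-plastome
work match single-copy removal — and `remove = "both"` is available.
SSC orientation is not normalised.

A subtlety for validation: the flanking base of a planted repeat matches
its partner by chance one time in four, and no detector can distinguish
such a base from repeat. The fixture generator therefore *seals* its toy
genomes (forces the flanking bases non-complementary), making the planted
arm length the unique correct answer; exactness tests are run on sealed
toys.

## Identity and consensus

Mean pairwise identity is averaged over all unordered *specimen* pairs of
the genus alignment (the alignment is the unit of analysis, not species
means). Per pair: columns gapped in both sequences are not compared,
`N`/`?` columns are never compared, and a gap against a residue counts as
a mismatch by default (`gap_mode = "exclude"` drops gapped columns
instead, for sensitivity analysis — published identity values rarely state
their convention).

The consensus takes, per column, the most frequent symbol among
`A, C, G, T, -` (ambiguity codes and missing symbols do not vote), with
ties broken by the fixed order `A < C < G < T < -`. Plurality rather than
a 50% threshold is used because the consensus feeds realignment and tree
building downstream and must be fully resolved. Gap-majority columns are
dropped from the emitted sequence; all-missing columns emit `N` with
support 0.

## Genus summaries and the statistical layer

`summarize_genus()` aggregates per-species profiles into the master row:
sum/mean/min/max of MDC sites, the per-length normalisation
`mdc_mean / alignment_columns × 1e4` (MDCs per 10 kb of alignment — the
scaling convention is documented here precisely because summary tables in
the literature leave it implicit), zero-MDC share, representativeness
(analysed / described species × 100), and habitat. Species are binned as
0, 1–10, 11–100, > 100 MDCs; only the outer edges of these bins are
conventional in the literature, and 11–100 is the exhaustive middle.
Genera need at least three species (the study inclusion rule), and
densely sampled species can be capped (default 50 specimens, seeded
subsampling).

Count-type summaries are heavily non-normal in real data, so the layer
screens with Shapiro–Wilk plus adjusted Fisher–Pearson skewness
(`e1071::skewness`, type 2), then fits log-link Poisson GLMs of each
summary on a log-scaled predictor. Three conventions had to be fixed:

* **Log base.** "Log-scaled predictor" does not pin a base; base 10 is
  the default and the slope is also reported on the natural-log scale
  (`slope_ln = slope / ln 10`), so either convention can be compared.
* **Non-integer counts.** Mean-type summaries are not integers; the
  default rounds to the nearest integer before the Poisson fit, with
  `round = FALSE` as the strict escape hatch.
* **Wald statistic.** Reported as `(slope / se)²` against χ²(1), the
  form conventional in the software that popularised these summaries;
  the likelihood-ratio χ² against the intercept-only model is reported
  alongside.

Habitat comparisons use the tie-corrected Kruskal–Wallis test and Dunn's
pairwise z tests. No installed package provides Dunn's test, so the
standard rank-sum z with tie correction is implemented directly, with
Bonferroni adjustment over the number of pairs (capped at 1) — an
adjustment is clearly in use when published pairwise p values reach
exactly 1.000. Groups with fewer than two observations are excluded with
a warning.

## The synthetic-data generator

`generate_genus()` emulates the *structure* of a per-genus plastome
alignment with exactly recoverable ground truth: a shared random backbone
(default 10 kb, a desk-scale stand-in for 113–145 kb alignments;
configurable up to plastome scale), multiple specimens per species,
planted species-specific events, specimen-private polymorphism, injected
`N` runs (geometric length, mean 50, emulating assembly gaps), and
optional twin species — pairs forced to identical sequence sets, which
reproduces by construction the zero-MDC phenomenon seen in recently
diverged or polyploid genera.

Planted kinds map to alignment-space patterns chosen so that each event
is diagnostic for exactly its focal species and nothing else:
substitutions give the focal species an alternative base; deletions gap
it; insertions gap *every other* species (the pipeline consumes aligned
input, so insertions exist only as gap columns in non-focal rows — no
realignment is simulated, which keeps truth exact); mixed events give the
focal species an alternative base while two non-twin reference species
are gapped and at least two others keep the backbone. That last
requirement is why mixed events need five or more species: with fewer, a
planted mixed column unavoidably either degenerates into an insertion or
leaks a diagnostic gap state into a reference species. For the same
reason events are required to be non-overlapping with at least one spacer
column *across* species, twins may not carry planted events, and twins
are copied after noise injection.

What the generator does **not** emulate: phylogenetically realistic
substitution processes (no GTR, no rate heterogeneity, no shared
ancestry beyond the backbone), alignment error, codon structure, or the
heavy-tailed between-genus distribution of MDC counts seen in real
cohorts. Passing the recovery tests therefore demonstrates that the
scanner and summaries are *correct on their own definitions*, not that
real plastome alignments are this clean; on real data, alignment quality
and the missing-data policy dominate.

`generate_cohort()` complements this at the cohort level: per-genus
covariates drawn from study-like ranges (3–41 species per genus, identity
96–100%) and MDC sums drawn from a known Poisson log-link model (default
intercept 8.0, i.e. mean sums in the low thousands, matching
whole-plastome magnitudes; default species-count slope 0.028, a
plausible published magnitude), so that `poisson_glm()` can be checked
for parameter recovery and test size against known truth.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in machine-readable
  tables; printed reports are 1-based inclusive.
* Input is case-insensitive and normalised to uppercase; `?` is a
  synonym of `N`.
* All-missing columns on either side of a species partition are skipped
  and counted in an attribute, not raised as errors.
* Constant vectors are rejected by the normality gate (Shapiro–Wilk is
  undefined); constant counts fit as a zero slope with LR χ² ≈ 0.
* Randomised steps (subsampling, simulation) take explicit integer seeds
  and restore RNG state on exit; rerunning a pipeline configuration is
  byte-identical, which the suite asserts over full output bundles.

## Validation problem sizes

The suite validates the scanner against a literal per-column oracle on
500 random alignments (up to 6 species × 4 specimens × 200 columns),
planted-truth recovery on 100 random clean configurations plus 15 noisy
ones (300–800 columns), statistical recovery at n = 500 observations and
96 genera with 200-replicate null calibrations, and IR handling on
3.6 kb sealed toys with 400 bp arms. These sizes were chosen to exercise
every code path and boundary (ties, twins, all-missing columns, masked
planted sites) while keeping the whole suite fast enough to run on every
change; the operations themselves are vectorised and run comfortably at
plastome scale (the 10 kb to 130 kb range of the generator's
`backbone_length`).

## Known limitations

* The pipeline consumes *aligned* FASTA; alignment itself (e.g. MAFFT)
  and tree building (e.g. IQ-TREE on the exported consensus sequences)
  are deliberate external hand-off points.
* MDC calling is alignment-dependent: a different alignment of the same
  sequences yields different columns, and no attempt is made to make
  calls alignment-invariant.
* The mixed category conflates several biological situations (substitution
  over a gap, gap over a substitution); the eight-type scheme follows the
  standard classification rather than attempting finer resolution.
* Dunn's test uses the normal approximation; very small groups (a handful
  of genera per habitat) give coarse p values.
* IR detection assumes a single dominant repeat pair; plastomes with
  aberrant architectures (IR loss, triplications) return the longest pair
  or no-IR, and SSC orientation is left as-is.
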