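# mdcscan

Molecular diagnostic characters (MDCs) from whole-plastome alignments,
for DNA super-barcoding studies.

## What it does

Species identification from complete chloroplast genomes stands or falls
with **pure diagnostic sites**: alignment columns at which every specimen
of a query species carries a state that no specimen of any congener
carries. Formally, with query state sets `Q_1 … Q_m` (one per specimen,
IUPAC codes expanded, `-` a literal state, `N`/`?` missing) and reference
union `R`, a column is diagnostic iff

```
Q_1 = Q_2 = … = Q_m = Q,   Q ∩ R = ∅
```

with query-polymorphic columns excluded. `mdcscan` implements, for
per-genus plastome alignments:

* **Plastome prep** — detection of the quadripartite LSC–IRb–SSC–IRa
  structure by a seed-and-extend inverted-repeat scan, and removal of the
  duplicated IR copy before alignment.
* **MDC scan** — the diagnostic-site rule above with configurable
  IUPAC/gap/missing semantics; maximal runs of consecutive sites merged
  into eight event types (substitution / deletion / insertion / mixed,
  and their `multi_` forms).
* **Identity & consensus** — mean pairwise identity over specimen pairs
  and plurality consensus sequences per genus.
* **Genus summaries** — MDC sum/mean/min/max, MDCs per 10 kb of alignment,
  zero-MDC share, representativeness, MDC bins (0, 1–10, 11–100, >100).
* **Statistics** — Shapiro–Wilk + skewness screening, log-link Poisson
  GLMs of count summaries on log10-scaled predictors (Wald and LR χ²),
  and Kruskal–Wallis with Dunn's Bonferroni-adjusted pairwise tests for
  habitat comparisons.
* **Synthetic data** — genus alignments with planted, exactly recoverable
  events (plus twin species that are zero-MDC by construction) and
  cohort tables drawn from known Poisson models, so every stage is
  testable without downloads.

Everything is tidyverse-shaped: alignments and results are tibbles,
fitted models have `tidy()`/`glance()` methods, and `autoplot()`/`plot_*`
give quick figures.

## Worked example

Simulate a four-species genus with two twin species, a substitution, a
4 bp deletion and a 2 bp insertion planted, then profile it:

```r
library(mdcscan)
library(dplyr)

cfg <- genus_sim_config(4, 2, 5000, planted = tibble::tibble(
  species = c(1, 1, 2), start = c(120, 840, 2300), length = c(1, 4, 2),
  kind = c("substitution", "deletion", "insertion")),
  twin_species = cbind(3, 4), genus = "Stipella", seed = 42)
g <- generate_genus(cfg)

species_mdc_profile(g$alignment, "Stipella_sp1")
#> MDC profile for Stipella_sp1
#>   diagnostic sites: 5  in 2 events
#>   sites by event type: substitution=1, multi_deletion=4

mean_pairwise_identity(g$alignment)
#> Mean pairwise identity for Stipella : 99.94% over 28 pairs

tab <- mdc_table(g$alignment)
summarize_genus(tab, mean_pairwise_identity(g$alignment), 5000,
  metadata = list(family = "Poaceae", habitat = "open",
                  described_species = 8))
#>   mdc_sum mdc_mean mdc_min mdc_max mdc_per_length_e4 zero_mdc_share_pct ...
#>         7     1.75       0       5               3.5                 50
```

The planted events come back exactly (5 sites for `sp1`: one
substitution plus one 4-column `multi_deletion`; 2 for `sp2`), and the
twin pair `sp3`/`sp4` — identical sequence sets — has zero MDCs and a
50% zero-MDC share, the pattern that makes some genera unidentifiable by
super-barcoding.

The statistical layer on a simulated 96-genus cohort with a known
species-count effect:

```r
co <- generate_cohort(n_genera = 96, slope_species = 0.028, seed = 7)
poisson_glm(co$table, mdc_sum, n_species)
#> Poisson GLM: mdc_sum ~ log 10 ( n_species ), n = 96
#>   slope = 0.02484 +/- 0.0071 (SE), Wald chi2 = 12.16, p = 0.000488
#>   log-likelihood = -529.6975, LR chi2 = 12.19, p = 0.000482
```

The planted slope 0.028 is recovered well within one standard error.

Full runs over many genera go through `run_pipeline(manifest, metadata,
out_dir = ...)`, which writes per-genus MDC/event tables, consensus
FASTA, the master summary TSV, a stats JSON and a run log, and is
byte-identical under a fixed seed. A thin command-line wrapper is
included at `inst/cli/mdcscan.R`.

## Layout

* `R/` — implementation; `tests/testthat/` — unit, property and
  acceptance suites (scanner vs brute-force oracle, planted-truth
  recovery, IRLS cross-checks, null-calibration simulations).
* `vignettes/mdcscan-methods.Rmd` — the model, conventions and design
  decisions in full.
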