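---
title: "Auditing research effort across bee taxa: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing research effort across bee taxa: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beebias)
```

Bee research concentrates on a handful of genera — above all the managed
honey bees and bumblebees — while most of the >20,000 described species
receive little or no attention. `beebias` implements, as reusable and
testable components, the quantitative machinery needed to audit that
concentration: counting publications per genus from bibliographic exports,
measuring each genus' structural importance in plant–pollinator visitation
networks, quantifying how much of functional trait space the studied taxa
cover, and fitting the statistical models that relate effort to popularity,
biodiversity, management status and centrality. This vignette explains the
models and the design decisions; the README shows the quick-start workflow.

## 1. Literature counting

### Record linkage

Bibliographic exports from two sources are first deduplicated within source
(first record per native identifier, then first record per canonical DOI,
where canonicalisation lower-cases, trims, and strips a leading `doi:`).
Across sources a precision-first, two-step matcher is used: exact merge on
canonical DOI, then — for the DOI-less remainder, grouped by identical
publication year — greedy best-first linking of title pairs whose token-set
similarity (shared tokens over the smaller token set) reaches a threshold.
The default threshold is 0.9; only near-identical titles link, which trades
a few missed duplicates for essentially no false merges. Greedy one-to-one
linking with ties broken by input order makes the partition deterministic.
The three resulting sets always satisfy the accounting identity
`|intersection| + |source-A-only| + |source-B-only| = |union|`, which the
test suite asserts on randomly generated corpora.

### Alias library and stemmed phrase index

Genus detection is dictionary-based. Every genus contributes (i) its
canonical name, (ii) binomial abbreviations generated from its species
list ("Apis mellifera" → "a. mellifera"), and (iii) curated common-name
expansions (honey bee/honeybee → *Apis*, bumble bee/bumblebee → *Bombus*,
carpenter bee → *Xylocopa*, mason bee → *Osmia*, leafcutter/leaf-cutting
bee → *Megachile*, mining bee → *Andrena*). Documents and aliases pass
through one shared reduction — lower-casing, punctuation stripping, Porter
stemming — so "Pollinating bees" and "pollinated bee" meet in the same
reduced vocabulary. The stemmer is the original Porter algorithm,
implemented in the package and verified against the published example
reductions ("pollinating" → "pollin").

Matching runs against an inverted index that maps each stemmed token to the
documents and token positions where it occurs. Multi-token aliases must
match as *consecutive* stemmed tokens: "honey bee" cannot fire on a
document that merely contains "honey" somewhere and "bee" elsewhere. A
document contributes at most one count per genus regardless of how many
aliases or occurrences it contains; per-document genus sets also feed the
co-occurrence counts. The `high_confidence` mode drops the inherently
ambiguous binomial abbreviations — the mode to use for validation against
manual counts. Abbreviations claimed by two genera (same initial, same
epithet) are dropped from both with a warning rather than guessed at;
full-name or common-name collisions are errors, because they indicate a
malformed attribute table.

Documents without a year are kept under a sentinel `NA`-year bucket and
reported, so nothing is silently lost; year-indexed models exclude that
bucket. Country assignment (`match_countries()`) is deliberately
conservative: exact, whole-phrase, case-insensitive gazetteer matches only.
Topic filtering is a pluggable predicate over documents and defaults to
pass-through; embedding-based filtering is out of scope here.

### Validation harness

`validate_counts()` compares automated against manual genus totals with
Spearman (average ranks on ties), Pearson, MAE, RMSE and the OLS slope of
manual on automated counts, plus a Wilson interval for precision when a
labelled detection sample is available. The harness accepts any labelled
sample; no particular stratification is assumed.

## 2. Network centrality

Interaction matrices (plants on rows, pollinators on columns, visitation
weights or presence/absence) are cleaned (empty rows/columns dropped,
orientation fixed), pollinator labels are parsed to genus (first token,
capitalised, synonym-mapped), and columns sharing a genus are summed so the
genus is a single node — the merge rule that matches a genus-level
analysis.

Two metrics are computed per pollinator column *j*:

* **Species strength** `s_j = Σ_i a_ij / r_i`, the summed dependence of all
  plants on *j*; strengths add up to the number of plant rows, a
  conservation identity asserted to `1e-9` in the tests.
* **Blüthgen's specialisation** `d_j = Σ_i p'_ij ln(p'_ij / q_i)` with
  `p'_ij = a_ij / A_j` and availability `q_i = r_i / m`, standardised to
  `d'_j = (d_j − d_min) / (d_max − d_min) ∈ [0, 1]`. The maximum
  concentrates the column total on the least-available plant
  (`d_max = ln(1/min q)`). For integer-valued column totals `d_min` is
  computed *exactly* over integer allocations by a unit-by-unit greedy:
  the objective is separable and convex on the integer simplex, where
  smallest-marginal-increase greedy allocation is provably optimal. The
  test suite confirms agreement with exhaustive enumeration of all integer
  allocations on small matrices. For non-integer totals the continuous
  minimum 0 is used. Columns whose total admits only maximally specialised
  allocations (e.g. a single recorded interaction) receive `d' = 1`;
  columns with no room for specialisation at all receive `d' = 0`.

Within each network the metrics are z-scored (a zero-variance network maps
to zeros rather than infinities), and networks with fewer than 3 matched
pollinator genera are dropped entirely. Genus-level centrality is the
*region-balanced* mean z-strength: z-scores are averaged within region and
the region means averaged unweighted, so heavily sampled regions do not
dominate; genera seen only in unlabelled networks fall back to an
interaction-weighted pooled mean. Both `d'` and strength are z-scored and
reported per network, but only z-strength feeds the genus centrality
summary, strength being the quantity the effort comparison is about.

Sensitivity machinery mirrors the analysis it supports:
`leave_one_region_out()` recomputes the aggregation and the Spearman
correlation with effort after excluding each region,
`bootstrap_centrality_correlation()` resamples networks with replacement
(default 1000 iterations, percentile intervals, seeded), and
`spearman_cor()` computes the rank correlation as Pearson on average ranks
with a t-approximation p-value (or a seeded permutation p).

## 3. Trait space

Raw intertegular distance (ITD, mm; a body-size proxy) and tongue length
(mm) cluster strongly by genus. To keep taxonomic clustering from
masquerading as functional structure, each trait is z-scored over species,
genus mean vectors are decomposed into principal components, each species
inherits its genus' leading PC scores (2 by default; 1–2 supported), and
the within-genus least-squares residuals against those scores become the
species' coordinates. Residuals are exactly orthogonal to the genus PC
regressors and centred at zero.

Coverage and overlap use a bivariate Gaussian product-kernel density on an
`n × n` grid (200 by default) with a rule-of-thumb (Silverman) bandwidth
per axis and the grid extended 3 bandwidths beyond the data range, which
keeps the grid integral within 1% of 1. An isopleth region at level `α`
(default 0.95) is the smallest highest-density set of cells holding `α` of
the grid mass. From these come:

* coverage: the cell-count fraction of a reference isopleth intersected by
  a group isopleth (how much of overall trait space a group covers);
* overlap mass `Σ min(f_A, f_B) · cell area` (symmetric);
* group-unique mass: a group's density mass outside the other group's
  isopleth region.

Null expectations come from permutation: same-size random species subsets
drawn without replacement from the pool, statistic recomputed per draw,
and the add-one estimator `p = (1 + #extreme) / (n_perm + 1)` (999 draws
by default, seeded). The tail is explicit — lower for coverage (groups are
suspected of covering *less* than chance), upper for centroid separation.
Calibration is verified in the tests: under a true null the p-values are
uniform (KS distance < 0.1 over 500 replicates).

## 4. Bias statistics

* **Popularity expectations.** Expected effort distributes the observed
  total proportionally to genus popularity: `E_g = T · pop_g / Σ pop`,
  conserving the total exactly; residuals `O_g − E_g` and percentage
  deviations `100 (O_g − E_g)/E_g` (rounded to integers for reporting)
  quantify over/under-representation relative to public interest.
* **Policy groups.** Genera are crossed into LELC/LEHC/HELC/HEHC by
  thresholds on effort (compared on the `log10(papers + 1)` scale) and on
  mean z-strength. Published analyses of this kind do not pin the
  thresholds, so the defaults are median splits, both configurable, and
  the thresholds used are always recorded in the output. The four groups
  partition the classified set by construction, and managed shares are
  reported per group.
* **Richness–effort scaling.** OLS of `log10(papers + 1)` on
  `log10(richness)` with HC3 standard errors
  (`(X'X)⁻¹ X' diag(e²/(1−h)²) X (X'X)⁻¹`), influence flags (Cook's
  D > 4/n or leverage > 2p/n), and four refits: dropping flagged genera,
  dropping named dominant genera (*Apis*, *Bombus* by default), and
  trimming the top 1% (`ceiling(0.01 n)`) by richness and by articles.
* **Family comparisons.** Welch's heteroscedastic one-way ANOVA with
  Satterthwaite-type denominator df, Games–Howell pairwise contrasts
  (unequal-variance SE, Welch df, studentised-range reference), and
  Benjamini–Hochberg adjustment. Families with fewer than two usable
  genera are excluded upstream by the caller.
* **Share trends.** Two-column binomial GLMs (logit link) of category
  share on calendar year; one-vs-rest fits per level with BH adjustment
  across levels; complete separation is flagged, not estimated.
  `era_share_change()` reports early-vs-recent window differences in mean
  share, in percentage points.
* **Count models.** `nb_glm()` fits a log-link negative-binomial
  regression with an exposure offset (log total papers that year), so
  coefficients describe shares of a growing literature rather than raw
  counts. Estimation alternates IRLS for the coefficients with
  maximum-likelihood Newton updates of the dispersion θ (on log θ) until
  the joint log-likelihood moves by less than 1e-8; θ beyond 1e4 raises a
  Poisson-limit flag. Effects are reported as incidence rate ratios
  `exp(β)` with Wald 95% intervals `exp(β ± 1.96 SE)`. This is a
  fixed-effects model by design: the audit's genus-level covariates
  (managed, managed × scaled year, sociality, nesting contrasts, scaled
  log1p richness, z-strength) enter the design matrix directly, and
  variance-component estimation is deliberately out of scope. Year is
  scaled as `(year − mean)/sd` over the modelled years.

## 5. What the synthetic generators emulate

All four stages are exercised end to end on generated data with known
truth, because the licensed corpora this kind of audit runs on cannot be
redistributed:

* `gen_corpus()` plants genus mentions (full names, abbreviations, common
  names at configurable rates) into distractor text drawn from a synthetic
  vocabulary that cannot collide with alias stems, and exports duplicates
  to two pseudo-sources with or without DOIs. With a clean vocabulary and
  no abbreviations, the counting engine recovers the planted genus-year
  table *exactly* — the closed-loop test of the whole counting path.
* `gen_networks()` allocates a multinomial total to plant × genus cells
  with probabilities proportional to plant weight × latent genus
  attractiveness; attractiveness is the planted centrality truth.
* `gen_traits()` draws species from per-group bivariate normals on the log
  scale (so ITD and tongue are positive and right-skewed), with per-genus
  mean offsets so residualisation has structure to remove.
* `gen_counts()` draws genus-year counts from a negative binomial around
  `exposure · exp(β₀ + β_managed·managed + β_mxy·managed·year_s +
  β_rich·richness_s)`. Defaults mirror the headline magnitudes this kind
  of audit reports — a managed premium IRR of 2.86 growing at 1.78 per SD
  of year, dispersion θ = 2, an exposure series growing 5% a year — so
  scaled-down reproductions behave like the documented phenomenon. They
  are an emulation with known truth, not a reproduction of any dataset.

What passing these tests shows — and does not show. Exact planted-count
recovery demonstrates that the indexing, phrase matching and per-document
deduplication logic are correct; it does not certify recall on real
abstracts, where morphology, hyphenation and homonyms (e.g. plant genera
sharing bee genus names) matter and where the printed validation exercise
(precision sampling, manual reference counts) is the relevant check.
Similarly, parameter recovery in the count models certifies the estimator,
not the causal interpretation of any coefficient on observational data.

## 6. Numerical choices and degenerate inputs

* Sample standard deviation for z-scores; all-equal vectors map to zeros.
* Degenerate `d'` columns: see §2.
* `d_min` greedy runs per unit of the column total — exact and fast for
  the visitation totals this package targets (thousands of interactions).
* Constant vectors give `NA` Spearman with a warning (not an error), so
  sensitivity loops can skip degenerate resamples; bootstrap resamples
  that collapse are skipped and counted.
* KDE grids: 200×200 default (120×120 in the pipeline stage for speed),
  3-bandwidth margins; two groups are compared on one shared grid passed
  via `xlim`/`ylim`.
* Permutation p-values use the add-one estimator, so 0 is impossible and
  the smallest attainable p is `1/(n_perm + 1)`.
* Seeds: every stochastic function takes an explicit seed; the pipeline
  derives per-stage seeds from one master seed, and generators are pure
  functions of their specs (ambient RNG state cannot leak in).
* Problem sizes in the shipped tests (chosen to keep the closed loop
  meaningful at interactive scale): corpora of 100–400 documents over 20
  genera, 6–8 networks of 12 plants × 8–50 genera, trait clouds of
  500–1000 species, count tables of 600–4900 genus-years, 200 replicate
  fits for the recovery study, 500 replicates for permutation calibration.

## 7. Known limitations

* Visitation is not pollination: centrality summarises structural position
  in recorded networks, and abundance/sampling effort inflate it.
* The alias approach cannot disambiguate true homonyms and relies on the
  curated common-name list; transformer NER is explicitly out of scope.
* The counting engine treats titles+abstracts as the text universe; full
  text is not parsed.
* Fixed-effects count models ignore genus- and country-level random
  variation by design; estimates are associations, not causal effects.
* The greedy `d_min` requires integer totals to be exact; weighted
  networks with non-integer weights fall back to the continuous bound.
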