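---
title: "Identifying and tracking antigen-reactive TCR-beta clones and CDR3 motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and tracking antigen-reactive TCR-beta clones and CDR3 motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdr3trackr)
```

## The problem

Autoreactive CD4+ T cells that recognize self-antigens such as
apolipoprotein B (APOB) expand clonally and can be read out through the
hypervariable CDR3 region of their TCR-beta chains. A common experimental
design sorts, per donor, an antigen-reactive compartment (`AIM_POS`,
cells upregulating activation-induced markers after peptide
restimulation) and a matched non-reactive control (`AIM_NEG`), plus
unenriched ex-vivo naive, central-memory (`TCM`) and effector-memory
(`TEM`) CD4+ T cells, and profiles each by bulk genomic-DNA TCR-beta
sequencing. Because each alpha-beta T cell carries one rearranged
TCR-beta template, template counts are clone-size proxies.

`cdr3trackr` implements the inference chain over such data:

1. **Clone selection** — derive a global clonal-frequency threshold from
   the non-reactive compartments, then call a clone antigen-reactive
   when it is strongly expanded (frequency above the threshold) *and*
   specifically enriched in the reactive sort (log10 odds ratio >= 1,
   BH-adjusted two-sided Fisher exact p < 0.01 on template counts).
2. **Lineage tracking** — trace selected clones into the ex-vivo
   repertoires by exact CDR3 amino-acid matching, quantifying naive vs
   memory overlap, TCM/TEM partitioning, memory expansion, and clone
   publicity across donors.
3. **Motif discovery** — cluster CDR3 interiors into specificity groups
   (local shared k-mers enriched over a naive reference; global
   single-mismatch convergence patterns with a `%` wildcard), score each
   group's clonal-expansion bias by permutation, and score reactive
   (AIM+) enrichment by fold change plus an exact two-rate Poisson test.
4. **Motif tracking and publicity** — assign ex-vivo CDR3s to the
   selected reactive motifs, classify naive/memory affiliation, build
   the donor-by-subset motif-sharing network, and call public motifs
   present in the memory pool of most donors.

## Statistical machinery

**Fisher exact test.** Per-clone reactive enrichment uses the 2x2
template-count table `[a, b; total_pos - a, total_neg - b]`. The
two-sided p-value sums hypergeometric point probabilities not exceeding
the observed one (with the conventional `1 + 1e-7` relative tolerance),
implemented in `fisher_exact_p()` so it can be applied to thousands of
candidate tables cheaply; its cost per table scales with the smallest
margin. Odds ratios use the Haldane-Anscombe +0.5-on-all-cells
correction only when a cell is zero, keeping `log10(OR)` finite without
perturbing non-degenerate tables. The test suite checks the
implementation against `stats::fisher.test` and against an exhaustive
enumeration oracle on every table with margins up to 60.

**Threshold derivation.** The global frequency threshold is the minimum
over donors of the largest non-reactive clonotype frequency, i.e. the
smallest cut that prunes every non-reactive clone in at least one donor;
selection uses a strict `>`. `rounding = "sig3_up"` rounds the value up
to three significant digits for reporting (1.387e-3 becomes 1.39e-3);
the default is no rounding because a rounding rule changes the candidate
set slightly and should be an explicit choice.

**"Poisson test".** Motif-level compartment enrichment compares summed
member template counts `cA`, `cB` over compartment totals `tA`, `tB`.
The exact two-rate Poisson comparison conditions on `n = cA + cB`, under
which `cA` is Binomial(n, tA / (tA + tB)) when rates are equal;
`poisson_rate_p()` returns the two-sided exact binomial p-value. Fold
changes use `log2((cA/tA + eps) / (cB/tB + eps))` with the pseudo-rate
`eps = 1 / max(tA, tB)`, so one-sided zero counts give large finite
folds instead of infinities.

**Expansion score.** A specificity group is expansion-biased when it
contains more expanded clonotypes (template count >= 2, the same
expanded/non-expanded dichotomy used for copy-number spectra) than a
random same-size draw of clonotypes from the dataset. For a draw of `m`
of `N` clonotypes of which `K` are expanded, the null statistic is
exactly hypergeometric, so the `n_perm` permutation draws are generated
as `rhyper` variates — distributionally identical to explicitly sampling
clonotype sets, seeded and reproducible — and
`p = (1 + #(null >= observed)) / (n_perm + 1)`, bounded below by
`1/(n_perm + 1)`. The default `n_perm = 1000` resolves the 0.05
significance level comfortably.

**Multiple testing and rank tests.** BH adjustment (`p.adjust`) is
applied per donor across the threshold-passing candidates only — the
tested family is the candidate set, not the whole repertoire. Group
comparisons across donors (naive vs memory overlap, V-gene usage) use
the two-sided exact Mann-Whitney test (`wilcox.test`); with six donors
per group the smallest attainable p-value is 0.0022.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `or_min_log10` | 1 | minimum log10 odds ratio for clone selection |
| `q_max` | 0.01 | FDR ceiling for clone selection |
| `rounding` | `"none"` | threshold reporting mode (`"sig3_up"` available) |
| `key` | `"aa"` | clonotype key; `"aa_v"` adds the V gene and tightens matching |
| `head`, `tail` | 3, 2 | CDR3 interior trimming offsets |
| `k_values`, `min_fold` | 2:4, 1000/100/10 | local k-mer sizes and per-size fold cuts vs the reference |
| `min_unique_local` | 3 | distinct sample CDR3s required per local k-mer |
| `min_unique_group` | 2 | distinct member CDR3s per specificity group |
| `n_perm` | 1000 | expansion-score permutations |
| `log2fold_min`, `neg_log10p_min` | 2, 5 | reactive-motif volcano cuts |
| `expansion_p_max` | 0.05 | expansion-score gate for reactive motifs |
| `donor_min_fraction` | 0.8 | strict publicity fraction (6 donors: >= 5) |

Trimming (3, 2) follows the convention that CDR3 epitope-contact
residues lie in the interior between the conserved Cys- and Phe-anchored
ends; both offsets are configurable and must match between discovery and
ex-vivo assignment. The per-size fold cuts compensate for the rapidly
growing background frequency of shorter k-mers (a specific 2-mer is
common in any repertoire; a 4-mer is rare).

## The synthetic cohort generator

`simulate_cohort()` is a first-class module, not a test fixture: it
defines the study conditions under which the pipeline is validated.

* **Background repertoires.** Each donor has one AIM clone pool from
  which `AIM_POS` and `AIM_NEG` template counts are drawn by independent
  multinomial resampling — so with nothing planted the two sorts are
  exchangeable draws of the same repertoire, the correct null for the
  enrichment test — plus separate naive/TCM/TEM pools. Clone sizes
  follow a truncated Zipf law (`clone_size_shape = 2.5`), capped at
  `max_background_clone_freq = 1.5e-3` so the non-reactive compartment
  carries no strongly expanded clone; that is the regime in which a
  non-reactive-derived frequency threshold is meaningful, and it places
  the derived threshold on the same order as thresholds reported for
  real sorted cohorts. CDR3s are `C` + uniform-random interior + `F`,
  lengths 11-18.
* **Planted reactive families.** `n_planted_families = 10` motif
  families with `members_per_family = 5` fresh member CDR3s per donor
  (50 reactive clones per donor). Every member embeds an instance of the
  family's wildcard pattern (length 5-6, one `%`) fully inside the
  trimmed interior; patterns are constructed to contain exactly one
  maximal exact 4-mer (the "core") so the local k-mer channel can
  discover them and each discovered group maps unambiguously to one
  family. Member target frequencies are `planted_freq_aim_pos = 4e-3`
  in `AIM_POS` and 20-fold lower in `AIM_NEG`
  (`planted_enrichment_fold = 20`), realized as Poisson counts.
* **Memory residence and publicity.** All donors carry all families in
  the AIM compartments (a shared immunodominant response), while
  `publicity_prob = 0.6` gates whether a family is resident in a given
  non-origin donor's memory; within resident families each member clone
  seeds memory with `memory_seeding_prob = 0.3`, splitting between TCM
  and TEM by `tcm_tem_mix`. Member sequences are freshly drawn per
  donor, so exact clones remain private across donors while the motif is
  shared — mirroring the observed regime of private clones but public
  motifs. A 1% `naive_leak_prob` plants occasional single naive copies.
* **Ground truth by recount.** Per-clone compartment flags are recorded
  from the realized counts, and per-family memory donor sets are
  recomputed by pattern-matching the family core against the emitted
  ex-vivo repertoires. Chance background matches are therefore part of
  the truth: whether a donor's memory pool "carries" a motif is a
  property of the sequences, planted or not, and it is the same question
  the pipeline answers.
* **V-gene bias.** The first 30% of families carry
  `preferred_v_gene = "TRBV15"`, giving the cross-donor V-gene usage
  test a planted positive.

**What the generator does not emulate:** V(D)J recombination statistics
(generation probabilities, positional residue biases, CDR3
length-composition coupling), HLA-restricted epitope binding, sequencing
error, and shared background clonotypes across donors. Passing tests
therefore demonstrate that the inference chain is correct under its own
assumptions — calibrated null behaviour, recovery of planted structure,
agreement with exact oracles — not that real repertoires satisfy those
assumptions.

## The naive reference panel

Local k-mer enrichment needs a background rate per k-mer. Tools of this
kind ship a large built-in reference of naive CDR3s from healthy donors;
`simulate_naive_reference()` provides the package's synthetic analogue
(12 donors x 40,000 unique clones, ~480,000 trimmed interiors, fixed
internal seed). Panel size matters: the expected count of a specific
4-mer in a panel of `N` sequences grows with `N` while its relative
Poisson noise shrinks as `1/sqrt(N)`, and with a small reference
(e.g. only the cohort's own six naive compartments) that noise is large
enough for the fold >= 10 cut to reject genuinely enriched 4-mers. For
real data, supply a `reference_set()` built from sequenced naive CDR3s;
exact reproduction of published group counts additionally depends on the
original tool's packaged reference, which this package does not
redistribute.

## Numerical and degenerate-input choices

* Two-sided tests throughout; the observed-probability comparison uses
  the standard `1 + 1e-7` relative tolerance.
* Group deduplication keeps, among groups with identical member CDR3
  sets, the longer pattern, then fewer wildcards, then the
  lexicographically first — the most specific description of the same
  evidence.
* Clonotype ordering is descending template count with lexicographic
  tie-break, so outputs are byte-stable.
* Empty inputs raise classed errors (`cdr3trackr_empty_error`,
  `cdr3trackr_config_error`, ...) rather than returning silent zeros;
  the one deliberate exception is a specificity group with no members in
  either compared compartment, which yields `log2_fold = 0`, `p = 1` and
  a `degenerate` flag.
* A motif matched by zero memory and zero naive ex-vivo CDR3s is
  `ABSENT`; `memory_enriched` is only meaningful for `BOTH` motifs, and
  memory affiliation is `MEMORY_ONLY` or (`BOTH` and memory-enriched).

## Problem sizes used in validation

The shipped validation cohorts use 6 donors with 20,000 templates in
each AIM compartment (15,000 TCM, 5,000 TEM, 20,000 naive in the
default planted cohort; 20,000 everywhere in the null cohorts), chosen
as a representative scale at which every statistical property of the
full-size design — threshold derivation, exchangeable nulls, planted
recovery, motif publicity — is exercised while a complete cohort
simulates and analyzes in seconds. Null calibration aggregates 20
independent cohorts. Published headline counts from the real deposited
cohort (hundreds of thousands of CDR3s per compartment, and group counts
produced by an external web tool with its own packaged reference) are
not reproducible at this scale and are not asserted by the test suite;
the tests instead assert the properties that make those numbers
trustworthy.

## Known limitations

* Exact-match tracking understates lineage overlap whenever the same
  specificity is carried by near-identical CDR3s; that gap is precisely
  what the motif channel addresses, and the two analyses are reported
  side by side rather than merged.
* Local discovery is limited to k <= 4 exact cores; a planted or real
  motif whose conserved residues are all non-contiguous would be visible
  only to the global (single-mismatch) channel.
* The V-gene-bias, length-distribution and clonal-network sub-scores of
  the full GLIPH2 scoring stack are out of scope; specificity grouping
  here rests on the local and global channels plus the reference,
  expansion and compartment-enrichment tests.
* `classify_affiliation()` assigns ex-vivo CDR3s into the already
  selected reactive motifs by pattern matching rather than re-clustering
  the ex-vivo repertoires; re-clustering would produce groups that are
  not comparable motif-by-motif with the reactive set.
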