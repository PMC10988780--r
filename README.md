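# cdr3trackr

Selection and cross-donor tracking of antigen-reactive TCR-beta CDR3
clones and motifs from bulk immunosequencing data.

## What it does, and for whom

Autoimmune and antigen-driven T-cell responses leave a clonal footprint
in the TCR-beta repertoire. A now-standard design sorts, per donor, an
antigen-**reactive** CD4+ compartment (`AIM_POS`: cells that upregulate
activation-induced markers after peptide restimulation) against a
matched **non-reactive** control (`AIM_NEG`), plus unenriched ex-vivo
naive, central-memory (`TCM`) and effector-memory (`TEM`) cells, and
profiles each compartment with immunoSEQ-style bulk TCR-beta sequencing
(one row per rearrangement: CDR3 nucleotide/amino-acid sequence, V/D/J
calls, template count, frequency).

`cdr3trackr` is for immunologists and computational biologists who have
such paired repertoires and want to answer, reproducibly:

* **Which clones are antigen-reactive?** A clone is selected when its
  `AIM_POS` frequency exceeds a global threshold derived from the
  non-reactive compartments (the smallest per-donor maximum `AIM_NEG`
  clonotype frequency — the cut that prunes every non-reactive clone in
  at least one donor), its odds ratio satisfies
  `log10(OR) >= 1`, and its two-sided Fisher exact test on the
  template-count table `[a, b; N+ - a, N- - b]` survives
  Benjamini-Hochberg adjustment at `q < 0.01`.
* **Are they antigen-experienced in vivo?** Selected clones are traced
  into the naive/TCM/TEM repertoires by exact CDR3 amino-acid matching;
  naive vs memory overlap percentages are compared by Mann-Whitney.
* **Which CDR3 motifs carry the reactivity?** CDR3 interiors (anchors
  trimmed 3 + 2) are clustered into specificity groups: *local* groups
  share an exact k-mer (k = 2-4) enriched over a naive reference panel,
  *global* groups are equal-length interiors differing at one position
  (pattern wildcard `%`). Groups are scored with a permutation
  expansion score, and reactive (APOB+-style) motifs are called at
  `log2 fold >= 2` and `-log10 p >= 5` on an exact two-rate Poisson
  test of `AIM_POS` vs `AIM_NEG` member templates.
* **Are motifs shared across donors?** Reactive motifs are assigned to
  ex-vivo CDR3s, classified as naive-only / memory-only / both (with
  memory-enrichment testing), linked into a donor-by-subset sharing
  network, and called **public** when present in the memory pool of more
  than 80% of donors.

A seeded synthetic-cohort generator (`simulate_cohort()`) with planted
reactive clone families and motif publicity, plus a synthetic naive
reference panel (`simulate_naive_reference()`), makes every stage
testable against known ground truth.

## Worked example

```r
library(cdr3trackr)

cfg <- simulation_config(seed = 42)    # 6 donors, 10 planted families
sim <- simulate_cohort(cfg)

sel <- select_reactive_clones(sim$cohort)
sel$threshold
#> [1] 0.00185
nrow(sel$clones); sum(sel$clones$selected)
#> [1] 300
#> [1] 280
```

The derived threshold (0.00185, i.e. the smallest per-donor maximum
non-reactive clonotype frequency) admits 300 candidate clones, of which
280 pass the odds-ratio and FDR cuts — the generator planted 50
reactive clones per donor, and a handful fall below `log10(OR) >= 1`
through sampling noise in their non-reactive counts:

```r
head(sel$clones[sel$clones$selected, ], 3)
#>   donor_id aa_seq            v_gene  freq_aim_pos freq_aim_neg log10_odds fdr_q
#> 1 D01      CGYYMAQEEFPFAEPF TRBV6-4      0.0042        0           2.23 4.74e-24
#> 2 D01      CMLIDVEDTVGPYF   TRBV6-5      0.00435       0.00005     1.94 8.75e-24
#> 3 D01      CHACEIDALQF      TRBV28       0.00405       0.00005     1.91 1.76e-22
```

Tracking the selected clones into the unenriched repertoires recovers
the planted memory residence — memory overlap an order of magnitude
above naive overlap:

```r
tracking <- track_cohort(sel$clones[sel$clones$selected, ], sim$cohort)
ov <- overlap_fractions(tracking)
ov$summary
#>   mean_pct_naive sem_pct_naive mean_pct_memory sem_pct_memory memory_naive_ratio
#> 1       2.144726      0.574477        23.91606       3.380911            11.1511
ov$mw_p
#> [1] 0.004697697
```

The motif chain discovers the planted cores as local specificity groups
and calls the public ones:

```r
ref <- simulate_naive_reference()      # synthetic 12-donor naive panel
res <- run_motif_pipeline(sim$cohort, reference = ref, seed = 7)
head(res$apob_motifs[, c("pattern", "kind", "n_unique_cdr3",
                         "log2_fold", "poisson_p", "expansion_p")], 3)
#>   pattern kind  n_unique_cdr3 log2_fold poisson_p expansion_p
#> 1 EFPF    LOCAL            31      4.63         0    0.000999
#> 2 IDAL    LOCAL            33      4.41         0    0.000999
#> 3 DTVG    LOCAL            33      4.33         0    0.000999

res$public$public[, c("pattern", "kind", "subset_detail", "n_donors_memory")]
#>   pattern kind  subset_detail n_donors_memory
#> 1 EFPF    LOCAL BOTH                        6
#> 2 DTVG    LOCAL BOTH                        5
#> 3 IFAT    LOCAL BOTH                        5
#> 4 RHEF    LOCAL BOTH                        5
#> 5 VRDK    LOCAL BOTH                        5
#> 6 YDCG    LOCAL BOTH                        5
```

Six motifs sit in the memory compartment of at least five of six donors
— exactly the six families the generator made public
(`sim$truth$motifs$public`). Each motif's member CDR3s can be exported
as a column-stochastic position-frequency matrix
(`position_frequency_matrix()`) for any logo renderer, and the sharing
network as GraphML (`write_sharing_network()`).

Real data enter through `read_repertoire()` / `read_cohort()`
(immunoSEQ-dialect TSV plus a manifest; column naming configurable via
`default_column_map()`).

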