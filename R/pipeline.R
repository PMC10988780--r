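#' Select antigen-reactive clones across a cohort
#'
#' Convenience wrapper for the per-donor selection chain: filter
#' productive records, derive the global frequency threshold from the
#' non-reactive compartments, and run the per-donor enrichment test.
#'
#' @param cohort Named list of `tcr_repertoire`s (as from [read_cohort()]
#'   or [simulate_cohort()]).
#' @param rounding Threshold rounding mode, see
#'   [derive_global_threshold()].
#' @param or_min_log10,q_max,key See [clone_enrichment_test()].
#' @return List with `threshold` and `clones` (stacked per-donor
#'   enrichment tibble; `selected` marks reactive calls).
#' @export
select_reactive_clones <- function(cohort, rounding = "none",
                                   or_min_log10 = 1, q_max = 0.01,
                                   key = "aa") {
  pos <- lapply(cohort_compartment(cohort, "AIM_POS"), filter_productive)
  neg <- lapply(cohort_compartment(cohort, "AIM_NEG"), filter_productive)
  stopifnot(length(pos) == length(neg), length(pos) > 0)
  threshold <- derive_global_threshold(neg, rounding, key)
  clones <- bind_rows(lapply(seq_along(pos), function(i) {
    clone_enrichment_test(pos[[i]], neg[[i]], threshold,
                          or_min_log10, q_max, key)
  }))
  list(threshold = threshold, clones = clones)
}

#' Track selected clones into the ex-vivo repertoires of a cohort
#'
#' @param selected Selected-clone tibble (`donor_id`, `aa_seq`, ...).
#' @param cohort Named list of `tcr_repertoire`s including `NAIVE`,
#'   `TCM`, `TEM` per donor.
#' @param key Matching key.
#' @return Stacked [track_clones()] tibble over donors.
#' @export
track_cohort <- function(selected, cohort, key = "aa") {
  donors <- unique(selected$donor_id)
  bind_rows(lapply(donors, function(d) {
    track_clones(
      selected[selected$donor_id == d, , drop = FALSE],
      filter_productive(cohort[[paste(d, "NAIVE", sep = ".")]]),
      filter_productive(cohort[[paste(d, "TCM", sep = ".")]]),
      filter_productive(cohort[[paste(d, "TEM", sep = ".")]]),
      key)
  }))
}

#' Run the full motif chain on a cohort
#'
#' Discovers specificity groups on the pooled reactive/non-reactive
#' sample, scores reactive enrichment, selects reactive motifs,
#' classifies ex-vivo affiliation, builds the sharing network and calls
#' public motifs.
#'
#' @param cohort Named list of `tcr_repertoire`s for all five
#'   compartments per donor.
#' @param reference A [reference_set()]; defaults to the cohort's own
#'   naive repertoires pooled (a user-supplied external naive reference
#'   is preferred for real data).
#' @param head,tail Trimming offsets.
#' @param n_perm,seed Expansion-score parameters.
#' @param log2fold_min,neg_log10p_min,expansion_p_max Reactive motif
#'   cuts.
#' @param donor_min_fraction Publicity threshold.
#' @return List with `groups`, `apob_motifs`, `affiliation`, `matches`,
#'   `network`, `public`.
#' @export
run_motif_pipeline <- function(cohort, reference = NULL, head = 3,
                               tail = 2, n_perm = 1000, seed = 1,
                               log2fold_min = 2, neg_log10p_min = 5,
                               expansion_p_max = 0.05,
                               donor_min_fraction = 0.8) {
  aim <- c(lapply(cohort_compartment(cohort, "AIM_POS"), filter_productive),
           lapply(cohort_compartment(cohort, "AIM_NEG"), filter_productive))
  exvivo <- unlist(lapply(c("NAIVE", "TCM", "TEM"), function(cp)
    lapply(cohort_compartment(cohort, cp), filter_productive)),
    recursive = FALSE)
  if (is.null(reference)) {
    naive_seqs <- unlist(lapply(cohort_compartment(cohort, "NAIVE"),
                                function(r) r$records$aa_seq))
    reference <- reference_set(naive_seqs, trim = TRUE, head, tail)
  }
  groups <- discover_motifs(aim, reference, head, tail,
                            n_perm = n_perm, seed = seed)
  totals <- c(
    AIM_POS = sum(vapply(cohort_compartment(cohort, "AIM_POS"),
                         function(r) r$total_templates, numeric(1))),
    AIM_NEG = sum(vapply(cohort_compartment(cohort, "AIM_NEG"),
                         function(r) r$total_templates, numeric(1))))
  groups <- motif_fold_and_poisson(groups, totals)
  apob <- select_apob_motifs(groups, log2fold_min, neg_log10p_min,
                             expansion_p_max)
  n_donors <- length(cohort_compartment(cohort, "AIM_POS"))
  if (nrow(apob) == 0) {
    return(list(groups = groups, apob_motifs = apob, affiliation = NULL,
                matches = NULL, network = NULL, public = NULL,
                n_donors = n_donors))
  }
  cls <- classify_affiliation(apob, exvivo, head, tail)
  network <- build_sharing_network(cls$affiliation, cls$matches)
  pub <- public_motifs(cls$affiliation, cls$matches, n_donors,
                       donor_min_fraction)
  list(groups = groups, apob_motifs = apob,
       affiliation = cls$affiliation, matches = cls$matches,
       network = network, public = pub, n_donors = n_donors)
}
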