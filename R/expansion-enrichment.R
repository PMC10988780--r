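#' Copy-number spectrum of a repertoire
#'
#' Fraction of unique clonotypes per copy-number bin (e.g. singletons and
#' low-copy clones vs clones with more than 10 copies).
#'
#' @param clonotypes A clonotype tibble from [aggregate_clonotypes()], or
#'   a productive-filtered `tcr_repertoire` (aggregated with the default
#'   key).
#' @param breaks Increasing copy-number bin edges, `cut()`-style with
#'   right-closed bins; the default gives the bins 1-10 and > 10.
#' @return Tibble with `bin`, `n_clonotypes`, `fraction` (fractions sum
#'   to 1).
#' @export
copy_number_spectrum <- function(clonotypes, breaks = c(0, 10, Inf)) {
  if (inherits(clonotypes, "tcr_repertoire")) {
    clonotypes <- aggregate_clonotypes(clonotypes)
  }
  bins <- cut(clonotypes$templates, breaks = breaks, right = TRUE)
  tab <- table(bins)
  tibble(bin = names(tab),
         n_clonotypes = as.integer(tab),
         fraction = as.integer(tab) / nrow(clonotypes))
}

#' Derive the global clonal-frequency threshold from AIM- repertoires
#'
#' The threshold is the smallest, over donors, of the maximum clonotype
#' frequency observed in that donor's non-reactive (`AIM_NEG`)
#' repertoire: by construction, selecting reactive candidates at strictly
#' greater frequency prunes out every non-reactive clone in at least one
#' donor. With `rounding = "sig3_up"` the value is rounded up to three
#' significant digits (e.g. a donor maximum of 1.387e-3 yields the
#' printed-style threshold 1.39e-3).
#'
#' @param aim_neg_reps List of per-donor `AIM_NEG` repertoires
#'   (productive-filtered), or clonotype tibbles.
#' @param rounding `"none"` or `"sig3_up"`.
#' @param key Clonotype aggregation key passed to
#'   [aggregate_clonotypes()].
#' @return A single frequency threshold; downstream selection uses
#'   strict `>`.
#' @export
derive_global_threshold <- function(aim_neg_reps,
                                    rounding = c("none", "sig3_up"),
                                    key = "aa") {
  rounding <- match.arg(rounding)
  if (length(aim_neg_reps) == 0) {
    stop_empty("derive_global_threshold() needs at least one repertoire")
  }
  maxima <- vapply(aim_neg_reps, function(rep) {
    cl <- if (inherits(rep, "tcr_repertoire")) {
      if (nrow(rep$records) == 0) stop_empty("empty AIM- repertoire")
      aggregate_clonotypes(rep, key)
    } else rep
    if (nrow(cl) == 0) stop_empty("empty AIM- repertoire")
    max(cl$frequency)
  }, numeric(1))
  thr <- min(maxima)
  if (rounding == "sig3_up") thr <- round_up_sig3(thr)
  thr
}

#' Per-clone AIM+ vs AIM- enrichment test
#'
#' Candidates are the donor's `AIM_POS` clonotypes with frequency
#' strictly above `threshold`. Each candidate is tested on the 2x2
#' template-count table `[a = templates in AIM+, b = templates in AIM-;
#' c = total AIM+ templates - a, d = total AIM- templates - b]` with the
#' two-sided Fisher exact test; odds ratios get the Haldane-Anscombe
#' +0.5-on-all-cells correction whenever any cell is zero, and p-values
#' are Benjamini-Hochberg adjusted across the donor's candidates. A clone
#' is selected when `log10(odds_ratio) >= or_min_log10` and the adjusted
#' p-value is below `q_max`.
#'
#' @param aim_pos,aim_neg Productive-filtered `tcr_repertoire`s from the
#'   same donor.
#' @param threshold Positive frequency threshold (strict `>`), typically
#'   from [derive_global_threshold()].
#' @param or_min_log10 Minimum log10 odds ratio (default 1).
#' @param q_max Maximum FDR-adjusted p (default 0.01).
#' @param key Clonotype aggregation key.
#' @return Tibble of per-candidate results: counts, frequencies,
#'   `odds_ratio`, `log10_odds`, `fisher_p`, `fdr_q`, `selected`.
#' @export
clone_enrichment_test <- function(aim_pos, aim_neg, threshold,
                                  or_min_log10 = 1, q_max = 0.01,
                                  key = "aa") {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop_config("threshold must be a positive frequency")
  }
  stopifnot(inherits(aim_pos, "tcr_repertoire"),
            inherits(aim_neg, "tcr_repertoire"))
  pos <- aggregate_clonotypes(aim_pos, key)
  neg <- aggregate_clonotypes(aim_neg, key)
  total_pos <- sum(pos$templates)
  total_neg <- sum(neg$templates)
  cand <- pos[pos$frequency > threshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble(donor_id = character(), aa_seq = character(),
                  v_gene = character(), j_gene = character(),
                  templates_aim_pos = integer(), templates_aim_neg = integer(),
                  freq_aim_pos = double(), freq_aim_neg = double(),
                  odds_ratio = double(), log10_odds = double(),
                  fisher_p = double(), fdr_q = double(),
                  selected = logical()))
  }
  neg_lookup <- setNames(neg$templates, neg$aa_seq)
  a <- cand$templates
  b <- as.integer(neg_lookup[cand$aa_seq])
  b[is.na(b)] <- 0L
  cc <- total_pos - a
  dd <- total_neg - b
  or <- odds_ratio_2x2(a, b, cc, dd)
  p <- fisher_exact_p(a, b, cc, dd)
  q <- p.adjust(p, method = "BH")
  tibble(
    donor_id = aim_pos$donor_id,
    aa_seq = cand$aa_seq,
    v_gene = cand$v_gene,
    j_gene = cand$j_gene,
    templates_aim_pos = a,
    templates_aim_neg = b,
    freq_aim_pos = a / total_pos,
    freq_aim_neg = b / total_neg,
    odds_ratio = or,
    log10_odds = log10(or),
    fisher_p = p,
    fdr_q = q,
    selected = log10(or) >= or_min_log10 & q < q_max
  ) |>
    arrange(desc(.data$log10_odds), .data$aa_seq)
}

#' V-gene usage odds ratios for selected clones vs control clonotypes
#'
#' For each V gene, counts selected reactive clones with/without the gene
#' against control clonotypes with/without, and computes
#' `OR = (with_sel / with_ctrl) / (without_sel / without_ctrl)` (the
#' number-of-V+-in-AIM+ over number-of-V+-in-AIM- formulation), with
#' +0.5 on all four counts whenever any is zero. The unit is the unique
#' clonotype, not the template.
#'
#' @param selected Tibble of selected clones (rows of
#'   [clone_enrichment_test()] output with `selected = TRUE`), carrying
#'   `donor_id` and `v_gene`.
#' @param control Productive-filtered control (`AIM_NEG`)
#'   `tcr_repertoire` for the same donor.
#' @param key Aggregation key for the control clonotypes.
#' @return Tibble per V gene with the four counts, `odds_ratio`,
#'   `freq_in_selected`, `freq_in_control`.
#' @export
vgene_usage_odds <- function(selected, control, key = "aa") {
  if (nrow(selected) == 0) stop_empty("no selected clones supplied")
  stopifnot(inherits(control, "tcr_repertoire"))
  ctrl <- aggregate_clonotypes(control, key)
  genes <- sort(unique(c(selected$v_gene, ctrl$v_gene)))
  genes <- genes[!is.na(genes)]
  n_sel <- nrow(selected)
  n_ctrl <- nrow(ctrl)
  sel_with <- vapply(genes, function(g)
    sum(selected$v_gene == g, na.rm = TRUE), integer(1), USE.NAMES = FALSE)
  ctrl_with <- vapply(genes, function(g)
    sum(ctrl$v_gene == g, na.rm = TRUE), integer(1), USE.NAMES = FALSE)
  a <- sel_with; b <- ctrl_with
  cc <- n_sel - sel_with; dd <- n_ctrl - ctrl_with
  zero <- a == 0 | b == 0 | cc == 0 | dd == 0
  a2 <- a + 0.5 * zero; b2 <- b + 0.5 * zero
  c2 <- cc + 0.5 * zero; d2 <- dd + 0.5 * zero
  tibble(
    donor_id = selected$donor_id[1],
    v_gene = genes,
    count_pos_with = sel_with,
    count_pos_without = cc,
    count_neg_with = ctrl_with,
    count_neg_without = dd,
    odds_ratio = (a2 / b2) / (c2 / d2),
    freq_in_selected = sel_with / n_sel,
    freq_in_control = ctrl_with / n_ctrl
  )
}

#' Cross-donor V-gene preference test
#'
#' Flags genes with odds ratio > 1 in at least `min_donors_preferred`
#' donors and tests each by a two-sided Mann-Whitney test on the
#' per-donor gene frequencies in selected clones vs control clonotypes.
#'
#' @param usages Tibble stacking [vgene_usage_odds()] results for two or
#'   more donors.
#' @param min_donors_preferred Minimum number of donors with OR > 1.
#' @param alpha Flagging level for the Mann-Whitney p-value.
#' @return Tibble per tested gene: `n_donors_or_gt1`, `mw_p`, `flagged`,
#'   plus the mean frequencies; attribute `"or_table"` holds the
#'   donor x gene odds-ratio table.
#' @export
cross_donor_usage_test <- function(usages, min_donors_preferred = 5,
                                   alpha = 0.01) {
  if (length(unique(usages$donor_id)) < 2) {
    stop_config("cross_donor_usage_test() needs at least 2 donors")
  }
  per_gene <- usages |>
    group_by(.data$v_gene) |>
    summarise(n_donors_or_gt1 = sum(.data$odds_ratio > 1),
              .groups = "drop")
  tested <- per_gene$v_gene[per_gene$n_donors_or_gt1 >=
                              min_donors_preferred]
  rows <- lapply(tested, function(g) {
    u <- usages[usages$v_gene == g, ]
    p <- if (all(u$freq_in_selected == u$freq_in_control)) 1 else
      suppressWarnings(wilcox.test(u$freq_in_selected, u$freq_in_control,
                                   exact = TRUE)$p.value)
    tibble(v_gene = g,
           n_donors_or_gt1 = sum(u$odds_ratio > 1),
           mean_freq_selected = mean(u$freq_in_selected),
           mean_freq_control = mean(u$freq_in_control),
           mw_p = p,
           flagged = p < alpha)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(v_gene = character(), n_donors_or_gt1 = integer(),
                  mean_freq_selected = double(), mean_freq_control = double(),
                  mw_p = double(), flagged = logical())
  }
  or_table <- usages |>
    select("donor_id", "v_gene", "odds_ratio") |>
    tidyr::pivot_wider(names_from = "donor_id", values_from = "odds_ratio")
  attr(out, "or_table") <- or_table
  out
}
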