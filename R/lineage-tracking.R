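#' Trace selected reactive clones into unenriched repertoires
#'
#' Matches each selected clone's key (exact amino-acid CDR3 by default)
#' against the donor's naive, central-memory and effector-memory
#' clonotypes, returning subset presence flags, memory template counts
#' and the memory partition (`TCM_ONLY`, `TEM_ONLY`, `BOTH`, `NONE`).
#' Memory copy number of a clone is the summed template count over all
#' TCM and TEM records matching the key.
#'
#' @param selected Tibble of selected clones with `donor_id` and
#'   `aa_seq` (and `v_gene` when `key = "aa_v"`).
#' @param naive,tcm,tem Productive-filtered `tcr_repertoire`s from the
#'   same donor.
#' @param key Matching key, `"aa"` or `"aa_v"`.
#' @return Tibble per clone: `found_naive`, `found_tcm`, `found_tem`,
#'   `templates_tcm`, `templates_tem`, `memory_templates`,
#'   `memory_partition`.
#' @export
track_clones <- function(selected, naive, tcm, tem, key = c("aa", "aa_v")) {
  key <- match.arg(key)
  keyof <- function(df) {
    if (key == "aa") df$aa_seq else paste(df$aa_seq, df$v_gene, sep = "|")
  }
  agg <- function(rep) aggregate_clonotypes(rep, key)
  nv <- agg(naive); tc <- agg(tcm); te <- agg(tem)
  k <- keyof(selected)
  tcm_templates <- setNames(tc$templates, keyof(tc))[k]
  tem_templates <- setNames(te$templates, keyof(te))[k]
  tcm_templates[is.na(tcm_templates)] <- 0L
  tem_templates[is.na(tem_templates)] <- 0L
  found_tcm <- tcm_templates > 0
  found_tem <- tem_templates > 0
  partition <- case_when(
    found_tcm & found_tem ~ "BOTH",
    found_tcm ~ "TCM_ONLY",
    found_tem ~ "TEM_ONLY",
    .default = "NONE"
  )
  tibble(
    donor_id = selected$donor_id,
    aa_seq = selected$aa_seq,
    v_gene = selected$v_gene %||% NA_character_,
    j_gene = selected$j_gene %||% NA_character_,
    found_naive = k %in% keyof(nv),
    found_tcm = unname(found_tcm),
    found_tem = unname(found_tem),
    templates_tcm = as.integer(unname(tcm_templates)),
    templates_tem = as.integer(unname(tem_templates)),
    memory_templates = as.integer(unname(tcm_templates + tem_templates)),
    memory_partition = partition
  )
}

#' Naive vs memory overlap fractions of selected clones
#'
#' Per donor, the percentage of selected clones found in the naive pool
#' and in the memory pool (TCM or TEM); across donors, means with
#' standard errors and a two-sided Mann-Whitney comparison of the
#' per-donor naive vs memory percentages.
#'
#' @param tracking Tibble stacking [track_clones()] results for one or
#'   more donors (unique clonotypes, one row per selected clone).
#' @return List with `per_donor` (tibble of `n_selected`, `pct_naive`,
#'   `pct_memory`), `summary` (means, SEMs, fold ratio) and `mw_p`.
#' @export
overlap_fractions <- function(tracking) {
  if (nrow(tracking) == 0) stop_empty("no tracking results supplied")
  per_donor <- tracking |>
    group_by(.data$donor_id) |>
    summarise(
      n_selected = n(),
      pct_naive = 100 * mean(.data$found_naive),
      pct_memory = 100 * mean(.data$found_tcm | .data$found_tem),
      .groups = "drop"
    )
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  summary <- tibble(
    mean_pct_naive = mean(per_donor$pct_naive),
    sem_pct_naive = sem(per_donor$pct_naive),
    mean_pct_memory = mean(per_donor$pct_memory),
    sem_pct_memory = sem(per_donor$pct_memory),
    memory_naive_ratio = mean(per_donor$pct_memory) /
      max(mean(per_donor$pct_naive), .Machine$double.eps)
  )
  mw_p <- if (nrow(per_donor) > 1 &&
              !all(per_donor$pct_naive == per_donor$pct_memory)) {
    suppressWarnings(wilcox.test(per_donor$pct_naive,
                                 per_donor$pct_memory)$p.value)
  } else 1
  list(per_donor = per_donor, summary = summary, mw_p = mw_p)
}

#' Expansion summary of memory-affiliated clones
#'
#' Per donor: the fraction of memory-affiliated clones with more than one
#' memory template, and a ranked table of the clones whose memory copy
#' number exceeds `cutoff`.
#'
#' @param tracking Stacked [track_clones()] results.
#' @param cutoff Strict copy-number cutoff for the top-clone table
#'   (default `> 6`).
#' @return List with `per_donor` (tibble `n_memory`,
#'   `expanded_fraction`) and `top_clones` (donor, V gene, CDR3, J gene,
#'   copies, ranked by copies).
#' @export
memory_expansion_summary <- function(tracking, cutoff = 6) {
  mem <- tracking[tracking$memory_partition != "NONE", , drop = FALSE]
  if (nrow(mem) == 0) stop_empty("no memory-affiliated clones supplied")
  per_donor <- mem |>
    group_by(.data$donor_id) |>
    summarise(n_memory = n(),
              expanded_fraction = mean(.data$memory_templates > 1),
              .groups = "drop")
  top <- mem[mem$memory_templates > cutoff, , drop = FALSE] |>
    select("donor_id", "v_gene", "aa_seq", "j_gene",
           copies = "memory_templates") |>
    arrange(desc(.data$copies), .data$aa_seq)
  list(per_donor = per_donor, top_clones = top)
}

#' Public/private labels for selected clones across donors
#'
#' A clone is public when its key occurs in the selected sets of at
#' least two donors; otherwise private.
#'
#' @param selected Tibble stacking selected clones across donors
#'   (`donor_id`, `aa_seq`, optionally `v_gene`).
#' @param key Matching key, `"aa"` or `"aa_v"`.
#' @return Input with `n_donors` and `public` columns added.
#' @export
clone_publicity <- function(selected, key = c("aa", "aa_v")) {
  key <- match.arg(key)
  if (length(unique(selected$donor_id)) < 2) {
    stop_config("clone_publicity() needs selected sets from >= 2 donors")
  }
  k <- if (key == "aa") selected$aa_seq else
    paste(selected$aa_seq, selected$v_gene, sep = "|")
  donors_per_key <- tapply(selected$donor_id, k,
                           function(d) length(unique(d)))
  n_donors <- as.integer(donors_per_key[k])
  mutate(selected, n_donors = n_donors, public = n_donors >= 2)
}
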