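#' Trim a CDR3 to its interior (epitope-contact) segment
#'
#' Removes the first `head` and last `tail` residues, the convention that
#' discards the conserved Cys-anchored start and Phe-anchored end of the
#' CDR3 so motif search concentrates on the hypervariable interior.
#' Sequences shorter than `head + tail + 1` cannot contribute an interior
#' and yield `NA` (they are excluded from motif analysis).
#'
#' @param aa_seq Character vector of CDR3 amino-acid sequences.
#' @param head,tail Number of residues removed from each end.
#' @return Character vector of interiors, `NA` for excluded sequences.
#' @export
trim_cdr3 <- function(aa_seq, head = 3, tail = 2) {
  n <- nchar(aa_seq)
  out <- substr(aa_seq, head + 1, n - tail)
  out[n < head + tail + 1] <- NA_character_
  out
}

# All k-mers of each string, counted once per string; returns a tibble
# (kmer, n_seqs) over the unique input sequences.
kmer_presence <- function(seqs, k) {
  seqs <- unique(seqs[!is.na(seqs) & nchar(seqs) >= k])
  if (length(seqs) == 0) return(tibble(kmer = character(), n_seqs = integer()))
  lens <- nchar(seqs)
  ids <- km <- vector("list", max(lens) - k + 1)
  for (i in seq_along(ids)) {
    ok <- which(lens >= i + k - 1)
    ids[[i]] <- ok
    km[[i]] <- substring(seqs[ok], i, i + k - 1)
  }
  id <- unlist(ids, use.names = FALSE)
  km <- unlist(km, use.names = FALSE)
  # count each k-mer once per sequence even if it occurs at several
  # offsets; the (sequence, k-mer) pair is encoded as a double, which is
  # exact here and much faster to deduplicate than pasted strings
  ukm <- unique(km)
  kmi <- match(km, ukm)
  key <- (as.numeric(id) - 1) * length(ukm) + kmi
  keep <- !duplicated(key)
  tibble(kmer = ukm,
         n_seqs = tabulate(kmi[keep], nbins = length(ukm)))
}

#' Build a reference set of trimmed CDR3s
#'
#' A reference set (typically naive CDR3s from healthy donors, or the
#' simulated naive repertoires) with a precomputed k-mer presence index
#' used to assess motif enrichment. Input sequences may be full CDR3s
#' (trimmed here) or pre-trimmed interiors (`trim = FALSE`).
#'
#' @param seqs Character vector of CDR3s.
#' @param trim Whether to apply [trim_cdr3()] first.
#' @param head,tail Trimming offsets.
#' @param k_values k-mer sizes to index.
#' @return A list of class `cdr3_reference`: unique trimmed sequences,
#'   their count, and a per-k presence index.
#' @export
reference_set <- function(seqs, trim = TRUE, head = 3, tail = 2,
                          k_values = 2:4) {
  if (length(seqs) == 0) stop_empty("reference set is empty")
  trimmed <- if (trim) trim_cdr3(seqs, head, tail) else seqs
  trimmed <- unique(trimmed[!is.na(trimmed)])
  if (length(trimmed) == 0) stop_empty("reference set is empty after trimming")
  index <- lapply(k_values, function(k) kmer_presence(trimmed, k))
  names(index) <- as.character(k_values)
  structure(list(seqs = trimmed, n = length(trimmed), index = index),
            class = "cdr3_reference")
}

#' Locally enriched k-mers in a CDR3 sample
#'
#' For each k-mer of each size, compares its sample occurrence rate
#' (fraction of unique sample interiors containing it) with its rate in
#' the reference (with one pseudo-occurrence when absent there), keeping
#' k-mers whose fold enrichment reaches `min_fold` for that k, whose
#' two-sided Fisher exact p-value (on containing/non-containing counts)
#' is below `p_max`, and which occur in at least `min_unique` distinct
#' sample CDR3s. The per-k fold defaults (1000/100/10 for k = 2/3/4)
#' compensate for the rapidly growing background rate of short k-mers.
#'
#' @param sample_seqs Character vector of trimmed sample interiors
#'   (duplicates collapse to unique sequences).
#' @param reference A [reference_set()].
#' @param k_values k-mer sizes.
#' @param min_fold Named (by k) or positional minimum fold per k.
#' @param p_max Fisher p-value cutoff.
#' @param min_unique Minimum distinct sample CDR3s containing the k-mer.
#' @return Tibble `kmer`, `k`, `n_sample`, `n_reference`, `fold`,
#'   `fisher_p`.
#' @export
local_motif_enrichment <- function(sample_seqs, reference, k_values = 2:4,
                                   min_fold = c(`2` = 1000, `3` = 100,
                                                `4` = 10),
                                   p_max = 0.05, min_unique = 3) {
  stopifnot(inherits(reference, "cdr3_reference"))
  sample_u <- unique(sample_seqs[!is.na(sample_seqs)])
  n_s <- length(sample_u)
  if (n_s == 0) stop_empty("no sample sequences for local motif search")
  out <- lapply(seq_along(k_values), function(i) {
    k <- k_values[i]
    fold_min <- if (!is.null(names(min_fold))) min_fold[[as.character(k)]]
      else min_fold[i]
    samp <- kmer_presence(sample_u, k)
    samp <- samp[samp$n_seqs >= min_unique, , drop = FALSE]
    if (nrow(samp) == 0) return(NULL)
    ref_idx <- reference$index[[as.character(k)]]
    if (is.null(ref_idx)) ref_idx <- kmer_presence(reference$seqs, k)
    n_ref <- unname(setNames(ref_idx$n_seqs, ref_idx$kmer)[samp$kmer])
    n_ref[is.na(n_ref)] <- 0L
    rate_s <- samp$n_seqs / n_s
    rate_r <- pmax(n_ref, 1L) / reference$n
    fold <- rate_s / rate_r
    keep1 <- fold >= fold_min
    if (!any(keep1)) return(NULL)
    samp <- samp[keep1, , drop = FALSE]
    n_ref <- n_ref[keep1]
    fold <- fold[keep1]
    p <- fisher_exact_p(samp$n_seqs, n_ref,
                        n_s - samp$n_seqs, reference$n - n_ref)
    keep2 <- p < p_max
    tibble(kmer = samp$kmer[keep2], k = k,
           n_sample = samp$n_seqs[keep2],
           n_reference = as.integer(n_ref[keep2]),
           fold = fold[keep2], fisher_p = p[keep2])
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(kmer = character(), k = integer(), n_sample = integer(),
                  n_reference = integer(), fold = double(),
                  fisher_p = double())
  }
  arrange(res, .data$fisher_p, desc(.data$fold), .data$kmer)
}

#' Global single-mismatch convergence groups
#'
#' Groups equal-length trimmed CDR3s that differ at no more than one
#' position; each group's pattern is the shared string with `%` at the
#' variable position (`%` matches exactly one arbitrary residue). A CDR3
#' may belong to several groups; groups with fewer than `min_unique`
#' distinct members are dropped.
#'
#' @param sample_seqs Character vector of trimmed interiors.
#' @param min_unique Minimum distinct member CDR3s per group.
#' @return Tibble `pattern`, `n_unique_cdr3`, `members` (list column of
#'   member interiors).
#' @export
global_convergence <- function(sample_seqs, min_unique = 2) {
  seqs <- unique(sample_seqs[!is.na(sample_seqs)])
  empty <- tibble(pattern = character(), n_unique_cdr3 = integer(),
                  members = list())
  if (length(seqs) < min_unique) return(empty)
  rows <- list()
  for (L in sort(unique(nchar(seqs)))) {
    sl <- seqs[nchar(seqs) == L]
    if (length(sl) < 2) next
    for (pos in seq_len(L)) {
      masked <- paste0(substr(sl, 1, pos - 1), "%",
                       substr(sl, pos + 1, L))
      dup <- duplicated(masked) | duplicated(masked, fromLast = TRUE)
      if (!any(dup)) next
      groups <- split(sl[dup], masked[dup])
      groups <- groups[lengths(groups) >= max(2, min_unique)]
      if (length(groups) == 0) next
      rows[[length(rows) + 1]] <- tibble(
        pattern = names(groups),
        n_unique_cdr3 = unname(lengths(groups)),
        members = unname(groups))
    }
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows) |> arrange(.data$pattern)
}

#' Match trimmed interiors against a motif pattern
#'
#' `LOCAL` patterns (no wildcard) match by substring containment;
#' `GLOBAL` patterns (one `%` wildcard) require equal length and
#' agreement at every non-wildcard position.
#'
#' @param trimmed Character vector of trimmed interiors (may contain
#'   `NA`).
#' @param pattern Motif pattern string.
#' @param kind `"LOCAL"` or `"GLOBAL"`.
#' @return Logical vector.
#' @export
motif_match <- function(trimmed, pattern, kind = c("LOCAL", "GLOBAL")) {
  kind <- match.arg(kind)
  out <- logical(length(trimmed))
  ok <- !is.na(trimmed)
  if (kind == "LOCAL") {
    out[ok] <- stringr::str_detect(trimmed[ok], stringr::fixed(pattern))
  } else {
    # patterns are amino-acid letters plus '%'; no regex metacharacters
    rx <- paste0("^", gsub("%", ".", pattern, fixed = TRUE), "$")
    out[ok] <- nchar(trimmed[ok]) == nchar(pattern) &
      grepl(rx, trimmed[ok])
  }
  out
}

#' Assemble specificity groups from local k-mers and global groups
#'
#' A `LOCAL` group collects every sample record whose trimmed interior
#' contains the k-mer; `GLOBAL` groups pass through with their members
#' re-annotated. Records are annotated with donor, compartment, template
#' count and frequency. Groups with identical member CDR3 sets are
#' deduplicated, keeping the more specific pattern (longer, then fewer
#' wildcards, then lexicographically first); groups with fewer than
#' `min_unique` distinct member CDR3s are dropped.
#'
#' @param local_kmers Output of [local_motif_enrichment()] (or a tibble
#'   with a `kmer` column).
#' @param global_groups Output of [global_convergence()].
#' @param sample_records Tibble with `donor_id`, `compartment`,
#'   `aa_seq`, `templates`, `frequency` for every sample record.
#' @param head,tail Trimming offsets (must match discovery).
#' @param min_unique Minimum distinct member CDR3s.
#' @return Tibble `pattern`, `kind`, `n_unique_cdr3`, `members` (list
#'   column of member-record tibbles with a `trimmed` column).
#' @export
build_specificity_groups <- function(local_kmers, global_groups,
                                     sample_records, head = 3, tail = 2,
                                     min_unique = 2) {
  recs <- mutate(sample_records,
                 trimmed = trim_cdr3(.data$aa_seq, head, tail))
  recs <- recs[!is.na(recs$trimmed), , drop = FALSE]
  specs <- bind_rows(
    if (!is.null(local_kmers) && nrow(local_kmers) > 0)
      tibble(pattern = local_kmers$kmer, kind = "LOCAL"),
    if (!is.null(global_groups) && nrow(global_groups) > 0)
      tibble(pattern = global_groups$pattern, kind = "GLOBAL")
  )
  if (is.null(specs) || nrow(specs) == 0) {
    return(tibble(pattern = character(), kind = character(),
                  n_unique_cdr3 = integer(), members = list()))
  }
  groups <- lapply(seq_len(nrow(specs)), function(i) {
    hit <- motif_match(recs$trimmed, specs$pattern[i], specs$kind[i])
    members <- recs[hit, , drop = FALSE]
    tibble(pattern = specs$pattern[i], kind = specs$kind[i],
           n_unique_cdr3 = length(unique(members$aa_seq)),
           members = list(members))
  })
  out <- bind_rows(groups)
  out <- out[out$n_unique_cdr3 >= min_unique, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  # dedup identical member CDR3 sets: longer pattern, fewer wildcards,
  # then lexicographic
  member_key <- vapply(out$members, function(m)
    paste(sort(unique(m$aa_seq)), collapse = "|"), character(1))
  n_wild <- stringr::str_count(out$pattern, stringr::fixed("%"))
  ord <- order(member_key, -nchar(out$pattern), n_wild, out$pattern)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(member_key[ord]), , drop = FALSE]
  arrange(out, desc(.data$n_unique_cdr3), .data$pattern)
}

#' Fisher enrichment of a specificity group against the reference
#'
#' Two-sided Fisher exact test on the 2x2 table of unique CDR3s matching
#' vs not matching the motif, in the sample vs the reference.
#'
#' @param groups Output of [build_specificity_groups()].
#' @param n_sample_unique Number of unique trimmed CDR3s in the sample.
#' @param reference A [reference_set()].
#' @return `groups` with `n_reference` and `fisher_ref_p` columns added.
#' @export
reference_enrichment_test <- function(groups, n_sample_unique, reference) {
  stopifnot(inherits(reference, "cdr3_reference"))
  if (nrow(groups) == 0) {
    return(mutate(groups, n_reference = integer(), fisher_ref_p = double()))
  }
  n_ref_match <- vapply(seq_len(nrow(groups)), function(i) {
    sum(motif_match(reference$seqs, groups$pattern[i], groups$kind[i]))
  }, numeric(1))
  a <- groups$n_unique_cdr3
  b <- n_ref_match
  p <- fisher_exact_p(a, b, n_sample_unique - a, reference$n - b)
  mutate(groups, n_reference = as.integer(n_ref_match), fisher_ref_p = p)
}

#' Permutation expansion score for specificity groups
#'
#' Tests whether a group's member clonotypes are more clonally expanded
#' (template count >= 2) than random same-size clonotype samples from
#' the whole dataset. The null statistic for a draw of `m` clonotypes
#' without replacement from `N` of which `K` are expanded is exactly
#' hypergeometric, so the `n_perm` null draws are generated as
#' hypergeometric variates; the p-value is
#' `(1 + #(null >= observed)) / (n_perm + 1)`, reproducible for a fixed
#' seed.
#'
#' @param groups Output of [build_specificity_groups()] (members carry
#'   `donor_id`, `compartment`, `aa_seq`, `templates`).
#' @param dataset_clonotypes Tibble of all dataset clonotype units
#'   (`donor_id`, `compartment`, `aa_seq`, `templates`).
#' @param n_perm Number of null draws (>= 100).
#' @param seed Seed for the draws.
#' @return `groups` with `n_expanded` and `expansion_p` columns added.
#' @export
expansion_score <- function(groups, dataset_clonotypes, n_perm = 1000,
                            seed = 1) {
  if (n_perm < 100) stop_config("n_perm must be >= 100")
  if (nrow(groups) == 0) {
    return(mutate(groups, n_expanded = integer(), expansion_p = double()))
  }
  N <- nrow(dataset_clonotypes)
  K <- sum(dataset_clonotypes$templates >= 2)
  withr::with_seed(seed, {
    res <- lapply(seq_len(nrow(groups)), function(i) {
      m <- nrow(groups$members[[i]])
      k_obs <- sum(groups$members[[i]]$templates >= 2)
      nulls <- rhyper(n_perm, K, N - K, min(m, N))
      p <- (1 + sum(nulls >= k_obs)) / (n_perm + 1)
      c(k_obs, p)
    })
  })
  mat <- do.call(rbind, res)
  mutate(groups, n_expanded = as.integer(mat[, 1]), expansion_p = mat[, 2])
}

#' Discover specificity groups in a set of repertoires
#'
#' Convenience wrapper running the full motif-discovery chain: trim the
#' pooled sample interiors, find locally enriched k-mers against the
#' reference, find global single-mismatch groups, assemble and
#' deduplicate specificity groups, and attach reference-enrichment and
#' expansion statistics.
#'
#' @param reps List of productive-filtered `tcr_repertoire`s forming the
#'   sample (typically all donors' `AIM_POS` and `AIM_NEG`).
#' @param reference A [reference_set()].
#' @param head,tail Trimming offsets.
#' @param k_values,min_fold,p_max,min_unique_local Local-channel
#'   parameters, see [local_motif_enrichment()].
#' @param min_unique_group Minimum distinct member CDR3s per group.
#' @param n_perm,seed Expansion-score parameters.
#' @return Tibble of specificity groups with `fisher_ref_p`,
#'   `n_expanded`, `expansion_p` and a `members` list column.
#' @export
discover_motifs <- function(reps, reference, head = 3, tail = 2,
                            k_values = 2:4,
                            min_fold = c(`2` = 1000, `3` = 100, `4` = 10),
                            p_max = 0.05, min_unique_local = 3,
                            min_unique_group = 2, n_perm = 1000, seed = 1) {
  records <- bind_rows(lapply(reps, function(r) {
    cl <- aggregate_clonotypes(r, "aa")
    tibble(donor_id = r$donor_id, compartment = r$compartment,
           aa_seq = cl$aa_seq, templates = cl$templates,
           frequency = cl$frequency)
  }))
  trimmed <- trim_cdr3(records$aa_seq, head, tail)
  sample_u <- unique(trimmed[!is.na(trimmed)])
  local <- local_motif_enrichment(sample_u, reference, k_values, min_fold,
                                  p_max, min_unique_local)
  glob <- global_convergence(sample_u, min_unique_group)
  groups <- build_specificity_groups(local, glob, records, head, tail,
                                     min_unique_group)
  groups <- reference_enrichment_test(groups, length(sample_u), reference)
  expansion_score(groups, records, n_perm, seed)
}
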