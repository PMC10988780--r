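#' Compartment fold change and Poisson-rate p-value per specificity group
#'
#' For each group, sums member templates in two compartments (e.g.
#' `AIM_POS` vs `AIM_NEG`), converts to rates over the compartment
#' template totals, and computes `log2((rateA + eps) / (rateB + eps))`
#' with the pseudo-rate `eps = 1 / max(totalA, totalB)` (so one-sided
#' zero counts stay finite), plus the exact two-rate Poisson p-value
#' ([poisson_rate_p()]). Groups with zero members in both compartments
#' get `log2_fold = 0`, `p = 1` and are flagged degenerate.
#'
#' @param groups Specificity groups with a `members` list column whose
#'   tibbles carry `compartment` and `templates`.
#' @param totals Named numeric vector of per-compartment template totals
#'   (must include both labels).
#' @param labels Length-2 character vector `(A, B)`; the fold is A over
#'   B.
#' @param epsilon Pseudo-rate; default `1 / max(totals[labels])`.
#' @return `groups` with `sum_templates_a`, `sum_templates_b`,
#'   `log2_fold`, `poisson_p`, `degenerate` columns added.
#' @export
motif_fold_and_poisson <- function(groups, totals,
                                   labels = c("AIM_POS", "AIM_NEG"),
                                   epsilon = NULL) {
  stopifnot(length(labels) == 2, all(labels %in% names(totals)))
  tA <- totals[[labels[1]]]
  tB <- totals[[labels[2]]]
  if (tA <= 0 || tB <= 0) stop_config("compartment totals must be positive")
  eps <- epsilon %||% (1 / max(tA, tB))
  if (nrow(groups) == 0) {
    return(mutate(groups, sum_templates_a = integer(),
                  sum_templates_b = integer(), log2_fold = double(),
                  poisson_p = double(), degenerate = logical()))
  }
  cA <- vapply(groups$members, function(m)
    sum(m$templates[m$compartment == labels[1]]), numeric(1))
  cB <- vapply(groups$members, function(m)
    sum(m$templates[m$compartment == labels[2]]), numeric(1))
  both_zero <- cA + cB == 0
  lf <- log2((cA / tA + eps) / (cB / tB + eps))
  lf[both_zero] <- 0
  p <- poisson_rate_p(cA, cB, tA, tB)
  p[both_zero] <- 1
  mutate(groups,
         sum_templates_a = as.integer(cA),
         sum_templates_b = as.integer(cB),
         log2_fold = lf, poisson_p = p, degenerate = both_zero)
}

#' Select reactive-compartment-enriched (APOB+) motifs
#'
#' Keeps expansion-significant groups whose fold and Poisson statistics
#' (computed with `(A, B) = (AIM_POS, AIM_NEG)`) pass the reactive
#' direction cuts: `log2_fold >= log2fold_min` and
#' `-log10(poisson_p) >= neg_log10p_min`. Setting both cuts to zero
#' returns all expansion-significant groups.
#'
#' @param enrichments Output of [motif_fold_and_poisson()] carrying
#'   `expansion_p`.
#' @param log2fold_min Minimum log2 fold in the reactive direction.
#' @param neg_log10p_min Minimum `-log10` Poisson p.
#' @param expansion_p_max Maximum expansion score p.
#' @return The selected subset, ranked by `poisson_p` then fold.
#' @export
select_apob_motifs <- function(enrichments, log2fold_min = 2,
                               neg_log10p_min = 5, expansion_p_max = 0.05) {
  sel <- enrichments |>
    filter(.data$expansion_p < expansion_p_max,
           .data$log2_fold >= log2fold_min,
           -log10(pmax(.data$poisson_p, .Machine$double.xmin)) >=
             neg_log10p_min)
  arrange(sel, .data$poisson_p, desc(.data$log2_fold), .data$pattern)
}

# Match ex-vivo repertoires against motifs; returns one row per matching
# (motif, donor, compartment, aa_seq) with templates and frequency.
match_exvivo <- function(motifs, exvivo_reps, head = 3, tail = 2) {
  recs <- bind_rows(lapply(exvivo_reps, function(r)
    mutate(aggregate_clonotypes(r), donor_id = r$donor_id,
           compartment = r$compartment)))
  recs$trimmed <- trim_cdr3(recs$aa_seq, head, tail)
  recs <- recs[!is.na(recs$trimmed), , drop = FALSE]
  hits <- lapply(seq_len(nrow(motifs)), function(i) {
    hit <- motif_match(recs$trimmed, motifs$pattern[i], motifs$kind[i])
    if (!any(hit)) return(NULL)
    mutate(recs[hit, c("donor_id", "compartment", "aa_seq", "v_gene",
                       "j_gene", "templates", "frequency")],
           pattern = motifs$pattern[i])
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble(donor_id = character(), compartment = character(),
                  aa_seq = character(), v_gene = character(),
                  j_gene = character(), templates = integer(),
                  frequency = double(), pattern = character())
  }
  out
}

#' Classify reactive motifs by ex-vivo naive/memory affiliation
#'
#' Assigns ex-vivo CDR3s (naive, TCM, TEM clonotypes from each donor) to
#' each reactive motif by pattern matching on trimmed interiors, then
#' classifies each motif as `NAIVE_ONLY`, `MEMORY_ONLY`, `BOTH` or
#' `ABSENT`. For `BOTH` motifs, memory-vs-naive enrichment (fold of
#' summed memory vs naive templates over pool totals, exact Poisson p)
#' decides `memory_enriched`; a motif is memory-affiliated when it is
#' `MEMORY_ONLY` or `BOTH` with significant memory enrichment.
#' `subset_detail` records whether memory matches come from TCM only,
#' TEM only, or both.
#'
#' @param motifs Selected motif tibble (`pattern`, `kind`).
#' @param exvivo_reps List of productive-filtered `NAIVE`/`TCM`/`TEM`
#'   repertoires for all donors.
#' @param head,tail Trimming offsets (must match discovery).
#' @param log2fold_min,p_max Memory-enrichment cuts for `BOTH` motifs.
#' @return List with `affiliation` (tibble per motif: `category`,
#'   `memory_enriched`, `memory_affiliated`, `subset_detail`,
#'   `donors_memory`, memory fold/p) and `matches` (per-motif ex-vivo
#'   match records).
#' @export
classify_affiliation <- function(motifs, exvivo_reps, head = 3, tail = 2,
                                 log2fold_min = 1, p_max = 0.05) {
  matches <- match_exvivo(motifs, exvivo_reps, head, tail)
  totals <- vapply(split(exvivo_reps, vapply(exvivo_reps, function(r)
    r$compartment, character(1))), function(rs)
      sum(vapply(rs, function(r) r$total_templates, numeric(1))),
    numeric(1))
  t_naive <- totals[["NAIVE"]]
  t_mem <- sum(totals[MEMORY_COMPARTMENTS])
  eps <- 1 / max(t_naive, t_mem)
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    m <- matches[matches$pattern == motifs$pattern[i], , drop = FALSE]
    in_naive <- any(m$compartment == "NAIVE")
    mem <- m[m$compartment %in% MEMORY_COMPARTMENTS, , drop = FALSE]
    in_mem <- nrow(mem) > 0
    category <- if (!in_naive && !in_mem) "ABSENT"
      else if (in_naive && !in_mem) "NAIVE_ONLY"
      else if (!in_naive && in_mem) "MEMORY_ONLY"
      else "BOTH"
    c_mem <- sum(mem$templates)
    c_naive <- sum(m$templates[m$compartment == "NAIVE"])
    mem_fold <- if (c_mem + c_naive == 0) 0 else
      log2((c_mem / t_mem + eps) / (c_naive / t_naive + eps))
    mem_p <- if (c_mem + c_naive == 0) 1 else
      poisson_rate_p(c_mem, c_naive, t_mem, t_naive)
    memory_enriched <- category == "BOTH" && mem_fold >= log2fold_min &&
      mem_p < p_max
    subset_detail <- if (!in_mem) "NA" else {
      has_tcm <- any(mem$compartment == "TCM")
      has_tem <- any(mem$compartment == "TEM")
      if (has_tcm && has_tem) "BOTH" else if (has_tcm) "TCM_ONLY"
        else "TEM_ONLY"
    }
    tibble(pattern = motifs$pattern[i], kind = motifs$kind[i],
           category = category,
           memory_log2_fold = mem_fold, memory_poisson_p = mem_p,
           memory_enriched = memory_enriched,
           memory_affiliated = category == "MEMORY_ONLY" ||
             (category == "BOTH" && memory_enriched),
           subset_detail = subset_detail,
           donors_memory = list(sort(unique(mem$donor_id))),
           n_donors_memory = length(unique(mem$donor_id)))
  })
  list(affiliation = bind_rows(rows), matches = matches)
}

#' Cross-donor motif sharing network
#'
#' Nodes are (donor, memory subset) pairs with at least one CDR3
#' matching at least one memory-affiliated motif; each motif's
#' "connection" is the set of nodes containing matches, and every node
#' pair within a connection of two or more nodes contributes to an edge
#' whose weight is the number of distinct shared motifs.
#'
#' @param affiliation Affiliation tibble (from [classify_affiliation()])
#'   restricted, by the caller or internally, to memory-affiliated
#'   motifs.
#' @param matches Ex-vivo match records from [classify_affiliation()].
#' @return A list of class `sharing_network`: `nodes`, `edges`
#'   (`node_a`, `node_b`, `weight`, `motifs` list), `connections`
#'   (per-motif node sets and per-node summed frequencies).
#' @export
build_sharing_network <- function(affiliation, matches) {
  mem_motifs <- affiliation$pattern[affiliation$memory_affiliated]
  mm <- matches[matches$pattern %in% mem_motifs &
                  matches$compartment %in% MEMORY_COMPARTMENTS, ,
                drop = FALSE]
  if (length(unique(mm$donor_id)) < 2 && nrow(mm) > 0) {
    # a single donor yields nodes but no edges; allowed downstream
  }
  mm$node <- paste(mm$donor_id, mm$compartment, sep = ".")
  nodes <- mm |>
    group_by(node = .data$node, donor_id = .data$donor_id,
             subset = .data$compartment) |>
    summarise(n_motifs = length(unique(.data$pattern)), .groups = "drop") |>
    arrange(.data$node)
  connections <- mm |>
    group_by(pattern = .data$pattern) |>
    summarise(nodes = list(sort(unique(.data$node))),
              n_nodes = length(unique(.data$node)),
              freq_by_node = list(
                tapply(.data$frequency, .data$node, sum)),
              .groups = "drop")
  edge_rows <- lapply(seq_len(nrow(connections)), function(i) {
    ns <- connections$nodes[[i]]
    if (length(ns) < 2) return(NULL)
    pairs <- utils::combn(ns, 2)
    tibble(node_a = pairs[1, ], node_b = pairs[2, ],
           pattern = connections$pattern[i])
  })
  edges <- bind_rows(edge_rows)
  if (nrow(edges) == 0) {
    edges <- tibble(node_a = character(), node_b = character(),
                    weight = integer(), motifs = list())
  } else {
    edges <- edges |>
      group_by(.data$node_a, .data$node_b) |>
      summarise(weight = length(unique(.data$pattern)),
                motifs = list(sort(unique(.data$pattern))),
                .groups = "drop")
  }
  structure(list(nodes = nodes, edges = edges, connections = connections),
            class = "sharing_network")
}

#' Convert a sharing network to an igraph object
#'
#' @param network A [build_sharing_network()] result.
#' @return An undirected `igraph` graph with edge `weight` attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "sharing_network"))
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("node_a", "node_b", "weight")],
    directed = FALSE,
    vertices = network$nodes[, c("node", "donor_id", "subset", "n_motifs")])
  g
}

#' Write a sharing network as GraphML plus a plain edge list
#'
#' @param network A [build_sharing_network()] result.
#' @param graphml_path,edges_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_sharing_network <- function(network, graphml_path = NULL,
                                  edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(network), graphml_path,
                        format = "graphml")
  }
  if (!is.null(edges_path)) {
    readr::write_tsv(network$edges[, c("node_a", "node_b", "weight")],
                     edges_path, progress = FALSE)
  }
  invisible(c(graphml_path, edges_path))
}

#' Call public motifs shared across most donors' memory pools
#'
#' A memory-affiliated motif is public when its memory matches span
#' strictly more than `donor_min_fraction` of the donors (with six
#' donors and the default 0.8, that is at least five donors). Reports
#' per-donor, per-subset summed frequencies of the matching memory
#' CDR3s.
#'
#' @param affiliation Affiliation tibble from [classify_affiliation()].
#' @param matches Ex-vivo match records from [classify_affiliation()].
#' @param n_donors Total number of donors in the cohort.
#' @param donor_min_fraction Publicity threshold (strict `>`).
#' @return List with `public` (ranked motif tibble) and `frequencies`
#'   (per motif x donor x subset summed frequency of matching memory
#'   CDR3s).
#' @export
public_motifs <- function(affiliation, matches, n_donors,
                          donor_min_fraction = 0.8) {
  mem <- affiliation[affiliation$memory_affiliated, , drop = FALSE]
  pub <- mem[mem$n_donors_memory > donor_min_fraction * n_donors, ,
             drop = FALSE]
  pub <- arrange(pub, desc(.data$n_donors_memory), .data$pattern)
  freqs <- matches[matches$pattern %in% pub$pattern &
                     matches$compartment %in% MEMORY_COMPARTMENTS, ,
                   drop = FALSE]
  freqs <- if (nrow(freqs) == 0) {
    tibble(pattern = character(), donor_id = character(),
           subset = character(), sum_frequency = double(),
           n_cdr3 = integer())
  } else {
    freqs |>
      group_by(pattern = .data$pattern, donor_id = .data$donor_id,
               subset = .data$compartment) |>
      summarise(sum_frequency = sum(.data$frequency), n_cdr3 = n(),
                .groups = "drop")
  }
  list(public = pub, frequencies = freqs)
}

#' Position frequency matrix of motif-matching CDR3s
#'
#' Builds a column-stochastic residue-by-position frequency matrix from
#' the CDR3s matching a motif, consumable by any sequence-logo renderer.
#' For `GLOBAL` motifs the sequences are equal length and align
#' directly; for `LOCAL` motifs they are anchored at the first motif
#' occurrence, and each column's frequencies are computed over the
#' sequences covering that position.
#'
#' @param seqs Character vector of matching CDR3s (or trimmed
#'   interiors).
#' @param pattern Motif pattern.
#' @param kind `"LOCAL"` or `"GLOBAL"`.
#' @return A numeric matrix, rows the 20 amino acids, columns positions
#'   (for `LOCAL`, positions relative to the motif start, which is
#'   position 1); every column sums to 1. The attribute `"n_seqs"`
#'   carries the number of sequences used.
#' @export
position_frequency_matrix <- function(seqs, pattern,
                                      kind = c("LOCAL", "GLOBAL")) {
  kind <- match.arg(kind)
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0) stop_empty("no sequences supplied for the matrix")
  if (kind == "GLOBAL") {
    if (length(unique(nchar(seqs))) != 1) {
      stop_config("GLOBAL position matrices need equal-length sequences")
    }
    offsets <- rep(0L, length(seqs))
  } else {
    starts <- regexpr(pattern, seqs, fixed = TRUE)
    if (any(starts < 0)) stop_config("a sequence does not contain the motif")
    offsets <- as.integer(starts) - 1L
  }
  rel_start <- 1L - offsets            # position of residue 1 relative to anchor
  rel_end <- nchar(seqs) - offsets
  positions <- min(rel_start):max(rel_end)
  mat <- matrix(0, nrow = length(AA20), ncol = length(positions),
                dimnames = list(AA20, positions))
  chars <- strsplit(seqs, "")
  for (i in seq_along(seqs)) {
    pos <- seq_len(nchar(seqs[i])) - offsets[i]
    idx <- match(pos, positions)
    aa <- match(chars[[i]], AA20)
    ok <- !is.na(aa)
    for (j in which(ok)) mat[aa[j], idx[j]] <- mat[aa[j], idx[j]] + 1
  }
  cs <- colSums(mat)
  keep <- cs > 0
  mat <- sweep(mat[, keep, drop = FALSE], 2, cs[keep], "/")
  attr(mat, "n_seqs") <- length(seqs)
  mat
}
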