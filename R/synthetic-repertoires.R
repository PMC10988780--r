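#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort of paired antigen-reactive (`AIM_POS`) /
#' non-reactive (`AIM_NEG`) sorted repertoires plus unenriched ex-vivo
#' `NAIVE`, `TCM` and `TEM` repertoires per donor, with planted reactive
#' clone families carrying shared CDR3 motifs. Defaults define the study
#' conditions used throughout the package's validation: six donors,
#' desk-scale compartment sizes with a realistic 3:1 TCM:TEM ratio, a
#' Zipf-like background clone-size law capped so the non-reactive
#' compartment carries no strongly expanded clone, and ten planted motif
#' families of five member clones each, 20-fold enriched in `AIM_POS`.
#'
#' @param n_donors Number of donors.
#' @param templates_per_compartment Named integer vector of template
#'   totals for `AIM_POS`, `AIM_NEG`, `NAIVE`, `TCM`, `TEM`.
#' @param clone_size_shape Power-law exponent (> 1) for background clone
#'   sizes; larger values give flatter repertoires.
#' @param max_background_clone_freq Cap on any background clone's target
#'   frequency; emulates sorted compartments without dominant expansions
#'   and keeps the derived global frequency threshold on a realistic
#'   scale.
#' @param cdr3_length_range Inclusive amino-acid length range for CDR3s.
#' @param n_planted_families Number of planted reactive motif families
#'   (0 gives a null cohort in which `AIM_POS`/`AIM_NEG` are exchangeable
#'   draws from the same clone pool).
#' @param members_per_family Planted member clones per family per donor.
#' @param planted_freq_aim_pos Target `AIM_POS` frequency of each planted
#'   clone.
#' @param planted_enrichment_fold Multiplicative `AIM_POS` vs `AIM_NEG`
#'   frequency ratio for planted clones (> 1); `AIM_NEG` copies may
#'   resample to zero.
#' @param memory_seeding_prob Probability that a planted clone of a
#'   memory-resident family also appears in `TCM`/`TEM`.
#' @param tcm_tem_mix Probability that a memory-seeded clone goes to
#'   `TCM` (vs `TEM`); both draws are independent, so a clone can land in
#'   both subsets.
#' @param publicity_prob Probability that a family is memory-resident in
#'   a non-origin donor; each family's origin donor is always
#'   memory-resident. Member sequences are freshly drawn per donor, so
#'   exact clones remain private while the motif is shared.
#' @param naive_leak_prob Probability that a planted clone leaks into the
#'   naive repertoire (one template).
#' @param preferred_v_gene V gene planted preferentially into reactive
#'   families, emulating the antigen-driven V-gene bias seen in real
#'   reactive repertoires (e.g. TRBV15).
#' @param preferred_v_fraction Fraction of planted families carrying the
#'   preferred V gene (the first `ceiling(fraction * n_families)`
#'   families); remaining families draw a V gene at random.
#' @param trim_head,trim_tail Interior-trimming offsets used to guarantee
#'   planted motifs sit fully inside the trimmed CDR3 interior.
#' @param seed Random seed; identical seed and config give identical
#'   cohorts.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_donors = 6,
                              templates_per_compartment = c(
                                AIM_POS = 20000, AIM_NEG = 20000,
                                NAIVE = 20000, TCM = 15000, TEM = 5000),
                              clone_size_shape = 2.5,
                              max_background_clone_freq = 1.5e-3,
                              cdr3_length_range = c(11L, 18L),
                              n_planted_families = 10,
                              members_per_family = 5,
                              planted_freq_aim_pos = 4e-3,
                              planted_enrichment_fold = 20,
                              memory_seeding_prob = 0.3,
                              tcm_tem_mix = 0.5,
                              publicity_prob = 0.6,
                              naive_leak_prob = 0.01,
                              preferred_v_gene = "TRBV15",
                              preferred_v_fraction = 0.3,
                              trim_head = 3, trim_tail = 2,
                              seed = 1) {
  cfg <- list(n_donors = as.integer(n_donors),
              templates_per_compartment = templates_per_compartment,
              clone_size_shape = clone_size_shape,
              max_background_clone_freq = max_background_clone_freq,
              cdr3_length_range = as.integer(cdr3_length_range),
              n_planted_families = as.integer(n_planted_families),
              members_per_family = as.integer(members_per_family),
              planted_freq_aim_pos = planted_freq_aim_pos,
              planted_enrichment_fold = planted_enrichment_fold,
              memory_seeding_prob = memory_seeding_prob,
              tcm_tem_mix = tcm_tem_mix,
              publicity_prob = publicity_prob,
              naive_leak_prob = naive_leak_prob,
              preferred_v_gene = preferred_v_gene,
              preferred_v_fraction = preferred_v_fraction,
              trim_head = as.integer(trim_head),
              trim_tail = as.integer(trim_tail),
              seed = as.integer(seed))
  probs <- c(cfg$memory_seeding_prob, cfg$tcm_tem_mix, cfg$publicity_prob,
             cfg$naive_leak_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_config("all probabilities must lie in [0, 1]")
  }
  if (cfg$n_donors < 1) stop_config("n_donors must be positive")
  if (cfg$clone_size_shape <= 1) stop_config("clone_size_shape must be > 1")
  if (cfg$planted_enrichment_fold <= 1) {
    stop_config("planted_enrichment_fold must be > 1")
  }
  if (!all(COMPARTMENTS %in% names(cfg$templates_per_compartment))) {
    stop_config("templates_per_compartment must name all five compartments")
  }
  if (any(cfg$templates_per_compartment < 1)) {
    stop_config("templates_per_compartment must be positive")
  }
  min_len <- cfg$trim_head + cfg$trim_tail + 6  # room for a length-6 motif
  if (cfg$n_planted_families > 0 && cfg$cdr3_length_range[1] < min_len) {
    stop_config(sprintf("cdr3_length_range[1] must be >= %d", min_len))
  }
  planted_demand <- cfg$n_planted_families * cfg$members_per_family *
    cfg$planted_freq_aim_pos * 2
  if (planted_demand >= 0.5) {
    stop_config("planted template demand exceeds compartment capacity")
  }
  structure(cfg, class = "simulation_config")
}

# sample() treats a length-1 numeric as 1:x; resample() never does.
resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

# Vectorised random CDR3s: C + uniform interior + F.
random_cdr3 <- function(n, len_range) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  out <- character(n)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    m <- matrix(sample(AA20, length(idx) * (L - 2L), replace = TRUE),
                nrow = length(idx))
    out[idx] <- do.call(paste0, c(list("C"), asplit(m, 2), list("F")))
  }
  out
}

# Zipf-like clone sizes truncated at smax.
zipf_sizes <- function(n, shape, smax) {
  smax <- max(1L, smax)
  sizes <- 1:smax
  sample(sizes, n, replace = TRUE, prob = sizes^(-shape))
}

# Draw a background clone pool: unique CDR3s with power-law target
# frequencies summing to 1.
background_pool <- function(n_clones, cfg, smax) {
  seqs <- random_cdr3(n_clones, cfg$cdr3_length_range)
  dup <- duplicated(seqs)
  while (any(dup)) {
    seqs[dup] <- random_cdr3(sum(dup), cfg$cdr3_length_range)
    dup <- duplicated(seqs)
  }
  sizes <- zipf_sizes(n_clones, cfg$clone_size_shape, smax)
  tibble(aa_seq = seqs,
         v_gene = sample(TRBV_GENES, n_clones, replace = TRUE),
         j_gene = sample(TRBJ_GENES, n_clones, replace = TRUE),
         weight = sizes / sum(sizes))
}

# Reverse-translate an amino-acid CDR3 with a fixed codon per residue so
# nucleotide sequences are deterministic functions of the protein.
aa_to_nt <- function(aa) {
  codons <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAG", R = "CGT",
              S = "AGC", T = "ACT", V = "GTG", W = "TGG", Y = "TAT")
  vapply(strsplit(aa, ""), function(ch) paste(codons[ch], collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# Planted motif patterns: one '%' wildcard at position 1 (length 5) or 2
# (length 6), so each pattern contains exactly one maximal exact 4-mer
# (its "core"), discoverable through the local k-mer channel.
make_motif_patterns <- function(n) {
  cores <- character(0)
  patterns <- character(0)
  while (length(patterns) < n) {
    len <- resample(c(5L, 6L))
    body <- paste(sample(AA20, len - 1, replace = TRUE), collapse = "")
    if (len == 5L) {
      pattern <- paste0("%", body)
      core <- body
    } else {
      pattern <- paste0(substr(body, 1, 1), "%", substr(body, 2, 5))
      core <- substr(body, 2, 5)
    }
    if (core %in% cores) next
    cores <- c(cores, core)
    patterns <- c(patterns, pattern)
  }
  tibble(pattern = patterns, core = cores)
}

# Instantiate one member CDR3 containing the pattern (wildcard filled at
# random) fully inside the trimmed interior.
instantiate_member <- function(pattern, cfg) {
  instance <- pattern
  wc <- regexpr("%", instance, fixed = TRUE)
  substr(instance, wc, wc) <- resample(AA20)
  len_inst <- nchar(instance)
  L <- resample(max(cfg$cdr3_length_range[1],
                    cfg$trim_head + cfg$trim_tail + len_inst):
                  cfg$cdr3_length_range[2])
  # interior spans positions trim_head+1 .. L - trim_tail
  start <- resample((cfg$trim_head + 1):(L - cfg$trim_tail - len_inst + 1))
  left <- c("C", sample(AA20, start - 2, replace = TRUE))
  right_n <- L - (start + len_inst - 1) - 1
  right <- c(sample(AA20, right_n, replace = TRUE), "F")
  paste(c(left, strsplit(instance, "")[[1]], right), collapse = "")
}

#' Simulate a cohort of repertoires with planted reactive clones
#'
#' For each donor, generates `AIM_POS`, `AIM_NEG`, `NAIVE`, `TCM` and
#' `TEM` repertoires. Background clones are drawn per donor from a shared
#' AIM clone pool (so the reactive and non-reactive sorts are exchangeable
#' samples of the same repertoire when nothing is planted) and from
#' separate ex-vivo pools; integer template counts come from multinomial
#' resampling of the target frequencies, so counts are self-consistent.
#' Planted families embed a wildcard motif in every member CDR3 and are
#' enriched `planted_enrichment_fold`-fold in `AIM_POS`; memory and naive
#' seeding follow the config probabilities.
#'
#' The returned ground truth records, per planted clone, the realized
#' compartment placements, and per planted family, both the planted
#' memory donors and a recount-based donor set obtained by pattern
#' matching the family core against the emitted ex-vivo repertoires
#' (chance background matches are therefore honestly part of the truth).
#'
#' @param config A [simulation_config()].
#' @return A list with `cohort` (named list of `tcr_repertoire`) and
#'   `truth` (list of tibbles `clones` and `motifs`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  donors <- sprintf("D%02d", seq_len(cfg$n_donors))
  tpc <- cfg$templates_per_compartment
  n_fam <- cfg$n_planted_families

  planted <- if (n_fam > 0) make_motif_patterns(n_fam) else
    tibble(pattern = character(), core = character())
  planted$family <- paste0("F", sprintf("%02d", seq_len(nrow(planted))))
  planted$origin_donor <- donors[((seq_len(nrow(planted)) - 1) %%
                                    cfg$n_donors) + 1]
  # V gene is shared within a family; the first families carry the
  # preferred gene, emulating antigen-driven V-gene bias
  if (n_fam > 0) {
    n_pref <- min(n_fam, ceiling(cfg$preferred_v_fraction * n_fam))
    planted$v_gene <- c(rep(cfg$preferred_v_gene, n_pref),
                        sample(TRBV_GENES, n_fam - n_pref, replace = TRUE))
  } else {
    planted$v_gene <- character(0)
  }

  cohort <- list()
  truth_clone_rows <- list()

  for (d in donors) {
    # --- planted clones for this donor -------------------------------
    if (n_fam > 0) {
      fam_idx <- rep(seq_len(n_fam), each = cfg$members_per_family)
      member <- tibble(
        family = planted$family[fam_idx],
        pattern = planted$pattern[fam_idx],
        core = planted$core[fam_idx],
        v_gene = planted$v_gene[fam_idx],
        j_gene = sample(TRBJ_GENES, length(fam_idx), replace = TRUE),
        aa_seq = vapply(planted$pattern[fam_idx], instantiate_member,
                        character(1), cfg = cfg, USE.NAMES = FALSE)
      )
      while (anyDuplicated(member$aa_seq)) {
        i <- which(duplicated(member$aa_seq))
        member$aa_seq[i] <- vapply(member$pattern[i], instantiate_member,
                                   character(1), cfg = cfg,
                                   USE.NAMES = FALSE)
      }
      lam_pos <- cfg$planted_freq_aim_pos * tpc[["AIM_POS"]]
      lam_neg <- lam_pos / cfg$planted_enrichment_fold *
        tpc[["AIM_NEG"]] / tpc[["AIM_POS"]]
      member$count_aim_pos <- pmax(1L, rpois(nrow(member), lam_pos))
      member$count_aim_neg <- rpois(nrow(member), lam_neg)
      # memory residence: family level (origin donor always eligible),
      # then per-clone seeding
      resident <- planted$origin_donor == d |
        runif(n_fam) < cfg$publicity_prob
      seeded <- resident[fam_idx] & runif(nrow(member)) < cfg$memory_seeding_prob
      in_tcm <- seeded & runif(nrow(member)) < cfg$tcm_tem_mix
      in_tem <- seeded & runif(nrow(member)) < (1 - cfg$tcm_tem_mix)
      neither <- seeded & !in_tcm & !in_tem
      in_tcm[neither] <- cfg$tcm_tem_mix >= 0.5
      in_tem[neither] <- cfg$tcm_tem_mix < 0.5
      member$count_tcm <- ifelse(in_tcm, 1L + rpois(nrow(member), 2), 0L)
      member$count_tem <- ifelse(in_tem, 1L + rpois(nrow(member), 2), 0L)
      member$count_naive <- ifelse(runif(nrow(member)) < cfg$naive_leak_prob,
                                   1L, 0L)
    } else {
      member <- tibble(family = character(), pattern = character(),
                       core = character(), v_gene = character(),
                       j_gene = character(), aa_seq = character(),
                       count_aim_pos = integer(), count_aim_neg = integer(),
                       count_tcm = integer(), count_tem = integer(),
                       count_naive = integer())
    }

    # --- background pools --------------------------------------------
    aim_n <- max(tpc[["AIM_POS"]], tpc[["AIM_NEG"]])
    smax_aim <- round(cfg$max_background_clone_freq * aim_n)
    aim_pool <- background_pool(round(aim_n / 2), cfg, smax_aim)
    comp_counts <- list()
    for (comp in c("AIM_POS", "AIM_NEG")) {
      planted_total <- sum(member[[paste0("count_",
                                          tolower(sub("AIM_", "aim_", comp)))]])
      free <- tpc[[comp]] - planted_total
      if (free < 0) stop_config("planted template demand exceeds compartment total")
      comp_counts[[comp]] <- as.integer(
        rmultinom(1, free, aim_pool$weight)[, 1])
    }
    exvivo_pool <- list()
    for (comp in c("NAIVE", "TCM", "TEM")) {
      smax <- round(cfg$max_background_clone_freq * tpc[[comp]])
      pool <- background_pool(round(tpc[[comp]] / 2), cfg, smax)
      planted_total <- sum(member[[paste0("count_", tolower(comp))]])
      free <- tpc[[comp]] - planted_total
      if (free < 0) stop_config("planted template demand exceeds compartment total")
      pool$count <- as.integer(rmultinom(1, free, pool$weight)[, 1])
      exvivo_pool[[comp]] <- pool
    }

    # --- assemble repertoires ----------------------------------------
    planted_col <- c(AIM_POS = "count_aim_pos", AIM_NEG = "count_aim_neg",
                     NAIVE = "count_naive", TCM = "count_tcm",
                     TEM = "count_tem")
    for (comp in COMPARTMENTS) {
      bg <- if (comp %in% c("AIM_POS", "AIM_NEG")) {
        mutate(aim_pool, count = comp_counts[[comp]])
      } else {
        exvivo_pool[[comp]]
      }
      bg <- filter(bg, .data$count > 0)
      pl <- member[member[[planted_col[[comp]]]] > 0, , drop = FALSE]
      recs <- bind_rows(
        tibble(aa_seq = bg$aa_seq, v_gene = bg$v_gene, j_gene = bg$j_gene,
               templates = bg$count),
        tibble(aa_seq = pl$aa_seq, v_gene = pl$v_gene, j_gene = pl$j_gene,
               templates = as.integer(pl[[planted_col[[comp]]]]))
      )
      total <- sum(recs$templates)
      records <- tibble(
        nucleotide_seq = aa_to_nt(recs$aa_seq),
        aa_seq = recs$aa_seq,
        v_gene = recs$v_gene,
        d_gene = NA_character_,
        j_gene = recs$j_gene,
        templates = as.integer(recs$templates),
        frequency = recs$templates / total,
        productive = TRUE
      )
      cohort[[paste(d, comp, sep = ".")]] <-
        new_repertoire(d, comp, records)
    }

    if (nrow(member) > 0) {
      truth_clone_rows[[d]] <- tibble(
        donor_id = d,
        family = member$family,
        aa_seq = member$aa_seq,
        v_gene = member$v_gene,
        j_gene = member$j_gene,
        templates_aim_pos = member$count_aim_pos,
        templates_aim_neg = member$count_aim_neg,
        in_naive = member$count_naive > 0,
        in_tcm = member$count_tcm > 0,
        in_tem = member$count_tem > 0,
        reactive = TRUE
      )
    }
  }

  truth_clones <- bind_rows(truth_clone_rows)
  truth_motifs <- motif_truth_recount(planted, truth_clones, cohort, cfg,
                                      donors)
  list(cohort = cohort,
       truth = list(clones = truth_clones, motifs = truth_motifs))
}

# Recount-based motif ground truth: which donors carry each family core
# in their ex-vivo repertoires (planted or by chance).
motif_truth_recount <- function(planted, truth_clones, cohort, cfg, donors) {
  if (nrow(planted) == 0) {
    return(tibble(family = character(), pattern = character(),
                  core = character(), origin_donor = character(),
                  donors_memory_planted = character(),
                  donors_memory = character(),
                  donors_naive = character(), n_donors_memory = integer(),
                  public = logical()))
  }
  interior <- function(rep) {
    trimmed <- trim_cdr3(rep$records$aa_seq, cfg$trim_head, cfg$trim_tail)
    trimmed[!is.na(trimmed)]
  }
  mem_by_donor <- lapply(donors, function(d) {
    unlist(lapply(MEMORY_COMPARTMENTS, function(cp)
      interior(cohort[[paste(d, cp, sep = ".")]])))
  })
  naive_by_donor <- lapply(donors, function(d)
    interior(cohort[[paste(d, "NAIVE", sep = ".")]]))
  names(mem_by_donor) <- names(naive_by_donor) <- donors

  rows <- lapply(seq_len(nrow(planted)), function(i) {
    core <- planted$core[i]
    mem_donors <- donors[vapply(mem_by_donor, function(s)
      any(stringr::str_detect(s, stringr::fixed(core))), logical(1))]
    naive_donors <- donors[vapply(naive_by_donor, function(s)
      any(stringr::str_detect(s, stringr::fixed(core))), logical(1))]
    fam_clones <- truth_clones[truth_clones$family == planted$family[i], ]
    planted_mem <- sort(unique(
      fam_clones$donor_id[fam_clones$in_tcm | fam_clones$in_tem]))
    tibble(family = planted$family[i],
           pattern = planted$pattern[i],
           core = core,
           origin_donor = planted$origin_donor[i],
           donors_memory_planted = paste(planted_mem, collapse = ";"),
           donors_memory = paste(mem_donors, collapse = ";"),
           donors_naive = paste(naive_donors, collapse = ";"),
           n_donors_memory = length(mem_donors),
           public = length(mem_donors) > 0.8 * length(donors))
  })
  bind_rows(rows)
}

#' Write a simulated cohort as an on-disk fixture
#'
#' Emits one immunoSEQ-dialect TSV per (donor, compartment), a
#' `manifest.tsv` readable by [read_cohort()], and the ground-truth
#' tables `truth_clones.tsv` and `truth_motifs.tsv`.
#'
#' @param sim Result of [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @param column_map Dialect map for the repertoire files.
#' @return The manifest path, invisibly.
#' @export
write_fixture <- function(sim, out_dir,
                          column_map = default_column_map()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory ", out_dir),
                   class = "cdr3trackr_io_error")
  }
  entries <- lapply(sim$cohort, function(rep) {
    fname <- paste0(rep$donor_id, "_", rep$compartment, ".tsv")
    write_repertoire(rep, file.path(out_dir, fname), column_map)
    tibble(donor_id = rep$donor_id, compartment = rep$compartment,
           path = fname)
  })
  manifest <- bind_rows(entries)
  if (nrow(manifest) == 0) {
    manifest <- tibble(donor_id = character(), compartment = character(),
                       path = character())
  }
  manifest_path <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, progress = FALSE)
  readr::write_tsv(sim$truth$clones, file.path(out_dir, "truth_clones.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$motifs, file.path(out_dir, "truth_motifs.tsv"),
                   progress = FALSE)
  invisible(manifest_path)
}

#' Simulate a healthy-donor naive CDR3 reference panel
#'
#' Generates a pooled panel of naive CDR3 sequences from several
#' synthetic healthy donors and returns it as a [reference_set()]. This
#' plays the role of the large built-in naive reference panel that
#' GLIPH-style tools ship (naive CDR3s from 12 healthy individuals):
#' motif discovery compares sample k-mer rates against this background,
#' and a panel much larger than the analysis sample keeps the background
#' k-mer rate estimates stable. The panel is synthetic (uniform-random
#' CDR3 interiors) and is intended for simulation studies and tests; for
#' real data a reference of sequenced naive CDR3s should be supplied
#' instead.
#'
#' @param n_donors Number of synthetic reference donors.
#' @param clones_per_donor Unique naive clones contributed per donor.
#' @param cdr3_length_range Inclusive CDR3 length range.
#' @param head,tail Trimming offsets for the reference index.
#' @param seed Seed; the panel is fixed given its arguments.
#' @return A `cdr3_reference`.
#' @export
simulate_naive_reference <- function(n_donors = 12,
                                     clones_per_donor = 40000,
                                     cdr3_length_range = c(11L, 18L),
                                     head = 3, tail = 2, seed = 104729) {
  withr::with_seed(seed, {
    seqs <- random_cdr3(n_donors * clones_per_donor, cdr3_length_range)
    reference_set(seqs, trim = TRUE, head = head, tail = tail)
  })
}

# Compact IMGT-style TRBV/TRBJ gene lists used by the generator.
TRBV_GENES <- c(
  "TRBV2", "TRBV3-1", "TRBV4-1", "TRBV4-2", "TRBV5-1", "TRBV5-4",
  "TRBV5-6", "TRBV6-1", "TRBV6-4", "TRBV6-5", "TRBV7-2", "TRBV7-3",
  "TRBV7-8", "TRBV7-9", "TRBV9", "TRBV10-3", "TRBV11-1", "TRBV11-2",
  "TRBV12-3", "TRBV12-5", "TRBV13", "TRBV14", "TRBV15", "TRBV16",
  "TRBV18", "TRBV19", "TRBV20-1", "TRBV24-1", "TRBV25-1", "TRBV27",
  "TRBV28", "TRBV29-1", "TRBV30")
TRBJ_GENES <- c(
  "TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5", "TRBJ1-6",
  "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5", "TRBJ2-6",
  "TRBJ2-7")
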