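test_that("CDR3 trimming removes the anchor residues", {
  expect_equal(trim_cdr3("CASSLEYEQYF"), "SLEYEQ")
  expect_true(is.na(trim_cdr3("CASSF")))          # too short: excluded
  expect_equal(trim_cdr3("SLEYEQ", head = 0, tail = 0), "SLEYEQ")
  expect_equal(trim_cdr3(c("CASSLEYEQYF", "CASSF")),
               c("SLEYEQ", NA))
})

test_that("local k-mer enrichment applies fold, p and uniqueness cuts", {
  set.seed(17)
  ref_seqs <- c(random_aa(9999, 6, 10), "QWYHM")
  reference <- reference_set(ref_seqs, trim = FALSE)
  # motif QWYH in 10 of 100 sample sequences vs 1 of ~10,000 reference
  sample_seqs <- c(paste0(random_aa(10, 2, 3), "QWYH"),
                   random_aa(90, 6, 10))
  hits <- local_motif_enrichment(sample_seqs, reference, k_values = 4,
                                 min_fold = 10)
  row <- hits[hits$kmer == "QWYH", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$n_sample, 10L)
  expect_equal(row$fold, (10 / 100) / (row$n_reference / reference$n))
  expect_gte(row$fold, 10)
  # a k-mer absent from the sample is never emitted
  expect_false("MMWW" %in% hits$kmer)
  # the uniqueness cut suppresses k-mers in fewer than min_unique CDR3s
  few <- local_motif_enrichment(c("AQWYHA", random_aa(99, 6, 10)),
                                reference, k_values = 4, min_fold = 1,
                                min_unique = 3)
  expect_false("QWYH" %in% few$kmer)
})

test_that("planted motif cores are all recovered by the local channel", {
  sim <- shared_sim()
  res <- shared_pipeline()
  local_patterns <- res$groups$pattern[res$groups$kind == "LOCAL"]
  expect_true(all(sim$truth$motifs$core %in% local_patterns))
})

test_that("global convergence groups single-mismatch CDR3s", {
  g <- global_convergence(c("SLEYE", "SLEFE"))
  expect_equal(g$pattern, "SLE%E")
  expect_equal(g$n_unique_cdr3, 2L)
  expect_setequal(g$members[[1]], c("SLEYE", "SLEFE"))
  # a lone sequence forms no group
  expect_equal(nrow(global_convergence("SLEYE")), 0)
  # sequences of different length never group
  expect_equal(nrow(global_convergence(c("SLEYE", "SLEYEA"))), 0)
})

test_that("global convergence equals the all-pairs brute force", {
  brute_force_global <- function(seqs, min_unique = 2) {
    seqs <- unique(seqs)
    pats <- character(0)
    for (i in seq_along(seqs)) for (j in seq_len(i - 1)) {
      a <- seqs[i]; b <- seqs[j]
      if (nchar(a) != nchar(b)) next
      ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
      diff <- which(ca != cb)
      if (length(diff) == 1) {
        ca[diff] <- "%"
        pats <- c(pats, paste(ca, collapse = ""))
      }
    }
    pats <- unique(pats)
    out <- lapply(pats, function(p) {
      rx <- paste0("^", gsub("%", ".", p, fixed = TRUE), "$")
      members <- seqs[nchar(seqs) == nchar(p) & grepl(rx, seqs)]
      if (length(members) < min_unique) return(NULL)
      list(pattern = p, members = sort(members))
    })
    out[!vapply(out, is.null, logical(1))]
  }
  set.seed(23)
  # short alphabet-limited strings force plenty of near-collisions
  seqs <- unique(vapply(1:200, function(i)
    paste(sample(c("A", "C", "D", "E"), sample(3:5, 1), replace = TRUE),
          collapse = ""), character(1)))
  got <- global_convergence(seqs)
  want <- brute_force_global(seqs)
  expect_equal(nrow(got), length(want))
  want_map <- setNames(lapply(want, `[[`, "members"),
                       vapply(want, `[[`, character(1), "pattern"))
  for (i in seq_len(nrow(got))) {
    expect_equal(sort(got$members[[i]]), want_map[[got$pattern[i]]])
  }
})

test_that("specificity groups collect members and deduplicate patterns", {
  records <- tibble::tibble(
    donor_id = "D01", compartment = "AIM_POS",
    aa_seq = c("CASSLEYEQYF", "CASGLEYAQYF", "CASSWWWWQYF"),
    templates = c(5L, 2L, 1L), frequency = c(0.5, 0.3, 0.2))
  km <- tibble::tibble(kmer = "LEY")
  groups <- build_specificity_groups(km, NULL, records)
  expect_equal(nrow(groups), 1)
  expect_equal(groups$n_unique_cdr3, 2L)
  expect_setequal(groups$members[[1]]$aa_seq,
                  c("CASSLEYEQYF", "CASGLEYAQYF"))
  # identical member sets: the longer (more specific) pattern wins
  km2 <- tibble::tibble(kmer = c("LEY", "LEYE"))
  records2 <- tibble::tibble(
    donor_id = c("D01", "D02"), compartment = "AIM_POS",
    aa_seq = c("CASSLEYEQYF", "CASGLEYEAYF"),
    templates = c(5L, 2L), frequency = c(0.7, 0.3))
  groups2 <- build_specificity_groups(km2, NULL, records2)
  expect_equal(nrow(groups2), 1)
  expect_equal(groups2$pattern, "LEYE")
  # membership-by-pattern: re-matching all members succeeds
  sim_groups <- shared_pipeline()$groups
  for (i in seq_len(nrow(sim_groups))) {
    m <- sim_groups$members[[i]]
    expect_true(all(motif_match(m$trimmed, sim_groups$pattern[i],
                                sim_groups$kind[i])))
  }
})

test_that("planted groups contain all planted members", {
  sim <- shared_sim()
  groups <- shared_pipeline()$groups
  truth <- sim$truth$clones
  for (i in seq_len(nrow(sim$truth$motifs))) {
    core <- sim$truth$motifs$core[i]
    fam_members <- truth$aa_seq[truth$family == sim$truth$motifs$family[i]]
    g <- groups[groups$pattern == core & groups$kind == "LOCAL", ]
    expect_equal(nrow(g), 1)
    expect_true(all(fam_members %in% g$members[[1]]$aa_seq))
  }
})

test_that("reference enrichment gives p ~ 1 at equal rates, tiny when skewed", {
  reference <- reference_set(
    c(rep("AAQWYHAA", 1), random_aa(99, 6, 10)), trim = FALSE)
  groups <- tibble::tibble(
    pattern = "QWYH", kind = "LOCAL", n_unique_cdr3 = 1L,
    members = list(tibble::tibble(aa_seq = "X")))
  # identical rates: 1/100 sample vs 1/100 reference
  res <- reference_enrichment_test(groups, 100, reference)
  expect_gt(res$fisher_ref_p, 0.99)
  # 20/1000 sample vs 1/100000 reference
  big_ref <- reference_set(c("AAQWYHAA", random_aa(99999, 6, 10)),
                           trim = FALSE)
  groups2 <- dplyr::mutate(groups, n_unique_cdr3 = 20L)
  res2 <- reference_enrichment_test(groups2, 1000, big_ref)
  expect_lt(res2$fisher_ref_p, 1e-10)
})

test_that("expansion scores are calibrated, bounded and reproducible", {
  singleton_data <- tibble::tibble(
    donor_id = "D01", compartment = "AIM_POS",
    aa_seq = paste0("S", 1:500), templates = 1L)
  g_single <- tibble::tibble(
    pattern = "XX", kind = "LOCAL", n_unique_cdr3 = 5L,
    members = list(singleton_data[1:5, ]))
  # an all-singleton dataset can never look expanded
  expect_equal(expansion_score(g_single, singleton_data,
                               seed = 1)$expansion_p, 1)
  # an all-expanded group in a mostly-singleton dataset is maximal
  mixed <- singleton_data
  mixed$templates[1:10] <- 5L
  g_exp <- tibble::tibble(
    pattern = "YY", kind = "LOCAL", n_unique_cdr3 = 10L,
    members = list(mixed[1:10, ]))
  p_exp <- expansion_score(g_exp, mixed, n_perm = 1000, seed = 1)$expansion_p
  expect_lte(p_exp, 1 / 1001 + 1e-12)
  # bounds and seed determinism
  expect_gte(p_exp, 1 / 1001)
  p_again <- expansion_score(g_exp, mixed, n_perm = 1000,
                             seed = 1)$expansion_p
  expect_identical(p_exp, p_again)
  expect_error(expansion_score(g_exp, mixed, n_perm = 10),
               class = "cdr3trackr_config_error")
})

test_that("expansion p falls stochastically as member expansion grows", {
  set.seed(31)
  base <- tibble::tibble(
    donor_id = "D01", compartment = "AIM_POS",
    aa_seq = paste0("S", 1:400),
    templates = ifelse(runif(400) < 0.2, 2L, 1L))
  mean_p <- vapply(c(2, 5, 8), function(k_expanded) {
    ps <- vapply(1:5, function(s) {
      members <- base[c(which(base$templates >= 2)[seq_len(k_expanded)],
                        which(base$templates == 1)[seq_len(10 - k_expanded)]), ]
      g <- tibble::tibble(pattern = "ZZ", kind = "LOCAL",
                          n_unique_cdr3 = 10L, members = list(members))
      expansion_score(g, base, n_perm = 500, seed = s)$expansion_p
    }, numeric(1))
    mean(ps)
  }, numeric(1))
  expect_true(all(diff(mean_p) < 0))
  # analytic check: the null draw statistic is hypergeometric, so the
  # expected p is the upper hypergeometric tail
  K <- sum(base$templates >= 2)
  p_analytic <- phyper(8 - 1, K, 400 - K, 10, lower.tail = FALSE)
  expect_lt(abs(mean_p[3] - p_analytic), 0.05)
})

test_that("AIM+ member frequencies are higher in expansion-significant groups", {
  res <- shared_pipeline()
  g <- res$groups
  mean_freq <- vapply(g$members, function(m)
    mean(m$frequency[m$compartment == "AIM_POS"]), numeric(1))
  sig <- g$expansion_p < 0.05
  expect_true(any(sig) && any(!sig))
  expect_gt(mean(mean_freq[sig], na.rm = TRUE),
            mean(mean_freq[!sig], na.rm = TRUE))
})
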