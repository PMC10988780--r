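group_row <- function(pattern, members, kind = "LOCAL") {
  tibble::tibble(pattern = pattern, kind = kind,
                 n_unique_cdr3 = length(unique(members$aa_seq)),
                 members = list(members))
}

test_that("fold change and Poisson p behave at symmetry and extremes", {
  totals <- c(AIM_POS = 1e4, AIM_NEG = 1e4)
  members_eq <- tibble::tibble(
    compartment = c("AIM_POS", "AIM_NEG"), templates = c(12L, 12L),
    aa_seq = c("CA", "CA"))
  g <- motif_fold_and_poisson(group_row("AAAA", members_eq), totals)
  expect_equal(g$log2_fold, 0)
  expect_equal(g$poisson_p, 1)
  # one-sided count: closed form 2 * (1/2)^12
  members_one <- tibble::tibble(
    compartment = "AIM_POS", templates = 12L, aa_seq = "CA")
  g2 <- motif_fold_and_poisson(group_row("AAAA", members_one), totals)
  expect_equal(g2$poisson_p, 2 * 0.5^12)
  expect_gt(g2$log2_fold, 0)
  # degenerate empty group
  members_none <- tibble::tibble(compartment = character(),
                                 templates = integer(),
                                 aa_seq = character())
  g3 <- motif_fold_and_poisson(group_row("AAAA", members_none), totals)
  expect_equal(g3$log2_fold, 0)
  expect_equal(g3$poisson_p, 1)
  expect_true(g3$degenerate)
})

test_that("reactive motif selection respects all three cuts monotonically", {
  enr <- tibble::tibble(
    pattern = c("A", "B", "C", "D"), kind = "LOCAL",
    n_unique_cdr3 = 3L, members = list(NULL),
    expansion_p = c(0.01, 0.01, 0.2, 0.01),
    log2_fold = c(4, 1, 4, 4),
    poisson_p = c(1e-9, 1e-9, 1e-9, 1e-3))
  sel <- select_apob_motifs(enr)
  expect_equal(sel$pattern, "A")     # B fails fold, C expansion, D poisson
  relaxed <- select_apob_motifs(enr, log2fold_min = 0, neg_log10p_min = 0)
  expect_setequal(relaxed$pattern, c("A", "B", "D"))
  # tightening any cut never grows the set
  tighter <- select_apob_motifs(enr, log2fold_min = 5)
  expect_true(all(tighter$pattern %in% sel$pattern))
})

test_that("planted motifs pass the reactive cuts; background never does", {
  sim <- shared_sim()
  res <- shared_pipeline()
  rec <- families_covered(sim$truth$motifs$core, res$apob_motifs$pattern)
  expect_true(all(rec))
  # every selected motif traces back to a planted family
  planted_cover <- vapply(res$apob_motifs$pattern, function(p) {
    any(vapply(sim$truth$motifs$core, function(co)
      grepl(co, p, fixed = TRUE) ||
        grepl(gsub("%", ".", sim$truth$motifs$pattern[
          sim$truth$motifs$core == co]), p), logical(1)))
  }, logical(1))
  expect_true(all(planted_cover))
})

test_that("affiliation classification follows compartment presence", {
  exvivo <- list(
    make_repertoire(c("CASNAIVEONLYF", "CASWWWWWWWWF"), c(1, 9),
                    donor_id = "D01", compartment = "NAIVE"),
    make_repertoire(c("CASTCMHITAAF", "CASWWWWWWWWF"), c(5, 5),
                    donor_id = "D01", compartment = "TCM"),
    make_repertoire("CASWWWWWWWWF", 10, donor_id = "D01",
                    compartment = "TEM"))
  motifs <- tibble::tibble(pattern = c("TCMHIT", "NAIVEO", "ZZZZ"),
                           kind = "LOCAL")
  cls <- classify_affiliation(motifs, exvivo)
  aff <- cls$affiliation
  expect_equal(aff$category,
               c("MEMORY_ONLY", "NAIVE_ONLY", "ABSENT"))
  expect_equal(aff$subset_detail, c("TCM_ONLY", "NA", "NA"))
  expect_equal(aff$memory_affiliated, c(TRUE, FALSE, FALSE))
  # affiliation partition covers every motif exactly once
  expect_equal(sum(table(aff$category)), nrow(motifs))
})

test_that("memory affiliation on the planted cohort matches ground truth", {
  sim <- shared_sim()
  res <- shared_pipeline()
  truth <- sim$truth$motifs
  # per family, the core motif's ex-vivo memory donor set must equal the
  # recount-based truth
  for (i in seq_len(nrow(truth))) {
    aff <- res$affiliation[res$affiliation$pattern == truth$core[i], ]
    expect_equal(nrow(aff), 1)
    expect_equal(aff$donors_memory[[1]],
                 sort(strsplit(truth$donors_memory[i], ";")[[1]]))
  }
})

test_that("sharing networks count shared motifs as edge weights", {
  affiliation <- tibble::tibble(
    pattern = c("AAA", "BBB"), kind = "LOCAL",
    memory_affiliated = TRUE)
  matches <- tibble::tibble(
    pattern = c("AAA", "AAA", "BBB"),
    donor_id = c("D01", "D02", "D01"),
    compartment = c("TCM", "TCM", "TEM"),
    aa_seq = c("CA", "CB", "CC"),
    templates = 1L, frequency = 0.1)
  net <- build_sharing_network(affiliation, matches)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1L)
  expect_setequal(c(net$edges$node_a, net$edges$node_b),
                  c("D01.TCM", "D02.TCM"))
  # single-node connection: kept in the per-motif table, no edge
  expect_equal(nrow(net$connections), 2)
  expect_equal(net$connections$n_nodes[net$connections$pattern == "BBB"], 1L)
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)
})

test_that("network edge weights equal brute-force per-motif pair counts", {
  set.seed(41)
  motifs <- paste0("M", 1:12)
  matches <- tibble::tibble(
    pattern = sample(motifs, 150, replace = TRUE),
    donor_id = sample(paste0("D0", 1:4), 150, replace = TRUE),
    compartment = sample(c("TCM", "TEM"), 150, replace = TRUE),
    aa_seq = paste0("C", 1:150), templates = 1L, frequency = 0.01)
  affiliation <- tibble::tibble(pattern = motifs, kind = "LOCAL",
                                memory_affiliated = TRUE)
  net <- build_sharing_network(affiliation, matches)
  brute <- new.env()
  for (p in motifs) {
    nodes <- sort(unique(paste(matches$donor_id[matches$pattern == p],
                               matches$compartment[matches$pattern == p],
                               sep = ".")))
    if (length(nodes) < 2) next
    for (i in seq_along(nodes)) for (j in seq_len(i - 1)) {
      key <- paste(nodes[j], nodes[i], sep = "~")
      prev <- if (is.null(brute[[key]])) 0L else brute[[key]]
      brute[[key]] <- prev + 1L
    }
  }
  expect_equal(nrow(net$edges), length(ls(brute)))
  for (k in seq_len(nrow(net$edges))) {
    key <- paste(net$edges$node_a[k], net$edges$node_b[k], sep = "~")
    expect_equal(net$edges$weight[k], brute[[key]])
  }
})

test_that("public motif calls demand memory presence in most donors", {
  affiliation <- tibble::tibble(
    pattern = c("WIDE", "NARROW"), kind = "LOCAL",
    memory_affiliated = TRUE,
    n_donors_memory = c(5L, 1L))
  matches <- tibble::tibble(
    pattern = c(rep("WIDE", 5), "NARROW"),
    donor_id = c(paste0("D0", 1:5), "D01"),
    compartment = "TCM", aa_seq = paste0("C", 1:6),
    templates = 1L, frequency = 0.002)
  pub <- public_motifs(affiliation, matches, n_donors = 6)
  expect_equal(pub$public$pattern, "WIDE")
  expect_equal(nrow(pub$frequencies), 5)
  expect_equal(unique(pub$frequencies$sum_frequency), 0.002)
})

test_that("public calls on the planted cohort equal the ground truth", {
  sim <- shared_sim()
  res <- shared_pipeline()
  truth <- sim$truth$motifs
  called <- families_covered(truth$core, res$public$public$pattern)
  expect_equal(unname(called), truth$public)
})

test_that("position frequency matrices are column-stochastic", {
  m1 <- position_frequency_matrix("SLEYE", "SLE", kind = "LOCAL")
  expect_true(all(colSums(m1) == 1))
  expect_equal(m1["S", "1"], 1)       # one-hot columns for one sequence
  m2 <- position_frequency_matrix(c("SLEYE", "SLEFE"), "SLE%E",
                                  kind = "GLOBAL")
  expect_equal(unname(m2[c("Y", "F"), "4"]), c(0.5, 0.5))
  expect_true(all(abs(colSums(m2) - 1) < 1e-12))
  # anchored alignment for LOCAL motifs at different offsets
  m3 <- position_frequency_matrix(c("AASLEYE", "SLEFEAA"), "SLE",
                                  kind = "LOCAL")
  expect_true(all(abs(colSums(m3) - 1) < 1e-12))
  expect_equal(m3["S", "1"], 1)
  set.seed(55)
  seqs <- paste0(random_aa(30, 2, 4), "QWY", random_aa(30, 2, 4))
  m4 <- position_frequency_matrix(seqs, "QWY", kind = "LOCAL")
  expect_true(all(abs(colSums(m4) - 1) < 1e-12))
  expect_error(position_frequency_matrix(character(0), "A", "LOCAL"),
               class = "cdr3trackr_empty_error")
})
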