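# Shared fixtures, memoized so expensive objects are built once per run.
.fixture_env <- new.env(parent = emptyenv())

memoize <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Large synthetic naive reference panel (analogue of a tool's built-in
# 12-donor healthy naive reference).
shared_reference <- function() {
  memoize("reference", function() simulate_naive_reference())
}

# Default planted cohort: the package's canonical validation conditions.
shared_sim <- function() {
  memoize("sim", function() simulate_cohort(simulation_config(seed = 42)))
}

shared_selection <- function() {
  memoize("selection", function() select_reactive_clones(shared_sim()$cohort))
}

shared_pipeline <- function() {
  memoize("pipeline", function() {
    run_motif_pipeline(shared_sim()$cohort, reference = shared_reference(),
                       seed = 7)
  })
}

# Build a repertoire in code from parallel vectors.
make_repertoire <- function(aa_seq, templates, donor_id = "D01",
                            compartment = "AIM_POS",
                            v_gene = "TRBV15", j_gene = "TRBJ2-1",
                            productive = TRUE) {
  n <- length(aa_seq)
  records <- tibble::tibble(
    nucleotide_seq = strrep("ACG", nchar(aa_seq)),
    aa_seq = aa_seq,
    v_gene = rep_len(v_gene, n),
    d_gene = NA_character_,
    j_gene = rep_len(j_gene, n),
    templates = as.integer(templates),
    frequency = templates / sum(templates),
    productive = rep_len(productive, n)
  )
  cdr3trackr:::new_repertoire(donor_id, compartment, records)
}

# Random CDR3 amino-acid sequences for structural tests.
random_aa <- function(n, len_min = 8, len_max = 16) {
  lens <- sample(len_min:len_max, n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(cdr3trackr:::AA20, L, replace = TRUE), collapse = "")
  }, character(1))
}

# Map planted families to called motifs: a motif covers a family when the
# family's exact core occurs in the motif pattern.
families_covered <- function(cores, patterns) {
  vapply(cores, function(co) {
    any(grepl(co, patterns, fixed = TRUE))
  }, logical(1))
}
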