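#' Column map for immunoSEQ-style CDR3 tables
#'
#' immunoSEQ exports vary in column naming across platform versions; a
#' column map resolves the required fields to the dialect at hand. The
#' default map matches the common
#' `nucleotide / aminoAcid / count (templates/reads) / vGeneName /
#' dGeneName / jGeneName / sequenceStatus` dialect, with frequencies
#' stored as fractions in `frequencyCount`. Set
#' `frequency_unit = "percent"` for exports carrying
#' `frequencyCount (%)`-style percent columns.
#'
#' @param nucleotide_seq,aa_seq,templates,frequency,v_gene,d_gene,j_gene,productive
#'   Column names in the file. `frequency` and `d_gene` are optional in
#'   the file: a missing frequency column is recomputed from templates and
#'   a missing d-gene column yields `NA` (unresolved D gene).
#' @param productive_values Values of the status column that mark a
#'   productive (in-frame, stop-free) rearrangement.
#' @param frequency_unit Either `"fraction"` or `"percent"`.
#' @return A list of class `cdr3_column_map`.
#' @export
default_column_map <- function(nucleotide_seq = "nucleotide",
                               aa_seq = "aminoAcid",
                               templates = "count (templates/reads)",
                               frequency = "frequencyCount",
                               v_gene = "vGeneName",
                               d_gene = "dGeneName",
                               j_gene = "jGeneName",
                               productive = "sequenceStatus",
                               productive_values = c("In", "TRUE"),
                               frequency_unit = c("fraction", "percent")) {
  frequency_unit <- match.arg(frequency_unit)
  structure(
    list(nucleotide_seq = nucleotide_seq, aa_seq = aa_seq,
         templates = templates, frequency = frequency,
         v_gene = v_gene, d_gene = d_gene, j_gene = j_gene,
         productive = productive, productive_values = productive_values,
         frequency_unit = frequency_unit),
    class = "cdr3_column_map"
  )
}

#' Normalize a TCR gene name to IMGT gene level
#'
#' Uppercases, strips allele suffixes (`*01`), converts the Adaptive
#' `TCRB...` prefix to the IMGT `TRB...` prefix and removes zero padding
#' from family/gene numbers, e.g. `"TCRBV07-09*01"` becomes `"TRBV7-9"`.
#' Unresolved markers (`""`, `"unresolved"`, `"unknown"`, `NA`) map to
#' `NA`.
#'
#' @param x Character vector of gene names.
#' @return Character vector of normalized gene-level symbols.
#' @export
normalize_gene <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% c("", "UNRESOLVED", "UNKNOWN", "NA")] <- NA_character_
  x <- sub("\\*.*$", "", x)
  x <- sub("^TCR", "TR", x)
  # strip zero padding in the numeric parts: TRBV07-09 -> TRBV7-9
  x <- gsub("(?<=[VDJ])0+(?=[0-9])", "", x, perl = TRUE)
  x <- gsub("(?<=-)0+(?=[0-9])", "", x, perl = TRUE)
  # single-gene families are zero-padded to "-01" by some platforms
  # (TCRBV15-01); collapse those to the IMGT gene name, leaving true
  # multi-gene family members (TRBV6-1, TRBV20-1, ...) untouched
  single <- c(paste0("TRBV", c(1, 2, 9, 13, 14, 15, 16, 17, 18, 19,
                               23, 27, 28, 30)),
              "TRBD1", "TRBD2")
  padded <- x %in% paste0(single, "-1")
  x[padded] <- sub("-1$", "", x[padded])
  x
}

new_repertoire <- function(donor_id, compartment, records) {
  structure(
    list(donor_id = as.character(donor_id),
         compartment = as.character(compartment),
         records = records,
         total_templates = sum(records$templates)),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf(
    "<tcr_repertoire> donor %s, compartment %s: %d records, %d templates\n",
    x$donor_id, x$compartment, nrow(x$records), x$total_templates))
  print(head(x$records, 5))
  invisible(x)
}

record_template <- function() {
  tibble(nucleotide_seq = character(), aa_seq = character(),
         v_gene = character(), d_gene = character(), j_gene = character(),
         templates = integer(), frequency = double(), productive = logical())
}

#' Read one immunoSEQ-style CDR3 table into a repertoire
#'
#' Reads a tab-separated rearrangement table (one row per rearrangement)
#' and returns every row, unfiltered; non-productive rows are retained
#' with `productive = FALSE` so that filtering remains a separate,
#' explicit step. Gene names are normalized to IMGT gene level. If the
#' file lacks a frequency column, frequencies are recomputed as
#' `templates / sum(templates)`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param donor_id Donor label.
#' @param compartment Compartment label, one of `AIM_POS`, `AIM_NEG`,
#'   `NAIVE`, `TCM`, `TEM` (other labels are allowed but unused by the
#'   pipeline helpers).
#' @param column_map A [default_column_map()]-style dialect map.
#' @return A `tcr_repertoire`: a list with `donor_id`, `compartment`,
#'   `records` (a tibble) and `total_templates`.
#' @export
read_repertoire <- function(path, donor_id, compartment,
                            column_map = default_column_map()) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    stop_empty(paste0("empty repertoire file: ", path))
  }
  required <- c("nucleotide_seq", "aa_seq", "templates", "v_gene",
                "j_gene", "productive")
  for (field in required) {
    col <- column_map[[field]]
    if (!col %in% names(raw)) {
      stop_format(sprintf("missing required column '%s' (field %s) in %s",
                          col, field, path))
    }
  }
  templates_chr <- raw[[column_map$templates]]
  templates_num <- suppressWarnings(as.numeric(templates_chr))
  bad <- which(is.na(templates_num) | templates_num != floor(templates_num))
  if (length(bad) > 0) {
    stop_parse(sprintf("non-integer template count '%s' at row %d of %s",
                       templates_chr[bad[1]], bad[1], path))
  }
  templates <- as.integer(templates_num)

  freq_col <- column_map$frequency
  if (!is.null(freq_col) && freq_col %in% names(raw)) {
    frequency <- as.numeric(raw[[freq_col]])
    if (identical(column_map$frequency_unit, "percent")) {
      frequency <- frequency / 100
    }
  } else {
    frequency <- templates / sum(templates)
  }

  d_col <- column_map$d_gene
  d_gene <- if (!is.null(d_col) && d_col %in% names(raw)) {
    normalize_gene(raw[[d_col]])
  } else {
    rep(NA_character_, nrow(raw))
  }

  records <- tibble(
    nucleotide_seq = raw[[column_map$nucleotide_seq]],
    aa_seq = raw[[column_map$aa_seq]],
    v_gene = normalize_gene(raw[[column_map$v_gene]]),
    d_gene = d_gene,
    j_gene = normalize_gene(raw[[column_map$j_gene]]),
    templates = templates,
    frequency = frequency,
    productive = raw[[column_map$productive]] %in% column_map$productive_values
  )
  new_repertoire(donor_id, compartment, records)
}

#' Write a repertoire as an immunoSEQ-style tab-separated table
#'
#' The inverse of [read_repertoire()]: emits UTF-8, LF line endings and a
#' fixed column order given by the column map. Reading the file back with
#' the same map reproduces all fields.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output path.
#' @inheritParams read_repertoire
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path, column_map = default_column_map()) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  r <- rep$records
  freq <- r$frequency
  if (identical(column_map$frequency_unit, "percent")) freq <- freq * 100
  status <- ifelse(r$productive, column_map$productive_values[1], "Out")
  out <- tibble(
    !!column_map$nucleotide_seq := r$nucleotide_seq,
    !!column_map$aa_seq := r$aa_seq,
    !!column_map$templates := r$templates,
    !!column_map$frequency := freq,
    !!column_map$v_gene := ifelse(is.na(r$v_gene), "unresolved", r$v_gene),
    !!column_map$d_gene := ifelse(is.na(r$d_gene), "unresolved", r$d_gene),
    !!column_map$j_gene := ifelse(is.na(r$j_gene), "unresolved", r$j_gene),
    !!column_map$productive := status
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Keep only productive rearrangements and renormalize frequencies
#'
#' Retains records with `productive = TRUE`, recomputes frequencies over
#' the retained templates (filtering invalidates file frequencies) and
#' updates the repertoire total.
#'
#' @param rep A `tcr_repertoire`.
#' @return A productive-only `tcr_repertoire`.
#' @export
filter_productive <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  kept <- rep$records[rep$records$productive, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop_empty(sprintf("no productive records remain in donor %s %s",
                       rep$donor_id, rep$compartment))
  }
  kept$frequency <- kept$templates / sum(kept$templates)
  new_repertoire(rep$donor_id, rep$compartment, kept)
}

#' Aggregate a repertoire into clonotypes
#'
#' Collapses records to one clonotype per distinct key: either the CDR3
#' amino-acid sequence alone (`key = "aa"`, the default, matching
#' tracking "by TCR-beta sequence alone") or amino-acid plus V gene
#' (`key = "aa_v"`). Templates and frequencies are summed. Output is
#' sorted by descending templates with ties broken lexicographically by
#' `aa_seq` (then `v_gene`), so the ordering is deterministic.
#'
#' @param rep A productive-filtered `tcr_repertoire`.
#' @param key Aggregation key, `"aa"` or `"aa_v"`.
#' @return A tibble with columns `aa_seq` (and `v_gene` for `"aa_v"`;
#'   for `"aa"` the V gene of the most abundant record is carried along
#'   for annotation), `j_gene`, `templates`, `frequency`, `n_records`.
#' @export
aggregate_clonotypes <- function(rep, key = c("aa", "aa_v")) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (!is.character(key)) stop_config("unknown clonotype key specification")
  key <- tryCatch(match.arg(key),
                  error = function(e) stop_config(
                    paste0("unknown clonotype key: ", key[1])))
  r <- rep$records[order(-rep$records$templates, rep$records$aa_seq), ,
                   drop = FALSE]
  keyv <- if (key == "aa") r$aa_seq else
    paste(r$aa_seq, r$v_gene, sep = "\r")
  # rowsum(reorder = FALSE) groups in order of first appearance, which
  # matches !duplicated(keyv); the first record per key is the most
  # abundant one and donates the annotation genes
  tsum <- rowsum(r$templates, keyv, reorder = FALSE)[, 1]
  fsum <- rowsum(r$frequency, keyv, reorder = FALSE)[, 1]
  nrec <- rowsum(rep(1L, nrow(r)), keyv, reorder = FALSE)[, 1]
  first <- !duplicated(keyv)
  out <- tibble(
    aa_seq = r$aa_seq[first],
    v_gene = r$v_gene[first],
    j_gene = r$j_gene[first],
    templates = as.integer(unname(tsum)),
    frequency = unname(fsum),
    n_records = as.integer(unname(nrec))
  )
  arrange(out, desc(.data$templates), .data$aa_seq)
}

#' Read a cohort manifest and load all repertoires
#'
#' The manifest maps `donor_id` x `compartment` to a file path, either as
#' a tab-separated table with those three columns or as a YAML list of
#' `{donor_id, compartment, path}` entries. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param manifest Path to a `.tsv`/`.txt` or `.yaml`/`.yml` manifest.
#' @inheritParams read_repertoire
#' @return A named list of `tcr_repertoire` objects, names
#'   `"<donor>.<compartment>"`; `(donor_id, compartment)` must be unique.
#' @export
read_cohort <- function(manifest, column_map = default_column_map()) {
  if (grepl("\\.ya?ml$", manifest, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(manifest)
    tab <- bind_rows(lapply(entries, as_tibble))
  } else {
    tab <- readr::read_tsv(manifest, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  }
  needed <- c("donor_id", "compartment", "path")
  if (!all(needed %in% names(tab))) {
    stop_format("manifest must provide donor_id, compartment and path columns")
  }
  if (anyDuplicated(tab[, c("donor_id", "compartment")])) {
    stop_format("duplicate (donor_id, compartment) entries in manifest")
  }
  base <- dirname(manifest)
  reps <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$path[i]
    if (!file.exists(p)) p <- file.path(base, tab$path[i])
    read_repertoire(p, tab$donor_id[i], tab$compartment[i], column_map)
  })
  names(reps) <- paste(tab$donor_id, tab$compartment, sep = ".")
  reps
}

# Subset a cohort list by compartment; returns the list in donor order.
cohort_compartment <- function(cohort, compartment) {
  reps <- Filter(function(r) r$compartment == compartment, cohort)
  reps[order(vapply(reps, function(r) r$donor_id, character(1)))]
}
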