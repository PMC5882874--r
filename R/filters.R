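# Tabular decision rules: putative-transporter annotation from homology
# evidence, and single-copy phylogenetic marker selection.  BLASTP / Pfam /
# TMHMM are never executed here; their evidence arrives as table columns and
# the contribution is the decision rule itself.

#' Filter putative transporter candidates
#'
#' A query passes when at least one of its homology records satisfies every
#' condition: `evalue <= evalue_max`, `similarity_pct >= similarity_min`,
#' `coverage_pct >= coverage_min`, `has_transporter_domain` is `TRUE` and
#' `n_tm_helices >= min_tm`.  Note the non-strict comparisons, which follow
#' the printed operators of the rule (E-value <= 1e-5, similarity >= 50%,
#' coverage >= 30%).
#'
#' @param records data.frame with columns `query_id`, `subject_id`, `evalue`,
#'   `similarity_pct`, `coverage_pct`, `has_transporter_domain`,
#'   `n_tm_helices`.
#' @param evalue_max,similarity_min,coverage_min,min_tm rule thresholds
#'   (defaults 1e-5, 50, 30, 1).
#' @return sorted unique character vector of passing `query_id`s.
#' @export
filter_transporter_candidates <- function(records, evalue_max = 1e-5,
                                          similarity_min = 50,
                                          coverage_min = 30, min_tm = 1L) {
  need <- c("query_id", "evalue", "similarity_pct", "coverage_pct",
            "has_transporter_domain", "n_tm_helices")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("similarity_pct", "coverage_pct")) {
    v <- records[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 100))
      stop("malformed percentage in column '", col, "'")
  }
  if (any(records$evalue < 0)) stop("negative E-value")
  ok <- records$evalue <= evalue_max &
    records$similarity_pct >= similarity_min &
    records$coverage_pct >= coverage_min &
    as.logical(records$has_transporter_domain) &
    records$n_tm_helices >= min_tm
  sort(unique(records$query_id[ok]))
}

#' Select single-copy phylogenetic marker proteins
#'
#' A protein is selected when, in *every* listed genome, it has exactly one
#' hit with `best_evalue <= evalue_max` and `best_coverage_pct` strictly
#' greater than `coverage_min` (the marker rule uses a strict `>`).
#'
#' @param table data.frame with columns `protein_id`, `genome_id`, `n_hits`,
#'   `best_evalue`, `best_coverage_pct`.
#' @param genomes character vector of genome ids the table must cover.
#' @param evalue_max,coverage_min thresholds (defaults 1e-5 and 50).
#' @return sorted character vector of selected `protein_id`s.
#' @export
select_single_copy_markers <- function(table, genomes, evalue_max = 1e-5,
                                       coverage_min = 50) {
  need <- c("protein_id", "genome_id", "n_hits", "best_evalue",
            "best_coverage_pct")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(genomes, unique(table$genome_id))
  if (length(absent))
    stop("genome(s) missing from table: ", paste(absent, collapse = ", "))
  sel <- vapply(sort(unique(table$protein_id)), function(p) {
    sub <- table[table$protein_id == p & table$genome_id %in% genomes, ,
                 drop = FALSE]
    if (!setequal(sub$genome_id, genomes)) return(FALSE)
    all(sub$n_hits == 1L & sub$best_evalue <= evalue_max &
          sub$best_coverage_pct > coverage_min)
  }, NA)
  names(sel)[sel]
}

#' Read a homology-evidence TSV
#'
#' Expects a header row; a column-mapping allows BLAST outfmt-6-like column
#' names to be adapted.
#'
#' @param path TSV path.
#' @param column_map optional named character vector mapping file columns to
#'   the canonical names (e.g. `c(qseqid = "query_id")`).
#' @return data.frame.
#' @export
read_homology_tsv <- function(path, column_map = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(d))
    names(d)[idx[!is.na(idx)]] <- column_map[!is.na(idx)]
  }
  d
}

#' Write a plain id list (one per line)
#' @param ids character vector.
#' @param path output path.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
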