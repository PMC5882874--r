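# Pipeline orchestration: scan -> locate -> classify -> report, plus the
# species x gene-category presence/absence matrix and a plain key=value
# config format.

#' Read a key=value configuration file
#'
#' Lines of the form `key=value`; `#` starts a comment; values containing
#' commas become vectors; numeric-looking values are converted.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    v <- strsplit(val, ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(v))
    out[[key]] <- if (!anyNA(num)) num else v
  }
  out
}

#' Write a key=value configuration file
#' @param config named list of scalars/vectors.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  writeLines(paste0(names(config), "=",
                    vapply(config, function(v) paste(v, collapse = ","), "")),
             path)
  invisible(path)
}

MATRIX_STATES <- c(ABSENT = 0L, GENE_ONLY = 1L, RS_AND_GENE = 2L)

#' Build the species x gene-category presence/absence matrix
#'
#' Cell states: `2` (`RS_AND_GENE`) when at least one located hit or
#' regulation call lies on a gene of that category in that species, `1`
#' (`GENE_ONLY`) when the species has such a gene but no hit, `0` (`ABSENT`)
#' when it has no gene of the category.  Genes missing from the category map
#' are reported via the `uncategorized` attribute.
#'
#' @param calls call (or context) data.frame with `gene_id`; rows whose
#'   `reg_type`/`context_class` indicates no gene association are ignored.
#' @param gene_categories data.frame with columns `gene_id`, `category`,
#'   `species`.
#' @param species optional character vector fixing row order (defaults to
#'   order of first appearance in `gene_categories`).
#' @return integer matrix (species x category) with attribute
#'   `uncategorized`.
#' @export
build_matrix <- function(calls, gene_categories, species = NULL) {
  need <- c("gene_id", "category", "species")
  miss <- setdiff(need, names(gene_categories))
  if (length(miss)) stop("gene_categories lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(species)) species <- unique(gene_categories$species)
  cats <- unique(gene_categories$category)
  m <- matrix(MATRIX_STATES[["ABSENT"]], length(species), length(cats),
              dimnames = list(species, cats))
  for (k in seq_len(nrow(gene_categories))) {
    r <- gene_categories[k, ]
    if (!r$species %in% species) next
    m[r$species, r$category] <- max(m[r$species, r$category],
                                    MATRIX_STATES[["GENE_ONLY"]])
  }
  hit_genes <- unique(calls$gene_id[!is.na(calls$gene_id)])
  uncategorized <- setdiff(hit_genes, gene_categories$gene_id)
  for (g in intersect(hit_genes, gene_categories$gene_id)) {
    rows <- gene_categories[gene_categories$gene_id == g, , drop = FALSE]
    for (k in seq_len(nrow(rows)))
      if (rows$species[k] %in% species)
        m[rows$species[k], rows$category[k]] <- MATRIX_STATES[["RS_AND_GENE"]]
  }
  empty <- rownames(m)[!rownames(m) %in% gene_categories$species]
  if (length(empty))
    warning("species with zero genes: ", paste(empty, collapse = ", "))
  attr(m, "uncategorized") <- uncategorized
  m
}

#' Write a presence/absence matrix as TSV
#' @param m matrix from [build_matrix()].
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(species = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Reads the genome, gene models and seed alignment named in the config,
#' builds the profile, scans every sequence, locates and classifies the hits,
#' applies any homology filter table, and writes `hits.tsv`, `hits.bed`,
#' `contexts.tsv`, `calls.tsv`, the presence/absence `matrix.tsv` (when a
#' category map is supplied) and a `run_log.txt` to the output directory.
#'
#' Recognised config keys: `genome` (FASTA, required), `gff` (GFF3,
#' optional), `seed_alignment` (aligned FASTA, required), `out_dir`,
#' `threshold_frac` (default 0.6), `threshold_bits` (overrides the fraction),
#' `pseudocount`, `gap_open`, `gap_extend`, `gene_categories` (TSV with
#' `gene_id`, `category`, `species`), `homology` (TSV for the transporter
#' filter), plus every [classifier_params()] field.
#'
#' @param config path to a key=value config file, or an equivalent named
#'   list.
#' @param out_dir output directory (overrides the config key).
#' @return (invisibly) list with the result tables and output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  for (key in c("genome", "seed_alignment")) {
    if (is.null(cfg[[key]])) stop("config lacks required key '", key, "'")
    if (!file.exists(cfg[[key]]))
      stop("input file for '", key, "' not found: ", cfg[[key]])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(out_dir, "run_log.txt")
  logln <- function(...) cat(..., "\n", sep = "", file = log, append = TRUE)
  cat("", file = log)
  logln("riboreg ", as.character(utils::packageVersion("riboreg")))
  logln("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  for (k in names(cfg)) logln("config ", k, "=", paste(cfg[[k]], collapse = ","))

  genomes <- read_fasta(cfg$genome)
  aln <- read_fasta(cfg$seed_alignment)
  profile <- build_profile(vapply(aln, `[[`, "", "sequence"),
                           pseudocount = cfg$pseudocount %||% 1,
                           gap_open = cfg$gap_open %||% -4,
                           gap_extend = cfg$gap_extend %||% -1)
  threshold <- cfg$threshold_bits %||%
    default_threshold(profile, cfg$threshold_frac %||% 0.6)
  logln("profile: ", profile$length, " columns, threshold ",
        round(threshold, 2), " bits")
  hits <- scan_genomes(profile, genomes)
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  logln(nrow(hits), " hit(s)")
  genes <- if (!is.null(cfg$gff)) read_gff3(cfg$gff, genomes) else list()
  contexts <- locate_hits(hits, genes)
  pars <- do.call(classifier_params,
                  cfg[intersect(names(cfg), names(formals(classifier_params)))])
  calls <- if (length(genes)) classify_hits(hits, contexts, genes, genomes, pars)
           else call_row("x", "x", "x", "x")[0L, , drop = FALSE]
  write_hits_tsv(hits, file.path(out_dir, "hits.tsv"))
  write_hits_bed(hits, file.path(out_dir, "hits.bed"))
  write_contexts_tsv(contexts, file.path(out_dir, "contexts.tsv"))
  write_calls_tsv(calls, file.path(out_dir, "calls.tsv"))
  outputs <- list(hits = hits, contexts = contexts, calls = calls,
                  profile = profile, threshold = threshold, out_dir = out_dir)
  if (!is.null(cfg$gene_categories)) {
    gcat <- read.delim(cfg$gene_categories, stringsAsFactors = FALSE)
    located <- contexts[!is.na(contexts$gene_id), , drop = FALSE]
    m <- build_matrix(located, gcat)
    write_matrix_tsv(m, file.path(out_dir, "matrix.tsv"))
    outputs$matrix <- m
    if (length(attr(m, "uncategorized")))
      logln("uncategorized gene(s) with hits: ",
            paste(attr(m, "uncategorized"), collapse = ", "))
  }
  if (!is.null(cfg$homology)) {
    hom <- read_homology_tsv(cfg$homology)
    ids <- filter_transporter_candidates(hom)
    write_id_list(ids, file.path(out_dir, "transporter_candidates.txt"))
    outputs$transporters <- ids
    logln(length(ids), " transporter candidate(s)")
  }
  logln("done")
  invisible(outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
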