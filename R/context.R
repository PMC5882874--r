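# Genomic-context assignment of aptamer hits relative to gene models.

CONTEXT_CLASSES <- c("FIVE_UTR_INTRON", "INTERNAL_INTRON", "THREE_UTR",
                     "FIVE_UTR_SINGLE_EXON", "FIVE_UTR_EXONIC",
                     "INTERGENIC", "AMBIGUOUS")

#' Locate one aptamer hit relative to gene models
#'
#' Assigns exactly one context class: an intronic class when the hit lies
#' fully inside a derived intron (`THREE_UTR_INTRON` introns report as
#' `THREE_UTR`), a 5'UTR-exonic class (split by single- vs multi-exon gene),
#' `THREE_UTR` for 3'UTR-exonic hits, `AMBIGUOUS` for hits straddling a
#' feature boundary or lying in coding exon sequence, and `INTERGENIC` when
#' no gene overlaps the hit.  When several genes overlap, the gene whose CDS
#' start is nearest downstream of the hit (in that gene's transcript
#' orientation) wins; ties break on lexicographic gene id.
#'
#' @param hit one-row data.frame (or list) with `hit_id`, `seq_id`, `start`,
#'   `end` as produced by [scan_genome()].
#' @param genes list of [GeneModel]s.
#' @return one-row data.frame: `hit_id`, `gene_id`, `context_class`,
#'   `intron_ordinal`, `intron_start`, `intron_end`, `intron_length`,
#'   `distance_to_cds_start` (transcript-orientation nt from hit 5' end to
#'   the first CDS base; positive when the CDS start is downstream).
#' @export
locate_hit <- function(hit, genes) {
  res <- function(gene_id = NA_character_, class, ord = NA_integer_,
                  is_ = NA_integer_, ie = NA_integer_, il = NA_integer_,
                  d = NA_integer_)
    data.frame(hit_id = hit$hit_id, gene_id = gene_id, context_class = class,
               intron_ordinal = ord, intron_start = is_, intron_end = ie,
               intron_length = il, distance_to_cds_start = d,
               stringsAsFactors = FALSE)
  overl <- Filter(function(g) {
    sp <- gene_span(g)
    g$seq_id == hit$seq_id && max(sp[1L], hit$start) < min(sp[2L], hit$end)
  }, genes)
  if (!length(overl)) return(res(class = "INTERGENIC"))
  dist <- vapply(overl, function(g) hit_cds_distance(hit, g), 0)
  ids <- vapply(overl, function(g) g$gene_id, "")
  down <- !is.na(dist) & dist >= 0
  pick <- if (any(down)) {
    cand <- which(down)
    cand[order(dist[cand], ids[cand])][1L]
  } else {
    ord <- order(is.na(dist), -dist, ids)
    ord[1L]
  }
  g <- overl[[pick]]
  d <- as.integer(dist[pick])
  introns <- derive_introns(g)
  for (k in seq_len(nrow(introns))) {
    if (introns$start[k] <= hit$start && introns$end[k] >= hit$end) {
      cls <- switch(introns$context[k],
                    FIVE_UTR_INTRON = "FIVE_UTR_INTRON",
                    INTERNAL_INTRON = "INTERNAL_INTRON",
                    THREE_UTR_INTRON = "THREE_UTR")
      return(res(g$gene_id, cls, introns$ordinal[k], introns$start[k],
                 introns$end[k], introns$length[k], d))
    }
  }
  if (iv_contained(hit$start, hit$end, g$utr5)) {
    cls <- if (nrow(g$exons) == 1L) "FIVE_UTR_SINGLE_EXON" else "FIVE_UTR_EXONIC"
    return(res(g$gene_id, cls, d = d))
  }
  if (iv_contained(hit$start, hit$end, g$utr3))
    return(res(g$gene_id, "THREE_UTR", d = d))
  # inside the gene but straddling a boundary, or in coding exon sequence
  res(g$gene_id, "AMBIGUOUS", d = d)
}

# transcript-orientation distance from the hit 5' end to the CDS start
hit_cds_distance <- function(hit, gene) {
  if (!nrow(gene$cds)) return(NA_real_)
  if (gene$strand == "+") min(gene$cds[, 1L]) - hit$start
  else hit$end - max(gene$cds[, 2L])
}

#' Locate a table of hits
#'
#' @param hits hit data.frame from [scan_genome()] / [scan_genomes()].
#' @param genes list of [GeneModel]s.
#' @return row-bound context data.frame, one row per hit.
#' @export
locate_hits <- function(hits, genes) {
  if (!nrow(hits))
    return(data.frame(hit_id = character(0), gene_id = character(0),
                      context_class = character(0), intron_ordinal = integer(0),
                      intron_start = integer(0), intron_end = integer(0),
                      intron_length = integer(0),
                      distance_to_cds_start = integer(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(hits)), function(k)
    locate_hit(hits[k, , drop = FALSE], genes))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write hit contexts as TSV
#' @param contexts data.frame from [locate_hits()].
#' @param path output path.
#' @export
write_contexts_tsv <- function(contexts, path) {
  write.table(contexts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
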