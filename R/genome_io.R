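# FASTA / GFF3 ingestion, gene models, intron derivation, sequence extraction.
# Internal coordinates: 0-based half-open on the plus strand of the genomic
# sequence.  GFF3 (1-based inclusive) is converted at this boundary only.

#' Construct a genome record
#'
#' @param seq_id sequence identifier.
#' @param sequence DNA string; lowercase and `U` are normalised on ingestion
#'   by [read_fasta()], so the constructor requires uppercase `A,C,G,T,N`.
#' @return an object of class `GenomeRecord` with fields `seq_id`,
#'   `sequence` and `length`.
#' @export
GenomeRecord <- function(seq_id, sequence) {
  stopifnot(is.character(seq_id), length(seq_id) == 1L, nzchar(seq_id),
            is.character(sequence), length(sequence) == 1L)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence for '", seq_id, "' contains characters outside {A,C,G,T,N}")
  structure(list(seq_id = seq_id, sequence = sequence,
                 length = nchar(sequence)),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat("<GenomeRecord>", x$seq_id, "-", x$length, "bp\n")
  invisible(x)
}

#' Construct a gene model
#'
#' One `GeneModel` per transcript (mRNA): multi-isoform genes yield several
#' independent models.  All interval sets are 0-based half-open genomic
#' coordinates, sorted and non-overlapping.  The CDS must be contained in the
#' exon union and UTRs are subsets of exons outside the CDS.
#'
#' @param gene_id transcript identifier (used as the gene key downstream).
#' @param seq_id identifier of the genomic sequence the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds,utr5,utr3 interval matrices (columns `start`, `end`) or
#'   objects coercible via `rbind`; `cds`/`utr5`/`utr3` may be empty.
#' @return an object of class `GeneModel`.
#' @export
GeneModel <- function(gene_id, seq_id, strand, exons,
                      cds = NULL, utr5 = NULL, utr3 = NULL) {
  as_ivm <- function(m) {
    if (is.null(m) || (is.matrix(m) && !nrow(m)))
      return(iv_mat(integer(0), integer(0)))
    m <- rbind(m)
    iv_mat(m[, 1L], m[, 2L])
  }
  exons <- as_ivm(exons); cds <- as_ivm(cds)
  utr5 <- as_ivm(utr5); utr3 <- as_ivm(utr3)
  if (!nrow(exons)) stop("gene '", gene_id, "' has no exons")
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene '", gene_id, "': exons overlap or are unsorted")
  for (k in seq_len(nrow(cds)))
    if (!iv_contained(cds[k, 1L], cds[k, 2L], exons))
      stop("gene '", gene_id, "': CDS interval (", cds[k, 1L], ",",
           cds[k, 2L], ") not inside any exon")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = exons, cds = cds, utr5 = utr5, utr3 = utr3),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("<GeneModel>", x$gene_id, "on", x$seq_id, x$strand, "-",
      nrow(x$exons), "exon(s),", nrow(x$cds), "CDS segment(s)\n")
  invisible(x)
}

gene_span <- function(gene) iv(gene$exons[1L, 1L], gene$exons[nrow(gene$exons), 2L])

# genomic position of the first CDS base in transcript orientation, or NA
cds_start_genomic <- function(gene) {
  if (!nrow(gene$cds)) return(NA_integer_)
  if (gene$strand == "+") min(gene$cds[, 1L]) else max(gene$cds[, 2L]) - 1L
}

#' Read a (multi-record) FASTA file
#'
#' Sequences are uppercased; `U` is mapped to `T` with a warning.  Anything
#' outside `A,C,G,T,N` is an error, as is a duplicated record id or an empty
#' file.
#'
#' @param path FASTA file path.
#' @return named list of [GenomeRecord] objects (names = `seq_id`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a valid FASTA file: ", path))
  if (!length(set)) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    s <- toupper(as.character(set[[k]]))
    if (grepl("U", s, fixed = TRUE)) {
      warning("sequence '", ids[k], "': U bases mapped to T")
      s <- gsub("U", "T", s, fixed = TRUE)
    }
    out[[k]] <- GenomeRecord(ids[k], s)
  }
  names(out) <- ids
  out
}

#' Write genome records as FASTA
#'
#' @param records list of [GenomeRecord] objects.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$seq_id), con)
    if (r$length == 0L) next
    starts <- seq(1L, r$length, by = width)
    writeLines(substring(r$sequence, starts,
                         pmin(starts + width - 1L, r$length)), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses the `gene`/`mRNA`/`exon`/`CDS` (plus optional `five_prime_UTR` /
#' `three_prime_UTR`) subset of GFF3 and returns one [GeneModel] per mRNA.
#' Coordinates are converted from 1-based inclusive to internal 0-based
#' half-open.  When UTR features are absent they are inferred as the exonic
#' complement of the CDS, split at the CDS boundaries.
#'
#' @param path GFF3 file path.
#' @param genome named list of [GenomeRecord]s used for bounds checking
#'   (optional; pass `NULL` to skip).
#' @return named list of [GeneModel] objects (names = mRNA id).
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- rtracklayer::readGFF(path,
                            columns = c("seqid", "type", "start", "end", "strand"),
                            tags = c("ID", "Parent"))
  g <- as.data.frame(g)
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, "")
  mrna <- g[g$type == "mRNA", , drop = FALSE]
  if (!nrow(mrna)) stop("GFF3 contains no mRNA features: ", path)
  out <- list()
  for (k in seq_len(nrow(mrna))) {
    mid <- mrna$ID[k]
    if (is.na(mid)) stop("mRNA feature without ID attribute in ", path)
    kids <- g[!is.na(g$Parent) & g$Parent == mid, , drop = FALSE]
    pick <- function(type) {
      f <- kids[kids$type == type, , drop = FALSE]
      iv_mat(f$start - 1L, f$end)                      # GFF3 -> 0-based half-open
    }
    exons <- pick("exon"); cds <- pick("CDS")
    utr5 <- pick("five_prime_UTR"); utr3 <- pick("three_prime_UTR")
    if (!nrow(exons)) stop("mRNA '", mid, "' has no exon features")
    seqid <- as.character(mrna$seqid[k])
    if (!is.null(genome)) {
      if (!seqid %in% names(genome))
        stop("mRNA '", mid, "' references unknown sequence '", seqid, "'")
      if (max(exons[, 2L]) > genome[[seqid]]$length || min(exons[, 1L]) < 0L)
        stop("mRNA '", mid, "': exon outside sequence bounds")
    }
    strand <- as.character(mrna$strand[k])
    if (!nrow(utr5) && !nrow(utr3) && nrow(cds)) {
      u <- infer_utrs(exons, cds, strand)
      utr5 <- u$utr5; utr3 <- u$utr3
    }
    out[[mid]] <- GeneModel(mid, seqid, strand, exons, cds, utr5, utr3)
  }
  out
}

# exon \ CDS split into 5' and 3' sides by transcript orientation
infer_utrs <- function(exons, cds, strand) {
  cs <- min(cds[, 1L]); ce <- max(cds[, 2L])
  non_cds <- do.call(rbind, lapply(seq_len(nrow(exons)), function(k)
    iv_setdiff(exons[k, 1L], exons[k, 2L], cds)))
  if (is.null(non_cds) || !nrow(non_cds))
    return(list(utr5 = iv_mat(integer(0), integer(0)),
                utr3 = iv_mat(integer(0), integer(0))))
  before <- non_cds[non_cds[, 2L] <= cs, , drop = FALSE]
  after  <- non_cds[non_cds[, 1L] >= ce, , drop = FALSE]
  if (strand == "+") list(utr5 = before, utr3 = after)
  else list(utr5 = after, utr3 = before)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`
#' features with `ID`/`Parent` attributes, converting back to the 1-based
#' inclusive GFF3 convention.
#'
#' @param genes list of [GeneModel] objects.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(seqid, type, m, strand, attrs) {
    if (!nrow(m)) return(character(0))
    sprintf("%s\triboreg\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, m[, 1L] + 1L, m[, 2L], strand, attrs)
  }
  for (g in genes) {
    span <- gene_span(g)
    gid <- paste0(g$gene_id, ".gene")
    writeLines(c(
      fmt(g$seq_id, "gene", rbind(span), g$strand, paste0("ID=", gid)),
      fmt(g$seq_id, "mRNA", rbind(span), g$strand,
          paste0("ID=", g$gene_id, ";Parent=", gid)),
      fmt(g$seq_id, "exon", g$exons, g$strand, paste0("Parent=", g$gene_id)),
      fmt(g$seq_id, "CDS", g$cds, g$strand, paste0("Parent=", g$gene_id)),
      fmt(g$seq_id, "five_prime_UTR", g$utr5, g$strand,
          paste0("Parent=", g$gene_id)),
      fmt(g$seq_id, "three_prime_UTR", g$utr3, g$strand,
          paste0("Parent=", g$gene_id))), con)
  }
  invisible(path)
}

#' Derive introns of a gene with context labels
#'
#' One intron per gap between consecutive exons.  `ordinal` counts introns in
#' transcript orientation (reverse genomic order for minus-strand genes).
#' `context` is `FIVE_UTR_INTRON` when the whole intron lies 5' of the CDS
#' start in transcript orientation, `THREE_UTR_INTRON` when 3' of the CDS end,
#' otherwise `INTERNAL_INTRON`.  Genes without an annotated CDS get
#' `INTERNAL_INTRON` for all introns.
#'
#' @param gene a [GeneModel].
#' @return data.frame with columns `gene_id`, `ordinal`, `start`, `end`,
#'   `length`, `context`; zero rows for single-exon genes.
#' @export
derive_introns <- function(gene) {
  ne <- nrow(gene$exons)
  empty <- data.frame(gene_id = character(0), ordinal = integer(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), context = character(0),
                      stringsAsFactors = FALSE)
  if (ne < 2L) return(empty)
  starts <- gene$exons[-ne, 2L]
  ends <- gene$exons[-1L, 1L]
  cs <- if (nrow(gene$cds)) min(gene$cds[, 1L]) else NA_integer_
  ce <- if (nrow(gene$cds)) max(gene$cds[, 2L]) else NA_integer_
  ctx <- vapply(seq_along(starts), function(k) {
    if (is.na(cs)) return("INTERNAL_INTRON")
    if (gene$strand == "+") {
      if (ends[k] <= cs) "FIVE_UTR_INTRON"
      else if (starts[k] >= ce) "THREE_UTR_INTRON"
      else "INTERNAL_INTRON"
    } else {
      if (starts[k] >= ce) "FIVE_UTR_INTRON"
      else if (ends[k] <= cs) "THREE_UTR_INTRON"
      else "INTERNAL_INTRON"
    }
  }, "")
  ord <- if (gene$strand == "+") seq_along(starts) else rev(seq_along(starts))
  data.frame(gene_id = gene$gene_id, ordinal = ord, start = starts,
             end = ends, length = ends - starts, context = ctx,
             stringsAsFactors = FALSE)[order(ord), , drop = FALSE]
}

#' Extract a (possibly reverse-complemented) subsequence
#'
#' @param genome a [GenomeRecord] or plain DNA string.
#' @param start,end 0-based half-open genomic interval.
#' @param strand `"+"` returns the subsequence as stored; `"-"` returns its
#'   reverse complement (the transcript-sense sequence of a minus-strand
#'   feature).
#' @return DNA string.
#' @export
extract_seq <- function(genome, start, end, strand = "+") {
  s <- if (inherits(genome, "GenomeRecord")) genome$sequence else genome
  n <- nchar(s)
  if (start < 0L || end > n || end < start)
    stop("interval (", start, ",", end, ") out of bounds for sequence of length ", n)
  x <- subseq0(s, start, end)
  if (strand == "-") revcomp(x) else x
}

# map a genomic interval to sense-strand offsets within a containing region
genomic_to_sense_offset <- function(start, end, region_start, region_end, strand) {
  if (strand == "+") c(start - region_start, end - region_start)
  else c(region_end - end, region_end - start)
}
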