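# Genome scanning: both strands, local affine-gap alignment against the
# profile, non-overlapping hit resolution, BED/TSV writers.

#' Scan a genome record for aptamer candidates
#'
#' Runs local, affine-gap alignment of the profile against both strands and
#' reports maximal-scoring non-overlapping segments with score at or above
#' `threshold_bits`, sorted by position.  Hits overlapping between strands are
#' resolved to the higher score (ties: leftmost, then plus strand).  Hit
#' intervals outside `[0.5, 2] x` profile length are discarded.
#'
#' @param profile a `ProfileModel` from [build_profile()].
#' @param genome a [GenomeRecord].
#' @param threshold_bits reporting threshold in bits; defaults to
#'   [default_threshold()] of the profile.
#' @param p1_len length of the 3'-proximal segment of the hit recorded as the
#'   P1/alpha' pairing window (default 9 nt).
#' @return data.frame with columns `hit_id`, `seq_id`, `start`, `end`,
#'   `strand`, `score`, `hit_sequence`, `p1_start`, `p1_end` (`p1_*` are
#'   0-based offsets within `hit_sequence`).
#' @export
scan_genome <- function(profile, genome, threshold_bits = default_threshold(profile),
                        p1_len = 9L) {
  stopifnot(inherits(profile, "ProfileModel"), inherits(genome, "GenomeRecord"))
  if (genome$length == 0L) stop("genome sequence is empty")
  fwd <- scan_dp_cpp(profile$match_logodds, encode_dna(genome$sequence),
                     profile$gap_open, profile$gap_extend, threshold_bits)
  rcseq <- revcomp(genome$sequence)
  rev <- scan_dp_cpp(profile$match_logodds, encode_dna(rcseq),
                     profile$gap_open, profile$gap_extend, threshold_bits)
  n <- genome$length
  hits <- rbind(
    data.frame(start = fwd$start, end = fwd$end, strand = rep("+", length(fwd$start)),
               score = fwd$score, stringsAsFactors = FALSE),
    data.frame(start = n - rev$end, end = n - rev$start,
               strand = rep("-", length(rev$start)), score = rev$score,
               stringsAsFactors = FALSE))
  if (nrow(hits)) {
    len_ok <- (hits$end - hits$start) >= 0.5 * profile$length &
              (hits$end - hits$start) <= 2 * profile$length
    hits <- hits[len_ok, , drop = FALSE]
  }
  hits <- resolve_overlaps(hits)
  if (!nrow(hits)) {
    return(data.frame(hit_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      hit_sequence = character(0), p1_start = integer(0),
                      p1_end = integer(0), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  hseq <- vapply(seq_len(nrow(hits)), function(k)
    extract_seq(genome, hits$start[k], hits$end[k], hits$strand[k]), "")
  p1s <- pmax(nchar(hseq) - p1_len, 0L)
  data.frame(hit_id = sprintf("%s_hit%d", genome$seq_id, seq_len(nrow(hits))),
             seq_id = genome$seq_id, start = hits$start, end = hits$end,
             strand = hits$strand, score = hits$score, hit_sequence = hseq,
             p1_start = as.integer(p1s), p1_end = nchar(hseq),
             stringsAsFactors = FALSE)
}

# keep the higher-scoring of any pair of overlapping hits
# (ties: leftmost, then '+' strand)
resolve_overlaps <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  pref <- order(-hits$score, hits$start, hits$strand)
  keep <- logical(nrow(hits))
  taken <- matrix(integer(0), 0L, 2L)
  for (k in pref) {
    if (!iv_overlaps(hits$start[k], hits$end[k], taken)) {
      keep[k] <- TRUE
      taken <- rbind(taken, c(hits$start[k], hits$end[k]))
    }
  }
  hits[keep, , drop = FALSE]
}

#' Scan several genome records
#'
#' @param profile a `ProfileModel`.
#' @param genomes named list of [GenomeRecord]s.
#' @param ... passed to [scan_genome()].
#' @return row-bound hit data.frame across records.
#' @export
scan_genomes <- function(profile, genomes, ...) {
  do.call(rbind, c(lapply(genomes, function(g) scan_genome(profile, g, ...)),
                   list(make.row.names = FALSE)))
}

#' Write hits as BED6
#'
#' 0-based half-open intervals; the BED score column carries the bit score
#' scaled by 100 and rounded to integer.
#'
#' @param hits hit data.frame from [scan_genome()].
#' @param path output path.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$seq_id, hits$start, hits$end, hits$hit_id,
                    as.integer(round(hits$score * 100)), hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write hits (with motif annotation columns) as TSV
#'
#' @param hits hit data.frame from [scan_genome()].
#' @param path output path.
#' @param motif_config motif spacing parameters, see [motif_config()]; set to
#'   `NULL` to omit the motif columns.
#' @export
write_hits_tsv <- function(hits, path, motif_config = riboreg::motif_config()) {
  # (motif_config() is resolved lazily so a NULL can be passed to skip it)
  out <- hits
  if (!is.null(motif_config) && nrow(hits)) {
    ann <- lapply(hits$hit_sequence, annotate_motifs, config = motif_config)
    for (m in c("GAGAU", "J45_GCG", "L5_UAAU", "GG_PAIR")) {
      out[[paste0(tolower(m), "_ok")]] <- vapply(ann, function(a)
        a$satisfied[a$motif_name == m], NA)
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
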