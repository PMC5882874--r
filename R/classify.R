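# Four-type classification of riboswitch-mediated regulation from splice
# sites, uORFs, in-frame stop codons, intron length and the alpha element.
#
# Rule precedence is fixed at II -> III -> I -> IV.  Type II carries the most
# specific evidence (alpha complementarity), Type III the next (length window
# plus in-frame stop); the genomic contexts make I and IV disjoint from the
# internal-intron types, but a fixed order guarantees exclusivity regardless.

REG_TYPES <- c("TYPE_I", "TYPE_II", "TYPE_III", "TYPE_IV", "UNCLASSIFIED")

#' Classifier rule parameters
#'
#' All thresholds of the Type I-IV rules, with the observed-range defaults.
#' Intervals are closed.
#'
#' @param len2_lo,len2_hi intron-length window (nt) for Type II (long
#'   internal intron; defaults 650-900).
#' @param len3_lo,len3_hi intron-length window for Type III (short internal
#'   intron; defaults 200-400).
#' @param max_separation maximal alpha-element-to-aptamer separation in nt
#'   (default 700, covering the observed ~500 nt).
#' @param min_complementarity minimal alpha/alpha' Watson-Crick pair count
#'   out of 9 (default 6).
#' @param min_uorf_codons,max_uorf_codons uORF codon bounds for Type I
#'   (defaults 10 and 100; "short uORF" is otherwise unquantified).
#' @param alpha_between_donors when `TRUE`, additionally require the alpha
#'   element to lie between donors S1 and S2 (default `FALSE`: 5' of the
#'   aptamer within `max_separation` suffices).
#' @param utr_exclusion_pad nt added on each side of the hit interval when
#'   excluding it from the Type IV splice-site-free check of the 5'UTR
#'   (default 10; absorbs slight trimming of scanned hit ends).
#' @return a list of class `classifier_params`.
#' @export
classifier_params <- function(len2_lo = 650L, len2_hi = 900L,
                              len3_lo = 200L, len3_hi = 400L,
                              max_separation = 700L, min_complementarity = 6L,
                              min_uorf_codons = 10L, max_uorf_codons = 100L,
                              alpha_between_donors = FALSE,
                              utr_exclusion_pad = 10L) {
  structure(as.list(environment()), class = "classifier_params")
}

call_row <- function(hit_id, gene_id, reg_type, context_class,
                     intron_length = NA_integer_, s1_pos = NA_integer_,
                     s2_pos = NA_integer_, acceptor_pos = NA_integer_,
                     uorf_start = NA_integer_, uorf_codons = NA_integer_,
                     alpha_pos = NA_integer_, alpha_complementarity = NA_integer_,
                     stop_pos = NA_integer_, notes = "") {
  data.frame(hit_id = hit_id, gene_id = gene_id, reg_type = reg_type,
             context_class = context_class, intron_length = intron_length,
             s1_pos = s1_pos, s2_pos = s2_pos, acceptor_pos = acceptor_pos,
             uorf_start = uorf_start, uorf_codons = uorf_codons,
             alpha_pos = alpha_pos,
             alpha_complementarity = alpha_complementarity,
             stop_pos = stop_pos, notes = notes, stringsAsFactors = FALSE)
}

#' Classify the regulatory mechanism implied by one located hit
#'
#' Applies the Type II, III, I, IV rules in that fixed order; the first rule
#' whose full evidence set is present wins, otherwise `UNCLASSIFIED` with a
#' trace naming every failed condition of every rule.
#'
#' * **Type II**: internal intron with length in the Type II window, at least
#'   two donor GT sites, and an alpha element (degenerate `RGCGGYRRY` 9-mer
#'   complementary to the aptamer P1 window) 5' of the aptamer.
#' * **Type III**: internal intron with length in the Type III window, a
#'   donor pair bracketing a stop codon in the reading frame of the upstream
#'   CDS, both donors 5' of the aptamer, and an acceptor AG downstream of
#'   the aptamer.
#' * **Type I**: 5'UTR intron containing a uORF 5' of the aptamer, donors
#'   both 5' of the uORF (S1) and between the uORF and the aptamer (S2), and
#'   an acceptor AG at the intron 3' end.
#' * **Type IV**: 5'UTR of a single-exon gene with no GT and no AG anywhere
#'   in the UTR outside the (padded) aptamer interval itself.
#'
#' All splice/ORF logic runs on the transcript-sense sequence, so minus-strand
#' genes share one code path; positions in the returned evidence are sense
#' offsets within the intron (or 5'UTR for Type IV).
#'
#' @param hit one-row hit data.frame (needs `hit_id`, `seq_id`, `start`,
#'   `end`, `p1_start`, `p1_end`, `hit_sequence`; [scan_genome()] output, or
#'   an equivalent built from ground truth).
#' @param context one-row context data.frame from [locate_hit()].
#' @param gene the [GeneModel] named in the context (or `NULL` for
#'   intergenic hits).
#' @param genome the [GenomeRecord] carrying the gene.
#' @param params a [classifier_params()].
#' @return one-row call data.frame (`reg_type`, full evidence, `notes`).
#' @export
classify_hit <- function(hit, context, gene, genome,
                         params = classifier_params()) {
  ctx <- context$context_class
  fail <- character(0)
  if (is.na(ctx) || ctx %in% c("INTERGENIC", "AMBIGUOUS") || is.null(gene)) {
    return(call_row(hit$hit_id, context$gene_id, "UNCLASSIFIED", ctx,
                    notes = paste0("no rule applies to context ", ctx)))
  }
  if (gene$seq_id != genome$seq_id)
    stop("gene '", gene$gene_id, "' is not on sequence '", genome$seq_id, "'")
  p1_seq <- subseq0(hit$hit_sequence, hit$p1_start, hit$p1_end)

  intronic <- ctx %in% c("FIVE_UTR_INTRON", "INTERNAL_INTRON")
  if (intronic) {
    is0 <- context$intron_start; ie0 <- context$intron_end
    ilen <- context$intron_length
    intron_seq <- extract_seq(genome, is0, ie0, gene$strand)
    ap <- genomic_to_sense_offset(hit$start, hit$end, is0, ie0, gene$strand)
    sites <- find_splice_sites(intron_seq)
    donors <- sites$position[sites$kind == "donor"]
    acceptors <- sites$position[sites$kind == "acceptor"]
  }

  # ---- Type II ----------------------------------------------------------
  if (ctx == "INTERNAL_INTRON" && ilen >= params$len2_lo &&
      ilen <= params$len2_hi) {
    if (length(donors) >= 2L) {
      alpha <- find_alpha_element(intron_seq, ap[1L], p1_seq,
                                  params$max_separation,
                                  params$min_complementarity)
      if (!is.null(alpha) && params$alpha_between_donors) {
        d_ok <- any(donors < alpha$position) &&
                any(donors > alpha$position + 9L & donors < ap[1L])
        if (!d_ok) {
          fail <- c(fail, "II: alpha element not between donors S1 and S2")
          alpha <- NULL
        }
      }
      if (!is.null(alpha)) {
        s1 <- max(donors[donors < alpha$position], min(donors))
        s2c <- donors[donors > s1 & donors < ap[1L]]
        return(call_row(hit$hit_id, gene$gene_id, "TYPE_II", ctx, ilen,
                        s1_pos = s1,
                        s2_pos = if (length(s2c)) s2c[length(s2c)] else NA_integer_,
                        alpha_pos = alpha$position,
                        alpha_complementarity = alpha$complementarity,
                        notes = paste0("TYPE_II: internal intron ", ilen,
                                       " nt in [", params$len2_lo, ",",
                                       params$len2_hi, "]; ", length(donors),
                                       " donors; alpha at ", alpha$position,
                                       " (", alpha$complementarity,
                                       "/9 pairs, separation ",
                                       alpha$separation, " nt)")))
      }
      fail <- c(fail, "II: no alpha element (RGCGGYRRY with sufficient complementarity) 5' of aptamer")
    } else fail <- c(fail, "II: fewer than 2 donor GT sites")
  } else if (ctx == "INTERNAL_INTRON") {
    fail <- c(fail, paste0("II: intron length ", ilen, " outside [",
                           params$len2_lo, ",", params$len2_hi, "]"))
  } else fail <- c(fail, paste0("II: context is ", ctx, ", not INTERNAL_INTRON"))

  # ---- Type III ---------------------------------------------------------
  if (ctx == "INTERNAL_INTRON" && ilen >= params$len3_lo &&
      ilen <= params$len3_hi) {
    phase <- upstream_cds_phase(gene, is0, ie0)
    stops <- inframe_stops(intron_seq, phase)
    acc_down <- acceptors[acceptors >= ap[2L]]
    pair <- donor_pair_with_stop(donors, stops, ap[1L])
    if (!is.null(pair) && length(acc_down)) {
      return(call_row(hit$hit_id, gene$gene_id, "TYPE_III", ctx, ilen,
                      s1_pos = pair$d1, s2_pos = pair$d2,
                      acceptor_pos = acc_down[1L], stop_pos = pair$stop,
                      notes = paste0("TYPE_III: internal intron ", ilen,
                                     " nt in [", params$len3_lo, ",",
                                     params$len3_hi, "]; in-frame stop at ",
                                     pair$stop, " between donors ", pair$d1,
                                     " and ", pair$d2, "; acceptor at ",
                                     acc_down[1L], " downstream of aptamer")))
    }
    if (is.null(pair))
      fail <- c(fail, "III: no donor pair 5' of aptamer bracketing an in-frame stop codon")
    if (!length(acc_down))
      fail <- c(fail, "III: no acceptor AG downstream of aptamer")
  } else if (ctx == "INTERNAL_INTRON") {
    fail <- c(fail, paste0("III: intron length ", ilen, " outside [",
                           params$len3_lo, ",", params$len3_hi, "]"))
  } else fail <- c(fail, paste0("III: context is ", ctx, ", not INTERNAL_INTRON"))

  # ---- Type I -----------------------------------------------------------
  if (ctx == "FIVE_UTR_INTRON") {
    uorfs <- find_uorfs(intron_seq, params$min_uorf_codons,
                        params$max_uorf_codons)
    acc_end <- substr(intron_seq, ilen - 1L, ilen) == "AG"
    picked <- NULL
    for (k in seq_len(nrow(uorfs))) {
      if (uorfs$end[k] > ap[1L]) next                 # uORF must be 5' of aptamer
      s1c <- donors[donors + 2L <= uorfs$start[k]]
      s2c <- donors[donors >= uorfs$end[k] & donors + 2L <= ap[1L]]
      if (length(s1c) && length(s2c)) {
        picked <- list(u = uorfs[k, ], s1 = s1c[1L], s2 = s2c[1L])
        break
      }
    }
    if (!is.null(picked) && acc_end) {
      return(call_row(hit$hit_id, gene$gene_id, "TYPE_I", ctx, ilen,
                      s1_pos = picked$s1, s2_pos = picked$s2,
                      acceptor_pos = ilen - 2L,
                      uorf_start = picked$u$start,
                      uorf_codons = picked$u$n_codons,
                      notes = paste0("TYPE_I: 5'UTR intron ", ilen,
                                     " nt; uORF of ", picked$u$n_codons,
                                     " codons at ", picked$u$start,
                                     "; donors S1=", picked$s1, " S2=",
                                     picked$s2, "; acceptor AG at intron 3' end")))
    }
    if (!nrow(uorfs))
      fail <- c(fail, "I: no uORF in 5'UTR intron")
    else if (is.null(picked))
      fail <- c(fail, "I: no uORF 5' of aptamer flanked by donors (S1 before, S2 between uORF and aptamer)")
    if (!acc_end) fail <- c(fail, "I: intron does not end with acceptor AG")
  } else fail <- c(fail, paste0("I: context is ", ctx, ", not FIVE_UTR_INTRON"))

  # ---- Type IV ----------------------------------------------------------
  if (ctx == "FIVE_UTR_SINGLE_EXON") {
    segs <- utr_outside_hit(gene, genome, hit, params$utr_exclusion_pad)
    offending <- any(vapply(segs, function(s)
      grepl("GT", s, fixed = TRUE) || grepl("AG", s, fixed = TRUE), NA))
    if (!offending) {
      return(call_row(hit$hit_id, gene$gene_id, "TYPE_IV", ctx,
                      notes = paste0("TYPE_IV: single-exon 5'UTR with no GT/AG",
                                     " outside the aptamer interval")))
    }
    fail <- c(fail, "IV: GT or AG dinucleotide present in 5'UTR outside aptamer")
  } else fail <- c(fail, paste0("IV: context is ", ctx,
                                ", not FIVE_UTR_SINGLE_EXON"))

  call_row(hit$hit_id, gene$gene_id, "UNCLASSIFIED", ctx,
           intron_length = if (intronic) ilen else NA_integer_,
           notes = paste(fail, collapse = "; "))
}

# number of CDS nucleotides upstream of an intron in transcript orientation,
# modulo 3 (the phase in which read-through translation enters the intron)
upstream_cds_phase <- function(gene, intron_start, intron_end) {
  if (!nrow(gene$cds)) return(0L)
  if (gene$strand == "+") {
    up <- gene$cds[gene$cds[, 2L] <= intron_start, , drop = FALSE]
  } else {
    up <- gene$cds[gene$cds[, 1L] >= intron_end, , drop = FALSE]
  }
  as.integer(iv_len(up) %% 3L)
}

# 5'-most donor pair (d1 < stop < d2), both donors 5' of the aptamer start
donor_pair_with_stop <- function(donors, stops, aptamer_offset) {
  donors <- donors[donors + 2L <= aptamer_offset]
  stops <- stops[stops + 3L <= aptamer_offset]
  for (d1 in donors) {
    ss <- stops[stops >= d1 + 2L]
    for (s in ss) {
      d2 <- donors[donors >= s + 3L]
      if (length(d2)) return(list(d1 = d1, stop = s, d2 = d2[1L]))
    }
  }
  NULL
}

# sense-strand 5'UTR sequence split around the (padded) hit interval;
# pieces are joined with '|' so no dinucleotide spans a removed region
utr_outside_hit <- function(gene, genome, hit, pad) {
  lapply(seq_len(nrow(gene$utr5)), function(k) {
    u <- gene$utr5[k, ]
    keep <- iv_setdiff(max(u[1L], 0L), u[2L],
                       rbind(c(max(hit$start - pad, 0L), hit$end + pad)))
    paste(vapply(seq_len(nrow(keep)), function(j)
      extract_seq(genome, keep[j, 1L], keep[j, 2L], gene$strand), ""),
      collapse = "|")
  })
}

#' Classify all located hits
#'
#' @param hits hit data.frame.
#' @param contexts matching context data.frame from [locate_hits()].
#' @param genes named list of [GeneModel]s.
#' @param genomes named list of [GenomeRecord]s.
#' @param params a [classifier_params()].
#' @return call data.frame, one row per hit.
#' @export
classify_hits <- function(hits, contexts, genes, genomes,
                          params = classifier_params()) {
  rows <- lapply(seq_len(nrow(hits)), function(k) {
    ctx <- contexts[k, , drop = FALSE]
    g <- if (!is.na(ctx$gene_id)) genes[[ctx$gene_id]] else NULL
    gn <- genomes[[hits$seq_id[k]]]
    classify_hit(hits[k, , drop = FALSE], ctx, g, gn, params)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- call_row("x", "x", "x", "x")[0L, , drop = FALSE]
  out
}

#' Write regulation calls as TSV
#' @param calls data.frame from [classify_hits()].
#' @param path output path.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
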