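# Splice-site, uORF and alpha-element detection on sense-strand region
# sequences (introns or UTRs).  All offsets are 0-based within the region.

#' Find candidate splice sites in a region
#'
#' Every `GT` occurrence is reported as a donor candidate and every `AG` as an
#' acceptor candidate; donors are labelled `S1`, `S2`, ... 5' to 3'.  `N`
#' bases fail the dinucleotide match.
#'
#' @param region sense-strand DNA string (an intron or UTR).
#' @return data.frame with columns `kind` (`donor`/`acceptor`), `position`
#'   (0-based offset of the dinucleotide), `dinucleotide`, `label` (`S1`,
#'   `S2`, ... for donors, `NA` for acceptors).
#' @export
find_splice_sites <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  don <- str_find_all(region, "GT")
  acc <- str_find_all(region, "AG")
  out <- rbind(
    if (length(don)) data.frame(kind = "donor", position = don,
                                dinucleotide = "GT",
                                label = paste0("S", seq_along(don)),
                                stringsAsFactors = FALSE),
    if (length(acc)) data.frame(kind = "acceptor", position = acc,
                                dinucleotide = "AG", label = NA_character_,
                                stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(kind = character(0), position = integer(0),
                      dinucleotide = character(0), label = character(0),
                      stringsAsFactors = FALSE)
  out[order(out$position, out$kind), , drop = FALSE]
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find upstream open reading frames
#'
#' Reports every `ATG ... in-frame stop` span with a codon count (stop
#' included) in `[min_codons, max_codons]` and no internal stop, in all three
#' frames, sorted by start.  Each ATG contributes at most one uORF (its first
#' in-frame stop).
#'
#' @param region sense-strand DNA string.
#' @param min_codons,max_codons inclusive codon-count bounds (stop included);
#'   `min_codons` must be >= 2.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `n_codons`, `frame` (start offset mod 3).
#' @export
find_uorfs <- function(region, min_codons = 10L, max_codons = 100L) {
  stopifnot(min_codons >= 2L, max_codons >= min_codons)
  n <- nchar(region)
  res <- list()
  for (a in str_find_all(region, "ATG")) {
    pos <- a + 3L
    while (pos + 3L <= n) {
      codon <- substr(region, pos + 1L, pos + 3L)
      if (codon %in% STOP_CODONS) {
        nc <- (pos + 3L - a) / 3L
        if (nc >= min_codons && nc <= max_codons)
          res[[length(res) + 1L]] <-
            data.frame(start = a, end = pos + 3L, n_codons = as.integer(nc),
                       frame = a %% 3L)
        break
      }
      pos <- pos + 3L
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      n_codons = integer(0), frame = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Find the alpha element of a long riboswitch-carrying intron
#'
#' Searches the intron 5' of the aptamer for 9-mers matching the degenerate
#' consensus `RGCGGYRRY` and scores each by its Watson-Crick complementarity
#' to the aptamer's 3'-proximal P1 window (alpha pairs antiparallel with
#' alpha', so complementarity is the number of positions at which the 9-mer
#' equals the reverse complement of the P1 window).  The best-complementarity
#' match within `max_separation` nt of the aptamer 5' end is returned (ties:
#' 5'-most); `NULL` when no 9-mer matches or the best complementarity is
#' below `min_complementarity`.
#'
#' @param intron_seq sense-strand intron sequence.
#' @param aptamer_offset 0-based offset of the aptamer 5' end within the
#'   intron.
#' @param p1_seq the aptamer's P1 window sequence (3'-proximal segment).
#' @param max_separation maximal nt between the 3' end of the 9-mer and the
#'   aptamer 5' end (default 700, covering the observed ~500 nt separation).
#' @param min_complementarity minimal Watson-Crick pair count (default 6).
#' @return `NULL` or a list with `position`, `matched`, `complementarity`,
#'   `separation`.
#' @export
find_alpha_element <- function(intron_seq, aptamer_offset, p1_seq,
                               max_separation = 700L, min_complementarity = 6L) {
  cand <- iupac_match("RGCGGYRRY", intron_seq)
  cand <- cand[cand + 9L <= aptamer_offset &
               aptamer_offset - (cand + 9L) <= max_separation]
  if (!length(cand)) return(NULL)
  target <- chars(revcomp(p1_seq))
  comp <- vapply(cand, function(p) {
    nine <- chars(subseq0(intron_seq, p, p + 9L))
    w <- min(length(nine), length(target))
    sum(nine[seq_len(w)] == target[seq_len(w)])
  }, 0)
  best <- which(comp == max(comp))[1L]              # ties: 5'-most
  if (comp[best] < min_complementarity) return(NULL)
  list(position = cand[best],
       matched = subseq0(intron_seq, cand[best], cand[best] + 9L),
       complementarity = as.integer(comp[best]),
       separation = as.integer(aptamer_offset - (cand[best] + 9L)))
}

# all 0-based offsets in region that start a stop codon in the reading frame
# continuing from `phase` upstream coding nucleotides
inframe_stops <- function(region, phase) {
  offs <- sort(unlist(lapply(STOP_CODONS, str_find_all, x = region),
               use.names = FALSE))
  offs[(phase + offs) %% 3L == 0L]
}
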