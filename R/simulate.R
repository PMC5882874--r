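# Ground-truth synthetic genomes: one gene architecture per genome record,
# with the planted evidence (aptamer, motifs, splice sites, uORF, alpha
# element, in-frame stop) recorded in a TruthRecord so every downstream stage
# can be scored exactly.

# Fixed default aptamer consensus, 100 nt.  Layout (0-based offsets):
#   0-4    CCACT        stabilising prefix (held invariant under mutation)
#   5-9    GAGAT        pyrimidine-ring recognition motif
#   10-23  G-free linker
#   24-26  GCG          J4/5 pyrophosphate-contact motif
#   27-39  G-free linker
#   40-43  TAAT         loop L5 closing motif
#   44-90  mixed linker
#   91-99  ATTACCGCT    P1 window; reverse complement AGCGGTAAT matches the
#                       degenerate alpha consensus RGCGGYRRY
# The G at 5 and the G at 24 form the non-canonical G-G pair with exactly 18
# intervening bases.
RIBOREG_CONSENSUS <- paste0(
  "CCACT", "GAGAT", "CACTCCATCATCCT", "GCG", "CACCTACTACCTA", "TAAT",
  "GGTCAACCTGGCAAGCTTCCAGGCTACCGATCCAGCTTGGACCTCAA", "ATTACCGCT")

#' Default aptamer consensus used by the synthetic generator
#' @return a 100 nt DNA string satisfying every planted-motif constraint.
#' @export
default_aptamer_consensus <- function() RIBOREG_CONSENSUS

#' Synthetic-data configuration
#'
#' The defaults state the simulated world: intron-length windows per
#' architecture type match the observed ranges (Type I 5'UTR intron 300-600
#' nt, Type II 650-900 nt, Type III 200-400 nt), the alpha-to-aptamer
#' separation is drawn around the observed ~500 nt, and decoy genes carry a
#' shuffled aptamer in a 450-550 nt internal intron (between the Type III and
#' Type II windows, so no length rule can fire).
#'
#' @param seed master integer seed; every architecture derives its own
#'   sub-seed from `(seed, gene index)` so generation order never matters.
#' @param n_per_type architectures per planted type (default 50).
#' @param n_decoys decoy genes (default 50).
#' @param intergenic_gc GC fraction of background sequence (default 0.45).
#' @param intron_len_I,intron_len_II,intron_len_III,intron_len_decoy
#'   inclusive length ranges of the riboswitch-carrying intron.
#' @param uorf_codons uORF codon-count range for Type I (default 10-40).
#' @param alpha_separation alpha-to-aptamer separation range for Type II
#'   (default 400-600 nt).
#' @param aptamer_mutation_rate per-base substitution rate outside held
#'   motif/P1 positions (default 0.02; must be <= 0.25).
#' @param consensus aptamer consensus string (validated on use).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_per_type = 50L, n_decoys = 50L,
                       intergenic_gc = 0.45,
                       intron_len_I = c(300L, 600L),
                       intron_len_II = c(650L, 900L),
                       intron_len_III = c(200L, 400L),
                       intron_len_decoy = c(450L, 550L),
                       uorf_codons = c(10L, 40L),
                       alpha_separation = c(400L, 600L),
                       aptamer_mutation_rate = 0.02,
                       consensus = default_aptamer_consensus()) {
  stopifnot(aptamer_mutation_rate >= 0, aptamer_mutation_rate <= 0.25,
            diff(intron_len_I) >= 0, diff(intron_len_II) >= 0,
            diff(intron_len_III) >= 0, diff(uorf_codons) >= 0,
            diff(alpha_separation) >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# ---- aptamer ------------------------------------------------------------

P1_LEN <- 9L

# offsets of planted motifs in a consensus, found by the same first-occurrence
# logic the annotator uses; errors name any violated constraint
consensus_layout <- function(consensus, gg_separation = 18L) {
  n <- nchar(consensus)
  if (grepl("[^ACGT]", consensus)) stop("consensus must be plain A/C/G/T")
  gagat <- str_find_all(consensus, "GAGAT")
  if (!length(gagat)) stop("consensus violates motif constraint: no GAGAT")
  gagat <- gagat[1L]
  gcg <- str_find_all(consensus, "GCG")
  gcg <- gcg[gcg >= gagat + 5L]
  if (!length(gcg)) stop("consensus violates motif constraint: no GCG downstream of GAGAT")
  gcg <- gcg[1L]
  taat <- str_find_all(consensus, "TAAT")
  taat <- taat[taat >= gcg + 3L]
  if (!length(taat)) stop("consensus violates motif constraint: no TAAT downstream of GCG")
  taat <- taat[1L]
  ann <- annotate_motifs(consensus, motif_config(gg_separation = gg_separation))
  if (!ann$satisfied[ann$motif_name == "GG_PAIR"])
    stop("consensus violates motif constraint: no G-G pair with ",
         gg_separation, " intervening bases")
  p1 <- c(n - P1_LEN, n)
  if (!length(iupac_match("RGCGGYRRY", revcomp(subseq0(consensus, p1[1L], p1[2L])))))
    stop("consensus violates motif constraint: reverse complement of P1 window",
         " does not match RGCGGYRRY")
  list(gagat = gagat, gcg = gcg, taat = taat, p1 = p1, length = n)
}

# positions (0-based) held invariant under mutation: both 10 nt edges (so
# local-alignment hit ends are stable) plus all motif spans and the P1 window
held_positions <- function(layout) {
  n <- layout$length
  sort(unique(c(0:9, layout$gagat + 0:4, layout$gcg + 0:2, layout$taat + 0:3,
                seq(max(n - 10L, 0L), n - 1L), layout$p1[1L]:(layout$p1[2L] - 1L))))
}

#' Generate one mutated aptamer from the consensus
#'
#' Substitutes each non-held base with probability `mutation_rate` (uniform
#' over the three alternatives), keeping every planted motif, the P1 window
#' and both 10 nt edges invariant.  Uses the current RNG state.
#'
#' @param consensus consensus string (validated; errors list the violated
#'   motif constraint).
#' @param mutation_rate per-base substitution probability.
#' @return list with `sequence`, `p1_window` (0-based interval within the
#'   aptamer) and the planted motif `offsets`.
#' @export
make_aptamer <- function(consensus = default_aptamer_consensus(),
                         mutation_rate = 0.02) {
  layout <- consensus_layout(consensus)
  s <- chars(consensus)
  held <- held_positions(layout) + 1L
  mutable <- setdiff(seq_along(s), held)
  mut <- mutable[runif(length(mutable)) < mutation_rate]
  for (i in mut) s[i] <- sample(setdiff(DNA_BASES, s[i]), 1L)
  list(sequence = paste(s, collapse = ""), p1_window = layout$p1,
       offsets = layout[c("gagat", "gcg", "taat")])
}

#' Generate a seed alignment of mutated aptamer replicates
#'
#' @param config a [sim_config()]; uses its consensus, mutation rate and seed.
#' @param n number of replicates (default 10).
#' @return character vector of equal-length ungapped sequences, named.
#' @export
make_seed_alignment <- function(config = sim_config(), n = 10L) {
  with_seed(derive_seed(config$seed, 900001L), {
    out <- vapply(seq_len(n), function(k)
      make_aptamer(config$consensus, config$aptamer_mutation_rate)$sequence, "")
    names(out) <- sprintf("seed_aptamer_%02d", seq_len(n))
    out
  })
}

# ---- small sequence builders -------------------------------------------

nonstop_codons <- function() {
  all3 <- as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                          DNA_BASES, paste0))
  setdiff(all3, STOP_CODONS)
}

# ATG + (n-2) random non-stop codons + TAA
random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(nonstop_codons(), n_codons - 2L, replace = TRUE),
               collapse = ""),
         "TAA")
}

# random DNA free of GT and AG dinucleotides (second base of any offending
# pair is rewritten to C, which can introduce neither pattern)
random_dna_no_splice <- function(n, gc) {
  s <- random_dna(n, gc)
  repeat {
    hits <- c(str_find_all(s, "GT"), str_find_all(s, "AG"))
    if (!length(hits)) return(s)
    for (p in hits) substr(s, p + 2L, p + 2L) <- "C"
  }
}

# rewrite the T of every ATG not overlapping an excluded interval to C;
# cannot create ATG, GT, AG or a stop codon, so one pass converges
scrub_atg <- function(s, exclude) {
  for (p in str_find_all(s, "ATG")) {
    if (iv_overlaps(p, p + 3L, exclude)) next
    substr(s, p + 2L, p + 2L) <- "C"
  }
  s
}

rint <- function(range) if (range[1L] == range[2L]) range[1L] else
  sample(range[1L]:range[2L], 1L)

# ---- architectures ------------------------------------------------------

empty_truth <- function() {
  data.frame(gene_id = character(0), seq_id = character(0),
             planted_type = character(0), strand = character(0),
             apt_start = integer(0), apt_end = integer(0),
             intron_start = integer(0), intron_end = integer(0),
             uorf_start = integer(0), uorf_end = integer(0),
             s1 = integer(0), s2 = integer(0), acceptor = integer(0),
             alpha = integer(0), stop = integer(0),
             stringsAsFactors = FALSE)
}

#' Generate one gene architecture with ground truth
#'
#' Builds, on its own genome record, a gene carrying (or, for decoys, failing
#' to carry) the full evidence of one regulation type:
#'
#' * `"I"`: two-exon gene; the 5'UTR intron holds donor S1, a uORF, donor S2
#'   and the aptamer, and ends with AG.  Linker ATGs are scrubbed so the
#'   planted uORF is the only one.
#' * `"II"`: three-exon gene; the second (internal) intron, 650-900 nt, holds
#'   S1, the alpha element (exact reverse complement of the aptamer P1
#'   window), S2 and the aptamer at the configured separation.
#' * `"III"`: two-exon gene; the internal intron, 200-400 nt, holds S1, a
#'   stop codon in the upstream CDS reading frame, S2, the aptamer and a
#'   terminal AG.
#' * `"IV"`: single-exon gene; the aptamer sits in a 5'UTR whose flanks are
#'   synthesised free of GT and AG dinucleotides.
#' * `"DECOY"`: two-exon gene with a column-shuffled aptamer inside a
#'   450-550 nt internal intron, so neither the scanner nor any length rule
#'   should fire.
#'
#' The strand is drawn at random; minus-strand genes are emitted as the
#' reverse complement with mirrored coordinates.
#'
#' @param planted_type one of `"I"`, `"II"`, `"III"`, `"IV"`, `"DECOY"`.
#' @param config a [sim_config()].
#' @param gene_index integer index used (with `config$seed`) to derive the
#'   architecture's private RNG stream.
#' @return list of class `riboreg_architecture` with elements `genome`
#'   ([GenomeRecord]), `gene` ([GeneModel]) and `truth` (one-row data.frame).
#' @export
make_architecture <- function(planted_type, config = sim_config(),
                              gene_index = 1L) {
  planted_type <- match.arg(planted_type, c("I", "II", "III", "IV", "DECOY"))
  with_seed(derive_seed(config$seed, gene_index), {
    build_architecture(planted_type, config, gene_index)
  })
}

build_architecture <- function(planted_type, config, gene_index) {
  gc <- config$intergenic_gc
  apt <- make_aptamer(config$consensus, config$aptamer_mutation_rate)
  alen <- nchar(apt$sequence)
  strand <- sample(c("+", "-"), 1L)
  gene_id <- sprintf("g%03d_%s", gene_index, planted_type)
  seq_id <- sprintf("sim%03d", gene_index)
  tr <- list(uorf = c(NA, NA), s1 = NA, s2 = NA, acceptor = NA,
             alpha = NA, stop = NA)

  if (planted_type == "I") {
    u1 <- rint(c(40L, 80L)); u2 <- 20L
    nc <- rint(config$uorf_codons)
    li <- rint(config$intron_len_I)
    uorf_off <- 10L
    uorf <- random_cds(nc)
    s2_off <- uorf_off + 3L * nc + 6L
    apt_off <- s2_off + 8L
    tail_n <- li - 2L - (apt_off + alen)
    if (tail_n < 0L) stop("Type I intron too short for planted elements")
    intron <- paste0("GT", random_dna(8L, gc), uorf, random_dna(6L, gc), "GT",
                     random_dna(6L, gc), apt$sequence, random_dna(tail_n, gc),
                     "AG")
    intron <- scrub_atg(intron, rbind(c(uorf_off, uorf_off + 3L),
                                      c(apt_off, apt_off + alen)))
    cds <- random_cds(82L)
    utr3 <- random_dna(40L, gc)
    body <- paste0(random_dna(u1, gc), intron, random_dna(u2, gc), cds, utr3)
    exons <- iv_mat(c(0L, u1 + li),
                    c(u1, u1 + li + u2 + nchar(cds) + nchar(utr3)))
    cds_iv <- iv_mat(u1 + li + u2, u1 + li + u2 + nchar(cds))
    intron_iv <- c(u1, u1 + li)
    apt_iv <- c(u1 + apt_off, u1 + apt_off + alen)
    tr$uorf <- c(u1 + uorf_off, u1 + uorf_off + 3L * nc)
    tr$s1 <- 0L; tr$s2 <- s2_off; tr$acceptor <- li - 2L
  } else if (planted_type == "II") {
    u1 <- 50L
    cds_total <- random_cds(100L)                     # 300 nt across 3 exons
    c1 <- 90L; c2 <- 120L; c3 <- 90L
    li1 <- 80L
    intron1 <- paste0("GT", random_dna(li1 - 4L, gc), "AG")
    li <- rint(config$intron_len_II)
    alpha <- revcomp(subseq0(apt$sequence, apt$p1_window[1L], apt$p1_window[2L]))
    alpha_off <- 12L
    sep_hi <- min(config$alpha_separation[2L], li - 23L - alen)
    if (sep_hi < config$alpha_separation[1L])
      stop("Type II intron range incompatible with alpha separation range")
    sep <- rint(c(config$alpha_separation[1L], sep_hi))
    apt_off <- alpha_off + 9L + sep
    s2_off <- alpha_off + 9L + 15L
    gap1 <- random_dna(15L, gc)
    gap2 <- random_dna(apt_off - (s2_off + 2L), gc)
    tail_n <- li - 2L - (apt_off + alen)
    intron <- paste0("GT", random_dna(10L, gc), alpha, gap1, "GT", gap2,
                     apt$sequence, random_dna(tail_n, gc), "AG")
    utr3 <- random_dna(50L, gc)
    e1 <- paste0(random_dna(u1, gc), substr(cds_total, 1L, c1))
    e2 <- substr(cds_total, c1 + 1L, c1 + c2)
    e3 <- paste0(substr(cds_total, c1 + c2 + 1L, c1 + c2 + c3), utr3)
    body <- paste0(e1, intron1, e2, intron, e3)
    o2 <- nchar(e1) + li1                             # exon2 start
    o3 <- o2 + c2 + li                                # exon3 start
    exons <- iv_mat(c(0L, o2, o3),
                    c(nchar(e1), o2 + c2, o3 + nchar(e3)))
    cds_iv <- iv_mat(c(u1, o2, o3), c(u1 + c1, o2 + c2, o3 + c3))
    intron_iv <- c(o2 + c2, o3)
    apt_iv <- c(intron_iv[1L] + apt_off, intron_iv[1L] + apt_off + alen)
    tr$s1 <- 0L; tr$s2 <- s2_off; tr$alpha <- alpha_off
    tr$acceptor <- li - 2L
  } else if (planted_type %in% c("III", "DECOY")) {
    u1 <- 50L
    c1 <- rint(c(80L, 130L))
    c2 <- 120L + (3L - (c1 + 120L) %% 3L) %% 3L
    cds_total <- random_cds((c1 + c2) / 3L)
    rng <- if (planted_type == "III") config$intron_len_III else
      config$intron_len_decoy
    li <- rint(rng)
    if (planted_type == "III") {
      s_off <- 10L + (3L - (c1 + 10L) %% 3L) %% 3L    # in-frame stop position
      s2_off <- s_off + 9L
      apt_off <- s2_off + 8L
      tail_n <- li - 2L - (apt_off + alen)
      if (tail_n < 0L) stop("Type III intron too short for planted elements")
      intron <- paste0("GT", random_dna(s_off - 2L, gc), "TAA",
                       random_dna(s2_off - s_off - 3L, gc), "GT",
                       random_dna(6L, gc), apt$sequence,
                       random_dna(tail_n, gc), "AG")
      planted_seq <- apt$sequence
      tr$s1 <- 0L; tr$s2 <- s2_off; tr$stop <- s_off; tr$acceptor <- li - 2L
    } else {
      planted_seq <- paste(sample(chars(apt$sequence)), collapse = "")
      apt_off <- rint(c(20L, li - alen - 20L))
      intron <- paste0("GT", random_dna(apt_off - 2L, gc), planted_seq,
                       random_dna(li - 2L - (apt_off + alen), gc), "AG")
    }
    utr3 <- random_dna(40L, gc)
    e1 <- paste0(random_dna(u1, gc), substr(cds_total, 1L, c1))
    e2 <- paste0(substr(cds_total, c1 + 1L, c1 + c2), utr3)
    body <- paste0(e1, intron, e2)
    o2 <- nchar(e1) + li
    exons <- iv_mat(c(0L, o2), c(nchar(e1), o2 + nchar(e2)))
    cds_iv <- iv_mat(c(u1, o2), c(u1 + c1, o2 + c2))
    intron_iv <- c(nchar(e1), o2)
    apt_iv <- c(intron_iv[1L] + apt_off, intron_iv[1L] + apt_off + alen)
  } else {                                            # Type IV
    fl5 <- random_dna_no_splice(60L, gc)
    fl3 <- random_dna_no_splice(40L, gc)
    cds <- random_cds(90L)
    utr3 <- random_dna(50L, gc)
    body <- paste0(fl5, apt$sequence, fl3, cds, utr3)
    exons <- iv_mat(0L, nchar(body))
    cds_start <- 60L + alen + 40L
    cds_iv <- iv_mat(cds_start, cds_start + nchar(cds))
    intron_iv <- c(NA_integer_, NA_integer_)
    apt_iv <- c(60L, 60L + alen)
  }

  flank5 <- random_dna(rint(c(150L, 250L)), gc)
  flank3 <- random_dna(rint(c(150L, 250L)), gc)
  off <- nchar(flank5)
  n_total <- off + nchar(body) + nchar(flank3)
  shift <- function(m) {
    m <- rbind(m) + off
    if (strand == "+") iv_mat(m[, 1L], m[, 2L])
    else iv_mat(n_total - m[, 2L], n_total - m[, 1L])
  }
  shift_iv <- function(v) {
    if (anyNA(v)) return(c(NA_integer_, NA_integer_))
    v <- v + off
    if (strand == "+") as.integer(v) else as.integer(c(n_total - v[2L], n_total - v[1L]))
  }
  seq_plus <- paste0(flank5, body, flank3)
  if (strand == "-") seq_plus <- revcomp(seq_plus)
  genome <- GenomeRecord(seq_id, seq_plus)
  exons_g <- shift(exons); cds_g <- shift(cds_iv)
  u <- infer_utrs(exons_g, cds_g, strand)
  gene <- GeneModel(gene_id, seq_id, strand, exons_g, cds_g, u$utr5, u$utr3)
  apt_g <- shift_iv(apt_iv); intr_g <- shift_iv(intron_iv)
  uorf_g <- shift_iv(unlist(tr$uorf))
  truth <- data.frame(gene_id = gene_id, seq_id = seq_id,
                      planted_type = planted_type, strand = strand,
                      apt_start = apt_g[1L], apt_end = apt_g[2L],
                      intron_start = intr_g[1L], intron_end = intr_g[2L],
                      uorf_start = uorf_g[1L], uorf_end = uorf_g[2L],
                      s1 = as.integer(tr$s1), s2 = as.integer(tr$s2),
                      acceptor = as.integer(tr$acceptor),
                      alpha = as.integer(tr$alpha),
                      stop = as.integer(tr$stop), stringsAsFactors = FALSE)
  structure(list(genome = genome, gene = gene, truth = truth),
            class = "riboreg_architecture")
}

#' Build hit rows from ground-truth aptamer intervals
#'
#' Mirrors the [scan_genome()] output format but takes the planted intervals
#' as the hits, for classifier tests that should not depend on the scanner.
#'
#' @param truth truth data.frame (row-bound `truth` elements).
#' @param genomes named list of [GenomeRecord]s.
#' @return hit data.frame.
#' @export
truth_hits <- function(truth, genomes) {
  hseq <- vapply(seq_len(nrow(truth)), function(k)
    extract_seq(genomes[[truth$seq_id[k]]], truth$apt_start[k],
                truth$apt_end[k], truth$strand[k]), "")
  data.frame(hit_id = paste0(truth$gene_id, "_truth"),
             seq_id = truth$seq_id, start = truth$apt_start,
             end = truth$apt_end, strand = truth$strand, score = NA_real_,
             hit_sequence = hseq,
             p1_start = nchar(hseq) - P1_LEN, p1_end = nchar(hseq),
             stringsAsFactors = FALSE)
}

# ---- perturbations ------------------------------------------------------

# replace the sense-strand bases of genomic interval [gs, ge) with a sense
# replacement of equal length
substitute_sense <- function(genome, gs, ge, strand, replacement) {
  stopifnot(nchar(replacement) == ge - gs)
  s <- genome$sequence
  rep_g <- if (strand == "+") replacement else revcomp(replacement)
  paste0(subseq0(s, 0L, gs), rep_g, subseq0(s, ge, genome$length))
}

#' Knock out the planted uORF of an architecture
#'
#' Rewrites the uORF start codon `ATG` to `ACC` in sense orientation, which
#' removes the uORF without moving any coordinate and cannot introduce a new
#' `ATG`, `GT` or `AG`.
#'
#' @param arch a `riboreg_architecture` with a planted uORF.
#' @return the modified architecture.
#' @export
perturb_delete_uorf <- function(arch) {
  t <- arch$truth
  if (is.na(t$uorf_start)) stop("architecture has no planted uORF")
  gs <- if (t$strand == "+") t$uorf_start else t$uorf_end - 3L
  arch$genome <- GenomeRecord(arch$genome$seq_id,
                              substitute_sense(arch$genome, gs, gs + 3L,
                                               t$strand, "ACC"))
  arch$truth$uorf_start <- NA_integer_
  arch$truth$uorf_end <- NA_integer_
  arch
}

#' Resize the riboswitch-carrying intron of an architecture
#'
#' Shrinks the intron to `new_length` by deleting filler sequence (3' tail
#' first, then the gap between donor S2 and the aptamer), never touching a
#' planted element.  All downstream coordinates shift accordingly.
#'
#' @param arch a `riboreg_architecture` with an intronic aptamer.
#' @param new_length target intron length in nt (smaller than current).
#' @return the modified architecture.
#' @export
perturb_resize_intron <- function(arch, new_length) {
  t <- arch$truth
  if (is.na(t$intron_start)) stop("architecture has no riboswitch intron")
  ilen <- t$intron_end - t$intron_start
  del <- ilen - new_length
  if (del <= 0L) stop("new_length must be smaller than the current intron")
  # sense offsets of removable filler within the intron
  ap <- genomic_to_sense_offset(t$apt_start, t$apt_end,
                                t$intron_start, t$intron_end, t$strand)
  tail_avail <- (ilen - 2L) - ap[2L]
  gap_lo <- if (!is.na(t$s2)) t$s2 + 2L else 2L
  gap_avail <- ap[1L] - gap_lo
  take_tail <- min(del, max(tail_avail, 0L))
  take_gap <- del - take_tail
  if (take_gap > max(gap_avail, 0L))
    stop("not enough filler sequence to shrink intron to ", new_length, " nt")
  blocks <- list()
  if (take_tail > 0L) blocks <- c(blocks, list(c(ap[2L], ap[2L] + take_tail)))
  if (take_gap > 0L) blocks <- c(blocks, list(c(ap[1L] - take_gap, ap[1L])))
  # map sense blocks to genomic and delete right-to-left
  gblocks <- lapply(blocks, function(b) {
    if (t$strand == "+") t$intron_start + b
    else c(t$intron_end - b[2L], t$intron_end - b[1L])
  })
  gblocks <- gblocks[order(-vapply(gblocks, `[`, 0, 1L))]
  for (b in gblocks) arch <- delete_genomic_block(arch, b[1L], b[2L])
  arch
}

# remove genomic interval [gs, ge) lying strictly inside an intron, shifting
# every downstream coordinate
delete_genomic_block <- function(arch, gs, ge) {
  d <- ge - gs
  sh <- function(x) ifelse(is.na(x), x, ifelse(x >= ge, x - d,
                                               ifelse(x > gs, gs, x)))
  g <- arch$gene
  gene <- GeneModel(g$gene_id, g$seq_id, g$strand,
                    cbind(sh(g$exons[, 1L]), sh(g$exons[, 2L])),
                    if (nrow(g$cds)) cbind(sh(g$cds[, 1L]), sh(g$cds[, 2L])),
                    if (nrow(g$utr5)) cbind(sh(g$utr5[, 1L]), sh(g$utr5[, 2L])),
                    if (nrow(g$utr3)) cbind(sh(g$utr3[, 1L]), sh(g$utr3[, 2L])))
  s <- arch$genome$sequence
  genome <- GenomeRecord(arch$genome$seq_id,
                         paste0(subseq0(s, 0L, gs), subseq0(s, ge, nchar(s))))
  t <- arch$truth
  for (f in c("apt_start", "apt_end", "intron_start", "intron_end",
              "uorf_start", "uorf_end"))
    t[[f]] <- as.integer(sh(t[[f]]))
  structure(list(genome = genome, gene = gene, truth = t),
            class = "riboreg_architecture")
}

# ---- homology tables ----------------------------------------------------

#' Generate a synthetic homology-evidence table with planted labels
#'
#' Pass rows satisfy all five transporter-filter conditions; each fail row
#' violates at least one sampled condition (too-large E-value, similarity
#' below 50, coverage below 30, missing transporter domain, or zero
#' transmembrane helices).
#'
#' @param n_pass,n_fail row counts.
#' @param seed integer seed.
#' @return list with `records` (data.frame) and `pass_ids` (character).
#' @export
make_homology_table <- function(n_pass, n_fail, seed = 1L) {
  stopifnot(n_pass >= 0L, n_fail >= 0L)
  with_seed(seed, {
    mk <- function(id, pass) {
      viol <- if (pass) 0L else sample(5L, 1L)
      data.frame(
        query_id = id,
        subject_id = sprintf("TCDB_%04d", sample(9999L, 1L)),
        evalue = if (viol == 1L) 10^runif(1, -4.9, -1) else 10^runif(1, -20, -5.1),
        similarity_pct = if (viol == 2L) runif(1, 0, 49.9) else runif(1, 50, 100),
        coverage_pct = if (viol == 3L) runif(1, 0, 29.9) else runif(1, 30, 100),
        has_transporter_domain = viol != 4L,
        n_tm_helices = if (viol == 5L) 0L else sample(1:12, 1L),
        stringsAsFactors = FALSE)
    }
    rows <- c(
      lapply(seq_len(n_pass), function(k) mk(sprintf("qpass%03d", k), TRUE)),
      lapply(seq_len(n_fail), function(k) mk(sprintf("qfail%03d", k), FALSE)))
    records <- if (length(rows)) do.call(rbind, rows) else
      data.frame(query_id = character(0), subject_id = character(0),
                 evalue = numeric(0), similarity_pct = numeric(0),
                 coverage_pct = numeric(0),
                 has_transporter_domain = logical(0),
                 n_tm_helices = integer(0), stringsAsFactors = FALSE)
    list(records = records,
         pass_ids = sort(sprintf("qpass%03d", seq_len(n_pass))))
  })
}

# ---- full simulation runs ----------------------------------------------

#' Generate a complete simulation run
#'
#' Builds `n_per_type` architectures of each planted type plus `n_decoys`
#' decoys, the seed alignment, and a labelled homology table.  With `out_dir`
#' set, writes `genome.fasta`, `genes.gff3`, `truth.tsv`,
#' `seed_alignment.fasta`, `homology.tsv` and a `sim_config.txt` echo;
#' outputs are byte-identical across reruns with the same config.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `genomes`, `genes`, `truth`, `seed_alignment`,
#'   `homology`, and `out_dir`.
#' @export
simulate_run <- function(config = sim_config(), out_dir = NULL) {
  types <- rep(c("I", "II", "III", "IV"), each = config$n_per_type)
  types <- c(types, rep("DECOY", config$n_decoys))
  archs <- lapply(seq_along(types), function(k)
    make_architecture(types[k], config, gene_index = k))
  genomes <- lapply(archs, `[[`, "genome")
  names(genomes) <- vapply(genomes, `[[`, "", "seq_id")
  genes <- lapply(archs, `[[`, "gene")
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  truth <- do.call(rbind, c(lapply(archs, `[[`, "truth"),
                            list(make.row.names = FALSE)))
  seed_aln <- make_seed_alignment(config)
  hom <- make_homology_table(10L, 10L, seed = derive_seed(config$seed, 900002L))
  out <- list(genomes = genomes, genes = genes, truth = truth,
              seed_alignment = seed_aln, homology = hom, out_dir = out_dir,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(genomes, file.path(out_dir, "genome.fasta"))
    write_gff3(genes, file.path(out_dir, "genes.gff3"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_fasta(mapply(GenomeRecord, names(seed_aln), seed_aln,
                       SIMPLIFY = FALSE),
                file.path(out_dir, "seed_alignment.fasta"))
    write.table(hom$records, file.path(out_dir, "homology.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cfg <- config[setdiff(names(config), "consensus")]
    writeLines(c(paste0("consensus=", config$consensus),
                 paste(names(cfg), vapply(cfg, function(v)
                   paste(v, collapse = ","), ""), sep = "=")),
               file.path(out_dir, "sim_config.txt"))
  }
  out
}
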