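# Conserved-motif annotation of aptamer hit sequences.  RNA motifs (GAGAU,
# J4/5 GCG, L5 UAAU) are stored and matched in the DNA alphabet because the
# scanned input is genomic DNA.

#' Motif spacing parameters
#'
#' @param gg_separation required number of intervening bases between the two
#'   G's of the non-canonical G-G pair (default 18).
#' @param gg_flank how far (nt) outside the GAGAU / J4/5-GCG motif spans a G
#'   may lie and still count as motif-proximal for the G-G pair (default 2).
#' @return a list of class `motif_config`.
#' @export
motif_config <- function(gg_separation = 18L, gg_flank = 2L) {
  stopifnot(gg_separation >= 0L, gg_flank >= 0L)
  structure(list(gg_separation = as.integer(gg_separation),
                 gg_flank = as.integer(gg_flank)),
            class = "motif_config")
}

#' Annotate conserved aptamer motifs in a hit sequence
#'
#' Reports, in the DNA alphabet: the first (5'-most) `GAGAT` (pyrimidine-ring
#' recognition), the first `GCG` downstream of it (J4/5, pyrophosphate
#' contact), the first `TAAT` downstream of the GCG (loop L5), and whether a
#' G-G pair exists with one G proximal to the GAGAT motif, one proximal to the
#' GCG motif, and exactly `gg_separation` intervening bases.  Each motif's
#' `satisfied` flag is independent; absence is reported, never an error.
#'
#' @param hit_sequence DNA string (sense strand of the aptamer hit).
#' @param config a [motif_config()].
#' @return data.frame with columns `motif_name` (`GAGAU`, `J45_GCG`,
#'   `L5_UAAU`, `GG_PAIR`), `position` (0-based offset or `NA`), `satisfied`,
#'   `spacing` (intervening bases for `GG_PAIR`, `NA` otherwise).
#' @export
annotate_motifs <- function(hit_sequence, config = motif_config()) {
  stopifnot(is.character(hit_sequence), length(hit_sequence) == 1L)
  s <- hit_sequence
  first_at <- function(pat, from) {
    p <- str_find_all(s, pat)
    p <- p[p >= from]
    if (length(p)) p[1L] else NA_integer_
  }
  gagat <- first_at("GAGAT", 0L)
  gcg <- if (is.na(gagat)) NA_integer_ else first_at("GCG", gagat + 5L)
  taat <- if (is.na(gcg)) NA_integer_ else first_at("TAAT", gcg + 3L)
  gg_pos <- NA_integer_; gg_space <- NA_integer_; gg_ok <- FALSE
  if (!is.na(gagat) && !is.na(gcg)) {
    gpos <- str_find_all(s, "G")
    fl <- config$gg_flank
    g1 <- gpos[gpos >= gagat - fl & gpos < gagat + 5L + fl]
    g2 <- gpos[gpos >= gcg - fl & gpos < gcg + 3L + fl]
    for (a in g1) {
      b <- a + config$gg_separation + 1L
      if (b %in% g2) { gg_pos <- a; gg_space <- config$gg_separation
                       gg_ok <- TRUE; break }
    }
  }
  data.frame(
    motif_name = c("GAGAU", "J45_GCG", "L5_UAAU", "GG_PAIR"),
    position = c(gagat, gcg, taat, gg_pos),
    satisfied = c(!is.na(gagat), !is.na(gcg), !is.na(taat), gg_ok),
    spacing = c(NA_integer_, NA_integer_, NA_integer_, gg_space),
    stringsAsFactors = FALSE)
}
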