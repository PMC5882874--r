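# Position-specific log-odds profile built from a seed alignment of aptamer
# sequences.  Plays the role a pretrained profile HMM plays in genome-wide
# riboswitch screens, but is reconstructed from a user-supplied alignment so
# the whole chain is self-contained.

#' Build a log-odds profile from a seed alignment
#'
#' Per match column `c` and base `b` the score is
#' `log2((count_b + pseudocount) / (n_c + 4 * pseudocount) / 0.25)` bits
#' against a uniform background.  Columns whose gap fraction exceeds 50% are
#' dropped from the match columns.  `U` is accepted and treated as `T`.
#'
#' @param seed_alignment character vector of >= 2 equal-length gapped DNA
#'   strings (gap character `-`).
#' @param pseudocount positive per-base pseudocount (default 1).
#' @param gap_open,gap_extend non-positive affine gap scores in bits used by
#'   [scan_genome()] for insertions/deletions relative to match columns.
#' @return an object of class `ProfileModel` with fields `length`,
#'   `match_logodds` (4 x length matrix, rows `A,C,G,T`), `gap_open`,
#'   `gap_extend`, `source_n`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          gap_open = -4, gap_extend = -1) {
  if (length(seed_alignment) < 2L)
    stop("seed alignment needs at least 2 sequences")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (gap_open > 0 || gap_extend > 0)
    stop("gap scores must be non-positive")
  seqs <- toupper(seed_alignment)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("seed alignment sequences differ in length")
  if (w == 0L) stop("seed alignment has zero columns")
  if (any(grepl("[^ACGTN-]", seqs)))
    stop("seed alignment contains characters outside {A,C,G,T,N,-}")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  keep <- colMeans(m == "-") <= 0.5
  if (!any(keep)) stop("no match columns left after gap filtering")
  m <- m[, keep, drop = FALSE]
  lo <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col %in% DNA_BASES]              # gaps and N excluded from counts
    counts <- table(factor(col, levels = DNA_BASES))
    n <- sum(counts)
    log2((as.numeric(counts) + pseudocount) / (n + 4 * pseudocount) / 0.25)
  }, numeric(4))
  rownames(lo) <- DNA_BASES
  structure(list(length = ncol(lo), match_logodds = lo,
                 gap_open = gap_open, gap_extend = gap_extend,
                 source_n = length(seqs)),
            class = "ProfileModel")
}

#' @export
print.ProfileModel <- function(x, ...) {
  cat("<ProfileModel>", x$length, "match columns from", x$source_n,
      "sequences; self-score", round(profile_self_score(x), 1), "bits\n")
  invisible(x)
}

#' Consensus string of a profile (per-column argmax base)
#' @param profile a `ProfileModel`.
#' @return DNA string of length `profile$length`.
#' @export
profile_consensus <- function(profile) {
  paste(DNA_BASES[apply(profile$match_logodds, 2L, which.max)], collapse = "")
}

#' Self-score of a profile
#'
#' Sum over columns of the maximal per-column log-odds: the score the
#' per-column consensus sequence achieves against the profile.
#'
#' @param profile a `ProfileModel`.
#' @return score in bits.
#' @export
profile_self_score <- function(profile) {
  sum(apply(profile$match_logodds, 2L, max))
}

#' Default scan threshold
#'
#' A fixed fraction (default 60%) of the profile self-score.  No bit-score
#' cutoff is inherited from any pretrained model, so the threshold is a
#' calibration knob, not a constant.
#'
#' @param profile a `ProfileModel`.
#' @param frac fraction of the self-score.
#' @return threshold in bits.
#' @export
default_threshold <- function(profile, frac = 0.6) {
  frac * profile_self_score(profile)
}
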