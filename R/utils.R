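# Low-level sequence and interval helpers shared by all modules.
# Sequence offsets are 0-based half-open throughout.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Accepts the alphabet A, C, G, T, N (uppercase).  `N` complements to `N`.
#'
#' @param x single DNA string.
#' @return the reverse complement as a single string.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substring by 0-based half-open interval
subseq0 <- function(x, start, end) {
  if (end < start) stop("interval end < start")
  if (end == start) return("")
  substr(x, start + 1L, end)
}

# vector of single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# all 0-based start offsets of pattern `pat` (a regex) in `x`, overlapping
str_find_all <- function(x, pat) {
  if (nchar(x) == 0L) return(integer(0))
  hits <- gregexpr(paste0("(?=", pat, ")"), x, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# IUPAC degenerate match: 0-based start offsets of all (overlapping) matches.
# N in the subject never matches (ambiguity is treated conservatively).
IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

#' Find degenerate IUPAC motif occurrences
#'
#' Expands a degenerate IUPAC pattern (e.g. `"RGCGGYRRY"`) into a character
#' class regex and reports all, possibly overlapping, occurrence offsets.
#' Subject `N` bases fail every position, including pattern `N`.
#'
#' @param pattern IUPAC pattern string (DNA alphabet; `U` treated as `T`).
#' @param subject DNA string to search.
#' @return integer vector of 0-based start offsets, possibly empty.
#' @export
#' @examples
#' iupac_match("RGCGGYRRY", "TTAGCGGTAATT")
iupac_match <- function(pattern, subject) {
  pat_chars <- chars(toupper(pattern))
  bad <- setdiff(pat_chars, names(IUPAC_CLASS))
  if (length(bad)) stop("unknown IUPAC code(s): ", paste(bad, collapse = ", "))
  rx <- paste(IUPAC_CLASS[pat_chars], collapse = "")
  str_find_all(subject, rx)
}

# encode DNA string to integer codes A=0 C=1 G=2 T=3 N=4 (others error)
encode_dna <- function(x) {
  if (nchar(x) == 0L) return(integer(0))
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)
  v <- code[chars(x)]
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T,N}")
  unname(v)
}

# deterministic sub-seed derived from a master seed and an index; < 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 12345) %%
               2147483647)
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# random DNA string with given GC fraction
random_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# interval helpers: intervals are length-2 numeric c(start, end), 0-based
# half-open; interval sets are n x 2 matrices with columns start, end.
iv <- function(start, end) {
  stopifnot(end >= start)
  c(start = as.integer(start), end = as.integer(end))
}

iv_mat <- function(starts, ends) {
  m <- cbind(start = as.integer(starts), end = as.integer(ends))
  if (nrow(m) && any(m[, 2L] < m[, 1L])) stop("interval end < start")
  m[order(m[, 1L]), , drop = FALSE]
}

iv_len <- function(m) if (is.matrix(m)) sum(m[, 2L] - m[, 1L]) else m[2L] - m[1L]

# is [s,e) fully contained in any row of matrix m?
iv_contained <- function(s, e, m) {
  if (!nrow(m)) return(FALSE)
  any(m[, 1L] <= s & m[, 2L] >= e)
}

# does [s,e) overlap any row of m?
iv_overlaps <- function(s, e, m) {
  if (!nrow(m)) return(FALSE)
  any(pmax(m[, 1L], s) < pmin(m[, 2L], e))
}

# set difference of one interval against a set of intervals, as a matrix
iv_setdiff <- function(s, e, m) {
  pieces <- list()
  cur <- s
  if (nrow(m)) {
    m <- m[order(m[, 1L]), , drop = FALSE]
    for (k in seq_len(nrow(m))) {
      a <- max(m[k, 1L], s); b <- min(m[k, 2L], e)
      if (a >= b) next
      if (a > cur) pieces[[length(pieces) + 1L]] <- c(cur, a)
      cur <- max(cur, b)
    }
  }
  if (cur < e) pieces[[length(pieces) + 1L]] <- c(cur, e)
  if (!length(pieces)) return(iv_mat(integer(0), integer(0)))
  iv_mat(vapply(pieces, `[`, 0, 1L), vapply(pieces, `[`, 0, 2L))
}
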