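# Independent oracles used by unit and acceptance tests.  These deliberately
# avoid the package's own algorithms: the scanner oracle enumerates matched
# index pairs in closed form, the uORF oracle enumerates start/stop codon
# pairs, and the IUPAC oracle expands the degenerate pattern into literals.

# Best local alignment score by exhaustive enumeration: every alignment is a
# strictly increasing sequence of matched (base, column) pairs; gaps between
# consecutive pairs cost open + (len-1) * extend per side.  Requires at least
# one matched pair.
oracle_local_score <- function(logodds, seq_codes, gap_open, gap_extend) {
  n <- length(seq_codes); L <- ncol(logodds)
  gap_cost <- function(g) if (g <= 0L) 0 else gap_open + (g - 1L) * gap_extend
  best <- -Inf
  for (k in seq_len(min(n, L))) {
    I <- utils::combn(n, k); J <- utils::combn(L, k)
    for (a in seq_len(ncol(I))) for (b in seq_len(ncol(J))) {
      ii <- I[, a]; jj <- J[, b]
      sc <- sum(vapply(seq_len(k), function(t) {
        c <- seq_codes[ii[t]]
        if (c <= 3L) logodds[c + 1L, jj[t]] else 0
      }, 0))
      if (k > 1L)
        sc <- sc + sum(vapply(seq_len(k - 1L), function(t)
          gap_cost(ii[t + 1L] - ii[t] - 1L) + gap_cost(jj[t + 1L] - jj[t] - 1L),
          0))
      if (sc > best) best <- sc
    }
  }
  best
}

# package-independent DNA encoder for the oracle (A=0 C=1 G=2 T=3 N=4)
oracle_encode <- function(x) {
  m <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)
  unname(m[strsplit(x, "")[[1L]]])
}

# best score reported by the package scanner on a raw coded sequence
scanner_best_score <- function(profile, seq_codes) {
  r <- riboreg:::scan_dp_cpp(profile$match_logodds, seq_codes,
                             profile$gap_open, profile$gap_extend,
                             threshold = -1e18, max_hits = 1L)
  if (length(r$score)) r$score[1L] else -Inf
}

# brute-force uORF finder: enumerate every (ATG, stop) codon-position pair,
# keep in-frame pairs with no stop codon strictly between them in that frame
oracle_uorfs <- function(region, min_codons, max_codons) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(region)
  codon_at <- function(p) substr(region, p + 1L, p + 3L)
  atg <- which(vapply(0:(max(n - 3L, 0L)), function(p)
    codon_at(p) == "ATG", NA)) - 1L
  stp <- which(vapply(0:(max(n - 3L, 0L)), function(p)
    codon_at(p) %in% stops, NA)) - 1L
  out <- list()
  for (a in atg) for (s in stp) {
    if (s <= a || (s - a) %% 3L != 0L) next
    between <- if (s - 3L >= a + 3L) seq(a + 3L, s - 3L, by = 3L) else integer(0)
    between <- between[between < s]
    if (length(between) && any(vapply(between, function(p)
      codon_at(p) %in% stops, NA))) next
    nc <- (s + 3L - a) / 3L
    if (nc < min_codons || nc > max_codons) next
    out[[length(out) + 1L]] <- data.frame(start = a, end = s + 3L,
                                          n_codons = as.integer(nc),
                                          frame = a %% 3L)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      n_codons = integer(0), frame = integer(0)))
  o <- do.call(rbind, out)
  o <- o[order(o$start, o$end), , drop = FALSE]
  rownames(o) <- NULL
  o
}

# expand a degenerate IUPAC pattern into all literal strings
iupac_expand <- function(pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"))
  combos <- expand.grid(lapply(strsplit(pattern, "")[[1L]], function(ch)
    sets[[ch]]), stringsAsFactors = FALSE)
  apply(combos, 1L, paste, collapse = "")
}

# literal (non-regex) occurrence offsets, overlapping, 0-based
literal_find_all <- function(x, lit) {
  n <- nchar(x); w <- nchar(lit)
  if (n < w) return(integer(0))
  starts <- 0:(n - w)
  starts[vapply(starts, function(p) substr(x, p + 1L, p + w) == lit, NA)]
}

random_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
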