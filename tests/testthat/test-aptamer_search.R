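test_that("build_profile matches the closed-form log-odds", {
  p <- build_profile(c("AA", "AA"), pseudocount = 1)
  # count 2 of A in n=2: log2((2+1)/(2+4)/0.25) = 1 bit
  expect_equal(unname(p$match_logodds["A", 1L]), 1.0)
  expect_equal(unname(p$match_logodds["C", 1L]), log2((0 + 1) / 6 / 0.25))
  expect_identical(p$length, 2L)
  expect_identical(p$source_n, 2L)

  # uniform column counts give exactly zero log-odds at any pseudocount
  pu <- build_profile(c("A", "C", "G", "T"), pseudocount = 0.37)
  expect_equal(unname(pu$match_logodds[, 1L]), rep(0, 4))

  # an all-gap column is dropped
  pg <- build_profile(c("A-A", "A-A", "A-A"))
  expect_identical(pg$length, 2L)

  expect_error(build_profile("ACGT"), "at least 2")
  expect_error(build_profile(c("", "")), "zero columns")
  expect_error(build_profile(c("AC", "ACG")), "differ in length")
})

test_that("profile self-score and consensus are consistent", {
  p <- build_profile(c("ACGT", "ACGA"), pseudocount = 0.5)
  expect_identical(substr(profile_consensus(p), 1L, 3L), "ACG")
  expect_equal(profile_self_score(p),
               sum(apply(p$match_logodds, 2L, max)))
  expect_equal(default_threshold(p), 0.6 * profile_self_score(p))
})

test_that("scanner equals exhaustive alignment enumeration (oracle)", {
  set.seed(4242)
  for (case in 1:60) {
    L <- sample(2:6, 1L); n <- sample(2:8, 1L)
    aln <- replicate(3L, random_seq(L))
    prof <- build_profile(aln, pseudocount = runif(1, 0.2, 2))
    s <- random_seq(n, letters = c("A", "C", "G", "T", if (case %% 7 == 0) "N"))
    got <- scanner_best_score(prof, oracle_encode(s))
    want <- oracle_local_score(prof$match_logodds, oracle_encode(s),
                               prof$gap_open, prof$gap_extend)
    expect_equal(got, want, tolerance = 1e-12,
                 label = paste("case", case, s))
  }
})

test_that("scan finds a planted consensus exactly, on either strand", {
  cons <- default_aptamer_consensus()
  prof <- build_profile(make_seed_alignment(sim_config(seed = 5L)))
  self <- profile_self_score(prof)
  set.seed(99)
  left <- random_seq(400); right <- random_seq(500)
  g <- GenomeRecord("t1", paste0(left, cons, right))
  hits <- scan_genome(prof, g, threshold_bits = 0.6 * self)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "+")
  expect_true(hits$start >= 395 && hits$end <= 505 + nchar(cons))
  expect_identical(hits$hit_sequence,
                   extract_seq(g, hits$start, hits$end, "+"))

  grc <- GenomeRecord("t1rc", revcomp(g$sequence))
  hits_rc <- scan_genome(prof, grc, threshold_bits = 0.6 * self)
  expect_identical(nrow(hits_rc), 1L)
  expect_identical(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score)
  expect_identical(unname(c(hits_rc$start, hits_rc$end)),
                   unname(c(grc$length - hits$end, grc$length - hits$start)))
  expect_identical(hits_rc$hit_sequence, hits$hit_sequence)
})

test_that("raising the threshold never adds hits (monotonicity)", {
  prof <- build_profile(make_seed_alignment(sim_config(seed = 6L)))
  set.seed(7)
  g <- GenomeRecord("m1", paste0(random_seq(300), default_aptamer_consensus(),
                                 random_seq(300), default_aptamer_consensus(),
                                 random_seq(200)))
  ths <- profile_self_score(prof) * c(0.3, 0.5, 0.7, 0.9, 1.01)
  sets <- lapply(ths, function(t) scan_genome(prof, g, threshold_bits = t))
  for (k in seq_along(ths)[-1L]) {
    lo <- sets[[k - 1L]]; hi <- sets[[k]]
    expect_true(all(hi$start %in% lo$start))
    expect_true(nrow(hi) <= nrow(lo))
  }
  expect_identical(nrow(sets[[length(sets)]]), 0L)   # above self-score
})

test_that("random sequence yields no hits at the self-score threshold", {
  prof <- build_profile(make_seed_alignment(sim_config(seed = 8L)))
  self <- profile_self_score(prof)
  set.seed(12)
  n_hit <- 0L
  for (rep in 1:20) {
    g <- GenomeRecord(paste0("r", rep), random_seq(5000))
    n_hit <- n_hit + nrow(scan_genome(prof, g, threshold_bits = self))
  }
  expect_identical(n_hit, 0L)
})

test_that("annotate_motifs finds planted motifs and rejects their absence", {
  cons <- default_aptamer_consensus()
  ann <- annotate_motifs(cons)
  expect_true(all(ann$satisfied))
  expect_identical(ann$position[ann$motif_name == "GAGAU"], 5L)
  expect_identical(ann$position[ann$motif_name == "J45_GCG"], 24L)
  expect_identical(ann$position[ann$motif_name == "L5_UAAU"], 40L)
  expect_identical(ann$spacing[ann$motif_name == "GG_PAIR"], 18L)

  none <- annotate_motifs(strrep("AC", 60))
  expect_false(any(none$satisfied))

  # motif order matters: GCG before GAGAT does not count
  ord <- annotate_motifs("GCGAAAAAGAGATAAAA")
  expect_true(ord$satisfied[ord$motif_name == "GAGAU"])
  expect_false(ord$satisfied[ord$motif_name == "J45_GCG"])
})

test_that("GG pair spacing agrees with brute force over arrangements", {
  # G's appear only inside the two motifs; brute-force all proximal G pairs
  set.seed(31)
  for (gap in 14:24) {
    s <- paste0("CCC", "GAGAT", strrep("C", gap), "GCG", "CCTAATCC")
    ann <- annotate_motifs(s, motif_config(gg_separation = 18L, gg_flank = 2L))
    gpos <- literal_find_all(s, "G")
    g1 <- gpos[gpos >= 3L - 2L & gpos < 8L + 2L]
    g2 <- gpos[gpos >= 8L + gap - 2L & gpos < 8L + gap + 3L + 2L]
    want <- any(outer(g2, g1, `-`) - 1L == 18L)
    expect_identical(ann$satisfied[ann$motif_name == "GG_PAIR"], want,
                     label = paste("gap", gap))
  }
  # spec example: 17 intervening bases is not 18
  s17 <- paste0("GAGAT", strrep("C", 15), "GCGTAAT")
  a17 <- annotate_motifs(s17)
  expect_false(a17$satisfied[a17$motif_name == "GG_PAIR"])
})

test_that("degenerate IUPAC matcher agrees with literal expansion", {
  lits <- iupac_expand("RGCGGYRRY")
  expect_identical(length(lits), 32L)
  set.seed(77)
  for (rep in 1:20) {
    s <- random_seq(1000)
    want <- sort(unique(unlist(lapply(lits, literal_find_all, x = s))))
    expect_identical(iupac_match("RGCGGYRRY", s), as.integer(want))
  }
  # N never matches
  expect_identical(iupac_match("RGCGGYRRY", "NGCGGTAAT"), integer(0))
  expect_identical(iupac_match("N", "N"), integer(0))
})
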