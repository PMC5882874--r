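test_that("find_splice_sites reports every GT/AG with 5'->3' donor labels", {
  s <- "GTAAGTCCCAG"
  sites <- find_splice_sites(s)
  don <- sites[sites$kind == "donor", ]
  expect_identical(don$position, c(0L, 4L))
  expect_identical(don$label, c("S1", "S2"))
  acc <- sites[sites$kind == "acceptor", ]
  expect_identical(acc$position, c(3L, 9L))           # all AGs, incl. 3' end
  expect_identical(nrow(find_splice_sites("CCCCCC")), 0L)
  d3 <- find_splice_sites("GTGTGT")
  expect_identical(d3$label[d3$kind == "donor"], c("S1", "S2", "S3"))
  expect_identical(nrow(find_splice_sites("GNTANG")), 0L)   # N fails matches
})

test_that("find_uorfs handles the boundary examples", {
  u <- find_uorfs("ATGAAATAG", min_codons = 2L, max_codons = 10L)
  expect_identical(u$n_codons, 3L)
  expect_identical(u$frame, 0L)
  expect_identical(c(u$start, u$end), c(0L, 9L))
  expect_identical(find_uorfs("ATGTAG", min_codons = 2L)$n_codons, 2L)
  expect_identical(nrow(find_uorfs("ATGAAA", min_codons = 2L)), 0L)
  expect_error(find_uorfs("ATGTAG", min_codons = 1L))
})

test_that("find_uorfs equals brute-force codon-pair enumeration (property)", {
  set.seed(55)
  for (rep in 1:25) {
    s <- random_seq(1000)
    got <- find_uorfs(s, min_codons = 2L, max_codons = 50L)
    want <- oracle_uorfs(s, 2L, 50L)
    rownames(got) <- NULL
    expect_equal(got, want, label = paste("rep", rep))
  }
})

test_that("find_alpha_element applies pattern, position and pairing rules", {
  p1 <- "ATTACCGCT"                       # revcomp = AGCGGTAAT, matches RGCGGYRRY
  alpha <- "AGCGGTAAT"
  intron <- paste0(strrep("C", 50), alpha, strrep("C", 200), "AAAA")
  apt_off <- nchar(intron) - 4L
  a <- find_alpha_element(intron, apt_off, p1)
  expect_identical(a$position, 50L)
  expect_identical(a$complementarity, 9L)
  expect_identical(a$matched, alpha)
  expect_identical(a$separation, apt_off - 59L)

  # first base T violates R -> no candidate
  bad <- paste0(strrep("C", 50), "TGCGGTAGC", strrep("C", 200))
  expect_null(find_alpha_element(bad, 250L, p1))
  # candidate 3' of the aptamer start only -> none
  expect_null(find_alpha_element(intron, 30L, p1))
  # outside max_separation -> none
  expect_null(find_alpha_element(intron, apt_off, p1, max_separation = 100L))
  # weak pairing below min_complementarity -> none
  expect_null(find_alpha_element(intron, apt_off, "TTTTTTTTT",
                                 min_complementarity = 6L))
})

test_that("each generated architecture classifies as its planted type", {
  cfg <- sim_config(seed = 97L, n_per_type = 3L, n_decoys = 3L)
  sim <- simulate_run(cfg)
  hits <- truth_hits(sim$truth, sim$genomes)
  ctx <- locate_hits(hits, sim$genes)
  calls <- classify_hits(hits, ctx, sim$genes, sim$genomes)
  want <- ifelse(sim$truth$planted_type == "DECOY", "UNCLASSIFIED",
                 paste0("TYPE_", sim$truth$planted_type))
  expect_identical(calls$reg_type, want)
  # determinism, including the trace
  calls2 <- classify_hits(hits, ctx, sim$genes, sim$genomes)
  expect_identical(calls, calls2)
})

test_that("an in-between intron length defeats both internal-intron rules", {
  # full Type III evidence but a 500 nt intron: outside [200,400] and [650,900]
  cons <- default_aptamer_consensus()
  u1 <- 30L; c1 <- 90L
  s_off <- 10L + (3L - (c1 + 10L) %% 3L) %% 3L
  intron <- paste0("GT", strrep("C", s_off - 2L), "TAA", strrep("C", 6L),
                   "GT", strrep("C", 6L), cons)
  intron <- paste0(intron, strrep("C", 500L - nchar(intron) - 2L), "AG")
  cds_total <- paste0("ATG", strrep("GAC", 69L), "TAA")   # 213 nt
  e1 <- paste0(strrep("T", u1), substr(cds_total, 1L, c1))
  e2 <- paste0(substr(cds_total, c1 + 1L, nchar(cds_total)), strrep("T", 30L))
  seqs <- paste0(e1, intron, e2)
  exons <- rbind(c(0L, nchar(e1)), c(nchar(e1) + 500L, nchar(seqs)))
  cds <- rbind(c(u1, u1 + c1),
               c(nchar(e1) + 500L, nchar(e1) + 500L + nchar(cds_total) - c1))
  gene <- toy_gene("mid1", "midseq", exons = exons, cds = cds)
  genome <- GenomeRecord("midseq", seqs)
  apt_start <- nchar(e1) + s_off + 17L
  hit <- toy_hit(apt_start, apt_start + nchar(cons), seq_id = "midseq",
                 hit_sequence = cons)
  ctx <- locate_hit(hit, list(gene))
  expect_identical(ctx$context_class, "INTERNAL_INTRON")
  expect_identical(ctx$intron_length, 500L)
  call <- classify_hit(hit, ctx, gene, genome)
  expect_identical(call$reg_type, "UNCLASSIFIED")
  expect_match(call$notes, "II: intron length 500 outside \\[650,900\\]")
  expect_match(call$notes, "III: intron length 500 outside \\[200,400\\]")
})

test_that("classification handles minus-strand genes via one sense path", {
  cfg <- sim_config(seed = 131L, n_per_type = 6L, n_decoys = 0L)
  sim <- simulate_run(cfg)
  strands <- sim$truth$strand
  expect_setequal(unique(strands), c("-", "+"))   # both strand paths exercised
  hits <- truth_hits(sim$truth, sim$genomes)
  ctx <- locate_hits(hits, sim$genes)
  calls <- classify_hits(hits, ctx, sim$genes, sim$genomes)
  expect_identical(calls$reg_type, paste0("TYPE_", sim$truth$planted_type))
})

test_that("uORF knockout and intron resizing flip calls to UNCLASSIFIED", {
  cfg <- sim_config(seed = 17L)
  a1 <- make_architecture("I", cfg, gene_index = 1L)
  a1p <- perturb_delete_uorf(a1)
  h <- truth_hits(a1p$truth, setNames(list(a1p$genome), a1p$genome$seq_id))
  ctx <- locate_hit(h[1L, ], list(a1p$gene))
  call <- classify_hit(h[1L, ], ctx, a1p$gene, a1p$genome)
  expect_identical(call$reg_type, "UNCLASSIFIED")
  expect_match(call$notes, "I: no uORF")

  a2 <- make_architecture("II", cfg, gene_index = 2L)
  a2p <- perturb_resize_intron(a2, 500L)
  expect_identical(unname(a2p$truth$intron_end - a2p$truth$intron_start), 500L)
  h2 <- truth_hits(a2p$truth, setNames(list(a2p$genome), a2p$genome$seq_id))
  ctx2 <- locate_hit(h2[1L, ], list(a2p$gene))
  expect_identical(ctx2$intron_length, 500L)
  call2 <- classify_hit(h2[1L, ], ctx2, a2p$gene, a2p$genome)
  expect_identical(call2$reg_type, "UNCLASSIFIED")
  expect_match(call2$notes, "intron length 500")
})
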