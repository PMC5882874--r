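test_that("make_aptamer holds motifs invariant and is seeded-deterministic", {
  cons <- default_aptamer_consensus()
  riboreg:::with_seed(1L, {
    a0 <- make_aptamer(cons, mutation_rate = 0)
    expect_identical(a0$sequence, cons)
  })
  h1 <- riboreg:::with_seed(5L, make_aptamer(cons, mutation_rate = 0.1))
  h2 <- riboreg:::with_seed(5L, make_aptamer(cons, mutation_rate = 0.1))
  expect_identical(h1$sequence, h2$sequence)
  dist <- sum(strsplit(h1$sequence, "")[[1L]] != strsplit(cons, "")[[1L]])
  expect_gt(dist, 0L)
  # every planted motif survives mutation
  ann <- annotate_motifs(h1$sequence)
  expect_true(all(ann$satisfied))
  expect_identical(substr(h1$sequence, 92L, 100L), substr(cons, 92L, 100L))
})

test_that("a consensus violating a motif constraint is rejected by name", {
  bad_taat <- gsub("TAAT", "CCCC", default_aptamer_consensus(), fixed = TRUE)
  expect_error(riboreg:::with_seed(1L, make_aptamer(bad_taat)), "TAAT")
  expect_error(riboreg:::with_seed(1L, make_aptamer(strrep("AC", 50))), "GAGAT")
})

test_that("architectures are reproducible and order-independent", {
  cfg <- sim_config(seed = 77L)
  a1 <- make_architecture("II", cfg, gene_index = 4L)
  a2 <- make_architecture("II", cfg, gene_index = 4L)
  expect_identical(a1$genome$sequence, a2$genome$sequence)
  expect_identical(a1$truth, a2$truth)
  a3 <- make_architecture("II", cfg, gene_index = 5L)
  expect_false(identical(a1$genome$sequence, a3$genome$sequence))
})

test_that("Type IV 5'UTRs carry no splice sites outside the aptamer", {
  cfg <- sim_config(seed = 201L)
  for (k in 1:5) {
    a <- make_architecture("IV", cfg, gene_index = k)
    t <- a$truth
    u <- a$gene$utr5
    expect_identical(nrow(u), 1L)
    utr_seq <- extract_seq(a$genome, u[1L, 1L], u[1L, 2L], t$strand)
    ap <- riboreg:::genomic_to_sense_offset(t$apt_start, t$apt_end,
                                            u[1L, 1L], u[1L, 2L], t$strand)
    outside <- paste(substr(utr_seq, 1L, ap[1L]), "|",
                     substr(utr_seq, ap[2L] + 1L, nchar(utr_seq)))
    expect_false(grepl("GT", outside, fixed = TRUE))
    expect_false(grepl("AG", outside, fixed = TRUE))
  }
})

test_that("decoy aptamers are composition-matched shuffles", {
  cfg <- sim_config(seed = 33L)
  a <- make_architecture("DECOY", cfg, gene_index = 9L)
  t <- a$truth
  dec <- extract_seq(a$genome, t$apt_start, t$apt_end, t$strand)
  expect_identical(nchar(dec), nchar(default_aptamer_consensus()))
  # same multiset of bases as some mutated aptamer: at least check length and
  # that the planted motifs are (overwhelmingly likely) destroyed
  ann <- annotate_motifs(dec)
  expect_false(all(ann$satisfied))
})

test_that("simulate_run output files are byte-identical across reruns", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 88L, n_per_type = 1L, n_decoys = 1L)
  simulate_run(cfg, d1)
  simulate_run(cfg, d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("emitted GFF3 re-read reproduces the truth coordinates", {
  d <- withr::local_tempdir()
  sim <- simulate_run(sim_config(seed = 55L, n_per_type = 1L, n_decoys = 0L), d)
  genomes <- read_fasta(file.path(d, "genome.fasta"))
  genes <- read_gff3(file.path(d, "genes.gff3"), genomes)
  truth <- read.delim(file.path(d, "truth.tsv"), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(truth))) {
    t <- truth[k, ]
    g <- genes[[t$gene_id]]
    expect_identical(g$strand, t$strand)
    if (!is.na(t$intron_start)) {
      i <- derive_introns(g)
      expect_true(any(i$start == t$intron_start & i$end == t$intron_end),
                  label = paste("intron of", t$gene_id))
    }
    sp <- riboreg:::gene_span(g)
    expect_true(t$apt_start >= sp[1L] && t$apt_end <= sp[2L])
  }
})
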