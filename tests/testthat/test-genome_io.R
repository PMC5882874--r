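test_that("read_fasta normalises case and alphabet and catches bad input", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgu"), p)
  expect_warning(recs <- read_fasta(p), "U bases mapped to T")
  expect_identical(recs$s1$sequence, "ACGT")
  expect_identical(recs$s1$length, 4L)

  writeLines(c(">a", "AC", ">b", "GT"), p)
  recs <- read_fasta(p)
  expect_named(recs, c("a", "b"))
  expect_identical(vapply(recs, `[[`, 0L, "length"), c(a = 2L, b = 2L))

  writeLines(c(">a", "AC", ">a", "GT"), p)
  expect_error(read_fasta(p), "duplicate.*a")

  writeLines(character(0), p)
  expect_error(read_fasta(p), "no records|valid FASTA")
})

test_that("read_gff3 converts coordinates, infers UTRs and validates", {
  p <- withr::local_tempfile(fileext = ".gff3")
  genome <- list(chr1 = GenomeRecord("chr1", strrep("A", 300)))
  gff <- c("##gff-version 3",
           "chr1\t.\tgene\t1\t250\t.\t+\t.\tID=g1",
           "chr1\t.\tmRNA\t1\t250\t.\t+\t.\tID=m1;Parent=g1",
           "chr1\t.\texon\t1\t100\t.\t+\t.\tParent=m1",
           "chr1\t.\texon\t151\t250\t.\t+\t.\tParent=m1",
           "chr1\t.\tCDS\t181\t250\t.\t+\t.\tParent=m1")
  writeLines(gff, p)
  genes <- read_gff3(p, genome)
  g <- genes$m1
  expect_identical(unname(g$exons[1L, ]), c(0L, 100L))
  expect_equal(unname(g$utr5), rbind(c(0L, 100L), c(150L, 180L)),
               ignore_attr = TRUE)
  expect_identical(nrow(g$utr3), 0L)

  writeLines(sub("CDS\t181\t250", "CDS\t121\t140", gff), p)
  expect_error(read_gff3(p, genome), "not inside any exon")

  writeLines(sub("exon\t151\t250", "exon\t151\t400", gff), p)
  expect_error(read_gff3(p, genome), "outside sequence bounds")
})

test_that("derive_introns assigns context and transcript-order ordinals", {
  g <- toy_gene(cds = rbind(c(180L, 240L)))      # CDS entirely in exon 2
  i <- derive_introns(g)
  expect_identical(nrow(i), 1L)
  expect_identical(i$start, 100L)
  expect_identical(i$end, 150L)
  expect_identical(i$length, 50L)
  expect_identical(i$context, "FIVE_UTR_INTRON")

  g2 <- toy_gene(cds = rbind(c(0L, 100L), c(150L, 200L)))
  expect_identical(derive_introns(g2)$context, "INTERNAL_INTRON")

  g3 <- GeneModel("sg", "chr1", "+", rbind(c(0L, 300L)))
  expect_identical(nrow(derive_introns(g3)), 0L)

  # minus strand: ordinal 1 is the genomically-last intron; contexts mirror
  g4 <- toy_gene(strand = "-", exons = rbind(c(0L, 100L), c(150L, 250L)),
                 cds = rbind(c(20L, 80L)))
  i4 <- derive_introns(g4)
  expect_identical(i4$ordinal, 1L)
  expect_identical(i4$context, "FIVE_UTR_INTRON")
})

test_that("extract_seq honours bounds, strand and empty intervals", {
  g <- GenomeRecord("x", "ACGTAC")
  expect_identical(extract_seq(g, 1L, 4L, "+"), "CGT")
  expect_identical(extract_seq(g, 1L, 4L, "-"), "ACG")
  expect_identical(extract_seq(g, 2L, 2L, "+"), "")
  expect_error(extract_seq(g, 3L, 9L), "out of bounds")
})

test_that("extract_seq on minus strand is the reverse complement (property)", {
  set.seed(101)
  for (rep in 1:25) {
    s <- random_seq(sample(10:80, 1L))
    g <- GenomeRecord("r", s)
    a <- sort(sample(0:nchar(s), 2L))
    expect_identical(extract_seq(g, a[1L], a[2L], "-"),
                     revcomp(extract_seq(g, a[1L], a[2L], "+")))
  }
})

test_that("exons plus derived introns tile the gene span (property)", {
  sim <- small_sim(seed = 21L, n_per_type = 2L, n_decoys = 1L)
  for (g in sim$genes) {
    i <- derive_introns(g)
    pieces <- rbind(g$exons, as.matrix(i[, c("start", "end")]))
    pieces <- pieces[order(pieces[, 1L]), , drop = FALSE]
    expect_true(all(pieces[-1L, 1L] == pieces[-nrow(pieces), 2L]),
                label = paste("contiguity for", g$gene_id))
    expect_identical(c(min(pieces[, 1L]), max(pieces[, 2L])),
                     unname(riboreg:::gene_span(g)))
  }
})

test_that("FASTA and GFF3 survive a write/read round trip", {
  sim <- small_sim(seed = 22L, n_per_type = 1L, n_decoys = 1L)
  fa <- withr::local_tempfile(fileext = ".fa")
  gf <- withr::local_tempfile(fileext = ".gff3")
  write_fasta(sim$genomes, fa)
  write_gff3(sim$genes, gf)
  g2 <- read_fasta(fa)
  expect_identical(lapply(g2, `[[`, "sequence"),
                   lapply(sim$genomes, `[[`, "sequence"))
  genes2 <- read_gff3(gf, g2)
  expect_setequal(names(genes2), names(sim$genes))
  for (id in names(sim$genes)) {
    a <- sim$genes[[id]]; b <- genes2[[id]]
    expect_identical(a$exons, b$exons)
    expect_identical(a$cds, b$cds)
    expect_identical(a$utr5, b$utr5)
    expect_identical(a$utr3, b$utr3)
    expect_identical(a$strand, b$strand)
  }
})
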