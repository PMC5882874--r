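hom_row <- function(q, evalue, sim, cov, dom = TRUE, tm = 4L) {
  data.frame(query_id = q, subject_id = "t1", evalue = evalue,
             similarity_pct = sim, coverage_pct = cov,
             has_transporter_domain = dom, n_tm_helices = tm,
             stringsAsFactors = FALSE)
}

test_that("transporter filter follows the printed operators", {
  recs <- rbind(
    hom_row("q1", 1e-6, 55, 35, TRUE, 4L),        # pass
    hom_row("q2", 1e-4, 90, 90, TRUE, 4L),        # E-value fails
    hom_row("q3", 1e-6, 55, 35, TRUE, 0L),        # TM requirement fails
    hom_row("q4", 1e-5, 50, 30, TRUE, 1L),        # all boundaries inclusive
    hom_row("q5", 1e-6, 49.9, 90, TRUE, 4L),      # similarity fails
    hom_row("q6", 1e-6, 55, 29.9, TRUE, 4L),      # coverage fails
    hom_row("q7", 1e-6, 55, 35, FALSE, 4L))       # domain flag fails
  expect_identical(filter_transporter_candidates(recs), c("q1", "q4"))
  # any one passing record suffices per query
  recs2 <- rbind(hom_row("q8", 1, 0, 0, FALSE, 0L),
                 hom_row("q8", 1e-8, 80, 80, TRUE, 6L))
  expect_identical(filter_transporter_candidates(recs2), "q8")
  expect_error(filter_transporter_candidates(hom_row("q", 1e-6, 101, 35)),
               "malformed percentage")
})

test_that("transporter filtering distributes over table concatenation", {
  t1 <- make_homology_table(5L, 5L, seed = 100L)
  t2 <- make_homology_table(4L, 6L, seed = 200L)
  both <- rbind(t1$records, t2$records)
  expect_identical(filter_transporter_candidates(both),
                   sort(union(filter_transporter_candidates(t1$records),
                              filter_transporter_candidates(t2$records))))
})

marker_tbl <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1L]], genome_id = r[[2L]],
               n_hits = as.integer(r[[3L]]), best_evalue = as.numeric(r[[4L]]),
               best_coverage_pct = as.numeric(r[[5L]]),
               stringsAsFactors = FALSE)))
}

test_that("single-copy marker selection requires one good hit everywhere", {
  gs <- c("gA", "gB", "gC", "gD")
  good <- do.call(marker_tbl, lapply(gs, function(g) list("p1", g, 1L, 1e-8, 60)))
  expect_identical(select_single_copy_markers(good, gs), "p1")

  two <- good; two$n_hits[2L] <- 2L
  expect_identical(select_single_copy_markers(rbind(two), gs), character(0))

  # coverage exactly 50 fails the strict > rule
  border <- good; border$best_coverage_pct[3L] <- 50
  expect_identical(select_single_copy_markers(border, gs), character(0))
  # E-value exactly at the cutoff passes the <= rule
  ecut <- good; ecut$best_evalue[1L] <- 1e-5
  expect_identical(select_single_copy_markers(ecut, gs), "p1")

  expect_error(select_single_copy_markers(good, c(gs, "gE")),
               "missing from table: gE")
})

test_that("synthetic homology tables are recovered exactly", {
  tab <- make_homology_table(10L, 10L, seed = 7L)
  expect_identical(filter_transporter_candidates(tab$records), tab$pass_ids)
  empty <- make_homology_table(0L, 5L, seed = 7L)
  expect_identical(filter_transporter_candidates(empty$records), character(0))
})

test_that("homology TSV reading honours a column mapping", {
  p <- withr::local_tempfile(fileext = ".tsv")
  tab <- make_homology_table(3L, 2L, seed = 9L)
  d <- tab$records
  names(d)[names(d) == "query_id"] <- "qseqid"
  write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_homology_tsv(p, column_map = c(qseqid = "query_id"))
  expect_identical(filter_transporter_candidates(back), tab$pass_ids)
})
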