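# Shared small fixtures, built in code.

# a plus-strand two-exon gene: exon1 pure 5'UTR, intron, exon2 carries CDS
toy_gene <- function(gene_id = "tg1", seq_id = "chr1", strand = "+",
                     exons = rbind(c(0L, 100L), c(150L, 250L)),
                     cds = rbind(c(180L, 240L))) {
  u <- riboreg:::infer_utrs(exons, cds, strand)
  GeneModel(gene_id, seq_id, strand, exons, cds, u$utr5, u$utr3)
}

toy_hit <- function(start, end, seq_id = "chr1", hit_id = "h1",
                    strand = "+", hit_sequence = strrep("A", end - start)) {
  data.frame(hit_id = hit_id, seq_id = seq_id, start = start, end = end,
             strand = strand, score = 100,
             hit_sequence = hit_sequence,
             p1_start = max(nchar(hit_sequence) - 9L, 0L),
             p1_end = nchar(hit_sequence), stringsAsFactors = FALSE)
}

# tiny deterministic profile over an explicit consensus: strong match scores
# for the consensus base, uniform elsewhere
toy_profile <- function(consensus, pseudocount = 0.1) {
  build_profile(c(consensus, consensus), pseudocount = pseudocount)
}

small_sim <- function(seed = 11L, n_per_type = 1L, n_decoys = 1L, ...) {
  simulate_run(sim_config(seed = seed, n_per_type = n_per_type,
                          n_decoys = n_decoys, ...))
}
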