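# shared fixtures, built in code at test time

write_sj_fixture <- function(lines, path = tempfile(fileext = ".tab")) {
  writeLines(lines, path)
  path
}

# minimal annotated cassette: donor exon ends at 99, acceptors at 201 and
# 401, middle exon 201-300 (the hand-checked classification fixture)
cassette_fixture <- function() {
  junctions <- data.frame(chrom = "chr1", intron_start = c(100L, 100L),
                          intron_end = c(200L, 400L), strand = "+",
                          stringsAsFactors = FALSE)
  annotation <- data.frame(gene_id = "G1",
                           transcript_id = c("T1", "T1", "T1", "T2", "T2"),
                           chrom = "chr1",
                           exon_start = c(1L, 201L, 401L, 1L, 401L),
                           exon_end = c(99L, 300L, 500L, 99L, 500L),
                           strand = "+", stringsAsFactors = FALSE)
  list(junctions = junctions, annotation = annotation)
}

# junction count frame for hand-built events: one row per junction/sample
jx_long <- function(chrom, s, e, strand, reads, sample) {
  data.frame(chrom = chrom, intron_start = s, intron_end = e,
             strand = strand, unique_reads = reads, sample_id = sample,
             stringsAsFactors = FALSE)
}

# small spot table with controlled statistics
spot_row <- function(id, rep, f_mean, f_med, b_mean = 100, b_med = 100,
                     b_sd = 50) {
  data.frame(protein_id = id, replicate = rep, F635_mean = f_mean,
             F635_median = f_med, B635_mean = b_mean, B635_median = b_med,
             B635_sd = b_sd, stringsAsFactors = FALSE)
}
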