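#' Read exon annotations from a GTF file
#'
#' Imports a GTF (1-based inclusive coordinates) and keeps only `exon`
#' features. Every exon must carry `gene_id` and `transcript_id`
#' attributes; a missing attribute is a parse error.
#'
#' @param path Path to a GTF file.
#' @return Data frame with `gene_id`, `transcript_id`, `chrom`,
#'   `exon_start`, `exon_end`, `strand`, sorted by (chrom, exon_start).
#' @export
read_gtf_exons <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), exon_start = integer(),
                      exon_end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  gid <- as.character(gr$gene_id)
  tid <- if ("transcript_id" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$transcript_id) else rep(NA_character_, length(gr))
  if (anyNA(gid) || anyNA(tid))
    stopf("GTF %s: exon feature missing gene_id or transcript_id attribute",
          path)
  out <- data.frame(gene_id = gid,
                    transcript_id = tid,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    exon_start = GenomicRanges::start(gr),
                    exon_end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$exon_start, out$exon_end, out$transcript_id), ,
      drop = FALSE]
}

#' Write exon annotations as GTF exon lines
#'
#' @param exons Data frame as returned by [read_gtf_exons()].
#' @param path Output path.
#' @export
write_gtf_exons <- function(exons, path) {
  ord <- order(exons$chrom, exons$exon_start, exons$exon_end,
               exons$transcript_id)
  e <- exons[ord, , drop = FALSE]
  lines <- sprintf(
    '%s\tsrdetect\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    e$chrom, e$exon_start, e$exon_end, e$strand, e$gene_id, e$transcript_id)
  writeLines(lines, path)
  invisible(path)
}
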