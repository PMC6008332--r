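#' Read a STAR splice-junction file (SJ.out.tab dialect)
#'
#' Parses the tab-separated splice-junction table that STAR writes for each
#' sample. Columns are: chromosome, first intronic base (1-based), last
#' intronic base (1-based), strand code (0 = undefined, 1 = +, 2 = -),
#' intron motif, annotation flag, uniquely mapping read count, multi-mapping
#' read count, maximum overhang. Only the uniquely mapping read count is
#' carried forward; multimappers are ignored.
#'
#' @param path Path to an SJ.out.tab-style file.
#' @param sample_id Identifier attached to every returned record.
#' @return A data frame with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand` (`"+"`, `"-"` or `"*"` for undefined), `unique_reads` and
#'   `sample_id`. Empty file gives a zero-row frame.
#' @export
read_star_junctions <- function(path, sample_id) {
  if (!file.exists(path)) stopf("junction file not found: %s", path)
  empty <- data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      unique_reads = integer(), sample_id = character(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- which(nf < 9L)[1L]
    stopf("malformed junction line %d in %s: %d columns (expected >= 9)",
          bad, path, nf[bad])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  scode <- suppressWarnings(as.integer(m[, 4]))
  ureads <- suppressWarnings(as.integer(m[, 7]))
  if (anyNA(start) || anyNA(end) || anyNA(scode) || anyNA(ureads)) {
    bad <- which(is.na(start) | is.na(end) | is.na(scode) | is.na(ureads))[1L]
    stopf("malformed junction line %d in %s: non-numeric field", bad, path)
  }
  if (any(ureads < 0L)) {
    stopf("negative unique read count at line %d of %s",
          which(ureads < 0L)[1L], path)
  }
  if (any(start > end)) {
    stopf("intron_start > intron_end at line %d of %s",
          which(start > end)[1L], path)
  }
  if (!all(scode %in% 0:2)) {
    stopf("invalid strand code at line %d of %s",
          which(!scode %in% 0:2)[1L], path)
  }
  data.frame(chrom = m[, 1],
             intron_start = start,
             intron_end = end,
             strand = c("*", "+", "-")[scode + 1L],
             unique_reads = ureads,
             sample_id = sample_id,
             stringsAsFactors = FALSE)
}

#' Write junction records in the SJ.out.tab dialect
#'
#' Inverse of [read_star_junctions()] for one sample: writes the nine-column
#' STAR layout (motif, annotation, multimapper and overhang columns are
#' filled with 0, 1, 0 and 50). Rows are sorted by coordinates so output is
#' deterministic.
#'
#' @param junctions Data frame with `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `unique_reads`.
#' @param path Output path.
#' @export
write_star_junctions <- function(junctions, path) {
  ord <- order(junctions$chrom, junctions$intron_start, junctions$intron_end,
               junctions$strand)
  j <- junctions[ord, , drop = FALSE]
  scode <- match(j$strand, c("*", "+", "-")) - 1L
  lines <- sprintf("%s\t%d\t%d\t%d\t0\t1\t%d\t0\t50",
                   j$chrom, j$intron_start, j$intron_end, scode,
                   j$unique_reads)
  writeLines(lines, path)
  invisible(path)
}

#' Read an RSEM-style isoform expression table
#'
#' Expects a headered TSV with an isoform id column (`transcript_id` or
#' `isoform_id`), a `gene_id` column and one expression column (default
#' `"TPM"`).
#'
#' @param path Path to the table.
#' @param sample_id Identifier attached to every record.
#' @param expr_col Name of the expression column to use.
#' @return Data frame with `isoform_id`, `gene_id`, `sample_id`,
#'   `expression`.
#' @export
read_isoform_expression <- function(path, sample_id, expr_col = "TPM") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  idcol <- intersect(c("transcript_id", "isoform_id"), names(tab))
  if (length(idcol) == 0L)
    stopf("isoform table %s lacks a transcript_id/isoform_id column", path)
  if (!"gene_id" %in% names(tab))
    stopf("isoform table %s lacks a gene_id column", path)
  if (!expr_col %in% names(tab))
    stopf("isoform table %s lacks the expression column '%s'", path, expr_col)
  expr <- as.numeric(tab[[expr_col]])
  if (anyNA(expr)) stopf("non-numeric expression values in %s", path)
  if (any(expr < 0)) stopf("negative expression values in %s", path)
  data.frame(isoform_id = as.character(tab[[idcol[1L]]]),
             gene_id = as.character(tab$gene_id),
             sample_id = sample_id,
             expression = expr,
             stringsAsFactors = FALSE)
}

#' Write an RSEM-style isoform expression table for one sample
#'
#' @param isoforms Data frame with `isoform_id`, `gene_id`, `expression`.
#' @param path Output path.
#' @export
write_isoform_expression <- function(isoforms, path) {
  ord <- order(isoforms$isoform_id)
  out <- data.frame(transcript_id = isoforms$isoform_id[ord],
                    gene_id = isoforms$gene_id[ord],
                    TPM = isoforms$expression[ord],
                    stringsAsFactors = FALSE)
  utils::write.table(format_tsv_columns(out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table as a deterministic headered TSV
#'
#' All stage outputs use this writer: rows are sorted by the first id-like
#' column (`event_id`, `ase_id` or `protein_id` if present, otherwise the
#' first column), doubles are written losslessly, so two runs on the same
#' input produce byte-identical files and `read_results_table()` round-trips
#' the frame exactly.
#'
#' @param records A data frame.
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  idcol <- intersect(c("event_id", "ase_id", "protein_id"), names(records))
  key <- if (length(idcol)) idcol[1L] else names(records)[1L]
  if (nrow(records) > 0L && !is.null(key) && !is.na(key)) {
    records <- records[order(records[[key]]), , drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(format_tsv_columns(records), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return The data frame, with numeric columns restored.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a cohort table
#'
#' A headered TSV with columns `sample_id`, `group` (binary 0/1), `time`
#' (survival time, > 0), `event` (1 = death observed, 0 = censored), then
#' one 0/1 occurrence column per alternative-splicing event.
#'
#' @param path Path to the cohort TSV.
#' @return A list with `samples` (data frame sample_id/group/time/event) and
#'   `occurrence` (numeric matrix, samples x ASEs).
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group", "time", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("cohort table %s lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  if (any(tab$time <= 0)) stopf("non-positive survival time in %s", path)
  ase_cols <- setdiff(names(tab), need)
  occ <- as.matrix(tab[, ase_cols, drop = FALSE])
  if (length(occ) && !all(occ %in% c(0, 1)))
    stopf("occurrence entries outside {0,1} in %s", path)
  rownames(occ) <- tab$sample_id
  list(samples = tab[, need], occurrence = occ)
}

#' Write a cohort table
#'
#' @param samples Data frame with `sample_id`, `group`, `time`, `event`.
#' @param occurrence Matrix (samples x ASEs) of 0/1 occurrence.
#' @param path Output path.
#' @export
write_cohort_table <- function(samples, occurrence, path) {
  out <- cbind(samples, as.data.frame(occurrence, check.names = FALSE))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(format_tsv_columns(out), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a microarray spot table
#'
#' Headered TSV with columns `protein_id`, `replicate`, `F635_mean`,
#' `F635_median`, `B635_mean`, `B635_median`, `B635_sd` (GenePix-style
#' foreground/background statistics for duplicated spots).
#'
#' @param path Path to the spot TSV.
#' @return Data frame of spot measurements.
#' @export
read_spot_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_id", "replicate", "F635_mean", "F635_median",
            "B635_mean", "B635_median", "B635_sd")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("spot table %s lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  num <- need[-1L]
  if (any(sapply(tab[num], function(x) any(x < 0))))
    stopf("negative fluorescence statistics in %s", path)
  tab
}
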