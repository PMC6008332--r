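# internal helpers shared across modules

# row-wise sample standard deviation (n-1 divisor); NA if any NA in row
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

# format a data frame for deterministic, lossless TSV output: doubles are
# written with 17 significant digits so that read-back reproduces the bits
format_tsv_columns <- function(df) {
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (is.double(x)) {
      out <- sprintf("%.17g", x)
      out[is.na(x)] <- "NA"
      df[[j]] <- out
    }
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
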