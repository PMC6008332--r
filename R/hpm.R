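# Proteome-microarray candidate filter: per-spot signal-to-noise ratio
# (SNR = (F635 mean - B635 mean) / B635 sd), per-spot fold change
# (F635 median / B635 median), and the coefficient of variation of the
# background-subtracted signal across the two duplicate spots.

#' Per-protein spot statistics from duplicated microarray spots
#'
#' @param spots Data frame of spot measurements (two replicate rows per
#'   protein) with columns `protein_id`, `replicate`, `F635_mean`,
#'   `F635_median`, `B635_mean`, `B635_median`, `B635_sd`.
#' @return Data frame, one row per protein: `snr1`, `snr2`, `fold1`,
#'   `fold2`, `cv` (sample sd / mean of the two background-subtracted mean
#'   signals), and `reason` (`NA` or an exclusion code for degenerate
#'   backgrounds: zero background sd or zero background median).
#' @export
compute_spot_stats <- function(spots) {
  need <- c("protein_id", "replicate", "F635_mean", "F635_median",
            "B635_mean", "B635_median", "B635_sd")
  miss <- setdiff(need, names(spots))
  if (length(miss)) stopf("spot table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  spots <- spots[order(spots$protein_id, spots$replicate), , drop = FALSE]
  cnt <- table(spots$protein_id)
  if (any(cnt != 2L))
    stopf("protein(s) without exactly two replicate spots: %s",
          paste(utils::head(names(cnt)[cnt != 2L]), collapse = ", "))
  i1 <- seq(1L, nrow(spots), by = 2L)
  i2 <- i1 + 1L
  s1 <- spots[i1, ]; s2 <- spots[i2, ]
  sig1 <- s1$F635_mean - s1$B635_mean
  sig2 <- s2$F635_mean - s2$B635_mean
  mu <- (sig1 + sig2) / 2
  sd2 <- abs(sig1 - sig2) / sqrt(2)  # sample sd of two values
  out <- data.frame(
    protein_id = s1$protein_id,
    snr1 = (s1$F635_mean - s1$B635_mean) / s1$B635_sd,
    snr2 = (s2$F635_mean - s2$B635_mean) / s2$B635_sd,
    fold1 = s1$F635_median / s1$B635_median,
    fold2 = s2$F635_median / s2$B635_median,
    cv = sd2 / mu,
    reason = NA_character_,
    stringsAsFactors = FALSE)
  bad_sd <- s1$B635_sd == 0 | s2$B635_sd == 0
  bad_med <- s1$B635_median == 0 | s2$B635_median == 0
  out$reason[bad_med] <- "zero_background_median"
  out$reason[bad_sd] <- "zero_background_sd"
  out$snr1[bad_sd] <- out$snr2[bad_sd] <- NA_real_
  out$fold1[bad_med] <- out$fold2[bad_med] <- NA_real_
  out
}

#' Filter microarray proteins on SNR, fold change and duplicate CV
#'
#' Default cutoffs: SNR >= 3 and fold change >= 5 on each of the two spots
#' (set `mode = "mean"` to apply them to the duplicate means instead), and
#' coefficient of variation < 0.15 across the duplicates. Proteins with a
#' degenerate background are excluded with their reason code.
#'
#' @param spots Spot measurement frame (see [compute_spot_stats()]).
#' @param snr_cutoff,fold_cutoff,cv_cutoff Filter cutoffs.
#' @param mode Apply SNR/fold cutoffs per spot (`"spot"`, stricter,
#'   default) or to the duplicate mean (`"mean"`).
#' @return Data frame of per-protein statistics with a logical `pass`
#'   column, sorted by protein id; candidates are the rows with
#'   `pass == TRUE`.
#' @export
hpm_filter <- function(spots, snr_cutoff = 3, fold_cutoff = 5,
                       cv_cutoff = 0.15, mode = c("spot", "mean")) {
  mode <- match.arg(mode)
  st <- compute_spot_stats(spots)
  if (mode == "spot") {
    snr_ok <- st$snr1 >= snr_cutoff & st$snr2 >= snr_cutoff
    fold_ok <- st$fold1 >= fold_cutoff & st$fold2 >= fold_cutoff
  } else {
    snr_ok <- (st$snr1 + st$snr2) / 2 >= snr_cutoff
    fold_ok <- (st$fold1 + st$fold2) / 2 >= fold_cutoff
  }
  st$pass <- is.na(st$reason) & snr_ok & fold_ok & st$cv < cv_cutoff
  st$pass[is.na(st$pass)] <- FALSE
  st[order(st$protein_id), , drop = FALSE]
}
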