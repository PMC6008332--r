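# The splicing-ratio-difference (srd) score.
#
# For one event in treatment sample j, with splicing ratio SR_tj and control
# splicing ratios SR_c1..SR_cNc:
#
#   srd = (1 + sum_i (SR_tj - SR_ci)) / (1 + sd(SR_c) / N_c)
#
# where sd is the sample standard deviation (N_c - 1 divisor). The numerator
# sums (not averages) the differences over controls, so srd scales with the
# number of controls; srd equals exactly 1 when the treatment ratio matches
# every control ratio with zero spread. An optional averaged form divides
# the summed difference by N_c.

#' Splicing-ratio-difference score
#'
#' @param sr_t Treatment splicing ratio (scalar, or vector over events).
#' @param sr_c Control splicing ratios: a numeric vector (one event) or a
#'   matrix with one row per event and one column per control sample.
#' @param average If `TRUE`, the summed difference in the numerator is
#'   divided by the number of controls (a documented deviation from the
#'   canonical score; default `FALSE`).
#' @return Numeric vector of srd scores; `NA` where any input ratio is
#'   missing.
#' @export
compute_srd <- function(sr_t, sr_c, average = FALSE) {
  if (is.null(dim(sr_c))) sr_c <- matrix(sr_c, nrow = length(sr_t),
                                         ncol = length(sr_c), byrow = TRUE)
  nc <- ncol(sr_c)
  if (nc < 2L) stopf("srd needs at least 2 control samples (got %d)", nc)
  num <- nc * sr_t - rowSums(sr_c)
  if (average) num <- num / nc
  (1 + num) / (1 + row_sds(sr_c) / nc)
}

#' Event-level srd from the two junction scores
#'
#' The two junctions of an event (inclusion and skipping) each carry an srd
#' in a given treatment sample; the event takes the larger of the two (so
#' both splicing directions land in the upper tail: when one junction's
#' ratio falls, its partner's rises by SR conservation). Ties break toward
#' the inclusion junction.
#'
#' @param srd_incl srd of the inclusion junction (vector over events).
#' @param srd_skip srd of the skipping junction.
#' @return A list with `srd` (pairwise max, `NA` if either side is `NA`)
#'   and `from_inclusion` (logical; `TRUE` where the inclusion junction
#'   supplied the score).
#' @export
event_srd <- function(srd_incl, srd_skip) {
  srd <- ifelse(is.na(srd_incl) | is.na(srd_skip), NA_real_,
                pmax(srd_incl, srd_skip))
  list(srd = srd, from_inclusion = srd_incl >= srd_skip)
}
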