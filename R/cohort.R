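# Cohort stage: event frequency filter, Fisher's exact association with a
# binary group label, survival association (log-rank + Cox hazard ratio),
# and Venn-style set intersections.

#' Frequency filter for cohort splicing events
#'
#' Events occurring in strictly more than `min_frequency` of cohort samples
#' are considered cohort-related (default 5%).
#'
#' @param occurrence 0/1 matrix, samples x events (column names are event
#'   ids).
#' @param min_frequency Frequency cutoff; retention requires frequency
#'   strictly greater than this.
#' @return Character vector of retained event ids.
#' @export
ase_frequency_filter <- function(occurrence, min_frequency = 0.05) {
  occurrence <- as.matrix(occurrence)
  if (nrow(occurrence) == 0L || ncol(occurrence) == 0L)
    stopf("empty occurrence matrix")
  freq <- colMeans(occurrence)
  colnames(occurrence)[freq > min_frequency]
}

#' Two-sided Fisher's exact probability of a 2x2 table
#'
#' Exhaustive hypergeometric enumeration over all tables with the observed
#' margins; the p-value sums the probabilities of tables no more probable
#' than the observed one (with the conventional `1 + 1e-7` relative
#' tolerance for ties).
#'
#' @param tab 2x2 integer matrix of counts.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_p <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (r1 == 0L || c1 == 0L || r1 == n || c1 == n) {
    warning("zero margin: Fisher p = 1")
    return(1)
  }
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher's exact association of event occurrence with a binary group
#'
#' @param occurrence 0/1 vector of event occurrence over samples.
#' @param group 0/1 vector of group labels.
#' @return List with `table` (2x2 counts: occurrence x group), `fisher_p`,
#'   `frequency` (overall), `frequency_by_group` (group 0, group 1).
#' @export
fisher_association <- function(occurrence, group) {
  stopifnot(length(occurrence) == length(group))
  keep <- !is.na(occurrence) & !is.na(group)
  occurrence <- occurrence[keep]; group <- group[keep]
  tab <- matrix(c(sum(occurrence == 1 & group == 1),
                  sum(occurrence == 1 & group == 0),
                  sum(occurrence == 0 & group == 1),
                  sum(occurrence == 0 & group == 0)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(occurrence = c("1", "0"),
                                group = c("1", "0")))
  list(table = tab,
       fisher_p = fisher_exact_p(tab),
       frequency = mean(occurrence),
       frequency_by_group = c(group0 = mean(occurrence[group == 0]),
                              group1 = mean(occurrence[group == 1])))
}

#' Survival association of an event (log-rank test and Cox hazard ratio)
#'
#' Log-rank statistic and p-value (chi-square, 1 df) between carriers and
#' non-carriers, and the hazard ratio of occurrence from a single-covariate
#' Cox proportional-hazards fit with Breslow tie handling. When one group
#' has no observed events the hazard ratio is unbounded and reported as
#' such (`Inf`/0 with `NA` confidence limits); the log-rank p is still
#' returned.
#'
#' @param occurrence 0/1 vector over samples.
#' @param time Survival times (> 0).
#' @param event_flag 1 = death observed, 0 = censored.
#' @return List with `logrank_stat`, `logrank_p`, `hazard_ratio`,
#'   `ci_lower`, `ci_upper`, `direction` (`"unfavorable"` iff HR > 1 for
#'   carriers, `"favorable"` if HR < 1, `NA` at HR = 1).
#' @export
survival_association <- function(occurrence, time, event_flag) {
  stopifnot(length(occurrence) == length(time),
            length(time) == length(event_flag))
  if (length(unique(occurrence)) < 2L)
    stopf("occurrence must have both carriers and non-carriers")
  surv <- survival::Surv(time, event_flag)
  sd1 <- survival::survdiff(surv ~ occurrence)
  stat <- sd1$chisq
  logrank_p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)

  ev_by_grp <- tapply(event_flag, occurrence, sum)
  if (any(ev_by_grp == 0)) {
    more_in_carriers <- ev_by_grp[["1"]] > 0
    return(list(logrank_stat = stat, logrank_p = logrank_p,
                hazard_ratio = if (more_in_carriers) Inf else 0,
                ci_lower = NA_real_, ci_upper = NA_real_,
                direction = if (more_in_carriers) "unfavorable"
                            else "favorable",
                note = "no observed events in one group; HR unbounded"))
  }
  fit <- survival::coxph(surv ~ occurrence, ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  hr <- exp(beta)
  list(logrank_stat = stat, logrank_p = logrank_p,
       hazard_ratio = hr,
       ci_lower = exp(beta - 1.959963984540054 * se),
       ci_upper = exp(beta + 1.959963984540054 * se),
       direction = if (hr > 1) "unfavorable"
                   else if (hr < 1) "favorable" else NA_character_)
}

#' All Venn regions of two or three labelled sets
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return List with `regions` (named list of ids per membership pattern,
#'   names like `"A"`, `"A&B"`), `counts`, and `core` (ids in every set).
#' @export
intersect_sets <- function(sets) {
  k <- length(sets)
  stopifnot(k %in% c(2L, 3L), !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  regions <- split(universe, pattern)
  list(regions = regions,
       counts = lengths(regions),
       core = universe[rowSums(member) == k])
}

#' Cohort association analysis of splicing events
#'
#' Runs the downstream cohort stage end to end: frequency filter, per-event
#' Fisher association with the binary group label (plus Benjamini-Hochberg
#' adjusted p), per-event survival association, and the three-set
#' intersection of frequency-passing, group-associated and
#' survival-associated events.
#'
#' @param cohort A list as returned by [read_cohort_table()] or
#'   [simulate_cohort()]: `samples` (sample_id, group, time, event) and
#'   `occurrence` matrix.
#' @param min_frequency Frequency cutoff (default 0.05, strict >).
#' @param p_cutoff Raw p-value cutoff used to call group- and
#'   survival-associated events (default 0.05).
#' @return Object of class `srd_cohort`: `results` (one row per
#'   frequency-passing event), `sets`, `venn`, and the call.
#' @export
cohort_associate <- function(cohort, min_frequency = 0.05, p_cutoff = 0.05) {
  occ <- cohort$occurrence
  samp <- cohort$samples
  keep <- ase_frequency_filter(occ, min_frequency)
  rows <- lapply(keep, function(id) {
    fa <- fisher_association(occ[, id], samp$group)
    sa <- tryCatch(survival_association(occ[, id], samp$time, samp$event),
                   error = function(e) NULL)
    data.frame(ase_id = id,
               frequency = fa$frequency,
               fisher_p = fa$fisher_p,
               logrank_p = sa$logrank_p %||% NA_real_,
               hazard_ratio = sa$hazard_ratio %||% NA_real_,
               hr_ci_lower = sa$ci_lower %||% NA_real_,
               hr_ci_upper = sa$ci_upper %||% NA_real_,
               direction = sa$direction %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ase_id = character(), frequency = numeric(),
               fisher_p = numeric(), logrank_p = numeric(),
               hazard_ratio = numeric(), hr_ci_lower = numeric(),
               hr_ci_upper = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  res$fisher_p_bh <- stats::p.adjust(res$fisher_p, method = "BH")
  res$logrank_p_bh <- stats::p.adjust(res$logrank_p, method = "BH")
  sets <- list(frequent = res$ase_id,
               group_associated = res$ase_id[!is.na(res$fisher_p) &
                                               res$fisher_p < p_cutoff],
               survival_associated = res$ase_id[!is.na(res$logrank_p) &
                                                  res$logrank_p < p_cutoff])
  venn <- if (nrow(res)) intersect_sets(sets) else NULL
  structure(list(results = res, sets = sets, venn = venn,
                 min_frequency = min_frequency, p_cutoff = p_cutoff,
                 call = match.call()),
            class = "srd_cohort")
}

#' @export
print.srd_cohort <- function(x, ...) {
  cat("Cohort association of splicing events\n")
  cat(sprintf("  frequency > %g: %d events\n", x$min_frequency,
              length(x$sets$frequent)))
  cat(sprintf("  group-associated (Fisher p < %g): %d\n", x$p_cutoff,
              length(x$sets$group_associated)))
  cat(sprintf("  survival-associated (log-rank p < %g): %d\n", x$p_cutoff,
              length(x$sets$survival_associated)))
  if (!is.null(x$venn))
    cat(sprintf("  triple-overlap core: %d\n", length(x$venn$core)))
  invisible(x)
}
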