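# Differential-splicing detection: srd scores per event per treatment
# sample, a heavy-tailed null per sample, tail significance, and the
# median-of-significance selection rule against a dynamic background
# threshold computed from leave-one-out control comparisons.

#' Detect differential alternative-splicing events
#'
#' The main fitting function. Junction read counts from treatment and
#' control samples are grouped by shared splice sites; every junction pair
#' sharing a site becomes a candidate event (typed CA/A3SS/A5SS/MXE against
#' the annotation). For each event and treatment sample the srd score
#' contrasts the sample's splicing ratio with the control ratios (see
#' [compute_srd()]; the event takes the larger of its two junctions'
#' scores). Each treatment sample's srd distribution is fitted with a
#' power-law tail ([fit_power_law()]) and scores are converted to tail
#' probabilities; candidates are the events whose median significance
#' across treatment samples falls at or below a threshold set from the
#' background distribution of leave-one-out control significances.
#'
#' @param junctions Long data frame of junction records over all samples
#'   (`chrom`, `intron_start`, `intron_end`, `strand`, `unique_reads`,
#'   `sample_id`), e.g. stacked outputs of [read_star_junctions()].
#' @param treatment,control Character vectors of sample ids; at least one
#'   treatment and three controls (the background needs leave-one-out
#'   comparisons with two or more remaining controls).
#' @param annotation Optional exon annotation ([read_gtf_exons()]) used for
#'   event typing.
#' @param q Background percentile setting the selection threshold
#'   (default 0.05: the 5th percentile of background median significances).
#' @param min_tail Minimum tail size for the power-law fit.
#' @param min_events Minimum number of events with a defined srd required
#'   per sample before fitting a null (default 100).
#' @param srd_average Use the averaged-numerator srd variant.
#' @return An object of class `srd_detect`: a list with `events` (one row
#'   per event with per-sample srd and significance, `median_p`,
#'   `bg_median_p`, `delta_sr`, `direction`, `selected`), `fits` and
#'   `background_fits` (per-sample `srd_plfit`s), `threshold`, `q`,
#'   `treatment`, `control`, `call`.
#' @export
srd_detect <- function(junctions, treatment, control, annotation = NULL,
                       q = 0.05, min_tail = 10, min_events = 100,
                       srd_average = FALSE) {
  samples <- c(treatment, control)
  if (length(treatment) < 1L) stopf("need at least one treatment sample")
  if (length(control) < 3L)
    stopf("need >= 3 control samples for the leave-one-out background")
  have <- unique(junctions$sample_id)
  miss <- setdiff(samples, have)
  if (length(miss)) stopf("samples absent from junction data: %s",
                          paste(miss, collapse = ", "))

  keys <- junctions[!duplicated(junction_key(junctions)),
                    c("chrom", "intron_start", "intron_end", "strand")]
  events <- build_events(keys, annotation)
  if (nrow(events) == 0L) stopf("no splice-site groups with >= 2 junctions")

  sr <- event_sr_matrices(junctions, events, samples)
  n_ev <- nrow(events)

  score_one <- function(t_sample, ctrl) {
    si <- compute_srd(sr$incl[, t_sample], sr$incl[, ctrl, drop = FALSE],
                      average = srd_average)
    ss <- compute_srd(sr$skip[, t_sample], sr$skip[, ctrl, drop = FALSE],
                      average = srd_average)
    event_srd(si, ss)$srd
  }
  fit_and_p <- function(srd_col) {
    ok <- sum(!is.na(srd_col) & srd_col > 0)
    if (ok < min_events)
      stopf("only %d events with a defined positive srd (< min_events = %d)",
            ok, min_events)
    fit <- fit_power_law(srd_col[!is.na(srd_col)], min_tail = min_tail)
    list(fit = fit, p = predict(fit, srd_col))
  }

  srd_mat <- sapply(treatment, score_one, ctrl = control)
  dim(srd_mat) <- c(n_ev, length(treatment))
  colnames(srd_mat) <- treatment
  fits <- apply(srd_mat, 2L, fit_and_p, simplify = FALSE)
  p_treat <- sapply(fits, `[[`, "p")
  dim(p_treat) <- dim(srd_mat)
  colnames(p_treat) <- treatment

  bg <- lapply(seq_along(control), function(i)
    fit_and_p(score_one(control[i], control[-i])))
  p_bg <- sapply(bg, `[[`, "p")
  dim(p_bg) <- c(n_ev, length(control))
  colnames(p_bg) <- control

  sel <- select_candidates(p_treat, p_bg, q = q)

  delta <- rowMeans(sr$incl[, treatment, drop = FALSE]) -
    rowMeans(sr$incl[, control, drop = FALSE])
  events$delta_sr <- delta
  events$direction <- classify_direction(events$type, delta)
  for (s in treatment) events[[paste0("srd_", s)]] <- srd_mat[, s]
  for (s in treatment) events[[paste0("p_", s)]] <- p_treat[, s]
  events$median_p <- sel$median_p
  events$bg_median_p <- sel$bg_median
  events$selected <- sel$selected

  structure(list(events = events,
                 fits = lapply(fits, `[[`, "fit"),
                 background_fits = lapply(bg, `[[`, "fit"),
                 srd = srd_mat, p = p_treat, p_background = p_bg,
                 threshold = sel$threshold, q = q,
                 treatment = treatment, control = control,
                 call = match.call()),
            class = "srd_detect")
}

# splicing ratios of each event's scoring junctions, within the full
# splice-site group sharing the event's site (not just the pair)
event_sr_matrices <- function(junctions, events, samples) {
  keys <- junction_key(junctions)
  ukey <- unique(keys)
  C <- matrix(0, nrow = length(ukey), ncol = length(samples),
              dimnames = list(ukey, samples))
  keep <- junctions$sample_id %in% samples
  C[cbind(match(keys[keep], ukey),
          match(junctions$sample_id[keep], samples))] <-
    junctions$unique_reads[keep]

  parts <- do.call(rbind, strsplit(ukey, ":", fixed = TRUE))
  left_gid <- paste(parts[, 1], parts[, 4], parts[, 2])
  right_gid <- paste(parts[, 1], parts[, 4], parts[, 3])
  TL <- rowsum(C, left_gid)
  TR <- rowsum(C, right_gid)

  ev_gid <- paste(events$chrom, events$strand, events$site_pos)
  tot <- matrix(NA_real_, nrow(events), length(samples))
  is_left <- events$shared_genomic == "left"
  tot[is_left, ] <- TL[match(ev_gid[is_left], rownames(TL)), , drop = FALSE]
  tot[!is_left, ] <- TR[match(ev_gid[!is_left], rownames(TR)), , drop = FALSE]
  tot[tot == 0] <- NA_real_

  key_of <- function(s, e) paste(events$chrom, s, e, events$strand, sep = ":")
  incl <- C[match(key_of(events$incl_start, events$incl_end), ukey), ,
            drop = FALSE] / tot
  skip <- C[match(key_of(events$skip_start, events$skip_end), ukey), ,
            drop = FALSE] / tot
  colnames(incl) <- colnames(skip) <- samples
  list(incl = incl, skip = skip)
}

#' Select candidate events by median significance against a dynamic
#' background threshold
#'
#' Per event, the median tail probability across treatment samples is
#' compared with a threshold set at the `q`-th quantile of the background
#' median significances (each control treated in turn as a pseudo-treatment
#' against the remaining controls). Significance 1 means "not in the fitted
#' tail": the atom of background medians at 1 carries no ranking
#' information, so the quantile is taken over the informative (sub-1) part
#' of the background distribution — this keeps the threshold stable when
#' most background medians equal 1 — and an event whose median significance
#' is 1 (e.g. identical splicing ratios in every sample) is never selected.
#'
#' @param p_treat Matrix of tail probabilities, events x treatment samples.
#' @param p_background Matrix of tail probabilities, events x controls.
#' @param q Background quantile (default 0.05).
#' @return List with `median_p`, `bg_median`, `threshold`, `selected`.
#' @export
select_candidates <- function(p_treat, p_background, q = 0.05) {
  med <- function(m) {
    v <- apply(m, 1L, stats::median, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }
  median_p <- med(p_treat)
  bg_median <- med(p_background)
  informative <- bg_median[!is.na(bg_median) & bg_median < 1]
  threshold <- if (length(informative))
    stats::quantile(informative, probs = q, names = FALSE) else 0
  list(median_p = median_p, bg_median = bg_median, threshold = threshold,
       selected = !is.na(median_p) & median_p < 1 & median_p <= threshold)
}

#' Rank candidate events by isoform-expression differences
#'
#' Candidates are sorted by the sum of absolute treatment-minus-control
#' differences of inclusion-class and skipping-class isoform expression
#' (isoforms containing the middle exon vs isoforms spliced over it).
#' Events with no mapped isoform score 0 and sort last; ties break by
#' event id, and the sort is stable under permutations of the input.
#'
#' @param candidates Data frame with at least `event_id`.
#' @param expression Long isoform expression frame (`isoform_id`,
#'   `sample_id`, `expression`), e.g. stacked [read_isoform_expression()]
#'   outputs.
#' @param isoform_map Data frame `event_id`, `isoform_id`, `class`
#'   (`"inclusion"`/`"skipping"`), e.g. from [map_event_isoforms()].
#' @param treatment,control Sample id vectors.
#' @return `candidates` with a `rank_score` column, ordered by decreasing
#'   score.
#' @export
rank_candidates <- function(candidates, expression, isoform_map,
                            treatment, control) {
  score <- numeric(nrow(candidates))
  m <- merge(isoform_map, expression, by = "isoform_id")
  if (nrow(m)) {
    grp <- paste(m$event_id, m$class, sep = "\r")
    tot <- stats::xtabs(expression ~ grp + sample_id, data =
                          data.frame(expression = m$expression, grp = grp,
                                     sample_id = m$sample_id))
    cols <- colnames(tot)
    tmiss <- setdiff(c(treatment, control), cols)
    if (length(tmiss)) {
      tot <- cbind(tot, matrix(0, nrow(tot), length(tmiss),
                               dimnames = list(NULL, tmiss)))
    }
    d <- abs(rowMeans(tot[, treatment, drop = FALSE]) -
               rowMeans(tot[, control, drop = FALSE]))
    ev <- sub("\r.*$", "", rownames(tot))
    per_event <- tapply(d, ev, sum)
    hit <- match(candidates$event_id, names(per_event))
    score <- ifelse(is.na(hit), 0, per_event[hit])
  }
  candidates$rank_score <- as.numeric(score)
  candidates[order(-candidates$rank_score, candidates$event_id), ,
             drop = FALSE]
}

#' Map annotated isoforms to an event's inclusion and skipping classes
#'
#' Inclusion isoforms contain the event's middle exon (for CA; the first
#' middle exon for MXE, whose second exon defines the skipping class);
#' skipping isoforms belong to the same gene and splice over it. For
#' A3SS/A5SS the two classes are the transcripts whose exon boundary
#' matches the proximal vs the distal splice-site choice.
#'
#' @param events Event frame from [build_events()].
#' @param annotation Exon annotation with `transcript_id`.
#' @return Data frame `event_id`, `isoform_id`, `class`.
#' @export
map_event_isoforms <- function(events, annotation) {
  idx <- ann_index(annotation)
  if (is.null(idx)) {
    return(data.frame(event_id = character(), isoform_id = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  tx_with_exon <- function(chrom, s, e, strand) {
    hits <- ann_lookup(idx, "by_start", chrom, s, strand)
    unique(idx$ann$transcript_id[hits[idx$ann$exon_end[hits] == e]])
  }
  tx_starting <- function(chrom, s, strand)
    unique(idx$ann$transcript_id[ann_lookup(idx, "by_start", chrom, s, strand)])
  tx_ending <- function(chrom, e, strand)
    unique(idx$ann$transcript_id[ann_lookup(idx, "by_end", chrom, e, strand)])

  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    incl <- skip <- character(0)
    if (ev$type == "CA") {
      incl <- tx_with_exon(ev$chrom, ev$exon_incl_start, ev$exon_incl_end,
                           ev$strand)
      gene_tx <- unique(idx$ann$transcript_id[idx$ann$gene_id == ev$gene_id])
      over <- idx$ann$transcript_id[idx$ann$chrom == ev$chrom &
                                      idx$ann$exon_start <= ev$exon_incl_end &
                                      idx$ann$exon_end >= ev$exon_incl_start]
      skip <- setdiff(gene_tx, unique(over))
    } else if (ev$type == "MXE") {
      incl <- tx_with_exon(ev$chrom, ev$exon_incl_start, ev$exon_incl_end,
                           ev$strand)
      skip <- tx_with_exon(ev$chrom, ev$exon2_start, ev$exon2_end, ev$strand)
    } else if (ev$shared_genomic == "left") {
      incl <- tx_starting(ev$chrom, ev$incl_end + 1, ev$strand)
      skip <- tx_starting(ev$chrom, ev$skip_end + 1, ev$strand)
    } else {
      incl <- tx_ending(ev$chrom, ev$incl_start - 1, ev$strand)
      skip <- tx_ending(ev$chrom, ev$skip_start - 1, ev$strand)
    }
    skip <- setdiff(skip, incl)
    n <- length(incl) + length(skip)
    if (n == 0L) next
    out[[i]] <- data.frame(event_id = ev$event_id,
                           isoform_id = c(incl, skip),
                           class = rep(c("inclusion", "skipping"),
                                       c(length(incl), length(skip))),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(data.frame(event_id = character(), isoform_id = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Intersect candidate sets from replicate comparisons
#'
#' Keeps events selected in every comparison with a concordant direction;
#' events present everywhere but with conflicting directions are dropped
#' and reported separately. A single input set is returned unchanged.
#'
#' @param sets A list of data frames, each with `event_id` and `direction`.
#' @return List with `consensus` (event_id, direction) and `discordant`
#'   (event_id and the per-set directions, possibly zero rows).
#' @export
intersect_comparisons <- function(sets) {
  stopifnot(length(sets) >= 1L)
  if (length(sets) == 1L) {
    s <- sets[[1L]]
    return(list(consensus = s[, c("event_id", "direction")],
                discordant = s[0L, c("event_id", "direction")]))
  }
  common <- Reduce(intersect, lapply(sets, `[[`, "event_id"))
  dirs <- sapply(sets, function(s) s$direction[match(common, s$event_id)])
  dirs <- matrix(dirs, nrow = length(common))
  conc <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
  consensus <- data.frame(event_id = common[conc],
                          direction = if (any(conc)) dirs[conc, 1L]
                                      else character(0),
                          stringsAsFactors = FALSE)
  consensus <- consensus[order(consensus$event_id), , drop = FALSE]
  discordant <- data.frame(event_id = common[!conc],
                           direction = rep(NA_character_, sum(!conc)),
                           stringsAsFactors = FALSE)
  rownames(consensus) <- rownames(discordant) <- NULL
  list(consensus = consensus, discordant = discordant)
}

#' Gene-level recovery of planted events
#'
#' Compares a detection fit against a list of planted gene ids (from the
#' synthetic-data generator): sensitivity is the fraction of planted genes
#' with at least one selected event; the false-discovery rate counts
#' selected genes (events without an annotated gene count individually)
#' outside the planted set.
#'
#' @param fit An `srd_detect` object.
#' @param planted_genes Character vector of planted gene ids.
#' @return List with `sensitivity`, `fdr`, `n_selected_events`,
#'   `selected_genes`.
#' @export
detection_performance <- function(fit, planted_genes) {
  ev <- fit$events[fit$events$selected, , drop = FALSE]
  g <- ev$gene_id
  g[is.na(g)] <- paste0("unannotated_", seq_len(sum(is.na(g))))
  g <- unique(g)
  tp <- length(intersect(g, planted_genes))
  fp <- length(setdiff(g, planted_genes))
  list(sensitivity = if (length(planted_genes)) tp / length(planted_genes)
                     else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       n_selected_events = nrow(ev),
       selected_genes = g)
}

#' @export
print.srd_detect <- function(x, ...) {
  ev <- x$events
  cat("Differential alternative-splicing detection (srd)\n")
  cat(sprintf("  %d events from %d treatment / %d control samples\n",
              nrow(ev), length(x$treatment), length(x$control)))
  cat(sprintf("  selection threshold (q = %g background quantile): %.4g\n",
              x$q, x$threshold))
  cat(sprintf("  selected: %d events\n", sum(ev$selected)))
  tb <- table(ev$type[ev$selected])
  if (length(tb)) {
    cat("  by type:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.srd_detect <- function(object, n = 10L, ...) {
  ev <- object$events[object$events$selected, , drop = FALSE]
  ev <- ev[order(ev$median_p, ev$event_id), , drop = FALSE]
  cols <- intersect(c("event_id", "type", "gene_id", "direction", "delta_sr",
                      "median_p", "rank_score"), names(ev))
  out <- list(top = utils::head(ev[, cols, drop = FALSE], n),
              n_selected = nrow(ev), threshold = object$threshold,
              alpha = vapply(object$fits, `[[`, 0, "alpha"))
  class(out) <- "summary.srd_detect"
  out
}

#' @export
print.summary.srd_detect <- function(x, ...) {
  cat(sprintf("%d selected events; threshold %.4g\n", x$n_selected,
              x$threshold))
  cat("fitted tail exponents:",
      paste(sprintf("%.2f", x$alpha), collapse = ", "), "\n\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' srd distribution of one treatment sample with its fitted tail
#'
#' @param x An `srd_detect` object.
#' @param sample Treatment sample id (default: first).
#' @param ... Passed to [plot.srd_plfit()].
#' @export
plot.srd_detect <- function(x, sample = x$treatment[1L], ...) {
  plot(x$fits[[sample]], data = x$srd[, sample],
       main = paste("srd tail,", sample), ...)
}
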