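# Splice-site grouping, splicing ratios and event construction.
#
# A junction is identified by its intron (first/last intronic base, 1-based).
# The donor (5') splice site sits at the intron_start side on "+" and at the
# intron_end side on "-"; the acceptor (3') site is the other end. Junctions
# with undefined strand ("*") use "+" geometry and group only with other
# undefined-strand junctions.

junction_key <- function(j) {
  paste(j$chrom, j$intron_start, j$intron_end, j$strand, sep = ":")
}

#' Group junctions that share a splice site
#'
#' Every junction belongs to exactly one donor-side group (same 5' splice
#' site) and one acceptor-side group (same 3' splice site); singleton groups
#' are kept. Grouping keys are (chrom, strand, shared coordinate), so equal
#' coordinates on different strands form distinct groups.
#'
#' @param junctions Data frame with `chrom`, `intron_start`, `intron_end`,
#'   `strand` (one row per distinct junction; duplicates are dropped).
#' @return Data frame with one row per junction per side: `side`
#'   (`"donor"`/`"acceptor"`), `site_pos` (shared intron coordinate),
#'   `group_id`, plus the junction columns.
#' @export
group_junctions_by_site <- function(junctions) {
  k <- junction_key(junctions)
  junctions <- junctions[!duplicated(k),
                         c("chrom", "intron_start", "intron_end", "strand")]
  minus <- junctions$strand == "-"
  donor_pos <- ifelse(minus, junctions$intron_end, junctions$intron_start)
  accep_pos <- ifelse(minus, junctions$intron_start, junctions$intron_end)
  one_side <- function(side, pos) {
    data.frame(side = side, site_pos = pos,
               group_id = paste(junctions$chrom, junctions$strand, side, pos,
                                sep = ":"),
               junctions, stringsAsFactors = FALSE)
  }
  rbind(one_side("donor", donor_pos), one_side("acceptor", accep_pos))
}

#' Splicing ratio of each junction within a splice-site group
#'
#' The splicing ratio (SR) of a junction in a sample is its read count
#' divided by the summed counts of all junctions sharing the same splice
#' site. A group with zero total coverage has no defined ratio: all values
#' are `NA`.
#'
#' @param counts Numeric vector of unique-read counts for the group's
#'   members in one sample (names preserved).
#' @return Numeric vector of ratios summing to 1, or all-`NA` when the
#'   total is zero.
#' @export
compute_sr <- function(counts) {
  if (any(counts < 0, na.rm = TRUE)) stopf("negative junction counts")
  tot <- sum(counts)
  if (is.na(tot) || tot == 0) {
    out <- rep(NA_real_, length(counts))
    names(out) <- names(counts)
    return(out)
  }
  counts / tot
}

# hashed index of annotation exons by (chrom, start) and (chrom, end);
# stranded queries filter hits to the matching strand, "*" accepts any
ann_index <- function(annotation) {
  if (is.null(annotation) || nrow(annotation) == 0L) return(NULL)
  list(by_start = split(seq_len(nrow(annotation)),
                        paste(annotation$chrom, annotation$exon_start)),
       by_end = split(seq_len(nrow(annotation)),
                      paste(annotation$chrom, annotation$exon_end)),
       ann = annotation)
}

ann_lookup <- function(idx, field, chrom, pos, strand) {
  hits <- idx[[field]][[paste(chrom, pos)]]
  if (is.null(hits)) return(integer(0))
  if (strand %in% c("+", "-")) hits <- hits[idx$ann$strand[hits] == strand]
  hits
}

# classify one junction pair sharing the genomic-left intron coordinate;
# introns (s..e1) and (s..e2) with e1 < e2; a spliced-in exon starts at e1+1
classify_left_pair <- function(chrom, strand, s, e1, e2, idx) {
  shared_side <- if (strand == "-") "acceptor" else "donor"
  mid <- integer(0)
  starters <- integer(0)
  if (!is.null(idx)) {
    starters <- ann_lookup(idx, "by_start", chrom, e1 + 1L, strand)
    cand <- starters[idx$ann$exon_end[starters] < e2]
    if (length(cand)) mid <- cand[which.min(idx$ann$exon_end[cand])]
  }
  if (length(mid)) {
    type <- "CA"
    incl_exon <- c(e1 + 1, idx$ann$exon_end[mid])
    gene_id <- idx$ann$gene_id[mid]
    low_conf <- FALSE
  } else {
    type <- if (shared_side == "donor") "A3SS" else "A5SS"
    incl_exon <- c(NA_real_, NA_real_)
    gene_id <- if (length(starters)) idx$ann$gene_id[starters[1L]]
               else NA_character_
    low_conf <- length(starters) == 0L
  }
  list(chrom = chrom, strand = strand, type = type, shared_side = shared_side,
       shared_genomic = "left", site_pos = s, incl = c(s, e1),
       skip = c(s, e2), incl_exon = incl_exon, gene_id = gene_id,
       low_confidence = low_conf)
}

# classify one junction pair sharing the genomic-right intron coordinate;
# introns (s1..e) and (s2..e) with s1 < s2; a spliced-in exon ends at s2-1
classify_right_pair <- function(chrom, strand, e, s1, s2, idx) {
  shared_side <- if (strand == "-") "donor" else "acceptor"
  mid <- integer(0)
  enders <- integer(0)
  if (!is.null(idx)) {
    enders <- ann_lookup(idx, "by_end", chrom, s2 - 1L, strand)
    cand <- enders[idx$ann$exon_start[enders] > s1]
    if (length(cand)) mid <- cand[which.max(idx$ann$exon_start[cand])]
  }
  if (length(mid)) {
    type <- "CA"
    incl_exon <- c(idx$ann$exon_start[mid], s2 - 1)
    gene_id <- idx$ann$gene_id[mid]
    low_conf <- FALSE
  } else {
    type <- if (shared_side == "donor") "A3SS" else "A5SS"
    incl_exon <- c(NA_real_, NA_real_)
    gene_id <- if (length(enders)) idx$ann$gene_id[enders[1L]]
               else NA_character_
    low_conf <- length(enders) == 0L
  }
  list(chrom = chrom, strand = strand, type = type, shared_side = shared_side,
       shared_genomic = "right", site_pos = e, incl = c(s2, e),
       skip = c(s1, e), incl_exon = incl_exon, gene_id = gene_id,
       low_confidence = low_conf)
}

pair_event_id <- function(ev) {
  side <- ifelse(ev$shared_genomic == "left", "L", "R")
  var1 <- ifelse(ev$shared_genomic == "left", ev$incl_end, ev$incl_start)
  var2 <- ifelse(ev$shared_genomic == "left", ev$skip_end, ev$skip_start)
  sprintf("%s:%s:%s%d:%d:%d", ev$chrom, ev$strand, side,
          as.integer(ev$site_pos), as.integer(var1), as.integer(var2))
}

#' Build alternative-splicing event candidates from junction pairs
#'
#' Every unordered pair of junctions sharing a splice site yields one event.
#' With a shared donor and two acceptors the pair is a cassette exon (CA)
#' when the nearer acceptor matches an annotated exon start whose exon ends
#' before the farther acceptor (a skippable middle exon exists), otherwise
#' an alternative 3' splice site (A3SS); a shared acceptor is symmetric (CA
#' vs A5SS). Reciprocal CA events over non-overlapping middle exons whose
#' skipping junctions land exactly on each other's middle exon, with the two
#' middle exons never annotated in the same transcript, are merged into one
#' mutually-exclusive-exon (MXE) event. Pairs with no annotation support
#' default to A3SS/A5SS and are flagged low-confidence.
#'
#' @param junctions Data frame of distinct junctions (`chrom`,
#'   `intron_start`, `intron_end`, `strand`).
#' @param annotation Optional exon annotation from [read_gtf_exons()].
#' @return Data frame of events: `event_id`, `type`, `chrom`, `strand`,
#'   `shared_side`, `shared_genomic`, `site_pos`, inclusion/skipping
#'   junction intron coordinates (`incl_*`, `skip_*`), middle-exon
#'   coordinates (`exon_incl_*`; `incl2_*`/`exon2_*` carry the second arm
#'   of an MXE), `gene_id`, `low_confidence`. Rows sorted by `event_id`.
#' @export
build_events <- function(junctions, annotation = NULL) {
  need <- c("chrom", "intron_start", "intron_end", "strand")
  miss <- setdiff(need, names(junctions))
  if (length(miss)) stopf("junction frame lacks column(s): %s",
                          paste(miss, collapse = ", "))
  k <- junction_key(junctions)
  junctions <- junctions[!duplicated(k), , drop = FALSE]
  idx <- ann_index(annotation)
  res <- list()

  left_key <- paste(junctions$chrom, junctions$strand, junctions$intron_start)
  for (grp in split(seq_len(nrow(junctions)), left_key)) {
    if (length(grp) < 2L) next
    ends <- sort(junctions$intron_end[grp])
    chrom <- junctions$chrom[grp[1L]]
    strand <- junctions$strand[grp[1L]]
    s <- junctions$intron_start[grp[1L]]
    prs <- utils::combn(length(ends), 2L)
    for (i in seq_len(ncol(prs))) {
      res[[length(res) + 1L]] <-
        classify_left_pair(chrom, strand, s, ends[prs[1L, i]],
                           ends[prs[2L, i]], idx)
    }
  }
  right_key <- paste(junctions$chrom, junctions$strand, junctions$intron_end)
  for (grp in split(seq_len(nrow(junctions)), right_key)) {
    if (length(grp) < 2L) next
    starts <- sort(junctions$intron_start[grp])
    chrom <- junctions$chrom[grp[1L]]
    strand <- junctions$strand[grp[1L]]
    e <- junctions$intron_end[grp[1L]]
    prs <- utils::combn(length(starts), 2L)
    for (i in seq_len(ncol(prs))) {
      res[[length(res) + 1L]] <-
        classify_right_pair(chrom, strand, e, starts[prs[1L, i]],
                            starts[prs[2L, i]], idx)
    }
  }
  if (length(res) == 0L) return(empty_events())

  num <- function(f) vapply(res, function(p) as.numeric(p[[f]]), 0)
  chr <- function(f) vapply(res, function(p) as.character(p[[f]]), "")
  ev <- data.frame(
    type = chr("type"),
    chrom = chr("chrom"),
    strand = chr("strand"),
    shared_side = chr("shared_side"),
    shared_genomic = chr("shared_genomic"),
    site_pos = num("site_pos"),
    incl_start = vapply(res, function(p) as.numeric(p$incl[1L]), 0),
    incl_end = vapply(res, function(p) as.numeric(p$incl[2L]), 0),
    skip_start = vapply(res, function(p) as.numeric(p$skip[1L]), 0),
    skip_end = vapply(res, function(p) as.numeric(p$skip[2L]), 0),
    exon_incl_start = vapply(res, function(p) as.numeric(p$incl_exon[1L]), 0),
    exon_incl_end = vapply(res, function(p) as.numeric(p$incl_exon[2L]), 0),
    incl2_start = NA_real_, incl2_end = NA_real_,
    exon2_start = NA_real_, exon2_end = NA_real_,
    gene_id = vapply(res, function(p) as.character(p$gene_id), ""),
    low_confidence = vapply(res, `[[`, TRUE, "low_confidence"),
    stringsAsFactors = FALSE)
  ev$event_id <- pair_event_id(ev)
  ev <- merge_mxe(ev, annotation)
  ev <- ev[order(ev$event_id), c("event_id", setdiff(names(ev), "event_id"))]
  rownames(ev) <- NULL
  ev
}

# merge reciprocal CA pairs into MXE events
merge_mxe <- function(ev, annotation) {
  la <- which(ev$type == "CA" & ev$shared_genomic == "left")
  rb <- which(ev$type == "CA" & ev$shared_genomic == "right")
  if (length(la) == 0L || length(rb) == 0L) return(ev)
  # b's middle exon ends where a's skipping junction says it should start
  bkey <- paste(ev$chrom[rb], ev$strand[rb], ev$exon_incl_start[rb],
                ev$skip_start[rb])
  drop <- logical(nrow(ev))
  for (a in la) {
    key <- paste(ev$chrom[a], ev$strand[a], ev$skip_end[a] + 1,
                 ev$exon_incl_end[a] + 1)
    hit <- rb[bkey == key]
    if (length(hit) != 1L) next
    b <- hit
    if (ev$exon_incl_end[a] >= ev$exon_incl_start[b]) next  # overlap
    if (exons_cooccur(annotation, ev$chrom[a],
                      ev$exon_incl_start[a], ev$exon_incl_end[a],
                      ev$exon_incl_start[b], ev$exon_incl_end[b])) next
    ev$type[a] <- "MXE"
    ev$incl2_start[a] <- ev$incl_start[b]
    ev$incl2_end[a] <- ev$incl_end[b]
    ev$exon2_start[a] <- ev$exon_incl_start[b]
    ev$exon2_end[a] <- ev$exon_incl_end[b]
    ev$event_id[a] <- paste0("MXE|", ev$event_id[a], "|", ev$event_id[b])
    drop[b] <- TRUE
  }
  ev[!drop, , drop = FALSE]
}

# TRUE when some transcript contains both exons exactly
exons_cooccur <- function(annotation, chrom, s1, e1, s2, e2) {
  if (is.null(annotation)) return(FALSE)
  a <- annotation[annotation$chrom == chrom, , drop = FALSE]
  t1 <- a$transcript_id[a$exon_start == s1 & a$exon_end == e1]
  t2 <- a$transcript_id[a$exon_start == s2 & a$exon_end == e2]
  length(intersect(t1, t2)) > 0L
}

empty_events <- function() {
  data.frame(event_id = character(), type = character(), chrom = character(),
             strand = character(), shared_side = character(),
             shared_genomic = character(), site_pos = numeric(),
             incl_start = numeric(), incl_end = numeric(),
             skip_start = numeric(), skip_end = numeric(),
             exon_incl_start = numeric(), exon_incl_end = numeric(),
             incl2_start = numeric(), incl2_end = numeric(),
             exon2_start = numeric(), exon2_end = numeric(),
             gene_id = character(), low_confidence = logical(),
             stringsAsFactors = FALSE)
}

#' Classify event direction from the inclusion-junction SR change
#'
#' For cassette and mutually-exclusive exons the event is excluded (EX) when
#' the inclusion junction's splicing ratio falls in treatment relative to
#' control and included (IN) when it rises; for A3SS/A5SS the direction is
#' reported as down/up of the first-listed (inclusion-side) junction. A zero
#' change is flagged as undirected (`NA`).
#'
#' @param type Character vector of event types.
#' @param delta_sr Numeric vector, mean treatment-minus-control SR of the
#'   inclusion junction.
#' @return Character vector in `{"EX","IN","down","up"}` with `NA` for
#'   zero change.
#' @export
classify_direction <- function(type, delta_sr) {
  stopifnot(length(type) == length(delta_sr))
  out <- rep(NA_character_, length(type))
  ca <- type %in% c("CA", "MXE")
  out[ca & delta_sr < 0] <- "EX"
  out[ca & delta_sr > 0] <- "IN"
  out[!ca & delta_sr < 0] <- "down"
  out[!ca & delta_sr > 0] <- "up"
  out
}
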