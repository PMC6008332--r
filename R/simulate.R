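# Synthetic-data generator: gene models with planted event geometry,
# negative-binomial junction counts at controlled PSI, matched isoform
# expression, tumor cohorts with planted associations and exponential
# survival, and duplicate-spot microarray tables. Every generator takes an
# explicit seed and is fully deterministic given it.

#' Gene models with planted alternative-splicing geometry
#'
#' Builds one gene per requested event, alternating strands, each realising
#' its type exactly as [build_events()] classifies it: cassette exons (CA)
#' with a skippable middle exon, alternative acceptor/donor choices
#' (A3SS/A5SS) inside an annotated exon, and mutually exclusive exon pairs
#' (MXE) with no transcript containing both middle exons. Deterministic
#' (no randomness in the geometry).
#'
#' @param events_per_type Named integer vector with any of `CA`, `A3SS`,
#'   `A5SS`, `MXE`.
#' @param chrom Chromosome name used for all genes.
#' @return List with `genes` (gene_id, type, strand, offset), `annotation`
#'   (exon frame as from [read_gtf_exons()]), `isoforms` (gene_id,
#'   transcript_id, class inclusion/skipping) and `junction_roles`
#'   (gene_id, intron coordinates, strand, role incl/skip).
#' @export
simulate_gene_models <- function(events_per_type = c(CA = 10),
                                 chrom = "chr1") {
  types <- rep(names(events_per_type), events_per_type)
  n <- length(types)
  if (n == 0L) stopf("no events requested")
  strands <- rep(c("+", "-"), length.out = n)
  ann <- list(); iso <- list(); jx <- list()
  for (g in seq_len(n)) {
    b <- (g - 1L) * 10000L + 1L
    gid <- sprintf("G%04d", g)
    t1 <- paste0(gid, ".T1"); t2 <- paste0(gid, ".T2")
    st <- strands[g]
    exon <- function(tid, s, e) data.frame(gene_id = gid, transcript_id = tid,
                                           chrom = chrom, exon_start = s,
                                           exon_end = e, strand = st,
                                           stringsAsFactors = FALSE)
    junc <- function(s, e, role) data.frame(gene_id = gid, chrom = chrom,
                                            intron_start = s,
                                            intron_end = e, strand = st,
                                            role = role,
                                            stringsAsFactors = FALSE)
    if (types[g] == "CA") {
      a <- rbind(exon(t1, b, b + 199), exon(t1, b + 300, b + 399),
                 exon(t1, b + 500, b + 699),
                 exon(t2, b, b + 199), exon(t2, b + 500, b + 699))
      j <- rbind(junc(b + 200, b + 299, "incl"),
                 junc(b + 400, b + 499, "incl"),
                 junc(b + 200, b + 499, "skip"))
    } else if (types[g] == "MXE") {
      a <- rbind(exon(t1, b, b + 199), exon(t1, b + 300, b + 399),
                 exon(t1, b + 700, b + 899),
                 exon(t2, b, b + 199), exon(t2, b + 500, b + 599),
                 exon(t2, b + 700, b + 899))
      j <- rbind(junc(b + 200, b + 299, "incl"),
                 junc(b + 400, b + 699, "incl"),
                 junc(b + 200, b + 499, "skip"),
                 junc(b + 600, b + 699, "skip"))
    } else if (types[g] == "A3SS") {
      if (st == "+") {
        a <- rbind(exon(t1, b, b + 199), exon(t1, b + 300, b + 599),
                   exon(t2, b, b + 199), exon(t2, b + 330, b + 599))
        j <- rbind(junc(b + 200, b + 299, "incl"),
                   junc(b + 200, b + 329, "skip"))
      } else {
        a <- rbind(exon(t1, b, b + 299), exon(t1, b + 400, b + 599),
                   exon(t2, b, b + 269), exon(t2, b + 400, b + 599))
        j <- rbind(junc(b + 300, b + 399, "incl"),
                   junc(b + 270, b + 399, "skip"))
      }
    } else if (types[g] == "A5SS") {
      if (st == "+") {
        a <- rbind(exon(t1, b, b + 229), exon(t1, b + 400, b + 599),
                   exon(t2, b, b + 199), exon(t2, b + 400, b + 599))
        j <- rbind(junc(b + 230, b + 399, "incl"),
                   junc(b + 200, b + 399, "skip"))
      } else {
        a <- rbind(exon(t1, b, b + 199), exon(t1, b + 370, b + 599),
                   exon(t2, b, b + 199), exon(t2, b + 400, b + 599))
        j <- rbind(junc(b + 200, b + 369, "incl"),
                   junc(b + 200, b + 399, "skip"))
      }
    } else stopf("unknown event type '%s'", types[g])
    ann[[g]] <- a
    jx[[g]] <- j
    iso[[g]] <- data.frame(gene_id = gid, transcript_id = c(t1, t2),
                           class = c("inclusion", "skipping"),
                           stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, ann)
  annotation <- annotation[order(annotation$chrom, annotation$exon_start,
                                 annotation$exon_end,
                                 annotation$transcript_id), ]
  rownames(annotation) <- NULL
  list(genes = data.frame(gene_id = sprintf("G%04d", seq_len(n)),
                          type = types, strand = strands, chrom = chrom,
                          offset = (seq_len(n) - 1L) * 10000L + 1L,
                          stringsAsFactors = FALSE),
       annotation = annotation,
       isoforms = do.call(rbind, iso),
       junction_roles = do.call(rbind, jx))
}

#' Junction read counts at controlled PSI with planted effects
#'
#' Per gene, a baseline inclusion level (PSI) is drawn from a Beta
#' distribution; inclusion junctions receive negative-binomial counts with
#' mean `depth * PSI` and skipping junctions `depth * (1 - PSI)`. Planted
#' genes have their PSI shifted by `delta_psi` (random sign) in every
#' treatment sample, clipped to (0.01, 0.99) with a warning.
#'
#' @param models Gene models from [simulate_gene_models()].
#' @param n_treatment,n_control Sample counts (defaults 2 and 3, the
#'   knockdown-style design of two treated replicates against controls).
#' @param depth Mean junction read depth per gene.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   0 gives Poisson counts.
#' @param n_planted Number of genes with a planted PSI shift.
#' @param delta_psi Magnitude of the planted shift.
#' @param psi_shape Beta shape parameters of the baseline PSI (default
#'   `c(2, 2)`).
#' @param seed Random seed (mandatory; default 17).
#' @return List with `junctions` (long frame over all samples), `psi`
#'   (gene x sample matrix), `truth` (gene_id, planted, delta_psi,
#'   direction), `treatment`, `control`.
#' @export
simulate_junction_counts <- function(models, n_treatment = 2, n_control = 3,
                                     depth = 100, dispersion = 0.05,
                                     n_planted = 0, delta_psi = 0.3,
                                     psi_shape = c(2, 2), seed = 17) {
  set.seed(seed)
  genes <- models$genes
  n <- nrow(genes)
  treatment <- sprintf("T%d", seq_len(n_treatment))
  control <- sprintf("C%d", seq_len(n_control))
  samples <- c(treatment, control)
  psi0 <- stats::rbeta(n, psi_shape[1L], psi_shape[2L])
  planted <- rep(FALSE, n)
  planted[sample.int(n, min(n_planted, n))] <- TRUE
  # the planted shift direction is drawn among directions that keep PSI in
  # (0.01, 0.99), so the planted effect size really is delta_psi; clipping
  # only occurs when no direction has room (very large shifts)
  up_ok <- psi0 + delta_psi <= 0.99
  dn_ok <- psi0 - delta_psi >= 0.01
  coin <- sample(c(-1, 1), n, replace = TRUE)
  sgn <- ifelse(up_ok & dn_ok, coin, ifelse(up_ok, 1, ifelse(dn_ok, -1, coin)))
  sgn[!planted] <- 0
  psi <- matrix(psi0, n, length(samples), dimnames = list(genes$gene_id,
                                                          samples))
  shifted <- psi0 + sgn * delta_psi
  clipped <- shifted < 0.01 | shifted > 0.99
  if (any(clipped & planted))
    warning(sprintf("%d planted PSI value(s) clipped to (0.01, 0.99)",
                    sum(clipped & planted)))
  psi[, treatment] <- shifted
  psi[] <- pmin(pmax(psi, 0.01), 0.99)

  jr <- models$junction_roles
  gi <- match(jr$gene_id, genes$gene_id)
  draw <- function(mu) {
    if (dispersion > 0) stats::rnbinom(length(mu), mu = mu,
                                       size = 1 / dispersion)
    else stats::rpois(length(mu), mu)
  }
  out <- lapply(samples, function(s) {
    frac <- ifelse(jr$role == "incl", psi[gi, s], 1 - psi[gi, s])
    data.frame(chrom = genes$chrom[gi], intron_start = jr$intron_start,
               intron_end = jr$intron_end, strand = jr$strand,
               unique_reads = draw(depth * frac), sample_id = s,
               stringsAsFactors = FALSE)
  })
  dir_ca <- ifelse(sgn > 0, "IN", ifelse(sgn < 0, "EX", NA))
  dir_ss <- ifelse(sgn > 0, "up", ifelse(sgn < 0, "down", NA))
  truth <- data.frame(gene_id = genes$gene_id, type = genes$type,
                      planted = planted, psi_baseline = psi0,
                      delta_psi = sgn * delta_psi,
                      direction = ifelse(genes$type %in% c("CA", "MXE"),
                                         dir_ca, dir_ss),
                      stringsAsFactors = FALSE)
  list(junctions = do.call(rbind, out), psi = psi, truth = truth,
       treatment = treatment, control = control)
}

#' Isoform expression consistent with the simulated PSI
#'
#' Each gene gets a lognormal overall level (fixed across samples); the
#' inclusion isoform's expression is proportional to `level * PSI` and the
#' skipping isoform's to `level * (1 - PSI)`, each with multiplicative
#' lognormal noise.
#'
#' @param models Gene models from [simulate_gene_models()].
#' @param psi Gene x sample PSI matrix (from [simulate_junction_counts()]).
#' @param gene_meanlog,gene_sdlog Lognormal parameters of the per-gene
#'   level (defaults log(100) and 0.25).
#' @param noise_sdlog Multiplicative noise sd on the log scale
#'   (default 0.1).
#' @param seed Random seed.
#' @return Long data frame `isoform_id`, `gene_id`, `sample_id`,
#'   `expression`.
#' @export
simulate_isoform_expression <- function(models, psi,
                                        gene_meanlog = log(100),
                                        gene_sdlog = 0.25,
                                        noise_sdlog = 0.1, seed = 17) {
  set.seed(seed)
  genes <- models$genes
  samples <- colnames(psi)
  level <- stats::rlnorm(nrow(genes), gene_meanlog, gene_sdlog)
  iso <- models$isoforms
  gi <- match(iso$gene_id, genes$gene_id)
  out <- lapply(samples, function(s) {
    frac <- ifelse(iso$class == "inclusion", psi[gi, s], 1 - psi[gi, s])
    data.frame(isoform_id = iso$transcript_id, gene_id = iso$gene_id,
               sample_id = s,
               expression = level[gi] * frac *
                 stats::rlnorm(nrow(iso), 0, noise_sdlog),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a tumor cohort with planted associations and survival
#'
#' Event occurrence is Bernoulli at the configured frequency; for planted
#' group-associated events the occurrence odds are multiplied by
#' `odds_ratio` in the `group = 1` stratum. Survival times are exponential
#' with the baseline hazard multiplied by `hazard_ratio` for each planted
#' survival event the sample carries; censoring is independent exponential
#' at `censor_rate` (0 disables censoring).
#'
#' @param n_samples Cohort size.
#' @param n_ases Number of splicing events in the occurrence matrix.
#' @param frequency Baseline occurrence frequency.
#' @param n_assoc Number of planted group-associated events.
#' @param odds_ratio Planted odds ratio.
#' @param group_fraction Fraction of samples in group 1.
#' @param baseline_hazard Exponential death hazard for non-carriers.
#' @param hazard_ratio Planted hazard ratio of carriers.
#' @param n_hr Number of planted survival-associated events.
#' @param censor_rate Exponential censoring rate.
#' @param seed Random seed.
#' @return List with `samples` (sample_id, group, time, event),
#'   `occurrence` (matrix samples x events) and `truth` (planted
#'   association and survival event ids).
#' @export
simulate_cohort <- function(n_samples = 200, n_ases = 50, frequency = 0.2,
                            n_assoc = 5, odds_ratio = 4,
                            group_fraction = 0.5, baseline_hazard = 0.1,
                            hazard_ratio = 2, n_hr = 5, censor_rate = 0.02,
                            seed = 17) {
  set.seed(seed)
  ase_ids <- sprintf("ASE_%03d", seq_len(n_ases))
  assoc <- sort(sample(ase_ids, min(n_assoc, n_ases)))
  surv <- sort(sample(ase_ids, min(n_hr, n_ases)))
  group <- stats::rbinom(n_samples, 1L, group_fraction)
  odds <- frequency / (1 - frequency)
  p_assoc <- odds * odds_ratio / (1 + odds * odds_ratio)
  occ <- sapply(ase_ids, function(id) {
    p <- if (id %in% assoc) ifelse(group == 1L, p_assoc, frequency)
         else rep(frequency, n_samples)
    stats::rbinom(n_samples, 1L, p)
  })
  dimnames(occ) <- list(sprintf("S%04d", seq_len(n_samples)), ase_ids)
  hazard <- baseline_hazard *
    hazard_ratio^rowSums(occ[, surv, drop = FALSE])
  t_death <- stats::rexp(n_samples, rate = hazard)
  t_cens <- if (censor_rate > 0) stats::rexp(n_samples, rate = censor_rate)
            else rep(Inf, n_samples)
  samples <- data.frame(sample_id = rownames(occ), group = group,
                        time = pmin(t_death, t_cens),
                        event = as.integer(t_death <= t_cens),
                        stringsAsFactors = FALSE)
  list(samples = samples, occurrence = occ,
       truth = list(assoc = assoc, survival = surv))
}

#' Simulate a duplicate-spot microarray table with planted binders
#'
#' Null proteins fluoresce near background (SNR well below 3, fold change
#' near 1); planted binders carry a strong, tightly duplicated signal so
#' that both spots pass SNR >= 3 and fold >= 5 with duplicate CV < 0.15.
#'
#' @param n_proteins Total proteins on the array.
#' @param n_binders Number of planted binders.
#' @param bg_mean,bg_sd Background fluorescence mean level and spot
#'   background sd level.
#' @param null_signal Mean background-subtracted signal of null proteins.
#' @param binder_signal Range (min, max) of binder signals.
#' @param dup_noise Multiplicative duplicate noise sd.
#' @param seed Random seed.
#' @return List with `spots` (two rows per protein) and `truth` (planted
#'   binder ids).
#' @export
simulate_spot_table <- function(n_proteins = 500, n_binders = 20,
                                bg_mean = 200, bg_sd = 40,
                                null_signal = 20,
                                binder_signal = c(3000, 6000),
                                dup_noise = 0.02, seed = 17) {
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  binders <- sort(sample(ids, min(n_binders, n_proteins)))
  base <- stats::runif(n_proteins, binder_signal[1L], binder_signal[2L])
  rows <- lapply(1:2, function(k) {
    b_mean <- stats::rnorm(n_proteins, bg_mean, bg_mean * 0.05)
    b_med <- b_mean * stats::rnorm(n_proteins, 1, 0.02)
    b_sd <- abs(stats::rnorm(n_proteins, bg_sd, bg_sd * 0.1))
    sig <- ifelse(ids %in% binders,
                  base * stats::rnorm(n_proteins, 1, dup_noise),
                  abs(stats::rnorm(n_proteins, null_signal,
                                   null_signal * 0.75)))
    data.frame(protein_id = ids, replicate = k,
               F635_mean = b_mean + sig,
               F635_median = b_med + sig * stats::rnorm(n_proteins, 1, 0.02),
               B635_mean = b_mean, B635_median = b_med, B635_sd = b_sd,
               stringsAsFactors = FALSE)
  })
  spots <- do.call(rbind, rows)
  spots <- spots[order(spots$protein_id, spots$replicate), ]
  rownames(spots) <- NULL
  list(spots = spots, truth = binders)
}

#' Write a complete synthetic study to a directory
#'
#' Emits every input the pipeline consumes: `annotation.gtf`, one
#' `sj_<sample>.tab` per sample, one `isoforms_<sample>.tsv` per sample,
#' `cohort.tsv`, `spots.tsv`, `truth.json` and `config.json` (the echoed
#' generator configuration, for provenance). Deterministic given the seed.
#'
#' @param dir Output directory (created if needed).
#' @param events_per_type Gene models to plant (see
#'   [simulate_gene_models()]).
#' @param seed Master seed; stage seeds are derived from it.
#' @param ... Overrides passed to [simulate_junction_counts()]
#'   (`n_treatment`, `n_control`, `depth`, `dispersion`, `n_planted`,
#'   `delta_psi`).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_study <- function(dir, events_per_type = c(CA = 200, A3SS = 100,
                                                    A5SS = 100, MXE = 100),
                           seed = 17, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- simulate_gene_models(events_per_type)
  counts <- simulate_junction_counts(models, seed = seed, ...)
  expr <- simulate_isoform_expression(models, counts$psi, seed = seed + 1)
  cohort <- simulate_cohort(seed = seed + 2)
  spots <- simulate_spot_table(seed = seed + 3)

  write_gtf_exons(models$annotation, file.path(dir, "annotation.gtf"))
  for (s in colnames(counts$psi)) {
    write_star_junctions(counts$junctions[counts$junctions$sample_id == s, ],
                         file.path(dir, paste0("sj_", s, ".tab")))
    write_isoform_expression(expr[expr$sample_id == s, ],
                             file.path(dir, paste0("isoforms_", s, ".tsv")))
  }
  write_cohort_table(cohort$samples, cohort$occurrence,
                     file.path(dir, "cohort.tsv"))
  write_results_table(spots$spots, file.path(dir, "spots.tsv"))
  truth <- list(planted_genes = counts$truth$gene_id[counts$truth$planted],
                delta_psi = counts$truth$delta_psi[counts$truth$planted],
                cohort = cohort$truth, binders = spots$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- c(list(events_per_type = as.list(events_per_type), seed = seed),
           list(...))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(models = models, counts = counts, expression = expr,
                 cohort = cohort, spots = spots, dir = dir))
}
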