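test_that("generators are deterministic under a fixed seed", {
  m <- simulate_gene_models(c(CA = 20, MXE = 5))
  a <- simulate_junction_counts(m, seed = 4)
  b <- simulate_junction_counts(m, seed = 4)
  expect_identical(a, b)
  c2 <- simulate_junction_counts(m, seed = 5)
  expect_false(identical(a$junctions$unique_reads,
                         c2$junctions$unique_reads))
  expect_identical(simulate_cohort(seed = 4), simulate_cohort(seed = 4))
  expect_identical(simulate_spot_table(seed = 4),
                   simulate_spot_table(seed = 4))
})

test_that("generated junction counts track the planted PSI", {
  m <- simulate_gene_models(c(CA = 60))
  cs <- simulate_junction_counts(m, n_treatment = 1, n_control = 1,
                                 depth = 10000, dispersion = 0, seed = 6)
  j <- cs$junctions[cs$junctions$sample_id == "C1", ]
  jr <- m$junction_roles
  frac <- sapply(m$genes$gene_id, function(g) {
    rows <- jr$gene_id == g
    # inclusion fraction at the shared donor group: first incl junction
    # against the skipping junction
    ji <- jr[rows & jr$role == "incl", ][1, ]
    js <- jr[rows & jr$role == "skip", ][1, ]
    ci <- j$unique_reads[j$intron_start == ji$intron_start &
                           j$intron_end == ji$intron_end]
    cskip <- j$unique_reads[j$intron_start == js$intron_start &
                              j$intron_end == js$intron_end]
    ci / (ci + cskip)
  })
  err <- frac - cs$psi[, "C1"]
  # Poisson counts at depth 10,000: per-gene se ~ 0.005
  expect_lt(abs(mean(err)), 3 * 0.005 / sqrt(60) + 0.002)
  expect_lt(max(abs(err)), 0.03)
})

test_that("planted shifts realise the requested effect size", {
  m <- simulate_gene_models(c(CA = 200))
  cs <- simulate_junction_counts(m, n_planted = 50, delta_psi = 0.3,
                                 seed = 8)
  planted <- cs$truth$planted
  shift <- cs$psi[, "T1"] - cs$psi[, "C1"]
  expect_equal(sum(planted), 50)
  expect_true(all(abs(abs(shift[planted]) - 0.3) < 1e-9))
  expect_true(all(shift[!planted] == 0))
  expect_true(all(cs$psi > 0 & cs$psi < 1))
})

test_that("isoform expression is proportional to PSI and gene level", {
  m <- simulate_gene_models(c(CA = 80))
  cs <- simulate_junction_counts(m, seed = 10)
  psi <- cs$psi
  psi[] <- 0.5
  expr <- simulate_isoform_expression(m, psi, noise_sdlog = 0.05, seed = 11)
  e1 <- expr[expr$sample_id == "C1", ]
  incl <- e1$expression[grepl("T1$", e1$isoform_id)]
  skip <- e1$expression[grepl("T2$", e1$isoform_id)]
  expect_equal(mean(log(incl / skip)), 0, tolerance = 0.05)
  # planted events separate in expression space
  cs2 <- simulate_junction_counts(m, n_planted = 20, delta_psi = 0.3,
                                  seed = 12)
  ex2 <- simulate_isoform_expression(m, cs2$psi, seed = 13)
  d <- sapply(m$genes$gene_id, function(g) {
    gi <- ex2[ex2$gene_id == g & grepl("T1$", ex2$isoform_id), ]
    abs(mean(gi$expression[gi$sample_id %in% cs2$treatment]) -
          mean(gi$expression[gi$sample_id %in% cs2$control]))
  })
  expect_gt(mean(d[cs2$truth$planted]), mean(d[!cs2$truth$planted]))
})

test_that("cohort generator hits its frequency and hazard targets", {
  co <- simulate_cohort(n_samples = 500, n_ases = 20, frequency = 0.2,
                        n_assoc = 0, n_hr = 0, censor_rate = 0, seed = 14)
  f <- colMeans(co$occurrence)
  se <- sqrt(0.2 * 0.8 / 500)
  expect_lt(abs(mean(f) - 0.2), 3 * se / sqrt(20))
  # null hazard: HR estimates centre on 1
  hr <- sapply(1:5, function(k)
    survival_association(co$occurrence[, k], co$samples$time,
                         co$samples$event)$hazard_ratio)
  expect_lt(abs(mean(log(hr))), 0.25)
})

test_that("a written study round-trips through every reader", {
  dir <- file.path(tempdir(), "study1")
  st <- simulate_study(dir, events_per_type = c(CA = 30, A3SS = 10,
                                                A5SS = 10, MXE = 10),
                       seed = 15, n_planted = 5)
  ann <- read_gtf_exons(file.path(dir, "annotation.gtf"))
  expect_equal(ann, st$models$annotation, ignore_attr = TRUE)
  sj <- read_star_junctions(file.path(dir, "sj_T1.tab"), "T1")
  orig <- st$counts$junctions[st$counts$junctions$sample_id == "T1", ]
  orig <- orig[order(orig$chrom, orig$intron_start, orig$intron_end,
                     orig$strand), ]
  expect_equal(sj$unique_reads, orig$unique_reads)
  iso <- read_isoform_expression(file.path(dir, "isoforms_C1.tsv"), "C1")
  expect_equal(sort(iso$isoform_id),
               sort(unique(st$expression$isoform_id)))
  co <- read_cohort_table(file.path(dir, "cohort.tsv"))
  expect_equal(co$samples$time, st$cohort$samples$time)
  sp <- read_spot_table(file.path(dir, "spots.tsv"))
  expect_equal(nrow(sp), nrow(st$spots$spots))
  expect_true(file.exists(file.path(dir, "truth.json")))

  # same seed, second directory: byte-identical junction files
  dir2 <- file.path(tempdir(), "study2")
  simulate_study(dir2, events_per_type = c(CA = 30, A3SS = 10, A5SS = 10,
                                           MXE = 10),
                 seed = 15, n_planted = 5)
  f1 <- file.path(dir, "sj_T1.tab"); f2 <- file.path(dir2, "sj_T1.tab")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
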