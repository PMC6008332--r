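test_that("junctions sharing a splice site form one group per side", {
  j <- data.frame(chrom = "chr1", intron_start = c(100L, 100L),
                  intron_end = c(200L, 300L), strand = "+",
                  stringsAsFactors = FALSE)
  g <- group_junctions_by_site(j)
  donor <- g[g$side == "donor", ]
  expect_equal(nrow(donor), 2L)
  expect_equal(length(unique(donor$group_id)), 1L)  # shared 5' site
  accep <- g[g$side == "acceptor", ]
  expect_equal(length(unique(accep$group_id)), 2L)  # distinct 3' sites

  lone <- group_junctions_by_site(j[1, ])
  expect_equal(nrow(lone), 2L)  # one donor + one acceptor singleton

  both <- rbind(j[1, ], transform(j[1, ], strand = "-"))
  g2 <- group_junctions_by_site(both)
  expect_equal(length(unique(g2$group_id[g2$side == "donor"])), 2L)
})

test_that("splicing ratios normalise within a group", {
  expect_equal(compute_sr(c(J1 = 30, J2 = 70)), c(J1 = 0.3, J2 = 0.7))
  expect_equal(unname(compute_sr(50)), 1)
  expect_true(all(is.na(compute_sr(c(0, 0)))))
  # pair conservation and normalisation over random groups
  set.seed(11)
  for (i in 1:50) {
    cnt <- rpois(sample(2:6, 1), 20)
    if (sum(cnt) == 0) next
    sr <- compute_sr(cnt)
    expect_equal(sum(sr), 1, tolerance = 1e-9)
    if (length(cnt) == 2) expect_equal(sr[1], 1 - sr[2], tolerance = 1e-12)
  }
})

test_that("a skippable annotated exon makes the pair a cassette", {
  fx <- cassette_fixture()
  ev <- build_events(fx$junctions, fx$annotation)
  left <- ev[ev$shared_genomic == "left", ]
  expect_equal(left$type, "CA")
  expect_equal(left$exon_incl_start, 201)
  expect_equal(left$exon_incl_end, 300)
  expect_equal(left$incl_end, 200)   # inclusion junction is the near one
  expect_equal(left$skip_end, 400)
  expect_equal(left$gene_id, "G1")
  expect_false(left$low_confidence)
})

test_that("acceptors inside one annotated exon give A3SS", {
  j <- data.frame(chrom = "chr1", intron_start = c(100L, 100L),
                  intron_end = c(200L, 230L), strand = "+",
                  stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = "G1", transcript_id = c("T1", "T2"),
                    chrom = "chr1", exon_start = c(201L, 231L),
                    exon_end = c(400L, 400L), strand = "+",
                    stringsAsFactors = FALSE)
  ev <- build_events(j, ann)
  expect_equal(ev$type, "A3SS")
  expect_false(ev$low_confidence)
  # without any annotation the default is A3SS flagged low-confidence
  ev0 <- build_events(j, NULL)
  expect_equal(ev0$type, "A3SS")
  expect_true(ev0$low_confidence)
})

test_that("event construction ignores junction order and singleton groups", {
  fx <- cassette_fixture()
  ev1 <- build_events(fx$junctions, fx$annotation)
  ev2 <- build_events(fx$junctions[2:1, ], fx$annotation)
  expect_equal(ev1, ev2)
  lone <- build_events(fx$junctions[1, , drop = FALSE], fx$annotation)
  expect_equal(nrow(lone), 0L)
})

test_that("planted gene models are classified back to their type, both strands", {
  m <- simulate_gene_models(c(CA = 4, A3SS = 4, A5SS = 4, MXE = 4))
  ev <- build_events(m$junction_roles, m$annotation)
  expect_false(any(ev$low_confidence))
  got <- split(ev$type, ev$gene_id)
  for (g in seq_len(nrow(m$genes))) {
    gid <- m$genes$gene_id[g]
    expect_true(all(got[[gid]] == m$genes$type[g]),
                info = paste(gid, m$genes$type[g], "->",
                             paste(got[[gid]], collapse = ",")))
  }
  # a cassette yields its two reciprocal pair-events; others one event
  n_ev <- lengths(got)[m$genes$gene_id]
  expect_equal(unname(n_ev), ifelse(m$genes$type == "CA", 2L, 1L))
})

test_that("MXE merging requires non-overlapping, never co-transcribed exons", {
  m <- simulate_gene_models(c(MXE = 2, CA = 2))
  ev <- build_events(m$junction_roles, m$annotation)
  mxe <- ev[ev$type == "MXE", ]
  expect_equal(nrow(mxe), 2L)
  expect_true(all(mxe$exon_incl_end < mxe$exon2_start))
  # the cassette's two reciprocal CA events share one middle exon: no merge
  expect_equal(sum(ev$type == "CA"), 4L)
})

test_that("direction follows the sign of the inclusion-junction SR change", {
  expect_equal(classify_direction("CA", 0.3 - 0.6), "EX")
  expect_equal(classify_direction("CA", 0.6 - 0.3), "IN")
  expect_true(is.na(classify_direction("CA", 0)))
  expect_equal(classify_direction(c("A3SS", "A5SS"), c(-0.1, 0.2)),
               c("down", "up"))
})
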