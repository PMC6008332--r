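test_that("candidate selection uses the median significance rule", {
  # one event, three treatment p's: median is the middle value
  p_treat <- matrix(c(0.01, 0.02, 0.5), nrow = 1)
  p_bg <- matrix(c(0.05, 1, 1, 0.10, 1, 1, 0.5, 0.9, 1), nrow = 3,
                 byrow = TRUE)
  sel <- select_candidates(p_treat, p_bg, q = 0.5)
  expect_equal(sel$median_p, 0.02)
  # events with significance 1 everywhere are never selected
  sel1 <- select_candidates(matrix(1, 2, 3), matrix(runif(6), 2, 3), q = 1)
  expect_false(any(sel1$selected))
  # threshold comes from the informative (sub-1) background medians
  bg <- matrix(1, 100, 3)
  bg[1:10, ] <- 0.05
  s <- select_candidates(matrix(0.04, 100, 2), bg, q = 0.5)
  expect_equal(s$threshold, 0.05)
  expect_true(all(s$selected))
})

test_that("detection separates planted from null events", {
  m <- simulate_gene_models(c(CA = 150))
  cs <- simulate_junction_counts(m, n_treatment = 2, n_control = 3,
                                 depth = 100, dispersion = 0.05,
                                 n_planted = 10, delta_psi = 0.3, seed = 5)
  fit <- srd_detect(cs$junctions, cs$treatment, cs$control,
                    annotation = m$annotation)
  planted <- fit$events$gene_id %in% cs$truth$gene_id[cs$truth$planted]
  expect_lt(mean(fit$events$median_p[planted]),
            mean(fit$events$median_p[!planted]))
  perf <- detection_performance(fit, cs$truth$gene_id[cs$truth$planted])
  expect_gte(perf$sensitivity, 0.5)
  # selected events carry a direction consistent with the planted shift
  sel <- fit$events[fit$events$selected & planted, ]
  tr <- cs$truth[match(sel$gene_id, cs$truth$gene_id), ]
  expect_gt(mean(sel$direction == tr$direction), 0.8)
})

test_that("the detect stage is deterministic given its inputs", {
  m <- simulate_gene_models(c(CA = 120))
  cs <- simulate_junction_counts(m, 2, 3, depth = 80, n_planted = 5,
                                 seed = 9)
  f1 <- srd_detect(cs$junctions, cs$treatment, cs$control, m$annotation)
  f2 <- srd_detect(cs$junctions, cs$treatment, cs$control, m$annotation)
  expect_equal(f1$events, f2$events)
  expect_equal(f1$threshold, f2$threshold)
})

test_that("detection demands enough controls and events", {
  m <- simulate_gene_models(c(CA = 30))
  cs <- simulate_junction_counts(m, 2, 3, seed = 1)
  expect_error(srd_detect(cs$junctions, cs$treatment, cs$control[1:2],
                          m$annotation), "3 control")
  expect_error(srd_detect(cs$junctions, cs$treatment, cs$control,
                          m$annotation, min_events = 100), "min_events")
})

test_that("ranking sums absolute isoform differences and is stable", {
  cand <- data.frame(event_id = c("e1", "e2", "e3"),
                     stringsAsFactors = FALSE)
  map <- data.frame(event_id = c("e1", "e1", "e2", "e2"),
                    isoform_id = c("i1", "i2", "i3", "i4"),
                    class = c("inclusion", "skipping",
                              "inclusion", "skipping"),
                    stringsAsFactors = FALSE)
  expr <- expand.grid(isoform_id = c("i1", "i2", "i3", "i4"),
                      sample_id = c("T1", "C1"), stringsAsFactors = FALSE)
  expr$expression <- c(10, 3, 1, 1, 5, 6, 1, 1)
  r <- rank_candidates(cand, expr, map, "T1", "C1")
  expect_equal(r$rank_score, c(8, 0, 0))  # |10-5| + |3-6|; unmapped 0
  expect_equal(r$event_id, c("e1", "e2", "e3"))  # ties broken by id
  r2 <- rank_candidates(cand[c(3, 1, 2), , drop = FALSE], expr, map,
                        "T1", "C1")
  expect_equal(r2$event_id, r$event_id)   # input order irrelevant
})

test_that("isoform mapping assigns inclusion and skipping transcripts", {
  m <- simulate_gene_models(c(CA = 2, A3SS = 2, A5SS = 2, MXE = 2))
  ev <- build_events(m$junction_roles, m$annotation)
  map <- map_event_isoforms(ev, m$annotation)
  truth <- m$isoforms
  hit <- merge(map, truth, by.x = "isoform_id", by.y = "transcript_id")
  expect_true(all(hit$class.x == hit$class.y))
  # every event maps both classes
  per_ev <- table(map$event_id, map$class)
  expect_true(all(per_ev > 0))
})

test_that("replicate comparisons intersect with direction concordance", {
  s1 <- data.frame(event_id = c("A", "B", "C"),
                   direction = c("EX", "IN", "EX"), stringsAsFactors = FALSE)
  s2 <- data.frame(event_id = c("B", "C", "D"),
                   direction = c("IN", "IN", "EX"), stringsAsFactors = FALSE)
  res <- intersect_comparisons(list(s1, s2))
  expect_equal(res$consensus$event_id, "B")     # C discordant (EX vs IN)
  expect_equal(res$discordant$event_id, "C")
  one <- intersect_comparisons(list(s1))
  expect_equal(one$consensus, s1)
})
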