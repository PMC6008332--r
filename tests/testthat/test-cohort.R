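test_that("frequency filter applies a strict cutoff", {
  occ <- cbind(a = c(rep(1, 3), rep(0, 37)),   # 7.5%
               b = c(rep(1, 2), rep(0, 38)),   # exactly 5.0%
               c = rep(0, 40))
  expect_equal(ase_frequency_filter(occ, 0.05), "a")
  expect_error(ase_frequency_filter(occ[0, , drop = FALSE]), "empty")
})

test_that("Fisher enumeration matches the closed-form balanced table", {
  expect_equal(fisher_exact_p(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-14)
  expect_warning(p <- fisher_exact_p(matrix(c(0, 0, 4, 6), 2)), "margin")
  expect_identical(p, 1)
})

test_that("Fisher enumeration agrees with stats::fisher.test", {
  set.seed(41)
  worst <- 0
  for (i in 1:300) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    worst <- max(worst, abs(fisher_exact_p(tab) -
                              stats::fisher.test(tab)$p.value))
  }
  expect_lt(worst, 1e-12)
})

test_that("association wraps occurrence and group into a 2x2 test", {
  occ <- c(rep(1, 5), rep(0, 5))
  grp <- c(rep(1, 5), rep(0, 5))
  fa <- fisher_association(occ, grp)
  expect_equal(fa$fisher_p, 2 / 252, tolerance = 1e-14)
  expect_equal(fa$frequency, 0.5)
  expect_equal(unname(fa$frequency_by_group), c(0, 1))
})

test_that("identical survival in both groups gives HR 1 and log-rank 0", {
  t0 <- c(2, 5, 7, 9, 12, 15)
  e0 <- c(1, 1, 0, 1, 1, 0)
  res <- survival_association(rep(c(0, 1), each = 6), c(t0, t0), c(e0, e0))
  expect_equal(res$hazard_ratio, 1, tolerance = 1e-6)
  expect_equal(res$logrank_stat, 0, tolerance = 1e-9)
})

test_that("hazard ratio and log-rank are invariant to time rescaling", {
  co <- simulate_cohort(n_samples = 120, n_ases = 3, n_assoc = 0, n_hr = 1,
                        hazard_ratio = 3, censor_rate = 0.02, seed = 13)
  id <- co$truth$survival[1]
  r1 <- survival_association(co$occurrence[, id], co$samples$time,
                             co$samples$event)
  r2 <- survival_association(co$occurrence[, id], 2 * co$samples$time,
                             co$samples$event)
  expect_equal(r1$hazard_ratio, r2$hazard_ratio, tolerance = 1e-8)
  expect_equal(r1$logrank_p, r2$logrank_p, tolerance = 1e-10)
  expect_equal(r1$direction, "unfavorable")
})

test_that("the Cox fit recovers a planted hazard ratio", {
  co <- simulate_cohort(n_samples = 1000, n_ases = 1, frequency = 0.5,
                        n_assoc = 0, n_hr = 1, hazard_ratio = 2,
                        censor_rate = 0, seed = 19)
  res <- survival_association(co$occurrence[, 1], co$samples$time,
                              co$samples$event)
  expect_gt(res$hazard_ratio, 1.7)
  expect_lt(res$hazard_ratio, 2.4)
  expect_true(res$ci_lower < res$hazard_ratio &
                res$hazard_ratio < res$ci_upper)
})

test_that("a group without events yields an unbounded hazard ratio", {
  occ <- rep(c(0, 1), each = 10)
  time <- c(rexp(10, 1), rexp(10, 5))
  ev <- c(rep(0, 10), rep(1, 10))
  res <- survival_association(occ, time, ev)
  expect_identical(res$hazard_ratio, Inf)
  expect_true(is.finite(res$logrank_p))
})

test_that("Venn regions partition the union", {
  sets <- list(A = c("x", "y"), B = c("y", "z"), C = c("y"))
  v <- intersect_sets(sets)
  expect_equal(v$core, "y")
  expect_equal(sum(v$counts), 3L)  # x, y, z each in exactly one region
  d <- intersect_sets(list(A = "a", B = "b"))
  expect_equal(length(d$core), 0L)
})

test_that("the cohort stage flags planted associations end to end", {
  co <- simulate_cohort(n_samples = 300, n_ases = 30, frequency = 0.2,
                        n_assoc = 4, odds_ratio = 6, n_hr = 4,
                        hazard_ratio = 3, censor_rate = 0.02, seed = 23)
  res <- cohort_associate(co)
  expect_s3_class(res, "srd_cohort")
  expect_gte(mean(co$truth$assoc %in% res$sets$group_associated), 0.75)
  expect_gte(mean(co$truth$survival %in% res$sets$survival_associated), 0.75)
  expect_true(all(c("fisher_p_bh", "hazard_ratio") %in% names(res$results)))
  expect_output(print(res), "Cohort association")
})
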