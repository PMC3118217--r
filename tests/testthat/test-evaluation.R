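test_that("concordance assigns every truth site to exactly one category", {
  truth <- tibble::tibble(region = "r", pos = c(10L, 20L, 30L),
                          class = c("het", "het", "homref"))
  calls <- tibble::tibble(region = "r", pos = c(10L, 30L),
                          status = c("passed", "passed"),
                          class = c("het", "het"))
  pu <- dplyr::bind_rows(
    make_column(pos = 10, counts = list(`A+` = 10, `G+` = 10)),
    make_column(pos = 30, counts = list(`A+` = 20, `G+` = 5))
  ) # position 20 has zero depth
  conc <- build_concordance(calls, truth, pu, min_depth = 6)
  expect_equal(sum(conc$n), nrow(truth))
  expect_equal(conc$n[conc$truth_class == "het" &
                        conc$called_class == "het"], 1)
  expect_equal(conc$n[conc$truth_class == "het" &
                        conc$called_class == "not_covered"], 1)
  expect_equal(conc$n[conc$truth_class == "homref" &
                        conc$called_class == "het"], 1)
  expect_error(
    build_concordance(calls, truth[c(1, 1), ], pu), "duplicate")
})

test_that("error-free simulation gives a diagonal concordance table", {
  cfg <- sim_config(region_spec("r1", 5000, 2, snv_density = 3),
                    per_site_error = 0, target_depth_per_copy = 25, seed = 31)
  sim <- simulate_dataset(cfg)
  pu <- build_pileups(sim$reads, sim$regions, sim$reference)
  calls <- classify_vaf(call_variants(pu), 2)
  # restrict to interior sites: within a read length of the region edge,
  # coverage tapers and sites legitimately fall in the not-covered class
  interior <- dplyr::filter(sim$truth, pos > 330, pos < 5000 - 330)
  conc <- build_concordance(calls, interior, pu)
  off_diag <- conc$n[conc$truth_class != conc$called_class]
  expect_equal(sum(off_diag), 0)
  expect_equal(sensitivity(conc, "het"), 100.0)
  expect_equal(specificity(conc, "het"), 100.0)
})

test_that("sensitivity and specificity follow the concordance-table arithmetic", {
  conc <- tibble::tibble(
    truth_class = c("het", "het", "het", "homvar", "homref"),
    called_class = c("het", "homvar", "not_covered", "het", "het"),
    n = c(237, 3, 4, 5, 10)
  )
  expect_equal(sensitivity(conc, "het"), round_half_up(100 * 237 / 244, 1))
  expect_equal(specificity(conc, "het"), round_half_up(100 * 237 / 252, 1))
  expect_error(sensitivity(conc, "4_of_6"), "no truth sites")
  expect_error(specificity(conc, "4_of_6"), "no calls")
})

test_that("density arithmetic and guards", {
  expect_equal(snv_density(0, 100), 0.0)
  expect_equal(snv_density(700, 100), 7.0)
  expect_error(snv_density(10, 0), "positive")
})

test_that("union of call sets deduplicates by position (or allele) and keeps known status", {
  s1 <- tibble::tibble(region = "r", pos = c(1L, 2L), alt = c("G", "T"),
                       known = c("known", "novel"))
  s2 <- tibble::tibble(region = "r", pos = c(2L, 3L, 4L, 5L),
                       alt = c("T", "A", "C", "G"),
                       known = c("known", "novel", "novel", "known"))
  u <- union_snvs(s1, s2)
  expect_equal(nrow(u), 5)
  # position 2 is known in one sample -> known in the union
  expect_equal(u$known[u$pos == 2], "known")
  # idempotence
  expect_equal(nrow(union_snvs(u, u)), 5)
  # disjoint sets add up
  s3 <- tibble::tibble(region = "q", pos = 1:3, alt = "G", known = "novel")
  expect_equal(nrow(union_snvs(s1, s3)), 5)
  # allele-aware union separates different alternates at one position
  a1 <- tibble::tibble(region = "r", pos = 1L, alt = "G", known = "novel")
  a2 <- tibble::tibble(region = "r", pos = 1L, alt = "T", known = "novel")
  expect_equal(nrow(union_snvs(a1, a2, match_allele = TRUE)), 2)
  expect_equal(nrow(union_snvs(a1, a2)), 1)
})

test_that("multicopy sensitivity extrapolation arithmetic", {
  res <- extrapolate_multicopy_sensitivity(100, 1.0, 1, 100)
  expect_equal(res$sensitivity_pct, 100)
  expect_equal(res$expected_multicopy, 100)
  expect_error(extrapolate_multicopy_sensitivity(10, 0, 2, 5), "sensitivity")
})

test_that("synthetic-data sensitivity matches the planted detection probability", {
  # error-free reads at good depth: every planted het should be recovered
  cfg <- sim_config(region_spec("r1", 8000, 2, snv_density = 5),
                    per_site_error = 0, target_depth_per_copy = 25, seed = 17)
  sim <- simulate_dataset(cfg)
  pu <- build_pileups(sim$reads, sim$regions, sim$reference)
  calls <- classify_vaf(call_variants(pu), 2)
  interior <- dplyr::filter(sim$truth, pos > 330, pos < 8000 - 330)
  conc <- build_concordance(calls, interior, pu)
  expect_equal(sensitivity(conc, "het"), 100.0)
})
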