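test_that("strand-evidence rule: both-orientation and single-orientation clauses", {
  # 3 forward + 3 reverse variant reads at Q20+, depth 12 -> call at 50% VAF
  col <- make_column(counts = list(`A+` = 3, `A-` = 3, `G+` = 3, `G-` = 3))
  call <- call_variants(col)
  expect_equal(nrow(call), 1)
  expect_equal(call$alt, "G")
  expect_equal(call$vaf, 50)

  # 4 variant reads all forward, depth 40 -> fails both clauses
  col <- make_column(counts = list(`A+` = 18, `A-` = 18, `G+` = 4))
  expect_equal(nrow(call_variants(col)), 0)

  # 5 variant reads all forward, depth 50 -> single-orientation clause, VAF 10
  col <- make_column(counts = list(`A+` = 22, `A-` = 23, `G+` = 5))
  call <- call_variants(col)
  expect_equal(nrow(call), 1)
  expect_equal(call$vaf, 10)

  # 5 in one orientation plus any in the other voids the one-sided clause
  col <- make_column(counts = list(`A+` = 20, `A-` = 23, `G+` = 5, `G-` = 2))
  expect_equal(nrow(call_variants(col)), 0)
})

test_that("deep low-VAF site: 14 of 104 reads gives 13.5% at one decimal", {
  col <- dplyr::bind_rows(
    make_column(counts = list(`A+` = 45, `A-` = 45, `G+` = 7, `G-` = 7))
  )
  call <- call_variants(col)
  expect_equal(call$depth, 104L)
  expect_equal(call$alt_count, 14L)
  expect_equal(round_half_up(call$vaf, 1), 13.5)
})

test_that("VAF floor suppresses sub-10% calls; low-quality support doesn't count", {
  # 3+3 variant reads but depth 70 -> VAF 8.6 < 10: suppressed
  col <- make_column(counts = list(`A+` = 32, `A-` = 32, `G+` = 3, `G-` = 3))
  expect_equal(nrow(call_variants(col)), 0)

  # variant support entirely below the quality floor -> no call, but the
  # low-quality reads still count toward depth
  hi <- make_column(counts = list(`A+` = 5, `A-` = 5))
  lo <- make_column(counts = list(`G+` = 3, `G-` = 3), qpass = FALSE)
  expect_equal(nrow(call_variants(dplyr::bind_rows(hi, lo))), 0)

  # q-passing support with extra low-quality support: all supporting reads
  # enter alt_count and VAF
  lo2 <- make_column(counts = list(`G+` = 2, `G-` = 2), qpass = FALSE)
  hi2 <- make_column(counts = list(`A+` = 2, `A-` = 2, `G+` = 3, `G-` = 3))
  call <- call_variants(dplyr::bind_rows(hi2, lo2))
  expect_equal(call$alt_count, 10L)
  expect_equal(call$depth, 14L)
})

test_that("multi-allelic columns emit the single best-supported alternate", {
  col <- make_column(counts = list(`A+` = 10, `A-` = 10,
                                   `G+` = 6, `G-` = 6,
                                   `T+` = 4, `T-` = 4))
  call <- call_variants(col)
  expect_equal(nrow(call), 1)
  expect_equal(call$alt, "G")

  # exact tie resolved by base order (C < T)
  col <- make_column(counts = list(`A+` = 5, `A-` = 5,
                                   `T+` = 4, `T-` = 4,
                                   `C+` = 4, `C-` = 4))
  expect_equal(call_variants(col)$alt, "C")
})

test_that("N bases never support a variant", {
  col <- make_column(counts = list(`A+` = 10, `A-` = 10, `N+` = 6, `N-` = 6))
  expect_equal(nrow(call_variants(col)), 0)
})

test_that("calling is deterministic and invariants hold on random columns", {
  set.seed(42)
  cols <- dplyr::bind_rows(lapply(1:300, function(i) {
    nA <- sample(0:30, 1); nG <- sample(0:12, 1)
    f <- rbinom(1, nG, 0.5)
    make_column(pos = i, counts = list(`A+` = nA, `A-` = max(1, nA),
                                       `G+` = f, `G-` = nG - f))
  }))
  calls1 <- call_variants(cols)
  calls2 <- call_variants(cols)
  expect_identical(calls1, calls2)
  if (nrow(calls1) > 0) {
    expect_true(all(calls1$alt_count >= 3))
    expect_true(all(calls1$vaf >= 10 & calls1$vaf <= 100))
    expect_true(all(calls1$alt_count == calls1$alt_fwd + calls1$alt_rev))
    expect_true(all(calls1$alt_count <= calls1$depth))
  }

  # monotonicity: adding a variant-supporting read never uncalls a site
  for (i in sample(unique(calls1$pos), min(20, nrow(calls1)))) {
    col <- cols[cols$pos == i, ]
    extra <- make_column(pos = i, counts = list(`G+` = 1))
    more <- call_variants(dplyr::bind_rows(col, extra))
    expect_gte(nrow(more), 1)
  }
})

test_that("error-free simulated het SNV yields exactly one call at the site", {
  cfg <- sim_config(region_spec("r1", 3000, 2, snv_density = 1),
                    per_site_error = 0, target_depth_per_copy = 25, seed = 21)
  sim <- simulate_dataset(cfg)
  calls <- call_variants(build_pileups(sim$reads, sim$regions, sim$reference))
  expect_equal(sort(calls$pos), sort(sim$truth$pos))
})
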