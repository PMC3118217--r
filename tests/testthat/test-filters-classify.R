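toy_calls <- function(pos, vaf = 50, depth = 50L, region = "r",
                      status = "raw") {
  n_alt <- as.integer(round(depth * vaf / 100))
  tibble::tibble(
    region = region, pos = as.integer(pos), ref = "A", alt = "G",
    depth = depth, alt_count = n_alt, alt_fwd = n_alt %/% 2L,
    alt_rev = n_alt - n_alt %/% 2L, vaf = vaf, p_error = NA_real_,
    status = status, known = NA_character_
  )
}

test_that("region mask hits inside positions only, honours half-open ends", {
  mask <- intervals("r", 100, 200) # 1-based 101..200
  calls <- toy_calls(c(50, 101, 200, 201))
  masked <- apply_region_mask(calls, mask)
  expect_equal(masked$status, c("raw", "masked", "masked", "raw"))
  # a call whose 0-based coordinate equals the mask end is outside
  expect_equal(masked$status[masked$pos == 201], "raw")
  # idempotent
  expect_identical(apply_region_mask(masked, mask), masked)
})

test_that("error filter splits calls at the 1e-3 threshold and is idempotent", {
  m <- error_model(0.023)
  calls <- dplyr::bind_rows(
    toy_calls(1, depth = 104L),
    toy_calls(2, depth = 50L)
  )
  calls$alt_count <- c(14L, 3L)
  calls$vaf <- 100 * calls$alt_count / calls$depth
  filtered <- apply_error_filter(calls, m)
  expect_equal(filtered$status[1], "passed")
  # P(X >= 3; n = 50, p = 0.023) ~ 0.11 > 1e-3 -> filtered
  expect_equal(filtered$status[2], "filtered")
  expect_gt(filtered$p_error[2], 1e-3)
  expect_identical(apply_error_filter(filtered, m), filtered)

  # all reads variant at depth 20: tail ~ p^20, passes
  all_var <- toy_calls(3, depth = 20L, vaf = 100)
  all_var$alt_count <- 20L
  expect_equal(apply_error_filter(all_var, m)$status, "passed")
})

test_that("masked calls are never resurrected by the error filter", {
  m <- error_model(0.023)
  calls <- toy_calls(1, depth = 104L)
  calls$alt_count <- 52L
  calls$status <- "masked"
  out <- apply_error_filter(calls, m)
  expect_equal(out$status, "masked")
  expect_true(is.na(out$p_error))
})

test_that("two-copy and six-copy VAF bands match the published scheme", {
  expect_equal(classify_vaf(tibble::tibble(vaf = 50), 2)$class, "het")
  expect_equal(classify_vaf(tibble::tibble(vaf = 97), 2)$class, "homvar")
  expect_equal(classify_vaf(tibble::tibble(vaf = 13), 2)$class, "homref")
  expect_equal(classify_vaf(tibble::tibble(vaf = 75), 2)$class, "het")
  expect_equal(classify_vaf(tibble::tibble(vaf = 50), 6)$class, "3_of_6")
  expect_equal(classify_vaf(tibble::tibble(vaf = 16.7), 6)$class, "1_of_6")
  expect_equal(classify_vaf(tibble::tibble(vaf = 93), 6)$class, "6_of_6")
  expect_error(classify_vaf(tibble::tibble(vaf = 5), 2), "10")
})

test_that("bands partition [10, 100] for every copy number 2..12", {
  for (cn in 2:12) {
    b <- vaf_bands(cn)
    expect_equal(b$lower[1], 10)
    expect_equal(b$upper[nrow(b)], 100)
    # contiguous and ordered
    expect_equal(b$lower[-1], b$upper[-nrow(b)])
    expect_true(all(b$lower < b$upper))
    # every probe VAF lands in exactly one band
    probes <- seq(10, 100, by = 0.5)
    hits <- vapply(probes, function(v) {
      sum((b$lower < v | (b$lower_closed & b$lower == v)) &
            (v < b$upper | (b$upper_closed & v == b$upper)))
    }, numeric(1))
    expect_true(all(hits == 1), label = sprintf("cn=%d", cn))
  }
})

test_that("known/novel annotation by position and by allele", {
  snp <- tibble::tibble(region = "r", pos = c(10L, 20L),
                        alt = c("G", "T"), id = c("rs1", "rs2"))
  calls <- toy_calls(c(10, 20, 30))
  ann <- annotate_known(calls, snp)
  expect_equal(ann$known, c("known", "known", "novel"))
  # allele-aware: position 20 listed with T, called G -> novel
  ann2 <- annotate_known(calls, snp, match_allele = TRUE)
  expect_equal(ann2$known, c("known", "novel", "novel"))
})

test_that("SNP tables load from TSV and VCF", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(region = "r", pos = 7L, alt = "C",
                                  id = "rs7"), tsv)
  expect_equal(read_snp_table(tsv)$pos, 7L)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "r\t7\trs7\tA\tC\t.\t.\t."), vcf)
  tab <- read_snp_table(vcf)
  expect_equal(tab$region, "r")
  expect_equal(tab$pos, 7L)
  expect_equal(tab$alt, "C")
})
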