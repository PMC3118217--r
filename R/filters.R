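#' Mask calls inside paralogous (low-copy-repeat) regions
#'
#' Near-identical segmental-duplication paralogs capture and map together
#' with the target, confounding variant assignment; calls inside the
#' supplied mask intervals are marked `masked` and excluded from all
#' downstream sets. Masking wins over every later status transition.
#'
#' @param calls Call tibble.
#' @param mask Interval tibble (0-based half-open; BED convention).
#' @return Calls with `status = "masked"` inside the mask; others untouched.
#' @export
apply_region_mask <- function(calls, mask) {
  if (nrow(calls) == 0) return(calls)
  inside <- in_intervals(mask, calls$region, calls$pos)
  calls$status[inside] <- "masked"
  calls
}

#' Filter calls by posterior error probability
#'
#' Stores `P = binomial_tail(depth, alt_count, p)` on every non-masked call
#' and marks calls with `P > threshold` as `filtered` (error-prone), the
#' rest `passed`. Masked calls keep their status (a masked call is never
#' resurrected). Re-application is idempotent.
#'
#' @param calls Call tibble.
#' @param model An `error_model`.
#' @return Calls with `p_error` filled and `status` set to
#'   `filtered`/`passed` (masked rows untouched).
#' @export
apply_error_filter <- function(calls, model) {
  stopifnot(inherits(model, "error_model"))
  if (nrow(calls) == 0) return(calls)
  live <- calls$status != "masked"
  calls$p_error[live] <- binomial_tail(calls$depth[live],
                                       calls$alt_count[live], model$p)
  calls$status[live] <- ifelse(calls$p_error[live] > model$threshold,
                               "filtered", "passed")
  calls
}

#' VAF genotype bands for a given diploid copy number
#'
#' For 2 copies the classes are the conventional three:
#' homref `[10, 25)`, het `[25, 75]`, homvar `(75, 100]` (an apparent
#' variant at under a quarter VAF in a two-copy locus is treated as
#' reference plus noise). For 6 copies, six `k_of_6` classes with bounds
#' `[10,25) [25,43) [43,59) [59,76) [76,93) [93,100]` (half-open closures
#' of the printed integer shorthand ranges). For any other copy number the
#' bands are generalized: class `k_of_cn` around each expected VAF
#' `100*k/cn`, with boundaries at midpoints between consecutive expected
#' values, the lowest bound floored at the 10% reporting floor. Bands
#' always partition `[10, 100]`.
#'
#' @param diploid_cn Diploid copy number (>= 2).
#' @return Tibble: `label`, `lower`, `upper`, `lower_closed`,
#'   `upper_closed` (percent scale).
#' @export
#' @examples
#' vaf_bands(2)
#' vaf_bands(6)
vaf_bands <- function(diploid_cn) {
  if (diploid_cn < 2) abort("`diploid_cn` must be >= 2")
  if (diploid_cn == 2) {
    return(tibble(
      label = c("homref", "het", "homvar"),
      lower = c(10, 25, 75), upper = c(25, 75, 100),
      lower_closed = c(TRUE, TRUE, FALSE),
      upper_closed = c(FALSE, TRUE, TRUE)
    ))
  }
  if (diploid_cn == 6) {
    lo <- c(10, 25, 43, 59, 76, 93)
    hi <- c(25, 43, 59, 76, 93, 100)
  } else {
    expected <- 100 * seq_len(diploid_cn) / diploid_cn
    mid <- (head(expected, -1) + tail(expected, -1)) / 2
    lo <- c(10, mid)
    hi <- c(mid, 100)
  }
  k <- seq_len(diploid_cn)
  tibble(
    label = sprintf("%d_of_%d", k, diploid_cn),
    lower = lo, upper = hi,
    lower_closed = rep(TRUE, diploid_cn),
    upper_closed = c(rep(FALSE, diploid_cn - 1), TRUE)
  )
}

classify_one <- function(vaf, bands) {
  hit <- (bands$lower < vaf | (bands$lower_closed & bands$lower == vaf)) &
    (vaf < bands$upper | (bands$upper_closed & vaf == bands$upper))
  bands$label[which(hit)[1]]
}

#' Classify calls into VAF genotype bands
#'
#' @param calls Call tibble (or any tibble with a `vaf` column in percent).
#' @param diploid_cn Diploid copy number of the calls' locus.
#' @return `calls` with a `class` column added.
#' @export
#' @examples
#' classify_vaf(tibble::tibble(vaf = c(50, 97, 13)), 2)$class
classify_vaf <- function(calls, diploid_cn) {
  if (any(calls$vaf < 10 | calls$vaf > 100)) {
    abort("`vaf` must lie in [10, 100] percent")
  }
  bands <- vaf_bands(diploid_cn)
  calls$class <- vapply(calls$vaf, classify_one, character(1), bands = bands)
  calls
}

#' Read a known-SNP table (VCF or 3-column TSV)
#'
#' The TSV dialect is `region`, `pos` (1-based), optional `alt`, optional
#' `id`, with a header. VCF input keeps CHROM/POS/ALT/ID.
#'
#' @param path Input path (`.vcf` selects VCF parsing).
#' @return Tibble `region`, `pos`, `alt` (may be `NA`), `id`.
#' @export
read_snp_table <- function(path) {
  if (tolower(tools::file_ext(path)) == "vcf") {
    lines <- readr::read_lines(path, progress = FALSE)
    lines <- lines[!startsWith(lines, "#")]
    f <- stringr::str_split_fixed(lines, "\t", 8)
    return(tibble(region = f[, 1], pos = as.integer(f[, 2]),
                  alt = dplyr::na_if(f[, 5], "."),
                  id = dplyr::na_if(f[, 3], ".")))
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("region", "pos") %in% names(x))) {
    abort("SNP table needs `region` and `pos` columns")
  }
  x$pos <- as.integer(x$pos)
  if (!"alt" %in% names(x)) x$alt <- NA_character_
  if (!"id" %in% names(x)) x$id <- NA_character_
  dplyr::select(x, "region", "pos", "alt", "id")
}

#' Annotate calls as known or putative novel against a SNP table
#'
#' Matching is by position by default (known-SNP resources are position
#' lists); `match_allele = TRUE` additionally requires the listed alternate
#' allele to equal the called one.
#'
#' @param calls Call tibble.
#' @param snp_table Tibble `region`, `pos`, optional `alt` (from
#'   [read_snp_table()] or built in code).
#' @param match_allele Require allele agreement as well (default `FALSE`).
#' @return `calls` with `known` set to `"known"` or `"novel"`.
#' @export
annotate_known <- function(calls, snp_table, match_allele = FALSE) {
  if (nrow(calls) == 0) return(calls)
  if (match_allele) {
    key <- paste(snp_table$region, snp_table$pos, snp_table$alt)
    hit <- paste(calls$region, calls$pos, calls$alt) %in% key
  } else {
    key <- paste(snp_table$region, snp_table$pos)
    hit <- paste(calls$region, calls$pos) %in% key
  }
  calls$known <- ifelse(hit, "known", "novel")
  calls
}
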