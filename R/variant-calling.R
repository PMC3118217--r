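#' Call candidate SNVs from pileup counts
#'
#' Implements the minimal-evidence rule used to nominate high-confidence
#' differences from deep pyrosequencing pileups: at each site the
#' most-supported non-reference base is called iff it is supported by at
#' least `min_each_strand` quality-passing reads in *both* orientations, or
#' by at least `min_single_strand` quality-passing reads when all its
#' evidence lies in a single orientation. Depth `n` counts every read
#' spanning the site regardless of base quality; the quality gate applies
#' only to variant support. The variant allele frequency (VAF) is computed
#' from all variant-supporting reads over depth, and calls below `min_vaf`
#' percent are suppressed (the reporting floor of the upstream mapper this
#' rule emulates).
#'
#' A single-site pileup is a valid input, so the function covers both
#' per-column calling and whole-target calling.
#'
#' @param pileups Pileup tibble from [build_pileups()].
#' @param min_each_strand Minimum quality-passing variant reads per strand
#'   for the two-orientation clause (default 3).
#' @param min_single_strand Minimum quality-passing variant reads when all
#'   evidence is in one orientation (default 5).
#' @param min_vaf VAF reporting floor in percent (default 10).
#' @return Position-sorted tibble of calls: `region`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, `alt_fwd`, `alt_rev`, `vaf` (percent, full
#'   precision), `p_error` (`NA` until [apply_error_filter()]), `status`
#'   (`"raw"`), `known` (`NA` until [annotate_known()]). Zero rows when no
#'   site passes; absence of a call is a normal outcome.
#' @export
#' @examples
#' pu <- tibble::tibble(
#'   region = "r", pos = 100L, ref = "A",
#'   base = c("A", "G", "G"), strand = c("+", "+", "-"),
#'   qpass = TRUE, n = c(6L, 3L, 3L)
#' )
#' call_variants(pu)
call_variants <- function(pileups, min_each_strand = 3L,
                          min_single_strand = 5L, min_vaf = 10) {
  empty <- tibble(
    region = character(0), pos = integer(0), ref = character(0),
    alt = character(0), depth = integer(0), alt_count = integer(0),
    alt_fwd = integer(0), alt_rev = integer(0), vaf = numeric(0),
    p_error = numeric(0), status = character(0), known = character(0)
  )
  if (nrow(pileups) == 0) return(empty)

  depth_tbl <- pileup_depth(pileups)

  alt_tbl <- pileups |>
    dplyr::filter(.data$base != .data$ref, .data$base != "N") |>
    dplyr::group_by(.data$region, .data$pos, .data$base) |>
    dplyr::summarise(
      alt_count = sum(.data$n),
      alt_fwd = sum(.data$n[.data$strand == "+"]),
      alt_rev = sum(.data$n[.data$strand == "-"]),
      q_fwd = sum(.data$n[.data$strand == "+" & .data$qpass]),
      q_rev = sum(.data$n[.data$strand == "-" & .data$qpass]),
      .groups = "drop"
    )
  if (nrow(alt_tbl) == 0) return(empty)

  # one alternate per site: highest quality-passing support, then highest
  # total support, then alphabetical base order
  best <- alt_tbl |>
    dplyr::arrange(.data$region, .data$pos,
                   dplyr::desc(.data$q_fwd + .data$q_rev),
                   dplyr::desc(.data$alt_count), .data$base) |>
    dplyr::distinct(.data$region, .data$pos, .keep_all = TRUE)

  calls <- best |>
    dplyr::inner_join(depth_tbl, by = c("region", "pos")) |>
    dplyr::mutate(
      called = (.data$q_fwd >= min_each_strand &
                  .data$q_rev >= min_each_strand) |
        ((.data$q_fwd + .data$q_rev) >= min_single_strand &
           (.data$q_fwd == 0L | .data$q_rev == 0L)),
      vaf = 100 * .data$alt_count / .data$depth
    ) |>
    dplyr::filter(.data$called, .data$vaf >= min_vaf) |>
    dplyr::transmute(
      region = .data$region, pos = .data$pos, ref = .data$ref,
      alt = .data$base, depth = as.integer(.data$depth),
      alt_count = as.integer(.data$alt_count),
      alt_fwd = as.integer(.data$alt_fwd),
      alt_rev = as.integer(.data$alt_rev),
      vaf = .data$vaf, p_error = NA_real_, status = "raw",
      known = NA_character_
    ) |>
    dplyr::arrange(.data$region, .data$pos)
  calls
}

#' Write calls in a VCF-style tab format (plus a flat TSV twin)
#'
#' Columns: CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO with INFO keys
#' `DP`, `AD`, `VAF` (one decimal, half-up), `P`, `STATUS`, `CLASS`,
#' `KNOWN` when available. The flat twin (same stem, `.tsv`) carries the
#' tibble columns verbatim.
#'
#' @param calls Call tibble.
#' @param path Output path for the VCF-style file.
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(calls, path) {
  info <- sprintf("DP=%d;AD=%d;VAF=%.1f;P=%s;STATUS=%s",
                  calls$depth, calls$alt_count,
                  round_half_up(calls$vaf, 1),
                  ifelse(is.na(calls$p_error), ".",
                         formatC(calls$p_error, format = "g", digits = 4)),
                  calls$status)
  if ("class" %in% names(calls)) {
    info <- paste0(info, ";CLASS=", calls$class)
  }
  if (any(!is.na(calls$known))) {
    info <- paste0(info, ";KNOWN=", ifelse(is.na(calls$known), ".",
                                           calls$known))
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=capvar",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
            calls$region, calls$pos, calls$ref, calls$alt,
            ifelse(calls$status %in% c("passed", "raw"), "PASS",
                   calls$status),
            info)
  )
  writeLines(lines, path)
  readr::write_tsv(calls, paste0(tools::file_path_sans_ext(path), ".tsv"),
                   progress = FALSE)
  invisible(path)
}
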