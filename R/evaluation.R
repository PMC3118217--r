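#' Genotype class implied by planted copy counts
#'
#' @param copies_variant,copies_total Integer vectors.
#' @return Character vector: `homref`, `het`, `homvar` for 2-copy loci,
#'   `k_of_c` otherwise.
#' @export
genotype_class <- function(copies_variant, copies_total) {
  dplyr::case_when(
    copies_variant == 0 ~ "homref",
    copies_variant == copies_total ~ "homvar",
    copies_total == 2 ~ "het",
    TRUE ~ sprintf("%d_of_%d", copies_variant, copies_total)
  )
}

#' Build a genotype concordance table against truth genotypes
#'
#' Each truth site is assigned to exactly one called category: sites with
#' depth below `min_depth` go to `not_covered`; truth sites with no call
#' and adequate depth go to `homref_nocall` (with the 10% VAF reporting
#' floor, absence of a call is itself the homozygous-reference signal);
#' otherwise the call's VAF class is used.
#'
#' @param calls Classified call tibble (must carry a `class` column, see
#'   [classify_vaf()]); masked/filtered calls are ignored.
#' @param truth Tibble `region`, `pos`, and either a `class` column or
#'   `copies_variant` + `copies_total`. Duplicate positions are an error.
#' @param pileups Pileup tibble for depth lookup (optional; without it all
#'   truth sites count as covered).
#' @param min_depth Below this depth a truth site is `not_covered`
#'   (default 6).
#' @return Concordance tibble: `truth_class`, `called_class`, `n`.
#' @export
build_concordance <- function(calls, truth, pileups = NULL, min_depth = 6) {
  if (anyDuplicated(truth[c("region", "pos")])) {
    abort("duplicate truth positions")
  }
  if (!"class" %in% names(truth)) {
    truth$class <- genotype_class(truth$copies_variant, truth$copies_total)
  }
  truth <- dplyr::rename(truth, truth_class = "class")

  live <- dplyr::filter(calls, !.data$status %in% c("masked", "filtered"))
  if (!"class" %in% names(live)) {
    abort("`calls` must be classified first (see classify_vaf())")
  }
  joined <- dplyr::left_join(
    truth,
    dplyr::select(live, "region", "pos", called = "class"),
    by = c("region", "pos")
  )
  if (!is.null(pileups)) {
    joined <- dplyr::left_join(joined, pileup_depth(pileups)[
      c("region", "pos", "depth")], by = c("region", "pos"))
    joined$depth <- dplyr::coalesce(joined$depth, 0L)
  } else {
    joined$depth <- Inf
  }
  joined$called_class <- dplyr::case_when(
    joined$depth < min_depth ~ "not_covered",
    is.na(joined$called) ~ "homref_nocall",
    TRUE ~ joined$called
  )
  dplyr::count(joined, .data$truth_class, .data$called_class, name = "n")
}

concordant_labels <- function(class) {
  # a truth-homref site is concordant both as an explicit homref-band call
  # and as absence of a call
  if (class == "homref") c("homref", "homref_nocall") else class
}

#' Sensitivity of a genotype class (concordance-table convention)
#'
#' Concordant calls of the class divided by the truth-class total (all
#' truth sites of that class, including uncovered ones), as a percentage
#' rounded half-up to one decimal.
#'
#' @param concordance Tibble `truth_class`, `called_class`, `n`.
#' @param class Genotype class, e.g. `"het"`.
#' @return Percent, one decimal.
#' @export
#' @examples
#' conc <- tibble::tibble(
#'   truth_class = "het",
#'   called_class = c("het", "homvar", "homref", "not_covered"),
#'   n = c(237, 3, 0, 4)
#' )
#' sensitivity(conc, "het") # 97.1
sensitivity <- function(concordance, class) {
  rows <- concordance[concordance$truth_class == class, , drop = FALSE]
  total <- sum(rows$n)
  if (total == 0) abort(sprintf("no truth sites of class '%s'", class))
  conc <- sum(rows$n[rows$called_class %in% concordant_labels(class)])
  round_half_up(100 * conc / total, 1)
}

#' Specificity of a genotype class (precision-style convention)
#'
#' Concordant calls of the class divided by all calls of that class at
#' truth-annotated sites. This is the arithmetic used in capture-vs-HapMap
#' concordance tables — a precision-like measure, not the textbook
#' true-negative-based specificity.
#'
#' @inheritParams sensitivity
#' @return Percent, one decimal.
#' @export
specificity <- function(concordance, class) {
  rows <- concordance[concordance$called_class == class, , drop = FALSE]
  total <- sum(rows$n)
  if (total == 0) abort(sprintf("no calls of class '%s' at annotated sites",
                                class))
  conc <- sum(rows$n[rows$truth_class == class])
  round_half_up(100 * conc / total, 1)
}

#' SNV density per kb of effective (unmasked) target
#'
#' @param snv_count Number of SNVs.
#' @param effective_length_kb Target length in kb after subtracting masked
#'   stretches.
#' @return Density, one decimal (half-up).
#' @export
#' @examples
#' snv_density(979 + 178, 234 - 69) # 7.0
snv_density <- function(snv_count, effective_length_kb) {
  if (effective_length_kb <= 0) {
    abort("`effective_length_kb` must be positive")
  }
  round_half_up(snv_count / effective_length_kb, 1)
}

#' Union of SNV call sets across samples
#'
#' @param ... Call tibbles (or a single list of them), each with `region`,
#'   `pos`, `alt`, and optionally `known`.
#' @param match_allele Key the union by allele as well as position
#'   (default `FALSE`).
#' @return Tibble of unique variants (`region`, `pos`, `alt`, `known`); a
#'   variant known in any sample is known in the union.
#' @export
union_snvs <- function(..., match_allele = FALSE) {
  sets <- list(...)
  if (length(sets) == 1 && !is.data.frame(sets[[1]])) sets <- sets[[1]]
  all <- dplyr::bind_rows(sets)
  if (!"known" %in% names(all)) all$known <- NA_character_
  if (!"alt" %in% names(all)) all$alt <- NA_character_
  keys <- if (match_allele) c("region", "pos", "alt") else c("region", "pos")
  all |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      alt = dplyr::first(.data$alt),
      known = if (any(.data$known == "known", na.rm = TRUE)) "known"
              else dplyr::first(.data$known),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(c("region", "pos", "alt", "known"))) |>
    dplyr::arrange(.data$region, .data$pos)
}

#' Extrapolate SNV detection sensitivity to a higher-copy locus
#'
#' From a 2-copy locus with `observed_single_copy` SNVs detected at
#' `single_copy_sensitivity`, the expected count at a locus with
#' `copy_multiple` times as many haploid copies is
#' `round(observed / sensitivity) * copy_multiple`; the observed multicopy
#' count over that expectation gives the multicopy sensitivity.
#'
#' @param observed_single_copy SNVs observed at the 2-copy locus.
#' @param single_copy_sensitivity Detection sensitivity there (fraction in
#'   (0, 1]).
#' @param copy_multiple Haploid copy multiple of the target locus.
#' @param observed_multicopy SNVs observed at the multicopy locus.
#' @return One-row tibble: `expected_diploid` (the rounded sensitivity-
#'   corrected 2-copy count), `expected_multicopy`, `sensitivity_pct`
#'   (integer percent, half-up).
#' @export
#' @examples
#' extrapolate_multicopy_sensitivity(673, 0.98, 3, 1157)
extrapolate_multicopy_sensitivity <- function(observed_single_copy,
                                              single_copy_sensitivity,
                                              copy_multiple,
                                              observed_multicopy) {
  if (single_copy_sensitivity <= 0 || single_copy_sensitivity > 1) {
    abort("`single_copy_sensitivity` must be in (0, 1]")
  }
  expected_diploid <- round_half_up(
    observed_single_copy / single_copy_sensitivity, 0)
  expected_multicopy <- expected_diploid * copy_multiple
  if (expected_multicopy == 0) abort("expected count is zero")
  tibble(
    expected_diploid = expected_diploid,
    expected_multicopy = expected_multicopy,
    sensitivity_pct = round_half_up(
      100 * observed_multicopy / expected_multicopy, 0)
  )
}
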