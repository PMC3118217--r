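gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
gcd_all <- function(x) Reduce(gcd2, x)

#' Find haplotyping candidate regions (dense SNV windows)
#'
#' A haplotyping candidate region (HTCR) is a run of SNVs dense enough that
#' single long reads span several of them: every 1-kb window anchored at an
#' SNV must hold at least `min_density` SNVs. Qualifying windows are merged
#' and trimmed to the first/last SNV they contain.
#'
#' @param calls Position-sorted call tibble (typically `status == "passed"`
#'   calls).
#' @param min_density Minimum SNVs per kb (default 9).
#' @param min_snvs Minimum SNVs per region (default 2).
#' @param window Window width in bases (default 1000).
#' @return Tibble: `region`, `start`, `end` (0-based half-open), `n_snvs`,
#'   `density` (SNVs/kb), `snv_pos` (list column of 1-based positions).
#' @export
find_htcrs <- function(calls, min_density = 9, min_snvs = 2L,
                       window = 1000L) {
  empty <- tibble(region = character(0), start = integer(0),
                  end = integer(0), n_snvs = integer(0),
                  density = numeric(0), snv_pos = list())
  if (nrow(calls) == 0) return(empty)
  min_count <- min_density * window / 1000

  out <- calls |>
    dplyr::distinct(.data$region, .data$pos) |>
    dplyr::arrange(.data$region, .data$pos) |>
    dplyr::group_split(.data$region)

  res <- purrr::map(out, function(g) {
    pos <- g$pos
    n <- length(pos)
    # SNVs inside [pos_i, pos_i + window)
    counts <- vapply(seq_len(n), function(i) {
      sum(pos >= pos[i] & pos < pos[i] + window)
    }, integer(1))
    anchors <- which(counts >= min_count)
    if (!length(anchors)) return(NULL)
    covered <- rep(FALSE, n)
    for (i in anchors) {
      covered[pos >= pos[i] & pos < pos[i] + window] <- TRUE
    }
    idx <- which(covered)
    # split covered SNVs into runs separated by > window bases
    grp <- cumsum(c(1L, diff(pos[idx]) > window))
    purrr::map_dfr(split(idx, grp), function(ii) {
      p <- pos[ii]
      span <- max(diff(range(p)), 1L)
      tibble(region = g$region[1], start = min(p) - 1L, end = max(p),
             n_snvs = length(p), density = length(p) / (span / 1000),
             snv_pos = list(p))
    })
  })
  res <- dplyr::bind_rows(purrr::compact(res))
  if (nrow(res) == 0) return(empty)
  dplyr::filter(res, .data$n_snvs >= min_snvs)
}

#' Split HTCR SNVs into read-spannable combinations
#'
#' Greedy consecutive runs: each combination takes successive SNVs while
#' its span stays within `max_span` bases (so typical reads can cover all
#' positions) and its size within `max_size`. Runs of fewer than 2 SNVs
#' are dropped.
#'
#' @param htcrs Result of [find_htcrs()].
#' @param max_size Maximum SNVs per combination (default 7).
#' @param max_span Maximum span in bases (default 250, comfortably inside
#'   a 330-base read).
#' @return Tibble: `region`, `combo_id`, `positions` (list column).
#' @export
select_combinations <- function(htcrs, max_size = 7L, max_span = 250L) {
  rows <- purrr::pmap(
    list(htcrs$region, htcrs$snv_pos, seq_len(nrow(htcrs))),
    function(region, pos, hid) {
      combos <- list()
      cur <- pos[1]
      for (p in pos[-1]) {
        if (length(cur) < max_size && p - cur[1] <= max_span) {
          cur <- c(cur, p)
        } else {
          combos <- c(combos, list(cur))
          cur <- p
        }
      }
      combos <- c(combos, list(cur))
      combos <- combos[lengths(combos) >= 2]
      if (!length(combos)) return(NULL)
      tibble(region = region,
             combo_id = sprintf("htcr%d_c%d", hid, seq_along(combos)),
             positions = combos)
    }
  )
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble(region = character(0), combo_id = character(0),
                  positions = list())
  }
  out
}

# per-read allele tuples over `positions`; reads must span all positions
# with called (non-N) bases of quality >= min_q at every position
read_haplotypes <- function(reads, region, positions, min_q = 20) {
  lo <- min(positions)
  hi <- max(positions)
  r <- reads[reads$region == region &
               reads$start <= lo &
               reads$start + nchar(reads$seq) - 1L >= hi, , drop = FALSE]
  if (nrow(r) == 0) return(character(0))
  haps <- rep("", nrow(r))
  ok <- rep(TRUE, nrow(r))
  for (p in positions) {
    off <- p - r$start + 1L
    b <- substr(r$seq, off, off)
    q <- as.integer(charToRaw(paste(substr(r$qual, off, off), collapse = ""))) - 33L
    ok <- ok & b %in% BASES & q >= min_q
    haps <- paste0(haps, b)
  }
  haps[ok]
}

#' Tally read-backed haplotypes over an SNV combination
#'
#' Counts reads per allele tuple over the combination's positions; only
#' reads spanning all positions with unambiguous, quality-passing bases are
#' counted. Tuples supported by fewer than `min_reads_per_hap` reads are
#' dropped, and the tally is returned only if the surviving total reaches
#' `min_total` (use 10 in a 2-copy context, 30 in a 6-copy one — five
#' reads per expected copy).
#'
#' @param reads Read tibble.
#' @param region Region name.
#' @param positions Ordered 1-based SNV positions (2..7 of them).
#' @param min_reads_per_hap Minimum reads per retained haplotype
#'   (default 5).
#' @param min_total Minimum surviving total (default 10).
#' @param min_q Minimum base quality at combination positions (default 20).
#' @return Tibble `haplotype`, `n` (descending by first appearance order of
#'   position), with attributes `positions`, `region`, `total`; or `NULL`
#'   if the combination is not callable (a normal outcome).
#' @export
tally_haplotypes <- function(reads, region, positions, min_reads_per_hap = 5L,
                             min_total = 10L, min_q = 20) {
  haps <- read_haplotypes(reads, region, positions, min_q)
  if (!length(haps)) return(NULL)
  tab <- sort(table(haps), decreasing = TRUE)
  tab <- tab[tab >= min_reads_per_hap]
  if (length(tab) == 0 || sum(tab) < min_total) return(NULL)
  out <- tibble(haplotype = names(tab), n = as.integer(tab))
  attr(out, "positions") <- positions
  attr(out, "region") <- region
  attr(out, "total") <- sum(out$n)
  out
}

# largest-remainder apportionment of `counts` into T integer copies
apportion <- function(counts, total) {
  quota <- counts * total / sum(counts)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Integer copy ratio underlying haplotype read counts
#'
#' Formalizes "round the read ratio to small integers": candidate totals
#' `T` are searched smallest first; for each `T` the counts are apportioned
#' to integer copies by largest remainder, and the first assignment whose
#' chi-square goodness of fit (expected `sum(counts) * c_i / T`) is not
#' rejected at level `alpha` is accepted. Assignments giving any haplotype
#' zero copies are invalid (an observed haplotype occupies at least one
#' copy).
#'
#' @param counts Positive read counts, one per haplotype (>= 2 of them).
#' @param alpha Rejection level for the goodness-of-fit acceptance
#'   (default 0.05).
#' @param max_total Largest total copy count searched (default 60).
#' @return List of class `integer_ratio`: `ratio` (integer vector),
#'   `total`, `statistic`, `p_value`, `counts`, `accepted` (`FALSE` when no
#'   total passed `alpha` and the best-fitting assignment is returned
#'   instead), `ambiguous` (`TRUE` when the accepted assignment is a scalar
#'   multiple of a smaller integer vector).
#' @export
#' @examples
#' integer_ratio(c(17, 34))$ratio # 1:2
integer_ratio <- function(counts, alpha = 0.05, max_total = 60L) {
  if (length(counts) < 2) abort("need at least two haplotype counts")
  if (any(counts <= 0)) abort("all haplotype counts must be positive")
  k <- length(counts)
  best <- NULL
  for (total in seq.int(k, max_total)) {
    ratio <- apportion(counts, total)
    if (any(ratio == 0)) next
    expected <- sum(counts) * ratio / total
    statistic <- sum((counts - expected)^2 / expected)
    p_value <- pchisq(statistic, df = k - 1, lower.tail = FALSE)
    cand <- list(ratio = ratio, total = total, statistic = statistic,
                 p_value = p_value, counts = counts)
    if (is.null(best) || p_value > best$p_value) best <- cand
    if (p_value >= alpha) {
      cand$accepted <- TRUE
      cand$ambiguous <- gcd_all(cand$ratio) > 1
      return(structure(cand, class = "integer_ratio"))
    }
  }
  best$accepted <- FALSE
  best$ambiguous <- gcd_all(best$ratio) > 1
  structure(best, class = "integer_ratio")
}

#' @export
print.integer_ratio <- function(x, ...) {
  cat(sprintf("<integer_ratio> %s -> %s (T = %d, chi-sq p = %.3g%s)\n",
              paste(x$counts, collapse = ":"),
              paste(x$ratio, collapse = ":"),
              x$total, x$p_value,
              if (!x$accepted) ", best fit only" else ""))
  invisible(x)
}

#' @rdname integer_ratio
#' @param x An `integer_ratio`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.integer_ratio <- function(x, ...) {
  tibble(ratio = paste(x$ratio, collapse = ":"), total = x$total,
         statistic = x$statistic, p_value = x$p_value,
         accepted = x$accepted, ambiguous = x$ambiguous)
}

#' Diploid copy number from an integer haplotype ratio
#'
#' With three or more distinct haplotypes the diploid copy number is the
#' ratio sum. With exactly two haplotypes the ratio is fundamentally
#' scale-ambiguous (1:1 fits 2, 4, 6... copies); the haploid multiplicity
#' `haploid_scale` must then come from external knowledge, and the estimate
#' is flagged ambiguous when it was left at its default.
#'
#' @param ratio Integer vector, or an `integer_ratio` object.
#' @param haploid_scale Multiplier relating the minimal ratio to actual
#'   copy counts for two-haplotype loci (default 1).
#' @param ploidy Unused placeholder for non-diploid organisms (default 2).
#' @param reads_used Total reads behind the ratio (optional, carried
#'   through).
#' @return One-row tibble: `n_haplotypes`, `ratio`, `haploid_scale`,
#'   `diploid_cn`, `reads_used`, `ambiguous`.
#' @export
#' @examples
#' cn_from_ratio(c(1, 2), haploid_scale = 2)$diploid_cn # 6
cn_from_ratio <- function(ratio, haploid_scale = 1L, ploidy = 2L,
                          reads_used = NA_integer_) {
  scale_defaulted <- missing(haploid_scale)
  if (haploid_scale < 1) abort("`haploid_scale` must be >= 1")
  if (inherits(ratio, "integer_ratio")) {
    if (is.na(reads_used)) reads_used <- sum(ratio$counts)
    ratio <- ratio$ratio
  }
  n_hap <- length(ratio)
  if (n_hap >= 3) {
    cn <- sum(ratio)
    ambiguous <- gcd_all(ratio) > 1
  } else {
    cn <- sum(ratio) * haploid_scale
    ambiguous <- scale_defaulted
  }
  tibble(n_haplotypes = n_hap, ratio = paste(ratio, collapse = ":"),
         haploid_scale = as.integer(haploid_scale),
         diploid_cn = as.integer(cn),
         reads_used = as.integer(reads_used), ambiguous = ambiguous)
}

#' Estimate copy number over all spannable SNV combinations
#'
#' Full read-backed haplotyping stage: find dense windows in the passed
#' calls, split them into read-spannable combinations, tally haplotypes
#' per combination, fit the integer ratio and convert to a diploid copy
#' number. Two-haplotype combinations are flagged ambiguous (their scale
#' defaults to 1).
#'
#' @param reads Read tibble.
#' @param calls Call tibble (passed calls are used).
#' @param min_density,min_snvs Passed to [find_htcrs()].
#' @param max_size,max_span Passed to [select_combinations()].
#' @param min_reads_per_hap,min_total,min_q Passed to [tally_haplotypes()].
#' @param alpha Passed to [integer_ratio()].
#' @return Tibble of estimates: `region`, `combo_id`, `n_snvs`,
#'   `n_haplotypes`, `total_reads`, `counts` (list column), `ratio`,
#'   `p_value`, `accepted`, `diploid_cn`, `ambiguous`.
#' @export
estimate_copy_numbers <- function(reads, calls, min_density = 9,
                                  min_snvs = 2L, max_size = 7L,
                                  max_span = 250L, min_reads_per_hap = 5L,
                                  min_total = 10L, min_q = 20,
                                  alpha = 0.05) {
  passed <- dplyr::filter(calls, .data$status %in% c("passed", "raw"))
  htcrs <- find_htcrs(passed, min_density = min_density,
                      min_snvs = min_snvs)
  combos <- select_combinations(htcrs, max_size = max_size,
                                max_span = max_span)
  rows <- purrr::pmap(
    list(combos$region, combos$combo_id, combos$positions),
    function(region, combo_id, positions) {
      tal <- tally_haplotypes(reads, region, positions,
                              min_reads_per_hap = min_reads_per_hap,
                              min_total = min_total, min_q = min_q)
      if (is.null(tal) || nrow(tal) < 2) return(NULL)
      ir <- integer_ratio(tal$n, alpha = alpha)
      est <- cn_from_ratio(ir)
      tibble(region = region, combo_id = combo_id,
             n_snvs = length(positions),
             n_haplotypes = nrow(tal),
             total_reads = sum(tal$n), counts = list(tal$n),
             ratio = est$ratio, p_value = ir$p_value,
             accepted = ir$accepted, diploid_cn = est$diploid_cn,
             ambiguous = est$ambiguous)
    }
  )
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble(region = character(0), combo_id = character(0),
                  n_snvs = integer(0), n_haplotypes = integer(0),
                  total_reads = integer(0), counts = list(),
                  ratio = character(0), p_value = numeric(0),
                  accepted = logical(0), diploid_cn = integer(0),
                  ambiguous = logical(0))
  }
  out
}

#' Pooled read ratio of two haplotype count sums
#'
#' Summing counts over many two-haplotype loci before taking the ratio
#' damps sampling noise ("artificially improved depth"); at a true 2-copy
#' locus set the pooled ratio should sit near 1.
#'
#' @param a,b Pooled read counts in tally order.
#' @return `a / b`, rounded half-up to two decimals.
#' @export
#' @examples
#' pooled_read_ratio(172, 173) # 0.99
pooled_read_ratio <- function(a, b) {
  round_half_up(a / b, 2)
}

#' Summarise copy-number estimates
#'
#' Arithmetic summary of the diploid copy numbers plus the pooled
#' two-haplotype read ratio over the two-haplotype loci.
#'
#' @param estimates Tibble from [estimate_copy_numbers()] (or any tibble
#'   with `diploid_cn`, `n_haplotypes`, `counts`).
#' @param include_ambiguous Keep scale-ambiguous estimates in the summary
#'   (default `TRUE`).
#' @return One-row tibble: `n`, `mean`, `min`, `max`, `sd`,
#'   `pooled_ratio` (`NA` when there are no two-haplotype loci).
#' @export
aggregate_cn <- function(estimates, include_ambiguous = TRUE) {
  if (nrow(estimates) == 0) abort("no copy-number estimates to aggregate")
  keep <- estimates
  if (!include_ambiguous) {
    keep <- dplyr::filter(keep, !.data$ambiguous)
  }
  if (nrow(keep) == 0) abort("no estimates left after ambiguity filter")
  two <- estimates[estimates$n_haplotypes == 2, , drop = FALSE]
  pooled <- if (nrow(two) > 0) {
    firsts <- sum(vapply(two$counts, `[`, numeric(1), 1))
    seconds <- sum(vapply(two$counts, `[`, numeric(1), 2))
    pooled_read_ratio(firsts, seconds)
  } else {
    NA_real_
  }
  tibble(
    n = nrow(keep),
    mean = mean(keep$diploid_cn),
    min = min(keep$diploid_cn),
    max = max(keep$diploid_cn),
    sd = if (nrow(keep) > 1) sd(keep$diploid_cn) else 0,
    pooled_ratio = pooled
  )
}
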