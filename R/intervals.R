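#' Interval sets (target, haplotyping-window and mask regions)
#'
#' Intervals are plain tibbles with columns `region`, `start`, `end` in
#' 0-based half-open convention (the BED convention), so a 1-based position
#' `p` lies inside `[start, end)` iff `start < p <= end`. All emitted variant
#' tables use 1-based positions; only interval tables are 0-based.
#'
#' @param region Character vector of region (sequence) names.
#' @param start,end Integer vectors, 0-based half-open.
#' @return A tibble with columns `region`, `start`, `end`.
#' @export
#' @examples
#' intervals("chr8", 0, 1000)
intervals <- function(region, start, end) {
  x <- tibble(region = as.character(region),
              start = as.integer(start), end = as.integer(end))
  if (any(x$start >= x$end)) {
    abort("interval starts must be strictly less than ends (0-based half-open)")
  }
  x
}

#' Read a BED file as an interval tibble
#'
#' @param path Path to a BED3+ file.
#' @return Interval tibble (`region`, `start`, `end`, and `name` if present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    region = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # back to 0-based half-open
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  out
}

#' Write an interval tibble as BED
#'
#' @param x Interval tibble (`region`, `start`, `end`, optional `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$region,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  if ("name" %in% names(x)) gr$name <- x$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Test 1-based positions for membership in an interval set
#'
#' @param ivs Interval tibble.
#' @param region Character vector of region names (recycled with `pos`).
#' @param pos Integer vector of 1-based positions.
#' @return Logical vector: `TRUE` where the position falls inside any
#'   interval of its region. A position equal to an interval's half-open
#'   `end` coordinate (0-based) is outside it.
#' @export
in_intervals <- function(ivs, region, pos) {
  if (nrow(ivs) == 0) return(rep(FALSE, length(pos)))
  pos0 <- pos - 1L
  by_region <- split(ivs, ivs$region)
  purrr::map2_lgl(region, pos0, function(r, p) {
    iv <- by_region[[r]]
    if (is.null(iv)) return(FALSE)
    any(iv$start <= p & p < iv$end)
  })
}

interval_span <- function(ivs) sum(ivs$end - ivs$start)
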