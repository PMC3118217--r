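#' Read and write reference FASTA
#'
#' Thin wrappers over Biostrings keeping the package's native representation
#' (a named character vector of sequences).
#'
#' @param path FASTA path.
#' @return `read_fasta()`: named character vector. `write_fasta()`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @param sequences Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path
  )
  invisible(path)
}

#' Read aligned reads from SAM/BAM or the 6-column TSV dialect
#'
#' The TSV dialect is `read_id, region, start, strand, seq, qual` with a
#' header, `start` 1-based, sequences stored in forward-reference
#' orientation and `qual` a Phred+33 string. For SAM/BAM, only primary
#' mapped records are used (mirroring a "fully and uniquely mapping"
#' upstream filter); the number of skipped records is reported.
#'
#' @param path Input path; format chosen by extension (`.sam`/`.bam` vs
#'   anything else as TSV).
#' @return Tibble of reads (`read_id`, `region`, `start`, `strand`, `seq`,
#'   `qual`).
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    read_alignments_sam(path)
  } else {
    read_alignments_tsv(path)
  }
}

read_alignments_tsv <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      read_id = readr::col_character(),
      region = readr::col_character(),
      start = readr::col_integer(),
      strand = readr::col_character(),
      seq = readr::col_character(),
      qual = readr::col_character()
    ),
    progress = FALSE
  )
  bad <- which(nchar(x$seq) != nchar(x$qual) | is.na(x$start) |
                 !(x$strand %in% c("+", "-")))
  if (length(bad)) {
    abort(sprintf("malformed read record at line %d of %s",
                  bad[1] + 1L, path))
  }
  x
}

read_alignments_sam <- function(path) {
  if (tolower(tools::file_ext(path)) == "sam") {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  res <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(
      flag = flags,
      what = c("qname", "rname", "pos", "strand", "seq", "qual")
    )
  )[[1]]
  total <- Rsamtools::countBam(path)$records
  kept <- length(res$qname)
  if (total > kept) {
    inform(sprintf("skipped %d unmapped/secondary record(s)", total - kept))
  }
  tibble(
    read_id = res$qname,
    region = as.character(res$rname),
    start = res$pos,
    strand = as.character(res$strand),
    seq = as.character(res$seq),
    qual = as.character(res$qual)
  )
}

#' Write aligned reads as TSV or SAM
#'
#' @param reads Read tibble (as returned by [simulate_reads()] or
#'   [read_alignments()]).
#' @param path Output path; `.sam` selects SAM, otherwise the TSV dialect.
#' @param reference Named character vector of reference sequences (required
#'   for the SAM header).
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path, reference = NULL) {
  if (tolower(tools::file_ext(path)) == "sam") {
    if (is.null(reference)) abort("`reference` is required to write SAM")
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                     nchar(reference)))
    rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                   reads$read_id, ifelse(reads$strand == "-", 16L, 0L),
                   reads$region, reads$start, nchar(reads$seq),
                   reads$seq, reads$qual)
    writeLines(c(hdr, rec), path)
  } else {
    readr::write_tsv(
      dplyr::select(reads, "read_id", "region", "start", "strand",
                    "seq", "qual"),
      path, progress = FALSE
    )
  }
  invisible(path)
}

#' Build per-site pileup counts from aligned reads
#'
#' Expands reads to per-base observations inside the supplied intervals and
#' aggregates them to counts per (region, position, observed base, strand,
#' quality-pass flag). Bases below `qual_floor` stay in the pileup (they
#' count toward depth `n`, keeping depth consistent with the error model's
#' `n`) but are flagged `qpass = FALSE`, so the calling rule can restrict
#' variant *support* to high-quality bases.
#'
#' @param reads Read tibble.
#' @param ivs Interval tibble restricting the pileup (e.g. target regions).
#' @param reference Named character vector of region reference sequences.
#' @param qual_floor Phred quality flag threshold (default 20).
#' @return Tibble: `region`, `pos` (1-based), `ref`, `base`, `strand`,
#'   `qpass`, `n`.
#' @export
build_pileups <- function(reads, ivs, reference, qual_floor = 20) {
  if (nrow(reads) == 0) {
    return(tibble(region = character(0), pos = integer(0),
                  ref = character(0), base = character(0),
                  strand = character(0), qpass = logical(0), n = integer(0)))
  }
  unknown <- setdiff(unique(reads$region), names(reference))
  if (length(unknown)) {
    abort(paste0("reads reference unknown region(s): ",
                 paste(unknown, collapse = ", ")))
  }
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad)) {
    abort(sprintf("read %s: quality string length differs from sequence",
                  reads$read_id[bad[1]]))
  }

  rl <- nchar(reads$seq)
  pos <- rep(reads$start, rl) + sequence(rl) - 1L
  obs <- tibble(
    region = rep(reads$region, rl),
    pos = pos,
    base = unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE),
    strand = rep(reads$strand, rl),
    qual = unlist(string_to_qual(reads$qual), use.names = FALSE)
  )

  # keep only observations inside the interval set
  keep <- rep(FALSE, nrow(obs))
  for (r in unique(obs$region)) {
    iv <- ivs[ivs$region == r, , drop = FALSE]
    if (nrow(iv) == 0) next
    flag <- rep(FALSE, max(iv$end))
    for (i in seq_len(nrow(iv))) {
      flag[(iv$start[i] + 1L):iv$end[i]] <- TRUE
    }
    sel <- obs$region == r
    p <- obs$pos[sel]
    keep[sel] <- p >= 1L & p <= length(flag) & flag[p]
  }
  obs <- obs[keep, , drop = FALSE]

  refchars <- lapply(reference, function(s) {
    strsplit(s, "", fixed = TRUE)[[1]]
  })
  obs$ref <- NA_character_
  for (r in unique(obs$region)) {
    sel <- obs$region == r
    obs$ref[sel] <- refchars[[r]][obs$pos[sel]]
  }

  obs$qpass <- obs$qual >= qual_floor
  dplyr::count(obs, .data$region, .data$pos, .data$ref, .data$base,
               .data$strand, .data$qpass, name = "n") |>
    dplyr::arrange(.data$region, .data$pos)
}

#' Per-site depth from a pileup
#'
#' @param pileups Pileup tibble from [build_pileups()].
#' @return Tibble `region`, `pos`, `ref`, `depth`.
#' @export
pileup_depth <- function(pileups) {
  dplyr::summarise(
    dplyr::group_by(pileups, .data$region, .data$pos, .data$ref),
    depth = sum(.data$n), .groups = "drop"
  )
}

#' Coverage summary over an interval set
#'
#' Mean depth is computed over *all* interval bases (uncovered bases count
#' as depth 0), and the covered fraction is the share of interval bases
#' with depth at least `k`.
#'
#' @param pileups Pileup tibble.
#' @param ivs Interval tibble.
#' @param k Minimum depth for the covered-fraction column (default 2).
#' @return Tibble: `region`, `bases`, `mean_depth`, `frac_ge_k`, `k`.
#' @export
coverage_summary <- function(pileups, ivs, k = 2) {
  depths <- pileup_depth(pileups)
  span <- dplyr::summarise(dplyr::group_by(ivs, .data$region),
                           bases = sum(.data$end - .data$start),
                           .groups = "drop")
  per_region <- dplyr::summarise(
    dplyr::group_by(depths, .data$region),
    depth_sum = sum(.data$depth),
    covered_k = sum(.data$depth >= k),
    .groups = "drop"
  )
  dplyr::left_join(span, per_region, by = "region") |>
    dplyr::mutate(
      depth_sum = dplyr::coalesce(.data$depth_sum, 0L),
      covered_k = dplyr::coalesce(.data$covered_k, 0L),
      mean_depth = .data$depth_sum / .data$bases,
      frac_ge_k = .data$covered_k / .data$bases,
      k = k
    ) |>
    dplyr::select("region", "bases", "mean_depth", "frac_ge_k", "k")
}
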