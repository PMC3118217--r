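# small in-code fixture builders shared across test files

# one pileup column from per-base/strand counts;
# counts: named list like list(`A+` = 6, `G-` = 3); qpass applies to all
make_column <- function(pos = 100L, ref = "A", counts = list(),
                        region = "r", qpass = TRUE) {
  rows <- lapply(names(counts), function(k) {
    tibble::tibble(
      region = region, pos = as.integer(pos), ref = ref,
      base = substr(k, 1, 1), strand = substr(k, 2, 2),
      qpass = qpass, n = as.integer(counts[[k]])
    )
  })
  dplyr::bind_rows(rows)
}

# a read tibble with uniform quality
make_read <- function(read_id, region, start, strand, seq, q = 30L) {
  tibble::tibble(
    read_id = read_id, region = region, start = as.integer(start),
    strand = strand, seq = seq,
    qual = vapply(nchar(seq), function(l) {
      paste(rep(rawToChar(as.raw(q + 33L)), l), collapse = "")
    }, character(1))
  )
}

# reads that all span `positions` of a toy region and carry given haplotype
# strings there, `n` reads per haplotype
make_hap_reads <- function(positions, haplotypes, n_per_hap,
                           region = "h", region_len = 400L) {
  stopifnot(length(haplotypes) == length(n_per_hap))
  ref <- paste(rep("A", region_len), collapse = "")
  out <- list()
  id <- 0L
  for (i in seq_along(haplotypes)) {
    for (j in seq_len(n_per_hap[i])) {
      id <- id + 1L
      chars <- strsplit(ref, "")[[1]]
      chars[positions] <- strsplit(haplotypes[i], "")[[1]]
      out[[id]] <- make_read(sprintf("rd%04d", id), region, 1L,
                             if (id %% 2 == 0) "+" else "-",
                             paste(chars, collapse = ""))
    }
  }
  dplyr::bind_rows(out)
}

# independent upper-tail oracle: direct pmf summation, smallest terms first
brute_tail <- function(n, d, p) {
  if (d == 0) return(1)
  sum(dbinom(n:d, n, p))
}
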