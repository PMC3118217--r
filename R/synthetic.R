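#' Describe one simulated target region
#'
#' A region emulates a targeted-capture locus: a contiguous reference
#' sequence present at a fixed number of copies per diploid genome, with
#' SNVs planted at a background density and, optionally, dense haplotyping
#' windows (high SNV density, the regime where single long reads span
#' several variant positions).
#'
#' @param name Region label (used as the FASTA record and alignment name).
#' @param length Region length in bases.
#' @param diploid_copy_number Copies per diploid genome (2 for an ordinary
#'   locus; 6 emulates an expanded defensin-cluster genotype).
#' @param snv_density Background planted-SNV density, variants per kb.
#' @param htcr_fraction Fraction of the region designated as high-density
#'   haplotyping windows.
#' @return One-row tibble describing the region.
#' @export
#' @examples
#' region_spec("ctrl", 10000, diploid_copy_number = 2, snv_density = 2)
region_spec <- function(name, length, diploid_copy_number = 2L,
                        snv_density = 2, htcr_fraction = 0) {
  if (length <= 0) abort("region `length` must be positive")
  if (diploid_copy_number < 1) abort("`diploid_copy_number` must be >= 1")
  if (snv_density < 0) abort("`snv_density` must be >= 0")
  if (htcr_fraction < 0 || htcr_fraction > 1) {
    abort("`htcr_fraction` must be in [0, 1]")
  }
  tibble(name = as.character(name), length = as.integer(length),
         diploid_copy_number = as.integer(diploid_copy_number),
         snv_density = as.numeric(snv_density),
         htcr_fraction = as.numeric(htcr_fraction))
}

#' Simulation configuration
#'
#' Defaults reflect the sequencing technology being emulated: pyrosequencing
#' reads of mean length 330 bases and a global per-site mismatch rate of
#' 2.3% in the alignments (sequencing plus mapping error combined). Capture
#' depth scales with copy number; `saturation` < 1 damps that scaling to
#' emulate array saturation at high target copy numbers.
#'
#' @param regions A tibble of region specifications, one or more rows from
#'   [region_spec()] (bind with `dplyr::bind_rows()`).
#' @param mean_read_length,read_length_sd Read length distribution (normal,
#'   truncated below at `min_read_length`).
#' @param per_site_error Per-base substitution error probability.
#' @param target_depth_per_copy Mean per-site read depth contributed by each
#'   copy of a region.
#' @param min_read_length Hard lower truncation for read lengths.
#' @param htcr_density Planted SNV density inside haplotyping windows,
#'   variants per kb.
#' @param known_fraction Fraction of planted SNVs flagged as known (present
#'   in the simulated SNP table).
#' @param saturation Multiplier on the depth-vs-copy-number scaling.
#' @param seed Integer seed; identical configurations give byte-identical
#'   output.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(region_spec("r1", 5000), seed = 7)
sim_config <- function(regions,
                       mean_read_length = 330,
                       read_length_sd = 40,
                       per_site_error = 0.023,
                       target_depth_per_copy = 25,
                       min_read_length = 50L,
                       htcr_density = 16,
                       known_fraction = 0.9,
                       saturation = 1,
                       seed = 1L) {
  stopifnot_scalar_prob(per_site_error, "per_site_error")
  if (target_depth_per_copy <= 0) abort("`target_depth_per_copy` must be > 0")
  if (!nrow(regions)) abort("`regions` must contain at least one region")
  structure(
    list(regions = regions,
         mean_read_length = mean_read_length,
         read_length_sd = read_length_sd,
         per_site_error = per_site_error,
         target_depth_per_copy = target_depth_per_copy,
         min_read_length = as.integer(min_read_length),
         htcr_density = htcr_density,
         known_fraction = known_fraction,
         saturation = saturation,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", nrow(x$regions), " region(s), ",
      "error ", x$per_site_error, ", depth/copy ",
      x$target_depth_per_copy, ", seed ", x$seed, "\n", sep = "")
  print(x$regions)
  invisible(x)
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_sequence <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Generate reference sequences for the configured regions
#'
#' @param config A [sim_config()].
#' @return A list with `sequences` (named character vector, one sequence per
#'   region) and `regions` (interval tibble covering each region).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(derive_seed(config$seed, 1L), {
    seqs <- setNames(
      vapply(config$regions$length, random_sequence, character(1)),
      config$regions$name
    )
    list(
      sequences = seqs,
      regions = intervals(config$regions$name, 0L, config$regions$length)
    )
  })
}

# place non-overlapping 1-kb haplotyping windows covering ~fraction of length
place_htcr_windows <- function(length, fraction, window = 1000L) {
  n_win <- floor(fraction * length / window)
  if (n_win < 1) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  # spread windows evenly, away from the extreme edges
  gap <- floor(length / n_win)
  starts <- as.integer((seq_len(n_win) - 1L) * gap + floor((gap - window) / 2))
  starts <- pmax(starts, 0L)
  tibble(start = starts, end = pmin(starts + window, as.integer(length)))
}

plant_region_variants <- function(name, seq, len, cn, density, htcr_fraction,
                                  htcr_density, known_fraction) {
  wins <- place_htcr_windows(len, htcr_fraction)
  htcr_kb <- sum(wins$end - wins$start) / 1000
  bg_kb <- len / 1000 - htcr_kb

  in_window <- rep(FALSE, len)
  for (i in seq_len(nrow(wins))) {
    in_window[(wins$start[i] + 1L):wins$end[i]] <- TRUE
  }
  bg_pos <- which(!in_window)
  win_pos <- which(in_window)

  n_bg <- rpois(1, density * bg_kb)
  n_win <- rpois(1, htcr_density * htcr_kb)
  pos <- sort(c(
    if (n_bg > 0) sample(bg_pos, min(n_bg, length(bg_pos))),
    if (n_win > 0) sample(win_pos, min(n_win, length(win_pos)))
  ))
  n <- length(pos)
  if (n == 0) {
    return(list(
      truth = tibble(region = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     copies_variant = integer(0), copies_total = integer(0),
                     known = logical(0)),
      copy_alt = matrix(FALSE, nrow = 0, ncol = cn),
      htcrs = wins
    ))
  }
  ref <- strsplit(seq, "")[[1]][pos]
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1),
                USE.NAMES = FALSE)
  copies_variant <- sample.int(cn, n, replace = TRUE)
  # which copies carry the alternate allele at each SNV
  copy_alt <- matrix(FALSE, nrow = n, ncol = cn)
  for (i in seq_len(n)) {
    copy_alt[i, sample.int(cn, copies_variant[i])] <- TRUE
  }
  list(
    truth = tibble(region = name, pos = as.integer(pos), ref = ref, alt = alt,
                   copies_variant = copies_variant,
                   copies_total = as.integer(cn),
                   known = runif(n) < known_fraction),
    copy_alt = copy_alt,
    htcrs = wins
  )
}

#' Plant SNVs and build per-copy haplotype sequences
#'
#' Background SNVs are planted as a Poisson process at the region's density;
#' haplotyping windows receive the elevated `htcr_density`. Each SNV is
#' assigned to a uniform number of copies (1..copy number) on a random
#' subset of copies, which induces the multi-copy haplotype structure that
#' the read-backed phasing stage later recovers.
#'
#' @param reference Result of [simulate_reference()].
#' @param config The same [sim_config()].
#' @return A list with `truth` (tibble: `region`, `pos` (1-based), `ref`,
#'   `alt`, `copies_variant`, `copies_total`, `known`), `haplotypes` (per
#'   region, a character vector of per-copy sequences), and `htcrs`
#'   (interval tibble of haplotyping windows).
#' @export
plant_variants <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(derive_seed(config$seed, 2L), {
    rs <- config$regions
    res <- purrr::pmap(
      list(rs$name, rs$length, rs$diploid_copy_number, rs$snv_density,
           rs$htcr_fraction),
      function(name, len, cn, dens, hfrac) {
        plant_region_variants(name, reference$sequences[[name]], len, cn,
                              dens, hfrac, config$htcr_density,
                              config$known_fraction)
      }
    )
    names(res) <- rs$name
    haplotypes <- purrr::imap(res, function(r, name) {
      cn <- rs$diploid_copy_number[rs$name == name]
      base_chars <- strsplit(reference$sequences[[name]], "")[[1]]
      vapply(seq_len(cn), function(k) {
        chars <- base_chars
        idx <- which(r$copy_alt[, k])
        if (length(idx)) chars[r$truth$pos[idx]] <- r$truth$alt[idx]
        paste(chars, collapse = "")
      }, character(1))
    })
    htcrs <- purrr::imap(res, function(r, name) {
      if (nrow(r$htcrs) == 0) return(NULL)
      intervals(name, r$htcrs$start, r$htcrs$end)
    })
    htcrs <- dplyr::bind_rows(purrr::compact(htcrs))
    if (nrow(htcrs) == 0) {
      htcrs <- tibble(region = character(0), start = integer(0),
                      end = integer(0))
    }
    list(
      truth = dplyr::bind_rows(purrr::map(res, "truth")),
      haplotypes = haplotypes,
      htcrs = htcrs
    )
  })
}

simulate_copy_reads <- function(region, copy_idx, hapseq, config, n_reads,
                                id_prefix) {
  len <- nchar(hapseq)
  starts <- sample.int(len, n_reads, replace = TRUE)
  rl <- as.integer(round(rnorm(n_reads, config$mean_read_length,
                               config$read_length_sd)))
  rl <- pmax(rl, config$min_read_length)
  rl <- pmin(rl, len - starts + 1L) # truncate at the region end
  seqs <- substring(hapseq, starts, starts + rl - 1L)

  # i.i.d. substitution errors, uniform over the three non-template bases
  n_err <- rbinom(n_reads, rl, config$per_site_error)
  err_idx <- which(n_err > 0)
  for (i in err_idx) {
    chars <- strsplit(seqs[i], "")[[1]]
    at <- sample.int(rl[i], n_err[i])
    chars[at] <- vapply(chars[at], function(b) sample(setdiff(BASES, b), 1),
                        character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(chars, collapse = "")
  }

  quals <- vapply(rl, function(l) {
    q <- as.integer(pmin(40, pmax(2, round(rnorm(l, 30, 6)))))
    qual_to_string(list(q))
  }, character(1))

  tibble(
    read_id = sprintf("%s_%06d", id_prefix, seq_len(n_reads)),
    region = region,
    start = starts,
    strand = ifelse(runif(n_reads) < 0.5, "+", "-"),
    seq = seqs,
    qual = quals,
    copy = copy_idx
  )
}

#' Simulate aligned pyrosequencing-style reads from haplotype sequences
#'
#' Reads are drawn uniformly along each copy, so per-site coverage is
#' approximately `target_depth_per_copy * diploid_copy_number` (times
#' `saturation`). Sequences are emitted already aligned to the forward
#' reference strand; `strand` records the sequenced orientation. Alignment
#' coordinates are emitted directly (no mapper is involved), which is what
#' makes the generator usable as ground truth.
#'
#' @param planted Result of [plant_variants()].
#' @param config The same [sim_config()].
#' @return Tibble of reads: `read_id`, `region`, `start` (1-based),
#'   `strand`, `seq`, `qual` (Phred+33 string), `copy` (source copy index).
#' @export
simulate_reads <- function(planted, config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(derive_seed(config$seed, 3L), {
    rs <- config$regions
    out <- purrr::pmap(
      list(rs$name, rs$length, rs$diploid_copy_number),
      function(name, len, cn) {
        haps <- planted$haplotypes[[name]]
        n_per_copy <- ceiling(len * config$target_depth_per_copy *
                                config$saturation / config$mean_read_length)
        purrr::map2(seq_len(cn), haps, function(k, h) {
          simulate_copy_reads(name, k, h, config, n_per_copy,
                              sprintf("%s_c%d", name, k))
        })
      }
    )
    dplyr::bind_rows(out)
  })
}

#' Run the full generator: reference, planted variants, reads
#'
#' @param config A [sim_config()].
#' @return List with `config`, `reference` (named sequences), `regions`,
#'   `truth`, `haplotypes`, `htcrs`, `reads`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(region_spec("r1", 2000), seed = 1))
#' sim$truth
simulate_dataset <- function(config) {
  ref <- simulate_reference(config)
  planted <- plant_variants(ref, config)
  reads <- simulate_reads(planted, config)
  list(config = config, reference = ref$sequences, regions = ref$regions,
       truth = planted$truth, haplotypes = planted$haplotypes,
       htcrs = planted$htcrs, reads = reads)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Writes `reference.fasta`, `regions.bed`, `htcrs.bed` (if any),
#' `truth.tsv` and `reads.tsv` (the documented 6-column aligned-read
#' dialect) under `dir`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$reference, file.path(dir, "reference.fasta"))
  write_bed(sim$regions, file.path(dir, "regions.bed"))
  if (nrow(sim$htcrs) > 0) write_bed(sim$htcrs, file.path(dir, "htcrs.bed"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  write_alignments(sim$reads, file.path(dir, "reads.tsv"))
  invisible(dir)
}
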