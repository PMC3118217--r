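#' Read a pipeline configuration from YAML
#'
#' @param path YAML path.
#' @return Config list (see [run_pipeline()]).
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

default_config <- function() {
  list(
    simulate = list(
      regions = list(
        list(name = "ctrl", length = 20000, diploid_copy_number = 2,
             snv_density = 2, htcr_fraction = 0),
        list(name = "defb", length = 20000, diploid_copy_number = 6,
             snv_density = 4, htcr_fraction = 0.3)
      ),
      per_site_error = 0.023,
      target_depth_per_copy = 15,
      seed = 1
    ),
    error = list(threshold = 1e-3),
    calling = list(min_each_strand = 3, min_single_strand = 5,
                   min_vaf = 10, qual_floor = 20),
    haplotype = list(min_density = 9, min_snvs = 2, max_size = 7,
                     max_span = 250, min_reads_per_hap = 5, alpha = 0.05),
    evaluate = list(min_depth = 6)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        is.null(names(override[[k]])) == is.null(names(base[[k]])) &&
        !is.null(names(override[[k]]))) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> pileup -> calibrate -> call -> mask ->
#' filter -> classify -> annotate -> haplotype/CN -> evaluate, writes each
#' stage's table under `out_dir` and a machine-readable run manifest
#' (parameters, seed, package version, output checksums). Re-running with
#' the same configuration reproduces identical outputs.
#'
#' @param config Config list (see [read_pipeline_config()]); omitted parts
#'   fall back to defaults. Provide either `config$simulate` (generator
#'   settings) or `config$input` with paths `reference`, `reads`, and
#'   optionally `mask`, `snp_table`, `truth`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory artifacts: `calls`,
#'   `coverage`, `error_model`, `cn_estimates`, `cn_summary`,
#'   `concordance`, `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("capvar_run_")) {
  cfg <- merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  mask <- tibble(region = character(0), start = integer(0),
                 end = integer(0))
  snp_table <- NULL

  if (!is.null(cfg$input)) {
    reference <- read_fasta(cfg$input$reference)
    reads <- read_alignments(cfg$input$reads)
    regions <- if (!is.null(cfg$input$regions)) {
      read_bed(cfg$input$regions)
    } else {
      intervals(names(reference), 0L, nchar(reference))
    }
    region_cn <- setNames(
      rep(2L, length(reference)), names(reference))
    if (!is.null(cfg$input$truth)) {
      truth <- readr::read_tsv(cfg$input$truth, show_col_types = FALSE,
                               progress = FALSE)
      cn_tbl <- dplyr::distinct(truth, .data$region, .data$copies_total)
      region_cn[cn_tbl$region] <- cn_tbl$copies_total
    }
    if (!is.null(cfg$input$mask)) mask <- read_bed(cfg$input$mask)
    if (!is.null(cfg$input$snp_table)) {
      snp_table <- read_snp_table(cfg$input$snp_table)
    }
  } else {
    s <- cfg$simulate
    rspecs <- dplyr::bind_rows(lapply(s$regions, function(r) {
      do.call(region_spec, r)
    }))
    sim_args <- s[setdiff(names(s), "regions")]
    scfg <- do.call(sim_config, c(list(regions = rspecs), sim_args))
    sim <- simulate_dataset(scfg)
    write_simulation(sim, file.path(out_dir, "sim"))
    reference <- sim$reference
    reads <- sim$reads
    regions <- sim$regions
    truth <- sim$truth
    region_cn <- setNames(rspecs$diploid_copy_number, rspecs$name)
    # the simulated known-SNP resource: planted variants flagged known
    snp_table <- dplyr::transmute(
      dplyr::filter(truth, .data$known),
      region = .data$region, pos = .data$pos, alt = .data$alt,
      id = NA_character_)
  }

  pileups <- build_pileups(reads, regions, reference,
                           qual_floor = cfg$calling$qual_floor)
  coverage <- coverage_summary(pileups, regions, k = 2)

  model <- if (!is.null(cfg$error$p)) {
    error_model(cfg$error$p, threshold = cfg$error$threshold)
  } else if (!is.null(truth)) {
    # calibrate on homozygous-variant truth sites of 2-copy regions
    ctrl <- dplyr::filter(
      truth, .data$copies_variant == .data$copies_total,
      .data$copies_total == 2)
    estimate_error_rate(pileups,
                        dplyr::transmute(ctrl, region = .data$region,
                                         pos = .data$pos,
                                         allele = .data$alt),
                        threshold = cfg$error$threshold)
  } else {
    abort("no error rate: supply config$error$p or a truth table")
  }

  calls <- call_variants(pileups,
                         min_each_strand = cfg$calling$min_each_strand,
                         min_single_strand = cfg$calling$min_single_strand,
                         min_vaf = cfg$calling$min_vaf)
  n_raw <- nrow(calls)
  calls <- apply_region_mask(calls, mask)
  n_masked <- sum(calls$status == "masked")
  calls <- apply_error_filter(calls, model)
  n_passed <- sum(calls$status == "passed")
  inform(sprintf("calls: %d raw, %d masked, %d filtered, %d passed",
                 n_raw, n_masked, n_raw - n_masked - n_passed, n_passed))

  if (nrow(calls) > 0) {
    calls <- dplyr::bind_rows(lapply(split(calls, calls$region),
                                     function(g) {
      classify_vaf(g, region_cn[[g$region[1]]])
    })) |> dplyr::arrange(.data$region, .data$pos)
  } else {
    calls$class <- character(0)
  }
  if (!is.null(snp_table)) {
    calls <- annotate_known(calls, snp_table)
  }

  h <- cfg$haplotype
  passed <- dplyr::filter(calls, .data$status == "passed")
  cn_estimates <- dplyr::bind_rows(lapply(
    split(passed, passed$region), function(g) {
      cn <- region_cn[[g$region[1]]]
      estimate_copy_numbers(
        reads, g, min_density = h$min_density, min_snvs = h$min_snvs,
        max_size = h$max_size, max_span = h$max_span,
        min_reads_per_hap = h$min_reads_per_hap,
        min_total = 5L * cn, min_q = cfg$calling$qual_floor,
        alpha = h$alpha)
    }))
  cn_summary <- if (nrow(cn_estimates) > 0) {
    aggregate_cn(cn_estimates)
  } else {
    NULL
  }

  concordance <- NULL
  if (!is.null(truth)) {
    concordance <- build_concordance(calls, truth, pileups,
                                     min_depth = cfg$evaluate$min_depth)
  }

  write_variant_calls(calls, file.path(out_dir, "calls.vcf"))
  readr::write_tsv(coverage, file.path(out_dir, "coverage.tsv"),
                   progress = FALSE)
  if (nrow(cn_estimates) > 0) {
    readr::write_tsv(
      dplyr::mutate(cn_estimates,
                    counts = vapply(.data$counts, paste, character(1),
                                    collapse = ":")),
      file.path(out_dir, "cn_estimates.tsv"), progress = FALSE)
  }
  if (!is.null(cn_summary)) {
    jsonlite::write_json(as.list(cn_summary),
                         file.path(out_dir, "cn_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(concordance)) {
    readr::write_tsv(concordance, file.path(out_dir, "concordance.tsv"),
                     progress = FALSE)
  }

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "capvar",
    version = as.character(utils::packageVersion("capvar")),
    config = cfg,
    error_model = list(p = model$p, threshold = model$threshold,
                       source_sites = model$source_sites),
    call_funnel = list(raw = n_raw, masked = n_masked,
                       filtered = n_raw - n_masked - n_passed,
                       passed = n_passed),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               sub(paste0(out_dir, "/"), "", outputs,
                                   fixed = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(calls = calls, coverage = coverage, error_model = model,
                 cn_estimates = cn_estimates, cn_summary = cn_summary,
                 concordance = concordance, manifest = manifest,
                 out_dir = out_dir))
}
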