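#' Estimate the pooled per-site error frequency from control sites
#'
#' Control sites are positions known (from an external genotype resource)
#' to be homozygous for a variant allele: every read that does not show the
#' expected allele there is an error of sequencing or read mapping. The
#' pooled rate over all control sites is the single global `p` of the
#' binomial error model; in a well-behaved pyrosequencing capture
#' experiment it comes out near 2.3%.
#'
#' @param pileups Pileup tibble covering the control sites.
#' @param control_sites Tibble with columns `region`, `pos`, `allele` (the
#'   homozygous expected allele at each site).
#' @param threshold Posterior error probability cutoff stored on the model
#'   (default `1e-3`).
#' @param floor Substitute rate if no mismatches are observed, so the
#'   binomial test stays defined (default `1e-4`).
#' @return An object of class `error_model`: the pooled rate `p`, the
#'   number of control sites used, and the filter threshold.
#' @export
estimate_error_rate <- function(pileups, control_sites, threshold = 1e-3,
                                floor = 1e-4) {
  obs <- dplyr::inner_join(
    pileups,
    dplyr::select(control_sites, "region", "pos", "allele"),
    by = c("region", "pos")
  )
  total <- sum(obs$n)
  if (total == 0) abort("control sites have zero total depth")
  mismatches <- sum(obs$n[obs$base != obs$allele])
  p <- mismatches / total
  if (p == 0) {
    warn(sprintf(
      "no mismatches at control sites; substituting floor rate %g", floor))
    p <- floor
  }
  structure(
    list(p = p, source_sites = nrow(control_sites), threshold = threshold,
         total_reads = total, mismatch_reads = mismatches),
    class = "error_model"
  )
}

#' Construct an error model directly from a known rate
#'
#' @param p Per-site error probability.
#' @param threshold Posterior error probability cutoff (default `1e-3`).
#' @param source_sites Number of control sites behind `p` (0 if assumed).
#' @return An `error_model` object.
#' @export
error_model <- function(p, threshold = 1e-3, source_sites = 0L) {
  if (p <= 0 || p >= 1) abort("`p` must be in (0, 1)")
  if (threshold <= 0) abort("`threshold` must be > 0")
  structure(list(p = p, source_sites = as.integer(source_sites),
                 threshold = threshold),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> p = %.4g (from %d control sites), threshold = %g\n",
              x$p, x$source_sites, x$threshold))
  invisible(x)
}

#' @rdname estimate_error_rate
#' @param x An `error_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.error_model <- function(x, ...) {
  tibble(p = x$p, source_sites = x$source_sites, threshold = x$threshold)
}

#' @rdname estimate_error_rate
#' @exportS3Method generics::glance
glance.error_model <- function(x, ...) {
  tibble(p = x$p, source_sites = x$source_sites, threshold = x$threshold,
         total_reads = x$total_reads %||% NA_integer_,
         mismatch_reads = x$mismatch_reads %||% NA_integer_)
}

#' Upper binomial tail: posterior probability of d error-only deviations
#'
#' `P = sum_{k=d..n} C(n,k) p^k (1-p)^(n-k)`, the probability of observing
#' at least `d` identical deviations at a site of depth `n` purely through
#' the error process with per-site rate `p`. The inclusive upper tail is
#' computed through the survival function, which is numerically stable for
#' depths well beyond 10^4.
#'
#' @param n Depth (vectorized).
#' @param d Deviant (variant-supporting) read count (vectorized).
#' @param p Per-site error probability.
#' @return Probability vector; `d = 0` gives 1.
#' @export
#' @examples
#' binomial_tail(104, 14, 0.023) # deep site with 13.5% VAF: passes 1e-3
binomial_tail <- function(n, d, p) {
  stopifnot_scalar_prob(p)
  if (p == 0) abort("`p` must be > 0")
  if (any(d > n)) abort("`d` cannot exceed `n`")
  if (any(d < 0 | n < 0)) abort("`n` and `d` must be non-negative")
  pbinom(d - 1, n, p, lower.tail = FALSE)
}

#' Simulate the expected VAF distribution for a genotype under the model
#'
#' Each replicate draws a depth from the supplied empirical depth
#' distribution and a variant-read count Binomial(n, q), where the allele
#' fraction `q = copies_variant / copies_total` is perturbed by the error
#' process: a true variant base is misread away with probability `p`, and
#' each non-variant base is misread *toward* the variant with probability
#' `p/3` (errors uniform over the three alternatives).
#'
#' @param model An `error_model`.
#' @param depths Integer vector: empirical depth distribution to resample.
#' @param copies_variant,copies_total Genotype, e.g. 1 and 6 for a variant
#'   on one of six copies.
#' @param replicates Number of simulated sites (default 2000).
#' @param seed Integer seed.
#' @return Tibble `depth`, `alt`, `vaf` (percent), one row per replicate,
#'   with the genotype attached as attributes.
#' @export
simulate_vaf_distribution <- function(model, depths, copies_variant,
                                      copies_total, replicates = 2000,
                                      seed = 1L) {
  stopifnot(inherits(model, "error_model"))
  if (length(depths) == 0) abort("`depths` must be non-empty")
  if (replicates < 1) abort("`replicates` must be >= 1")
  q <- copies_variant / copies_total
  q_err <- q * (1 - model$p) + (1 - q) * model$p / 3
  depths <- as.integer(depths)
  with_local_seed(seed, {
    # guard the scalar case: sample(100) would mean sample(1:100)
    n <- depths[sample.int(length(depths), replicates, replace = TRUE)]
    d <- rbinom(replicates, n, q_err)
    out <- tibble(depth = n, alt = d, vaf = 100 * d / n)
    attr(out, "copies_variant") <- copies_variant
    attr(out, "copies_total") <- copies_total
    attr(out, "p") <- model$p
    out
  })
}

#' Histogram of a simulated (or observed) VAF distribution
#'
#' @param vafs Tibble with a `vaf` column (e.g. from
#'   [simulate_vaf_distribution()] or a call set).
#' @param binwidth Histogram bin width in VAF percent (default 2.5).
#' @return A ggplot object.
#' @export
plot_vaf_distribution <- function(vafs, binwidth = 2.5) {
  ggplot2::ggplot(vafs, ggplot2::aes(x = .data$vaf)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(x = "variant allele frequency (%)", y = "sites") +
    ggplot2::theme_minimal()
}
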