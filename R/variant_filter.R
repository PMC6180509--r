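#' Filter configuration for the variant cascade
#'
#' Holds the thresholds of the multi-rule filtering cascade: the per-sample
#' rare-allele rule (minimum alternative-allele reads and frequency), the
#' extreme-coverage masks (quantile of samples and high-coverage factor) and
#' an optional homology mask of intervals to exclude.
#'
#' Boundary semantics are strict on the "less than" side: an alternative
#' allele with exactly `min_alt_reads` reads or exactly `min_alt_freq`
#' frequency is retained.
#'
#' @param min_alt_reads minimum reads supporting an alternative allele in a
#'   sample (default 4; alleles with fewer are zeroed).
#' @param min_alt_freq minimum within-sample frequency of an alternative
#'   allele relative to the total site depth (default 0.10).
#' @param quantile_frac fraction of samples that must agree for a site to be
#'   masked as extreme coverage (default 0.75).
#' @param high_factor multiple of the per-sample median depth at or above
#'   which coverage counts as exceptionally high (default 5).
#' @param homology_mask optional data frame of 0-based half-open intervals
#'   (`replicon`, `start`, `end`) to exclude, e.g. cross-genome homology.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_alt_reads = 4L, min_alt_freq = 0.10,
                          quantile_frac = 0.75, high_factor = 5,
                          homology_mask = NULL) {
  stopifnot(min_alt_reads >= 0, min_alt_freq >= 0, min_alt_freq <= 1,
            quantile_frac > 0, quantile_frac <= 1, high_factor > 1)
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 min_alt_freq = min_alt_freq,
                 quantile_frac = quantile_frac,
                 high_factor = high_factor,
                 homology_mask = homology_mask),
            class = "filter_config")
}

#' Remove rare alternative alleles
#'
#' Within each (site, sample), every alternative allele supported by fewer
#' than `min_alt_reads` reads or with a frequency below `min_alt_freq`
#' (relative to the total site depth in that sample) has its depth zeroed.
#' Reference depths are never touched. Sites where no sample retains any
#' alternative allele are dropped. A sample with zero total depth at a site
#' contributes frequency 0, so its alternative alleles are zeroed without
#' error.
#'
#' @param m an [acm()] object.
#' @param cfg a [filter_config()].
#' @return The filtered `acm`.
#' @export
filter_rare_alleles <- function(m, cfg = filter_config()) {
  if (n_sites(m) == 0) return(m)
  tot <- total_depth(m)
  A <- dim(m$depths)[3]
  d <- m$depths
  for (a in seq_len(A)[-1]) {
    da <- d[, , a, drop = FALSE]
    dim(da) <- dim(tot)
    freq <- ifelse(tot > 0, da / tot, 0)
    kill <- da < cfg$min_alt_reads | freq < cfg$min_alt_freq
    da[kill] <- 0L
    d[, , a] <- da
  }
  m$depths <- d
  keep <- rowSums(d[, , -1, drop = FALSE], dims = 1) > 0
  acm_subset(m, sites = keep)
}

## deterministic integer median: lower-middle element of the sorted vector
lower_median <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x, method = "radix")[floor((n + 1) / 2)]
}

#' Mask sites with exceptionally low or high coverage
#'
#' For each included sample, the median total depth over all variant sites is
#' computed (lower-middle element, deterministic for even counts). A site is
#' removed as LOW coverage when its depth is strictly below the sample median
#' for at least `quantile_frac` of the included samples, and as HIGH coverage
#' when its depth is at least `high_factor` times the sample median for at
#' least `quantile_frac` of the included samples. Samples where the symbiont
#' is absent should be excluded from the denominators via `include_samples`.
#'
#' @param m an [acm()] object with at least 2 sites (medians defined).
#' @param cfg a [filter_config()].
#' @param include_samples optional character vector of sample IDs to use in
#'   the median/fraction computations (default: all samples).
#' @return A list with elements `matrix` (the filtered `acm`) and `report`
#'   (data frame of removed sites with columns `replicon`, `pos`, `reason`).
#' @export
mask_extreme_coverage <- function(m, cfg = filter_config(),
                                  include_samples = NULL) {
  if (n_sites(m) < 2) stop("need at least 2 sites to define median coverage")
  incl <- if (is.null(include_samples)) seq_len(n_samples(m)) else {
    idx <- match(include_samples, m$samples)
    if (anyNA(idx)) stop("unknown sample(s) in include_samples")
    idx
  }
  if (length(incl) == 0) stop("no samples included in coverage masking")
  tot <- total_depth(m)[, incl, drop = FALSE]
  med <- apply(tot, 2, lower_median)
  low_frac <- rowMeans(sweep(tot, 2, med, `<`))
  high_frac <- rowMeans(sweep(tot, 2, cfg$high_factor * med, `>=`))
  low <- low_frac >= cfg$quantile_frac
  high <- !low & high_frac >= cfg$quantile_frac
  report <- data.frame(
    replicon = m$sites$replicon[low | high],
    pos = m$sites$pos[low | high],
    reason = ifelse(low[low | high], "low_coverage", "high_coverage"),
    stringsAsFactors = FALSE)
  list(matrix = acm_subset(m, sites = !(low | high)), report = report)
}

#' Drop sites inside homology-mask intervals
#'
#' Intervals are 0-based half-open; a site at position `end` of an interval
#' is kept. Intervals on replicons absent from the matrix raise a warning
#' and are ignored.
#'
#' @param m an [acm()] object.
#' @param mask data frame of intervals (`replicon`, `start`, `end`).
#' @return The filtered `acm`.
#' @export
apply_homology_mask <- function(m, mask) {
  if (is.null(mask) || nrow(mask) == 0 || n_sites(m) == 0) return(m)
  unknown <- setdiff(unique(mask$replicon), unique(m$sites$replicon))
  if (length(unknown) > 0) {
    warning("homology-mask intervals on unknown replicon(s) ignored: ",
            paste(unknown, collapse = ", "))
  }
  drop <- rep(FALSE, n_sites(m))
  for (k in seq_len(nrow(mask))) {
    drop <- drop | (m$sites$replicon == mask$replicon[k] &
                      m$sites$pos >= mask$start[k] &
                      m$sites$pos < mask$end[k])
  }
  acm_subset(m, sites = !drop)
}

#' Run the full variant-filtering cascade
#'
#' Canonical order: rare-allele removal, extreme-coverage masking, homology
#' masking. Returns the trusted variant matrix together with a report whose
#' per-rule counts reconcile exactly with the input and output site counts.
#'
#' @param m an [acm()] object of raw called variants.
#' @param cfg a [filter_config()]; its `homology_mask` is applied unless
#'   `mask` overrides it.
#' @param mask optional homology-mask data frame overriding the config.
#' @param include_samples samples counted in the extreme-coverage rule
#'   denominators (see [mask_extreme_coverage()]).
#' @return A list with `matrix` (filtered `acm`) and `report` (list of
#'   per-rule removed-site counts plus the per-site mask reasons).
#' @export
filter_variants <- function(m, cfg = filter_config(), mask = NULL,
                            include_samples = NULL) {
  if (is.null(mask)) mask <- cfg$homology_mask
  n_in <- n_sites(m)
  m1 <- filter_rare_alleles(m, cfg)
  n_rare <- n_in - n_sites(m1)
  if (n_sites(m1) >= 2) {
    step2 <- mask_extreme_coverage(m1, cfg, include_samples)
    m2 <- step2$matrix
    cov_report <- step2$report
  } else {
    m2 <- m1
    cov_report <- data.frame(replicon = character(), pos = integer(),
                             reason = character(), stringsAsFactors = FALSE)
  }
  m3 <- apply_homology_mask(m2, mask)
  n_hom <- n_sites(m2) - n_sites(m3)
  report <- list(
    sites_in = n_in,
    removed_rare = n_rare,
    removed_low = sum(cov_report$reason == "low_coverage"),
    removed_high = sum(cov_report$reason == "high_coverage"),
    removed_homology = n_hom,
    sites_out = n_sites(m3),
    mask_reasons = cov_report)
  stopifnot(report$sites_in - report$removed_rare - report$removed_low -
              report$removed_high - report$removed_homology ==
              report$sites_out)
  list(matrix = m3, report = report)
}
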