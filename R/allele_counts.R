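#' @title Allele-count matrices
#'
#' @description An `acm` (allele-count matrix) stores, for every variant site
#' and every sample, the read depth observed for the reference allele and for
#' each alternative allele. It is the central container consumed by the
#' filtering cascade, the profile builder and the coinfection detector.
#'
#' Internally positions are 0-based; conversion to the 1-based VCF convention
#' happens only in [read_vcf()] / [write_vcf()].
#'
#' @param sites data frame with columns `replicon` (character), `pos`
#'   (0-based integer), `ref` (character allele) and `alts` (list column of
#'   character vectors, possibly empty).
#' @param samples character vector of sample identifiers.
#' @param depths integer array of dimension `n_sites x n_samples x max_alleles`
#'   where allele slot 1 is the reference allele and slots `2..(1+n_alts)` the
#'   alternative alleles of the site. Slots beyond a site's allele count must
#'   be zero.
#' @param missing logical matrix `n_sites x n_samples`; `TRUE` marks a sample
#'   with no data at the site (as opposed to genuinely zero depth). Defaults
#'   to all `FALSE`.
#' @return An object of class `acm`.
#' @export
acm <- function(sites, samples, depths, missing = NULL) {
  if (is.null(missing)) {
    missing <- matrix(FALSE, nrow(sites), length(samples))
  }
  m <- structure(
    list(sites = sites, samples = as.character(samples),
         depths = depths, missing = missing),
    class = "acm")
  validate_acm(m)
  m
}

validate_acm <- function(m) {
  s <- m$sites
  stopifnot(is.data.frame(s),
            all(c("replicon", "pos", "ref", "alts") %in% names(s)),
            is.list(s$alts))
  if (nrow(s) > 0) {
    if (any(s$pos < 0)) stop("site positions must be >= 0")
    if (any(!nzchar(s$ref))) stop("reference alleles must be non-empty")
    dup <- duplicated(paste(s$replicon, s$pos))
    if (any(dup)) stop("duplicate sites: ", paste(s$replicon[dup], s$pos[dup])[1])
    o <- order_sites(s)
    if (!identical(o, seq_len(nrow(s)))) {
      stop("sites must be sorted by (replicon, position)")
    }
    for (i in seq_len(nrow(s))) {
      a <- s$alts[[i]]
      if (anyDuplicated(c(s$ref[i], a))) {
        stop("alleles at ", s$replicon[i], ":", s$pos[i], " are not distinct")
      }
    }
  }
  d <- dim(m$depths)
  if (length(d) != 3L || d[1] != nrow(s) || d[2] != length(m$samples)) {
    stop("depth array dimensions do not match sites x samples")
  }
  if (d[3] < max(c(1L, 1L + lengths(s$alts)))) {
    stop("depth array has too few allele slots")
  }
  if (nrow(s) > 0 && any(m$depths < 0)) stop("negative depths")
  if (!identical(dim(m$missing), d[1:2])) {
    stop("missing-flag matrix dimensions do not match sites x samples")
  }
  invisible(m)
}

## deterministic, locale-independent site ordering
order_sites <- function(sites) {
  order(sites$replicon, sites$pos, method = "radix")
}

#' Number of sites / samples in an allele-count matrix
#' @param m an [acm()] object.
#' @return Integer count.
#' @export
n_sites <- function(m) nrow(m$sites)

#' @rdname n_sites
#' @export
n_samples <- function(m) length(m$samples)

#' Alleles of one site
#' @param m an [acm()] object.
#' @param i site index.
#' @return Character vector, reference allele first.
#' @export
site_alleles <- function(m, i) c(m$sites$ref[i], m$sites$alts[[i]])

## per-site allele counts (1 + number of alternatives)
acm_n_alleles <- function(m) 1L + lengths(m$sites$alts)

#' Total read depth per site and sample
#' @param m an [acm()] object.
#' @return Numeric matrix `n_sites x n_samples` of summed allele depths.
#' @export
total_depth <- function(m) {
  if (n_sites(m) == 0) {
    return(matrix(0, 0, n_samples(m)))
  }
  rowSums(m$depths, dims = 2)
}

#' Subset an allele-count matrix
#' @param m an [acm()] object.
#' @param sites integer or logical index over sites.
#' @param samples integer, logical or character index over samples.
#' @return The subsetted `acm`.
#' @export
acm_subset <- function(m, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(n_sites(m)) else seq_len(n_sites(m))[sites]
  sj <- if (is.null(samples)) {
    seq_len(n_samples(m))
  } else if (is.character(samples)) {
    idx <- match(samples, m$samples)
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    idx
  } else {
    seq_len(n_samples(m))[samples]
  }
  acm(m$sites[si, , drop = FALSE],
      m$samples[sj],
      m$depths[si, sj, , drop = FALSE],
      m$missing[si, sj, drop = FALSE])
}

#' @export
print.acm <- function(x, ...) {
  cat(sprintf("<acm> %d sites x %d samples (%d replicon%s)\n",
              n_sites(x), n_samples(x),
              length(unique(x$sites$replicon)),
              if (length(unique(x$sites$replicon)) == 1) "" else "s"))
  invisible(x)
}

## build an acm from a long table of (replicon, pos, ref, alts, sample depths)
## where `depth_rows` is a list (one per site) of numeric matrices
## alleles x samples. Used by readers and the simulator.
acm_from_lists <- function(sites, samples, depth_rows, missing = NULL) {
  nal <- 1L + lengths(sites$alts)
  A <- max(c(1L, nal))
  d <- array(0L, c(nrow(sites), length(samples), A))
  for (i in seq_len(nrow(sites))) {
    d[i, , seq_len(nal[i])] <- t(depth_rows[[i]])
  }
  acm(sites, samples, d, missing)
}
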