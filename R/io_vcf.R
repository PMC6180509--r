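#' Read a multi-sample VCF with per-allele depths into an allele-count matrix
#'
#' Parses a VCF 4.x file whose per-sample FORMAT carries an allelic-depth
#' field: either `AD` (modern samtools/GATK) or `DPR` (older samtools
#' mpileup). Both list the reference-allele depth first, followed by one
#' depth per alternative allele. Multiallelic records are kept as a single
#' site with all alternatives, because downstream most-abundant-allele calls
#' need all alleles of a locus together. VCF 1-based positions are converted
#' to the internal 0-based convention.
#'
#' Samples with a missing genotype (`.` or `./.`) or a missing depth field
#' get all-zero depths and are flagged in the `missing` matrix, so "no reads"
#' and "no data" stay distinguishable.
#'
#' @param path path to an uncompressed VCF file.
#' @return An [acm()] object.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  chrom_line <- grep("^#CHROM\t", lines)
  if (length(chrom_line) != 1) stop("VCF is missing the #CHROM header line")
  cols <- strsplit(lines[chrom_line], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10) stop("VCF has no sample columns")
  samples <- cols[10:length(cols)]
  body <- lines[-hdr]
  if (length(body) == 0) {
    sites <- data.frame(replicon = character(), pos = integer(),
                        ref = character(), stringsAsFactors = FALSE)
    sites$alts <- list()
    return(acm(sites, samples, array(0L, c(0, length(samples), 1)),
               matrix(FALSE, 0, length(samples))))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols))) {
    stop("malformed VCF record at line ", which(nf != length(cols))[1])
  }
  rec <- do.call(rbind, fields)
  replicon <- rec[, 1]
  pos1 <- as.integer(rec[, 2])
  ref <- rec[, 4]
  alt_raw <- rec[, 5]
  alts <- lapply(alt_raw, function(a) {
    if (a == "." || a == "") character(0) else strsplit(a, ",", fixed = TRUE)[[1]]
  })

  ## sortedness: replicons in radix order, positions increasing within
  key_order <- order(replicon, pos1, method = "radix")
  if (!identical(key_order, seq_along(pos1))) {
    bad <- which(key_order != seq_along(pos1))[1]
    stop("VCF records are not sorted; first offending record: ",
         replicon[bad], ":", pos1[bad])
  }

  n_site <- length(pos1)
  nal <- 1L + lengths(alts)
  A <- max(nal)
  depths <- array(0L, c(n_site, length(samples), A))
  missing <- matrix(FALSE, n_site, length(samples))

  fmt_keys <- strsplit(rec[, 9], ":", fixed = TRUE)
  ad_idx <- vapply(fmt_keys, function(k) {
    i <- match("AD", k)
    if (is.na(i)) i <- match("DPR", k)
    if (is.na(i)) 0L else i
  }, integer(1))
  if (any(ad_idx == 0L)) {
    stop("VCF lacks an allelic-depth FORMAT field (AD or DPR) at record ",
         which(ad_idx == 0L)[1], "; cannot recover allele counts")
  }

  for (j in seq_along(samples)) {
    gvals <- rec[, 9 + j]
    parts <- strsplit(gvals, ":", fixed = TRUE)
    for (i in seq_len(n_site)) {
      p <- parts[[i]]
      ad <- if (length(p) >= ad_idx[i]) p[ad_idx[i]] else "."
      if (p[1] %in% c(".", "./.", ".|.") || ad == ".") {
        missing[i, j] <- TRUE
        next
      }
      v <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
      if (anyNA(v) || length(v) != nal[i]) {
        stop("allelic depths at ", replicon[i], ":", pos1[i], " for sample ",
             samples[j], " do not match the allele count")
      }
      depths[i, j, seq_len(nal[i])] <- v
    }
  }

  sites <- data.frame(replicon = replicon, pos = pos1 - 1L, ref = ref,
                      stringsAsFactors = FALSE)
  sites$alts <- alts
  acm(sites, samples, depths, missing)
}

#' Write an allele-count matrix as a minimal VCF
#'
#' Emits a deterministic, canonical VCF 4.2 with an `AD` FORMAT field only.
#' `write_vcf()` and [read_vcf()] round-trip: positions, alleles, depths and
#' missing flags are preserved, and re-writing a file produced by
#' `write_vcf()` is byte-identical.
#'
#' @param m an [acm()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=holostrain",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref first)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$samples), collapse = "\t"))
  n <- n_sites(m)
  if (n == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  nal <- acm_n_alleles(m)
  alt_str <- vapply(m$sites$alts, function(a) {
    if (length(a) == 0) "." else paste(a, collapse = ",")
  }, character(1))
  recs <- character(n)
  for (i in seq_len(n)) {
    cells <- character(n_samples(m))
    for (j in seq_len(n_samples(m))) {
      cells[j] <- if (m$missing[i, j]) "." else
        paste(m$depths[i, j, seq_len(nal[i])], collapse = ",")
    }
    recs[i] <- paste(c(m$sites$replicon[i], m$sites$pos[i] + 1L, ".",
                       m$sites$ref[i], alt_str[i], ".", ".", ".", "AD", cells),
                     collapse = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
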