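#' Build a sample's variant profile (most-abundant-allele haplotype)
#'
#' At each site the allele with the highest read depth in the sample is
#' chosen. When the maximum is tied -- whether the reference ties an
#' alternative or two alternatives tie each other -- the reference allele is
#' kept and the site is flagged as a tie. Sites with zero total depth (or an
#' explicit missing flag) are flagged missing and fall back to the reference
#' allele.
#'
#' `tie_fraction` is the share of tie-flagged sites among the sample's
#' non-missing *variable* sites, where a variable site has at least two
#' distinct observed or chosen alleles across all samples of the matrix.
#'
#' @param m a filtered [acm()] object.
#' @param sample sample identifier present in `m`.
#' @return A list of class `variant_profile` with fields `sample`,
#'   `allele_idx` (1 = reference), `tie`, `missing`, `tie_fraction` and
#'   `sites` (the site table of `m`).
#' @export
build_profile <- function(m, sample) {
  j <- match(sample, m$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  build_profiles(m)[[sample]]
}

#' Build variant profiles for every sample of a matrix
#'
#' @param m a filtered [acm()] object.
#' @return Named list of `variant_profile` objects (class `profile_set`),
#'   with attributes `sites` and `variable` (logical vector of variable
#'   sites).
#' @export
build_profiles <- function(m) {
  n <- n_sites(m)
  S <- n_samples(m)
  nal <- acm_n_alleles(m)
  A <- dim(m$depths)[3]
  chosen <- matrix(1L, n, S)
  tie <- matrix(FALSE, n, S)
  miss <- matrix(FALSE, n, S)
  observed <- matrix(FALSE, n, max(A, 1L))
  if (n > 0) {
    slot_valid <- outer(nal, seq_len(A), `>=`)
    for (j in seq_len(S)) {
      d <- matrix(m$depths[, j, ], n, A)
      d[!slot_valid] <- -1L
      mx <- do.call(pmax, as.data.frame(d))
      nmax <- rowSums(d == mx)
      first <- max.col(d, ties.method = "first")
      miss[, j] <- (mx <= 0) | m$missing[, j]
      tie[, j] <- nmax > 1 & !miss[, j]
      chosen[, j] <- ifelse(miss[, j] | tie[, j], 1L, first)
      observed <- observed | (d > 0)
    }
  }
  n_chosen <- apply(chosen, 1, function(x) length(unique(x)))
  variable <- (rowSums(observed) >= 2) | (n_chosen >= 2)
  out <- lapply(seq_len(S), function(j) {
    denom <- variable & !miss[, j]
    structure(list(
      sample = m$samples[j],
      allele_idx = chosen[, j],
      tie = tie[, j],
      missing = miss[, j],
      tie_fraction = if (any(denom)) mean(tie[denom, j]) else 0,
      sites = m$sites
    ), class = "variant_profile")
  })
  names(out) <- m$samples
  structure(out, sites = m$sites, variable = variable, class = "profile_set")
}

#' Exclude samples with too many ambiguous (tied) sites
#'
#' Samples where more than `max_tie_fraction` of variable sites yielded
#' equally abundant alleles are moved to the excluded set (a tie fraction of
#' exactly `max_tie_fraction` is kept; the bound is strict).
#'
#' @param profiles a `profile_set` or list of `variant_profile` objects.
#' @param max_tie_fraction exclusion threshold (default 0.05).
#' @return List with `kept` and `excluded` (each a named list of profiles);
#'   excluded profiles carry a `reason` field.
#' @export
exclude_ambiguous_samples <- function(profiles, max_tie_fraction = 0.05) {
  tf <- vapply(profiles, `[[`, numeric(1), "tie_fraction")
  out <- vapply(profiles, function(p) p$tie_fraction > max_tie_fraction,
                logical(1))
  excluded <- profiles[out]
  for (i in seq_along(excluded)) {
    excluded[[i]]$reason <- sprintf(
      "tie fraction %.4f exceeds %.4f", tf[out][i], max_tie_fraction)
  }
  list(kept = profiles[!out], excluded = excluded)
}

## key identifying a profile's chosen-allele vector; missing is its own value
profile_key <- function(p) {
  paste(ifelse(p$missing, "M", p$allele_idx), collapse = ",")
}

#' Deduplicate identical variant profiles
#'
#' Groups profiles by exact equality of their chosen-allele vectors (a
#' missing site is a distinct value, so it never matches a called allele).
#' The representative of each group is the lexicographically smallest sample
#' identifier, so trees built on representatives can be re-expanded.
#'
#' @param profiles a `profile_set` or list of `variant_profile` objects.
#' @return List with `representatives` (named list of profiles) and `groups`
#'   (named list: representative -> character vector of member samples).
#' @export
deduplicate_profiles <- function(profiles) {
  keys <- unname(vapply(profiles, profile_key, character(1)))
  ids <- unname(vapply(profiles, `[[`, character(1), "sample"))
  groups <- split(ids, keys)
  reps <- vapply(groups, function(g) sort(g, method = "radix")[1], character(1))
  names(groups) <- reps
  groups <- groups[sort(reps, method = "radix")]
  list(representatives = profiles[names(groups)], groups = groups)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Synthesize per-sample gene sequences from a variant profile
#'
#' For each gene, the chosen non-reference alleles whose reference span
#' intersects the gene are applied to the reference subsequence in
#' descending coordinate order (so earlier edits never shift later
#' coordinates); minus-strand genes are reverse-complemented after editing.
#' Missing sites keep the reference allele. An indel spanning a gene
#' boundary is truncated to the overlap with a warning. Output names follow
#' `"{sample}|{gene_id}"`.
#'
#' @param reference named character vector of replicon sequences.
#' @param genes gene-model data frame ([read_gene_models()] layout).
#' @param profile a `variant_profile`.
#' @return Named character vector of gene sequences.
#' @export
apply_profile_to_genes <- function(reference, genes, profile) {
  sites <- profile$sites
  alt_of <- function(i) {
    a <- site_alleles_row(sites, i)
    a[profile$allele_idx[i]]
  }
  chosen_alt <- which(profile$allele_idx > 1L & !profile$missing)
  ref_len <- vapply(seq_len(nrow(sites)), function(i) nchar(sites$ref[i]),
                    integer(1))
  out <- character(nrow(genes))
  names(out) <- paste(profile$sample, genes$gene_id, sep = "|")
  for (g in seq_len(nrow(genes))) {
    repl <- genes$replicon[g]
    if (!repl %in% names(reference)) {
      stop("gene ", genes$gene_id[g], " on unknown replicon ", repl)
    }
    gs <- genes$start[g]
    ge <- genes$end[g]
    seq <- substr(reference[[repl]], gs + 1L, ge)
    hit <- chosen_alt[sites$replicon[chosen_alt] == repl &
                        sites$pos[chosen_alt] < ge &
                        (sites$pos[chosen_alt] + ref_len[chosen_alt]) > gs]
    if (length(hit) > 1) {
      o <- order(sites$pos[hit])
      spans <- cbind(sites$pos[hit][o], sites$pos[hit][o] + ref_len[hit][o])
      if (any(spans[-1, 1] < spans[-nrow(spans), 2])) {
        stop("overlapping chosen variants within gene ", genes$gene_id[g])
      }
    }
    for (i in hit[order(sites$pos[hit], decreasing = TRUE)]) {
      pos <- sites$pos[i]
      ra <- sites$ref[i]
      aa <- alt_of(i)
      h1 <- max(0L, gs - pos)                      # overhang before gene
      h2 <- max(0L, (pos + nchar(ra)) - ge)        # overhang after gene
      in_len <- nchar(ra) - h1 - h2
      if (h1 > 0 || h2 > 0) {
        warning("variant at ", repl, ":", pos, " spans a boundary of gene ",
                genes$gene_id[g], "; edit truncated to the overlap")
        ## drop the out-of-gene overhangs; the part of the edit that falls
        ## outside the gene (e.g. a deletion continuing past its end) must
        ## not consume in-gene sequence
        aa <- substr(aa, h1 + 1L, h1 + max(nchar(aa) - h1 - h2, in_len))
      }
      in_start <- pos + h1 - gs                    # 0-based within gene
      seq <- paste0(substr(seq, 1L, in_start),
                    aa,
                    substr(seq, in_start + in_len + 1L, nchar(seq)))
    }
    if (genes$strand[g] == "-") seq <- revcomp(seq)
    out[g] <- seq
  }
  out
}

site_alleles_row <- function(sites, i) c(sites$ref[i], sites$alts[[i]])

#' Write a profile set as TSV
#'
#' One row per sample; site columns named `replicon:pos` hold the chosen
#' allele string, `"."` for missing sites.
#'
#' @param profiles a `profile_set` or list of `variant_profile` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (length(profiles) == 0) stop("no profiles to write")
  sites <- profiles[[1]]$sites
  cols <- paste(sites$replicon, sites$pos, sep = ":")
  rows <- vapply(profiles, function(p) {
    al <- vapply(seq_len(nrow(sites)), function(i) {
      if (p$missing[i]) "." else site_alleles_row(sites, i)[p$allele_idx[i]]
    }, character(1))
    paste(c(p$sample, al), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("sample", cols), collapse = "\t"), rows), path)
  invisible(path)
}
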