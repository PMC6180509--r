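#' Summarize a per-position coverage track
#'
#' Computes the per-sample, per-symbiont coverage statistics used for
#' presence calls and variant-calling eligibility: mean depth over all
#' reference positions (zeros included), breadth covered by at least five
#' reads, fraction of positions covered by fewer than two reads, and the
#' mean per-read edit distance when supplied.
#'
#' @param depths integer vector of per-position depths (whole replicon or
#'   concatenated genome).
#' @param edit_distances optional integer vector of per-read edit distances.
#' @param sample,symbiont identifiers carried through to the summary.
#' @return A list of class `coverage_summary` with fields `sample`,
#'   `symbiont`, `mean_depth`, `breadth_ge5`, `frac_lt2`,
#'   `mean_edit_distance` (`NA` when no distances were given).
#' @export
summarize_coverage <- function(depths, edit_distances = NULL,
                               sample = NA_character_,
                               symbiont = NA_character_) {
  if (is.list(depths)) depths <- unlist(depths, use.names = FALSE)
  if (length(depths) == 0) stop("empty coverage track")
  if (any(depths < 0)) stop("negative depth in coverage track")
  structure(list(
    sample = sample,
    symbiont = symbiont,
    mean_depth = mean(depths),
    breadth_ge5 = mean(depths >= 5),
    frac_lt2 = mean(depths < 2),
    mean_edit_distance = if (is.null(edit_distances)) NA_real_ else
      mean(edit_distances)
  ), class = "coverage_summary")
}

#' Call symbiont presence from a coverage summary
#'
#' Three-way call: `absent` below 1x mean depth; `analysable` above 10x mean
#' depth with homogeneous coverage (at most 90% of positions under two
#' reads); otherwise `present_low` (detected but not eligible for variant
#' calling). The 1x and 10x bounds are strict, so a mean depth of exactly
#' 1 or 10 is `present_low`.
#'
#' @param summary a `coverage_summary` from [summarize_coverage()], or a list
#'   with fields `mean_depth` and `frac_lt2`.
#' @param absent_below mean-depth threshold below which the symbiont is
#'   absent (default 1).
#' @param analysable_above mean-depth threshold above which variant calling
#'   is allowed (default 10).
#' @param homogeneity_max_frac_lt2 maximum tolerated fraction of positions
#'   with depth < 2 (default 0.90).
#' @return A list of class `presence_call` with fields `sample`, `symbiont`,
#'   `status` (one of `absent`, `present_low`, `analysable`) and the
#'   thresholds used.
#' @export
call_presence <- function(summary, absent_below = 1,
                          analysable_above = 10,
                          homogeneity_max_frac_lt2 = 0.90) {
  stopifnot(absent_below > 0, analysable_above > 0)
  status <- if (summary$mean_depth < absent_below) {
    "absent"
  } else if (summary$mean_depth > analysable_above &&
             summary$frac_lt2 <= homogeneity_max_frac_lt2) {
    "analysable"
  } else {
    "present_low"
  }
  structure(list(
    sample = summary$sample,
    symbiont = summary$symbiont,
    status = status,
    thresholds = c(absent_below = absent_below,
                   analysable_above = analysable_above,
                   homogeneity_max_frac_lt2 = homogeneity_max_frac_lt2)
  ), class = "presence_call")
}

#' Assemble presence calls into a samples-by-symbionts status matrix
#'
#' @param calls list of `presence_call` objects, at most one per
#'   (sample, symbiont) pair.
#' @return Character matrix (rows samples, columns symbionts) of statuses;
#'   pairs without a call are `"absent"`.
#' @export
build_presence_matrix <- function(calls) {
  samples <- unique(vapply(calls, `[[`, character(1), "sample"))
  symbionts <- unique(vapply(calls, `[[`, character(1), "symbiont"))
  mat <- matrix("absent", length(samples), length(symbionts),
                dimnames = list(samples, symbionts))
  seen <- character(0)
  for (cl in calls) {
    key <- paste(cl$sample, cl$symbiont, sep = "\r")
    if (key %in% seen) {
      stop("duplicate presence call for sample ", cl$sample,
           ", symbiont ", cl$symbiont)
    }
    seen <- c(seen, key)
    mat[cl$sample, cl$symbiont] <- cl$status
  }
  mat
}

#' Write a presence matrix as TSV
#'
#' Statuses are encoded `0` (absent), `low` (present, under-covered) and
#' `ok` (analysable).
#'
#' @param mat matrix from [build_presence_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(mat, path) {
  enc <- matrix(c("absent" = "0", "present_low" = "low",
                  "analysable" = "ok")[mat],
                nrow(mat), ncol(mat), dimnames = dimnames(mat))
  utils::write.table(enc, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
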