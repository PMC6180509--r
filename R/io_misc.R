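#' Read a per-position depth track
#'
#' Consumes the three-column `samtools depth` dialect (replicon, 1-based
#' position, depth). Positions absent from the file are filled with depth 0,
#' so sparse output is accepted.
#'
#' @param path TSV file path.
#' @param lengths named integer vector giving the length of each replicon to
#'   densify; names are replicon identifiers.
#' @return Named list of integer depth vectors, one per replicon in
#'   `lengths`, each of the stated length.
#' @export
read_coverage <- function(path, lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("`lengths` must be a named vector of replicon lengths")
  }
  tracks <- lapply(lengths, function(L) integer(L))
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = c("character", "integer", "integer"),
                             col.names = c("replicon", "pos", "depth"))
    if (any(tab$depth < 0)) stop("negative depth in coverage track")
    for (rep in unique(tab$replicon)) {
      if (!rep %in% names(lengths)) {
        warning("coverage rows for unknown replicon ", rep, " ignored")
        next
      }
      sel <- tab$replicon == rep
      p <- tab$pos[sel]
      if (any(p < 1 | p > lengths[[rep]])) {
        stop("coverage position outside replicon ", rep)
      }
      tracks[[rep]][p] <- tab$depth[sel]
    }
  }
  tracks
}

#' Write a per-position depth track
#'
#' Inverse of [read_coverage()]: writes every position (dense, 1-based).
#'
#' @param tracks named list of integer depth vectors.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rep in names(tracks)) {
    d <- tracks[[rep]]
    writeLines(paste(rep, seq_along(d), d, sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that add
#' eager syntax validation: unbalanced parentheses are reported with the
#' character offset of the first offence. Round trips preserve topology,
#' branch lengths (to 1e-9) and labels.
#'
#' @param path Newick file path.
#' @return `read_tree()`: an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("unbalanced parentheses in Newick at character offset ", i)
    }
  }
  if (depth != 0L) {
    stop("unbalanced parentheses in Newick: ", depth,
         " unclosed at character offset ", length(chars))
  }
  t <- ape::read.tree(text = txt)
  if (is.null(t)) stop("failed to parse Newick in ", path)
  t
}

#' @rdname read_tree
#' @param tree an [ape::phylo] object.
#' @return `write_tree()`: `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read / write FASTA sequence sets
#'
#' Backed by Biostrings; sequences are exposed as plain named character
#' vectors because profile application edits them as strings.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of DNA sequences.
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports via rtracklayer and converts to the internal 0-based half-open
#' convention. Only features of type `gene` are kept (all features if none
#' is typed `gene`).
#'
#' @param path GFF3 file path.
#' @return Data frame with columns `gene_id`, `replicon`, `start` (0-based),
#'   `end` (half-open) and `strand` (`+` or `-`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene")) {
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- paste0("gene_", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(gene_id = as.character(ids),
             replicon = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = strand,
             stringsAsFactors = FALSE)
}

#' Write gene models to GFF3
#'
#' @param genes data frame as returned by [read_gene_models()].
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a BED interval file (0-based half-open, kept as-is)
#'
#' @param path BED file path (first three columns used).
#' @return Data frame with columns `replicon`, `start`, `end`.
#' @export
read_bed <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) {
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(replicon = as.character(tab[[1]]),
             start = as.integer(tab[[2]]),
             end = as.integer(tab[[3]]),
             stringsAsFactors = FALSE)
}

#' Read a symbiont-to-host tip mapping TSV
#'
#' Two columns: symbiont tip, host tip. Many symbiont tips may map to one
#' host tip; each symbiont tip maps to exactly one host.
#'
#' @param path TSV file path.
#' @return Named character vector: names are symbiont tips, values host tips.
#' @export
read_tip_mapping <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]])) {
    stop("symbiont tip mapped more than once: ",
         tab[[1]][duplicated(tab[[1]])][1])
  }
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' @rdname read_tip_mapping
#' @param mapping named character vector (symbiont tip -> host tip).
#' @return `write_tip_mapping()`: `path`, invisibly.
#' @export
write_tip_mapping <- function(mapping, path) {
  utils::write.table(data.frame(names(mapping), unname(mapping)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
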