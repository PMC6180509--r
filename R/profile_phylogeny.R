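#' Pairwise distance between two variant profiles
#'
#' The number of sites at which both profiles are non-missing and the chosen
#' alleles differ, divided by the total number of variants detected on the
#' genome (a fixed denominator, so distances stay comparable across pairs
#' even when missingness differs).
#'
#' @param p,q `variant_profile` objects sharing a site list.
#' @param total_variants total number of variant sites detected on the
#'   genome (> 0).
#' @return A numeric distance in `[0, 1]`.
#' @export
profile_distance <- function(p, q, total_variants) {
  if (total_variants == 0) stop("total_variants must be > 0")
  if (length(p$allele_idx) != length(q$allele_idx)) {
    stop("profiles do not share a site list")
  }
  ok <- !p$missing & !q$missing
  sum(p$allele_idx[ok] != q$allele_idx[ok]) / total_variants
}

#' Profile distance matrix
#'
#' @param profiles a `profile_set` or list of `variant_profile` objects.
#' @param total_variants denominator; defaults to the number of sites in the
#'   shared site list.
#' @return Symmetric numeric matrix with sample labels, zero diagonal.
#' @export
profile_distance_matrix <- function(profiles, total_variants = NULL) {
  n <- length(profiles)
  labels <- vapply(profiles, `[[`, character(1), "sample")
  if (is.null(total_variants)) {
    total_variants <- length(profiles[[1]]$allele_idx)
  }
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <-
          profile_distance(profiles[[i]], profiles[[j]], total_variants)
      }
    }
  }
  d
}

fmt_brlen <- function(x) sprintf("%.17g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration on the Q-criterion, implemented here so
#' tie-breaking and negative-branch handling are fully specified: at each
#' step the pair minimizing Q is joined, ties broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest tip
#' label); a negative inferred branch length is clamped to zero and the
#' deficit transferred to the sister branch. For an additive distance matrix
#' the generating topology and branch lengths are recovered exactly.
#'
#' @param d symmetric numeric matrix with unique labels (n >= 3).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (anyNA(d) || any(!is.finite(d))) stop("NaN or non-finite entries in distance matrix")
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("distance matrix needs unique row/column labels")
  }
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  newick <- labels     # growing subtree strings
  minlab <- labels     # smallest tip label within each cluster
  D <- d

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (nrow(D) > 3) {
    nn <- nrow(D)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin & upper.tri(Q), arr.ind = TRUE)
    keys1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
    keys2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
    pick <- order(keys1, keys2, method = "radix")[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- D[i, j] - li
    l <- clamp_pair(li, lj)
    merged <- sprintf("(%s:%s,%s:%s)", newick[i], fmt_brlen(l[1]),
                      newick[j], fmt_brlen(l[2]))
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(nn), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    newick <- c(newick[keep], merged)
    minlab <- c(minlab[keep], min(minlab[c(i, j)]))
  }

  ## closed-form star resolution for the last three clusters
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 newick[1], fmt_brlen(max(la, 0)),
                 newick[2], fmt_brlen(max(lb, 0)),
                 newick[3], fmt_brlen(max(lc, 0)))
  ape::read.tree(text = txt)
}

## ---- bipartitions ------------------------------------------------------

## Non-trivial bipartitions of a tree's tip set, as canonical keys:
## the side NOT containing the lexicographically smallest tip, sorted and
## joined by "|". Works for rooted and unrooted trees.
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  refs <- sort(tips, method = "radix")[1]
  n <- length(tips)
  splits <- unique(unlist(lapply(node_descendant_sets(tree), function(side) {
    if (length(side) < 2 || length(side) > n - 2) return(NULL)
    if (refs %in% side) side <- setdiff(tips, side)
    paste(sort(side, method = "radix"), collapse = "|")
  })))
  splits[!is.na(splits)]
}

## list over internal nodes: tip labels descending from each internal node
node_descendant_sets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets[(n + 1):(n + nn)]
}

#' Compare two tree topologies (Robinson-Foulds)
#'
#' Symmetric-difference count of non-trivial bipartitions; 0 iff the
#' unrooted topologies are identical.
#'
#' @param t1,t2 [ape::phylo] trees over the same tip set.
#' @return List with `rf` (integer distance), `shared`, `only1`, `only2`
#'   (bipartition keys).
#' @export
compare_topologies <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("tip sets differ: only in first tree {",
         paste(setdiff(t1$tip.label, t2$tip.label), collapse = ", "),
         "}; only in second tree {",
         paste(setdiff(t2$tip.label, t1$tip.label), collapse = ", "), "}")
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  list(rf = length(setdiff(b1, b2)) + length(setdiff(b2, b1)),
       shared = intersect(b1, b2),
       only1 = setdiff(b1, b2),
       only2 = setdiff(b2, b1))
}

#' Site-bootstrap supports on a neighbor-joining profile tree
#'
#' The main tree is built from the full site set. Variant sites (columns)
#' are then resampled with replacement `n_reps` times, an NJ tree is built
#' from each resample, and the support of each internal bipartition of the
#' main tree is the percentage of replicate trees containing it. The
#' denominator of the profile distance stays at `total_variants` for every
#' replicate.
#'
#' @param profiles a `profile_set` or list of `variant_profile` objects
#'   (>= 4 profiles).
#' @param total_variants fixed distance denominator (default: number of
#'   sites).
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return The main NJ tree with integer percentage supports in
#'   `node.label` (empty for the basal node).
#' @export
bootstrap_support <- function(profiles, total_variants = NULL,
                              n_reps = 1000, seed = NULL) {
  if (n_reps <= 0) stop("n_reps must be positive")
  if (length(profiles) < 4) stop("need at least 4 profiles")
  if (!is.null(seed)) set.seed(seed)
  nsite <- length(profiles[[1]]$allele_idx)
  if (is.null(total_variants)) total_variants <- nsite
  main <- neighbor_joining(profile_distance_matrix(profiles, total_variants))
  keys <- tree_bipartitions(main)
  hits <- stats::setNames(integer(length(keys)), keys)
  resample <- function(p, idx) {
    p$allele_idx <- p$allele_idx[idx]
    p$missing <- p$missing[idx]
    p
  }
  for (r in seq_len(n_reps)) {
    idx <- sample.int(nsite, nsite, replace = TRUE)
    rp <- lapply(profiles, resample, idx = idx)
    bt <- neighbor_joining(profile_distance_matrix(rp, total_variants))
    bk <- tree_bipartitions(bt)
    present <- keys %in% bk
    hits[present] <- hits[present] + 1L
  }
  support <- round(100 * hits / n_reps)
  ## attach per internal node: a node's bipartition key (if non-trivial)
  sets <- node_descendant_sets(main)
  tips <- main$tip.label
  refs <- sort(tips, method = "radix")[1]
  labs <- vapply(sets, function(side) {
    if (length(side) < 2 || length(side) > length(tips) - 2) return("")
    if (refs %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side, method = "radix"), collapse = "|")
    as.character(support[[key]])
  }, character(1))
  main$node.label <- labs
  main
}

#' Root a tree with an outgroup
#'
#' The root is placed on the branch separating the outgroup from the
#' ingroup, splitting that branch's length equally. The outgroup must be
#' monophyletic in the unrooted tree.
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup character vector of outgroup tip labels.
#' @return A rooted [ape::phylo] tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  tips <- tree$tip.label
  if (!all(outgroup %in% tips)) {
    stop("outgroup tips not in tree: ",
         paste(setdiff(outgroup, tips), collapse = ", "))
  }
  if (setequal(outgroup, tips)) stop("outgroup cannot be the whole tip set")
  if (length(outgroup) > 1) {
    key <- paste(sort(outgroup, method = "radix"), collapse = "|")
    refs <- sort(tips, method = "radix")[1]
    side <- if (refs %in% outgroup) {
      paste(sort(setdiff(tips, outgroup), method = "radix"), collapse = "|")
    } else key
    if (length(tips) - length(outgroup) >= 2 && length(outgroup) >= 2 &&
        !(side %in% tree_bipartitions(tree))) {
      stop("outgroup is not monophyletic; conflicting tips: ",
           paste(outgroup, collapse = ", "))
    }
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root_node <- length(rooted$tip.label) + 1L
  basal <- which(rooted$edge[, 1] == root_node)
  if (length(basal) == 2 && !is.null(rooted$edge.length)) {
    tot <- sum(rooted$edge.length[basal])
    rooted$edge.length[basal] <- tot / 2
  }
  rooted
}

#' Make a rooted tree ultrametric by clade size (Grafen's method)
#'
#' Each node is assigned height `(d - 1) / (n - 1)` where `d` is its number
#' of descendant tips and `n` the total tip count; tips sit at height 0 and
#' every root-to-tip path has length 1.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @return The tree with Grafen branch lengths.
#' @export
ultrametrize_grafen <- function(tree) {
  n <- length(tree$tip.label)
  if (n == 1) return(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  counts <- integer(n + tree$Nnode)
  counts[seq_len(n)] <- 1L
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    counts[ord$edge[k, 1]] <- counts[ord$edge[k, 1]] + counts[ord$edge[k, 2]]
  }
  h <- (counts - 1) / (n - 1)
  tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  tree
}
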