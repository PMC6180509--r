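# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Build an acm from a 3D depth array [site, sample, allele].
# Site i sits at position 10*i on replicon "chr1"; ref allele "A", alts
# drawn from C,G,T in order. n_alt per site defaults to (alleles - 1).
make_acm <- function(depths, n_alt = NULL, missing = NULL,
                     samples = NULL, replicon = "chr1") {
  if (length(dim(depths)) == 2) {
    depths <- array(depths, c(nrow(depths), ncol(depths), 1))
  }
  ns <- dim(depths)[1]
  S <- dim(depths)[2]
  A <- dim(depths)[3]
  if (is.null(n_alt)) n_alt <- rep(A - 1L, ns)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(S))
  alt_pool <- c("C", "G", "T")
  sites <- data.frame(replicon = replicon, pos = 10L * seq_len(ns),
                      ref = "A", stringsAsFactors = FALSE)
  sites$alts <- lapply(seq_len(ns), function(i) alt_pool[seq_len(n_alt[i])])
  acm(sites, samples, depths, missing)
}

# Random acm with Poisson depths: some sites carry a genuine alt signal.
random_acm <- function(n_site, n_sample, lambda = 30, p_alt = 0.3,
                       max_alt = 2) {
  A <- max_alt + 1L
  d <- array(0L, c(n_site, n_sample, A))
  n_alt <- sample(seq_len(max_alt), n_site, replace = TRUE)
  for (i in seq_len(n_site)) {
    for (j in seq_len(n_sample)) {
      tot <- rpois(1, lambda)
      has_alt <- runif(1) < p_alt
      if (has_alt && n_alt[i] >= 1) {
        a <- sample(n_alt[i], 1)
        frac <- runif(1, 0.05, 0.95)
        alt_n <- rbinom(1, tot, frac)
        d[i, j, 1] <- tot - alt_n
        d[i, j, 1 + a] <- alt_n
      } else {
        d[i, j, 1] <- tot
      }
    }
  }
  make_acm(d, n_alt = n_alt)
}

# Minimal variant_profile construction from an allele-index matrix
# (rows sites, columns samples).
make_profiles <- function(idx, missing = NULL, samples = NULL) {
  ns <- nrow(idx)
  S <- ncol(idx)
  if (is.null(missing)) missing <- matrix(FALSE, ns, S)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(S))
  sites <- data.frame(replicon = "chr1", pos = 10L * seq_len(ns), ref = "A",
                      stringsAsFactors = FALSE)
  sites$alts <- rep(list(c("C", "G", "T")), ns)
  out <- lapply(seq_len(S), function(j) {
    structure(list(sample = samples[j], allele_idx = idx[, j],
                   tie = rep(FALSE, ns), missing = missing[, j],
                   tie_fraction = 0, sites = sites),
              class = "variant_profile")
  })
  names(out) <- samples
  out
}

# Write a one-off text fixture to a temp file and return its path.
textConnection_file <- function(...) {
  f <- tempfile()
  writeLines(c(...), f)
  f
}

# Random rooted binary tree with positive branch lengths (ape::rtree).
random_binary_tree <- function(n, labels = NULL) {
  t <- ape::rtree(n)
  if (!is.null(labels)) t$tip.label <- labels
  t
}
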