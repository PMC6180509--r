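test_that("build_profile picks the most abundant allele, ref on ties", {
  d <- array(0L, c(4, 2, 3))
  d[1, 1, ] <- c(10L, 30L, 0L)   # alt wins
  d[2, 1, ] <- c(20L, 20L, 0L)   # ref-alt tie -> ref, flagged
  d[3, 1, ] <- c(5L, 9L, 9L)     # alt-alt tie -> ref kept, flagged
  d[4, 1, ] <- c(0L, 0L, 0L)     # no reads -> missing
  d[, 2, 1] <- 15L               # second sample: all reference
  m <- make_acm(d, n_alt = rep(2L, 4))
  p <- build_profile(m, "s01")
  expect_equal(p$allele_idx, c(2L, 1L, 1L, 1L))
  expect_equal(p$tie, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(p$missing, c(FALSE, FALSE, FALSE, TRUE))
  # variable sites here: 1, 2, 3 (alt observed); non-missing for s01: 1:3
  expect_equal(p$tie_fraction, 2 / 3)
  expect_error(build_profile(m, "nope"), "unknown sample")
})

test_that("build_profile is invariant to allele input order", {
  set.seed(21)
  for (rep in 1:10) {
    m <- random_acm(30, 3, max_alt = 3)
    p <- build_profiles(m)
    # permute alt-allele slots consistently (site table and depths)
    m2 <- m
    for (i in seq_len(n_sites(m))) {
      k <- length(m$sites$alts[[i]])
      perm <- sample(k)
      m2$sites$alts[[i]] <- m$sites$alts[[i]][perm]
      m2$depths[i, , 1 + seq_len(k)] <- m$depths[i, , 1 + perm]
    }
    p2 <- build_profiles(m2)
    for (s in names(p)) {
      a1 <- mapply(function(i, ai) site_alleles(m, i)[ai],
                   seq_len(n_sites(m)), p[[s]]$allele_idx)
      a2 <- mapply(function(i, ai) site_alleles(m2, i)[ai],
                   seq_len(n_sites(m)), p2[[s]]$allele_idx)
      expect_equal(a1, a2)
      expect_equal(p[[s]]$tie, p2[[s]]$tie)
    }
  }
})

test_that("ambiguous-sample exclusion uses a strict 5% bound", {
  prof <- make_profiles(matrix(1L, 10, 3))
  prof[[1]]$tie_fraction <- 0.06
  prof[[2]]$tie_fraction <- 0.05
  prof[[3]]$tie_fraction <- 0
  res <- exclude_ambiguous_samples(prof)
  expect_equal(names(res$excluded), "s01")
  expect_match(res$excluded[[1]]$reason, "tie fraction")
  expect_equal(names(res$kept), c("s02", "s03"))

  res2 <- exclude_ambiguous_samples(make_profiles(matrix(1L, 5, 4)))
  expect_equal(length(res2$kept), 4)
})

test_that("deduplication groups by exact equality, missing distinct", {
  idx <- cbind(c(1L, 2L, 1L), c(1L, 2L, 1L), c(1L, 2L, 2L), c(1L, 2L, 1L))
  miss <- matrix(FALSE, 3, 4)
  miss[3, 4] <- TRUE   # s04 matches s01 except missing at site 3
  prof <- make_profiles(idx, miss)
  res <- deduplicate_profiles(prof)
  expect_equal(names(res$groups), c("s01", "s03", "s04"))
  expect_equal(res$groups[["s01"]], c("s01", "s02"))
  expect_equal(res$groups[["s04"]], "s04")
})

test_that("dedup partition equals the O(n^2) oracle and is an equivalence", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    idx <- matrix(sample(1:2, 8 * n, replace = TRUE, prob = c(0.8, 0.2)),
                  8, n)
    miss <- matrix(runif(8 * n) < 0.1, 8, n)
    prof <- make_profiles(idx, miss)
    res <- deduplicate_profiles(prof)
    got <- unname(lapply(res$groups, sort))
    want <- oracle_dedup_partition(prof)
    expect_setequal(sapply(got, paste, collapse = ","),
                    sapply(want, paste, collapse = ","))
    # partition property: disjoint cover
    expect_setequal(unlist(got), names(prof))
    expect_equal(anyDuplicated(unlist(got)), 0)
  }
})

test_that("apply_profile_to_genes edits plus and minus strand genes", {
  ref <- c(chr1 = "AACGTT")
  genes <- data.frame(gene_id = c("plus", "minus"), replicon = "chr1",
                      start = 1L, end = 5L, strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  sites <- data.frame(replicon = "chr1", pos = 2L, ref = "C",
                      stringsAsFactors = FALSE)
  sites$alts <- list("T")
  prof <- structure(list(sample = "x", allele_idx = 2L, tie = FALSE,
                         missing = FALSE, tie_fraction = 0, sites = sites),
                    class = "variant_profile")
  out <- apply_profile_to_genes(ref, genes, prof)
  expect_equal(unname(out["x|plus"]), "ATGT")
  expect_equal(unname(out["x|minus"]), oracle_revcomp("ATGT"))
  expect_equal(names(out), c("x|plus", "x|minus"))
})

test_that("a 1-bp deletion shortens the gene and indels apply back to front", {
  ref <- c(chr1 = "AAACGTACGTAA")
  genes <- data.frame(gene_id = "g", replicon = "chr1", start = 2L,
                      end = 10L, strand = "+", stringsAsFactors = FALSE)
  sites <- data.frame(replicon = "chr1", pos = c(3L, 7L), ref = c("CG", "C"),
                      stringsAsFactors = FALSE)
  sites$alts <- list("C", "CAA")   # 1-bp deletion then 2-bp insertion
  prof <- structure(list(sample = "x", allele_idx = c(2L, 2L),
                         tie = c(FALSE, FALSE), missing = c(FALSE, FALSE),
                         tie_fraction = 0, sites = sites),
                    class = "variant_profile")
  out <- apply_profile_to_genes(ref, genes, prof)
  # gene = ACGTACGT; deletion at offset 1 (CG->C) -> ACTACGT;
  # insertion at original offset 5 (C->CAA) -> ACTACAAGT
  expect_equal(unname(out), "ACTACAAGT")
})

test_that("indel spanning a gene boundary is truncated with a warning", {
  ref <- c(chr1 = "AACGTTTT")
  genes <- data.frame(gene_id = "g", replicon = "chr1", start = 0L,
                      end = 4L, strand = "+", stringsAsFactors = FALSE)
  sites <- data.frame(replicon = "chr1", pos = 3L, ref = "GTT",
                      stringsAsFactors = FALSE)
  sites$alts <- list("G")
  prof <- structure(list(sample = "x", allele_idx = 2L, tie = FALSE,
                         missing = FALSE, tie_fraction = 0, sites = sites),
                    class = "variant_profile")
  expect_warning(out <- apply_profile_to_genes(ref, genes, prof),
                 "truncated")
  expect_equal(unname(out), "AACG")
})

test_that("simulated gene sequences are recovered through the full path", {
  cfg <- sim_config(n_hosts = 6, genome_length = 30000, variant_density = 3,
                    depth_lambda = 30, error_rate = 0.01, switch_rate = 0,
                    loss_prob = 0, seed = 4242)
  sim <- simulate_holobiont(cfg)
  flt <- filter_variants(sim$matrix, filter_config())
  profs <- build_profiles(flt$matrix)
  # random non-overlapping genes over the genome
  set.seed(1)
  starts <- seq(1000L, 25000L, by = 3000L)
  genes <- data.frame(gene_id = sprintf("g%02d", seq_along(starts)),
                      replicon = "genome", start = starts,
                      end = starts + 900L,
                      strand = rep(c("+", "-"), length.out = length(starts)),
                      stringsAsFactors = FALSE)
  truth <- sim$truth
  ref <- sim$reference
  # expected strain sequence per gene, built independently from truth
  strain_gene <- function(tip, g) {
    sites <- truth$sites[truth$geno[, tip], , drop = FALSE]
    sites <- sites[order(sites$pos, decreasing = TRUE), , drop = FALSE]
    seqg <- substr(ref[["genome"]], genes$start[g] + 1, genes$end[g])
    for (i in seq_len(nrow(sites))) {
      p <- sites$pos[i]
      if (p >= genes$start[g] && p + nchar(sites$ref[i]) <= genes$end[g]) {
        rel <- p - genes$start[g]
        seqg <- paste0(substr(seqg, 1, rel), sites$alt[i],
                       substr(seqg, rel + nchar(sites$ref[i]) + 1,
                              nchar(seqg)))
      }
    }
    if (genes$strand[g] == "-") seqg <- oracle_revcomp(seqg)
    seqg
  }
  hosts <- names(truth$presence)[truth$presence]
  checked <- 0L
  for (h in hosts[1:3]) {
    tip <- truth$samples[[h]]$strains[1]
    got <- apply_profile_to_genes(ref, genes, profs[[h]])
    for (g in seq_len(nrow(genes))) {
      expect_equal(unname(got[paste0(h, "|", genes$gene_id[g])]),
                   strain_gene(tip, g))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 20L)
})
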