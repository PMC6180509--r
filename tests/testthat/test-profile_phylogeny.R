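test_that("profile distance follows the fixed-denominator definition", {
  p <- make_profiles(cbind(rep(1L, 10), c(rep(2L, 3), rep(1L, 7))))
  expect_equal(profile_distance(p[[1]], p[[1]], 10), 0)
  expect_equal(profile_distance(p[[1]], p[[2]], 10), 0.3)
  q <- make_profiles(cbind(rep(1L, 10), rep(2L, 10)))
  expect_equal(profile_distance(q[[1]], q[[2]], 10), 1)
  expect_error(profile_distance(p[[1]], p[[2]], 0), "total_variants")
})

test_that("pairwise-missing sites leave the denominator unchanged", {
  miss <- matrix(FALSE, 10, 2)
  miss[1:2, 2] <- TRUE
  p <- make_profiles(cbind(rep(1L, 10), rep(2L, 10)), miss)
  # 8 comparable differing sites over the fixed denominator 10
  expect_equal(profile_distance(p[[1]], p[[2]], 10), 0.8)
})

test_that("profile distance is a semimetric on random profiles", {
  set.seed(88)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    idx <- matrix(sample(1:3, 30 * n, replace = TRUE), 30, n)
    miss <- matrix(runif(30 * n) < 0.05, 30, n)
    prof <- make_profiles(idx, miss)
    d <- profile_distance_matrix(prof, 30)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("3-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- neighbor_joining(d)
  bl <- setNames(t$edge.length[match(seq_along(t$tip.label),
                                     t$edge[, 2])], t$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    true <- ape::rtree(n)
    d <- ape::cophenetic.phylo(true)
    got <- neighbor_joining(d)
    expect_equal(oracle_rf(true, got), 0)
    dd <- ape::cophenetic.phylo(got)[rownames(d), colnames(d)]
    expect_lt(max(abs(dd - d)), 1e-9)
  }
})

test_that("NJ matches the ape reference implementation on additive input", {
  set.seed(203)
  for (rep in 1:5) {
    true <- ape::rtree(8)
    d <- ape::cophenetic.phylo(true)
    expect_equal(oracle_rf(neighbor_joining(d), ape::nj(d)), 0)
  }
})

test_that("NJ rejects bad input and is deterministic on all-equal matrices", {
  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  expect_error(neighbor_joining({d2 <- d; d2[1, 2] <- NaN; d2}), "NaN")
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 5)
  # internal branches all zero on a star-like matrix
  internal <- t1$edge[, 2] > length(t1$tip.label)
  expect_true(all(abs(t1$edge.length[internal]) < 1e-12))
})

test_that("negative inferred branches are clamped with deficit transfer", {
  # classic non-additive matrix producing a negative NJ branch
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 2, 9, 10, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 0.2; d["B", "A"] <- 0.2   # force negativity
  t <- neighbor_joining(d)
  expect_true(all(t$edge.length >= 0))
})

test_that("bootstrap supports: congruent signal gives 100, seeds reproduce", {
  idx <- cbind(c(rep(1L, 20), rep(2L, 20)),
               c(rep(1L, 20), rep(2L, 20)),
               c(rep(2L, 20), rep(1L, 20)),
               c(rep(2L, 20), rep(1L, 20)))
  # make the two pairs differ from each other at every site
  idx[, 3:4] <- idx[, 3:4] + 1L
  prof <- make_profiles(idx)
  t <- bootstrap_support(prof, total_variants = 40, n_reps = 50, seed = 9)
  sup <- suppressWarnings(as.numeric(t$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  t2 <- bootstrap_support(prof, total_variants = 40, n_reps = 50, seed = 9)
  expect_identical(ape::write.tree(t), ape::write.tree(t2))
  expect_error(bootstrap_support(prof, n_reps = 0), "positive")
})

test_that("conflicting site classes yield intermediate-to-high support", {
  set.seed(31)
  # 70% of sites support ((A,B),(C,D)); 30% support ((A,C),(B,D))
  n_ab <- 70; n_ac <- 30
  idx <- rbind(
    cbind(rep(2L, n_ab), rep(2L, n_ab), rep(1L, n_ab), rep(1L, n_ab)),
    cbind(rep(2L, n_ac), rep(1L, n_ac), rep(2L, n_ac), rep(1L, n_ac)))
  prof <- make_profiles(idx, samples = c("A", "B", "C", "D"))
  t <- bootstrap_support(prof, total_variants = 100, n_reps = 50, seed = 4)
  sup <- suppressWarnings(as.numeric(t$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 70))
})

test_that("outgroup rooting splits the basal branch equally", {
  t <- ape::read.tree(text = "(A:1,B:1,(C:1,D:2):1);")
  r <- root_with_outgroup(t, "D")
  expect_true(ape::is.rooted(r))
  root <- length(r$tip.label) + 1L
  basal <- which(r$edge[, 1] == root)
  expect_equal(r$edge.length[basal][1], r$edge.length[basal][2])
  # D sister to the rest
  d_edge <- which(r$edge[, 2] == which(r$tip.label == "D"))
  expect_equal(r$edge[d_edge, 1], root)

  expect_error(root_with_outgroup(t, c("A", "B", "C", "D")), "whole tip set")
  expect_error(root_with_outgroup(t, "Z"), "not in tree")
})

test_that("non-monophyletic outgroups are rejected with the tips named", {
  t <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
  expect_error(root_with_outgroup(t, c("A", "C")), "monophyletic")
  r <- root_with_outgroup(t, c("A", "B"))
  expect_true(ape::is.rooted(r))
})

test_that("unrooting a rooted tree returns the original topology", {
  set.seed(61)
  for (rep in 1:10) {
    t <- ape::unroot(ape::rtree(sample(5:10, 1)))
    og <- sample(t$tip.label, 1)
    r <- root_with_outgroup(t, og)
    expect_equal(oracle_rf(ape::unroot(r), t), 0)
  }
})

test_that("Grafen heights follow (d-1)/(n-1) exactly", {
  cherry <- ape::read.tree(text = "(A:5,B:1);")
  u <- ultrametrize_grafen(cherry)
  expect_equal(u$edge.length, c(1, 1))

  cat4 <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  u4 <- ultrametrize_grafen(cat4)
  depths <- ape::node.depth.edgelength(u4)
  expect_equal(max(depths), 1)
  # root at height 1, internal nodes at 2/3 and 1/3: tip depths all 1
  expect_equal(unname(depths[1:4]), rep(1, 4))
  # internal-node heights: cherry 1/3, its parent 2/3, root 1
  nh <- 1 - depths[5:7]
  expect_equal(sort(unname(nh)), c(1 / 3, 2 / 3, 1))
})

test_that("Grafen ultrametrization agrees with the ape reference", {
  set.seed(71)
  for (rep in 1:10) {
    t <- ape::rtree(sample(4:15, 1))
    u <- ultrametrize_grafen(t)
    depths <- ape::node.depth.edgelength(u)[seq_along(t$tip.label)]
    expect_lt(max(depths) - min(depths), 1e-9)
    ref <- ape::compute.brlen(t, method = "Grafen", power = 1)
    expect_equal(u$edge.length, ref$edge.length, tolerance = 1e-12)
  }
})

test_that("topology comparison counts bipartition differences", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(compare_topologies(t1, t1)$rf, 0)
  expect_equal(compare_topologies(t1, t2)$rf, 2)
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(compare_topologies(t1, t3), "tip sets differ")
})

test_that("RF distance equals the prop.part oracle and phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(81)
  for (rep in 1:15) {
    n <- sample(5:12, 1)
    t1 <- ape::rtree(n)
    t2 <- ape::rtree(n)
    t2$tip.label <- t1$tip.label[sample(n)]
    got <- compare_topologies(t1, t2)$rf
    expect_equal(got, oracle_rf(t1, t2))
    expect_equal(got,
                 as.numeric(phangorn::RF.dist(ape::unroot(t1),
                                              ape::unroot(t2))))
  }
})
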