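#' Simulation configuration for synthetic holobiont datasets
#'
#' The defaults define the reference simulated world: 12 host lineages, a
#' 200 kb symbiont genome at 3 variants/kb (a primary-endosymbiont-like
#' diversity), mean read depth 50x, 1% sequencing error, moderate host
#' switching and occasional loss. Variants are 95% substitutions and 5%
#' short (1-3 bp) indels under a Jukes-Cantor-like uniform model with
#' near-infinite sites (each mutation event creates a new variant site).
#'
#' @param n_hosts number of host tips (>= 2).
#' @param birth_rate Yule speciation rate for the host tree.
#' @param switch_rate expected host switches per symbiont branch.
#' @param loss_prob per-branch probability that the symbiont lineage dies.
#' @param variant_density target variants per kilobase across the dataset.
#' @param genome_length symbiont genome length in bp (>= 1000).
#' @param depth_lambda mean per-position read depth (Poisson).
#' @param error_rate per-base miscall probability (< 0.5).
#' @param pool_sizes optional integer vector; each entry adds a pooled
#'   sample mixing that many infected hosts with symmetric-Dirichlet
#'   weights.
#' @param coinfection optional numeric pair `c(depth_major, depth_minor)`;
#'   adds one sample carrying the two most divergent strains at those mean
#'   depths.
#' @param seed integer seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_hosts = 12, birth_rate = 1, switch_rate = 0.5,
                       loss_prob = 0.1, variant_density = 3,
                       genome_length = 200000L, depth_lambda = 50,
                       error_rate = 0.01, pool_sizes = NULL,
                       coinfection = NULL, seed = 1L) {
  stopifnot(n_hosts >= 2, birth_rate > 0, switch_rate >= 0,
            loss_prob >= 0, loss_prob <= 1, variant_density >= 0,
            genome_length >= 1000, depth_lambda >= 0,
            error_rate >= 0, error_rate < 0.5)
  structure(list(n_hosts = as.integer(n_hosts), birth_rate = birth_rate,
                 switch_rate = switch_rate, loss_prob = loss_prob,
                 variant_density = variant_density,
                 genome_length = as.integer(genome_length),
                 depth_lambda = depth_lambda, error_rate = error_rate,
                 pool_sizes = pool_sizes, coinfection = coinfection,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a host tree under a Yule process
#'
#' Pure-birth forward simulation; tips are labelled `host_001`, ... in
#' traversal order and extend to a common present time (the tree is
#' ultrametric).
#'
#' @param n_hosts number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed optional integer seed.
#' @return An [ape::phylo] rooted binary tree.
#' @export
simulate_host_tree <- function(n_hosts, birth_rate = 1, seed = NULL) {
  if (n_hosts < 2) stop("n_hosts must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  ## active lineages: list of environments so splits mutate in place
  new_node <- function(born) {
    e <- new.env(parent = emptyenv())
    e$born <- born; e$children <- NULL; e$split <- NA_real_
    e
  }
  root <- new_node(0)
  active <- list(root)
  t <- 0
  while (length(active) < n_hosts) {
    k <- length(active)
    t <- t + stats::rexp(1, birth_rate * k)
    i <- sample.int(k, 1)
    v <- active[[i]]
    v$split <- t
    v$children <- list(new_node(t), new_node(t))
    active <- c(active[-i], v$children)
  }
  t_end <- t + stats::rexp(1, birth_rate * n_hosts)
  counter <- 0L
  to_newick <- function(v) {
    if (is.null(v$children)) {
      counter <<- counter + 1L
      sprintf("host_%03d:%s", counter, fmt_brlen(t_end - v$born))
    } else {
      sprintf("(%s,%s):%s",
              to_newick(v$children[[1]]), to_newick(v$children[[2]]),
              fmt_brlen((if (is.na(v$split)) t_end else v$split) - v$born))
    }
  }
  txt <- paste0(sub(":[^:]*$", "", to_newick(root)), ";")
  ape::read.tree(text = txt)
}

#' Simulate a symbiont history along a host tree
#'
#' The symbiont lineage starts at the host root and co-diverges at every
#' host speciation. On each host branch it occupies, the lineage dies with
#' probability `loss_prob`; otherwise a Poisson(`switch_rate`) number of
#' switch events is drawn and, at the first switch time, the lineage moves
#' to a uniformly chosen contemporaneous host branch. Realized events
#' (cospeciations with both daughters surviving, switches, losses) are
#' tallied as ground truth.
#'
#' @param host a rooted, ultrametric [ape::phylo] host tree.
#' @param switch_rate expected switches per symbiont branch occupancy.
#' @param loss_prob per-branch loss probability.
#' @param seed optional integer seed.
#' @param max_retries retries when the symbiont dies out entirely.
#' @return List with `tree` (symbiont [ape::phylo]), `mapping` (named
#'   character, symbiont tip -> host tip) and `events` (named counts of
#'   `cospeciation`, `host_switch`, `loss`).
#' @export
simulate_symbiont_history <- function(host, switch_rate = 0.5,
                                      loss_prob = 0.1, seed = NULL,
                                      max_retries = 100) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(host$tip.label)
  node_time <- ape::node.depth.edgelength(host)
  edge_parent_t <- node_time[host$edge[, 1]]
  edge_child_t <- node_time[host$edge[, 2]]
  root <- n + 1L
  root_edges <- which(host$edge[, 1] == root)

  for (attempt in seq_len(max_retries)) {
    events <- c(cospeciation = 0L, host_switch = 0L, loss = 0L)
    tip_counter <- new.env(parent = emptyenv())
    mapping <- character(0)

    follow <- function(eidx, t0, len0) {
      if (stats::runif(1) < loss_prob) {
        events[["loss"]] <<- events[["loss"]] + 1L
        return(NULL)
      }
      tc <- edge_child_t[eidx]
      nsw <- stats::rpois(1, switch_rate)
      if (nsw > 0) {
        ts <- min(stats::runif(nsw, t0, tc))
        targets <- which(edge_parent_t < ts & ts < edge_child_t &
                           seq_along(edge_child_t) != eidx)
        if (length(targets) > 0) {
          events[["host_switch"]] <<- events[["host_switch"]] + 1L
          tgt <- targets[sample.int(length(targets), 1)]
          return(follow(tgt, ts, len0 + (ts - t0)))
        }
      }
      child <- host$edge[eidx, 2]
      if (child <= n) {
        hlab <- host$tip.label[child]
        cnt <- (get0(hlab, tip_counter, ifnotfound = 0L)) + 1L
        assign(hlab, cnt, tip_counter)
        lab <- if (cnt == 1L) paste0("sym_", hlab) else
          paste0("sym_", hlab, "_", cnt)
        mapping[[lab]] <<- hlab
        return(list(tip = lab, length = len0 + (tc - t0)))
      }
      kids <- which(host$edge[, 1] == child)
      l <- follow(kids[1], tc, 0)
      r <- follow(kids[2], tc, 0)
      if (is.null(l) && is.null(r)) return(NULL)
      if (is.null(l) || is.null(r)) {
        surv <- if (is.null(l)) r else l
        surv$length <- surv$length + len0 + (tc - t0)
        return(surv)
      }
      events[["cospeciation"]] <<- events[["cospeciation"]] + 1L
      list(left = l, right = r, length = len0 + (tc - t0))
    }

    l <- follow(root_edges[1], node_time[root], 0)
    r <- follow(root_edges[2], node_time[root], 0)
    if (!is.null(l) && !is.null(r)) {
      events[["cospeciation"]] <- events[["cospeciation"]] + 1L
      res <- list(left = l, right = r, length = 0)
    } else if (!is.null(l)) {
      res <- l
    } else {
      res <- r
    }
    if (is.null(res)) next
    n_tips <- length(mapping)
    if (n_tips < 2) next

    to_newick <- function(v) {
      if (!is.null(v$tip)) {
        sprintf("%s:%s", v$tip, fmt_brlen(v$length))
      } else {
        sprintf("(%s,%s):%s", to_newick(v$left), to_newick(v$right),
                fmt_brlen(v$length))
      }
    }
    txt <- if (!is.null(res$tip)) NULL else paste0(to_newick(res), ";")
    if (is.null(txt)) next  # single surviving lineage: not a tree
    tree <- ape::read.tree(text = txt)
    return(list(tree = tree, mapping = mapping, events = events))
  }
  stop("symbiont lineage died out in every attempt (", max_retries,
       " retries)")
}

## draw counts of k errors split uniformly over 3 wrong alleles; vectorized
split3 <- function(k) {
  n1 <- stats::rbinom(length(k), k, 1 / 3)
  n2 <- stats::rbinom(length(k), k - n1, 1 / 2)
  cbind(n1, n2, k - n1 - n2)
}

#' Simulate sequences, allele counts and coverage for a symbiont history
#'
#' Generates a uniform-random root genome (the reference), places mutation
#' events on the symbiont tree as a Poisson process proportional to branch
#' length (rate chosen so the expected variant count matches
#' `variant_density`), each event creating a new variant site (95%
#' substitutions, 5% 1-3 bp indels), and then simulates per-sample read
#' counts: per-position depth is Poisson(`depth_lambda`), reads report their
#' strain's allele and are miscalled with probability `error_rate` to a
#' uniformly chosen wrong base. Candidate variant sites are emitted when any
#' sample shows at least two reads of the same non-reference allele,
#' mimicking the evidence threshold of a variant caller, so the output
#' contains both true variants and error-driven false positives. Samples are
#' all host tips (uninfected hosts get zero coverage), plus optional pooled
#' and coinfected samples.
#'
#' @param history output of [simulate_symbiont_history()].
#' @param cfg a [sim_config()].
#' @param host the host tree used to generate `history`.
#' @return List with `matrix` (an [acm()]), `tracks` (per-sample list of
#'   per-replicon depth vectors), `reference` (named character), `truth`
#'   (site table, strain genotype matrix, per-sample strain composition,
#'   presence, events, trees).
#' @export
simulate_sequences_and_counts <- function(history, cfg, host) {
  set.seed(cfg$seed %% 900000000L + 7L)
  L <- cfg$genome_length
  tree <- history$tree
  tips <- tree$tip.label
  ntip <- length(tips)

  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  ## ---- mutation events -> true variant sites ---------------------------
  target <- cfg$variant_density * L / 1000
  TL <- sum(tree$edge.length)
  if (TL <= 0) stop("symbiont tree has zero total length")
  mu <- target / TL
  n_mut <- stats::rpois(nrow(tree$edge), mu * tree$edge.length)
  M <- sum(n_mut)
  if (M > L / 20) stop("variant density too high for genome length")
  occ <- logical(L)
  pos <- integer(M)
  for (i in seq_len(M)) {
    placed <- FALSE
    for (try in 1:100) {
      p <- sample.int(L - 20L, 1) + 8L
      if (!any(occ[(p - 7):(p + 7)])) {
        occ[(p - 7):(p + 7)] <- TRUE
        pos[i] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place variant sites: genome too dense")
  }
  is_indel <- stats::runif(M) < 0.05
  ref_allele <- character(M)
  alt_allele <- character(M)
  for (i in seq_len(M)) {
    p <- pos[i]
    if (!is_indel[i]) {
      ref_allele[i] <- ref[p]
      alt_allele[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[p]), 1)
    } else if (stats::runif(1) < 0.5) {  # deletion of 1-3 bp after anchor
      k <- sample.int(3, 1)
      ref_allele[i] <- paste(ref[p:(p + k)], collapse = "")
      alt_allele[i] <- ref[p]
    } else {                             # insertion of 1-3 bp after anchor
      k <- sample.int(3, 1)
      ref_allele[i] <- ref[p]
      alt_allele[i] <- paste(c(ref[p], sample(c("A", "C", "G", "T"), k,
                                              replace = TRUE)),
                             collapse = "")
    }
  }

  ## genotype: which tips carry the alt allele of each event (new site per
  ## event: alt carried by every tip below the edge the event sits on)
  geno <- matrix(FALSE, M, ntip, dimnames = list(NULL, tips))
  if (M > 0) {
    edge_of <- rep(seq_len(nrow(tree$edge)), n_mut)
    below <- node_descendant_sets_all(tree)
    for (i in seq_len(M)) {
      child <- tree$edge[edge_of[i], 2]
      geno[i, below[[child]]] <- TRUE
    }
  }

  ## ---- sample composition ---------------------------------------------
  lineages_of <- split(names(history$mapping), history$mapping)
  hosts <- host$tip.label
  presence <- stats::setNames(hosts %in% names(lineages_of), hosts)
  samples <- list()
  for (h in hosts) {
    str <- if (presence[[h]]) lineages_of[[h]] else character(0)
    samples[[h]] <- list(strains = str,
                         weights = if (length(str)) rep(1 / length(str),
                                                        length(str)) else
                           numeric(0),
                         depth = if (presence[[h]]) cfg$depth_lambda else 0)
  }
  infected <- hosts[presence]
  for (k in seq_along(cfg$pool_sizes)) {
    sz <- min(cfg$pool_sizes[k], length(infected))
    members <- sample(infected, sz)
    str <- unlist(lineages_of[members], use.names = FALSE)
    w <- stats::rgamma(length(str), 1)
    samples[[sprintf("pool_%02d", k)]] <-
      list(strains = str, weights = w / sum(w), depth = cfg$depth_lambda)
  }
  coinf_truth <- NULL
  if (!is.null(cfg$coinfection)) {
    ## pick the two most divergent strains
    if (ntip < 2) stop("coinfection needs at least two strains")
    dd <- crossprod(geno, !geno) + crossprod(!geno, geno)
    ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
    samples[["coinf_1"]] <- list(strains = tips[ij],
                                 weights = cfg$coinfection /
                                   sum(cfg$coinfection),
                                 depth = sum(cfg$coinfection))
    coinf_truth <- list(sample = "coinf_1", strains = tips[ij],
                        depths = cfg$coinfection)
  }
  sample_ids <- names(samples)
  S <- length(sample_ids)

  ## ---- coverage tracks -------------------------------------------------
  tracks <- lapply(samples, function(sm) {
    list(genome = stats::rpois(L, sm$depth))
  })

  ## ---- counts at true variant sites -----------------------------------
  err <- cfg$error_rate
  bases <- c("A", "C", "G", "T")
  ## allele slots per true site: 1 = ref, 2 = alt, 3.. = other bases (SNPs)
  other_bases <- vector("list", M)
  for (i in seq_len(M)) {
    other_bases[[i]] <- if (is_indel[i]) character(0) else
      setdiff(bases, c(ref_allele[i], alt_allele[i]))
  }
  Amax <- 4L
  true_counts <- array(0L, c(max(M, 1L), S, Amax))
  for (j in seq_len(S)) {
    sm <- samples[[j]]
    if (length(sm$strains) == 0 || M == 0) next
    dep <- tracks[[j]]$genome[pos]
    ## allocate reads among member strains
    W <- length(sm$strains)
    alloc <- if (W == 1) matrix(dep, M, 1) else
      t(vapply(seq_len(M),
               function(i) stats::rmultinom(1, dep[i], sm$weights)[, 1],
               integer(W)))
    for (w in seq_len(W)) {
      nreads <- alloc[, w]
      carries_alt <- geno[, sm$strains[w]]
      n_err <- stats::rbinom(M, nreads, err)
      good <- nreads - n_err
      ## correct reads
      slot <- ifelse(carries_alt, 2L, 1L)
      for (sl in 1:2) {
        sel <- slot == sl
        true_counts[sel, j, sl] <- true_counts[sel, j, sl] + good[sel]
      }
      ## erroneous reads: uniform over the 3 wrong alleles (SNPs); at
      ## indel sites errors flip to the opposite primary allele
      idx_indel <- which(is_indel & n_err > 0)
      if (length(idx_indel)) {
        oth <- ifelse(carries_alt[idx_indel], 1L, 2L)
        for (k in seq_along(idx_indel)) {
          i <- idx_indel[k]
          true_counts[i, j, oth[k]] <- true_counts[i, j, oth[k]] + n_err[i]
        }
      }
      idx_snp <- which(!is_indel & n_err > 0)
      if (length(idx_snp)) {
        sp <- split3(n_err[idx_snp])
        for (k in seq_along(idx_snp)) {
          i <- idx_snp[k]
          true_allele <- if (carries_alt[i]) alt_allele[i] else ref_allele[i]
          wrong <- setdiff(bases, true_allele)
          site_alleles <- c(ref_allele[i], alt_allele[i], other_bases[[i]])
          for (b in 1:3) {
            sl <- match(wrong[b], site_alleles)
            true_counts[i, j, sl] <- true_counts[i, j, sl] + sp[k, b]
          }
        }
      }
    }
  }

  ## ---- error-driven candidate sites at non-variant positions ----------
  nonvar <- rep(TRUE, L)
  nonvar[pos] <- FALSE
  E <- matrix(0L, L, S)
  for (j in seq_len(S)) {
    if (samples[[j]]$depth == 0) next
    E[, j] <- stats::rbinom(L, tracks[[j]]$genome, err)
  }
  E[!nonvar, ] <- 0L
  spl <- vector("list", S)   # per sample: pos + 3-base error split
  for (j in seq_len(S)) {
    cand <- which(E[, j] >= 2L)
    if (length(cand)) {
      spl[[j]] <- cbind(pos = cand, split3(E[cand, j]))
    }
  }
  qual_pos <- sort(unique(unlist(lapply(spl, function(x) {
    if (is.null(x)) integer(0) else x[apply(x[, 2:4, drop = FALSE], 1, max) >= 2, 1]
  }))))
  n_spur <- length(qual_pos)
  spur_counts <- array(0L, c(max(n_spur, 1L), S, Amax))
  spur_alts <- vector("list", n_spur)
  if (n_spur > 0) {
    pos_index <- stats::setNames(seq_len(n_spur), qual_pos)
    wrong_of <- lapply(qual_pos, function(p) setdiff(bases, ref[p]))
    base_cnt <- array(0L, c(n_spur, S, 3L))
    for (j in seq_len(S)) {
      x <- spl[[j]]
      if (!is.null(x)) {
        hit <- x[, 1] %in% qual_pos
        if (any(hit)) {
          r <- pos_index[as.character(x[hit, 1])]
          base_cnt[r, j, ] <- base_cnt[r, j, , drop = FALSE] +
            array(x[hit, 2:4], c(length(r), 1, 3))
        }
      }
      ## single stray errors at qualifying positions: random wrong base
      one <- which(E[, j] == 1L)
      one <- one[one %in% qual_pos]
      if (length(one)) {
        r <- pos_index[as.character(one)]
        b <- sample.int(3, length(one), replace = TRUE)
        for (k in seq_along(one)) {
          base_cnt[r[k], j, b[k]] <- base_cnt[r[k], j, b[k]] + 1L
        }
      }
    }
    for (i in seq_len(n_spur)) {
      seen <- which(colSums(matrix(base_cnt[i, , ], S, 3)) > 0)
      spur_alts[[i]] <- wrong_of[[i]][seen]
      for (j in seq_len(S)) {
        spur_counts[i, j, 1] <- tracks[[j]]$genome[qual_pos[i]] - E[qual_pos[i], j]
        spur_counts[i, j, 1 + seq_along(seen)] <- base_cnt[i, j, seen]
      }
    }
  }

  ## ---- assemble the acm ------------------------------------------------
  true_alts <- vector("list", M)
  for (i in seq_len(M)) {
    extra <- other_bases[[i]][colSums(matrix(true_counts[i, ,
                                                         2 + seq_along(other_bases[[i]])],
                                             S)) > 0]
    true_alts[[i]] <- c(alt_allele[i], extra)
  }
  all_pos <- c(pos, qual_pos)
  all_ref <- c(ref_allele, ref[qual_pos])
  all_alts <- c(true_alts, spur_alts)
  ord <- order(all_pos)
  n_all <- length(all_pos)
  depths <- array(0L, c(n_all, S, Amax))
  for (r in seq_len(n_all)) {
    i <- ord[r]
    if (i <= M) {
      sa <- c(ref_allele[i], alt_allele[i], other_bases[[i]])
      keep <- c(1L, 1L + match(true_alts[[i]], sa[-1]))
      depths[r, , seq_along(keep)] <- true_counts[i, , keep]
    } else {
      k <- i - M
      depths[r, , seq_len(1 + length(spur_alts[[k]]))] <-
        spur_counts[k, , seq_len(1 + length(spur_alts[[k]]))]
    }
  }
  sites <- data.frame(replicon = "genome", pos = all_pos[ord] - 1L,
                      ref = all_ref[ord], stringsAsFactors = FALSE)
  sites$alts <- all_alts[ord]
  m <- acm(sites, sample_ids, depths)

  truth_sites <- data.frame(replicon = "genome", pos = pos - 1L,
                            ref = ref_allele, alt = alt_allele,
                            indel = is_indel, stringsAsFactors = FALSE)
  list(matrix = m,
       tracks = tracks,
       reference = c(genome = paste(ref, collapse = "")),
       truth = list(sites = truth_sites, geno = geno,
                    samples = samples, presence = presence,
                    events = history$events, tree = tree,
                    mapping = history$mapping, host = host,
                    coinfection = coinf_truth))
}

## tip labels below every node (tips and internals)
node_descendant_sets_all <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

#' Simulate a full holobiont dataset
#'
#' Chains [simulate_host_tree()], [simulate_symbiont_history()] and
#' [simulate_sequences_and_counts()] under one seed.
#'
#' @param cfg a [sim_config()].
#' @return See [simulate_sequences_and_counts()].
#' @export
simulate_holobiont <- function(cfg) {
  host <- simulate_host_tree(cfg$n_hosts, cfg$birth_rate,
                             seed = cfg$seed %% 900000000L + 1L)
  hist <- simulate_symbiont_history(host, cfg$switch_rate, cfg$loss_prob,
                                    seed = cfg$seed %% 900000000L + 3L)
  simulate_sequences_and_counts(hist, cfg, host)
}

#' Simulate allele counts for a single (possibly coinfected) sample
#'
#' Focused generator for the coinfection detector's operating
#' characteristics: `n_sites` biallelic sites at which a resident strain
#' carries the reference allele and a second, divergent strain carries the
#' alternative. With `depth_minor = NULL` the sample is mono-strain (the
#' alternative allele then only ever appears through sequencing error).
#' Per-site strain depths are Poisson; each read is miscalled to a uniform
#' wrong base with probability `error_rate`.
#'
#' @param n_sites number of variant sites.
#' @param depth_major mean depth of the resident (major) strain.
#' @param depth_minor mean depth of the second strain, or `NULL` for a
#'   mono-strain sample.
#' @param error_rate per-base miscall probability.
#' @param seed optional integer seed.
#' @param sample sample identifier.
#' @return An [acm()] with one sample.
#' @export
simulate_coinfection_counts <- function(n_sites, depth_major,
                                        depth_minor = NULL,
                                        error_rate = 0.01, seed = NULL,
                                        sample = "S1") {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  refb <- sample(bases, n_sites, replace = TRUE)
  altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1), character(1))
  d1 <- stats::rpois(n_sites, depth_major)
  d2 <- if (is.null(depth_minor)) integer(n_sites) else
    stats::rpois(n_sites, depth_minor)
  counts <- array(0L, c(n_sites, 1, 4))
  for (i in seq_len(n_sites)) {
    row <- stats::setNames(integer(4), c(refb[i], altb[i],
                                         setdiff(bases, c(refb[i], altb[i]))))
    for (src in 1:2) {
      nn <- if (src == 1) d1[i] else d2[i]
      al <- if (src == 1) refb[i] else altb[i]
      ne <- stats::rbinom(1, nn, error_rate)
      row[al] <- row[al] + nn - ne
      if (ne > 0) {
        wrong <- setdiff(bases, al)
        sp <- stats::rmultinom(1, ne, rep(1 / 3, 3))[, 1]
        row[wrong] <- row[wrong] + sp
      }
    }
    counts[i, 1, ] <- row
  }
  sites <- data.frame(replicon = "genome",
                      pos = seq_len(n_sites) * 10L,
                      ref = refb, stringsAsFactors = FALSE)
  sites$alts <- lapply(seq_len(n_sites), function(i)
    c(altb[i], setdiff(bases, c(refb[i], altb[i]))))
  acm(sites, sample, counts)
}
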