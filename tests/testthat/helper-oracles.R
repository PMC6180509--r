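# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops or enumeration, sharing no code with the
# package implementations they check.

# --- coverage -----------------------------------------------------------

oracle_coverage_summary <- function(depths) {
  n <- length(depths)
  s <- 0; b5 <- 0; lt2 <- 0
  for (d in depths) {
    s <- s + d
    if (d >= 5) b5 <- b5 + 1
    if (d < 2) lt2 <- lt2 + 1
  }
  list(mean_depth = s / n, breadth_ge5 = b5 / n, frac_lt2 = lt2 / n)
}

# --- filter rules -------------------------------------------------------

# naive per-element rare-allele filter on an acm; returns depth array + keep
oracle_rare_filter <- function(m, min_reads = 4, min_freq = 0.10) {
  d <- m$depths
  nal <- 1L + lengths(m$sites$alts)
  for (i in seq_len(nrow(m$sites))) {
    for (j in seq_along(m$samples)) {
      tot <- sum(d[i, j, seq_len(nal[i])])
      for (a in seq_len(nal[i])[-1]) {
        dep <- d[i, j, a]
        f <- if (tot > 0) dep / tot else 0
        if (dep < min_reads || f < min_freq) d[i, j, a] <- 0L
      }
    }
  }
  keep <- logical(nrow(m$sites))
  for (i in seq_len(nrow(m$sites))) {
    keep[i] <- sum(d[i, , seq_len(nal[i])[-1]]) > 0
  }
  list(depths = d, keep = keep)
}

oracle_lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]

# naive extreme-coverage mask: returns per-site reason ("", "low", "high")
oracle_extreme_mask <- function(m, quantile_frac = 0.75, high_factor = 5,
                                incl = seq_along(m$samples)) {
  tot <- matrix(0, nrow(m$sites), length(m$samples))
  nal <- 1L + lengths(m$sites$alts)
  for (i in seq_len(nrow(m$sites))) {
    for (j in seq_along(m$samples)) {
      tot[i, j] <- sum(m$depths[i, j, seq_len(nal[i])])
    }
  }
  med <- sapply(incl, function(j) oracle_lower_median(tot[, j]))
  reason <- character(nrow(m$sites))
  for (i in seq_len(nrow(m$sites))) {
    nlow <- 0; nhigh <- 0
    for (k in seq_along(incl)) {
      if (tot[i, incl[k]] < med[k]) nlow <- nlow + 1
      if (tot[i, incl[k]] >= high_factor * med[k]) nhigh <- nhigh + 1
    }
    if (nlow / length(incl) >= quantile_frac) reason[i] <- "low"
    else if (nhigh / length(incl) >= quantile_frac) reason[i] <- "high"
  }
  reason
}

# naive O(sites x intervals) overlap
oracle_mask_overlap <- function(sites, mask) {
  drop <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    for (k in seq_len(nrow(mask))) {
      if (sites$replicon[i] == mask$replicon[k] &&
          sites$pos[i] >= mask$start[k] && sites$pos[i] < mask$end[k]) {
        drop[i] <- TRUE
      }
    }
  }
  drop
}

# --- profiles -----------------------------------------------------------

# O(n^2) pairwise-equality partition of profiles
oracle_dedup_partition <- function(profiles) {
  n <- length(profiles)
  ids <- sapply(profiles, function(p) p$sample)
  eq <- function(p, q) {
    a <- ifelse(p$missing, NA_integer_, p$allele_idx)
    b <- ifelse(q$missing, NA_integer_, q$allele_idx)
    identical(a, b)
  }
  comp <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[i] <- cid
      if (i < n) for (j in (i + 1):n) {
        if (comp[j] == 0L && eq(profiles[[i]], profiles[[j]])) comp[j] <- cid
      }
    }
  }
  unname(lapply(split(ids, comp), sort))
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# --- trees --------------------------------------------------------------

# bipartition keys via ape::prop.part (independent of the package's
# edge-walking implementation)
oracle_bipartitions <- function(tree) {
  tips <- tree$tip.label
  refs <- sort(tips)[1]
  pp <- ape::prop.part(ape::unroot(tree))
  keys <- character(0)
  for (side in pp) {
    lab <- attr(pp, "labels")[side]
    if (length(lab) < 2 || length(lab) > length(tips) - 2) next
    if (refs %in% lab) lab <- setdiff(tips, lab)
    keys <- c(keys, paste(sort(lab), collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# --- cophylogeny: exhaustive enumeration over internal-node mappings ----

# Event model per internal symbiont node p at host image h with child
# images g1, g2: cospeciation (children in distinct child subtrees of h,
# losses from the respective host child down), duplication (both children
# in subtree(h), losses from h down), host switch (exactly one child lands
# on a host node incomparable to h, no losses for the jumper). Both
# children leaving is invalid.
oracle_reconcile_cost <- function(host, symbiont, mapping, costs) {
  hn <- length(host$tip.label) + host$Nnode
  parent <- rep(0L, hn)
  for (k in seq_len(nrow(host$edge))) parent[host$edge[k, 2]] <- host$edge[k, 1]
  # DESC[a, b]: a ancestor-or-self of b; DIST: edge distance when related
  DESC <- matrix(FALSE, hn, hn)
  DIST <- matrix(NA_integer_, hn, hn)
  for (b in seq_len(hn)) {
    v <- b; d <- 0L
    repeat {
      DESC[v, b] <- TRUE
      DIST[v, b] <- d
      if (parent[v] == 0L) break
      v <- parent[v]; d <- d + 1L
    }
  }
  kids <- vector("list", hn)
  for (k in seq_len(nrow(host$edge))) {
    kids[[host$edge[k, 1]]] <- c(kids[[host$edge[k, 1]]], host$edge[k, 2])
  }

  sn <- length(symbiont$tip.label) + symbiont$Nnode
  skids <- vector("list", sn)
  for (k in seq_len(nrow(symbiont$edge))) {
    skids[[symbiont$edge[k, 1]]] <- c(skids[[symbiont$edge[k, 1]]],
                                      symbiont$edge[k, 2])
  }
  internal <- (length(symbiont$tip.label) + 1):sn
  tip_img <- match(mapping[symbiont$tip.label], host$tip.label)

  grid <- as.matrix(expand.grid(rep(list(seq_len(hn)), length(internal))))
  colnames(grid) <- as.character(internal)
  img_of <- function(node) {
    if (node <= length(symbiont$tip.label)) {
      rep(tip_img[node], nrow(grid))
    } else grid[, as.character(node)]
  }

  total <- rep(0, nrow(grid))
  cc <- costs$cospeciation; cd <- costs$duplication
  cs <- costs$host_switch; cl <- costs$loss
  for (p in internal) {
    h <- img_of(p)
    g1 <- img_of(skids[[p]][1])
    g2 <- img_of(skids[[p]][2])
    v1 <- DESC[cbind(h, g1)]
    v2 <- DESC[cbind(h, g2)]
    comp1 <- v1 | DESC[cbind(g1, h)]
    comp2 <- v2 | DESC[cbind(g2, h)]
    cost_p <- rep(Inf, nrow(grid))

    both <- v1 & v2
    if (any(both)) {
      idx <- which(both)
      hh <- h[idx]
      kid1 <- vapply(kids, function(k) if (length(k) == 2) k[1] else NA_integer_,
                     integer(1))
      kid2 <- vapply(kids, function(k) if (length(k) == 2) k[2] else NA_integer_,
                     integer(1))
      cL <- kid1[hh]; cR <- kid2[hh]
      dup <- cd + cl * (DIST[cbind(hh, g1[idx])] + DIST[cbind(hh, g2[idx])])
      safe_desc <- function(a, b) {
        ok <- !is.na(a)
        out <- rep(FALSE, length(a))
        out[ok] <- DESC[cbind(a[ok], b[ok])]
        out
      }
      safe_dist <- function(a, b) {
        out <- rep(NA_real_, length(a))
        ok <- !is.na(a)
        out[ok] <- DIST[cbind(a[ok], b[ok])]
        out
      }
      ev1 <- cc + cl * (safe_dist(cL, g1[idx]) + safe_dist(cR, g2[idx]))
      ev1[!(safe_desc(cL, g1[idx]) & safe_desc(cR, g2[idx]))] <- Inf
      ev1[is.na(ev1)] <- Inf
      ev2 <- cc + cl * (safe_dist(cR, g1[idx]) + safe_dist(cL, g2[idx]))
      ev2[!(safe_desc(cR, g1[idx]) & safe_desc(cL, g2[idx]))] <- Inf
      ev2[is.na(ev2)] <- Inf
      cost_p[idx] <- pmin(dup, ev1, ev2)
    }
    sw1 <- v1 & !comp2   # child 2 jumps
    if (any(sw1)) {
      idx <- which(sw1)
      cand <- cs + cl * DIST[cbind(h[idx], g1[idx])]
      cost_p[idx] <- pmin(cost_p[idx], cand)
    }
    sw2 <- v2 & !comp1   # child 1 jumps
    if (any(sw2)) {
      idx <- which(sw2)
      cand <- cs + cl * DIST[cbind(h[idx], g2[idx])]
      cost_p[idx] <- pmin(cost_p[idx], cand)
    }
    total <- total + cost_p
  }
  min(total)
}
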