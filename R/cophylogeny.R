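#' Event costs for reconciliation
#'
#' Default scheme: cospeciation 0, duplication 1, host switch 1, loss
#' (sorting event) 1.
#'
#' @param cospeciation,duplication,host_switch,loss non-negative unit costs.
#' @return A list of class `cost_scheme`.
#' @export
cost_scheme <- function(cospeciation = 0, duplication = 1,
                        host_switch = 1, loss = 1) {
  stopifnot(cospeciation >= 0, duplication >= 0, host_switch >= 0, loss >= 0)
  structure(list(cospeciation = cospeciation, duplication = duplication,
                 host_switch = host_switch, loss = loss),
            class = "cost_scheme")
}

#' Prune symbiont tips that cannot be reconciled reliably
#'
#' Symbiont tips whose sample has presence status `present_low` (detected
#' but with coverage too thin for reliable variant calling) are removed from
#' the symbiont tree, so they are not miscounted as losses. Samples where
#' the symbiont is absent stay in the host tree as true absences. Degree-2
#' nodes created by pruning are suppressed with branch lengths summed.
#'
#' @param host host [ape::phylo] tree (unchanged, returned for symmetry).
#' @param symbiont symbiont [ape::phylo] tree.
#' @param presence named character vector: status per host sample for this
#'   symbiont (`absent`, `present_low`, `analysable`).
#' @param mapping named character vector symbiont tip -> host tip.
#' @return List with `host`, `symbiont` (pruned) and `mapping` (subset).
#' @export
prune_unusable_tips <- function(host, symbiont, presence, mapping) {
  stopifnot(all(symbiont$tip.label %in% names(mapping)))
  status <- presence[mapping[symbiont$tip.label]]
  drop <- symbiont$tip.label[!is.na(status) & status == "present_low"]
  if (length(drop) == length(symbiont$tip.label)) {
    stop("pruning would remove every symbiont tip")
  }
  pruned <- if (length(drop) > 0) ape::drop.tip(symbiont, drop) else symbiont
  list(host = host, symbiont = pruned,
       mapping = mapping[pruned$tip.label])
}

## internal: structural tables for a rooted binary phylo
tree_tables <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  children <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    children[[tree$edge[k, 1]]] <- c(children[[tree$edge[k, 1]]],
                                     tree$edge[k, 2])
  }
  root <- n + 1L
  depth <- integer(nn)
  ord <- integer(0)
  stack <- root
  while (length(stack) > 0) {          # preorder
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (c in children[[v]]) {
      depth[c] <- depth[v] + 1L
      stack <- c(stack, c)
    }
  }
  post <- rev(ord)
  ## desc[a, b]: is a an ancestor-or-self of b
  desc <- matrix(FALSE, nn, nn)
  for (v in post) {
    desc[v, v] <- TRUE
    for (c in children[[v]]) desc[v, ] <- desc[v, ] | desc[c, ]
  }
  comparable <- desc | t(desc)
  list(n_tip = n, n_node = nn, root = root, children = children,
       post = post, depth = depth, desc = desc, comparable = comparable)
}

## internal fast path: minimal DP cost given precomputed tables and
## tip images (host node index per symbiont tip, in tip order)
dtl_cost <- function(H, P, tip_img, costs) {
  nh <- H$n_node
  cl <- costs$loss; cc <- costs$cospeciation
  cd <- costs$duplication; cs <- costs$host_switch
  C <- matrix(Inf, P$n_node, nh)
  A <- matrix(Inf, P$n_node, nh)
  for (p in P$post) {
    if (p <= P$n_tip) {
      crow <- rep(Inf, nh)
      crow[tip_img[p]] <- 0
    } else {
      kids <- P$children[[p]]
      a <- kids[1]; b <- kids[2]
      outA <- vapply(seq_len(nh), function(h) {
        v <- C[a, !H$comparable[h, ]]
        if (length(v) == 0) Inf else min(v)
      }, numeric(1))
      outB <- vapply(seq_len(nh), function(h) {
        v <- C[b, !H$comparable[h, ]]
        if (length(v) == 0) Inf else min(v)
      }, numeric(1))
      crow <- rep(Inf, nh)
      for (h in seq_len(nh)) {
        best <- cd + A[a, h] + A[b, h]
        sw <- cs + min(A[a, h] + outB[h], A[b, h] + outA[h])
        if (sw < best) best <- sw
        hk <- H$children[[h]]
        if (length(hk) == 2) {
          co <- cc + min(A[a, hk[1]] + A[b, hk[2]],
                         A[a, hk[2]] + A[b, hk[1]])
          if (co < best) best <- co
        }
        crow[h] <- best
      }
    }
    C[p, ] <- crow
    arow <- crow
    for (h in H$post) {
      for (ch in H$children[[h]]) arow[h] <- min(arow[h], arow[ch] + cl)
    }
    A[p, ] <- arow
  }
  min(C[P$root, ])
}

check_binary_rooted <- function(tree, what) {
  if (length(tree$tip.label) >= 2 &&
      (!ape::is.rooted(tree) || !ape::is.binary(tree))) {
    stop(what, " tree must be rooted and binary")
  }
}

#' Reconcile a symbiont tree with its host tree (exact event-cost DP)
#'
#' Computes the minimal total cost of mapping the symbiont phylogeny onto
#' the host phylogeny under the four-event model (cospeciation, duplication,
#' host switch, loss), by an exact dynamic program over symbiont nodes and
#' host nodes. Host switches may land on any host node not ancestrally
#' related to the current one; no transfer time-consistency is enforced, so
#' a reported optimum may include switches a time-aware method would forbid.
#' Branch lengths are ignored.
#'
#' Event counts describe one optimal reconciliation; ties are broken by the
#' event priority cospeciation > loss > switch > duplication, then by the
#' smallest host-node index.
#'
#' @param host,symbiont rooted binary [ape::phylo] trees. A single-tip
#'   symbiont may be given as a character scalar (its tip name).
#' @param mapping named character vector symbiont tip -> host tip (total on
#'   symbiont tips; many-to-one allowed).
#' @param costs a [cost_scheme()].
#' @param count_events if `FALSE`, only the minimal cost is returned
#'   (faster; used by the permutation test).
#' @return A list of class `reconciliation` with `cost` and (when counted)
#'   `events` (named integer vector) and `root_host` (host node index of the
#'   symbiont root in the reported optimum).
#' @export
reconcile <- function(host, symbiont, mapping, costs = cost_scheme(),
                      count_events = TRUE) {
  if (is.character(symbiont) && length(symbiont) == 1) {
    if (!symbiont %in% names(mapping)) stop("mapping misses tip ", symbiont)
    return(structure(list(cost = 0, events = c(cospeciation = 0L,
                                               duplication = 0L,
                                               host_switch = 0L, loss = 0L)),
                     class = "reconciliation"))
  }
  check_binary_rooted(host, "host")
  check_binary_rooted(symbiont, "symbiont")
  if (!all(symbiont$tip.label %in% names(mapping))) {
    stop("mapping misses symbiont tip(s): ",
         paste(setdiff(symbiont$tip.label, names(mapping)), collapse = ", "))
  }
  if (!all(mapping[symbiont$tip.label] %in% host$tip.label)) {
    stop("mapping images outside host tips: ",
         paste(setdiff(mapping[symbiont$tip.label], host$tip.label),
               collapse = ", "))
  }

  H <- tree_tables(host)
  P <- tree_tables(symbiont)
  nh <- H$n_node
  cl <- costs$loss; cc <- costs$cospeciation
  cd <- costs$duplication; cs <- costs$host_switch

  ## C[p, h]: min cost of symbiont subtree p given p is mapped on h
  ## A[p, h]: min over h' in subtree(h) of C[p, h'] + loss * dist(h, h')
  C <- matrix(Inf, P$n_node, nh)
  A <- matrix(Inf, P$n_node, nh)
  host_tip_idx <- stats::setNames(seq_len(H$n_tip), host$tip.label)

  fill_A <- function(crow) {
    a <- crow
    for (h in H$post) {
      for (ch in H$children[[h]]) a[h] <- min(a[h], a[ch] + cl)
    }
    a
  }
  out_min <- function(crow) {
    vapply(seq_len(nh), function(h) {
      v <- crow[!H$comparable[h, ]]
      if (length(v) == 0) Inf else min(v)
    }, numeric(1))
  }

  for (p in P$post) {
    if (p <= P$n_tip) {
      crow <- rep(Inf, nh)
      crow[host_tip_idx[[mapping[[symbiont$tip.label[p]]]]]] <- 0
      C[p, ] <- crow
      A[p, ] <- fill_A(crow)
    } else {
      kids <- P$children[[p]]
      a <- kids[1]; b <- kids[2]
      outA <- out_min(C[a, ])
      outB <- out_min(C[b, ])
      crow <- rep(Inf, nh)
      for (h in seq_len(nh)) {
        best <- cd + A[a, h] + A[b, h]                       # duplication
        sw <- cs + min(A[a, h] + outB[h], A[b, h] + outA[h]) # host switch
        if (sw < best) best <- sw
        hk <- H$children[[h]]
        if (length(hk) == 2) {                               # cospeciation
          co <- cc + min(A[a, hk[1]] + A[b, hk[2]],
                         A[a, hk[2]] + A[b, hk[1]])
          if (co < best) best <- co
        }
        crow[h] <- best
      }
      C[p, ] <- crow
      A[p, ] <- fill_A(crow)
    }
  }

  proot <- P$root
  total <- min(C[proot, ])
  if (!count_events) {
    return(structure(list(cost = total), class = "reconciliation"))
  }

  ## ---- backtrack one optimal solution -----------------------------------
  counts <- c(cospeciation = 0L, duplication = 0L, host_switch = 0L,
              loss = 0L)
  eps <- 1e-9

  ## follow A[p, h]: descend (counting losses) to the node achieving the min
  resolve_A <- function(p, h) {
    d <- 0L
    repeat {
      if (C[p, h] <= A[p, h] + eps) break
      moved <- FALSE
      for (ch in H$children[[h]]) {
        if (A[p, ch] + cl <= A[p, h] + eps) {
          h <- ch; d <- d + 1L; moved <- TRUE; break
        }
      }
      if (!moved) break
    }
    counts[["loss"]] <<- counts[["loss"]] + d
    h
  }

  expand <- function(p, h) {
    if (p <= P$n_tip) return(invisible(NULL))
    kids <- P$children[[p]]
    a <- kids[1]; b <- kids[2]
    target <- C[p, h]
    hk <- H$children[[h]]
    ## priority: cospeciation first
    if (length(hk) == 2) {
      for (pairing in list(c(1, 2), c(2, 1))) {
        if (cc + A[a, hk[pairing[1]]] + A[b, hk[pairing[2]]] <= target + eps) {
          counts[["cospeciation"]] <<- counts[["cospeciation"]] + 1L
          ha <- resolve_A(a, hk[pairing[1]])
          hb <- resolve_A(b, hk[pairing[2]])
          expand(a, ha); expand(b, hb)
          return(invisible(NULL))
        }
      }
    }
    ## then host switch
    outB_nodes <- which(!H$comparable[h, ])
    for (opt in list(list(stay = a, move = b), list(stay = b, move = a))) {
      stay_cost <- A[opt$stay, h]
      for (hh in outB_nodes[order(outB_nodes)]) {
        if (cs + stay_cost + C[opt$move, hh] <= target + eps) {
          counts[["host_switch"]] <<- counts[["host_switch"]] + 1L
          hs <- resolve_A(opt$stay, h)
          expand(opt$stay, hs)
          expand(opt$move, hh)
          return(invisible(NULL))
        }
      }
    }
    ## finally duplication
    if (cd + A[a, h] + A[b, h] <= target + eps) {
      counts[["duplication"]] <<- counts[["duplication"]] + 1L
      ha <- resolve_A(a, h)
      hb <- resolve_A(b, h)
      expand(a, ha); expand(b, hb)
      return(invisible(NULL))
    }
    stop("internal error: backtracking found no optimal event at (",
         p, ", ", h, ")")
  }

  root_candidates <- which(C[proot, ] <= total + eps)
  h0 <- root_candidates[1]
  expand(proot, h0)
  check <- counts[["cospeciation"]] * cc + counts[["duplication"]] * cd +
    counts[["host_switch"]] * cs + counts[["loss"]] * cl
  if (abs(check - total) > 1e-6) {
    stop("internal error: event counts (cost ", check,
         ") disagree with DP cost ", total)
  }
  structure(list(cost = total, events = counts, root_host = h0),
            class = "reconciliation")
}

#' Permutation test for cospeciation signal
#'
#' The observed reconciliation cost is compared with the costs obtained
#' after permuting the images of the tip mapping uniformly at random
#' `n_perm` times. The p-value uses the add-one estimator
#' `p = (1 + #\{permuted cost <= observed\}) / (n_perm + 1)`. A small
#' p-value means the observed co-diversification is cheaper than expected
#' by chance, i.e. a significant cospeciation signal.
#'
#' @inheritParams reconcile
#' @param n_perm number of permutations (default 500).
#' @param seed optional integer seed.
#' @return A list of class `cospeciation_test` with `p_value`,
#'   `observed_cost`, `permuted_costs` and `n_perm`.
#' @export
cospeciation_test <- function(host, symbiont, mapping,
                              costs = cost_scheme(), n_perm = 500,
                              seed = NULL) {
  if (n_perm <= 0) stop("n_perm must be positive")
  if (!is.null(seed)) set.seed(seed)
  check_binary_rooted(host, "host")
  check_binary_rooted(symbiont, "symbiont")
  H <- tree_tables(host)
  P <- tree_tables(symbiont)
  tips <- symbiont$tip.label
  phi <- mapping[tips]
  host_tip_idx <- stats::setNames(seq_len(H$n_tip), host$tip.label)
  img <- unname(host_tip_idx[phi])
  if (anyNA(img)) stop("mapping images outside host tips")
  obs <- dtl_cost(H, P, img, costs)
  perm_costs <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm_costs[i] <- dtl_cost(H, P, sample(img), costs)
  }
  structure(list(
    p_value = (1 + sum(perm_costs <= obs)) / (n_perm + 1),
    observed_cost = obs,
    permuted_costs = perm_costs,
    n_perm = n_perm
  ), class = "cospeciation_test")
}
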