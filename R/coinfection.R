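#' Collect intra-sample polymorphic sites
#'
#' After filtering, a site is intra-sample polymorphic when at least two
#' alleles retain nonzero depth in the sample. The two largest depths are
#' recorded as the major and minor allele depths, together with the allele
#' slots they belong to, for later depth-based phasing.
#'
#' @param m a filtered [acm()] object.
#' @param sample sample identifier.
#' @return A list of class `poly_sites` with `sample`, `site` (row indices
#'   into `m$sites`), `major`, `minor` (depths), `major_allele`,
#'   `minor_allele` (allele slot indices, 1 = reference), and `sites` (site
#'   table).
#' @export
collect_polymorphic_sites <- function(m, sample) {
  j <- match(sample, m$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  n <- n_sites(m)
  A <- dim(m$depths)[3]
  d <- matrix(m$depths[, j, ], n, A)
  pos_cnt <- rowSums(d > 0)
  sel <- which(pos_cnt >= 2 & !m$missing[, j])
  major <- integer(length(sel)); minor <- integer(length(sel))
  major_a <- integer(length(sel)); minor_a <- integer(length(sel))
  for (k in seq_along(sel)) {
    row <- d[sel[k], ]
    o <- order(row, seq_along(row) != 1L, decreasing = TRUE)  # ref wins ties
    major[k] <- row[o[1]]; minor[k] <- row[o[2]]
    major_a[k] <- o[1]; minor_a[k] <- o[2]
  }
  structure(list(sample = sample, site = sel, major = major, minor = minor,
                 major_allele = major_a, minor_allele = minor_a,
                 sites = m$sites),
            class = "poly_sites")
}

poisson_loglik <- function(x, lambda) sum(stats::dpois(x, lambda, log = TRUE))

## EM for a 2-component Poisson mixture; returns loglik, means, weights
em_pois2 <- function(x, l1, l2, w = 0.5, tol = 1e-8, max_iter = 500) {
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- stats::dpois(x, l1) * w
    d2 <- stats::dpois(x, l2) * (1 - w)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    w <- mean(g)
    if (w <= 0 || w >= 1) break
    l1 <- sum(g * x) / sum(g)
    l2 <- sum((1 - g) * x) / sum(1 - g)
    if (l1 <= 0) l1 <- 1e-6
    if (l2 <= 0) l2 <- 1e-6
    ll <- sum(log(stats::dpois(x, l1) * w + stats::dpois(x, l2) * (1 - w) +
                    .Machine$double.xmin))
    if (abs(ll - ll_old) < tol) {
      return(list(loglik = ll, means = c(l1, l2), weights = c(w, 1 - w),
                  converged = TRUE, iter = it))
    }
    ll_old <- ll
  }
  list(loglik = ll_old, means = c(l1, l2), weights = c(w, 1 - w),
       converged = FALSE, iter = max_iter)
}

#' Fit a 1- vs 2-component Poisson mixture to allele depths
#'
#' Pools the major and minor allele depths of a sample's polymorphic sites
#' and fits Poisson mixtures with one and two components (EM with 50 seeded
#' quantile-based restarts, convergence when the log-likelihood changes by
#' less than 1e-8, at most 500 iterations). The sample is called `bi`
#' (two coexisting strains) only when all three gates hold: at least
#' `min_sites` polymorphic sites, BIC of the 2-component fit beats the
#' 1-component fit by more than `delta_bic`, and the component means are
#' separated by at least `min_ratio`. The two component means are the
#' estimated strain depths.
#'
#' @param s a `poly_sites` object from [collect_polymorphic_sites()].
#' @param min_sites minimum number of polymorphic sites (default 100).
#' @param seed optional integer seed (restart initializations).
#' @param delta_bic required BIC improvement of k = 2 over k = 1 (default 10).
#' @param min_ratio required ratio of the larger to smaller mean (default 2).
#' @param n_restarts number of EM restarts (default 50).
#' @return A list of class `mixture_fit` with `k`, `call` (`"mono"` or
#'   `"bi"`), `means` (descending for k = 2), `weights`, `bic` (named, k1
#'   and k2), `delta_bic`, `n_sites`, and `reason` when gated out.
#' @export
fit_depth_mixture <- function(s, min_sites = 100, seed = NULL,
                              delta_bic = 10, min_ratio = 2,
                              n_restarts = 50) {
  x <- c(s$major, s$minor)
  ns <- length(s$site)
  if (ns < min_sites) {
    return(structure(list(k = 1L, call = "mono", reason = "insufficient sites",
                          means = if (ns > 0) mean(x) else NA_real_,
                          weights = 1, bic = c(k1 = NA_real_, k2 = NA_real_),
                          delta_bic = NA_real_, n_sites = ns),
                     class = "mixture_fit"))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  lam1 <- mean(x)
  ll1 <- poisson_loglik(x, lam1)
  bic1 <- -2 * ll1 + log(n)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    qs <- sort(stats::runif(2))
    init <- stats::quantile(x, probs = qs, names = FALSE, type = 1)
    init <- pmax(init, 0.5)
    if (init[1] == init[2]) init[2] <- init[2] + 1
    fit <- em_pois2(x, init[2], init[1])
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best) || !is.finite(best$loglik)) {
    stop("EM failed to produce a finite log-likelihood (n = ", n, ")")
  }
  ll2 <- best$loglik
  bic2 <- -2 * ll2 + 3 * log(n)
  o <- order(best$means, decreasing = TRUE)
  means2 <- best$means[o]
  weights2 <- best$weights[o]
  dbic <- bic1 - bic2
  ratio <- means2[1] / max(means2[2], 1e-12)
  is_bi <- (bic2 < bic1 - delta_bic) && (ratio >= min_ratio)
  structure(list(
    k = if (is_bi) 2L else 1L,
    call = if (is_bi) "bi" else "mono",
    reason = if (is_bi) NULL else "2-component fit not supported",
    means = if (is_bi) means2 else lam1,
    weights = if (is_bi) weights2 else 1,
    means_k2 = means2, weights_k2 = weights2,
    bic = c(k1 = bic1, k2 = bic2),
    delta_bic = dbic,
    n_sites = ns
  ), class = "mixture_fit")
}

#' Phase polymorphic alleles into two strains by depth
#'
#' For each polymorphic site, the allele whose depth is more likely under
#' the high-mean component is assigned to strain 1 and the other to strain
#' 2. An exact likelihood tie sends the major allele to strain 1 with
#' confidence 0.5. Confidence is the posterior probability of the chosen
#' assignment under the fitted mixture.
#'
#' @param s a `poly_sites` object.
#' @param fit a `mixture_fit` with `call == "bi"`.
#' @return Data frame with one row per polymorphic site: `site`,
#'   `strain1_allele`, `strain2_allele` (allele slot indices), `confidence`.
#' @export
phase_by_depth <- function(s, fit) {
  if (fit$call != "bi") stop("phasing requires a bi (two-strain) mixture call")
  mu <- fit$means   # descending: mu[1] high component
  n <- length(s$site)
  s1 <- integer(n); s2 <- integer(n); conf <- numeric(n)
  for (k in seq_len(n)) {
    ## likelihood that (major -> high, minor -> low) vs the swap
    l_maj_high <- stats::dpois(s$major[k], mu[1], log = TRUE) +
      stats::dpois(s$minor[k], mu[2], log = TRUE)
    l_min_high <- stats::dpois(s$minor[k], mu[1], log = TRUE) +
      stats::dpois(s$major[k], mu[2], log = TRUE)
    p1 <- 1 / (1 + exp(l_min_high - l_maj_high))
    if (l_maj_high >= l_min_high) {
      s1[k] <- s$major_allele[k]; s2[k] <- s$minor_allele[k]
      conf[k] <- p1
    } else {
      s1[k] <- s$minor_allele[k]; s2[k] <- s$major_allele[k]
      conf[k] <- 1 - p1
    }
  }
  data.frame(site = s$site, strain1_allele = s1, strain2_allele = s2,
             confidence = conf)
}

#' Contamination check on control genomes
#'
#' A coinfection signal is trusted only when control genomes that should be
#' strain-pure in the sample (the primary symbiont and the mitochondrion)
#' show essentially no intra-sample polymorphism.
#'
#' @param control_sets named list of `poly_sites` objects for the control
#'   genomes (an element may be `NULL` when the control genome is absent).
#' @param control_n_sites named integer vector: total variant sites
#'   considered on each control genome.
#' @param max_poly_fraction ceiling on the polymorphic-site fraction
#'   (default 0.001).
#' @return `TRUE` (clean), `FALSE` (not clean) or `NA` when every control
#'   genome is absent.
#' @export
contamination_check <- function(control_sets, control_n_sites,
                                max_poly_fraction = 0.001) {
  fracs <- c()
  for (nm in names(control_sets)) {
    cs <- control_sets[[nm]]
    if (is.null(cs)) next
    total <- control_n_sites[[nm]]
    if (is.null(total) || is.na(total) || total == 0) next
    fracs <- c(fracs, length(cs$site) / total)
  }
  if (length(fracs) == 0) return(NA)
  all(fracs <= max_poly_fraction)
}
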