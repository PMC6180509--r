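## stable hash of a config list, invariant to key order
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x), method = "radix")]
      lapply(x, canon)
    } else x
  }
  txt <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}

## seed substream: derived deterministically per named stage
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + h) %% 2000000000L
}

#' Run the full holobiont analysis pipeline
#'
#' Wires the stages end to end for a set of symbionts: coverage screening
#' and presence calls, variant filtering, profile building (with ambiguous
#' sample exclusion and deduplication), neighbor-joining tree with optional
#' outgroup rooting, coinfection scan, and cospeciation testing of every
#' secondary symbiont against the host tree. By default the primary
#' symbiont's profile tree, ultrametrized, serves as the host-matriline
#' proxy (the primary symbiont being strictly maternally inherited);
#' an explicit host tree file may be supplied instead.
#'
#' Symbionts that fail the analysable coverage gate in every sample are
#' recorded in the manifest and skipped, not fatal.
#'
#' @param config list with entries: `symbionts` (named list; each element a
#'   list with `vcf`, `depths` (coverage TSV), `replicon_lengths` (named
#'   vector), optional `mask` (BED), optional `outgroup` (character)),
#'   `primary` (name of the primary symbiont used as host proxy), optional
#'   `host_tree` (Newick path overriding the proxy), optional `n_perm`
#'   (default 500) and `seed` (default 1).
#' @param out_dir output directory (created if needed).
#' @return The run manifest (list), invisibly written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$symbionts) || length(config$symbionts) == 0) {
    stop("config$symbionts is mandatory")
  }
  if (is.null(config$primary) && is.null(config$host_tree)) {
    stop("config needs either a primary symbiont or a host tree")
  }
  for (nm in names(config$symbionts)) {
    sy <- config$symbionts[[nm]]
    for (field in c("vcf", "depths")) {
      if (is.null(sy[[field]]) || !all(file.exists(unlist(sy[[field]])))) {
        stop("missing mandatory input '", field, "' for symbiont ", nm)
      }
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_perm <- if (is.null(config$n_perm)) 500L else as.integer(config$n_perm)

  manifest <- list(config_hash = config_hash(config),
                   version = as.character(utils::packageVersion("holostrain")),
                   stages = list())
  calls <- list()
  trees <- list()
  presence_by_symbiont <- list()
  profiles_by_symbiont <- list()

  for (nm in names(config$symbionts)) {
    sy <- config$symbionts[[nm]]
    sdir <- file.path(out_dir, nm)
    dir.create(sdir, showWarnings = FALSE)
    m <- read_vcf(sy$vcf)
    tracks_by_sample <- list()
    pres <- character(0)
    for (s in m$samples) {
      dpath <- if (length(sy$depths) > 1) sy$depths[[s]] else sy$depths
      tr <- read_coverage(dpath, sy$replicon_lengths)
      ## a multi-sample depth file is expected as one file per sample;
      ## with a single file all samples share it
      tracks_by_sample[[s]] <- tr
      cs <- summarize_coverage(unlist(tr, use.names = FALSE),
                               sample = s, symbiont = nm)
      pc <- call_presence(cs)
      calls[[length(calls) + 1]] <- pc
      pres[[s]] <- pc$status
    }
    presence_by_symbiont[[nm]] <- pres
    analysable <- names(pres)[pres == "analysable"]
    stage <- list(symbiont = nm, n_samples = n_samples(m),
                  n_sites_raw = n_sites(m),
                  analysable_samples = analysable)
    if (length(analysable) < 3) {
      stage$skipped <- "fewer than 3 analysable samples"
      manifest$stages[[nm]] <- stage
      next
    }
    mask <- if (!is.null(sy$mask)) read_bed(sy$mask) else NULL
    flt <- filter_variants(m, filter_config(), mask = mask,
                           include_samples = analysable)
    stage$filter_report <- flt$report[setdiff(names(flt$report),
                                              "mask_reasons")]
    write_vcf(flt$matrix, file.path(sdir, "filtered.vcf"))
    prof <- build_profiles(acm_subset(flt$matrix, samples = analysable))
    keepx <- exclude_ambiguous_samples(prof)
    stage$excluded_ambiguous <- names(keepx$excluded)
    dedup <- deduplicate_profiles(keepx$kept)
    stage$duplicate_groups <- dedup$groups
    write_profiles(keepx$kept, file.path(sdir, "profiles.tsv"))
    if (length(dedup$representatives) >= 3) {
      d <- profile_distance_matrix(dedup$representatives,
                                   n_sites(flt$matrix))
      tr <- neighbor_joining(d)
      if (!is.null(sy$outgroup) &&
          all(sy$outgroup %in% tr$tip.label) &&
          !setequal(sy$outgroup, tr$tip.label)) {
        tr <- root_with_outgroup(tr, sy$outgroup)
      }
      write_tree(tr, file.path(sdir, "tree.nwk"))
      trees[[nm]] <- tr
      stage$tree = file.path(sdir, "tree.nwk")
    } else {
      stage$skipped_tree <- "fewer than 3 distinct profiles"
    }
    ## coinfection scan
    coinf <- list()
    for (s in analysable) {
      ps <- collect_polymorphic_sites(flt$matrix, s)
      fit <- fit_depth_mixture(ps, seed = stage_seed(seed,
                                                     paste0("coinf:", nm, s)))
      if (fit$call == "bi") {
        coinf[[s]] <- list(call = "bi", means = fit$means,
                           delta_bic = fit$delta_bic,
                           n_sites = fit$n_sites)
      }
    }
    stage$coinfection <- coinf
    profiles_by_symbiont[[nm]] <- keepx$kept
    manifest$stages[[nm]] <- stage
  }

  ## presence matrix over all symbionts
  pm <- build_presence_matrix(calls)
  write_presence_matrix(pm, file.path(out_dir, "presence_matrix.tsv"))
  manifest$presence_matrix <- file.path(out_dir, "presence_matrix.tsv")

  ## host tree: explicit file or primary-symbiont proxy
  host <- NULL
  if (!is.null(config$host_tree)) {
    host <- read_tree(config$host_tree)
  } else if (!is.null(trees[[config$primary]])) {
    host <- trees[[config$primary]]
    if (!ape::is.rooted(host)) {
      host <- root_with_outgroup(host, host$tip.label[1])
    }
  }
  if (!is.null(host)) {
    host <- ultrametrize_grafen(ape::multi2di(host))
    write_tree(host, file.path(out_dir, "host_proxy.nwk"))
    secondaries <- setdiff(names(trees), config$primary)
    recon <- list()
    for (nm in secondaries) {
      sy_tree <- trees[[nm]]
      shared <- intersect(sy_tree$tip.label, host$tip.label)
      if (length(shared) < 3) next
      sy_tree <- ape::keep.tip(sy_tree, shared)
      if (!ape::is.rooted(sy_tree)) {
        sy_tree <- root_with_outgroup(sy_tree, sy_tree$tip.label[1])
      }
      sy_tree <- ape::multi2di(sy_tree)
      mapping <- stats::setNames(sy_tree$tip.label, sy_tree$tip.label)
      pruned <- prune_unusable_tips(host, sy_tree,
                                    presence_by_symbiont[[nm]], mapping)
      ct <- cospeciation_test(host, pruned$symbiont, pruned$mapping,
                              n_perm = n_perm,
                              seed = stage_seed(seed, paste0("recon:", nm)))
      rec <- reconcile(host, pruned$symbiont, pruned$mapping)
      recon[[nm]] <- list(cost = rec$cost, events = as.list(rec$events),
                          p_value = ct$p_value)
    }
    manifest$reconciliations <- recon
  }

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
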