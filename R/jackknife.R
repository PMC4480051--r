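#' Jackknife configuration
#'
#' Settings for the outgroup-randomization experiment: in each iteration one
#' representative is drawn uniformly at random from every outgroup pool
#' (independently across iterations, with replacement), a tree is inferred,
#' the outgroups are pruned and the ingroup topologies are compared across
#' iterations.  Sixteen iterations is the conventional default.
#'
#' Per-iteration seeds are derived as `seed + iteration`, so any single
#' iteration is reproducible in isolation.
#'
#' @param n_iterations number of random outgroup draws (default 16)
#' @param seed master seed (integer)
#' @param backend `"builtin_nj"` (Jukes-Cantor distances, neighbor joining,
#'   nonparametric bootstrap) — a pluggable external maximum-likelihood
#'   backend can be supplied to [outgroup_jackknife()] as a function.
#' @param bootstrap_replicates bootstrap replicates for the builtin backend
#'   (default 100)
#' @return a `jackknife_config` list
#' @export
jackknife_config <- function(n_iterations = 16L, seed = 1L,
                             backend = "builtin_nj",
                             bootstrap_replicates = 100L) {
  stopifnot(n_iterations >= 1, bootstrap_replicates >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 backend = backend,
                 bootstrap_replicates = as.integer(bootstrap_replicates)),
            class = "jackknife_config")
}

#' Draw outgroup representatives for every iteration
#'
#' @param pools named list of candidate taxon label vectors (one pool per
#'   donor lineage)
#' @param config a [jackknife_config()]
#' @return list of length `n_iterations`; each element a named character
#'   vector with one chosen label per pool
#' @export
sample_outgroups <- function(pools, config) {
  if (length(pools) == 0 || any(lengths(pools) == 0)) {
    stop("every outgroup pool must be nonempty", call. = FALSE)
  }
  lapply(seq_len(config$n_iterations), function(i) {
    set.seed(config$seed + i)
    vapply(pools, function(p) p[sample.int(length(p), 1L)], character(1))
  })
}

aln_to_DNAbin <- function(aln) {
  m <- tolower(aln$mat)
  ape::as.DNAbin(m)
}

## Jukes-Cantor + neighbor joining + nonparametric bootstrap over columns.
## Assumes set.seed() was called by the caller (run_iteration).
builtin_nj_backend <- function(aln, bootstrap_replicates) {
  dna <- aln_to_DNAbin(aln)
  dist_fun <- function(x) ape::dist.dna(x, model = "JC69",
                                        pairwise.deletion = TRUE)
  d <- dist_fun(dna)
  if (any(!is.finite(d))) {
    stop("undefined Jukes-Cantor distance (no shared unambiguous columns ",
         "or saturation)", call. = FALSE)
  }
  main <- ape::nj(d)
  nc <- ncol(dna)
  boots <- vector("list", bootstrap_replicates)
  for (b in seq_len(bootstrap_replicates)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    db <- dist_fun(dna[, cols])
    if (any(!is.finite(db))) db[!is.finite(db)] <- max(db[is.finite(db)], 1)
    boots[[b]] <- ape::nj(db)
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- round(100 * counts / bootstrap_replicates, 2)
  main
}

#' Run one jackknife iteration
#'
#' Subsets the pre-aligned matrix to the ingroup plus the chosen outgroups,
#' infers a support-annotated tree with the backend, and prunes the
#' outgroups to obtain the ingroup topology.
#'
#' @param aln a [multiple_alignment()] holding ingroup and all candidate
#'   outgroup rows (pre-aligned)
#' @param ingroup character vector of ingroup taxa
#' @param outgroups character vector of chosen outgroup taxa for this
#'   iteration
#' @param config a [jackknife_config()]
#' @param iteration iteration index (drives the derived seed)
#' @param backend_fun optional function `(alignment, config)` returning a
#'   support-annotated [ape::phylo]; overrides the builtin backend (hook for
#'   wrapping external maximum-likelihood programs)
#' @return list with `iteration`, `outgroups`, `tree` (full inferred tree)
#'   and `ingroup_tree` (outgroups pruned, unrooted)
#' @export
run_iteration <- function(aln, ingroup, outgroups, config, iteration,
                          backend_fun = NULL) {
  missing_taxa <- setdiff(c(ingroup, outgroups), aln$taxa)
  if (length(missing_taxa) > 0) {
    stop(sprintf("taxa absent from alignment: %s",
                 paste(missing_taxa, collapse = ", ")), call. = FALSE)
  }
  sel <- c(ingroup, unname(outgroups))
  sub <- multiple_alignment(aln$mat[sel, , drop = FALSE])
  ## backend seed depends on the master seed and the selected taxa only, so
  ## identical inputs yield identical trees and supports no matter the
  ## iteration index (outgroup sampling uses seed + iteration instead)
  h <- sum(utf8ToInt(paste(sort(sel), collapse = ";")) *
             seq_along(utf8ToInt(paste(sort(sel), collapse = ";"))))
  set.seed((config$seed + h) %% 2147483647L)
  tree <- if (is.null(backend_fun)) {
    builtin_nj_backend(sub, config$bootstrap_replicates)
  } else {
    backend_fun(sub, config)
  }
  ingroup_tree <- ape::unroot(ape::drop.tip(tree, unname(outgroups)))
  list(iteration = iteration, outgroups = outgroups, tree = tree,
       ingroup_tree = ingroup_tree)
}

#' Randomized outgroup jackknife
#'
#' For each iteration, draws one outgroup per pool, re-infers the tree,
#' prunes the outgroups, and finally compares the ingroup topologies and
#' summarizes per-node support variability.
#'
#' @inheritParams run_iteration
#' @param pools named list of outgroup candidate label vectors
#' @return list of class `outgroup_jackknife` with elements `config`,
#'   `selections`, `iterations`, `congruence` (see
#'   [compare_ingroup_topologies()]) and `support` (see
#'   [summarize_node_support()])
#' @export
outgroup_jackknife <- function(aln, ingroup, pools, config = jackknife_config(),
                               backend_fun = NULL) {
  overlap <- intersect(ingroup, unlist(pools))
  if (length(overlap) > 0) {
    stop(sprintf("outgroup candidates overlap the ingroup: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  }
  selections <- sample_outgroups(pools, config)
  iterations <- lapply(seq_len(config$n_iterations), function(i) {
    run_iteration(aln, ingroup, selections[[i]], config, i, backend_fun)
  })
  structure(list(config = config,
                 selections = selections,
                 iterations = iterations,
                 congruence = compare_ingroup_topologies(iterations),
                 support = summarize_node_support(iterations)),
            class = "outgroup_jackknife")
}

#' Compare pruned ingroup topologies across iterations
#'
#' @param results list of iteration results from [run_iteration()]
#' @return list with `rf` (matrix of pairwise unrooted Robinson-Foulds
#'   distances), `all_identical` (all distances zero) and `consensus`
#'   (strict consensus of the ingroup topologies, an [ape::phylo])
#' @export
compare_ingroup_topologies <- function(results) {
  if (length(results) < 2) stop("need at least two iterations", call. = FALSE)
  trees <- lapply(results, `[[`, "ingroup_tree")
  leaves <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(leaves[-1], identical, logical(1), leaves[[1]]))) {
    stop("ingroup leaf sets differ between iterations", call. = FALSE)
  }
  n <- length(trees)
  rf <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rf[i, j] <- rf[j, i] <- rf_distance(trees[[i]], trees[[j]])
    }
  }
  cons <- ape::consensus(trees, p = 1)
  list(rf = rf, all_identical = all(rf == 0L), consensus = cons)
}

#' Summarize bootstrap support per ingroup node across iterations
#'
#' For every non-trivial ingroup bipartition present in the strict consensus
#' of the pruned topologies, collects the support values across the
#' iterations in which the bipartition occurs (supports are read from the
#' full inferred trees and restricted to the ingroup leaf set; when two
#' full-tree splits collapse to the same ingroup split after outgroup
#' removal, the larger support is kept).  Reports the mean and sample
#' (n - 1) standard deviation.
#'
#' @param results list of iteration results from [run_iteration()]
#' @return data.frame with columns `node` (canonical leaf-set split),
#'   `mean_support`, `sd_support`, `n`
#' @export
summarize_node_support <- function(results) {
  if (length(results) < 2) stop("need at least two iterations", call. = FALSE)
  ingroup <- sort(results[[1]]$ingroup_tree$tip.label)
  per_iter <- lapply(results, function(res) {
    full <- res$tree
    sup <- tree_bipartitions(full, supports = TRUE)
    ## restrict each split to ingroup leaves and re-canonicalize
    ref <- ingroup[1]
    out <- numeric(0)
    for (k in seq_along(sup)) {
      side <- intersect(strsplit(names(sup)[k], ",", fixed = TRUE)[[1]],
                        ingroup)
      if (length(side) <= 1 || length(side) >= length(ingroup) - 1) next
      if (ref %in% side) side <- setdiff(ingroup, side)
      key <- paste(sort(side), collapse = ",")
      val <- sup[k]
      if (is.na(val)) next
      if (!is.null(out[key]) && !is.na(out[key])) {
        out[key] <- max(out[key], val, na.rm = TRUE)
      } else {
        out[key] <- val
      }
    }
    out
  })
  cons <- compare_ingroup_topologies(results)$consensus
  nodes <- tree_bipartitions(cons)
  rows <- lapply(sort(nodes), function(key) {
    vals <- unlist(lapply(per_iter, function(m)
      if (key %in% names(m)) m[[key]] else NULL))
    data.frame(node = key,
               mean_support = mean(vals),
               sd_support = if (length(vals) > 1) stats::sd(vals) else 0,
               n = length(vals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(node = character(0), mean_support = numeric(0),
                      sd_support = numeric(0), n = integer(0))
  }
  rownames(out) <- NULL
  out
}
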