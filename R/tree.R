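#' Read a phylogenetic tree from Newick
#'
#' Numeric internal-node labels are interpreted as support values and kept in
#' `node.label` (ape convention).
#'
#' @param path Newick file
#' @return an [ape::phylo] tree
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop(sprintf(
                   "malformed Newick in %s: %s", path, conditionMessage(e)),
                   call. = FALSE))
  if (is.null(tr)) stop(sprintf("malformed Newick in %s", path), call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels in tree", call. = FALSE)
  }
  tr
}

#' Write a tree as Newick
#' @param tree an [ape::phylo]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Root a tree on the branch separating an outgroup from the ingroup
#'
#' @param tree an [ape::phylo]
#' @param outgroup character vector of leaf labels; must be a proper nonempty
#'   subset of the leaves and separable from the ingroup by one branch.
#' @return a rooted [ape::phylo]
#' @export
root_with_outgroup <- function(tree, outgroup) {
  tips <- tree$tip.label
  if (length(outgroup) == 0 || !all(outgroup %in% tips)) {
    stop("outgroup must be a nonempty subset of the tree leaves",
         call. = FALSE)
  }
  if (length(setdiff(tips, outgroup)) == 0) {
    stop("outgroup must be a proper subset of the leaves", call. = FALSE)
  }
  if (length(outgroup) > 1 &&
      !ape::is.monophyletic(ape::unroot(tree), outgroup)) {
    stop("outgroup is not separable from the ingroup (non-monophyletic)",
         call. = FALSE)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

## states: integer vector (0/1/NA) named by leaf labels
check_character_states <- function(tree, states) {
  if (is.null(names(states))) stop("character states must be named by leaf")
  missing_tips <- setdiff(tree$tip.label, names(states))
  if (length(missing_tips) > 0) {
    stop(sprintf("no state for leaves: %s",
                 paste(missing_tips, collapse = ", ")), call. = FALSE)
  }
  s <- states[tree$tip.label]
  if (all(is.na(s))) stop("character is missing for every leaf", call. = FALSE)
  s
}

#' Minimum number of state changes of a binary character on a tree
#'
#' Small-parsimony step count under unit costs (Fitch), computed by a
#' dynamic program over the node cost vectors so the result is exact on
#' multifurcating trees as well.  Leaves with `NA` carry the full state set
#' and contribute no constraint.  The count is identical under any rooting.
#'
#' @param tree an [ape::phylo] (rooted or unrooted)
#' @param states integer vector over `0`, `1`, `NA`, named by leaf label
#' @return integer minimum change count
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_steps(tr, c(A = 1, B = 1, C = 0, D = 0))  # 1
#' @export
fitch_steps <- function(tree, states) {
  s <- check_character_states(tree, states)
  n_tip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  cost <- matrix(Inf, nrow = n_node, ncol = 2)  # columns: state 0, state 1
  for (i in seq_len(n_tip)) {
    if (is.na(s[i])) cost[i, ] <- 0 else cost[i, s[i] + 1L] <- 0
  }
  internal <- unique(tree$edge[, 1])
  cost[internal, ] <- 0
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]; chi <- tree$edge[k, 2]
    cost[par, 1] <- cost[par, 1] + min(cost[chi, 1], cost[chi, 2] + 1)
    cost[par, 2] <- cost[par, 2] + min(cost[chi, 2], cost[chi, 1] + 1)
  }
  root <- tree$edge[nrow(tree$edge), 1]
  as.integer(min(cost[root, ]))
}

#' Classify a binary indel character on a rooted tree
#'
#' Determines the derived state (opposite the outgroup state when known,
#' otherwise the minority state among scored leaves, ties resolved to
#' state 1), then tests whether the derived leaves form a clade.  A derived
#' set of two or more leaves forming a clade is a putative synapomorphy
#' (equivalently, one Fitch step with that polarity); two or more Fitch
#' steps means putative homoplasy.  Characters invariant across scored
#' leaves are excluded, and a single derived leaf is flagged
#' `autapomorphic` (such characters should not survive indel scoring).
#'
#' @param tree rooted [ape::phylo] whose leaves all carry states
#' @param states integer vector over `0`, `1`, `NA`, named by leaf
#' @param outgroup_state `0`, `1` or `NA` (unknown); state observed in the
#'   outgroup used only to polarize the character.
#' @return list with `fitch_steps`, `status` (`synapomorphic`,
#'   `homoplastic`, `invariant_excluded`, `autapomorphic`), `derived_state`
#'   and `supported_clade` (leaf labels; only for synapomorphies)
#' @export
classify_character <- function(tree, states, outgroup_state = NA) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  s <- check_character_states(tree, states)
  obs <- s[!is.na(s)]
  if (length(unique(obs)) < 2) {
    return(list(fitch_steps = 0L, status = "invariant_excluded",
                derived_state = NA_integer_, supported_clade = NULL))
  }
  steps <- fitch_steps(tree, states)
  if (!is.na(outgroup_state)) {
    derived <- 1L - as.integer(outgroup_state)
  } else {
    n1 <- sum(obs == 1L); n0 <- sum(obs == 0L)
    derived <- if (n1 < n0) 1L else if (n0 < n1) 0L else 1L
  }
  d_leaves <- names(s)[!is.na(s) & s == derived]
  if (length(d_leaves) < 2) {
    return(list(fitch_steps = steps, status = "autapomorphic",
                derived_state = derived, supported_clade = d_leaves))
  }
  mrca <- ape::getMRCA(tree, d_leaves)
  clade <- ape::extract.clade(tree, mrca)$tip.label
  clade_states <- s[clade]
  mono <- all(is.na(clade_states) | clade_states == derived)
  if (mono) {
    list(fitch_steps = steps, status = "synapomorphic",
         derived_state = derived, supported_clade = clade)
  } else {
    list(fitch_steps = steps, status = "homoplastic",
         derived_state = derived, supported_clade = NULL)
  }
}

#' Classify every character of a binary matrix against a reference tree
#'
#' The tree is rooted on `outgroup`; each character is polarized with the
#' outgroup state (consensus across outgroup rows, conflicting or missing
#' outgroup states fall back to the minority-state rule), the outgroup is
#' pruned and the ingroup character is classified with
#' [classify_character()].
#'
#' @param tree an [ape::phylo] containing all matrix taxa as leaves
#' @param mat a `binary_character_matrix` (taxa x characters)
#' @param outgroup character vector of outgroup taxa (may be empty; the tree
#'   must then already be rooted)
#' @return data.frame with one row per character: `character_id`,
#'   `fitch_steps`, `status`, `derived_state`, `supported_clade`
#'   (comma-joined sorted leaves, `NA` unless synapomorphic)
#' @export
classify_characters <- function(tree, mat, outgroup = character(0)) {
  missing_taxa <- setdiff(rownames(mat), tree$tip.label)
  if (length(missing_taxa) > 0) {
    stop(sprintf("taxa absent from tree: %s",
                 paste(missing_taxa, collapse = ", ")), call. = FALSE)
  }
  if (length(outgroup) > 0) {
    tree <- root_with_outgroup(tree, outgroup)
    ingroup_tree <- ape::drop.tip(tree, outgroup)
  } else {
    if (!ape::is.rooted(tree)) stop("tree must be rooted when no outgroup given",
                                    call. = FALSE)
    ingroup_tree <- tree
  }
  res <- vector("list", ncol(mat))
  for (j in seq_len(ncol(mat))) {
    og_state <- NA_integer_
    if (length(outgroup) > 0) {
      og <- mat[outgroup, j]
      og <- og[!is.na(og)]
      if (length(og) > 0 && length(unique(og)) == 1) og_state <- og[1]
    }
    cl <- classify_character(ingroup_tree,
                             mat[setdiff(rownames(mat), outgroup), j],
                             og_state)
    res[[j]] <- data.frame(
      character_id = colnames(mat)[j],
      fitch_steps = cl$fitch_steps,
      status = cl$status,
      derived_state = cl$derived_state,
      supported_clade = if (cl$status == "synapomorphic")
        paste(sort(cl$supported_clade), collapse = ",") else NA_character_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Tabulate synapomorphic indel characters per named clade
#'
#' Counts, for each named clade definition, the synapomorphic characters
#' whose supported clade equals that leaf set exactly; synapomorphies
#' matching no definition are listed under their literal leaf sets, and the
#' homoplastic total is reported as one extra row.
#'
#' @param classifications data.frame from [classify_characters()]
#' @param clade_defs named list of character vectors (leaf sets)
#' @return data.frame with columns `clade`, `n_taxa`, `indels`
#' @export
tabulate_clades <- function(classifications, clade_defs = list()) {
  keys <- vapply(clade_defs, function(x) paste(sort(x), collapse = ","),
                 character(1))
  syn <- classifications[classifications$status == "synapomorphic", ,
                         drop = FALSE]
  rows <- list()
  for (i in seq_along(clade_defs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      clade = names(clade_defs)[i],
      n_taxa = length(clade_defs[[i]]),
      indels = sum(syn$supported_clade == keys[i]),
      stringsAsFactors = FALSE)
  }
  unmatched <- setdiff(unique(syn$supported_clade), keys)
  for (u in sort(unmatched)) {
    rows[[length(rows) + 1L]] <- data.frame(
      clade = u, n_taxa = length(strsplit(u, ",")[[1]]),
      indels = sum(syn$supported_clade == u), stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    clade = "Homoplasious indels", n_taxa = NA_integer_,
    indels = sum(classifications$status == "homoplastic"),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- bipartitions and Robinson-Foulds --------------------------------

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each bipartition is canonicalized as the sorted, comma-joined leaf set on
#' the side NOT containing the alphabetically first leaf, so identical splits
#' from different trees over the same leaves compare equal.
#'
#' @param tree an [ape::phylo]
#' @param supports if `TRUE`, return a named numeric vector of node supports
#'   (from `node.label`) instead of a character vector of splits
#' @return character vector of canonical splits, or named numeric supports
#' @export
tree_bipartitions <- function(tree, supports = FALSE) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  n_tip <- length(tips)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  out <- character(0)
  sup <- numeric(0)
  node_sup <- rep(NA_real_, tree$Nnode)
  if (supports && !is.null(tree$node.label)) {
    node_sup <- suppressWarnings(as.numeric(tree$node.label))
  }
  for (i in seq_along(pp)) {
    side <- labels[pp[[i]]]
    if (length(side) <= 1 || length(side) >= n_tip - 1) next
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = ",")
    out <- c(out, key)
    sup <- c(sup, node_sup[i])
  }
  if (supports) setNames(sup, out) else out
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Symmetric difference of the non-trivial bipartition sets; 0 means
#' identical unrooted topologies.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set
#' @return integer RF distance
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees must share an identical leaf set", call. = FALSE)
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}
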