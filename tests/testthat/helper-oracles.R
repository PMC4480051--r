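# Independent oracles and fixture builders.  These deliberately use naive
# enumeration / per-character scans so they share no code with the package
# implementations they check.

# exhaustive minimum-change count: enumerate all state assignments to
# internal nodes and to missing leaves
brute_fitch <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  s <- states[tree$tip.label]
  free_leaves <- which(is.na(s))
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  free <- c(free_leaves, internal)
  combos <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  node_states <- cbind(
    matrix(rep(s, each = nrow(combos)), nrow(combos), n_tip),
    matrix(0, nrow(combos), tree$Nnode))
  node_states[, free] <- combos
  par <- tree$edge[, 1]; chi <- tree$edge[, 2]
  changes <- rowSums(node_states[, par, drop = FALSE] !=
                     node_states[, chi, drop = FALSE])
  min(changes)
}

# as brute_fitch, but with the root state fixed (known ancestral polarity)
brute_fitch_rooted <- function(tree, states, root_state) {
  n_tip <- length(tree$tip.label)
  s <- states[tree$tip.label]
  root <- n_tip + 1
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  free <- c(which(is.na(s)), setdiff(internal, root))
  combos <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  node_states <- cbind(
    matrix(rep(s, each = nrow(combos)), nrow(combos), n_tip),
    matrix(0, nrow(combos), tree$Nnode))
  if (length(free) > 0) node_states[, free] <- combos
  node_states[, root] <- root_state
  par <- tree$edge[, 1]; chi <- tree$edge[, 2]
  min(rowSums(node_states[, par, drop = FALSE] !=
              node_states[, chi, drop = FALSE]))
}

random_gapped_alignment <- function(n_taxa, n_col, gap_prob = 0.1) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_col, replace = TRUE),
                n_taxa, n_col)
  mat[matrix(runif(n_taxa * n_col) < gap_prob, n_taxa, n_col)] <- "-"
  rownames(mat) <- paste0("tx", seq_len(n_taxa))
  multiple_alignment(mat)
}

random_binary_character <- function(tips, missing_prob = 0) {
  repeat {
    x <- sample(0:1, length(tips), replace = TRUE)
    if (missing_prob > 0) x[runif(length(x)) < missing_prob] <- NA
    obs <- x[!is.na(x)]
    if (length(unique(obs)) == 2) break
  }
  setNames(x, tips)
}

# naive per-character scan for maximal gap runs in one row string
scan_gap_runs <- function(row_chars) {
  runs <- list()
  in_run <- FALSE
  start <- NA
  for (j in seq_along(row_chars)) {
    if (row_chars[j] == "-" && !in_run) {
      in_run <- TRUE; start <- j
    } else if (row_chars[j] != "-" && in_run) {
      runs[[length(runs) + 1]] <- c(start, j - 1)
      in_run <- FALSE
    }
  }
  if (in_run) runs[[length(runs) + 1]] <- c(start, length(row_chars))
  runs
}

# bipartition set of an unrooted tree computed naively by edge deletion
brute_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n_tip <- length(tips)
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    node <- tree$edge[e, 2]
    if (node <= n_tip) next
    side <- ape::extract.clade(tree, node)$tip.label
    if (length(side) <= 1 || length(side) >= n_tip - 1) next
    if (sort(tips)[1] %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

toy_alignment <- function() {
  multiple_alignment(c(
    alpha = "ACGTACGTAC",
    beta  = "ACGTACGTAC",
    gamma = "ACTTACGAAC",
    delta = "ACGTACGTAC"))
}
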