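#' Simulation configuration
#'
#' Defaults describe a desk-scale plastome-like dataset: 20 taxa on a
#' clock-like Yule tree, 20 kb of sequence under an HKY model with gamma
#' rate heterogeneity at plastome-typical divergence, indel events of
#' minimum length 2 injected on branches with roughly half attributable to
#' slipped-strand mispairing, a small mononucleotide fraction exercising the
#' homopolymer exclusion rule, and occasional terminal-gap missing data.
#'
#' @param n_taxa number of leaves (>= 4; default 20)
#' @param birth_rate Yule speciation rate (default 1); tree heights are in
#'   time units and divergence is controlled by `rate`.
#' @param sequence_length ungapped sequence length in nt (default 20000)
#' @param kappa HKY transition/transversion rate ratio (default 3)
#' @param gamma_shape shape of the 4-category discrete gamma across sites
#'   (default 1; `Inf` disables rate heterogeneity)
#' @param rate expected substitutions per site per unit branch length
#'   (default 0.02, giving low plastome-like divergence; set 0 for
#'   substitution-free ground-truth runs)
#' @param base_freq equilibrium base frequencies A,C,G,T (default slightly
#'   AT-rich, as in plastomes)
#' @param events_per_branch Poisson mean indel events per branch
#'   (default 1.6, about 60 events on a 20-taxon rooted tree)
#' @param ssm_fraction fraction of non-mononucleotide events that are
#'   slipped-strand-mispairing type (default 0.47, the fraction observed in
#'   plastome indel surveys)
#' @param length_p geometric parameter for event lengths (minimum 2;
#'   default 0.35, mean about 3.9 bp)
#' @param mononucleotide_fraction fraction of events that are homopolymer
#'   expansions (default 0.10)
#' @param mean_feature_length mean annotation feature length in columns
#'   (default 600)
#' @param class_mixture probabilities of feature classes coding, intron,
#'   igs (default c(0.45, 0.10, 0.45))
#' @param terminal_gap_fraction fraction of taxa receiving a truncated
#'   (missing) alignment end (default 0.15)
#' @param terminal_gap_max maximum truncation length in columns
#'   (default 150)
#' @param flank_noise number of substitutions sprinkled into each SSM flank
#'   copy (default 0; the stress mode for degrading repeat identity below
#'   the detection threshold in negative tests)
#' @param seed integer seed
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_taxa = 20L,
                              birth_rate = 1,
                              sequence_length = 20000L,
                              kappa = 3,
                              gamma_shape = 1,
                              rate = 0.02,
                              base_freq = c(A = 0.31, C = 0.19,
                                            G = 0.19, T = 0.31),
                              events_per_branch = 1.6,
                              ssm_fraction = 0.47,
                              length_p = 0.35,
                              mononucleotide_fraction = 0.10,
                              mean_feature_length = 600,
                              class_mixture = c(coding = 0.45,
                                                intron = 0.10,
                                                igs = 0.45),
                              terminal_gap_fraction = 0.15,
                              terminal_gap_max = 150L,
                              flank_noise = 0L,
                              seed = 1L) {
  stopifnot(n_taxa >= 4, sequence_length >= 1000, birth_rate > 0,
            rate >= 0, events_per_branch >= 0,
            ssm_fraction >= 0, ssm_fraction <= 1,
            length_p > 0, length_p < 1,
            mononucleotide_fraction >= 0, mononucleotide_fraction <= 1)
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 sequence_length = as.integer(sequence_length),
                 kappa = kappa, gamma_shape = gamma_shape, rate = rate,
                 base_freq = base_freq / sum(base_freq),
                 events_per_branch = events_per_branch,
                 ssm_fraction = ssm_fraction, length_p = length_p,
                 mononucleotide_fraction = mononucleotide_fraction,
                 mean_feature_length = mean_feature_length,
                 class_mixture = class_mixture / sum(class_mixture),
                 terminal_gap_fraction = terminal_gap_fraction,
                 terminal_gap_max = as.integer(terminal_gap_max),
                 flank_noise = as.integer(flank_noise),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a clock-like Yule tree
#'
#' Pure-birth construction: two lineages start at the root, each interval
#' with `k` lineages lasts Exp(`k * birth_rate`), a uniformly chosen lineage
#' splits, and after the n-th lineage appears one final Exp(`n * birth_rate`)
#' interval elapses before sampling.  All tips are contemporaneous; the
#' expected root height is `(1/birth_rate) * sum_{k=2}^{n} 1/k`.
#'
#' @param n_taxa number of leaves
#' @param birth_rate speciation rate
#' @param seed optional seed (set the RNG yourself to chain simulations)
#' @return a rooted ultrametric [ape::phylo] with tips `t1..tn`
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ## active lineages: id and birth time; splits recorded as (parent-lineage,
  ## child1, child2, split time)
  births <- c(0, 0)
  parent <- c(NA_integer_, NA_integer_)  # lineage that split into this one
  active <- c(1L, 2L)
  split_time <- numeric(0)
  children <- list()
  t_now <- 0
  k <- 2L
  next_id <- 3L
  while (k < n_taxa) {
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    who <- active[sample.int(k, 1L)]
    c1 <- next_id; c2 <- next_id + 1L; next_id <- next_id + 2L
    births[c1] <- t_now; births[c2] <- t_now
    children[[who]] <- c(c1, c2)
    split_time[who] <- t_now
    active <- c(setdiff(active, who), c1, c2)
    k <- k + 1L
  }
  t_now <- t_now + stats::rexp(1, rate = n_taxa * birth_rate)
  height <- t_now
  ## convert to Newick: lineage subtree as string
  tip_counter <- new.env()
  tip_counter$i <- 0L
  as_newick <- function(id) {
    if (id <= length(children) && !is.null(children[[id]])) {
      ch <- children[[id]]
      sub <- paste(vapply(ch, as_newick, character(1)), collapse = ",")
      len <- split_time[id] - births[id]
      sprintf("(%s):%.10f", sub, len)
    } else {
      tip_counter$i <- tip_counter$i + 1L
      sprintf("t%d:%.10f", tip_counter$i, height - births[id])
    }
  }
  nwk <- sprintf("(%s,%s);", as_newick(1L), as_newick(2L))
  ape::read.tree(text = nwk)
}

## HKY rate matrix scaled to one expected substitution per unit time
hky_transition_matrices <- function(kappa, base_freq, times) {
  bases <- ALN_BASES
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    r <- if (any(transitions[, 1] == bases[i] &
                 transitions[, 2] == bases[j])) kappa else 1
    Q[i, j] <- r * base_freq[bases[j]]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freq[bases] * diag(Q))
  Q <- Q / mu
  eig <- eigen(Q)
  Vi <- solve(eig$vectors)
  lapply(times, function(t) {
    P <- eig$vectors %*% diag(exp(eig$values * t)) %*% Vi
    P <- pmax(Re(P), 0)
    P <- P / rowSums(P)
    dimnames(P) <- list(bases, bases)
    P
  })
}

#' Evolve gapless sequences along a tree under an HKY model
#'
#' Simulates a root sequence at the equilibrium frequencies and evolves it
#' along every branch with HKY transition probabilities; per-site rates come
#' from a 4-category discrete gamma.  Without indels every column is
#' homologous across taxa, which is the homology map later used to build the
#' true alignment.
#'
#' @param tree a [ape::phylo] with branch lengths
#' @param config a [simulation_config()]
#' @return character matrix of tip sequences (taxa x columns)
#' @export
evolve_sequences <- function(tree, config) {
  L <- config$sequence_length
  bases <- ALN_BASES
  freq <- config$base_freq[bases]
  root_seq <- sample(bases, L, replace = TRUE, prob = freq)
  ## discrete gamma categories (equal-probability, category means)
  if (is.finite(config$gamma_shape)) {
    k <- 4L
    q <- stats::qgamma((seq_len(k) - 0.5) / k, shape = config$gamma_shape,
                       rate = config$gamma_shape)
    cat_rates <- q / mean(q)
    site_cat <- sample.int(k, L, replace = TRUE)
  } else {
    cat_rates <- 1
    site_cat <- rep(1L, L)
  }
  tree <- stats::reorder(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  seqs[[root]] <- root_seq
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    bl <- tree$edge.length[e] * config$rate
    parent_seq <- seqs[[par]]
    if (bl == 0) {
      seqs[[chi]] <- parent_seq
      next
    }
    child <- parent_seq
    Ps <- hky_transition_matrices(config$kappa, config$base_freq,
                                  cat_rates * bl)
    for (ci in seq_along(cat_rates)) {
      idx <- which(site_cat == ci)
      if (length(idx) == 0) next
      P <- Ps[[ci]]
      for (b in bases) {
        here <- idx[parent_seq[idx] == b]
        if (length(here) == 0) next
        child[here] <- sample(bases, length(here), replace = TRUE,
                              prob = P[b, ])
      }
    }
    seqs[[chi]] <- child
  }
  out <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(out) <- tree$tip.label
  out
}

branch_descendants <- function(tree) {
  n_tip <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chi <- po$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[chi]])
  }
  desc
}

rgeom_min2 <- function(n, p) 2L + stats::rgeom(n, p)

#' Inject ground-truth indel events into simulated sequences
#'
#' Draws a Poisson number of events per branch, assigns each a type
#' (slipped-strand-mispairing insertion/deletion, plain insertion/deletion,
#' or mononucleotide expansion) and a geometric length (minimum 2), places
#' the events without overlap by rejection sampling with generous
#' separation, and rebuilds the true alignment with `-` where a segment is
#' absent.  Events are inherited by all descendants of their branch.
#'
#' Construction guarantees at zero substitution rate: SSM insertions are
#' exact tandem copies of the upstream flank, SSM deletions remove one copy
#' of an adjacent duplicate planted in the background sequence, plain events
#' are rejection-sampled to show no flank similarity at the detection
#' threshold, and mononucleotide events extend a homopolymer whose flanking
#' base matches.  `flank_noise > 0` deliberately degrades the SSM copies.
#'
#' @param tip_seqs character matrix from [evolve_sequences()]
#' @param tree the generating [ape::phylo]
#' @param config a [simulation_config()]
#' @return a `synthetic_dataset` list: `alignment`
#'   ([multiple_alignment()]), `tree`, `annotation`
#'   ([region_annotation()]), `truth` (data.frame of events with columns
#'   `branch`, `type`, `start`, `end`, `length`, `members` comma-joined) and
#'   `sequences` (ungapped per-taxon final sequences)
#' @export
inject_indels <- function(tip_seqs, tree, config) {
  L <- ncol(tip_seqs)
  taxa <- rownames(tip_seqs)
  n_tip <- length(taxa)
  desc <- branch_descendants(tree)
  edges <- tree$edge
  n_events <- stats::rpois(nrow(edges), config$events_per_branch)
  total <- sum(n_events)
  max_len <- 2L + stats::qgeom(0.999, config$length_p)
  margin <- max(200L, 2L * (config$terminal_gap_max + max_len))
  sep <- 2L * max_len + 10L
  occupied <- matrix(numeric(0), ncol = 2)
  events <- list()
  retries <- 200L * max(total, 1L)
  draw_type <- function() {
    if (stats::runif(1) < config$mononucleotide_fraction) return("mononucleotide")
    ssm <- stats::runif(1) < config$ssm_fraction
    ins <- stats::runif(1) < 0.5
    if (ssm && ins) "ssm_insertion"
    else if (ssm) "ssm_deletion"
    else if (ins) "plain_insertion"
    else "plain_deletion"
  }
  for (e in seq_len(nrow(edges))) {
    members <- desc[[edges[e, 2]]]
    if (n_events[e] == 0) next
    for (k in seq_len(n_events[e])) {
      type <- draw_type()
      len <- rgeom_min2(1L, config$length_p)
      len <- min(len, max_len)
      placed <- FALSE
      while (retries > 0) {
        retries <- retries - 1L
        pos <- sample(seq.int(margin, L - margin), 1L)
        lo <- pos - len - sep; hi <- pos + len + sep
        if (nrow(occupied) == 0 ||
            all(hi < occupied[, 1] | lo > occupied[, 2])) {
          occupied <- rbind(occupied, c(lo, hi))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("cannot place requested indel density without overlap; ",
             "reduce events_per_branch or lengthen the sequence",
             call. = FALSE)
      }
      events[[length(events) + 1L]] <-
        list(branch = edges[e, 2], type = type, pos = pos, len = len,
             members = members)
    }
  }
  ## --- background surgery (applied to all rows so footprints stay clean)
  mutate_copy <- function(seg) {
    if (config$flank_noise == 0 || length(seg) == 0) return(seg)
    idx <- sample.int(length(seg), min(config$flank_noise, length(seg)))
    seg[idx] <- vapply(seg[idx], function(b)
      sample(setdiff(ALN_BASES, b), 1L), character(1))
    seg
  }
  random_segment <- function(len) {
    sample(ALN_BASES, len, replace = TRUE, prob = config$base_freq)
  }
  seg_identity <- function(a, b) if (length(a) == 0) 0 else mean(a == b)
  thr <- 0.80
  ## SSM motifs must not be homopolymers: a one-base tandem repeat is a
  ## mononucleotide repeat and is excluded from scoring by definition
  random_motif <- function(len) {
    repeat {
      seg <- random_segment(len)
      if (length(unique(seg)) > 1) return(seg)
    }
  }
  for (ev in events) {
    pos <- ev$pos; len <- ev$len
    first <- ev$members[1]
    if (ev$type == "ssm_insertion") {
      ## the copied motif: upstream flank [pos-len+1, pos]; force it common
      motif <- random_motif(len)
      tip_seqs[, (pos - len + 1L):pos] <-
        matrix(motif, n_tip, len, byrow = TRUE)
    } else if (ev$type == "ssm_deletion") {
      ## plant a duplicate upstream of the deleted segment in every row
      motif <- random_motif(len)
      tip_seqs[, pos:(pos + len - 1L)] <-
        matrix(motif, n_tip, len, byrow = TRUE)
      tip_seqs[, (pos - len):(pos - 1L)] <-
        matrix(mutate_copy(motif), n_tip, len, byrow = TRUE)
    } else if (ev$type == "mononucleotide") {
      b <- tip_seqs[first, pos]
      tip_seqs[, pos] <- b
    } else if (ev$type == "plain_deletion") {
      ## rewrite the doomed segment until its flanks show no repeat signal
      for (try in 1:100) {
        seg <- random_segment(len)
        up <- tip_seqs[first, (pos - len):(pos - 1L)]
        down <- tip_seqs[first, (pos + len):(pos + 2L * len - 1L)]
        if (length(unique(seg)) > 1 &&
            seg_identity(seg, up) < thr - 0.1 &&
            seg_identity(seg, down) < thr - 0.1) break
      }
      tip_seqs[, pos:(pos + len - 1L)] <-
        matrix(seg, n_tip, len, byrow = TRUE)
    }
  }
  ## --- build the true alignment
  ins_events <- Filter(function(ev)
    ev$type %in% c("ssm_insertion", "plain_insertion", "mononucleotide"),
    events)
  del_events <- Filter(function(ev)
    ev$type %in% c("ssm_deletion", "plain_deletion"), events)
  ins_pos <- vapply(ins_events, `[[`, numeric(1), "pos")
  ins_len <- vapply(ins_events, function(ev) ev$len, numeric(1))
  o <- order(ins_pos)
  ins_events <- ins_events[o]; ins_pos <- ins_pos[o]; ins_len <- ins_len[o]
  ## final index of master column j
  shift_at <- function(j) {
    if (length(ins_pos) == 0) return(j)
    j + sum(ins_len[ins_pos <= j - 1])
  }
  n_final <- L + sum(ins_len)
  aln_mat <- matrix(ALN_GAP, nrow = n_tip, ncol = n_final,
                    dimnames = list(taxa, NULL))
  master_final <- vapply(seq_len(L), shift_at, numeric(1))
  aln_mat[, master_final] <- tip_seqs
  truth <- list()
  for (i in seq_along(ins_events)) {
    ev <- ins_events[[i]]
    at <- shift_at(ev$pos)
    cols <- (at + 1L):(at + ev$len)
    content <- switch(ev$type,
      ssm_insertion = mutate_copy(tip_seqs[ev$members[1],
                                           (ev$pos - ev$len + 1L):ev$pos]),
      mononucleotide = rep(tip_seqs[ev$members[1], ev$pos], ev$len),
      plain_insertion = {
        up <- tip_seqs[ev$members[1], (ev$pos - ev$len + 1L):ev$pos]
        down <- tip_seqs[ev$members[1], (ev$pos + 1L):(ev$pos + ev$len)]
        seg <- up
        for (try in 1:100) {
          seg <- sample(ALN_BASES, ev$len, replace = TRUE,
                        prob = config$base_freq)
          if (length(unique(seg)) > 1 &&
              mean(seg == up) < thr - 0.1 &&
              mean(seg == down) < thr - 0.1) break
        }
        seg
      })
    aln_mat[ev$members, cols] <-
      matrix(content, length(ev$members), ev$len, byrow = TRUE)
    truth[[length(truth) + 1L]] <- data.frame(
      branch = ev$branch, type = ev$type, start = cols[1],
      end = cols[length(cols)], length = ev$len,
      members = paste(sort(ev$members), collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (ev in del_events) {
    cols <- shift_at(ev$pos):shift_at(ev$pos + ev$len - 1L)
    aln_mat[ev$members, cols] <- ALN_GAP
    truth[[length(truth) + 1L]] <- data.frame(
      branch = ev$branch, type = ev$type, start = cols[1],
      end = cols[length(cols)], length = ev$len,
      members = paste(sort(ev$members), collapse = ","),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(branch = integer(0), type = character(0), start = integer(0),
               end = integer(0), length = integer(0), members = character(0))
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  ## --- terminal-gap missing data
  n_trunc <- round(config$terminal_gap_fraction * n_tip)
  if (n_trunc > 0 && config$terminal_gap_max > 0) {
    rows <- sample.int(n_tip, n_trunc)
    for (r in rows) {
      tl <- sample.int(config$terminal_gap_max, 1L)
      if (stats::runif(1) < 0.5) {
        aln_mat[r, seq_len(tl)] <- ALN_GAP
      } else {
        aln_mat[r, (n_final - tl + 1L):n_final] <- ALN_GAP
      }
    }
  }
  aln <- multiple_alignment(aln_mat)
  annotation <- simulate_annotation(n_final, config)
  sequences <- vapply(taxa, function(t)
    paste(aln_mat[t, aln_mat[t, ] != ALN_GAP], collapse = ""), character(1))
  structure(list(alignment = aln, tree = tree, annotation = annotation,
                 truth = truth, sequences = sequences),
            class = "synthetic_dataset")
}

## tile the alignment into coding/intron/igs features; consecutive igs
## tiles merge so the annotation round-trips through GFF3 (igs is implicit)
simulate_annotation <- function(n_columns, config) {
  start <- integer(0); end <- integer(0); cls <- character(0)
  at <- 1L
  while (at <= n_columns) {
    len <- max(50L, stats::rpois(1, config$mean_feature_length))
    to <- min(n_columns, at + len - 1L)
    klass <- sample(names(config$class_mixture), 1L,
                    prob = config$class_mixture)
    if (klass == "igs" && length(cls) > 0 && cls[length(cls)] == "igs") {
      end[length(end)] <- to
    } else {
      start <- c(start, at); end <- c(end, to); cls <- c(cls, klass)
    }
    at <- to + 1L
  }
  within_class <- stats::ave(seq_along(cls), cls, FUN = seq_along)
  region_annotation(start, end, cls, sprintf("%s_%03d", cls, within_class))
}

#' Simulate a complete synthetic dataset
#'
#' Tree, sequences, indel injection and annotation, all driven by one seed.
#'
#' @param config a [simulation_config()]
#' @return a `synthetic_dataset` (see [inject_indels()])
#' @export
simulate_dataset <- function(config = simulation_config()) {
  set.seed(config$seed)
  tree <- simulate_tree(config$n_taxa, config$birth_rate)
  seqs <- evolve_sequences(tree, config)
  inject_indels(seqs, tree, config)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `alignment.fasta`, `tree.nwk`, `annotation.gff3` and `truth.tsv`;
#' [read_dataset()] reproduces the dataset from these files.
#'
#' @param dataset a `synthetic_dataset`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(dataset$alignment, file.path(dir, "alignment.fasta"))
  write_tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_region_annotation(dataset$annotation,
                          file.path(dir, "annotation.gff3"))
  write_tsv_with_header(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a synthetic dataset written by [write_dataset()]
#' @param dir dataset directory
#' @return a `synthetic_dataset` (without per-taxon node sequences)
#' @export
read_dataset <- function(dir) {
  aln <- read_alignment(file.path(dir, "alignment.fasta"))
  tree <- read_tree(file.path(dir, "tree.nwk"))
  annotation <- read_region_annotation(file.path(dir, "annotation.gff3"),
                                       n_columns(aln))
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
  sequences <- vapply(aln$taxa, function(t)
    paste(aln$mat[t, aln$mat[t, ] != ALN_GAP], collapse = ""), character(1))
  structure(list(alignment = aln, tree = tree, annotation = annotation,
                 truth = truth, sequences = sequences),
            class = "synthetic_dataset")
}
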