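# Independent brute-force oracles used across the suite.  These deliberately
# go through ape primitives (extract.clade, keep.tip, is.monophyletic) or
# plain enumeration rather than the package's own internals.

# all clades of a rooted tree as sorted label vectors (root clade included)
oracle_clades <- function(tree) {
  n <- length(tree$tip.label)
  lapply(seq.int(n + 1L, n + tree$Nnode), function(v)
    sort(ape::extract.clade(tree, v)$tip.label))
}

oracle_clade_keys <- function(tree, nontrivial = TRUE) {
  cl <- oracle_clades(tree)
  if (nontrivial) {
    n <- length(tree$tip.label)
    cl <- Filter(function(s) length(s) >= 2 && length(s) <= n - 1, cl)
  }
  unique(vapply(cl, paste, "", collapse = "\r"))
}

# resolution of one triple by pruning the tree to it
oracle_triple <- function(tree, trio) {
  trio <- sort(trio)
  sub <- ape::keep.tip(tree, trio)
  if (ape::is.monophyletic(sub, trio[c(1, 2)])) "ab|c"
  else if (ape::is.monophyletic(sub, trio[c(1, 3)])) "ac|b"
  else if (ape::is.monophyletic(sub, trio[c(2, 3)])) "bc|a"
  else NA_character_
}

# clade frequency tally across trees (percentages)
oracle_clade_tally <- function(trees) {
  keys <- unlist(lapply(trees, oracle_clade_keys))
  tab <- table(keys)
  stats::setNames(100 * as.vector(tab) / length(trees), names(tab))
}

# minimal Dollo loss count by exhaustive search over loss-edge subsets
oracle_dollo_count <- function(tree, states, gain_labels) {
  labs <- tree$tip.label
  n <- length(labs)
  clades <- c(as.list(labs), oracle_clades(tree))
  inside <- Filter(function(cl) all(cl %in% gain_labels) &&
                     length(cl) < length(gain_labels), clades)
  m <- length(inside)
  best <- Inf
  for (mask in 0:(2^m - 1)) {
    sel <- inside[bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L]
    if (length(sel) >= best) next
    lost <- unique(unlist(sel))
    impl <- ifelse(labs %in% gain_labels & !(labs %in% lost),
                   "present", "absent")
    ok <- TRUE
    for (i in seq_len(n)) {
      st <- states[[labs[i]]]
      if (st %in% c("present", "P") && impl[i] != "present") ok <- FALSE
      if (st %in% c("absent", "A") && impl[i] != "absent") ok <- FALSE
      if (!ok) break
    }
    if (ok) best <- length(sel)
  }
  best
}

# every rooted binary topology on a label set (105 trees for 5 labels)
all_rooted_topologies <- function(labels) {
  to_nwk <- function(t) {
    if (is.character(t)) t
    else paste0("(", to_nwk(t[[1]]), ",", to_nwk(t[[2]]), ")")
  }
  insert_everywhere <- function(t, lab) {
    res <- list(list(t, lab))
    if (is.list(t)) {
      for (i in 1:2) {
        for (s in insert_everywhere(t[[i]], lab)) {
          t2 <- t
          t2[[i]] <- s
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  trees <- list(labels[1])
  for (lab in labels[-1])
    trees <- unlist(lapply(trees, insert_everywhere, lab = lab),
                    recursive = FALSE)
  lapply(trees, function(t) ape::read.tree(text = paste0(to_nwk(t), ";")))
}

# expected triple counts on the caterpillar ((((A,B),C),D),E) with internal
# branch lengths tau (named by the clade's pipe-joined sorted leaves); paths
# are hand-enumerated, independent of the package's path machinery
caterpillar5_expected_counts <- function(tau_ab, tau_abc, tau_abcd, N = 1000) {
  species <- c("A", "B", "C", "D", "E")
  cmb <- utils::combn(5L, 3L)
  # join depth of each leaf pair on the caterpillar: A,B -> 4; +C -> 3; +D -> 2; +E -> 1
  joinlev <- matrix(0L, 5, 5)
  joinlev[1, 2] <- 4L
  joinlev[1:2, 3] <- 3L
  joinlev[1:3, 4] <- 2L
  joinlev[1:4, 5] <- 1L
  joinlev <- joinlev + t(joinlev)
  taus <- c(tau_abcd, tau_abc, tau_ab)  # tau of edge above node at level 2,3,4
  counts <- matrix(0, ncol(cmb), 3)
  for (t in seq_len(ncol(cmb))) {
    i <- cmb[1, t]; j <- cmb[2, t]; k <- cmb[3, t]
    lv <- c(joinlev[i, j], joinlev[i, k], joinlev[j, k])
    cherry <- which.max(lv)
    top <- min(lv)
    # path = edges above nodes at levels (top+1) .. max(lv)... wait: edges with child node levels top+1..deepest? child levels strictly below top down to cherry level
    path_levels <- seq.int(top + 1L, max(lv))
    Tt <- sum(taus[path_levels - 1L])
    p <- 1 - (2 / 3) * exp(-Tt)
    pr <- rep((1 - p) / 2, 3)
    pr[cherry] <- p
    counts[t, ] <- N * pr
  }
  redphylo::triple_counts(species, counts, n_trees = N)
}
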