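# Rooted-tree utilities shared by the whole pipeline.  Trees are ape "phylo"
# objects throughout; rooted semantics (clades, triples) are what matter here.

.root_node <- function(phy) length(phy$tip.label) + 1L

.parent_vec <- function(phy) {
  p <- integer(length(phy$tip.label) + phy$Nnode)
  p[phy$edge[, 2L]] <- phy$edge[, 1L]
  p
}

.children_list <- function(phy) {
  N <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", N)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1L]]] <- c(kids[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  kids
}

# topological depth (edge count from the root) of every node
.node_depths <- function(phy) {
  n <- length(phy$tip.label)
  d <- rep.int(NA_integer_, n + phy$Nnode)
  e <- stats::reorder(phy, "cladewise")$edge
  d[n + 1L] <- 0L
  for (i in seq_len(nrow(e))) d[e[i, 2L]] <- d[e[i, 1L]] + 1L
  d
}

# tip-index sets below every node (tips included as singletons)
.clade_leafsets <- function(phy) {
  n <- length(phy$tip.label)
  e <- stats::reorder(phy, "postorder")$edge
  sets <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  for (i in seq_len(nrow(e)))
    sets[[e[i, 1L]]] <- c(sets[[e[i, 1L]]], sets[[e[i, 2L]]])
  sets
}

.KEYSEP <- "\r"

.clade_key <- function(labels) paste(sort(labels), collapse = .KEYSEP)

# canonical keys of the non-trivial clades (2 <= size <= n-1) of a rooted tree
.clade_keys_nontrivial <- function(phy) {
  labs <- phy$tip.label
  n <- length(labs)
  sets <- .clade_leafsets(phy)
  out <- character(0)
  for (v in seq.int(n + 1L, n + phy$Nnode)) {
    s <- sets[[v]]
    if (length(s) >= 2L && length(s) <= n - 1L)
      out <- c(out, .clade_key(labs[s]))
  }
  unique(out)
}

.compatible_sets <- function(a, b) {
  inter <- length(intersect(a, b))
  inter == 0L || inter == length(a) || inter == length(b)
}

.check_newick_string <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i),
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at character %d",
                 depth, length(chars)), call. = FALSE)
  if (!grepl(";[[:space:]]*$", s))
    stop(sprintf("malformed Newick: missing ';' at character %d", nchar(s)),
         call. = FALSE)
  invisible(TRUE)
}

#' Read trees from Newick text or file
#'
#' Thin wrapper around [ape::read.tree()] that first validates bracket
#' balance and the terminal semicolon, reporting the character offset of the
#' first problem.  Internal node labels, when present, are kept verbatim
#' (they typically carry support percentages).
#'
#' @param file Path to a Newick file (one tree per line, `;`-terminated).
#' @param text Newick string(s); used when `file` is `NULL`.
#' @param simplify If `TRUE` (default) a single tree is returned as a `phylo`
#'   object rather than a length-1 `multiPhylo`.
#' @return A `phylo` or `multiPhylo` object.
#' @export
read_newick <- function(file = NULL, text = NULL, simplify = TRUE) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'")
    text <- readLines(file, warn = FALSE)
  }
  text <- text[nzchar(trimws(text))]
  if (!length(text)) stop("no Newick trees found")
  for (s in text) .check_newick_string(s)
  trees <- ape::read.tree(text = paste(text, collapse = "\n"))
  if (simplify && inherits(trees, "multiPhylo") && length(trees) == 1L)
    trees <- trees[[1L]]
  trees
}

#' Write trees as Newick
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param file Optional path; when `NULL` the Newick string(s) are returned.
#' @param digits Significant digits for branch lengths (default 10).
#' @return The Newick string(s), invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10L) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Root a tree with an outgroup
#'
#' Places the root on the branch separating `outgroup` from all remaining
#' leaves.  The outgroup must be separable, i.e. some bipartition of the
#' unrooted topology must divide it from the ingroup; otherwise an error
#' names the leaves entangled with it.  A tree already rooted this way is
#' returned unchanged.
#'
#' @param tree A `phylo` object.
#' @param outgroup Character vector of outgroup leaf labels.
#' @return A rooted `phylo` object whose root separates `outgroup` from the
#'   ingroup.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  outgroup <- unique(outgroup)
  labs <- tree$tip.label
  miss <- setdiff(outgroup, labs)
  if (length(miss))
    stop("outgroup label(s) not in tree: ", paste(miss, collapse = ", "))
  if (length(outgroup) >= length(labs))
    stop("outgroup must be a proper subset of the leaves")
  og <- sort(match(outgroup, labs))
  sets <- .clade_leafsets(tree)
  # identity case: root already separates outgroup from ingroup
  kids <- .children_list(tree)[[.root_node(tree)]]
  for (k in kids)
    if (identical(sort(sets[[k]]), og) ||
        identical(sort(sets[[k]]), sort(setdiff(seq_along(labs), og))))
      if (length(kids) == 2L) return(tree)
  if (length(outgroup) > 1L) {
    comp <- sort(setdiff(seq_along(labs), og))
    sep <- any(vapply(sets, function(s) identical(sort(s), og) ||
                        identical(sort(s), comp), logical(1L)))
    if (!sep) {
      mr <- ape::getMRCA(tree, outgroup)
      extra <- setdiff(labs[sets[[mr]]], outgroup)
      stop("outgroup {", paste(sort(outgroup), collapse = ","),
           "} is not separable: its smallest containing clade also holds {",
           paste(sort(extra), collapse = ","), "}")
    }
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Test whether a label set forms a clade
#'
#' `TRUE` iff some node of the rooted tree has exactly the given labels as
#' its leaf descendants.  Singletons are trivially monophyletic.
#'
#' @param tree A rooted `phylo` object.
#' @param labels Character vector of leaf labels (all must occur in the tree).
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, labels) {
  labs <- tree$tip.label
  labels <- unique(labels)
  miss <- setdiff(labels, labs)
  if (length(miss)) stop("unknown label(s): ", paste(miss, collapse = ", "))
  target <- sort(match(labels, labs))
  if (length(target) <= 1L) return(TRUE)
  sets <- .clade_leafsets(tree)
  any(vapply(sets, function(s) length(s) == length(target) &&
               identical(sort(s), target), logical(1L)))
}

# Pairwise MRCA topological depths over tips, by one postorder sweep
# (avoids per-tree ape::mrca/reorder overhead when counting many gene trees).
.mrca_depths <- function(phy) {
  n <- length(phy$tip.label)
  kids <- .children_list(phy)
  D <- matrix(0L, n, n)
  rec <- function(v, d) {
    if (v <= n) return(v)
    merged <- integer(0)
    for (ch in kids[[v]]) {
      s <- rec(ch, d + 1L)
      if (length(merged)) {
        ii <- rep(merged, times = length(s))
        jj <- rep(s, each = length(merged))
        D[cbind(ii, jj)] <<- d
        D[cbind(jj, ii)] <<- d
      }
      merged <- c(merged, s)
    }
    merged
  }
  rec(n + 1L, 0L)
  D
}

# Resolution codes for a triple i<j<k (indices into the sorted species
# vector): 1 = ij|k, 2 = ik|j, 3 = jk|i, NA = unresolved (polytomy).
.triple_resolutions <- function(tree, species, cmb) {
  pos <- match(species, tree$tip.label)
  Dm <- .mrca_depths(tree)[pos, pos, drop = FALSE]
  i <- cmb[1L, ]; j <- cmb[2L, ]; k <- cmb[3L, ]
  dij <- Dm[cbind(i, j)]; dik <- Dm[cbind(i, k)]; djk <- Dm[cbind(j, k)]
  mx <- pmax(dij, dik, djk)
  nmx <- (dij == mx) + (dik == mx) + (djk == mx)
  res <- rep(NA_integer_, length(i))
  res[nmx == 1L & dij == mx] <- 1L
  res[nmx == 1L & dik == mx] <- 2L
  res[nmx == 1L & djk == mx] <- 3L
  res
}

#' Extract all rooted triples of a tree
#'
#' Restricts the rooted tree to every 3-leaf subset and reports the induced
#' resolution.  Labels `a < b < c` are sorted; the resolution names the
#' cherry pair (`"ab|c"` means `a` and `b` coalesce first).  Triples falling
#' on a polytomy get `NA`.
#'
#' @param tree A rooted `phylo` with at least 3 leaves.
#' @return A data frame with columns `a`, `b`, `c`, `resolution`.
#' @export
extract_triples <- function(tree) {
  labs <- tree$tip.label
  if (anyDuplicated(labs)) stop("duplicate leaf labels in tree")
  n <- length(labs)
  if (n < 3L) stop("tree has fewer than 3 leaves")
  S <- sort(labs)
  cmb <- utils::combn(n, 3L)
  res <- .triple_resolutions(tree, S, cmb)
  data.frame(a = S[cmb[1L, ]], b = S[cmb[2L, ]], c = S[cmb[3L, ]],
             resolution = c("ab|c", "ac|b", "bc|a")[res],
             stringsAsFactors = FALSE)
}

#' Majority-rule consensus of rooted trees
#'
#' Tallies non-trivial clades across the input trees.  In `"strict"`
#' (majority-rule) mode only clades occurring in more than half of the trees
#' are kept; `"extended"` mode (the Phylip `consense` default) then greedily
#' adds the remaining clades in descending frequency whenever they are
#' compatible with everything accepted so far.  Clades at exactly 50% are
#' excluded from the majority stage but eligible for greedy addition.
#' Internal node labels of the result carry the percentage of input trees
#' containing each clade, rounded to one decimal.
#'
#' @param trees A list or `multiPhylo` of rooted trees on one leaf set.
#' @param mode `"extended"` (default) or `"strict"`.
#' @return A `phylo` object, possibly with polytomies; node labels are
#'   support percentages in `[0, 100]`.
#' @export
consensus_tree <- function(trees, mode = c("extended", "strict")) {
  mode <- match.arg(mode)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one input tree")
  labs0 <- sort(trees[[1L]]$tip.label)
  for (t in trees) {
    lt <- sort(t$tip.label)
    if (!identical(lt, labs0)) {
      dd <- sort(unique(c(setdiff(labs0, lt), setdiff(lt, labs0))))
      stop("input trees do not share one leaf set; symmetric difference: ",
           paste(dd, collapse = ", "))
    }
  }
  ntr <- length(trees)
  tab <- table(unlist(lapply(trees, .clade_keys_nontrivial)))
  cnt <- as.integer(tab)
  keys <- names(tab)
  pct <- 100 * cnt / ntr
  ord <- order(-cnt, keys)
  acc_sets <- list()
  acc_sup <- numeric(0)
  for (idx in ord) {
    s <- strsplit(keys[idx], .KEYSEP, fixed = TRUE)[[1L]]
    take <- if (pct[idx] > 50) TRUE
            else if (mode == "strict") FALSE
            else all(vapply(acc_sets, .compatible_sets, logical(1L), b = s))
    if (take) {
      acc_sets <- c(acc_sets, list(s))
      acc_sup <- c(acc_sup, pct[idx])
    }
  }
  .build_from_clades(labs0, acc_sets, acc_sup)
}

# Build a rooted tree from a mutually compatible set of clades; supports are
# attached as internal node labels (1 decimal place).  The root carries no
# label.  Child order is by smallest contained leaf label, for determinism.
.build_from_clades <- function(labels, sets, supports) {
  fmt <- function(x) sprintf("%.10g", round(x, 1))
  build <- function(members, idx) {
    # idx: indices of sets strictly inside 'members'
    maxi <- idx[vapply(idx, function(i) {
      !any(vapply(idx, function(j) j != i &&
                    all(sets[[i]] %in% sets[[j]]), logical(1L)))
    }, logical(1L))]
    parts <- character(0)
    mins <- character(0)
    used <- character(0)
    for (i in maxi) {
      s <- sets[[i]]
      inner <- idx[vapply(idx, function(j) length(sets[[j]]) < length(s) &&
                            all(sets[[j]] %in% s), logical(1L))]
      parts <- c(parts, paste0(build(s, inner), fmt(supports[i])))
      mins <- c(mins, min(s))
      used <- c(used, s)
    }
    singles <- sort(setdiff(members, used))
    parts <- c(parts, singles)
    mins <- c(mins, singles)
    parts <- parts[order(mins)]
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(build(labels, seq_along(sets)), ";")
  ape::read.tree(text = nwk)
}

#' Rooted Robinson-Foulds distance
#'
#' The size of the symmetric difference between the non-trivial clade sets of
#' two rooted trees on the same leaves.
#'
#' @param t1,t2 Rooted `phylo` objects with identical leaf sets.
#' @return Non-negative integer.
#' @export
rf_dist <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    dd <- sort(unique(c(setdiff(t1$tip.label, t2$tip.label),
                        setdiff(t2$tip.label, t1$tip.label))))
    stop("leaf sets differ; symmetric difference: ", paste(dd, collapse = ", "))
  }
  k1 <- .clade_keys_nontrivial(t1)
  k2 <- .clade_keys_nontrivial(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# Canonical topology string: children sorted recursively; used for
# de-duplication and deterministic tie-breaking in the tree search.
canonical_newick <- function(tree) {
  labs <- tree$tip.label
  kids <- .children_list(tree)
  rec <- function(v) {
    if (v <= length(labs)) return(labs[v])
    subs <- sort(vapply(kids[[v]], rec, character(1L)))
    paste0("(", paste(subs, collapse = ","), ")")
  }
  paste0(rec(.root_node(tree)), ";")
}
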