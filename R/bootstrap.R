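# Two-level nonparametric bootstrap for coalescence-based species trees:
# genes are resampled with replacement, sites are resampled within each
# sampled gene, per-gene trees are estimated and rooted, a pseudo-likelihood
# species tree is fit per replicate, and replicates are summarised by
# majority-rule consensus.

#' Resample genes with replacement
#'
#' @param alignments Named list of alignments.
#' @param seed Optional RNG seed.
#' @return A list of the same size drawn uniformly with replacement.
#' @export
resample_genes <- function(alignments, seed = NULL) {
  if (!length(alignments)) stop("no alignments to resample")
  if (!is.null(seed)) set.seed(seed)
  alignments[sample.int(length(alignments), length(alignments),
                        replace = TRUE)]
}

#' Resample alignment sites with replacement
#'
#' Each output column is a copy of a uniformly drawn input column; rows are
#' kept intact, so within-column linkage is preserved.  The column count is
#' unchanged.
#'
#' @param aln A character matrix alignment with at least one column.
#' @param seed Optional RNG seed.
#' @return The pseudo-alignment.
#' @export
resample_sites <- function(aln, seed = NULL) {
  if (!ncol(aln)) stop("alignment has no columns")
  if (!is.null(seed)) set.seed(seed)
  out <- aln[, sample.int(ncol(aln), ncol(aln), replace = TRUE), drop = FALSE]
  attr(out, "id") <- attr(aln, "id")
  out
}

#' Poisson-corrected protein distance
#'
#' Pairwise mismatch proportion `p` over columns where both rows are non-gap,
#' corrected as `d = -ln(1 - p)`.  Pairs with no shared non-gap column or
#' with `p = 1` are capped at `cap` with a warning; finite corrections are
#' also truncated at `cap`.
#'
#' @param aln A character matrix alignment.
#' @param cap Upper bound on any distance (default 10).
#' @return A `dist` object over the alignment rows.
#' @export
protein_distance <- function(aln, cap = 10) {
  n <- nrow(aln)
  if (n < 2L) stop("need at least two sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  nongap <- aln != "-"
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- nongap[i, ] & nongap[j, ]
      ns <- sum(ok)
      if (!ns) {
        d <- cap
        warned <- TRUE
      } else {
        p <- sum(aln[i, ok] != aln[j, ok]) / ns
        if (p >= 1) {
          d <- cap
          warned <- TRUE
        } else d <- min(-log(1 - p), cap)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (warned)
    warning("saturated or non-overlapping sequence pair(s); distance capped at ",
            cap)
  stats::as.dist(D)
}

#' Neighbor-joining tree from a distance matrix, optionally rooted
#'
#' @param d A `dist` object or symmetric matrix.
#' @param outgroup Optional label set; labels present in `d` are used to
#'   root the NJ tree via [root_with_outgroup()].
#' @return A `phylo` object (rooted when an outgroup label is present).
#' @export
distance_tree <- function(d, outgroup = NULL) {
  tr <- ape::nj(stats::as.dist(d))
  if (!is.null(outgroup)) {
    og <- intersect(outgroup, tr$tip.label)
    if (length(og)) tr <- root_with_outgroup(tr, og)
  }
  tr
}

#' Estimate a rooted gene tree from a protein alignment
#'
#' The internal distance-based estimator: neighbor joining on the
#' Poisson-corrected distance of [protein_distance()], rooted with the
#' outgroup.  Row ids of the form `"taxon|gene"` are relabelled to their
#' taxon prefix so the tree's leaves are species ids.  This is a fast
#' substitute for per-gene maximum-likelihood inference; any function with
#' the same signature can replace it in [mpest_bootstrap()].
#'
#' @param aln A character matrix alignment with at least 3 rows.
#' @param outgroup Character vector of outgroup taxon ids (used for rooting
#'   when present).
#' @return A rooted `phylo` whose tips are taxon ids.
#' @export
estimate_gene_tree <- function(aln, outgroup = outgroup_priority()) {
  if (nrow(aln) < 3L) stop("need at least 3 sequences")
  tax <- seq_taxon(rownames(aln))
  if (anyDuplicated(tax))
    stop("multiple rows per taxon: ",
         paste(unique(tax[duplicated(tax)]), collapse = ", "))
  rownames(aln) <- tax
  d <- protein_distance(aln)
  distance_tree(d, outgroup = outgroup)
}

#' Two-level bootstrap species-tree analysis
#'
#' Per replicate: genes are resampled with replacement, sites are resampled
#' within each sampled gene, the outgroup is reduced to one prioritised
#' green sequence, a rooted gene tree is estimated per gene, outgroup tips
#' are pruned (they exist only to root and may differ across genes), and a
#' pseudo-likelihood species tree is fit with [mpest()].  Replicates are
#' summarised by majority-rule consensus; node labels of the consensus give
#' the percentage of replicate trees containing each clade, which equals the
#' clade's raw frequency among replicates.
#'
#' Gene- and site-level RNG streams are derived from the master seed by
#' replicate and gene index, so each replicate is individually reproducible.
#' A failing replicate is recorded and skipped; the run errors if more than
#' 10% of replicates fail.
#'
#' @param alignments Named list of gene alignments (rows `"taxon|gene"`),
#'   already filtered (see [select_single_copy()], [filter_alignments()]).
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Master RNG seed (required for reproducibility).
#' @param outgroup Ordered outgroup priority (default [outgroup_priority()]).
#' @param gene_tree_fun Function `(alignment, outgroup) -> rooted phylo`;
#'   default [estimate_gene_tree()].
#' @param n_restarts Restarts passed to [mpest()] per replicate (default 2).
#' @param consensus_mode Passed to [consensus_tree()].
#' @param resample_genes,resample_sites Logical switches for the two
#'   resampling levels (both `TRUE` for the bootstrap proper; disabling them
#'   is useful for diagnostics).
#' @return An object of class `"mpest_boot"`: list with `replicates`
#'   (`multiPhylo`), `consensus` (`phylo` with percent supports as node
#'   labels), `log` (per-replicate data frame), `n_replicates`, `seed`.
#' @export
mpest_bootstrap <- function(alignments, n_replicates = 100L, seed = NULL,
                            outgroup = outgroup_priority(),
                            gene_tree_fun = estimate_gene_tree,
                            n_restarts = 2L,
                            consensus_mode = c("extended", "strict"),
                            resample_genes = TRUE, resample_sites = TRUE) {
  consensus_mode <- match.arg(consensus_mode)
  if (!length(alignments)) stop("no alignments supplied")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  G <- length(alignments)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  rep_trees <- vector("list", n_replicates)
  ok <- logical(n_replicates)
  msg <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      set.seed(rep_seeds[r])
      idx <- if (resample_genes)
        sample.int(G, G, replace = TRUE) else seq_len(G)
      gene_seeds <- sample.int(.Machine$integer.max - 1L, G)
      gts <- vector("list", G)
      for (g in seq_len(G)) {
        a <- alignments[[idx[g]]]
        if (resample_sites) a <- resample_sites(a, seed = gene_seeds[g])
        a <- reduce_outgroup(a, priority = outgroup)
        tr <- gene_tree_fun(a, outgroup)
        og <- intersect(tr$tip.label, outgroup)
        if (length(og)) tr <- ape::drop.tip(tr, og)
        gts[[g]] <- tr
      }
      fit <- mpest(count_triples(gts), n_restarts = n_restarts)
      .strip_lengths(fit$tree)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      ok[r] <- FALSE
      msg[r] <- conditionMessage(res)
    } else {
      ok[r] <- TRUE
      rep_trees[[r]] <- res
    }
  }
  if (sum(!ok) > 0.1 * n_replicates)
    stop(sprintf("%d of %d bootstrap replicates failed; first error: %s",
                 sum(!ok), n_replicates, msg[which(!ok)[1L]]))
  trees <- rep_trees[ok]
  class(trees) <- "multiPhylo"
  structure(list(replicates = trees,
                 consensus = consensus_tree(trees, mode = consensus_mode),
                 log = data.frame(replicate = seq_len(n_replicates),
                                  seed = rep_seeds, ok = ok, error = msg,
                                  stringsAsFactors = FALSE),
                 n_replicates = n_replicates, seed = seed),
            class = "mpest_boot")
}

#' @export
print.mpest_boot <- function(x, ...) {
  cat("Two-level bootstrap species-tree analysis\n")
  cat("  replicates:", length(x$replicates), "of", x$n_replicates,
      "successful\n")
  cat("  consensus: ", ape::write.tree(x$consensus), "\n", sep = "")
  invisible(x)
}

#' @method plot mpest_boot
#' @export
plot.mpest_boot <- function(x, ...) {
  ape::plot.phylo(x$consensus, ...)
  if (!is.null(x$consensus$node.label))
    ape::nodelabels(x$consensus$node.label, frame = "none", adj = c(1.1, -0.3))
  invisible(x)
}
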