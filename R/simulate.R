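# Synthetic-data generators: multispecies-coalescent gene trees, protein
# alignments evolved on them, orthogroup fixtures with planted filter
# verdicts, and presence/absence characters with planted loss events.
# Everything is deterministic given its seed.

#' Simulate gene trees under the multispecies coalescent
#'
#' One lineage is sampled per species.  Within each species-tree branch of
#' length `t` (coalescent units), `k` lineages coalesce with exponential
#' waiting times at rate `k(k-1)/2`, truncated at `t`; lineages remaining at
#' the root coalesce in an unbounded root branch.  Gene-tree branch lengths
#' are in coalescent units.
#'
#' @param species_tree Binary rooted `phylo` with branch lengths in
#'   coalescent units.
#' @param n_genes Number of gene trees to draw.
#' @param seed Optional RNG seed.
#' @return A `multiPhylo` list of rooted binary gene trees on the species
#'   labels.
#' @export
sim_msc_gene_trees <- function(species_tree, n_genes, seed = NULL) {
  .check_binary_rooted(species_tree)
  if (is.null(species_tree$edge.length) || anyNA(species_tree$edge.length))
    stop("species tree needs branch lengths in coalescent units")
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  phy <- species_tree
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  po <- stats::reorder(phy, "postorder")
  pe <- po$edge
  ce <- stats::reorder(phy, "cladewise")
  d <- numeric(N)
  for (i in seq_len(nrow(ce$edge)))
    d[ce$edge[i, 2L]] <- d[ce$edge[i, 1L]] + ce$edge.length[i]
  age <- max(d[seq_len(n)]) - d
  root <- n + 1L
  nint <- 2L * n - 1L
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    gage <- numeric(nint)
    gch1 <- integer(nint)
    gch2 <- integer(nint)
    gage[seq_len(n)] <- age[seq_len(n)]
    cnt <- n
    coalesce <- function(L, start, top) {
      k <- length(L)
      cur <- start
      while (k >= 2L) {
        w <- stats::rexp(1L, k * (k - 1L) / 2)
        if (cur + w > top) break
        cur <- cur + w
        pick <- sample.int(k, 2L)
        cnt <<- cnt + 1L
        gage[cnt] <<- cur
        gch1[cnt] <<- L[pick[1L]]
        gch2[cnt] <<- L[pick[2L]]
        L <- c(L[-pick], cnt)
        k <- k - 1L
      }
      L
    }
    lin <- vector("list", N)
    for (i in seq_len(n)) lin[[i]] <- i
    for (i in seq_len(nrow(pe))) {
      p <- pe[i, 1L]
      ch <- pe[i, 2L]
      lin[[p]] <- c(lin[[p]], coalesce(lin[[ch]], age[ch], age[p]))
    }
    coalesce(lin[[root]], age[root], Inf)
    # renumber so the root (last-created internal node) becomes n+1
    perm <- seq_len(nint)
    if (nint - 1L >= n + 1L) perm[(n + 1L):(nint - 1L)] <- (n + 2L):nint
    perm[nint] <- n + 1L
    e <- matrix(0L, 2L * (n - 1L), 2L)
    el <- numeric(2L * (n - 1L))
    r <- 0L
    for (gid in (n + 1L):nint) {
      for (chg in c(gch1[gid], gch2[gid])) {
        r <- r + 1L
        e[r, 1L] <- perm[gid]
        e[r, 2L] <- perm[chg]
        el[r] <- gage[gid] - gage[chg]
      }
    }
    tr <- list(edge = e, edge.length = el, tip.label = phy$tip.label,
               Nnode = n - 1L)
    class(tr) <- "phylo"
    out[[g]] <- tr
  }
  class(out) <- "multiPhylo"
  out
}

#' Simulate a protein alignment on a gene tree
#'
#' The root sequence is uniform over the 20 amino acids; along each branch of
#' length `b` (expected substitutions/site, after scaling by `rate`) each
#' site changes with probability `(19/20)(1 - exp(-(20/19) b))` and, when it
#' changes, moves to one of the other 19 residues uniformly (the 20-state
#' equal-exchangeability model, for which branch composition is exact).
#'
#' @param gene_tree Rooted `phylo` with branch lengths.
#' @param n_columns Number of alignment columns.
#' @param seed Optional RNG seed.
#' @param rate Multiplier mapping the tree's branch-length units to expected
#'   substitutions/site (default 1).
#' @return A character matrix alignment (rows = tips).
#' @export
sim_alignment <- function(gene_tree, n_columns, seed = NULL, rate = 1) {
  if (is.null(gene_tree$edge.length) || anyNA(gene_tree$edge.length))
    stop("gene tree needs branch lengths")
  if (n_columns < 1L) stop("need at least one column")
  if (!is.null(seed)) set.seed(seed)
  phy <- stats::reorder(gene_tree, "cladewise")
  n <- length(phy$tip.label)
  seqs <- matrix(0L, n + phy$Nnode, n_columns)
  seqs[n + 1L, ] <- sample.int(20L, n_columns, replace = TRUE)
  for (i in seq_len(nrow(phy$edge))) {
    b <- phy$edge.length[i] * rate
    pchange <- (19 / 20) * (1 - exp(-(20 / 19) * b))
    s <- seqs[phy$edge[i, 1L], ]
    flip <- stats::runif(n_columns) < pchange
    nf <- sum(flip)
    if (nf)
      s[flip] <- ((s[flip] - 1L + sample.int(19L, nf, replace = TRUE)) %% 20L) + 1L
    seqs[phy$edge[i, 2L], ] <- s
  }
  m <- matrix(.AA[seqs[seq_len(n), , drop = FALSE]], n, n_columns)
  rownames(m) <- phy$tip.label
  m
}

.random_aa_rows <- function(ids, n_col) {
  m <- matrix(sample(.AA, length(ids) * n_col, replace = TRUE),
              length(ids), n_col)
  rownames(m) <- ids
  m
}

#' Generate an orthogroup fixture with planted filter verdicts
#'
#' Builds groups and alignments realising, by construction, each category of
#' the single-copy selection and alignment filters: `clean` (passes
#' everything; the first clean group sits exactly on the passing boundary:
#' 151 columns, 15 sequences given the 18-taxon design), `multi_copy` (one
#' taxon contributes two members), `red_missing` (`max_missing_red + 1`
#' red taxa absent), `green_missing` (`max_missing_green + 1` green taxa
#' absent), `short_alignment` (150 columns, one short of passing) and
#' `few_sequences` (one sequence below `min_sequences`).
#'
#' @param taxa Taxon table (defaults to [rhodophyta_taxa()]).
#' @param counts Named integer vector of groups per category.
#' @param seed Optional RNG seed.
#' @param length_range Column-count range for non-boundary alignments.
#' @param max_missing_red,max_missing_green Thresholds the violators are
#'   planted against (defaults 3 and 1).
#' @return A list with `groups` (an `"orthogroups"` object), `alignments`
#'   (named list of matrices) and `truth` (data frame `group`, `category`,
#'   `expected_pass`).
#' @export
sim_orthogroup_fixture <- function(taxa = rhodophyta_taxa(),
                                   counts = c(clean = 10L, multi_copy = 5L,
                                              red_missing = 5L,
                                              green_missing = 5L,
                                              short_alignment = 3L,
                                              few_sequences = 3L),
                                   seed = NULL,
                                   length_range = c(160L, 300L),
                                   max_missing_red = 3L,
                                   max_missing_green = 1L) {
  if (any(counts < 0)) stop("category counts must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  red <- taxa$taxon_id[taxa$group == "red"]
  green <- taxa$taxon_id[taxa$group == "green"]
  cats <- rep(names(counts), counts)
  ng <- length(cats)
  gids <- sprintf("OG%04d", seq_len(ng))
  groups <- vector("list", ng)
  names(groups) <- gids
  alns <- vector("list", ng)
  names(alns) <- gids
  rand_len <- function() sample(length_range[1L]:length_range[2L], 1L)
  for (i in seq_len(ng)) {
    cat_i <- cats[i]
    nc <- rand_len()
    present <- c(red, green)
    extra <- character(0)
    if (cat_i == "clean") {
      first_clean <- !any(cats[seq_len(i - 1L)] == "clean")
      if (first_clean) {
        present <- c(red[-seq_len(3L)], green)  # boundary: 15 rows
        nc <- 151L
      } else {
        # joint missingness capped so clean groups keep >= 15 sequences
        drop_g <- sample(0:max_missing_green, 1L)
        drop_r <- sample(0:(max_missing_red - drop_g), 1L)
        present <- c(if (drop_r) red[-sample(seq_along(red), drop_r)] else red,
                     if (drop_g) green[-sample(seq_along(green), drop_g)]
                     else green)
      }
    } else if (cat_i == "multi_copy") {
      extra <- red[1L]
    } else if (cat_i == "red_missing") {
      present <- c(red[-sample(seq_along(red), max_missing_red + 1L)], green)
    } else if (cat_i == "green_missing") {
      present <- c(red, green[-sample(seq_along(green),
                                      max_missing_green + 1L)])
    } else if (cat_i == "short_alignment") {
      nc <- 150L
    } else if (cat_i == "few_sequences") {
      present <- c(red[-sample(seq_along(red), max_missing_red)],
                   green[-sample(seq_along(green), max_missing_green)])
    } else stop("unknown category: ", cat_i)
    member_tax <- c(present, extra)
    genes <- paste0(gids[i], "_g", seq_along(member_tax))
    members <- paste0(member_tax, "|", genes)
    groups[[i]] <- data.frame(taxon = member_tax, gene = genes,
                              member = members, stringsAsFactors = FALSE)
    a <- .random_aa_rows(members, nc)
    attr(a, "id") <- gids[i]
    alns[[i]] <- a
  }
  class(groups) <- "orthogroups"
  list(groups = groups, alignments = alns,
       truth = data.frame(group = gids, category = cats,
                          expected_pass = cats == "clean",
                          stringsAsFactors = FALSE))
}

#' Generate a presence/absence character with planted losses
#'
#' Leaves under any planted loss clade are scored `absent` (or `ambiguous`
#' when listed in `ambiguous_taxa`); all other leaves are `present`.  On
#' non-degenerate scenarios (disjoint, non-adjacent loss clades each
#' retaining at least one strict absence) [dollo_losses()] recovers exactly
#' the planted loss edges.
#'
#' @param species_tree Rooted `phylo`.
#' @param loss_clades List of character vectors; each must be a clade of the
#'   tree and they must be pairwise disjoint.
#' @param ambiguous_taxa Leaves (within loss clades) to score `ambiguous`
#'   instead of `absent`.
#' @return Named character vector of states over the tree's leaves.
#' @export
sim_presence_scenario <- function(species_tree, loss_clades,
                                  ambiguous_taxa = character(0)) {
  labs <- species_tree$tip.label
  states <- stats::setNames(rep("present", length(labs)), labs)
  seen <- character(0)
  for (cl in loss_clades) {
    if (!is_monophyletic(species_tree, cl))
      stop("planted loss set {", paste(sort(cl), collapse = ","),
           "} is not a clade of the species tree")
    ov <- intersect(seen, cl)
    if (length(ov))
      stop("overlapping loss clades at: ", paste(sort(ov), collapse = ", "))
    seen <- c(seen, cl)
    states[cl] <- "absent"
  }
  amb <- intersect(ambiguous_taxa, seen)
  states[amb] <- "ambiguous"
  states
}
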