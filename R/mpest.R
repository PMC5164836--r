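# Maximum pseudo-likelihood species-tree estimation from rooted gene trees
# under the multispecies coalescent (MP-EST-style).  The sufficient statistic
# is the table of rooted-triple resolution counts across gene trees; the
# pseudo-likelihood treats triples as independent multinomials whose
# concordance probability is 1 - (2/3)exp(-T), with T the internal
# coalescent-unit path length separating the triple's two speciation nodes.

#' Rooted-triple resolution probabilities under the coalescent
#'
#' For a species triple whose two speciation nodes are separated by an
#' internal path of length `T` coalescent units, the gene-tree triple matches
#' the species tree with probability `1 - (2/3) exp(-T)`; each of the two
#' discordant resolutions has probability `(1/3) exp(-T)`.
#'
#' @param T Non-negative coalescent-unit path length(s).
#' @return A matrix with columns `concordant`, `discordant1`, `discordant2`;
#'   rows sum to 1.
#' @export
triple_probabilities <- function(T) {
  if (any(!is.finite(T) & !is.infinite(T)) || any(T < 0))
    stop("coalescent path length T must be >= 0")
  pc <- 1 - (2 / 3) * exp(-T)
  cbind(concordant = pc, discordant1 = (1 - pc) / 2, discordant2 = (1 - pc) / 2)
}

#' Construct a triple-count table
#'
#' @param species Sorted character vector of species labels (n >= 3).
#' @param counts `choose(n, 3) x 3` matrix of non-negative counts; row order
#'   follows `utils::combn(n, 3)` over the sorted species, columns are the
#'   resolutions `ij|k`, `ik|j`, `jk|i` for the triple `i < j < k`.
#' @param n_trees Number of gene trees the counts were taken from.
#' @return An object of class `"triple_counts"`.
#' @export
triple_counts <- function(species, counts, n_trees = max(rowSums(counts))) {
  species <- as.character(species)
  if (is.unsorted(species)) stop("species must be sorted")
  n <- length(species)
  if (n < 3L) stop("need at least 3 species")
  m <- choose(n, 3L)
  counts <- as.matrix(counts)
  if (nrow(counts) != m || ncol(counts) != 3L)
    stop(sprintf("counts must be %d x 3", m))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(species = species, triples = t(utils::combn(n, 3L)),
                 counts = counts, n_trees = n_trees),
            class = "triple_counts")
}

#' Count rooted-triple resolutions across gene trees
#'
#' Each rooted gene tree contributes one count to exactly one resolution for
#' every species triple it contains; triples involving a species absent from
#' a gene contribute nothing for that gene.  Triples falling on a gene-tree
#' polytomy are unresolved and skipped.
#'
#' @param gene_trees List or `multiPhylo` of rooted gene trees whose leaf
#'   labels are species ids (at most one leaf per species per gene).
#' @param species Optional species set (default: union over gene trees).
#' @return A `"triple_counts"` object.
#' @export
count_triples <- function(gene_trees, species = NULL) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  if (!length(gene_trees)) stop("no gene trees supplied")
  for (tr in gene_trees) {
    dup <- tr$tip.label[duplicated(tr$tip.label)]
    if (length(dup))
      stop("duplicate species label within a gene tree: ",
           paste(unique(dup), collapse = ", "))
  }
  if (is.null(species))
    species <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  else species <- sort(species)
  n <- length(species)
  if (n < 3L) stop("fewer than 3 species across gene trees")
  cmb_all <- utils::combn(n, 3L)
  m <- ncol(cmb_all)
  idx3 <- array(0L, dim = c(n, n, n))
  idx3[cbind(cmb_all[1L, ], cmb_all[2L, ], cmb_all[3L, ])] <- seq_len(m)
  counts <- matrix(0L, m, 3L)
  gene_trees <- unclass(gene_trees)
  loc_cache <- list()
  for (tr in gene_trees) {
    unk <- setdiff(tr$tip.label, species)
    if (length(unk))
      stop("gene tree label(s) outside the species set: ",
           paste(unk, collapse = ", "))
    pres <- sort(match(tr$tip.label, species))
    np <- length(pres)
    if (np < 3L) next
    key <- as.character(np)
    loc <- loc_cache[[key]]
    if (is.null(loc)) loc <- loc_cache[[key]] <- utils::combn(np, 3L)
    res <- .triple_resolutions(tr, species[pres], loc)
    rows <- idx3[cbind(pres[loc[1L, ]], pres[loc[2L, ]], pres[loc[3L, ]])]
    ok <- !is.na(res)
    ij <- cbind(rows[ok], res[ok])
    counts[ij] <- counts[ij] + 1L
  }
  structure(list(species = species, triples = t(cmb_all), counts = counts,
                 n_trees = length(gene_trees)), class = "triple_counts")
}

#' @export
print.triple_counts <- function(x, ...) {
  cat("Rooted-triple counts:", length(x$species), "species,",
      nrow(x$counts), "triples,", x$n_trees, "gene trees\n")
  invisible(x)
}

.check_binary_rooted <- function(phy) {
  n <- length(phy$tip.label)
  if (phy$Nnode != n - 1L)
    stop("tree must be binary and rooted (", phy$Nnode,
         " internal nodes for ", n, " leaves)")
}

# Species-tree structure needed by the pseudo-likelihood: per triple, the
# concordant resolution and the set of internal edges on the path between
# the cherry MRCA and the triple MRCA.
.species_tree_paths <- function(phy, species, cmb) {
  labs <- phy$tip.label
  extra <- setdiff(species, labs)
  if (length(extra))
    stop("species in counts absent from tree: ", paste(extra, collapse = ", "))
  if (length(labs) != length(species))
    stop("tree has leaves without counts: ",
         paste(setdiff(labs, species), collapse = ", "))
  n <- length(species)
  pos <- match(species, labs)
  d <- .node_depths(phy)
  Mr <- ape::mrca(phy)[pos, pos, drop = FALSE]
  par <- .parent_vec(phy)
  ich <- phy$edge[, 2L][phy$edge[, 2L] > n]
  K <- length(ich)
  eidx <- integer(n + phy$Nnode)
  eidx[ich] <- seq_len(K)
  sets <- .clade_leafsets(phy)
  tau_names <- vapply(ich, function(v) .clade_key(labs[sets[[v]]]),
                      character(1L))
  m <- ncol(cmb)
  res <- integer(m)
  inc <- matrix(0, m, K)
  for (t in seq_len(m)) {
    mm <- c(Mr[cmb[1L, t], cmb[2L, t]],
            Mr[cmb[1L, t], cmb[3L, t]],
            Mr[cmb[2L, t], cmb[3L, t]])
    ds <- d[mm]
    w <- which.max(ds)
    res[t] <- w
    v <- mm[w]
    top <- mm[which.min(ds)]
    while (v != top) {
      inc[t, eidx[v]] <- 1
      v <- par[v]
    }
  }
  list(res = res, inc = inc, tau_names = tau_names)
}

.pll_value <- function(sp, counts, tau) {
  Tt <- as.vector(sp$inc %*% tau)
  nc <- counts[cbind(seq_len(nrow(counts)), sp$res)]
  nd <- rowSums(counts) - nc
  sum(nc * log1p(-(2 / 3) * exp(-Tt)) + nd * (log(1 / 3) - Tt))
}

.pll_grad <- function(sp, counts, tau) {
  Tt <- as.vector(sp$inc %*% tau)
  nc <- counts[cbind(seq_len(nrow(counts)), sp$res)]
  nd <- rowSums(counts) - nc
  e <- (2 / 3) * exp(-Tt)
  as.vector(crossprod(sp$inc, nc * e / (1 - e) - nd))
}

.resolve_tau <- function(tree, tau, tau_names) {
  if (is.null(tau)) {
    n <- length(tree$tip.label)
    if (is.null(tree$edge.length))
      stop("supply 'tau' or a tree with internal branch lengths")
    sets <- .clade_leafsets(tree)
    tau <- numeric(0)
    for (i in seq_len(nrow(tree$edge))) {
      ch <- tree$edge[i, 2L]
      if (ch > n) tau[.clade_key(tree$tip.label[sets[[ch]]])] <-
          tree$edge.length[i]
    }
  }
  if (!is.null(names(tau))) {
    miss <- setdiff(tau_names, names(tau))
    if (length(miss)) stop("tau lacks values for some internal branches")
    tau <- tau[tau_names]
  } else if (length(tau) != length(tau_names)) {
    stop("tau must have one value per internal branch (", length(tau_names), ")")
  }
  unname(tau)
}

#' Pseudo-log-likelihood of a species tree given triple counts
#'
#' Sum over species triples of the multinomial log-probability of the
#' observed resolution counts under [triple_probabilities()], with `T` the
#' sum of internal branch lengths on the path between the triple's two
#' speciation nodes.  Constant multinomial coefficients are omitted, so the
#' value is comparable across branch lengths and topologies on the same
#' counts.  Triples with zero total count contribute zero.
#'
#' @param tree Binary rooted species tree over the counted species.
#' @param counts A `"triple_counts"` object.
#' @param tau Internal branch lengths in coalescent units: either a vector
#'   named by clade keys, an unnamed vector in internal-edge order, or `NULL`
#'   to take them from `tree$edge.length`.
#' @return The pseudo-log-likelihood (<= 0).
#' @export
pseudo_loglik <- function(tree, counts, tau = NULL) {
  if (!inherits(counts, "triple_counts")) stop("counts must be triple_counts")
  .check_binary_rooted(tree)
  sp <- .species_tree_paths(tree, counts$species, t(counts$triples))
  .pll_value(sp, counts$counts, .resolve_tau(tree, tau, sp$tau_names))
}

# attach tau as internal edge lengths; terminal branches are not estimable
# from triples and get NA
.attach_tau <- function(phy, tau) {
  n <- length(phy$tip.label)
  sets <- .clade_leafsets(phy)
  el <- rep(NA_real_, nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[i, 2L]
    if (ch > n) el[i] <- tau[[.clade_key(phy$tip.label[sets[[ch]]])]]
  }
  phy$edge.length <- el
  phy
}

#' Optimize coalescent branch lengths on a fixed topology
#'
#' Maximizes [pseudo_loglik()] over the internal branch lengths of a binary
#' rooted topology by bounded quasi-Newton (L-BFGS-B) with analytic
#' gradients; bounds are `[lower, upper]` coalescent units.
#'
#' @param topology Binary rooted species tree (branch lengths ignored).
#' @param counts A `"triple_counts"` object.
#' @param tau_init Starting value for every internal branch (default 1).
#' @param lower,upper Box bounds on each branch length (defaults `1e-8`, 20).
#' @return An object of class `"mpest"` (see [mpest()]).
#' @export
optimize_branch_lengths <- function(topology, counts, tau_init = 1,
                                    lower = 1e-8, upper = 20) {
  if (!inherits(counts, "triple_counts")) stop("counts must be triple_counts")
  .check_binary_rooted(topology)
  sp <- .species_tree_paths(topology, counts$species, t(counts$triples))
  cm <- counts$counts
  par0 <- rep_len(tau_init, length(sp$tau_names))
  opt <- stats::optim(par0,
                      fn = function(x) -.pll_value(sp, cm, x),
                      gr = function(x) -.pll_grad(sp, cm, x),
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = 500L))
  tau <- opt$par
  names(tau) <- sp$tau_names
  topology$edge.length <- NULL
  structure(list(tree = .attach_tau(topology, tau), tau = tau,
                 logLik = -opt$value, counts = counts,
                 convergence = opt$convergence, n_genes = counts$n_trees),
            class = "mpest")
}

# all rooted NNI neighbours of a binary rooted tree (2 per internal
# non-root node); edge lengths are dropped
.rooted_nni_neighbors <- function(phy) {
  n <- length(phy$tip.label)
  par <- .parent_vec(phy)
  kids <- .children_list(phy)
  out <- list()
  for (v in seq.int(n + 1L, n + phy$Nnode)) {
    u <- par[v]
    if (u == 0L) next
    sib <- setdiff(kids[[u]], v)[1L]
    for (ch in kids[[v]]) {
      e <- phy$edge
      e[e[, 1L] == u & e[, 2L] == sib, 2L] <- ch
      e[e[, 1L] == v & e[, 2L] == ch, 2L] <- sib
      nb <- list(edge = e, tip.label = phy$tip.label, Nnode = phy$Nnode)
      class(nb) <- "phylo"
      out <- c(out, list(nb))
    }
  }
  out
}

# deterministic greedy start: agglomerate the pair of clusters with the
# highest mean pairwise triple support, ties broken lexicographically
.greedy_start_tree <- function(counts) {
  sp <- counts$species
  n <- length(sp)
  tri <- counts$triples
  cm <- counts$counts
  W <- matrix(0, n, n)
  add <- function(a, b, w) {
    W[cbind(a, b)] <<- W[cbind(a, b)] + w
    W[cbind(b, a)] <<- W[cbind(b, a)] + w
  }
  add(tri[, 1L], tri[, 2L], cm[, 1L])
  add(tri[, 1L], tri[, 3L], cm[, 2L])
  add(tri[, 2L], tri[, 3L], cm[, 3L])
  members <- as.list(seq_len(n))
  frag <- sp
  while (length(members) > 1L) {
    best <- NULL
    bestscore <- -Inf
    bestkey <- ""
    for (a in seq_len(length(members) - 1L))
      for (b in seq.int(a + 1L, length(members))) {
        sc <- mean(W[members[[a]], members[[b]]])
        key <- paste(sort(c(frag[a], frag[b])), collapse = ",")
        if (sc > bestscore + 1e-12 ||
            (sc > bestscore - 1e-12 && key < bestkey)) {
          bestscore <- sc
          bestkey <- key
          best <- c(a, b)
        }
      }
    a <- best[1L]; b <- best[2L]
    newfrag <- paste0("(", frag[a], ",", frag[b], ")")
    newmem <- c(members[[a]], members[[b]])
    frag <- c(frag[-c(a, b)], newfrag)
    members <- c(members[-c(a, b)], list(newmem))
  }
  ape::read.tree(text = paste0(frag[1L], ";"))
}

#' Fit a species tree by maximum pseudo-likelihood
#'
#' Estimates the rooted species-tree topology and internal coalescent-unit
#' branch lengths from rooted gene trees (or a precomputed triple-count
#' table) by hill climbing over rooted NNI neighbourhoods.  Each candidate
#' topology is scored by [optimize_branch_lengths()]; a neighbour is accepted
#' iff it improves the optimized pseudo-log-likelihood by more than `tol`,
#' and the search stops when no neighbour improves.  Random restarts perturb
#' the deterministic greedy start tree by `perturb_moves` random NNI moves;
#' equal-scoring topologies are tie-broken by lexicographically smallest
#' canonical Newick string.  Terminal branch lengths are not estimable from
#' triples and are reported as `NA`.
#'
#' @param x Rooted gene trees (list / `multiPhylo`) or a `"triple_counts"`
#'   object covering at least 4 species.
#' @param start Optional starting topology (binary rooted `phylo`); default
#'   is a greedy triple-majority agglomeration.
#' @param n_restarts Total number of hill-climbing starts (default 10).
#' @param seed Optional RNG seed making restarts reproducible.
#' @param perturb_moves Random NNI moves applied per restart (default 3).
#' @param tol Minimal pseudo-log-likelihood improvement to accept a move.
#' @return An object of class `"mpest"`: list with `tree` (rooted `phylo`,
#'   internal branch lengths in coalescent units), `tau` (named vector),
#'   `logLik`, `counts`, `start`, `n_genes`.
#' @seealso [count_triples()], [pseudo_loglik()], [mpest_bootstrap()]
#' @examples
#' sp <- rhodophyta_tree()
#' gts <- sim_msc_gene_trees(sp, n_genes = 50, seed = 1)
#' fit <- mpest(gts, n_restarts = 2, seed = 1)
#' fit
#' @export
mpest <- function(x, start = NULL, n_restarts = 10L, seed = NULL,
                  perturb_moves = 3L, tol = 1e-8) {
  counts <- if (inherits(x, "triple_counts")) x else count_triples(x)
  if (length(counts$species) < 4L)
    stop("pseudo-likelihood tree search needs counts covering >= 4 species")
  if (!is.null(seed)) set.seed(seed)
  start_tree <- if (is.null(start)) .greedy_start_tree(counts) else start
  .check_binary_rooted(start_tree)
  climb <- function(tree0) {
    cur <- optimize_branch_lengths(tree0, counts)
    visited <- new.env(hash = TRUE, parent = emptyenv())
    assign(canonical_newick(tree0), TRUE, envir = visited)
    repeat {
      best <- NULL
      bestkey <- ""
      for (nb in .rooted_nni_neighbors(cur$tree)) {
        key <- canonical_newick(nb)
        if (exists(key, envir = visited, inherits = FALSE)) next
        assign(key, TRUE, envir = visited)
        fit <- optimize_branch_lengths(nb, counts)
        if (is.null(best) || fit$logLik > best$logLik + 1e-12 ||
            (fit$logLik > best$logLik - 1e-12 && key < bestkey)) {
          best <- fit
          bestkey <- key
        }
      }
      if (!is.null(best) && best$logLik > cur$logLik + tol) cur <- best
      else break
    }
    cur
  }
  bestfit <- climb(start_tree)
  if (n_restarts > 1L) {
    for (r in seq_len(n_restarts - 1L)) {
      t0 <- start_tree
      t0$edge.length <- NULL
      for (k in seq_len(perturb_moves)) {
        nbs <- .rooted_nni_neighbors(t0)
        t0 <- nbs[[sample.int(length(nbs), 1L)]]
      }
      fit <- climb(t0)
      if (fit$logLik > bestfit$logLik + 1e-12 ||
          (fit$logLik > bestfit$logLik - 1e-12 &&
           canonical_newick(fit$tree) < canonical_newick(bestfit$tree)))
        bestfit <- fit
    }
  }
  bestfit$start <- start_tree
  bestfit$call <- match.call()
  bestfit
}

#' @export
print.mpest <- function(x, ...) {
  cat("Species tree by maximum pseudo-likelihood (rooted-triple MSC model)\n")
  cat("  species:      ", length(x$counts$species), "\n", sep = "")
  cat("  gene trees:   ", x$n_genes, "\n", sep = "")
  cat("  pseudo-logLik:", format(x$logLik, digits = 8), "\n")
  cat("  topology:     ", ape::write.tree(.strip_lengths(x$tree)), "\n", sep = "")
  invisible(x)
}

.strip_lengths <- function(phy) {
  phy$edge.length <- NULL
  phy
}

#' @method summary mpest
#' @export
summary.mpest <- function(object, ...) {
  keys <- names(object$tau)
  clades <- vapply(strsplit(keys, .KEYSEP, fixed = TRUE),
                   function(s) paste(s, collapse = ","), character(1L))
  out <- list(fit = object,
              branches = data.frame(clade = clades, tau = unname(object$tau),
                                    stringsAsFactors = FALSE))
  class(out) <- "summary.mpest"
  out
}

#' @export
print.summary.mpest <- function(x, ...) {
  print(x$fit)
  cat("\nInternal branch lengths (coalescent units):\n")
  b <- x$branches
  b$tau <- signif(b$tau, 5)
  print(b, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @method coef mpest
#' @export
coef.mpest <- function(object, ...) object$tau

#' @method logLik mpest
#' @export
logLik.mpest <- function(object, ...) {
  structure(object$logLik, df = length(object$tau),
            nobs = sum(object$counts$counts), class = "logLik")
}

#' Simulate gene trees from a fitted species tree
#'
#' Draws multispecies-coalescent gene trees on the fitted topology with its
#' estimated internal branch lengths; terminal branches (not estimable from
#' triples) are set to zero, which leaves the gene-tree topology distribution
#' unchanged.
#'
#' @param object A fitted `"mpest"` object.
#' @param nsim Number of gene trees.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of `phylo` gene trees.
#' @export
simulate.mpest <- function(object, nsim = 1L, seed = NULL, ...) {
  tr <- object$tree
  tr$edge.length[is.na(tr$edge.length)] <- 0
  sim_msc_gene_trees(tr, n_genes = nsim, seed = seed)
}
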