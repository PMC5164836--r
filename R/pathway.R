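# Pathway evolution machinery: candidate selection from BLAST-style hit
# tables, monophyly-based ortholog validation on gene trees, gene
# presence/absence calls that respect data-type evidence, and Dollo
# parsimony mapping of losses onto the species tree.

#' MVA pathway enzymes
#'
#' The seven mevalonate-pathway enzymes in pathway order; the default "core"
#' used for pathway-level calls is the 3rd-6th enzymes (HMGR, MVK, PMK,
#' MVD), whose joint absence marks loss of the pathway trunk.
#' @param core If `TRUE` return only the core enzymes.
#' @return Character vector of enzyme symbols.
#' @export
mva_enzymes <- function(core = FALSE) {
  all <- c("ACAT", "HMGS", "HMGR", "MVK", "PMK", "MVD", "IDI")
  if (core) all[3:6] else all
}

#' MEP pathway enzymes
#' @return Character vector of enzyme symbols in pathway order.
#' @export
mep_enzymes <- function() {
  c("DXS", "DXR", "MCT", "CMK", "MDS", "HDS", "HDR", "IDI")
}

#' Read a BLAST tabular hit file
#'
#' Expects outfmt-6 column order (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`).  The subject taxon is
#' the `|`-prefix of the subject id.
#'
#' @param file Path to the TSV (no header).
#' @return A data frame with columns `query`, `subject`, `taxon`, `pident`,
#'   `evalue`, `bitscore`.
#' @export
read_hit_table <- function(file) {
  h <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(h) < 12L)
    stop("expected >= 12 outfmt-6 columns, found ", ncol(h))
  out <- data.frame(query = as.character(h[[1L]]),
                    subject = as.character(h[[2L]]),
                    taxon = seq_taxon(as.character(h[[2L]])),
                    pident = as.numeric(h[[3L]]),
                    evalue = as.numeric(h[[11L]]),
                    bitscore = as.numeric(h[[12L]]),
                    stringsAsFactors = FALSE)
  if (any(out$pident < 0 | out$pident > 100))
    stop("percent identity outside [0, 100]")
  if (any(out$bitscore <= 0)) stop("non-positive bit score")
  if (any(out$evalue < 0)) stop("negative e-value")
  out
}

#' Select candidate homologs from a hit table
#'
#' Per query, the union of the `k` highest-bit-score subjects and the `k`
#' highest-identity subjects; ties are broken by subject id order.
#'
#' @param hits Data frame with columns `query`, `subject`, `pident`,
#'   `bitscore` (e.g. from [read_hit_table()]).
#' @param k Number of top hits per ranking (default 3).
#' @return Named list: query -> sorted character vector of subject ids.
#' @export
select_candidates <- function(hits, k = 3L) {
  if (!nrow(hits)) return(stats::setNames(list(), character(0)))
  out <- lapply(split(hits, hits$query), function(hq) {
    by_score <- hq$subject[order(-hq$bitscore, hq$subject)]
    by_ident <- hq$subject[order(-hq$pident, hq$subject)]
    sort(union(utils::head(by_score, k), utils::head(by_ident, k)))
  })
  out[sort(names(out))]
}

#' Validate orthologs by monophyly with a reference sequence
#'
#' Walks rootward from the reference leaf while the enclosing clade contains
#' only the reference plus eligible labels, and returns the candidates
#' inside the largest such clade - i.e. the candidates forming a
#' monophyletic group with the reference to the exclusion of non-eligible
#' homologs (out-paralogs, non-red-algal sequences).
#'
#' @param gene_tree Rooted `phylo` of the reference and its homologs.
#' @param reference Leaf label of the reference sequence.
#' @param candidates Candidate leaf labels (labels absent from the tree are
#'   ignored).
#' @param eligible Labels allowed inside the ortholog clade besides the
#'   reference; defaults to `candidates` (supply all red-algal labels to let
#'   non-candidate red sequences pass through the clade).
#' @return Sorted character vector of validated candidate labels (possibly
#'   empty).
#' @export
validate_orthologs <- function(gene_tree, reference, candidates,
                               eligible = candidates) {
  labs <- gene_tree$tip.label
  if (!reference %in% labs)
    stop("reference '", reference, "' is not a leaf of the gene tree")
  candidates <- intersect(candidates, labs)
  allowed <- unique(c(reference, eligible, candidates))
  par <- .parent_vec(gene_tree)
  sets <- .clade_leafsets(gene_tree)
  v <- match(reference, labs)
  best <- v
  while (par[v] != 0L) {
    u <- par[v]
    if (all(labs[sets[[u]]] %in% allowed)) {
      best <- u
      v <- u
    } else break
  }
  sort(intersect(labs[sets[[best]]], candidates))
}

#' Call gene presence/absence across taxa
#'
#' A gene is `P` (present) in a taxon with at least one validated ortholog.
#' Otherwise the call depends on the evidence the data type can carry:
#' genome and partial-genome taxa are `A` (absent), transcriptome taxa get
#' `transcriptome_absence` (`"?"` ambiguous by default, since transcriptome
#' absence is weak evidence; `"absent"` when absences have been confirmed
#' independently).
#'
#' @param validated Named list: gene -> character vector of taxa with a
#'   validated ortholog.
#' @param taxa Taxon table (see [read_taxon_table()]); every taxon needs a
#'   non-missing `data_type`.
#' @param transcriptome_absence `"ambiguous"` or `"absent"`.
#' @return Character matrix (genes x taxa) with values `P`, `A`, `?`.
#' @export
call_presence <- function(validated, taxa,
                          transcriptome_absence = c("ambiguous", "absent")) {
  transcriptome_absence <- match.arg(transcriptome_absence)
  if (any(is.na(taxa$data_type) | !nzchar(taxa$data_type)))
    stop("taxon without data_type: ",
         paste(taxa$taxon_id[is.na(taxa$data_type) |
                               !nzchar(taxa$data_type)], collapse = ", "))
  absent_code <- stats::setNames(rep("A", nrow(taxa)), taxa$taxon_id)
  if (transcriptome_absence == "ambiguous")
    absent_code[taxa$data_type == "transcriptome"] <- "?"
  genes <- names(validated)
  M <- matrix("", length(genes), nrow(taxa),
              dimnames = list(genes, taxa$taxon_id))
  for (g in genes) {
    unk <- setdiff(validated[[g]], taxa$taxon_id)
    if (length(unk))
      stop("validated taxon not in taxon table: ", paste(unk, collapse = ", "))
    M[g, ] <- ifelse(taxa$taxon_id %in% validated[[g]], "P",
                     absent_code[taxa$taxon_id])
  }
  M
}

#' Pathway-level presence call
#'
#' A pathway is called present in a taxon iff at least `min_present` of its
#' designated core enzymes are present.  The aggregation rule is a
#' configurable majority construction (the per-enzyme calls are the primary
#' result; see the package vignette).
#'
#' @param presence Presence matrix from [call_presence()].
#' @param enzymes Core enzyme rows to aggregate (default [mva_enzymes()]
#'   core).
#' @param min_present Minimum number of present core enzymes (default:
#'   majority, `ceiling(length(enzymes)/2)`).
#' @return Named logical vector over taxa.
#' @export
pathway_call <- function(presence, enzymes = mva_enzymes(core = TRUE),
                         min_present = ceiling(length(enzymes) / 2)) {
  miss <- setdiff(enzymes, rownames(presence))
  if (length(miss))
    stop("enzymes absent from presence matrix: ", paste(miss, collapse = ", "))
  colSums(presence[enzymes, , drop = FALSE] == "P") >= min_present
}

.normalize_states <- function(states) {
  map <- c(present = "present", absent = "absent", ambiguous = "ambiguous",
           P = "present", A = "absent", "?" = "ambiguous")
  out <- map[as.character(states)]
  if (anyNA(out))
    stop("invalid state(s): ",
         paste(unique(states[is.na(out)]), collapse = ", "))
  stats::setNames(unname(out), names(states))
}

#' Dollo parsimony loss mapping
#'
#' Under Dollo parsimony a character is gained once - at the MRCA of all
#' present leaves (or at the root when `gain = "root"`, for characters
#' presumed ancestral) - and lost any number of times inside the gain clade.
#' The minimal loss set consists of the maximal subtrees within the gain
#' clade whose leaves are all absent or ambiguous and that contain at least
#' one strict absence: one loss on each such subtree's root edge explains
#' every absence, no loss edge sits above a present leaf, and no smaller set
#' can cover distinct maximal subtrees (their MRCA has a present
#' descendant).  Ambiguous leaves never force a loss but are absorbed into
#' an adjacent loss clade.
#'
#' @param species_tree Rooted `phylo`.
#' @param states Named vector over all leaves with values
#'   `present`/`absent`/`ambiguous` (or `P`/`A`/`?`).
#' @param gain `"mrca"` (default) or `"root"`.
#' @return An object of class `"dollo"`: list with `gain` (leaf labels of
#'   the gain clade), `losses` (list of leaf-label vectors, one per loss
#'   edge), `loss_count`, `states`, `tree`.
#' @export
dollo_losses <- function(species_tree, states, gain = c("mrca", "root")) {
  gain <- match.arg(gain)
  labs <- species_tree$tip.label
  states <- .normalize_states(states)
  miss <- setdiff(labs, names(states))
  if (length(miss))
    stop("no state for leaf/leaves: ", paste(miss, collapse = ", "))
  states <- states[labs]
  pres <- which(states == "present")
  if (!length(pres))
    stop("character has no present leaf; no gain can be placed")
  n <- length(labs)
  par <- .parent_vec(species_tree)
  sets <- .clade_leafsets(species_tree)
  gain_node <- if (gain == "root") .root_node(species_tree)
    else if (length(pres) == 1L) pres
    else ape::getMRCA(species_tree, labs[pres])
  # postorder flags over all nodes
  N <- n + species_tree$Nnode
  nonpresent <- logical(N)
  hasabs <- logical(N)
  for (v in seq_len(N)) {
    lv <- states[sets[[v]]]
    nonpresent[v] <- all(lv != "present")
    hasabs[v] <- any(lv == "absent")
  }
  under_gain <- function(v) {
    while (v != 0L) {
      if (v == gain_node) return(TRUE)
      v <- par[v]
    }
    FALSE
  }
  loss_nodes <- Filter(function(v) {
    if (v == gain_node || !nonpresent[v] || !hasabs[v]) return(FALSE)
    if (!under_gain(v)) return(FALSE)
    # maximality: the parent subtree (still inside the gain clade) retains a
    # present leaf
    par[v] == gain_node || !nonpresent[par[v]]
  }, seq_len(N))
  losses <- lapply(loss_nodes, function(v) sort(labs[sets[[v]]]))
  ord <- order(vapply(losses, `[`, "", 1L))
  structure(list(gain = sort(labs[sets[[gain_node]]]),
                 losses = losses[ord],
                 loss_count = length(losses),
                 states = states, tree = species_tree),
            class = "dollo")
}

#' @export
print.dollo <- function(x, ...) {
  cat("Dollo parsimony loss map\n")
  cat("  gain clade:", length(x$gain), "leaves\n")
  cat("  losses:    ", x$loss_count, "\n", sep = "")
  for (l in x$losses)
    cat("    - {", paste(l, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Dollo loss report for a presence matrix
#'
#' Applies [dollo_losses()] to every gene (row) of a presence matrix and
#' tabulates the minimal loss events.
#'
#' @param species_tree Rooted `phylo` over the matrix's taxa.
#' @param presence Matrix from [call_presence()] (genes x taxa).
#' @param gain Passed to [dollo_losses()].
#' @return Data frame with columns `gene`, `gain_size`, `loss_count`,
#'   `loss_clades` (loss clades separated by `;`, leaves by `,`).
#' @export
dollo_report <- function(species_tree, presence, gain = "mrca") {
  rows <- lapply(rownames(presence), function(g) {
    dm <- dollo_losses(species_tree, presence[g, ], gain = gain)
    data.frame(gene = g, gain_size = length(dm$gain),
               loss_count = dm$loss_count,
               loss_clades = paste(vapply(dm$losses, paste, "",
                                          collapse = ","), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
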