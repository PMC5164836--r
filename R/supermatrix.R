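# Supermatrix construction: retained per-gene alignments are concatenated
# into one partitioned super-alignment, exported for external concatenation
# analyses (FASTA / relaxed PHYLIP + RAxML-style partition file).

#' Concatenate gene alignments into a supermatrix
#'
#' Rows are matched to taxa by the `|`-prefix of their sequence ids.  Taxa
#' absent from a gene receive an all-gap (`-`) block of that gene's length.
#' Genes are concatenated in input order; partitions use 1-based inclusive
#' coordinates.
#'
#' @param alignments Named list of character matrix alignments (at most one
#'   row per taxon per gene).
#' @param taxa Optional character vector fixing the taxon set and row order;
#'   defaults to the sorted union of taxa seen across genes.
#' @return An object of class `"supermatrix"`: list with `matrix` (taxon x
#'   site character matrix) and `partitions` (data frame `gene`, `start`,
#'   `end`).
#' @export
concatenate_alignments <- function(alignments, taxa = NULL) {
  if (!length(alignments)) stop("no alignments to concatenate")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be a named list (gene ids)")
  rowtax <- lapply(alignments, function(a) seq_taxon(rownames(a)))
  for (g in names(alignments)) {
    dup <- rowtax[[g]][duplicated(rowtax[[g]])]
    if (length(dup))
      stop(sprintf("gene '%s' has multiple rows for taxon: %s",
                   g, paste(unique(dup), collapse = ", ")))
  }
  if (is.null(taxa)) taxa <- sort(unique(unlist(rowtax)))
  lens <- vapply(alignments, ncol, integer(1L))
  total <- sum(lens)
  M <- matrix("-", nrow = length(taxa), ncol = total,
              dimnames = list(taxa, NULL))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    tx <- rowtax[[i]]
    hit <- tx %in% taxa
    if (any(hit))
      M[tx[hit], starts[i]:ends[i]] <- a[hit, , drop = FALSE]
  }
  structure(list(matrix = M,
                 partitions = data.frame(gene = names(alignments),
                                         start = starts, end = ends,
                                         row.names = NULL,
                                         stringsAsFactors = FALSE)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", nrow(x$matrix), "taxa x", ncol(x$matrix), "sites,",
      nrow(x$partitions), "gene partitions\n")
  invisible(x)
}

#' Extract one gene partition from a supermatrix
#'
#' @param sm A `"supermatrix"` object.
#' @param gene Gene id of the partition.
#' @param drop_gap_only If `TRUE` (default) taxa that are entirely gaps in
#'   this partition (absent from the gene) are dropped.
#' @return A character matrix alignment.
#' @export
get_partition <- function(sm, gene, drop_gap_only = TRUE) {
  i <- match(gene, sm$partitions$gene)
  if (is.na(i)) stop("no partition for gene '", gene, "'")
  a <- sm$matrix[, sm$partitions$start[i]:sm$partitions$end[i], drop = FALSE]
  if (drop_gap_only) a <- a[rowSums(a != "-") > 0L, , drop = FALSE]
  attr(a, "id") <- gene
  a
}

#' Write a supermatrix to disk
#'
#' `"fasta"` writes standard FASTA; `"phylip"` writes relaxed PHYLIP with the
#' header `"<ntaxa> <ncols>"` followed by `name  sequence` lines (taxon names
#' must not contain whitespace).
#'
#' @param sm A `"supermatrix"` object.
#' @param file Output path.
#' @param format `"fasta"` (default) or `"phylip"`.
#' @return `file`, invisibly.
#' @export
write_supermatrix <- function(sm, file, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  M <- sm$matrix
  seqs <- apply(M, 1L, paste, collapse = "")
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(seqs)
    names(ss) <- rownames(M)
    Biostrings::writeXStringSet(ss, filepath = file)
  } else {
    if (any(grepl("[[:space:]]", rownames(M))))
      stop("taxon names must not contain whitespace in PHYLIP output")
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste(nrow(M), ncol(M)), con)
    writeLines(paste0(rownames(M), "  ", seqs), con)
  }
  invisible(file)
}

#' Write a RAxML-style partition file
#'
#' One line per gene: `PROT, <gene> = <start>-<end>`.
#'
#' @param sm A `"supermatrix"` object.
#' @param file Output path; when `NULL` the lines are returned.
#' @return The partition lines, invisibly when written.
#' @export
write_partitions <- function(sm, file = NULL) {
  p <- sm$partitions
  lines <- sprintf("PROT, %s = %d-%d", p$gene, p$start, p$end)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
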