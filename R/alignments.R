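# Protein multiple alignments are plain character matrices: one row per
# sequence (rownames = sequence ids, usually "taxon|gene"), one column per
# site.  Gaps are "-", unknown residues "X".

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Build an alignment matrix from sequences
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param id Optional gene/group identifier stored as the `"id"` attribute.
#' @return A character matrix with one row per sequence.
#' @export
alignment_matrix <- function(seqs, id = NULL) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  nc <- unique(nchar(seqs))
  if (length(nc) > 1L)
    stop("ragged alignment: sequence lengths ", paste(sort(nc), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(0), 0L, 0L)
  rownames(m) <- names(seqs)
  attr(m, "id") <- id
  m
}

#' Read an aligned FASTA file
#'
#' Uses [Biostrings::readBStringSet()] and converts to the package's matrix
#' representation.  All sequences must have equal length.
#'
#' @param file Path to a FASTA file.
#' @param id Optional gene id attached to the result (defaults to the file
#'   name without extension).
#' @return A character matrix alignment.
#' @export
read_fasta_alignment <- function(file, id = NULL) {
  ss <- Biostrings::readBStringSet(file)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(file))
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  alignment_matrix(seqs, id = id)
}

#' Write an alignment as FASTA
#'
#' @param aln A character matrix alignment.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta_alignment <- function(aln, file) {
  seqs <- apply(aln, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(aln)
  Biostrings::writeXStringSet(ss, filepath = file)
  invisible(file)
}

#' Drop gap-rich columns
#'
#' Plumbing stand-in for upstream alignment trimming (TrimAl-style tools):
#' removes every column whose gap fraction exceeds `max_gap_frac`.  It is
#' not equivalent to score-based trimmers and is intended only to keep the
#' pipeline runnable end to end.
#'
#' @param aln A character matrix alignment.
#' @param max_gap_frac Columns with a gap fraction strictly above this are
#'   dropped (default 0.5).
#' @return The trimmed alignment (attributes preserved).
#' @export
trim_gap_columns <- function(aln, max_gap_frac = 0.5) {
  if (!nrow(aln) || !ncol(aln)) return(aln)
  gf <- colMeans(aln == "-")
  out <- aln[, gf <= max_gap_frac, drop = FALSE]
  attr(out, "id") <- attr(aln, "id")
  out
}

# taxon prefix of "taxon|gene" sequence ids (ids without "|" are returned
# unchanged, i.e. already taxon-level)
seq_taxon <- function(ids) sub("\\|.*$", "", ids)
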