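# Single-copy orthogroup selection: OrthoMCL-style cluster files are filtered
# by copy number and lineage-specific missingness, per-gene alignments by a
# strict length and a minimum-sequence criterion, and outgroup representation
# is reduced to a single prioritised green alga per gene.

#' Read a taxon table
#'
#' Expects a TSV with columns `taxon_id`, `name`, `group` (`red`/`green`),
#' `class` (e.g. Seaweed, Mesophile, Extremophile) and `data_type`
#' (`genome`, `partial genome`, `transcriptome`).
#'
#' @param file Path to the TSV.
#' @return A data frame with those columns; `taxon_id` values are unique.
#' @export
read_taxon_table <- function(file) {
  tt <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("taxon_id", "name", "group", "class", "data_type")
  miss <- setdiff(need, names(tt))
  if (length(miss))
    stop("taxon table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tt$taxon_id))
    stop("duplicate taxon_id: ",
         paste(unique(tt$taxon_id[duplicated(tt$taxon_id)]), collapse = ", "))
  bad <- setdiff(unique(tt$group), c("red", "green"))
  if (length(bad)) stop("unknown lineage group(s): ", paste(bad, collapse = ", "))
  tt
}

#' Parse an OrthoMCL-style groups file
#'
#' Lines have the form `"GROUPID: taxonA|gene1 taxonB|gene2 ..."`.  The taxon
#' of each member is the prefix before the first `|`.
#'
#' @param file Path to a groups file; alternatively supply `lines` directly.
#' @param lines Character vector of group lines (overrides `file`).
#' @param taxa Optional taxon table; when given, members referencing unknown
#'   taxa raise an error naming them.
#' @return An object of class `"orthogroups"`: a named list mapping group id
#'   to a data frame with columns `taxon`, `gene`, `member`.
#' @export
parse_groups <- function(file = NULL, lines = NULL, taxa = NULL) {
  if (is.null(lines)) {
    if (is.null(file)) stop("supply 'file' or 'lines'")
    lines <- readLines(file, warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  groups <- list()
  for (ln in seq_along(lines)) {
    m <- regmatches(lines[ln], regexec("^\\s*([^:\\s]+):\\s*(.*)$", lines[ln]))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("malformed groups line %d: %s", ln, lines[ln]))
    gid <- m[2L]
    members <- strsplit(trimws(m[3L]), "\\s+")[[1L]]
    members <- members[nzchar(members)]
    if (gid %in% names(groups))
      stop(sprintf("duplicate group id '%s' at line %d", gid, ln))
    if (anyDuplicated(members))
      stop(sprintf("duplicate member id within group '%s' (line %d)", gid, ln))
    taxon <- seq_taxon(members)
    gene <- sub("^[^|]*\\|", "", members)
    groups[[gid]] <- data.frame(taxon = taxon, gene = gene, member = members,
                                stringsAsFactors = FALSE)
  }
  if (!is.null(taxa)) {
    known <- taxa$taxon_id
    for (gid in names(groups)) {
      unk <- setdiff(groups[[gid]]$taxon, known)
      if (length(unk))
        stop(sprintf("group '%s' references unknown taxon: %s",
                     gid, paste(unique(unk), collapse = ", ")))
    }
  }
  structure(groups, class = "orthogroups")
}

#' Write orthogroups in OrthoMCL format
#'
#' @param groups An `"orthogroups"` object.
#' @param file Output path; when `NULL` the lines are returned.
#' @return The lines, invisibly when written.
#' @export
write_groups <- function(groups, file = NULL) {
  lines <- vapply(names(groups), function(g)
    paste0(g, ": ", paste(groups[[g]]$member, collapse = " ")), character(1L))
  if (is.null(file)) return(unname(lines))
  writeLines(lines, file)
  invisible(unname(lines))
}

#' @export
print.orthogroups <- function(x, ...) {
  cat("Orthogroup set:", length(x), "groups,",
      sum(vapply(x, nrow, integer(1L))), "members\n")
  invisible(x)
}

#' Select single-copy orthologous groups
#'
#' A group passes iff (i) no taxon contributes two or more members,
#' (ii) at most `max_missing_red` red-lineage taxa are absent, and
#' (iii) at most `max_missing_green` green-lineage taxa are absent.
#' "Absent" means the taxon contributes zero members.  Rejection reasons are
#' evaluated in the fixed order multi-copy, red missingness, green
#' missingness, and the first violation is recorded.
#'
#' @param groups An `"orthogroups"` object.
#' @param taxa Taxon table (see [read_taxon_table()]); every member taxon
#'   must appear in it.
#' @param max_missing_red Maximum number of absent red taxa (default 3).
#' @param max_missing_green Maximum number of absent green taxa (default 1).
#' @return A list with `selected` (character vector of passing group ids) and
#'   `report` (data frame: `group`, `pass`, `reason`, `n_red_missing`,
#'   `n_green_missing`).
#' @export
select_single_copy <- function(groups, taxa,
                               max_missing_red = 3L, max_missing_green = 1L) {
  red <- taxa$taxon_id[taxa$group == "red"]
  green <- taxa$taxon_id[taxa$group == "green"]
  gid <- names(groups)
  pass <- logical(length(gid))
  reason <- character(length(gid))
  nrm <- integer(length(gid))
  ngm <- integer(length(gid))
  for (i in seq_along(gid)) {
    g <- groups[[i]]
    unk <- setdiff(g$taxon, taxa$taxon_id)
    if (length(unk))
      stop(sprintf("group '%s' references taxon not in taxon table: %s",
                   gid[i], paste(unique(unk), collapse = ", ")))
    cc <- table(g$taxon)
    nrm[i] <- sum(!(red %in% g$taxon))
    ngm[i] <- sum(!(green %in% g$taxon))
    if (any(cc >= 2L)) {
      reason[i] <- "multi-copy"
    } else if (nrm[i] > max_missing_red) {
      reason[i] <- "red missingness"
    } else if (ngm[i] > max_missing_green) {
      reason[i] <- "green missingness"
    } else {
      pass[i] <- TRUE
      reason[i] <- ""
    }
  }
  list(selected = gid[pass],
       report = data.frame(group = gid, pass = pass, reason = reason,
                           n_red_missing = nrm, n_green_missing = ngm,
                           stringsAsFactors = FALSE))
}

#' Filter alignments by length and sequence count
#'
#' Retains an alignment iff its column count is strictly greater than
#' `min_length_exclusive` and its row count is at least `min_sequences`
#' (defaults: >150 columns, >=15 sequences).
#'
#' @param alignments Named list of character matrix alignments.
#' @param min_length_exclusive Exclusive lower bound on alignment length.
#' @param min_sequences Inclusive lower bound on the number of sequences.
#' @return The retained sublist; a data frame report is attached as the
#'   `"report"` attribute (`id`, `n_col`, `n_seq`, `retained`).
#' @export
filter_alignments <- function(alignments, min_length_exclusive = 150L,
                              min_sequences = 15L) {
  if (is.null(names(alignments)) && length(alignments))
    stop("alignments must be a named list")
  ncols <- vapply(alignments, ncol, integer(1L))
  nseqs <- vapply(alignments, nrow, integer(1L))
  keep <- ncols > min_length_exclusive & nseqs >= min_sequences
  out <- alignments[keep]
  attr(out, "report") <- data.frame(id = names(alignments), n_col = ncols,
                                    n_seq = nseqs, retained = keep,
                                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Default outgroup priority order
#'
#' Green algal taxa in the order in which a single outgroup sequence is
#' retained per gene.
#' @return Character vector of taxon ids.
#' @export
outgroup_priority <- function() {
  c("Chlamydomonas_reinhardtii", "Chlorella_variabilis", "Micromonas_pusilla")
}

#' Reduce outgroup representation to one sequence
#'
#' Keeps exactly the highest-priority green algal row present in the
#' alignment and drops the other green rows; red rows are untouched.  When no
#' green row is present the alignment is returned unchanged with a warning.
#'
#' @param aln A character matrix alignment; row taxa are the `|`-prefixes of
#'   the row names.
#' @param priority Ordered character vector of green taxon ids; it defines
#'   which taxa count as outgroup and their retention order.
#' @return The reduced alignment.
#' @export
reduce_outgroup <- function(aln, priority = outgroup_priority()) {
  tax <- seq_taxon(rownames(aln))
  green_rows <- which(tax %in% priority)
  if (!length(green_rows)) {
    warning("no outgroup sequence present; alignment returned unchanged")
    return(aln)
  }
  keep_tax <- priority[min(match(tax[green_rows], priority))]
  drop <- green_rows[tax[green_rows] != keep_tax]
  out <- if (length(drop)) aln[-drop, , drop = FALSE] else aln
  attr(out, "id") <- attr(aln, "id")
  out
}
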