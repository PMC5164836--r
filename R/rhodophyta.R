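# Bundled study design: the 15 red + 3 green algal taxon set and the
# reference species-tree topology used throughout examples and simulations.

#' Red + green algal taxon table
#'
#' The 18-taxon sampling design the package is built around: 15 red algae
#' (5 seaweeds, 8 non-seaweed mesophiles, 2 extremophiles) plus 3 green
#' algal outgroup taxa, with taxonomic class and data-type annotations.
#'
#' @return A data frame with columns `taxon_id`, `name`, `group`
#'   (`red`/`green`), `class` (`Seaweed`, `Mesophile`, `Extremophile`,
#'   `Green`), `taxon_class` (taxonomic class) and `data_type`.
#' @export
rhodophyta_taxa <- function() {
  txt <- c(
    "Hildenbrandia_rubra|Hildenbrandia rubra|red|Seaweed|Florideophyceae|transcriptome",
    "Palmaria_palmata|Palmaria palmata|red|Seaweed|Florideophyceae|transcriptome",
    "Calliarthron_tuberculosum|Calliarthron tuberculosum|red|Seaweed|Florideophyceae|partial genome",
    "Chondrus_crispus|Chondrus crispus|red|Seaweed|Florideophyceae|genome",
    "Porphyra_umbilicalis|Porphyra umbilicalis|red|Seaweed|Bangiophyceae|transcriptome",
    "Purpureofilum_apyrenoidigerum|Purpureofilum apyrenoidigerum|red|Mesophile|Stylonematophyceae|transcriptome",
    "Rhodosorus_marinus|Rhodosorus marinus|red|Mesophile|Stylonematophyceae|transcriptome",
    "Rhodochaete_pulchella|Rhodochaete pulchella|red|Mesophile|Compsopogonophyceae|transcriptome",
    "Compsopogon_coeruleus|Compsopogon coeruleus|red|Mesophile|Compsopogonophyceae|transcriptome",
    "Rhodella_maculata|Rhodella maculata|red|Mesophile|Rhodellophyceae|transcriptome",
    "Erythrolobus_australicus|Erythrolobus australicus|red|Mesophile|Porphyridiophyceae|transcriptome",
    "Timspurckia_oligopyrenoides|Timspurckia oligopyrenoides|red|Mesophile|Porphyridiophyceae|transcriptome",
    "Porphyridium_purpureum|Porphyridium purpureum|red|Mesophile|Porphyridiophyceae|transcriptome",
    "Galdieria_sulphuraria|Galdieria sulphuraria|red|Extremophile|Cyanidiophyceae|transcriptome",
    "Cyanidioschyzon_merolae|Cyanidioschyzon merolae|red|Extremophile|Cyanidiophyceae|genome",
    "Chlorella_variabilis|Chlorella variabilis|green|Green|Trebouxiophyceae|genome",
    "Chlamydomonas_reinhardtii|Chlamydomonas reinhardtii|green|Green|Chlorophyceae|genome",
    "Micromonas_pusilla|Micromonas pusilla|green|Green|Mamiellophyceae|genome")
  f <- strsplit(txt, "|", fixed = TRUE)
  data.frame(taxon_id = vapply(f, `[`, "", 1L),
             name = vapply(f, `[`, "", 2L),
             group = vapply(f, `[`, "", 3L),
             class = vapply(f, `[`, "", 4L),
             taxon_class = vapply(f, `[`, "", 5L),
             data_type = vapply(f, `[`, "", 6L),
             stringsAsFactors = FALSE)
}

#' Write the bundled taxon table to TSV
#'
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_taxon_table <- function(file) {
  utils::write.table(rhodophyta_taxa(), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Reference red algal species-tree topology
#'
#' The rooted 15-taxon red algal topology: Cyanidiophyceae
#' (Galdieria, Cyanidioschyzon) sister to all mesophiles; among mesophiles an
#' early split between the seaweeds (Bangiophyceae + Florideophyceae, with
#' Hildenbrandia basal and Palmaria sister to Calliarthron + Chondrus) and
#' the non-seaweed lineages (Stylonematophyceae basal, Compsopogonophyceae
#' sister to Porphyridiophyceae + Rhodellophyceae).
#'
#' @param internal_length Branch length, in coalescent units, assigned to
#'   every internal branch (default 1.0).
#' @param terminal_length Branch length assigned to terminal branches
#'   (default 1.0); only relevant when simulating.
#' @param include_outgroup If `TRUE`, attach the 3-taxon green algal clade as
#'   sister to the red algae.
#' @return A rooted binary `phylo` object.
#' @export
rhodophyta_tree <- function(internal_length = 1.0, terminal_length = 1.0,
                            include_outgroup = FALSE) {
  red <- paste0(
    "((Galdieria_sulphuraria,Cyanidioschyzon_merolae),",
    "((Porphyra_umbilicalis,(Hildenbrandia_rubra,(Palmaria_palmata,",
    "(Calliarthron_tuberculosum,Chondrus_crispus)))),",
    "((Rhodosorus_marinus,Purpureofilum_apyrenoidigerum),",
    "((Compsopogon_coeruleus,Rhodochaete_pulchella),",
    "(Rhodella_maculata,(Porphyridium_purpureum,",
    "(Erythrolobus_australicus,Timspurckia_oligopyrenoides)))))))")
  nwk <- if (include_outgroup)
    paste0("(((Chlamydomonas_reinhardtii,Chlorella_variabilis),",
           "Micromonas_pusilla),", red, ");")
  else paste0(red, ";")
  tr <- ape::read.tree(text = nwk)
  n <- length(tr$tip.label)
  tr$edge.length <- ifelse(tr$edge[, 2L] <= n, terminal_length, internal_length)
  tr
}
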