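#' Dehydrin gene presence across the five Brachypodium genomes
#'
#' The packaged gene-by-genome table of the Brachypodium dehydrin family:
#' one row per annotated gene copy (gene name, genome, species, database
#' accession) across B. distachyon Bd21, B. stacei ABR114, both B. hybridum
#' ABR113 subgenomes and B. sylvaticum Ain-1.
#'
#' @return A tibble with `gene`, `genome_id`, `species`, `accession`.
#' @export
brachypodium_gene_presence <- function() {
  readr::read_tsv(
    system.file("extdata", "brachypodium_gene_presence.tsv", package = "dhnkit"),
    show_col_types = FALSE
  )
}

#' Dehydrin ortholog counts in outgroup grasses
#'
#' Per-species counts of dehydrin orthologs retrieved from the six outgroup
#' grass genomes.
#'
#' @return A tibble with `species`, `n_genes`.
#' @export
outgroup_dhn_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "outgroup_dhn_counts.tsv", package = "dhnkit"),
    show_col_types = FALSE
  )
}

#' Gene census of a dehydrin family survey
#'
#' Totals the family across genomes: all Brachypodium copies, the
#' B. distachyon reference genome alone, and the outgroup orthologs.
#'
#' @param presence Gene presence tibble ([brachypodium_gene_presence()]).
#' @param outgroup Outgroup count tibble ([outgroup_dhn_counts()]).
#' @param reference_genome Genome id counted as the focal reference.
#' @return A one-row tibble: `n_brachypodium`, `n_reference`, `n_outgroup`,
#'   plus `n_per_genome` as a list-column of per-genome counts.
#' @export
gene_census <- function(presence = brachypodium_gene_presence(),
                        outgroup = outgroup_dhn_counts(),
                        reference_genome = "Bd21") {
  per_genome <- dplyr::count(presence, .data$genome_id, name = "n_genes")
  tibble::tibble(
    n_brachypodium = nrow(presence),
    n_reference = as.integer(sum(per_genome$n_genes[per_genome$genome_id == reference_genome])),
    n_outgroup = as.integer(sum(outgroup$n_genes)),
    n_per_genome = list(per_genome)
  )
}
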