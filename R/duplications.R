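#' Default cross-family homology pairs
#'
#' Gene families treated as homologous for duplication calling, in addition
#' to same-family pairs: the Bdhn1/Bdhn2, Bdhn4/Bdhn5 and Bdhn7/Bdhn8
#' pairs.
#'
#' @return A tibble with `family_a`, `family_b`.
#' @export
dhn_homology_pairs <- function() {
  tibble::tibble(
    family_a = c("Bdhn1", "Bdhn4", "Bdhn7"),
    family_b = c("Bdhn2", "Bdhn5", "Bdhn8")
  )
}

canonical_pair <- function(a, b) {
  list(a = pmin(a, b), b = pmax(a, b))
}

#' Classify homologous gene pairs as tandem or segmental duplications
#'
#' Within each genome, every unordered pair of loci whose families are
#' homologous (same family, or a pair listed in `homology`) is classified:
#' tandem when both lie on one chromosome with an intergenic gap of at most
#' `tandem_max_gap` bp (inclusive; overlapping or adjacent loci have gap
#' 0), segmental otherwise (different chromosomes, or beyond the gap).
#' Several locus pairs with the same family pair and kind inside one genome
#' collapse to a single call.  Loci from different genomes are never
#' compared.
#'
#' @param loci Locus tibble (`gene_id`, `family`, `genome_id`,
#'   `genome_group`, `chromosome`, `start`, `end`, `strand`; 0-based
#'   half-open coordinates).
#' @param tandem_max_gap Maximum intergenic distance of a tandem pair, bp.
#' @param homology Cross-family homology table ([dhn_homology_pairs()]).
#' @return A tibble of per-genome calls: `genome_id`, `genome_group`,
#'   `family_a`, `family_b` (lexicographically canonicalized), `kind`.
#' @export
call_duplications <- function(loci, tandem_max_gap = 50000L,
                              homology = dhn_homology_pairs()) {
  validate_loci(loci)
  dup_id <- loci |>
    dplyr::count(.data$genome_id, .data$gene_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup_id) > 0) {
    stop("gene ids occur more than once within a genome: ",
      paste(dup_id$gene_id, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"genome_group" %in% names(loci)) loci$genome_group <- NA_character_
  hom <- with(canonical_pair(homology$family_a, homology$family_b), paste(a, b))
  calls <- list()
  for (g in unique(loci$genome_id)) {
    sub <- loci[loci$genome_id == g, ]
    if (nrow(sub) < 2L) next
    idx <- utils::combn(nrow(sub), 2L)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1L, k]
      j <- idx[2L, k]
      fa <- sub$family[i]
      fb <- sub$family[j]
      cp <- canonical_pair(fa, fb)
      homologous <- fa == fb || paste(cp$a, cp$b) %in% hom
      if (!homologous) next
      same_chr <- sub$chromosome[i] == sub$chromosome[j]
      gap <- if (same_chr) {
        max(
          0L,
          max(sub$start[i], sub$start[j]) - min(sub$end[i], sub$end[j])
        )
      } else {
        NA_integer_
      }
      kind <- if (same_chr && gap <= tandem_max_gap) "tandem" else "segmental"
      calls[[length(calls) + 1L]] <- tibble::tibble(
        genome_id = g, genome_group = sub$genome_group[i],
        family_a = cp$a, family_b = cp$b, kind = kind
      )
    }
  }
  if (length(calls) == 0L) {
    return(tibble::tibble(
      genome_id = character(), genome_group = character(),
      family_a = character(), family_b = character(), kind = character()
    ))
  }
  dplyr::bind_rows(calls) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$genome_id, .data$family_a, .data$family_b, .data$kind)
}

#' Merge per-genome duplication calls into events across genome groups
#'
#' Identical `(family pair, kind)` calls within one genome group collapse
#' to a single duplication event; the same pair observed in different
#' groups stays distinct.
#'
#' @param calls Output of [call_duplications()].
#' @param genome_groups Optional tibble `genome_id`, `genome_group`
#'   overriding (or supplying) the group of each genome.
#' @return A tibble of events: `genome_group`, `family_a`, `family_b`,
#'   `kind`, `n_genomes`, `genomes` (comma-joined supporting genome ids).
#' @export
merge_duplication_events <- function(calls, genome_groups = NULL) {
  if (!is.null(genome_groups)) {
    calls <- calls |>
      dplyr::select(-dplyr::any_of("genome_group")) |>
      dplyr::left_join(genome_groups, by = "genome_id")
  }
  if (any(is.na(calls$genome_group))) {
    stop("genome without a genome group: ",
      paste(unique(calls$genome_id[is.na(calls$genome_group)]), collapse = ", "),
      call. = FALSE
    )
  }
  calls |>
    dplyr::group_by(.data$genome_group, .data$family_a, .data$family_b, .data$kind) |>
    dplyr::summarise(
      n_genomes = dplyr::n_distinct(.data$genome_id),
      genomes = paste(sort(unique(.data$genome_id)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$genome_group, .data$family_a, .data$family_b)
}

#' Count merged duplication events by kind
#'
#' @param events Output of [merge_duplication_events()].
#' @return A tibble `kind`, `n_events`.
#' @export
duplication_event_counts <- function(events) {
  events |>
    dplyr::count(.data$kind, name = "n_events") |>
    dplyr::arrange(.data$kind)
}

#' Reference duplication locus fixture
#'
#' A locus table transcribing the published chromosomal layout of the
#' dehydrin duplications across the five Brachypodium genomes (Bd21 and the
#' B. hybridum D subgenome form the D-type group; B. stacei ABR114, the
#' B. hybridum S subgenome and B. sylvaticum Ain-1 the S-type group):
#' tandem Bdhn7-Bdhn8 pairs on Bd3/Bs4/Bsy4, the tandem Bdhn4-Bdhn5 pair on
#' Bd4 (Bd21 only), the tandem Bdhn1a-Bdhn1b pair on Bsy9 (Ain-1 only) and
#' cross-chromosome Bdhn1-Bdhn2 segmental pairs in every genome, plus
#' singleton Bdhn3/Bdhn9/Bdhn10 loci that yield no calls.  Coordinates are
#' synthetic; only chromosome assignment and intergenic gaps carry
#' information.
#'
#' @return A locus tibble.
#' @export
brachypodium_duplication_loci <- function() {
  gene_len <- 1500L
  row <- function(genome, group, family, chrom, start, id = NULL) {
    tibble::tibble(
      gene_id = if (is.null(id)) paste0(genome, ":", family) else paste0(genome, ":", id),
      family = family, genome_id = genome, genome_group = group,
      chromosome = chrom, start = start, end = start + gene_len, strand = "+"
    )
  }
  d_genome <- function(genome, with_bdhn4) {
    g <- dplyr::bind_rows(
      row(genome, "D-type", "Bdhn7", "Bd3", 1000000L),
      row(genome, "D-type", "Bdhn8", "Bd3", 1011500L), # 10 kb gap
      row(genome, "D-type", "Bdhn1", "Bd3", 20000000L),
      row(genome, "D-type", "Bdhn2", "Bd5", 3000000L),
      row(genome, "D-type", "Bdhn3", "Bd1", 5000000L),
      row(genome, "D-type", "Bdhn9", "Bd2", 7000000L),
      row(genome, "D-type", "Bdhn10", "Bd1", 9000000L)
    )
    if (with_bdhn4) {
      g <- dplyr::bind_rows(
        g,
        row(genome, "D-type", "Bdhn4", "Bd4", 5000000L),
        row(genome, "D-type", "Bdhn5", "Bd4", 5021500L) # 20 kb gap
      )
    }
    g
  }
  s_genome <- function(genome, chr_prefix) {
    c4 <- paste0(chr_prefix, "4")
    c9 <- paste0(chr_prefix, "9")
    dplyr::bind_rows(
      row(genome, "S-type", "Bdhn7", c4, 1000000L),
      row(genome, "S-type", "Bdhn8", c4, 1011500L),
      row(genome, "S-type", "Bdhn1", c9, 2000000L),
      row(genome, "S-type", "Bdhn2", c4, 8000000L),
      row(genome, "S-type", "Bdhn3", paste0(chr_prefix, "1"), 5000000L),
      row(genome, "S-type", "Bdhn9", paste0(chr_prefix, "2"), 7000000L),
      row(genome, "S-type", "Bdhn10", paste0(chr_prefix, "1"), 9000000L)
    )
  }
  sylvaticum <- dplyr::bind_rows(
    row("Ain-1", "S-type", "Bdhn7", "Bsy4", 1000000L),
    row("Ain-1", "S-type", "Bdhn8", "Bsy4", 1011500L),
    row("Ain-1", "S-type", "Bdhn1", "Bsy9", 2000000L, id = "Bdhn1a"),
    row("Ain-1", "S-type", "Bdhn1", "Bsy9", 2031500L, id = "Bdhn1b"), # 30 kb gap
    row("Ain-1", "S-type", "Bdhn2", "Bsy4", 8000000L),
    row("Ain-1", "S-type", "Bdhn3", "Bsy1", 5000000L),
    row("Ain-1", "S-type", "Bdhn9", "Bsy2", 7000000L),
    row("Ain-1", "S-type", "Bdhn10", "Bsy1", 9000000L)
  )
  dplyr::bind_rows(
    d_genome("Bd21", with_bdhn4 = TRUE),
    d_genome("ABR113-D", with_bdhn4 = FALSE),
    s_genome("ABR114", "Bs"),
    s_genome("ABR113-S", "Bs"),
    sylvaticum
  )
}
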