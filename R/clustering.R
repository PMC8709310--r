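#' Pairwise similarity of two proteins under a global BLOSUM62 alignment
#'
#' Aligns globally with BLOSUM62 and affine gap penalties (open 11, extend
#' 1) and reports the fraction of identical aligned positions over the full
#' alignment length, gap columns included.
#'
#' @param a,b Protein sequences (single strings).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return A one-row tibble: `id_a`, `id_b`, `similarity` in `[0, 1]`,
#'   `alignment_length`.
#' @export
pairwise_similarity <- function(a, b, gap_opening = 11, gap_extension = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  tibble::tibble(
    id_a = names(a) %||% NA_character_,
    id_b = names(b) %||% NA_character_,
    similarity = mean(pa == pb),
    alignment_length = length(pa)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# identity of many sequences against one representative, vectorized over
# the pattern set
similarity_to_rep <- function(seqs, rep_seq, gap_opening = 11, gap_extension = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs), Biostrings::AAString(rep_seq),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  # identical positions over full alignment length, gap columns included
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Cluster a multi-ecotype gene panel at an identity threshold
#'
#' Greedy centroid clustering with an iterative rescue pass.  Pass 1:
#' sequences are processed in descending length order (ties broken by id);
#' each joins the first existing cluster whose representative (its founding
#' member) it matches at or above `threshold`, otherwise it founds a new
#' cluster.  Clusters below `min_size` are then dissolved.  Pass 2:
#' dissolved and unplaced sequences are re-compared to the surviving
#' clusters' representatives and rescued at the same threshold; the
#' remainder stays unclassified.
#'
#' A sequence matching two representatives within 1 percentage point of
#' similarity is flagged `ambiguous` (it stays in its best cluster).
#'
#' @param seqs Named character vector of protein sequences, `AAStringSet`,
#'   or FASTA path.
#' @param threshold Identity threshold in `[0, 1]`.
#' @param min_size Minimum members of a primary cluster.
#' @return A tibble: `seq_id`, `cluster_id` (NA when unclassified),
#'   `representative`, `similarity` (to the representative), `status`
#'   (`primary`, `rescued`, `unclassified`) and `ambiguous`.
#' @export
cluster_panel <- function(seqs, threshold = 0.95, min_size = 3L) {
  seqs <- as_protein_vector(seqs)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence ids", call. = FALSE)
  }
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  n <- length(seqs)
  # pass 1: founding is sequential, but each new representative is compared
  # to the whole panel in one vectorized alignment call
  rep_idx <- integer(0)
  sim_mat <- matrix(numeric(0), nrow = n, ncol = 0)
  for (i in seq_len(n)) {
    if (ncol(sim_mat) == 0L || !any(sim_mat[i, ] >= threshold)) {
      rep_idx <- c(rep_idx, i)
      sim_mat <- cbind(sim_mat, similarity_to_rep(unname(seqs), seqs[[i]]))
    }
  }
  reps <- names(seqs)[rep_idx]
  assign_id <- rep(NA_character_, n)
  best_sim <- rep(NA_real_, n)
  ambiguous <- rep(FALSE, n)
  names(assign_id) <- names(seqs)
  for (i in seq_len(n)) {
    eligible <- which(rep_idx <= i) # clusters existing when i was processed
    sims <- sim_mat[i, eligible]
    hit <- which(sims >= threshold)
    first <- hit[1]
    assign_id[i] <- reps[eligible[first]]
    best_sim[i] <- sims[first]
    ambiguous[i] <- sum(sims >= max(sims) - 0.01) > 1 && sims[first] < 1
  }
  sizes <- table(assign_id)
  surviving <- names(sizes)[sizes >= min_size]
  surviving <- intersect(reps, surviving)
  status <- ifelse(assign_id %in% surviving, "primary", "unclassified")
  # rescue pass against surviving representatives (similarities already
  # computed in pass 1)
  surv_cols <- match(surviving, reps)
  for (i in which(status == "unclassified")) {
    if (length(surviving) == 0) {
      assign_id[i] <- NA_character_
      best_sim[i] <- NA_real_
      next
    }
    sims <- sim_mat[i, surv_cols]
    hit <- which(sims >= threshold)
    if (length(hit) > 0) {
      first <- hit[1]
      assign_id[i] <- surviving[first]
      best_sim[i] <- sims[first]
      ambiguous[i] <- sum(sims >= max(sims) - 0.01) > 1 && sims[first] < 1
      status[i] <- "rescued"
    } else {
      assign_id[i] <- NA_character_
      best_sim[i] <- NA_real_
    }
  }
  tibble::tibble(
    seq_id = names(seqs),
    cluster_id = ifelse(is.na(assign_id), NA_character_,
      paste0("cluster_", match(assign_id, reps))
    ),
    representative = assign_id,
    similarity = best_sim,
    status = status,
    ambiguous = ambiguous
  ) |>
    dplyr::arrange(.data$seq_id)
}

#' Fraction of ecotypes carrying every expected gene cluster
#'
#' For panels with `ecotype|gene` sequence ids: the share of ecotypes in
#' which all `n_expected` primary clusters are represented (the
#' completeness statistic of a multi-ecotype survey).
#'
#' @param clusters Output of [cluster_panel()].
#' @param n_expected Expected number of gene clusters; defaults to the
#'   number of distinct primary clusters observed.
#' @return A one-row tibble: `n_ecotypes`, `n_complete`, `fraction_complete`
#'   (percent).
#' @export
ecotype_completeness <- function(clusters, n_expected = NULL) {
  classified <- clusters |>
    dplyr::filter(!is.na(.data$cluster_id)) |>
    dplyr::mutate(ecotype = sub("\\|.*$", "", .data$seq_id))
  if (is.null(n_expected)) {
    n_expected <- dplyr::n_distinct(classified$cluster_id)
  }
  per_eco <- classified |>
    dplyr::group_by(.data$ecotype) |>
    dplyr::summarise(n_clusters = dplyr::n_distinct(.data$cluster_id), .groups = "drop")
  tibble::tibble(
    n_ecotypes = nrow(per_eco),
    n_complete = sum(per_eco$n_clusters >= n_expected),
    fraction_complete = 100 * sum(per_eco$n_clusters >= n_expected) / nrow(per_eco)
  )
}
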