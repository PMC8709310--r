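#' Conserved dehydrin segment consensus sequences
#'
#' The six short motifs that compose the dehydrin domain: the K-segment (the
#' family identifier), the Y- and S-segments, the polar \eqn{\phi}-linker, the
#' F-segment and a nuclear-localization (NLS) motif.  The S-segment is a run
#' pattern (five or more consecutive serines) rather than a fixed-length query.
#'
#' @param max_mismatch Mismatch tolerance for fixed-length queries (Hamming
#'   distance over an ungapped window).  The family rule admits a K-segment
#'   with at most 4 mismatches.
#' @param k_relaxed_max Upper mismatch bound of the relaxed K tier ("K*"),
#'   used for HIRD11-type dehydrins whose K-segment is degraded beyond the
#'   standard tolerance.  Windows with mismatches in
#'   `(max_mismatch, k_relaxed_max]` against the K query are reported with
#'   `relaxed = TRUE`.
#'
#' @return A tibble with columns `segment_type`, `query`, `max_mismatch`,
#'   `relaxed_max` (NA except for K).
#' @export
#' @examples
#' dhn_consensus()
dhn_consensus <- function(max_mismatch = 4L, k_relaxed_max = 8L) {
  tibble::tibble(
    segment_type = c("K", "Y", "S", "\u03D5", "F", "NLS"),
    query = c(
      "EKKGIMDKIKEKLPG", # K
      "VDEYGNP",         # Y
      "SSSSS",           # S (run pattern, >= 5)
      "EDDGQGR",         # phi
      "DRGLFDKFIGKK",    # F
      "KKDKKKKKEKK"      # NLS
    ),
    is_run = segment_type == "S",
    max_mismatch = as.integer(max_mismatch),
    relaxed_max = ifelse(segment_type == "K", as.integer(k_relaxed_max), NA_integer_)
  )
}

# amino-acid alphabet used for validation and mutation draws
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

assert_protein <- function(seq, allow_x = TRUE) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("protein sequence must be a single non-empty string", call. = FALSE)
  }
  ok <- c(AA_ALPHABET, if (allow_x) "X")
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), ok)
  if (length(bad) > 0) {
    stop("non-amino-acid characters in sequence: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(seq)
}

# Hamming mismatch count of `query` against every window of `seq`.
# Returns an integer vector of length nchar(seq) - nchar(query) + 1 (or
# length 0 when the sequence is shorter than the query).  'X' in the
# sequence always counts as a mismatch.
window_mismatches <- function(seq, query) {
  n <- nchar(seq)
  m <- nchar(query)
  if (n < m) {
    return(integer(0))
  }
  s <- utf8ToInt(seq)
  q <- utf8ToInt(query)
  x <- utf8ToInt("X")
  n_win <- n - m + 1L
  mm <- integer(n_win)
  for (j in seq_len(m)) {
    sj <- s[j:(j + n_win - 1L)]
    mm <- mm + as.integer(sj != q[j] | sj == x)
  }
  mm
}

#' Locate one conserved segment type in a protein sequence
#'
#' Slides an ungapped window of the query length along the sequence and
#' reports windows whose Hamming distance to the query does not exceed the
#' tolerance.  Overlapping candidate windows are resolved greedily: lowest
#' mismatch count first, then leftmost.  The S-segment is treated as a run
#' pattern: every maximal run of five or more consecutive serines is one hit.
#' For the K-segment a relaxed tier (`relaxed = TRUE`) reports windows with
#' mismatches between `max_mismatch + 1` and `relaxed_max`; relaxed windows
#' never displace a standard hit because the greedy pass prefers lower
#' mismatch counts.
#'
#' All coordinates are 0-based, half-open.
#'
#' @param seq A protein sequence (single string, 20-letter alphabet; `X`
#'   tolerated and always counted as a mismatch).
#' @param consensus One row of [dhn_consensus()] (or a compatible one-row
#'   data frame).
#' @return A tibble of hits: `segment_type`, `start`, `end`, `mismatches`,
#'   `relaxed`, sorted by position.  A sequence shorter than the query yields
#'   zero rows.
#' @export
#' @examples
#' find_segment_hits("EKKGIMDKIKEKLPG", dplyr::filter(dhn_consensus(), segment_type == "K"))
find_segment_hits <- function(seq, consensus) {
  assert_protein(seq)
  stopifnot(is.data.frame(consensus), nrow(consensus) == 1L)
  type <- consensus$segment_type
  if (isTRUE(consensus$is_run)) {
    return(s_run_hits(seq, type))
  }
  query <- consensus$query
  mm <- window_mismatches(seq, query)
  lim <- consensus$max_mismatch
  relax <- consensus$relaxed_max
  cap <- if (!is.na(relax)) relax else lim
  keep <- which(mm <= cap)
  if (length(keep) == 0L) {
    return(empty_hits())
  }
  cand <- tibble::tibble(
    segment_type = type,
    start = keep - 1L,
    end = keep - 1L + nchar(query),
    mismatches = mm[keep],
    relaxed = mm[keep] > lim
  )
  resolve_overlaps(cand)
}

s_run_hits <- function(seq, type = "S") {
  m <- gregexpr("S{5,}", seq)[[1]]
  if (m[1] == -1L) {
    return(empty_hits())
  }
  tibble::tibble(
    segment_type = type,
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + attr(m, "match.length"),
    mismatches = 0L,
    relaxed = FALSE
  )
}

empty_hits <- function() {
  tibble::tibble(
    segment_type = character(), start = integer(), end = integer(),
    mismatches = integer(), relaxed = logical()
  )
}

# Greedy non-overlap selection: lowest mismatch first, then leftmost, with
# segment type as the final (deterministic) tie-break.
resolve_overlaps <- function(cand) {
  cand <- dplyr::arrange(cand, .data$mismatches, .data$start, .data$segment_type)
  taken_start <- integer(0)
  taken_end <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]
    e <- cand$end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  dplyr::arrange(cand[keep, ], .data$start)
}

#' Scan a protein for all six conserved dehydrin segments
#'
#' Runs [find_segment_hits()] for every consensus and resolves overlaps
#' *across* segment types with the same greedy rule (lowest mismatch, then
#' leftmost, then type), so the returned hits are non-overlapping and
#' position-sorted — the form required by [assign_architecture()].
#'
#' @inheritParams find_segment_hits
#' @param consensus The consensus table, by default [dhn_consensus()].
#' @return A position-sorted tibble of non-overlapping segment hits.
#' @export
scan_segments <- function(seq, consensus = dhn_consensus()) {
  assert_protein(seq)
  cand <- purrr::map_dfr(
    seq_len(nrow(consensus)),
    function(i) find_segment_hits(seq, consensus[i, ])
  )
  resolve_overlaps(cand)
}

#' Decide whether a segment-hit set identifies a dehydrin
#'
#' In `strict` mode a protein is a dehydrin if and only if it carries at
#' least one K-segment within the standard mismatch tolerance.  `extended`
#' mode additionally admits HIRD11-like proteins: a relaxed K* hit
#' co-occurring with an S-run or an NLS hit.
#'
#' @param hits A tibble of segment hits from [scan_segments()].
#' @param mode `"strict"` or `"extended"`.
#' @return A single logical.
#' @export
is_dehydrin <- function(hits, mode = c("strict", "extended")) {
  mode <- match.arg(mode)
  has_k <- any(hits$segment_type == "K" & !hits$relaxed)
  if (mode == "strict") {
    return(has_k)
  }
  has_kstar <- any(hits$segment_type == "K" & hits$relaxed)
  has_companion <- any(hits$segment_type %in% c("S", "NLS"))
  has_k || (has_kstar && has_companion)
}

#' Build the architecture string from position-sorted segment hits
#'
#' Tokens are emitted in sequence order; consecutive identical tokens
#' collapse with a multiplicity suffix (K,K becomes "K2"); relaxed K hits
#' render as "K*"; an NLS token is joined to what follows with a hyphen
#' (giving strings such as "NLS-K*S").
#'
#' @param hits Non-overlapping, position-sorted hits ([scan_segments()]).
#' @return A single string, `""` for zero hits.
#' @export
#' @examples
#' arch <- scan_segments("VDEYGNPVDEYGNPVDEYGNPSSSSSEDDGQGREKKGIMDKIKEKLPGEKKGIMDKIKEKLPG")
#' assign_architecture(arch)
assign_architecture <- function(hits) {
  if (nrow(hits) == 0L) {
    return("")
  }
  if (is.unsorted(hits$start)) {
    hits <- dplyr::arrange(hits, .data$start)
  }
  if (any(hits$start[-1] < hits$end[-nrow(hits)])) {
    stop("overlapping hits: resolve overlaps before assigning an architecture",
      call. = FALSE
    )
  }
  tok <- ifelse(hits$segment_type == "K" & hits$relaxed, "K*", hits$segment_type)
  r <- rle(tok)
  piece <- paste0(r$values, ifelse(r$lengths > 1L, r$lengths, ""))
  out <- ""
  for (i in seq_along(piece)) {
    sep <- if (i > 1L && r$values[i - 1L] == "NLS") "-" else ""
    out <- paste0(out, sep, piece[i])
  }
  out
}

#' Annotate a panel of protein sequences
#'
#' Scans every record of a protein set for conserved dehydrin segments,
#' classifies each as dehydrin or not, and assigns its architecture string.
#'
#' @param fasta A named character vector of protein sequences, a
#'   `Biostrings::AAStringSet`, or a path to a protein FASTA file.
#' @param mode Dehydrin rule, `"strict"` or `"extended"` (see
#'   [is_dehydrin()]).
#' @param consensus Consensus table; tune `max_mismatch` / `k_relaxed_max`
#'   through [dhn_consensus()].
#' @return A tibble with one row per record: `protein_id`, `is_dehydrin`,
#'   `architecture`, `hit_string` (`type:start-end:mm`, semicolon-joined) and
#'   a list-column `hits` of the per-protein hit tibbles.
#' @export
annotate_panel <- function(fasta, mode = c("strict", "extended"),
                           consensus = dhn_consensus()) {
  mode <- match.arg(mode)
  seqs <- as_protein_vector(fasta)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence ids: ",
      paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
      call. = FALSE
    )
  }
  hits <- purrr::map(unname(seqs), scan_segments, consensus = consensus)
  tibble::tibble(
    protein_id = names(seqs),
    is_dehydrin = purrr::map_lgl(hits, is_dehydrin, mode = mode),
    architecture = purrr::map_chr(hits, assign_architecture),
    hit_string = purrr::map_chr(hits, hit_string),
    hits = hits
  )
}

hit_string <- function(hits) {
  if (nrow(hits) == 0L) {
    return("")
  }
  paste0(hits$segment_type, ":", hits$start, "-", hits$end, ":", hits$mismatches,
    collapse = ";"
  )
}

#' Summarize architecture usage across an annotated panel
#'
#' @param annotation Output of [annotate_panel()].
#' @return A tibble of architecture, gene count, sorted by decreasing count.
#' @export
architecture_census <- function(annotation) {
  annotation |>
    dplyr::filter(.data$is_dehydrin) |>
    dplyr::count(.data$architecture, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$architecture)
}
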