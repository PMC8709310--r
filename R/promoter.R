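#' Build a position weight matrix object
#'
#' Normalizes a 4 x width count (or probability) matrix column-wise,
#' applies the pseudocount, and stores the background base composition used
#' for log-odds scoring.
#'
#' @param matrix Numeric matrix with rows `A`, `C`, `G`, `T`.
#' @param motif_id Motif identifier.
#' @param pseudocount Added to every probability before renormalizing.
#' @param background Named base frequencies, summing to 1.
#' @return A `dhn_pwm` list: `motif_id`, `matrix` (probabilities),
#'   `background`, `pseudocount`, `width`.
#' @export
pwm_from_matrix <- function(matrix, motif_id = "motif",
                            pseudocount = 0.01,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(nrow(matrix) == 4L, ncol(matrix) >= 4L)
  rownames(matrix) <- c("A", "C", "G", "T")
  p <- sweep(matrix, 2, colSums(matrix), "/")
  p <- sweep(p + pseudocount, 2, colSums(p + pseudocount), "/")
  structure(
    list(
      motif_id = motif_id, matrix = p, background = background,
      pseudocount = pseudocount, width = ncol(p)
    ),
    class = "dhn_pwm"
  )
}

#' @export
print.dhn_pwm <- function(x, ...) {
  cat("<dhn_pwm>", x$motif_id, "width", x$width, "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per column)
#'
#' @param pwm A `dhn_pwm` object.
#' @return A string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$matrix)[apply(pwm$matrix, 2, which.max)], collapse = "")
}

pwm_revcomp <- function(pwm) {
  m <- pwm$matrix[c("T", "G", "C", "A"), rev(seq_len(pwm$width)), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  bg <- pwm$background[c("T", "G", "C", "A")]
  names(bg) <- c("A", "C", "G", "T")
  structure(
    list(
      motif_id = pwm$motif_id, matrix = m, background = bg,
      pseudocount = pwm$pseudocount, width = pwm$width
    ),
    class = "dhn_pwm"
  )
}

#' Extract a promoter window around a transcription start site
#'
#' Plus-strand genes get the `[tss - 500, tss + 200)` window; minus-strand
#' genes the reverse complement of `[tss - 200, tss + 500]`-mirrored
#' window, so positions always read 5' to 3' relative to the gene.
#' Windows are truncated, with a warning, at contig edges.
#'
#' @param genome_seq Contig sequence (single string or `DNAString`), or a
#'   named vector / `DNAStringSet` together with `contig`.
#' @param tss 0-based TSS coordinate on the contig.
#' @param strand `"+"` or `"-"`.
#' @param gene_id Identifier attached to the window.
#' @param upstream,downstream Window extent around the TSS, bp.
#' @param contig Contig name when `genome_seq` holds several sequences.
#' @return A one-row tibble: `gene_id`, `sequence`, `strand`,
#'   `window_start` (offset of the first returned base relative to the TSS,
#'   gene orientation), `truncated`.
#' @export
extract_promoter <- function(genome_seq, tss, strand = "+", gene_id = "gene",
                             upstream = 500L, downstream = 200L, contig = NULL) {
  seqs <- as_dna_vector(genome_seq)
  seq <- if (!is.null(contig)) seqs[[contig]] else seqs[[1]]
  n <- nchar(seq)
  if (tss < 0 || tss >= n) stop("TSS outside the contig", call. = FALSE)
  if (strand == "+") {
    from <- tss - upstream
    to <- tss + downstream # exclusive
  } else {
    from <- tss - downstream + 1L
    to <- tss + upstream + 1L
  }
  clip_from <- max(0L, from)
  clip_to <- min(n, to)
  truncated <- clip_from > from || clip_to < to
  if (truncated) {
    warning("promoter window truncated at contig edge for ", gene_id, call. = FALSE)
  }
  window <- substr(seq, clip_from + 1L, clip_to)
  if (strand == "-") {
    window <- revcomp(window)
    offset <- -(clip_to - 1L - tss) # most upstream retained base, gene orientation
  } else {
    offset <- clip_from - tss
  }
  tibble::tibble(
    gene_id = gene_id, sequence = window, strand = strand,
    window_start = as.integer(offset), truncated = truncated
  )
}

score_windows <- function(seq_chars, pwm) {
  w <- pwm$width
  n <- length(seq_chars)
  if (n < w) {
    return(numeric(0))
  }
  lo <- log2(pwm$matrix / pwm$background[rownames(pwm$matrix)])
  n_win <- n - w + 1L
  sc <- numeric(n_win)
  bad <- !seq_chars %in% c("A", "C", "G", "T")
  for (j in seq_len(w)) {
    b <- seq_chars[j:(j + n_win - 1L)]
    col <- lo[cbind(match(b, c("A", "C", "G", "T")), j)]
    sc <- sc + ifelse(is.na(col), NA_real_, col)
  }
  if (any(bad)) {
    message("windows overlapping degenerate bases were skipped")
  }
  sc
}

#' Scan a promoter window with a position weight matrix
#'
#' Scores every offset on both strands as the sum of log2 probability over
#' background ratios and reports hits scoring at least `threshold` bits.
#' Overlapping hits, including opposite-strand hits at one position, are
#' all reported.  Windows containing degenerate bases are skipped.
#'
#' @param window A promoter tibble row from [extract_promoter()], or a
#'   plain sequence string (then `window_start` is taken as 0 and positions
#'   are window offsets).
#' @param pwm A `dhn_pwm` object.
#' @param threshold Minimum score, bits.
#' @return A tibble of hits: `gene_id`, `motif_id`, `position` (relative to
#'   the TSS when the window carries an offset; 0-based start of the
#'   match), `strand`, `score`.
#' @export
scan_pwm <- function(window, pwm, threshold = 9) {
  if (is.character(window)) {
    window <- tibble::tibble(
      gene_id = names(window) %||% "window", sequence = unname(window),
      strand = "+", window_start = 0L, truncated = FALSE
    )
  }
  out <- purrr::map_dfr(seq_len(nrow(window)), function(i) {
    chars <- strsplit(window$sequence[i], "")[[1]]
    fwd <- score_windows(chars, pwm)
    rev <- score_windows(chars, pwm_revcomp(pwm))
    pos <- seq_along(fwd) - 1L + window$window_start[i]
    hits <- dplyr::bind_rows(
      tibble::tibble(position = pos, strand = "+", score = fwd),
      tibble::tibble(position = pos, strand = "-", score = rev)
    )
    hits <- hits[!is.na(hits$score) & hits$score >= threshold, ]
    if (nrow(hits) == 0L) {
      return(tibble::tibble(
        gene_id = character(), motif_id = character(), position = integer(),
        strand = character(), score = numeric()
      ))
    }
    tibble::tibble(
      gene_id = window$gene_id[i], motif_id = pwm$motif_id,
      position = as.integer(hits$position), strand = hits$strand,
      score = hits$score
    )
  })
  dplyr::arrange(out, .data$gene_id, .data$position, .data$strand)
}

#' Per-gene CRE hit counts
#'
#' @param hits Output of [scan_pwm()] (possibly row-bound over genes and
#'   motifs).
#' @return A tibble `gene_id`, `motif_id`, `n_sites`.
#' @export
cre_site_counts <- function(hits) {
  dplyr::count(hits, .data$gene_id, .data$motif_id, name = "n_sites")
}
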