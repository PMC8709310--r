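#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water mass, in Daltons.
#'
#' @param seq Protein sequence (standard 20-letter alphabet).
#' @return Molecular weight in Da.
#' @export
#' @examples
#' molecular_weight("GG")
molecular_weight <- function(seq) {
  chars <- prop_residues(seq)
  sum(RESIDUE_MASS[chars]) + WATER_MASS
}

prop_residues <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% PROP_AA)
  if (length(bad) > 0) {
    stop("unknown residue '", chars[bad[1]], "' at position ", bad[1], call. = FALSE)
  }
  chars
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy index over all residues.  Negative values
#' indicate hydrophilic proteins; dehydrins built from the conserved
#' segments are always negative.
#'
#' @inheritParams molecular_weight
#' @return GRAVY score (dimensionless, within `[-4.5, 4.5]`).
#' @export
gravy <- function(seq) {
  chars <- prop_residues(seq)
  mean(KYTE_DOOLITTLE[chars])
}

net_charge <- function(counts, ph, pka = PKA_EMBOSS) {
  pos <- 1 / (1 + 10^(ph - pka$nterm)) +
    sum(counts[names(pka$positive)] / (1 + 10^(ph - pka$positive)), na.rm = TRUE)
  neg <- 1 / (1 + 10^(pka$cterm - ph)) +
    sum(counts[names(pka$negative)] / (1 + 10^(pka$negative - ph)), na.rm = TRUE)
  pos - neg
}

#' Isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge of the free termini
#' and the D, E, C, Y, H, K, R side chains crosses zero, found by bisection.
#' Uses the EMBOSS pKa set by default (the table is a named, swappable
#' constant).
#'
#' @inheritParams molecular_weight
#' @param pka pKa table: a list with `nterm`, `cterm`, `positive`,
#'   `negative` entries.
#' @param tol Bisection stops when the net charge magnitude falls below
#'   this.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = PKA_EMBOSS, tol = 1e-4) {
  chars <- prop_residues(seq)
  counts <- table(factor(chars, levels = PROP_AA))
  lo <- 0
  hi <- 14
  # net charge is strictly decreasing in pH, so the root is unique
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- net_charge(counts, mid, pka)
    if (abs(q) < tol) {
      return(mid)
    }
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Instability index
#'
#' Guruprasad dipeptide-weight score: `(10 / L) * sum(DIWV(x_i, x_{i+1}))`
#' over the `L - 1` dipeptides of a length-`L` sequence.  Values above 40
#' suggest an unstable protein.
#'
#' @inheritParams molecular_weight
#' @return Instability index (dimensionless).
#' @export
instability_index <- function(seq) {
  chars <- prop_residues(seq)
  n <- length(chars)
  if (n < 2L) stop("instability index needs at least 2 residues", call. = FALSE)
  (10 / n) * sum(DIWV[cbind(chars[-n], chars[-1])])
}

#' Biochemical property table for a protein panel
#'
#' Computes length, molecular weight, isoelectric point, GRAVY and
#' instability index for every record.
#'
#' @param fasta Named character vector, `AAStringSet`, or protein FASTA
#'   path.
#' @return A tibble: `protein_id`, `length`, `mol_wt` (Da), `pI`, `gravy`,
#'   `instability`.
#' @export
protein_properties <- function(fasta) {
  seqs <- as_protein_vector(fasta)
  tibble::tibble(
    protein_id = names(seqs),
    length = nchar(unname(seqs)),
    mol_wt = purrr::map_dbl(unname(seqs), molecular_weight),
    pI = purrr::map_dbl(unname(seqs), isoelectric_point),
    gravy = purrr::map_dbl(unname(seqs), gravy),
    instability = purrr::map_dbl(unname(seqs), instability_index)
  )
}
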