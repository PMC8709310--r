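#' @importFrom rlang .data
#' @importFrom tibble tibble
NULL

# Coerce FASTA path / AAStringSet / named character vector to a named
# character vector of sequences.
as_protein_vector <- function(x) {
  if (methods::is(x, "AAStringSet") || methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- Biostrings::readAAStringSet(x)
    out <- as.character(set)
    names(out) <- sub("\\s.*$", "", names(set))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) {
      names(x) <- paste0("seq", seq_along(x))
    }
    return(x)
  }
  stop("cannot interpret input as protein sequences", call. = FALSE)
}

as_dna_vector <- function(x) {
  if (methods::is(x, "DNAStringSet") || methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    set <- Biostrings::readDNAStringSet(x)
    out <- as.character(set)
    names(out) <- sub("\\s.*$", "", names(set))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) {
      names(x) <- paste0("seq", seq_along(x))
    }
    return(x)
  }
  stop("cannot interpret input as DNA sequences", call. = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- switch(type,
    AA = Biostrings::AAStringSet(seqs),
    DNA = Biostrings::DNAStringSet(seqs)
  )
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene locus table
#'
#' Accepts either a tab-separated table with columns `gene_id`, `family`,
#' `genome_id`, `genome_group`, `chromosome`, `start`, `end`, `strand`
#' (0-based half-open coordinates) or a GFF3 file of gene features carrying
#' `family`, `genome_id` and `genome_group` attributes (GFF 1-based closed
#' coordinates are converted to 0-based half-open).
#'
#' @param path File path.
#' @return A locus tibble.
#' @export
read_locus_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##gff")) {
    return(read_locus_gff3(path))
  }
  loci <- readr::read_tsv(path, show_col_types = FALSE, na = ".")
  validate_loci(loci)
  loci
}

read_locus_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  attr_get <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
    ifelse(lengths(m) == 1L, sub(paste0(".*", key, "="), "", unlist(m)), NA_character_)
  }
  att <- vapply(f, `[`, "", 9L)
  tibble::tibble(
    gene_id = attr_get(att, "ID"),
    family = attr_get(att, "family"),
    genome_id = attr_get(att, "genome_id"),
    genome_group = attr_get(att, "genome_group"),
    chromosome = vapply(f, `[`, "", 1L),
    start = as.integer(vapply(f, `[`, "", 4L)) - 1L, # to 0-based half-open
    end = as.integer(vapply(f, `[`, "", 5L)),
    strand = vapply(f, `[`, "", 7L)
  )
}

validate_loci <- function(loci) {
  need <- c("gene_id", "family", "genome_id", "chromosome", "start", "end", "strand")
  miss <- setdiff(need, names(loci))
  if (length(miss) > 0) {
    stop("locus table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(loci$end <= loci$start)) stop("locus end must exceed start", call. = FALSE)
  if (any(loci$start < 0)) stop("negative locus coordinates", call. = FALSE)
  invisible(loci)
}

#' Read a JASPAR-like position weight matrix file
#'
#' Parses the four-row `A/C/G/T [ counts... ]` text layout.  Counts (or
#' probabilities) are normalized column-wise to probabilities.
#'
#' @param path PWM text file; may contain several motifs, each introduced by
#'   a `>motif_id name` header.
#' @return A named list of PWM objects as built by [pwm_from_matrix()].
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0L) stop("no '>' motif headers found in ", path, call. = FALSE)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    id <- strsplit(sub("^>", "", lines[heads[i]]), "\\s+")[[1]][1]
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- block[grepl(paste0("^", b, "\\b"), block)]
      if (length(ln) != 1L) stop("motif ", id, ": missing row for base ", b, call. = FALSE)
      as.numeric(strsplit(gsub("[][ACGT]", "", ln), "\\s+")[[1]] |> (\(x) x[nzchar(x)])())
    })
    mat <- do.call(rbind, rows)
    rownames(mat) <- c("A", "C", "G", "T")
    out[[id]] <- pwm_from_matrix(mat, motif_id = id)
  }
  out
}

#' Write a tab-separated table
#'
#' Thin wrapper enforcing the package's TSV dialect (tab separator, `.` for
#' missing values).  List-columns are dropped.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_out <- function(x, path) {
  x <- x[, !vapply(x, is.list, TRUE), drop = FALSE]
  readr::write_tsv(x, path, na = ".")
  invisible(path)
}
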