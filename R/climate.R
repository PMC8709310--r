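#' Classify ecotype climate niches from the first principal component
#'
#' Standardizes the climate variables, eigendecomposes their correlation
#' matrix and scores ecotypes on the first axis.  The axis sign is anchored
#' so that the designated anchor variable — by default the
#' coldest-quarter temperature (`bio11`), negated — loads positively,
#' making high scores "cold".  Scores above `cutoff` are classed `cold`,
#' below `-cutoff` `warm`, and `mesic` otherwise.
#'
#' @param climate Tibble: `ecotype` plus numeric climate columns
#'   (worldclim-style, 19 variables in the reference layout).
#' @param cutoff Absolute PC1 score separating cold/warm from mesic.
#' @param anchor Column anchoring the axis orientation.
#' @return A tibble `ecotype`, `pc1_score`, `class`, with attributes
#'   `variance_explained` (fraction of total variance on PC1) and
#'   `loadings`.
#' @export
climate_pc1_classes <- function(climate, cutoff = 2.5, anchor = "bio11") {
  vars <- setdiff(names(climate), "ecotype")
  mat <- as.matrix(climate[vars])
  constant <- apply(mat, 2, stats::sd) == 0
  if (any(constant)) {
    warning("constant climate columns dropped: ",
      paste(vars[constant], collapse = ", "),
      call. = FALSE
    )
    mat <- mat[, !constant, drop = FALSE]
    vars <- vars[!constant]
  }
  if (nrow(mat) < 3L || length(vars) < 2L) {
    stop("need at least 3 ecotypes and 2 non-constant variables", call. = FALSE)
  }
  pca <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  scores <- pca$x[, 1]
  loading <- pca$rotation[, 1]
  if (anchor %in% vars && loading[[anchor]] > 0) {
    # orient so the negated anchor (cold-quarter temperature) loads positively
    scores <- -scores
    loading <- -loading
  }
  var_explained <- pca$sdev[1]^2 / sum(pca$sdev^2)
  out <- tibble::tibble(
    ecotype = climate$ecotype,
    pc1_score = unname(scores),
    class = dplyr::case_when(
      scores > cutoff ~ "cold",
      scores < -cutoff ~ "warm",
      TRUE ~ "mesic"
    )
  )
  attr(out, "variance_explained") <- var_explained
  attr(out, "loadings") <- loading
  out
}

#' Standardized trait matrix ordered by tree tips
#'
#' Builds the matrix behind a phylo-heatmap: traits standardized to zero
#' mean and unit variance, rows ordered by the tip order of the tree.
#'
#' @param tree An `ape::phylo` tree.
#' @param values Tibble with an `ecotype` column matching tip labels plus
#'   numeric columns.
#' @return A tibble ordered by tree tips, values standardized per column.
#' @export
phyloheatmap_matrix <- function(tree, values) {
  missing_tips <- setdiff(tree$tip.label, values$ecotype)
  if (length(missing_tips) > 0) {
    stop("no values for tips: ", paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  ordered <- values[match(tree$tip.label, values$ecotype), ]
  num <- vapply(ordered, is.numeric, logical(1))
  ordered[num] <- lapply(ordered[num], function(x) as.numeric(scale(x)))
  ordered
}
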