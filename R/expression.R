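tpm_long <- function(tpm, design) {
  need <- c("sample", "ecotype", "water")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) {
    stop("design table is missing columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  long <- tidyr::pivot_longer(tpm, -"gene", names_to = "sample", values_to = "tpm")
  unknown <- setdiff(long$sample, design$sample)
  if (length(unknown) > 0) {
    stop("samples missing from the design table: ",
      paste(utils::head(unknown, 5), collapse = ", "),
      call. = FALSE
    )
  }
  dplyr::left_join(long, design, by = "sample")
}

contrast_groups <- function(design, contrast) {
  parts <- strsplit(contrast, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("contrast must be of the form 'W-D', 'C-H' or 'CW-HW'", call. = FALSE)
  }
  label_of <- function(part) {
    if (part %in% c("W", "D")) {
      design$water == part
    } else if (part %in% c("C", "H")) {
      design$temperature == part
    } else if (nchar(part) == 2L) {
      design$temperature == substr(part, 1, 1) & design$water == substr(part, 2, 2)
    } else {
      stop("unknown contrast level: ", part, call. = FALSE)
    }
  }
  list(
    a = design$sample[label_of(parts[1])],
    b = design$sample[label_of(parts[2])],
    label = contrast
  )
}

#' Wilcoxon rank-sum differential expression
#'
#' Two-sided rank-sum test per gene between the two groups of a contrast
#' (`"W-D"` pooled water levels, `"C-H"` pooled temperatures, or explicit
#' cells like `"CW-HW"`), with Benjamini-Hochberg adjustment across all
#' genes (and contrasts) in the batch.  The test is exact (full
#' enumeration) whenever both groups have at most 8 samples and there are
#' no ties, and uses the tie-corrected normal approximation otherwise.
#'
#' @param tpm Wide TPM tibble (`gene` column + one column per sample).
#' @param design Design tibble (`sample`, `ecotype`, `water`,
#'   `temperature`, `replicate`).
#' @param contrasts Character vector of contrasts; all results share one BH
#'   family.
#' @return A tibble: `gene`, `contrast`, `n_a`, `n_b`, `statistic`,
#'   `raw_p`, `bh_adjusted_p`, `direction` (sign of the median difference,
#'   first group minus second).
#' @export
wilcoxon_de <- function(tpm, design, contrasts = "W-D") {
  long <- tpm_long(tpm, design)
  res <- purrr::map_dfr(contrasts, function(ct) {
    grp <- contrast_groups(design, ct)
    purrr::map_dfr(unique(long$gene), function(g) {
      xa <- long$tpm[long$gene == g & long$sample %in% grp$a]
      xb <- long$tpm[long$gene == g & long$sample %in% grp$b]
      if (length(xa) < 2L || length(xb) < 2L) {
        warning("gene ", g, " skipped in ", ct, ": a group has < 2 samples",
          call. = FALSE
        )
        return(NULL)
      }
      if (stats::sd(c(xa, xb)) == 0) {
        # degenerate all-tied case: no evidence against equality
        return(tibble::tibble(
          gene = g, contrast = ct, n_a = length(xa), n_b = length(xb),
          statistic = length(xa) * length(xb) / 2, raw_p = 1, direction = 0
        ))
      }
      exact <- length(xa) <= 8L && length(xb) <= 8L &&
        !any(duplicated(c(xa, xb)))
      wt <- suppressWarnings(
        stats::wilcox.test(xa, xb, alternative = "two.sided", exact = exact)
      )
      tibble::tibble(
        gene = g, contrast = ct, n_a = length(xa), n_b = length(xb),
        statistic = unname(wt$statistic), raw_p = wt$p.value,
        direction = sign(stats::median(xa) - stats::median(xb))
      )
    })
  })
  res$bh_adjusted_p <- stats::p.adjust(res$raw_p, method = "BH")
  res
}

#' Kruskal-Wallis omnibus test with Tukey HSD letters across ecotypes
#'
#' Within each water treatment, tests per gene whether expression differs
#' among ecotypes (Kruskal-Wallis rank test with tie correction), then
#' runs Tukey HSD on the group means via the studentized-range
#' distribution and summarizes pairwise differences as a compact letter
#' display: ecotypes sharing a letter are not significantly different.
#'
#' @inheritParams wilcoxon_de
#' @param within Design column splitting the analysis (default `water`).
#' @param alpha Significance level of the letter display.
#' @return A list of two tibbles: `omnibus` (`gene`, `treatment`,
#'   `statistic`, `df`, `p_value`) and `letters` (`gene`, `treatment`,
#'   `ecotype`, `letters`).
#' @export
kruskal_tukey <- function(tpm, design, within = "water", alpha = 0.05) {
  long <- tpm_long(tpm, design)
  omnibus <- list()
  letters_out <- list()
  for (g in unique(long$gene)) {
    for (lev in unique(design[[within]])) {
      sub <- long[long$gene == g & long[[within]] == lev, ]
      groups <- factor(sub$ecotype)
      if (nlevels(groups) < 3L) {
        stop("kruskal_tukey needs at least 3 ecotype groups", call. = FALSE)
      }
      kw <- stats::kruskal.test(sub$tpm, groups)
      omnibus[[length(omnibus) + 1L]] <- tibble::tibble(
        gene = g, treatment = lev, statistic = unname(kw$statistic),
        df = unname(kw$parameter), p_value = kw$p.value
      )
      tk <- stats::TukeyHSD(stats::aov(tpm ~ ecotype, data = sub))$ecotype
      p <- tk[, "p adj"]
      letters_out[[length(letters_out) + 1L]] <- tibble::tibble(
        gene = g, treatment = lev,
        ecotype = levels(groups),
        letters = compact_letters(levels(groups), p, alpha)
      )
    }
  }
  list(
    omnibus = dplyr::bind_rows(omnibus),
    letters = dplyr::bind_rows(letters_out)
  )
}

# Compact letter display by insert-absorb over the significant-difference
# matrix; `p` is named "B-A" style as returned by TukeyHSD.
compact_letters <- function(groups, p, alpha = 0.05) {
  k <- length(groups)
  diff_mat <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (nm in names(p)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% groups)) next
    sig <- !is.na(p[[nm]]) && p[[nm]] < alpha
    diff_mat[pair[1], pair[2]] <- sig
    diff_mat[pair[2], pair[1]] <- sig
  }
  # start from one letter covering everything; split on each significant pair
  sets <- list(groups)
  for (a in groups) {
    for (b in groups) {
      if (a < b && diff_mat[a, b]) {
        new_sets <- list()
        for (s in sets) {
          if (all(c(a, b) %in% s)) {
            new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        # absorb sets contained in another set
        keep <- rep(TRUE, length(new_sets))
        for (u in seq_along(new_sets)) {
          for (v in seq_along(new_sets)) {
            if (u != v && keep[u] && keep[v] &&
              all(new_sets[[u]] %in% new_sets[[v]]) &&
              length(new_sets[[u]]) < length(new_sets[[v]])) {
              keep[u] <- FALSE
            }
          }
        }
        sets <- unique(new_sets[keep])
      }
    }
  }
  lab <- vapply(groups, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
      collapse = ""
    )
  }, character(1))
  unname(lab)
}

#' Drought-induced percent change of expression
#'
#' Per ecotype, `(mean_D - mean_W) / mean_W * 100`; the gene-level value
#' is the unweighted mean across ecotypes.  Ecotypes with `mean_W = 0` are
#' skipped with a warning.
#'
#' @inheritParams wilcoxon_de
#' @param by_ecotype Return the per-ecotype table instead of the gene-level
#'   summary.
#' @return A tibble `gene`, `percent_change`, `n_ecotypes` (or the
#'   per-ecotype table when `by_ecotype = TRUE`).
#' @export
percent_change <- function(tpm, design, by_ecotype = FALSE) {
  long <- tpm_long(tpm, design)
  per_eco <- long |>
    dplyr::group_by(.data$gene, .data$ecotype, .data$water) |>
    dplyr::summarise(m = mean(.data$tpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "water", values_from = "m")
  if (!all(c("W", "D") %in% names(per_eco))) {
    stop("design must contain both W and D water levels", call. = FALSE)
  }
  zero <- per_eco$W == 0
  if (any(zero)) {
    warning(sum(zero), " (gene, ecotype) cells skipped: watered mean is zero",
      call. = FALSE
    )
    per_eco <- per_eco[!zero, ]
  }
  per_eco <- dplyr::mutate(per_eco,
    percent_change = (.data$D - .data$W) / .data$W * 100
  )
  if (by_ecotype) {
    return(dplyr::select(per_eco, "gene", "ecotype", "W", "D", "percent_change"))
  }
  per_eco |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      percent_change = mean(.data$percent_change),
      n_ecotypes = dplyr::n(), .groups = "drop"
    )
}

#' Between-gene correlation of drought expression
#'
#' Pearson correlation of `log(TPM + 1)` ecotype means between every gene
#' pair under one condition, with two-sided p-values.
#'
#' @inheritParams wilcoxon_de
#' @param condition Water level to correlate under (default `"D"`).
#' @return A tibble `gene_a`, `gene_b`, `r`, `p_value`, `n` for all
#'   unordered pairs; zero-variance genes are flagged with `NA` and a
#'   warning.
#' @export
gene_correlation <- function(tpm, design, condition = "D") {
  long <- tpm_long(tpm, design)
  means <- long |>
    dplyr::filter(.data$water == condition) |>
    dplyr::group_by(.data$gene, .data$ecotype) |>
    dplyr::summarise(m = mean(log(.data$tpm + 1)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "m")
  genes <- setdiff(names(means), "ecotype")
  if (nrow(means) < 3L) stop("need at least 3 ecotypes", call. = FALSE)
  pairs <- utils::combn(genes, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- means[[pairs[1, k]]]
    b <- means[[pairs[2, k]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance gene in pair ", pairs[1, k], "/", pairs[2, k],
        call. = FALSE
      )
      return(tibble::tibble(
        gene_a = pairs[1, k], gene_b = pairs[2, k],
        r = NA_real_, p_value = NA_real_, n = length(a)
      ))
    }
    ct <- stats::cor.test(a, b, method = "pearson")
    tibble::tibble(
      gene_a = pairs[1, k], gene_b = pairs[2, k],
      r = unname(ct$estimate), p_value = ct$p.value, n = length(a)
    )
  })
}
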