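#' The twelve drought-response phenotypic traits
#'
#' @return Character vector of trait column names: relative and absolute
#'   leaf water content, leaf mass per area, proline, above/below-ground
#'   and total biomass, root mass ratio, carbon isotope discrimination
#'   (water-use-efficiency proxy), leaf carbon and nitrogen content and
#'   their ratio.
#' @export
dhn_trait_names <- function() {
  c(
    "leaf_rwc", "leaf_wc", "lma", "pro", "abvgrd", "blwgrd", "ttlmass",
    "rmr", "delta13c", "leafc", "leafn", "cn"
  )
}

#' Drought-induced trait change summary
#'
#' For every trait column: the mean percent change across ecotypes between
#' the paired dry and watered values (`(D - W) / W * 100`), with a paired
#' two-sided Wilcoxon signed-rank test of D versus W.  Ecotypes without a
#' complete W/D pair are excluded with a warning.
#'
#' @param traits Wide trait tibble: `ecotype`, `treatment` (`W`/`D`), one
#'   column per trait.
#' @param trait_cols Trait columns to summarize; defaults to every column
#'   except `ecotype` and `treatment`.
#' @return A tibble: `trait`, `percent_change`, `p_value`, `n_ecotypes`.
#' @export
trait_change_summary <- function(traits, trait_cols = NULL) {
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(names(traits), c("ecotype", "treatment"))
  }
  paired <- traits |>
    dplyr::count(.data$ecotype) |>
    dplyr::filter(.data$n == 2L)
  dropped <- setdiff(unique(traits$ecotype), paired$ecotype)
  if (length(dropped) > 0) {
    warning("ecotypes without a W/D pair excluded: ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
    traits <- traits[traits$ecotype %in% paired$ecotype, ]
  }
  purrr::map_dfr(trait_cols, function(tr) {
    wide <- traits |>
      dplyr::select("ecotype", "treatment", dplyr::all_of(tr)) |>
      tidyr::pivot_wider(names_from = "treatment", values_from = dplyr::all_of(tr))
    pc <- (wide$D - wide$W) / wide$W * 100
    identical_pairs <- all(wide$D == wide$W)
    p <- if (identical_pairs) {
      1
    } else {
      suppressWarnings(
        stats::wilcox.test(wide$D, wide$W, paired = TRUE, exact = FALSE)$p.value
      )
    }
    tibble::tibble(
      trait = tr, percent_change = mean(pc), p_value = p, n_ecotypes = nrow(wide)
    )
  })
}

#' Regress a trait on dehydrin gene expression
#'
#' Ordinary least squares of the ecotype-level trait value on the
#' ecotype-level expression of one gene (replicates averaged first; the
#' ecotype is the unit of analysis).
#'
#' @param traits Wide trait tibble (`ecotype`, `treatment`, trait columns).
#' @param expr_summary Tibble `ecotype`, `treatment`, `gene`, `expression`
#'   (ecotype-level mean expression).
#' @param trait,gene Which trait column and gene to relate.
#' @param treatment Restrict to one treatment (`"D"`, `"W"`), or `NULL` to
#'   pool both.
#' @param log_expression Regress on `log(expression + 1)` instead of the
#'   raw scale.
#' @return A one-row tibble: `trait`, `gene`, `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided, on the slope), `n`.
#' @export
fit_trait_expression_regression <- function(traits, expr_summary, trait, gene,
                                            treatment = NULL,
                                            log_expression = FALSE) {
  ex <- expr_summary[expr_summary$gene == gene, ]
  if (!is.null(treatment)) {
    ex <- ex[ex$treatment == treatment, ]
    traits <- traits[traits$treatment == treatment, ]
  }
  dat <- dplyr::inner_join(
    dplyr::select(traits, "ecotype", "treatment", y = dplyr::all_of(trait)),
    dplyr::select(ex, "ecotype", "treatment", x = "expression"),
    by = c("ecotype", "treatment")
  )
  if (nrow(dat) < 3L) stop("need at least 3 matched ecotypes", call. = FALSE)
  if (log_expression) dat$x <- log(dat$x + 1)
  fit <- stats::lm(y ~ x, data = dat)
  sm <- summary(fit)
  tibble::tibble(
    trait = trait, gene = gene,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n = nrow(dat)
  )
}

#' All trait x gene expression regressions
#'
#' Maps [fit_trait_expression_regression()] over every trait column and
#' every gene in the expression summary.
#'
#' @inheritParams fit_trait_expression_regression
#' @param trait_cols Trait columns; defaults to all non-id columns.
#' @return A tibble with one row per (trait, gene).
#' @export
trait_expression_regressions <- function(traits, expr_summary, trait_cols = NULL,
                                         treatment = NULL, log_expression = FALSE) {
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(names(traits), c("ecotype", "treatment"))
  }
  genes <- unique(expr_summary$gene)
  tidyr::expand_grid(trait = trait_cols, gene = genes) |>
    purrr::pmap_dfr(function(trait, gene) {
      fit_trait_expression_regression(
        traits, expr_summary, trait, gene,
        treatment = treatment, log_expression = log_expression
      )
    })
}

#' Ecotype-level expression summary from a TPM experiment
#'
#' Averages replicates to one value per gene, ecotype and treatment — the
#' form consumed by the trait regressions and by [gen_trait_table()].
#'
#' @inheritParams wilcoxon_de
#' @return A tibble `gene`, `ecotype`, `treatment`, `expression`.
#' @export
expression_summary <- function(tpm, design) {
  tpm_long(tpm, design) |>
    dplyr::group_by(.data$gene, .data$ecotype, treatment = .data$water) |>
    dplyr::summarise(expression = mean(.data$tpm), .groups = "drop")
}
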