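#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline in one list: segment mismatch
#' tolerances, the tandem gap, clustering threshold and minimum size, the
#' promoter window, the PWM bit-score cutoff, test settings and the master
#' seed.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
dhn_config <- function(...) {
  config <- list(
    max_mismatch = 4L, k_relaxed_max = 8L, dehydrin_mode = "extended",
    tandem_max_gap = 50000L,
    cluster_threshold = 0.95, cluster_min_size = 3L,
    promoter_upstream = 500L, promoter_downstream = 200L, pwm_threshold = 9,
    n_perm = 999L, bh_alpha = 0.05, pc1_cutoff = 2.5,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  utils::modifyList(config, overrides)
}

#' A sharp example PWM
#'
#' A 10-bp near-deterministic, non-palindromic matrix (consensus
#' `TACGTGTCAC`, an ACGT-core ABRE-like element), convenient for planting
#' and recovering promoter sites.
#'
#' @param motif_id Motif name.
#' @param sharpness Probability mass on the consensus base per column.
#' @return A `dhn_pwm` object.
#' @export
example_pwm <- function(motif_id = "ABRE-like", sharpness = 0.97) {
  consensus <- c("T", "A", "C", "G", "T", "G", "T", "C", "A", "C")
  m <- matrix((1 - sharpness) / 3, nrow = 4, ncol = length(consensus),
    dimnames = list(c("A", "C", "G", "T"), NULL)
  )
  for (j in seq_along(consensus)) m[consensus[j], j] <- sharpness
  pwm_from_matrix(m, motif_id = motif_id, pseudocount = 0.01)
}

#' Simulate a complete dehydrin study bundle
#'
#' Generates every input the pipeline consumes, with ground truth: the
#' reference protein panel, the duplication locus fixture, a
#' multi-ecotype panel, promoters with planted sites, a TPM experiment
#' with the four published drought effect sizes (5.74, 39, 67.8 and 97.8
#' percent) plus null decoy genes, traits coupled to expression, a climate
#' table and a tree with a Brownian tip trait.
#'
#' @param seed Master seed; each component derives its own sub-seed.
#' @param n_ecotypes_expr,n_replicates Expression design size.
#' @param n_ecotypes_panel Ecotypes in the protein panel.
#' @param n_tips Tree size.
#' @return A named list of inputs and `truth` components.
#' @export
simulate_study <- function(seed = 1L, n_ecotypes_expr = 32L, n_replicates = 4L,
                           n_ecotypes_panel = 12L, n_tips = 30L) {
  proteins <- gen_reference_panel(seed = seed)
  panel_sources <- proteins$sequences[c("Bdhn1a", "Bdhn2", "Bdhn3", "Bdhn7")]
  theta <- c(
    Bdhn1a = 0.0574, Bdhn2 = 0.39, Bdhn3 = 0.678, Bdhn7 = 0.978,
    decoy1 = 0, decoy2 = 0
  )
  pwm <- example_pwm()
  list(
    proteins = proteins,
    loci = brachypodium_duplication_loci(),
    panel = gen_ecotype_panel(panel_sources,
      n_ecotypes = n_ecotypes_panel,
      divergence = 0.02, dropout = 0, seed = seed + 101L
    ),
    promoters = gen_promoter_set(pwm,
      n_prom = 3L, sites_per_prom = 1L,
      length = 700L, seed = seed + 202L
    ),
    pwm = pwm,
    expression = gen_expression_matrix(theta,
      baseline = 100, dispersion = 0.2,
      n_ecotypes = n_ecotypes_expr, n_replicates = n_replicates,
      seed = seed + 303L
    ),
    climate = gen_climate_table(n_ecotypes = 54L, noise_sd = 0.1, seed = seed + 404L),
    phylo = gen_tree_with_trait(n_tips, lambda_true = 1, seed = seed + 505L),
    seed = seed
  )
}

#' Run the full dehydrin analysis pipeline
#'
#' Executes annotation, biochemical properties, duplication calling,
#' ecotype clustering, promoter scanning, differential expression, trait
#' statistics, climate classification and phylogenetic signal on a study
#' bundle ([simulate_study()] or equivalently shaped real inputs).  Any
#' stage failure aborts with an error naming the stage; results of
#' completed stages are retained in the error condition's `partial` field.
#'
#' @param inputs Study bundle, as from [simulate_study()].
#' @param config Configuration list ([dhn_config()]).
#' @param out_dir Optional directory; when given, every tabular result is
#'   written as TSV together with a JSON run manifest (config, hash,
#'   package version, seed).
#' @return A named list of result tibbles.
#' @export
run_pipeline <- function(inputs, config = dhn_config(), out_dir = NULL) {
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(paste0("stage '", name, "' failed: ", conditionMessage(e)))
      err$partial <- results
      stop(err)
    })
  }
  consensus <- dhn_consensus(config$max_mismatch, config$k_relaxed_max)

  results$annotation <- stage("annotate", annotate_panel(
    inputs$proteins$sequences,
    mode = config$dehydrin_mode, consensus = consensus
  ))
  results$architecture_census <- stage("annotate", architecture_census(results$annotation))
  results$properties <- stage("properties", protein_properties(inputs$proteins$sequences))
  results$duplication_calls <- stage("duplications", call_duplications(
    inputs$loci,
    tandem_max_gap = config$tandem_max_gap
  ))
  results$duplication_events <- stage(
    "duplications",
    merge_duplication_events(results$duplication_calls)
  )
  results$clusters <- stage("cluster", cluster_panel(
    inputs$panel$sequences,
    threshold = config$cluster_threshold,
    min_size = config$cluster_min_size
  ))
  results$cre_hits <- stage("scan", scan_pwm(
    tibble::tibble(
      gene_id = names(inputs$promoters$sequences),
      sequence = unname(inputs$promoters$sequences),
      strand = "+", window_start = 0L, truncated = FALSE
    ),
    inputs$pwm,
    threshold = config$pwm_threshold
  ))
  results$de <- stage("de", wilcoxon_de(
    inputs$expression$tpm, inputs$expression$design,
    contrasts = "W-D"
  ))
  results$percent_change <- stage("de", percent_change(
    inputs$expression$tpm, inputs$expression$design
  ))
  expr_summary <- stage("traits", expression_summary(
    inputs$expression$tpm, inputs$expression$design
  ))
  mean_expr <- expr_summary |>
    dplyr::group_by(.data$ecotype, .data$treatment) |>
    dplyr::summarise(expression = mean(.data$expression), .groups = "drop")
  traits <- stage("traits", gen_trait_table(
    mean_expr, dhn_default_trait_slopes(),
    intercepts = 100, noise_sd = 1, seed = inputs$seed + 606L
  ))
  results$trait_changes <- stage("traits", trait_change_summary(traits))
  results$trait_regressions <- stage("traits", trait_expression_regressions(
    traits,
    dplyr::filter(expr_summary, .data$gene == "Bdhn7")
  ))
  results$niche_classes <- stage("climate", climate_pc1_classes(
    inputs$climate$climate,
    cutoff = config$pc1_cutoff
  ))
  results$signal_k <- stage("physig", tidy(blomberg_k(
    inputs$phylo$tree, inputs$phylo$trait,
    n_perm = config$n_perm, seed = inputs$seed + 707L
  )))
  results$signal_lambda <- stage("physig", tidy(pagel_lambda(
    inputs$phylo$tree, inputs$phylo$trait
  )))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      if (is.data.frame(results[[nm]])) {
        write_tsv_out(results[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
      }
    }
    manifest <- list(
      package = "dhnkit",
      version = as.character(utils::packageVersion("dhnkit")),
      seed = inputs$seed,
      config = config,
      config_hash = rlang::hash(config)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  results
}
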