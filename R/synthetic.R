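# Synthetic-data generators.  Every downstream stage of the package can be
# exercised on these outputs with known ground truth, so the whole pipeline
# is testable without reference genomes or RNA-seq.

LINKER_ALPHABET <- c("G", "E", "T", "H", "Q", "A") # small/polar, dehydrin-like

#' Parse an architecture string into segment tokens
#'
#' Tokens are `F`, `S`, `K`, `K*`, `Y`, `NLS` and the phi linker, each with
#' an optional integer multiplicity (`"Y3SϕK2"` expands to
#' Y,Y,Y,S,ϕ,K,K).  Hyphens (as in `"NLS-K*S"`) are separators only.
#'
#' @param architecture Architecture string.
#' @return Character vector of expanded tokens.
#' @export
parse_architecture <- function(architecture) {
  s <- gsub("-", "", architecture, fixed = TRUE)
  out <- character(0)
  while (nzchar(s)) {
    m <- regmatches(s, regexpr("^(NLS|K\\*|[FSKY\u03D5])([0-9]+)?", s))
    if (length(m) == 0L || !nzchar(m)) {
      stop("unknown architecture token at: '", s, "'", call. = FALSE)
    }
    tok <- sub("[0-9]+$", "", m)
    mult <- sub("^(NLS|K\\*|[FSKY\u03D5])", "", m)
    mult <- if (nzchar(mult)) as.integer(mult) else 1L
    out <- c(out, rep(tok, mult))
    s <- substr(s, nchar(m) + 1L, nchar(s))
  }
  out
}

segment_sequence_for <- function(token) {
  cons <- dhn_consensus()
  base <- stats::setNames(cons$query, cons$segment_type)
  switch(token,
    "K*" = base[["K"]], # substitutions applied by the caller
    base[[token]]
  )
}

mutate_residues <- function(seq, rate) {
  if (rate <= 0) {
    return(seq)
  }
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate one synthetic dehydrin protein with known segment truth
#'
#' Concatenates the consensus sequence of every token of `architecture`,
#' separated by random low-complexity linkers, then applies an independent
#' per-residue substitution load.  The `K*` token renders the K consensus
#' with exactly six planted substitutions, placing it above the standard
#' 4-mismatch tolerance but inside the relaxed K* tier.
#'
#' @param architecture Architecture string over `F,S,K,K*,Y,ϕ,NLS`
#'   with optional multiplicities, e.g. `"Y3SϕK2"`.
#' @param linker_length Residues between consecutive segments (sampled from
#'   G,E,T,H,Q,A).
#' @param mutation_rate Per-residue substitution probability in `[0, 0.27)`
#'   (below 4/15, so a K-segment stays within tolerance in expectation).
#' @param seed Integer seed; identical inputs give identical output.
#' @return A list: `sequence` and `truth` (a list with `architecture`,
#'   `mutation_rate`, `seed` and a `segments` tibble of 0-based half-open
#'   spans).
#' @export
#' @examples
#' gen_dehydrin_protein("K", 0, 0, 1)$sequence
gen_dehydrin_protein <- function(architecture, linker_length = 10L,
                                 mutation_rate = 0, seed = 1L) {
  stopifnot(linker_length >= 0, mutation_rate >= 0, mutation_rate < 1)
  tokens <- parse_architecture(architecture)
  withr::with_seed(seed, {
    for (attempt in 1:50) {
      pieces <- character(0)
      seg_type <- character(0)
      seg_start <- integer(0)
      seg_end <- integer(0)
      pos <- 0L
      for (i in seq_along(tokens)) {
        if (i > 1L && linker_length > 0L) {
          pieces <- c(pieces, paste(
            sample(LINKER_ALPHABET, linker_length, replace = TRUE),
            collapse = ""
          ))
          pos <- pos + linker_length
        }
        seg <- segment_sequence_for(tokens[i])
        if (tokens[i] == "K*") {
          chars <- strsplit(seg, "")[[1]]
          idx <- sample(length(chars), 6L)
          for (j in idx) chars[j] <- sample(setdiff(AA_ALPHABET, chars[j]), 1L)
          seg <- paste(chars, collapse = "")
        }
        pieces <- c(pieces, seg)
        seg_type <- c(seg_type, tokens[i])
        seg_start <- c(seg_start, pos)
        seg_end <- c(seg_end, pos + nchar(seg))
        pos <- pos + nchar(seg)
      }
      clean <- paste(pieces, collapse = "")
      if (plant_matches_scan(clean, seg_type, seg_start, seg_end)) break
      if (attempt == 50L) {
        stop("could not build a protein whose linkers stay clear of the consensus queries",
          call. = FALSE
        )
      }
    }
    sequence <- mutate_residues(clean, mutation_rate)
    list(
      sequence = sequence,
      truth = list(
        architecture = architecture,
        mutation_rate = mutation_rate,
        seed = seed,
        segments = tibble::tibble(
          segment_type = seg_type, start = seg_start, end = seg_end
        )
      )
    )
  })
}

# TRUE when a zero-mutation assembly scans back to exactly the planted
# spans (linkers can, rarely, imitate a short query; the generator redraws
# them until they do not).
plant_matches_scan <- function(seq, seg_type, seg_start, seg_end) {
  hits <- scan_segments(seq)
  tok <- ifelse(hits$segment_type == "K" & hits$relaxed, "K*", hits$segment_type)
  length(tok) == length(seg_type) &&
    all(tok == seg_type) &&
    all(hits$start == seg_start) &&
    all(hits$end == seg_end)
}

#' Reference dehydrin gene layouts
#'
#' The eleven protein layouts of the Brachypodium dehydrin family (Bdhn1a
#' and Bdhn1b are distinct proteins of the Bdhn1 gene pair), covering the
#' eight architectures observed in the family, with YSϕK2 carried by
#' four genes (Bdhn3, Bdhn6, Bdhn7, Bdhn8).  The per-gene assignments of
#' the non-YSϕK2 architectures are a synthetic reconstruction (the
#' family vocabulary is published; the gene-by-gene figure is not machine
#' readable) consistent with the published structure classes: FSKn for
#' Bdhn1b/Bdhn2, YnSKn for Bdhn3-Bdhn9, SK-type (ERD14-like) for Bdhn1a and
#' the K*-NLS-S HIRD11 layout for Bdhn10.
#'
#' @return A tibble with `gene` and `architecture`.
#' @export
dhn_reference_layouts <- function() {
  tibble::tibble(
    gene = c(
      "Bdhn1a", "Bdhn1b", "Bdhn2", "Bdhn3", "Bdhn4", "Bdhn5",
      "Bdhn6", "Bdhn7", "Bdhn8", "Bdhn9", "Bdhn10"
    ),
    architecture = c(
      "S\u03D5K2", "FSK2", "FSK3", "YS\u03D5K2", "Y3S\u03D5K",
      "Y3S\u03D5K2", "YS\u03D5K2", "YS\u03D5K2", "YS\u03D5K2",
      "YS\u03D5K", "NLS-K*S"
    )
  )
}

#' Generate the reference dehydrin protein panel
#'
#' One synthetic protein per [dhn_reference_layouts()] row.
#'
#' @inheritParams gen_dehydrin_protein
#' @return A list: `sequences` (named character vector) and `truth` (named
#'   list of per-protein truths).
#' @export
gen_reference_panel <- function(linker_length = 10L, mutation_rate = 0, seed = 1L) {
  layouts <- dhn_reference_layouts()
  sims <- purrr::map2(
    layouts$architecture, seed + seq_len(nrow(layouts)) - 1L,
    function(a, s) gen_dehydrin_protein(a, linker_length, mutation_rate, s)
  )
  list(
    sequences = stats::setNames(purrr::map_chr(sims, "sequence"), layouts$gene),
    truth = stats::setNames(purrr::map(sims, "truth"), layouts$gene)
  )
}

#' Generate a gene locus table with planted duplication events
#'
#' Emits a locus table containing every planted tandem (same chromosome,
#' inter-gene gap `gap_tandem`) or segmental (different chromosomes) pair,
#' plus singleton decoy families that must not produce duplication calls.
#'
#' @param events A tibble with columns `genome_id`, `genome_group`,
#'   `family_a`, `family_b`, `kind` (`"tandem"` or `"segmental"`),
#'   `chromosome_a`, `chromosome_b` (equal to `chromosome_a` for tandem).
#' @param gap_tandem Intergenic distance planted for tandem pairs, bp.
#' @param n_decoys Singleton decoy families per genome.
#' @param gene_length Length of each gene, bp.
#' @param seed Integer seed.
#' @return A list: `loci` (locus tibble) and `truth` (the `events` input).
#' @export
gen_locus_table <- function(events, gap_tandem = 10000L, n_decoys = 2L,
                            gene_length = 1500L, seed = 1L) {
  stopifnot(all(events$kind %in% c("tandem", "segmental")), gap_tandem >= 0)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      start_a <- sample.int(5e6, 1L) + 1e5
      if (ev$kind == "tandem") {
        start_b <- start_a + gene_length + gap_tandem
        chr_b <- ev$chromosome_a
      } else {
        start_b <- sample.int(5e6, 1L) + 1e5
        chr_b <- ev$chromosome_b
        if (identical(chr_b, ev$chromosome_a)) {
          stop("segmental events need distinct chromosomes", call. = FALSE)
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = paste0(ev$genome_id, ":", c(ev$family_a, ev$family_b), ":", i, c("a", "b")),
        family = c(ev$family_a, ev$family_b),
        genome_id = ev$genome_id,
        genome_group = ev$genome_group,
        chromosome = c(ev$chromosome_a, chr_b),
        start = c(start_a, start_b),
        end = c(start_a, start_b) + gene_length,
        strand = sample(c("+", "-"), 2L, replace = TRUE)
      )
    }
    for (g in unique(events$genome_id)) {
      grp <- events$genome_group[match(g, events$genome_id)]
      for (d in seq_len(n_decoys)) {
        st <- sample.int(5e6, 1L) + 1e5
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_id = paste0(g, ":decoy", d),
          family = paste0("decoy", d),
          genome_id = g, genome_group = grp,
          chromosome = paste0("chr_decoy", d),
          start = st, end = st + gene_length,
          strand = sample(c("+", "-"), 1L)
        )
      }
    }
    loci <- dplyr::bind_rows(rows)
    if (any(loci$start < 0)) stop("negative coordinates generated", call. = FALSE)
    list(loci = loci, truth = events)
  })
}

#' Multi-ecotype protein panel with planted cluster labels
#'
#' Each base sequence spawns `n_ecotypes` mutated copies (substitutions
#' only, so pairwise identity to the source is `1 - realized load / length`);
#' `dropout` removes copies at random.
#'
#' @param base_seqs Named character vector of source proteins (one per gene
#'   type).
#' @param n_ecotypes Copies per source.
#' @param divergence Per-residue substitution probability (keep `< 0.05` so
#'   planted members stay above the 95 percent identity threshold).
#' @param dropout Probability that any one copy is removed.
#' @param seed Integer seed.
#' @return A list: `sequences` (named `ecotype|gene` vector) and `truth`
#'   (tibble `seq_id`, `ecotype`, `source_gene`).
#' @export
gen_ecotype_panel <- function(base_seqs, n_ecotypes = 54L, divergence = 0.02,
                              dropout = 0, seed = 1L) {
  if (divergence >= 1) stop("divergence must be < 1", call. = FALSE)
  stopifnot(!is.null(names(base_seqs)), dropout >= 0, dropout < 1)
  withr::with_seed(seed, {
    ids <- character(0)
    seqs <- character(0)
    src <- character(0)
    eco <- character(0)
    for (g in names(base_seqs)) {
      for (e in seq_len(n_ecotypes)) {
        ecotype <- sprintf("eco%02d", e)
        ids <- c(ids, paste0(ecotype, "|", g))
        seqs <- c(seqs, mutate_residues(base_seqs[[g]], divergence))
        src <- c(src, g)
        eco <- c(eco, ecotype)
      }
    }
    keep <- stats::runif(length(ids)) >= dropout
    list(
      sequences = stats::setNames(seqs[keep], ids[keep]),
      truth = tibble::tibble(seq_id = ids[keep], ecotype = eco[keep], source_gene = src[keep])
    )
  })
}

#' Promoter set with planted PWM consensus sites
#'
#' Background bases are sampled from `background`; each planted site is the
#' PWM consensus (column-wise most probable base) inserted at a recorded
#' position and strand.
#'
#' @param pwm A PWM object ([pwm_from_matrix()]).
#' @param n_prom Number of promoters.
#' @param sites_per_prom Planted sites per promoter.
#' @param length Promoter length, bp (must be at least the motif width).
#' @param background Base composition of the background.
#' @param seed Integer seed.
#' @param max_tries Redraw budget for non-overlapping site placement.
#' @return A list: `sequences` (named character vector) and `truth`
#'   (tibble `prom_id`, `position` 0-based, `strand`).
#' @export
gen_promoter_set <- function(pwm, n_prom = 3L, sites_per_prom = 1L, length = 700L,
                             background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                             seed = 1L, max_tries = 100L) {
  w <- ncol(pwm$matrix)
  if (length < w) stop("promoter length below motif width", call. = FALSE)
  consensus <- pwm_consensus(pwm)
  withr::with_seed(seed, {
    seqs <- character(n_prom)
    truth <- list()
    for (p in seq_len(n_prom)) {
      chars <- sample(names(background), length, replace = TRUE, prob = background)
      placed <- integer(0)
      strands <- character(0)
      tries <- 0L
      while (base::length(placed) < sites_per_prom) {
        tries <- tries + 1L
        if (tries > max_tries) stop("could not place non-overlapping sites", call. = FALSE)
        pos <- sample.int(length - w + 1L, 1L) - 1L # 0-based
        if (any(pos < placed + w & pos + w > placed)) next
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") consensus else revcomp(consensus)
        chars[(pos + 1L):(pos + w)] <- strsplit(ins, "")[[1]]
        placed <- c(placed, pos)
        strands <- c(strands, strand)
      }
      seqs[p] <- paste(chars, collapse = "")
      if (sites_per_prom > 0L) {
        truth[[p]] <- tibble::tibble(
          prom_id = sprintf("prom%02d", p), position = placed, strand = strands
        )
      }
    }
    names(seqs) <- sprintf("prom%02d", seq_len(n_prom))
    list(
      sequences = seqs,
      truth = if (base::length(truth) > 0) dplyr::bind_rows(truth) else
        tibble::tibble(prom_id = character(), position = integer(), strand = character())
    )
  })
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Synthetic TPM matrix with multiplicative drought effects
#'
#' Watered (W) samples fluctuate log-normally around the per-gene baseline;
#' dry (D) samples around `baseline * (1 + theta)`.  Replicates are split
#' evenly between cool (C) and hot (H) temperature blocks; the drought
#' effect is temperature independent.
#'
#' @param theta Named numeric: per-gene multiplicative drought effect
#'   (`theta = 0.978` plants a 97.8 percent mean increase).
#' @param baseline Named numeric (or scalar) baseline TPM, `> 0`.
#' @param dispersion Standard deviation of the log-normal replicate noise on
#'   the log scale (`0` gives noiseless data).
#' @param n_ecotypes,n_replicates Design size; `n_replicates >= 2` per
#'   water level.
#' @param seed Integer seed.
#' @return A list: `tpm` (wide tibble, `gene` + one column per sample),
#'   `design` (tibble `sample`, `ecotype`, `water`, `temperature`,
#'   `replicate`) and `truth` (tibble `gene`, `theta`, `baseline`).
#' @export
gen_expression_matrix <- function(theta, baseline = 100, dispersion = 0.2,
                                  n_ecotypes = 32L, n_replicates = 4L, seed = 1L) {
  stopifnot(!is.null(names(theta)), all(theta > -1), n_replicates >= 2L)
  genes <- names(theta)
  baseline <- if (length(baseline) == 1L) {
    stats::setNames(rep(baseline, length(genes)), genes)
  } else {
    baseline[genes]
  }
  if (any(baseline <= 0)) stop("baseline TPM must be positive", call. = FALSE)
  design <- tidyr::expand_grid(
    ecotype = sprintf("eco%02d", seq_len(n_ecotypes)),
    water = c("W", "D"),
    replicate = seq_len(n_replicates)
  ) |>
    dplyr::mutate(
      temperature = ifelse(.data$replicate <= ceiling(n_replicates / 2), "C", "H"),
      sample = paste0(.data$ecotype, "_", .data$water, "_", .data$temperature,
        "_r", .data$replicate
      )
    ) |>
    dplyr::select("sample", "ecotype", "water", "temperature", "replicate")
  withr::with_seed(seed, {
    mu <- outer(baseline, ifelse(design$water == "D", 1, 0), function(b, d) b) *
      (1 + outer(theta, as.integer(design$water == "D"), `*`))
    noise <- if (dispersion > 0) {
      matrix(stats::rlnorm(length(mu), meanlog = 0, sdlog = dispersion), nrow = nrow(mu))
    } else {
      1
    }
    tpm_mat <- mu * noise
  })
  dimnames(tpm_mat) <- list(genes, design$sample)
  list(
    tpm = dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(tpm_mat)),
    design = design,
    truth = tibble::tibble(gene = genes, theta = unname(theta), baseline = unname(baseline))
  )
}

#' Trait table linearly coupled to dehydrin expression
#'
#' Trait value = intercept + slope x expression + Gaussian noise, per
#' ecotype and treatment.
#'
#' @param expr_summary Tibble `ecotype`, `treatment`, `expression` (mean
#'   dehydrin expression of that ecotype under that treatment).
#' @param slopes Named numeric, one slope per trait.
#' @param intercepts Named numeric (or scalar) per-trait intercept.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A wide tibble: `ecotype`, `treatment`, one column per trait.
#' @export
gen_trait_table <- function(expr_summary, slopes, intercepts = 0, noise_sd = 0,
                            seed = 1L) {
  stopifnot(!is.null(names(slopes)))
  traits <- names(slopes)
  intercepts <- if (length(intercepts) == 1L) {
    stats::setNames(rep(intercepts, length(traits)), traits)
  } else {
    intercepts[traits]
  }
  withr::with_seed(seed, {
    out <- expr_summary
    for (tr in traits) {
      out[[tr]] <- intercepts[[tr]] + slopes[[tr]] * expr_summary$expression +
        stats::rnorm(nrow(expr_summary), sd = noise_sd)
    }
  })
  dplyr::select(out, -"expression")
}

#' Default drought-response trait slope signs
#'
#' Sign pattern of the association between dehydrin expression and the 12
#' phenotypic traits: positive for pro, blwgrd, rmr, delta13c (WUE), leafc
#' and cn; negative for leaf_rwc, leaf_wc and leafn; the biomass and lma
#' traits carry small effects of the sign their drought response suggests.
#'
#' @return Named numeric vector of 12 slopes.
#' @export
dhn_default_trait_slopes <- function() {
  c(
    leaf_rwc = -0.5, leaf_wc = -1.0, lma = 0.3, pro = 1.5, abvgrd = -0.8,
    blwgrd = 0.4, ttlmass = -0.6, rmr = 0.5, delta13c = 0.4, leafc = 0.3,
    leafn = -0.4, cn = 0.8
  )
}

#' Paired W/D trait table with planted percent changes
#'
#' Emulates the drought experiment summary: per ecotype, the dry-treatment
#' trait value is the watered value scaled by `1 + effect`, plus noise.
#'
#' @param effects Named numeric of per-trait fractional changes (`0.33`
#'   plants a +33 percent drought effect).
#' @param n_ecotypes Number of ecotypes.
#' @param baseline Watered-treatment trait mean.
#' @param between_sd SD of ecotype-level baseline variation.
#' @param noise_sd SD of residual noise added to each cell.
#' @param seed Integer seed.
#' @return Wide trait tibble (`ecotype`, `treatment`, traits).
#' @export
gen_trait_change_table <- function(effects, n_ecotypes = 32L, baseline = 100,
                                   between_sd = 5, noise_sd = 2, seed = 1L) {
  stopifnot(!is.null(names(effects)))
  withr::with_seed(seed, {
    eco <- sprintf("eco%02d", seq_len(n_ecotypes))
    base <- baseline + stats::rnorm(n_ecotypes, sd = between_sd)
    rows <- tidyr::expand_grid(ecotype = eco, treatment = c("W", "D"))
    for (tr in names(effects)) {
      w <- base[match(rows$ecotype, eco)]
      rows[[tr]] <- ifelse(rows$treatment == "D", w * (1 + effects[[tr]]), w) +
        stats::rnorm(nrow(rows), sd = noise_sd)
    }
    rows
  })
}

#' Random tree with a lambda-structured tip trait
#'
#' Topology from a Yule (pure-birth) process, branch lengths redrawn iid
#' Exp(1); the trait is multivariate normal with covariance equal to the
#' shared-path-length matrix whose off-diagonals are scaled by
#' `lambda_true` (1 = Brownian motion, 0 = independent tips).
#'
#' @param n_tips Number of tips (at least 4).
#' @param lambda_true Pagel lambda used for simulation, in `[0, 1]`.
#' @param sigma2 Brownian rate.
#' @param seed Integer seed.
#' @return A list: `tree` (ape `phylo`), `trait` (named numeric) and
#'   `lambda_true`.
#' @export
gen_tree_with_trait <- function(n_tips, lambda_true = 1, sigma2 = 1, seed = 1L) {
  if (lambda_true < 0 || lambda_true > 1) {
    stop("lambda_true must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_tips >= 4L)
  withr::with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1)
    C <- ape::vcv(tree)
    Cl <- lambda_transform(C, lambda_true)
    trait <- as.numeric(MASS::mvrnorm(1, mu = rep(0, n_tips), Sigma = sigma2 * Cl))
    names(trait) <- rownames(C)
  })
  list(tree = tree, trait = trait, lambda_true = lambda_true)
}

#' Synthetic climate table driven by one latent gradient
#'
#' Nineteen worldclim-style variables (bio1-bio11 temperature, bio12-bio19
#' precipitation) are linear in a latent "coldness" gradient: temperature
#' variables decrease with it, precipitation variables increase.  With
#' `noise_sd = 0` the table is exactly rank one and the first principal
#' component carries all the variance.
#'
#' @param n_ecotypes Number of ecotypes.
#' @param noise_sd SD of independent noise added to each standardized cell.
#' @param seed Integer seed.
#' @return A list: `climate` (tibble `ecotype` + 19 variables) and `truth`
#'   (tibble `ecotype`, `gradient`, `pc1_ideal`, `class` using the +/-2.5
#'   score cutoffs).
#' @export
gen_climate_table <- function(n_ecotypes = 54L, noise_sd = 0.1, seed = 1L) {
  withr::with_seed(seed, {
    eco <- sprintf("eco%02d", seq_len(n_ecotypes))
    g <- stats::rnorm(n_ecotypes)
    vars <- paste0("bio", 1:19)
    signs <- c(rep(-1, 11), rep(1, 8)) # temperature down, precipitation up with coldness
    mat <- sapply(seq_along(vars), function(j) {
      signs[j] * g + stats::rnorm(n_ecotypes, sd = noise_sd)
    })
    colnames(mat) <- vars
  })
  z <- as.numeric(scale(g))
  pc1_ideal <- sqrt(length(vars)) * z
  truth <- tibble::tibble(
    ecotype = eco, gradient = g, pc1_ideal = pc1_ideal,
    class = dplyr::case_when(
      pc1_ideal > 2.5 ~ "cold",
      pc1_ideal < -2.5 ~ "warm",
      TRUE ~ "mesic"
    )
  )
  list(
    climate = dplyr::bind_cols(tibble::tibble(ecotype = eco), tibble::as_tibble(mat)),
    truth = truth
  )
}
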