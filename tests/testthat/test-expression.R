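small_design <- function(n_eco = 2, n_rep = 4) {
  gen_expression_matrix(c(g = 0), 10, 0, n_eco, n_rep, seed = 1)$design
}

test_that("identical groups give p = 1; full separation gives the exact 2/70", {
  des <- small_design(1, 4) # 4 W + 4 D samples in one ecotype
  tpm_same <- tibble::tibble(gene = "g1", !!!stats::setNames(as.list(rep(5, 8)), des$sample))
  res <- wilcoxon_de(tpm_same, des)
  expect_equal(res$raw_p, 1)
  vals <- ifelse(des$water == "W", 1:4, 101:104)[order(des$sample)]
  tpm_sep <- tibble::tibble(
    gene = "g1",
    !!!stats::setNames(as.list(ifelse(des$water == "W", c(1, 2, 3, 4), c(101, 102, 103, 104))), des$sample)
  )
  res2 <- wilcoxon_de(tpm_sep, des)
  expect_equal(res2$raw_p, 2 / 70, tolerance = 1e-12)
})

test_that("exact Wilcoxon agrees with full permutation enumeration", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      nx <- sample(3:6, 1)
      ny <- sample(3:6, 1)
      x <- sample(1000, nx) / 7 # distinct values, no ties
      y <- sample(2000, ny) / 7 + 0.01
    })
    des <- tibble::tibble(
      sample = paste0("s", seq_len(nx + ny)),
      ecotype = "e1",
      water = c(rep("W", nx), rep("D", ny)),
      temperature = "C",
      replicate = c(seq_len(nx), seq_len(ny))
    )
    tpm <- tibble::tibble(
      gene = "g1", !!!stats::setNames(as.list(c(x, y)), des$sample)
    )
    res <- wilcoxon_de(tpm, des)
    expect_equal(res$raw_p, enumerate_wilcox_p(x, y), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone and matches the step-up formula", {
  th <- c(a = 1, b = 0.6, c = 0.2, d = 0, e = 0, f = 0)
  ex <- gen_expression_matrix(th, 50, 0.3, 6, 4, seed = 3)
  res <- wilcoxon_de(ex$tpm, ex$design)
  expect_true(all(res$bh_adjusted_p >= res$raw_p))
  o <- order(res$raw_p)
  expect_true(all(diff(res$bh_adjusted_p[o]) >= -1e-12))
  m <- nrow(res)
  manual <- rev(cummin(rev(res$raw_p[o] * m / seq_len(m))))
  expect_equal(res$bh_adjusted_p[o], pmin(1, manual))
})

test_that("planted effects are significant and decoys are not", {
  th <- c(up1 = 1.5, up2 = 2.0, null1 = 0, null2 = 0, null3 = 0)
  ex <- gen_expression_matrix(th, 100, 0.2, 12, 4, seed = 5)
  res <- wilcoxon_de(ex$tpm, ex$design)
  sig <- res$gene[res$bh_adjusted_p < 0.05]
  expect_setequal(sig, c("up1", "up2"))
  # direction: D has higher values, first group of W-D is W
  expect_true(all(res$direction[res$gene %in% c("up1", "up2")] == -1))
})

test_that("permuting the W/D labels destroys planted significance", {
  th <- c(up = 1.5, null = 0)
  ex <- gen_expression_matrix(th, 100, 0.2, 8, 4, seed = 6)
  des_perm <- ex$design
  des_perm$water <- withr::with_seed(11, sample(des_perm$water))
  res <- wilcoxon_de(ex$tpm, des_perm)
  expect_true(all(res$bh_adjusted_p > 0.05))
})

test_that("percent change recovers trivial and planted effects", {
  ex <- gen_expression_matrix(c(g = 1), 40, 0, 4, 3, seed = 1)
  expect_equal(percent_change(ex$tpm, ex$design)$percent_change, 100)
  ex0 <- gen_expression_matrix(c(g = 0), 40, 0, 4, 3, seed = 1)
  expect_equal(percent_change(ex0$tpm, ex0$design)$percent_change, 0)
  per_eco <- percent_change(ex$tpm, ex$design, by_ecotype = TRUE)
  expect_equal(nrow(per_eco), 4L)
  expect_true(all(per_eco$percent_change == 100))
})

test_that("Kruskal-Wallis H matches manual rank arithmetic on a toy table", {
  vals <- c(1.1, 5.2, 3.3, 9.4, 7.5, 2.6, 8.7, 4.8, 6.9)
  eco <- rep(c("e1", "e2", "e3"), each = 3)
  des <- tibble::tibble(
    sample = paste0("s", 1:9), ecotype = eco, water = "W",
    temperature = "C", replicate = rep(1:3, 3)
  )
  tpm <- tibble::tibble(gene = "g1", !!!stats::setNames(as.list(vals), des$sample))
  out <- kruskal_tukey(tpm, des)
  expect_equal(out$omnibus$statistic, manual_kruskal_h(vals, eco), tolerance = 1e-10)
  expect_equal(out$omnibus$df, 2)
})

test_that("a strongly shifted ecotype receives its own letter", {
  withr::with_seed(21, {
    base <- rnorm(12, 10, 1)
  })
  vals <- base + rep(c(0, 0, 30), each = 4) # e3 shifted by 30 SD
  des <- tibble::tibble(
    sample = paste0("s", 1:12), ecotype = rep(c("e1", "e2", "e3"), each = 4),
    water = "W", temperature = "C", replicate = rep(1:4, 3)
  )
  tpm <- tibble::tibble(gene = "g1", !!!stats::setNames(as.list(vals), des$sample))
  out <- kruskal_tukey(tpm, des)
  lt <- out$letters
  expect_false(lt$letters[lt$ecotype == "e3"] %in% lt$letters[lt$ecotype != "e3"])
  expect_equal(lt$letters[lt$ecotype == "e1"], lt$letters[lt$ecotype == "e2"])
  expect_error(
    kruskal_tukey(tpm, dplyr::mutate(des, ecotype = rep(c("e1", "e2"), 6))),
    "3"
  )
})

test_that("identically distributed groups share one letter", {
  vals <- rep(c(8, 9, 11, 12), 3) # every ecotype holds the same values
  des <- tibble::tibble(
    sample = paste0("s", 1:12), ecotype = rep(c("e1", "e2", "e3"), each = 4),
    water = "W", temperature = "C", replicate = rep(1:4, 3)
  )
  tpm <- tibble::tibble(gene = "g1", !!!stats::setNames(as.list(vals), des$sample))
  lt <- kruskal_tukey(tpm, des)$letters
  expect_equal(unique(lt$letters), "a")
})

test_that("gene correlation detects shared ecotype effects and self-correlation", {
  withr::with_seed(8, {
    eco_effect <- rnorm(20, 0, 1)
    g1 <- 50 * exp(eco_effect + rnorm(20, 0, 0.1))
    g2 <- 30 * exp(eco_effect + rnorm(20, 0, 0.1))
    g3 <- 40 * exp(rnorm(20, 0, 0.5))
  })
  des <- tibble::tibble(
    sample = paste0("e", 1:20, "_D"), ecotype = paste0("e", 1:20),
    water = "D", temperature = "C", replicate = 1
  )
  tpm <- dplyr::bind_rows(
    tibble::tibble(gene = "g1", !!!stats::setNames(as.list(g1), des$sample)),
    tibble::tibble(gene = "g1b", !!!stats::setNames(as.list(g1), des$sample)),
    tibble::tibble(gene = "g2", !!!stats::setNames(as.list(g2), des$sample)),
    tibble::tibble(gene = "g3", !!!stats::setNames(as.list(g3), des$sample))
  )
  res <- gene_correlation(tpm, des, condition = "D")
  self <- res[res$gene_a == "g1" & res$gene_b == "g1b", ]
  expect_equal(self$r, 1, tolerance = 1e-12)
  shared <- res[res$gene_a == "g1" & res$gene_b == "g2", ]
  expect_gt(shared$r, 0.8)
  expect_lt(shared$p_value, 0.001)
})

test_that("explicit cell contrasts split on water and temperature", {
  th <- c(g = 0.5)
  ex <- gen_expression_matrix(th, 50, 0.1, 6, 4, seed = 12)
  res <- wilcoxon_de(ex$tpm, ex$design, contrasts = c("CW-HW", "CD-HD"))
  expect_setequal(unique(res$contrast), c("CW-HW", "CD-HD"))
  # drought effect is temperature-independent: both contrasts null
  expect_true(all(res$bh_adjusted_p > 0.05))
})
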