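test_that("promoter windows follow the TSS window definition", {
  contig <- paste(rep("ACGT", 500), collapse = "") # 2000 bp
  w <- extract_promoter(contig, tss = 1000, strand = "+", gene_id = "g1")
  expect_equal(nchar(w$sequence), 700L)
  expect_equal(w$window_start, -500L)
  expect_identical(w$sequence, substr(contig, 501, 1200))
  expect_false(w$truncated)
})

test_that("minus-strand windows are the reverse complement of the mirrored window", {
  set.seed(5)
  contig <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  minus <- extract_promoter(contig, tss = 1000, strand = "-", gene_id = "g1")
  mirrored <- substr(contig, 1000 - 200 + 2, 1000 + 500 + 1) # [tss-199, tss+500] 1-based
  expect_equal(minus$sequence, revcomp_chr(mirrored))
  expect_equal(nchar(minus$sequence), 700L)
  expect_equal(minus$window_start, -500L)
})

test_that("edge windows are truncated with a warning; bad TSS errors", {
  contig <- paste(rep("ACGT", 200), collapse = "")
  expect_warning(w <- extract_promoter(contig, tss = 100, strand = "+"), "truncated")
  expect_equal(nchar(w$sequence), 300L)
  expect_equal(w$window_start, -100L)
  expect_error(extract_promoter(contig, tss = 5000, strand = "+"), "outside")
})

test_that("the consensus scores the maximal possible log-odds", {
  pwm <- example_pwm()
  cons <- pwm_consensus(pwm)
  hits <- scan_pwm(stats::setNames(cons, "w"), pwm, threshold = 0)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  max_score <- sum(log2(apply(pwm$matrix, 2, max) / 0.25))
  expect_equal(fwd$score, max_score, tolerance = 1e-10)
})

test_that("scanning matches the brute-force per-offset oracle on background", {
  pwm <- example_pwm()
  set.seed(42)
  bgseq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  for (th in c(2, 6, 9)) {
    got <- scan_pwm(stats::setNames(bgseq, "bg"), pwm, threshold = th)
    want_f <- oracle_pwm_scan(bgseq, pwm$matrix, pwm$background, th)
    got_f <- got[got$strand == "+", ]
    expect_equal(got_f$position, want_f$position, info = paste("threshold", th))
    expect_equal(got_f$score, want_f$score, tolerance = 1e-10)
    # minus strand via the oracle on the reverse complement
    rc <- revcomp_chr(bgseq)
    want_r <- oracle_pwm_scan(rc, pwm$matrix, pwm$background, th)
    got_r <- got[got$strand == "-", ]
    expect_equal(sort(got_r$position), sort(nchar(bgseq) - pwm$width - want_r$position))
  }
})

test_that("planted sites are recovered exactly at mutation zero", {
  pwm <- example_pwm()
  ps <- gen_promoter_set(pwm, n_prom = 3, sites_per_prom = 1, length = 700, seed = 2)
  windows <- tibble::tibble(
    gene_id = names(ps$sequences), sequence = unname(ps$sequences),
    strand = "+", window_start = 0L, truncated = FALSE
  )
  hits <- scan_pwm(windows, pwm, threshold = 9)
  truth <- ps$truth
  for (i in seq_len(nrow(truth))) {
    match <- hits$gene_id == truth$prom_id[i] &
      hits$position == truth$position[i] &
      hits$strand == truth$strand[i]
    expect_equal(sum(match), 1L, info = truth$prom_id[i])
  }
  counts <- cre_site_counts(hits)
  expect_equal(counts$n_sites, rep(1L, 3L))
})

test_that("raising the threshold never adds hits", {
  pwm <- example_pwm(sharpness = 0.8)
  set.seed(9)
  seqs <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  lo <- scan_pwm(stats::setNames(seqs, "x"), pwm, threshold = 3)
  hi <- scan_pwm(stats::setNames(seqs, "x"), pwm, threshold = 6)
  expect_true(all(paste(hi$position, hi$strand) %in% paste(lo$position, lo$strand)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("strand consistency: scanning the reverse complement mirrors hits", {
  pwm <- example_pwm(sharpness = 0.85)
  set.seed(7)
  seqs <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  fwd <- scan_pwm(stats::setNames(seqs, "x"), pwm, threshold = 4)
  rc <- scan_pwm(stats::setNames(revcomp_chr(seqs), "x"), pwm, threshold = 4)
  # a + hit at p maps to a - hit at n - w - p on the reverse complement
  n <- nchar(seqs)
  mapped <- sort(n - pwm$width - fwd$position[fwd$strand == "+"])
  expect_equal(sort(rc$position[rc$strand == "-"]), mapped)
})

test_that("JASPAR-like PWM files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".pwm")
  writeLines(c(
    ">BES1 test-motif",
    "A [ 10  0  1  8 ]",
    "C [  0  1  9  0 ]",
    "G [  0  9  0  1 ]",
    "T [  0  0  0  1 ]"
  ), path)
  pwms <- read_jaspar(path)
  expect_named(pwms, "BES1")
  expect_equal(pwms$BES1$width, 4L)
  expect_equal(colSums(pwms$BES1$matrix), rep(1, 4), tolerance = 1e-12)
  expect_equal(pwm_consensus(pwms$BES1), "AGCA")
  expect_error(read_jaspar(withr::local_tempfile(lines = "no header")), "header")
})
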