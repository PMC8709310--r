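k_row <- function() dplyr::filter(dhn_consensus(), segment_type == "K")

test_that("consensus queries match themselves exactly", {
  cons <- dhn_consensus()
  for (i in which(!cons$is_run)) {
    h <- find_segment_hits(cons$query[i], cons[i, ])
    expect_equal(nrow(h), 1L)
    expect_equal(h$start, 0L)
    expect_equal(h$end, nchar(cons$query[i]))
    expect_equal(h$mismatches, 0L)
    expect_false(h$relaxed)
  }
})

test_that("a K window with five substitutions is rejected at the default tolerance", {
  k <- "EKKGIMDKIKEKLPG"
  mutated <- k
  for (i in 1:5) substr(mutated, i, i) <- "W" # W never occurs in the query
  # oracle: exhaustive Hamming count confirms 5 mismatches
  expect_equal(sum(strsplit(mutated, "")[[1]] != strsplit(k, "")[[1]]), 5L)
  h <- find_segment_hits(mutated, k_row())
  expect_false(any(!h$relaxed)) # not a standard K hit
  expect_true(all(h$mismatches[h$relaxed] >= 5L))
})

test_that("S-segments are maximal serine runs of five or more", {
  s_row <- dplyr::filter(dhn_consensus(), segment_type == "S")
  h <- find_segment_hits("AAASSSSSSAAA", s_row)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(3L, 9L))
  expect_equal(nrow(find_segment_hits("SSSS", s_row)), 0L) # run of 4: no hit
  h2 <- find_segment_hits("SSSSSAASSSSSSS", s_row)
  expect_equal(h2$start, c(0L, 7L))
  expect_equal(h2$end, c(5L, 14L))
})

test_that("hit set equals brute-force window enumeration on random sequences", {
  cons <- dhn_consensus()
  for (seed in 1:12) {
    seq <- random_peptide(sample(c(30, 120, 200), 1), seed)
    for (i in which(!cons$is_run)) {
      got <- find_segment_hits(seq, cons[i, ])
      want <- brute_force_hits(seq, cons$query[i], cons$max_mismatch[i],
        relaxed_max = cons$relaxed_max[i]
      )
      expect_equal(got$start, want$start, info = paste("seed", seed, cons$segment_type[i]))
      expect_equal(got$mismatches, want$mm)
    }
  }
})

test_that("raising the mismatch tolerance never removes a hit", {
  for (seed in 1:6) {
    sim <- gen_dehydrin_protein("Y3S\u03D5K2", 10, 0.15, seed)
    for (mm in 0:3) {
      lo <- scan_segments(sim$sequence, dhn_consensus(max_mismatch = mm))
      hi <- scan_segments(sim$sequence, dhn_consensus(max_mismatch = mm + 1L))
      strict_lo <- lo[!lo$relaxed, ]
      strict_hi <- hi[!hi$relaxed, ]
      for (r in seq_len(nrow(strict_lo))) {
        expect_true(any(
          strict_hi$start == strict_lo$start[r] &
            strict_hi$segment_type == strict_lo$segment_type[r]
        ))
      }
    }
  }
})

test_that("the dehydrin rule distinguishes strict and extended modes", {
  k_hit <- tibble::tibble(
    segment_type = "K", start = 0L, end = 15L, mismatches = 0L, relaxed = FALSE
  )
  expect_true(is_dehydrin(k_hit, "strict"))
  expect_false(is_dehydrin(k_hit[0, ], "strict"))
  expect_false(is_dehydrin(k_hit[0, ], "extended"))
  hird11 <- tibble::tibble(
    segment_type = c("NLS", "K", "S"),
    start = c(0L, 20L, 45L), end = c(11L, 35L, 50L),
    mismatches = c(0L, 6L, 0L), relaxed = c(FALSE, TRUE, FALSE)
  )
  expect_false(is_dehydrin(hird11, "strict"))
  expect_true(is_dehydrin(hird11, "extended"))
  # a lone relaxed K* without companion S/NLS is not enough
  lone_kstar <- hird11[2, ]
  expect_false(is_dehydrin(lone_kstar, "extended"))
})

test_that("architecture strings collapse multiplicities and render K*/NLS", {
  mk <- function(types, relaxed = rep(FALSE, length(types))) {
    w <- 10L
    tibble::tibble(
      segment_type = types,
      start = seq(0L, by = w + 2L, length.out = length(types)),
      end = seq(0L, by = w + 2L, length.out = length(types)) + w,
      mismatches = 0L, relaxed = relaxed
    )
  }
  expect_equal(
    assign_architecture(mk(c("Y", "Y", "Y", "S", "\u03D5", "K", "K"))),
    "Y3S\u03D5K2"
  )
  expect_equal(assign_architecture(mk("K")), "K")
  expect_equal(
    assign_architecture(mk(c("NLS", "K", "S"), relaxed = c(FALSE, TRUE, FALSE))),
    "NLS-K*S"
  )
  expect_error(
    assign_architecture(tibble::tibble(
      segment_type = c("K", "Y"), start = c(0L, 5L), end = c(15L, 12L),
      mismatches = 0L, relaxed = FALSE
    )),
    "overlap"
  )
})

test_that("zero-mutation generator output scans back to the planted truth", {
  layouts <- dhn_reference_layouts()
  for (i in seq_len(nrow(layouts))) {
    sim <- gen_dehydrin_protein(layouts$architecture[i], 10, 0, seed = 40 + i)
    hits <- scan_segments(sim$sequence)
    expect_equal(hits$start, sim$truth$segments$start, info = layouts$gene[i])
    expect_equal(hits$end, sim$truth$segments$end)
    tok <- ifelse(hits$segment_type == "K" & hits$relaxed, "K*", hits$segment_type)
    expect_equal(tok, sim$truth$segments$segment_type)
    expect_equal(assign_architecture(hits), layouts$architecture[i])
  }
})

test_that("panel annotation is record-order invariant and rejects duplicate ids", {
  panel <- gen_reference_panel(seed = 3)
  ann1 <- annotate_panel(panel$sequences, mode = "extended")
  shuffled <- panel$sequences[rev(seq_along(panel$sequences))]
  ann2 <- annotate_panel(shuffled, mode = "extended")
  expect_equal(
    dplyr::arrange(ann1[1:3], protein_id),
    dplyr::arrange(ann2[1:3], protein_id)
  )
  dup <- panel$sequences[c(1, 1)]
  expect_error(annotate_panel(dup), "duplicate")
})

test_that("empty and short sequences are handled per contract", {
  expect_error(find_segment_hits("", k_row()), "non-empty")
  expect_equal(nrow(find_segment_hits("EKK", k_row())), 0L)
  expect_error(scan_segments("EKB"), "non-amino-acid")
})
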