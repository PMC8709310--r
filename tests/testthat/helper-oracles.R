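# Independent brute-force oracles used across tests.  These deliberately
# re-derive results with the most naive algebra available so they stay
# independent of the package's implementation paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(n, seed) {
  withr::with_seed(seed, paste(sample(AA20, n, replace = TRUE), collapse = ""))
}

# naive per-window Hamming mismatch scan + the same greedy rule, written
# with an explicit double loop
brute_force_hits <- function(seq, query, max_mm, relaxed_max = NA) {
  s <- strsplit(seq, "")[[1]]
  q <- strsplit(query, "")[[1]]
  m <- length(q)
  cand <- data.frame(start = integer(0), mm = integer(0))
  if (length(s) >= m) {
    for (i in seq_len(length(s) - m + 1L)) {
      win <- s[i:(i + m - 1L)]
      mm <- sum(win != q | win == "X")
      cap <- if (is.na(relaxed_max)) max_mm else relaxed_max
      if (mm <= cap) cand <- rbind(cand, data.frame(start = i - 1L, mm = mm))
    }
  }
  cand <- cand[order(cand$mm, cand$start), ]
  taken <- data.frame(s = integer(0), e = integer(0))
  keep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    st <- cand$start[i]
    en <- st + m
    if (!any(st < taken$e & en > taken$s)) {
      keep[i] <- TRUE
      taken <- rbind(taken, data.frame(s = st, e = en))
    }
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

# two-sided exact rank-sum p by full enumeration of group assignments
enumerate_wilcox_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(all_v), n)
  u_of <- function(sel) {
    xs <- all_v[sel]
    ys <- all_v[-sel]
    sum(outer(xs, ys, ">")) # Mann-Whitney U
  }
  u_obs <- u_of(seq_len(n))
  us <- apply(idx, 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Kruskal-Wallis H from the definition (no tie correction needed when
# values are distinct)
manual_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  h
}

# dense-algebra K statistic written independently (explicit GLS pieces)
oracle_blomberg_k <- function(tree, trait) {
  C <- ape::vcv(tree)
  y <- trait[rownames(C)]
  n <- length(y)
  V <- solve(C)
  one <- matrix(1, n, 1)
  a <- as.numeric((t(one) %*% V %*% y) / (t(one) %*% V %*% one))
  d <- matrix(y - a, ncol = 1)
  ratio <- (as.numeric(t(d) %*% d) / (n - 1)) /
    (as.numeric(t(d) %*% V %*% d) / (n - 1))
  expect <- (sum(diag(C)) - n / as.numeric(t(one) %*% V %*% one)) / (n - 1)
  ratio / expect
}

# naive PWM scan: explicit per-offset log2-odds sum over one strand
oracle_pwm_scan <- function(seq, prob, bg, threshold) {
  s <- strsplit(seq, "")[[1]]
  w <- ncol(prob)
  hits <- integer(0)
  scores <- numeric(0)
  for (i in seq_len(length(s) - w + 1L)) {
    sc <- 0
    for (j in seq_len(w)) {
      sc <- sc + log2(prob[s[i + j - 1L], j] / bg[[s[i + j - 1L]]])
    }
    if (sc >= threshold) {
      hits <- c(hits, i - 1L)
      scores <- c(scores, sc)
    }
  }
  data.frame(position = hits, score = scores)
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
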