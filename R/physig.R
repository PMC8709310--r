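# Phylogenetic-signal statistics for continuous tip traits.

lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

check_tip_match <- function(tree, trait) {
  if (is.null(names(trait))) {
    stop("trait vector must be named by tip label", call. = FALSE)
  }
  off_tree <- setdiff(names(trait), tree$tip.label)
  off_trait <- setdiff(tree$tip.label, names(trait))
  if (length(off_tree) > 0 || length(off_trait) > 0) {
    stop(
      "tip labels and trait names do not match; offenders: ",
      paste(c(off_tree, off_trait), collapse = ", "),
      call. = FALSE
    )
  }
  trait[tree$tip.label]
}

# GLS ancestral mean and the two mean squared errors of the K statistic
k_ratio <- function(y, Cinv, n) {
  one <- rep(1, n)
  denom <- sum(Cinv %*% one)
  a <- sum(Cinv %*% y) / denom
  d <- y - a
  mse0 <- sum(d^2) / (n - 1)
  mse <- as.numeric(t(d) %*% Cinv %*% d) / (n - 1)
  mse0 / mse
}

#' Blomberg's K for a continuous trait on a tree
#'
#' K compares the observed ratio of the mean squared error of the trait
#' around its phylogenetic (GLS) mean to the phylogenetically corrected
#' mean squared error, against the expectation of that ratio under
#' Brownian motion on the same tree; K near 1 means Brownian-consistent
#' signal, K near 0 means none.  Significance comes from tip-label
#' permutations of the observed ratio (add-one smoothed).
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param trait Named numeric tip trait; names must match tip labels.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @return A `phylo_signal` object: `statistic = "K"`, `estimate`,
#'   `p_value`, `n_tips`, `method`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999L, seed = 1L) {
  y <- check_tip_match(tree, trait)
  n <- length(y)
  C <- ape::vcv(tree)
  Cinv <- solve(C)
  one <- rep(1, n)
  expected <- (sum(diag(C)) - n / sum(Cinv %*% one)) / (n - 1)
  obs <- k_ratio(y, Cinv, n)
  k <- obs / expected
  perm_ratios <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      k_ratio(sample(y), Cinv, n)
    }, numeric(1))
  })
  p <- (1 + sum(perm_ratios >= obs)) / (n_perm + 1)
  new_phylo_signal("K", k, p, n, sprintf("%d tip-label permutations", n_perm))
}

lambda_loglik <- function(lambda, y, C) {
  n <- length(y)
  Cl <- lambda_transform(C, lambda)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) {
    return(-Inf)
  }
  Clinv <- chol2inv(ch)
  one <- rep(1, n)
  a <- sum(Clinv %*% y) / sum(Clinv %*% one)
  d <- y - a
  s2 <- as.numeric(t(d) %*% Clinv %*% d) / n
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

lambda_upper_bound <- function(C, cap = 1.1) {
  ok <- function(l) {
    !is.null(tryCatch(chol(lambda_transform(C, l)), error = function(e) NULL))
  }
  if (ok(cap)) {
    return(cap)
  }
  lo <- 0
  hi <- cap
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (ok(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Pagel's lambda for a continuous trait on a tree
#'
#' Maximizes the multivariate-normal log-likelihood of the trait over the
#' lambda transformation (off-diagonal covariances scaled by lambda) with
#' the Brownian rate profiled out, by bounded scalar optimization.  The
#' upper bound is the largest lambda keeping the covariance positive
#' definite, capped at 1.1.  Significance is a likelihood-ratio test of
#' the estimate against lambda = 0 (chi-squared, 1 df).
#'
#' @inheritParams blomberg_k
#' @param tol Optimizer tolerance on lambda.
#' @return A `phylo_signal` object: `statistic = "lambda"`, `estimate`,
#'   `p_value`, `n_tips`, `method`, plus `logL` at the optimum and `logL0`
#'   at lambda 0.
#' @export
pagel_lambda <- function(tree, trait, tol = 1e-8) {
  y <- check_tip_match(tree, trait)
  C <- ape::vcv(tree)
  if (is.null(tryCatch(chol(lambda_transform(C, 0)), error = function(e) NULL))) {
    stop("covariance is not positive definite at lambda = 0", call. = FALSE)
  }
  upper <- lambda_upper_bound(C)
  opt <- stats::optimize(lambda_loglik,
    interval = c(0, upper), y = y, C = C,
    maximum = TRUE, tol = tol
  )
  # the optimum may sit on a boundary that optimize() never samples exactly
  cand <- c(0, opt$maximum, upper)
  ll <- vapply(cand, lambda_loglik, numeric(1), y = y, C = C)
  best <- which.max(ll)
  ll0 <- ll[1]
  lrt <- max(0, 2 * (ll[best] - ll0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  out <- new_phylo_signal(
    "lambda", cand[best], p, length(y),
    "likelihood-ratio test against lambda = 0"
  )
  out$logL <- ll[best]
  out$logL0 <- ll0
  out
}

new_phylo_signal <- function(statistic, estimate, p_value, n_tips, method) {
  structure(
    list(
      statistic = statistic, estimate = estimate, p_value = p_value,
      n_tips = n_tips, method = method
    ),
    class = "phylo_signal"
  )
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(
    "Phylogenetic signal:", x$statistic, "=", format(x$estimate, digits = 4),
    "(p =", format(x$p_value, digits = 3), ",", x$n_tips, "tips)\n"
  )
  cat("Method:", x$method, "\n")
  invisible(x)
}

#' Tidy a phylogenetic-signal fit
#'
#' @param x A `phylo_signal` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `estimate`, `p_value`, `n_tips`.
#' @method tidy phylo_signal
#' @export
tidy.phylo_signal <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, estimate = x$estimate,
    p_value = x$p_value, n_tips = x$n_tips
  )
}

#' Glance at a phylogenetic-signal fit
#'
#' @inheritParams tidy.phylo_signal
#' @return One-row tibble with the estimate, p-value, tip count, method and
#'   (for lambda) the log-likelihoods.
#' @method glance phylo_signal
#' @export
glance.phylo_signal <- function(x, ...) {
  out <- tidy(x)
  out$method <- x$method
  if (!is.null(x$logL)) {
    out$logL <- x$logL
    out$logL0 <- x$logL0
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
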