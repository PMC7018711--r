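#' Pairwise PERMANOVA between time bins
#'
#' One-factor permutational multivariate ANOVA on the distance submatrix of
#' each bin pair. The pseudo-F statistic is built from sums of squared
#' distances: `SS_total = sum(d^2)/n` over all pairs of the two bins pooled,
#' `SS_within` the analogous quantity per bin, `F = (SS_between/(g-1)) /
#' (SS_within/(n-g))`. Significance comes from permuting bin labels: all
#' distinct assignments are enumerated when there are at most `max_exact`
#' of them, otherwise `n_perm` Monte-Carlo permutations are drawn and the
#' observed assignment is counted among them. Taxa present in both bins of
#' a pair carry no information on separation and are excluded from that
#' comparison.
#'
#' @param dist a `morph_dist` (or plain distance matrix with dimnames).
#' @param membership named list of taxon vectors, one per bin.
#' @param n_perm Monte-Carlo permutations (default 999; the observed
#'   labelling is always included, so p >= 1/(n_perm + 1)).
#' @param seed integer seed.
#' @param max_exact enumerate exhaustively when the number of distinct
#'   assignments does not exceed this.
#' @return data frame (class `pairwise_tests`): `bin1`, `bin2`, `statistic`
#'   (pseudo-F), `p`, `p_adj` (Benjamini-Hochberg), `test`, `n_perm`
#'   (permutations used; `NA` marks exhaustive enumeration), `n1`, `n2`.
#'   Pairs where a bin has fewer than 2 usable taxa are skipped with a
#'   warning.
#' @export
pairwise_permanova <- function(dist, membership, n_perm = 999, seed = NULL,
                               max_exact = 10000) {
  D <- if (inherits(dist, "morph_dist")) dist$D else as.matrix(dist)
  if (!is.null(seed)) set.seed(seed)
  bins <- names(membership)
  rows <- list()
  for (i in seq_along(bins)) for (j in seq_along(bins)) {
    if (j <= i) next
    g1 <- intersect(membership[[i]], rownames(D))
    g2 <- intersect(membership[[j]], rownames(D))
    shared <- intersect(g1, g2)
    g1 <- setdiff(g1, shared); g2 <- setdiff(g2, shared)
    if (length(g1) < 2 || length(g2) < 2) {
      warning(sprintf("skipping %s vs %s: a bin has < 2 usable taxa",
                      bins[i], bins[j]))
      next
    }
    res <- permanova_f_test(D[c(g1, g2), c(g1, g2)],
                            rep(c(1L, 2L), c(length(g1), length(g2))),
                            n_perm = n_perm, max_exact = max_exact)
    rows[[length(rows) + 1]] <- data.frame(
      bin1 = bins[i], bin2 = bins[j], statistic = res$statistic,
      p = res$p, test = "PERMANOVA", n_perm = res$n_perm,
      n1 = length(g1), n2 = length(g2), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no bin pair had enough taxa")
  out$p_adj <- adjust_fdr(out$p)
  out <- out[, c("bin1", "bin2", "statistic", "p", "p_adj", "test",
                 "n_perm", "n1", "n2")]
  class(out) <- c("pairwise_tests", "data.frame")
  out
}

#' One-factor PERMANOVA on a distance matrix
#'
#' The permutation engine behind [pairwise_permanova()], usable directly.
#'
#' @param D symmetric distance matrix.
#' @param groups integer/factor vector of group labels, one per row of `D`.
#' @param n_perm Monte-Carlo permutations.
#' @param max_exact exhaustive-enumeration threshold (two-group designs).
#' @return list: `statistic` (pseudo-F), `p`, `n_perm` (`NA` if exhaustive).
#' @export
permanova_f_test <- function(D, groups, n_perm = 999, max_exact = 10000) {
  D <- as.matrix(D)
  groups <- as.integer(factor(groups))
  n <- length(groups)
  stopifnot(nrow(D) == n)
  A <- D^2
  f_obs <- .pseudo_f(A, groups)
  sizes <- tabulate(groups)
  g <- length(sizes)
  n_arrange <- if (g == 2) choose(n, sizes[1]) else Inf
  if (n_arrange <= max_exact) {
    combos <- utils::combn(n, sizes[1])
    fs <- apply(combos, 2, function(idx) {
      z <- rep(2L, n); z[idx] <- 1L
      .pseudo_f(A, z)
    })
    p <- mean(fs >= f_obs - 1e-12)
    return(list(statistic = f_obs, p = p, n_perm = NA_integer_))
  }
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    z <- groups[sample(n)]
    if (.pseudo_f(A, z) >= f_obs - 1e-12) exceed <- exceed + 1L
  }
  list(statistic = f_obs, p = (1 + exceed) / (n_perm + 1),
       n_perm = n_perm)
}

.pseudo_f <- function(A, groups) {
  n <- nrow(A)
  ss_total <- sum(A[upper.tri(A)]) / n
  ss_within <- 0
  g <- max(groups)
  for (k in seq_len(g)) {
    idx <- groups == k
    Ak <- A[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(Ak[upper.tri(Ak)]) / sum(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

#' Pairwise Welch t-tests of disparity between bins
#'
#' Compares per-bin disparity value distributions with two-sided Welch
#' two-sample t-tests. The sample unit is selectable: `"pairs"` uses the
#' upper-triangle pairwise distances within each bin (default);
#' `"bootstrap"` uses per-replicate disparity values supplied as a named
#' list of numeric vectors in `membership` instead of taxa.
#'
#' @param dist a `morph_dist` (ignored when `unit = "bootstrap"`).
#' @param membership named list: taxon vectors per bin (`unit = "pairs"`)
#'   or numeric replicate vectors per bin (`unit = "bootstrap"`).
#' @param unit sample unit, `"pairs"` or `"bootstrap"`.
#' @return data frame (class `pairwise_tests`): `bin1`, `bin2`, `statistic`
#'   (t), `p`, `p_adj`, `test`, `df`, `n1`, `n2`.
#' @export
pairwise_disparity_ttests <- function(dist, membership,
                                      unit = c("pairs", "bootstrap")) {
  unit <- match.arg(unit)
  vals <- if (unit == "pairs") {
    D <- if (inherits(dist, "morph_dist")) dist$D else as.matrix(dist)
    lapply(membership, function(members) {
      idx <- match(intersect(members, rownames(D)), rownames(D))
      d <- D[idx, idx, drop = FALSE]
      v <- d[upper.tri(d)]
      v[!is.na(v)]
    })
  } else {
    lapply(membership, as.numeric)
  }
  bins <- names(membership)
  rows <- list()
  for (i in seq_along(bins)) for (j in seq_along(bins)) {
    if (j <= i) next
    x <- vals[[i]]; y <- vals[[j]]
    if (length(x) < 2 || length(y) < 2) next
    res <- .welch_safe(x, y)
    rows[[length(rows) + 1]] <- data.frame(
      bin1 = bins[i], bin2 = bins[j], statistic = res$t, p = res$p,
      test = "Welch t", df = res$df, n1 = length(x), n2 = length(y),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no bin pair had enough values")
  out$p_adj <- adjust_fdr(out$p)
  out <- out[, c("bin1", "bin2", "statistic", "p", "p_adj", "test",
                 "df", "n1", "n2")]
  class(out) <- c("pairwise_tests", "data.frame")
  out
}

.welch_safe <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR control: with `m` p-values sorted ascending,
#' `q_i = min_{j >= i} p_j * m / j`, capped at 1, returned in input order.
#' Delegates to [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
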