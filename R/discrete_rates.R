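#' Marginal ancestral state reconstruction under the Mk model
#'
#' For every character, fits a symmetric equal-rates Mk model (transition
#' rate between any two specific states estimated by maximum likelihood via
#' Felsenstein pruning) and returns marginal ancestral state probabilities
#' at every internal node from a two-pass (inside/outside) algorithm with a
#' flat root prior — equivalent to re-rooting the tree at each node.
#' Missing tip states enter as uninformative partial likelihoods;
#' polymorphic tips as an indicator over their state set. Invariant
#' characters get probability 1 for the single observed state everywhere
#' without optimisation.
#'
#' @param matrix a [character_matrix()]; taxa must include all tree tips.
#' @param tree a [dated_tree()] (branch durations > 0).
#' @return object of class `asr_mk`: list with `prob` (list, one
#'   nodes-x-states probability matrix per character; rows named by node
#'   number, columns by state), `rates` (ML rate per character, my^-1),
#'   `states` (observed state values per character), `tree`.
#' @export
asr_mk <- function(matrix, tree) {
  stopifnot(inherits(matrix, "char_matrix"), inherits(tree, "dated_tree"))
  missing_tips <- setdiff(tree$tip.label, matrix$taxa)
  if (length(missing_tips))
    stop("tree tips absent from matrix: ",
         paste(missing_tips, collapse = ", "))
  if (any(tree$edge.length <= 0)) stop("branch durations must be positive")
  n_tip <- ape::Ntip(tree)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  taxon_row <- match(tree$tip.label, matrix$taxa)

  prob <- vector("list", matrix$n_char)
  rates <- numeric(matrix$n_char)
  state_sets <- vector("list", matrix$n_char)
  for (ch in seq_len(matrix$n_char)) {
    cells <- .cell_sets(matrix$states[taxon_row, ch])
    obs <- sort(unique(unlist(cells)))
    state_sets[[ch]] <- obs
    k <- length(obs)
    nodes <- (n_tip + 1L):(n_tip + tree$Nnode)
    if (k <= 1) {
      p <- matrix(1, tree$Nnode, max(k, 1))
      colnames(p) <- as.character(if (k) obs else NA)
      rownames(p) <- nodes
      prob[[ch]] <- p
      rates[ch] <- 0
      next
    }
    ## tip partial likelihoods over the observed state alphabet
    L <- matrix(1, n_tip + tree$Nnode, k)
    for (i in seq_len(n_tip)) {
      s <- cells[[i]]
      if (length(s)) L[i, ] <- as.numeric(obs %in% s)
    }
    ## bracket the ML rate on a log grid first: the likelihood flattens for
    ## large rates and a blind golden-section search can stall there
    f <- function(q) .mk_pruning_loglik(q, L, tree, post, k, n_tip)
    qgrid <- exp(seq(log(1e-6), log(20), length.out = 25))
    vals <- vapply(qgrid, f, 0)
    i <- which.max(vals)
    rate <- stats::optimize(f, interval = c(qgrid[max(1, i - 1)],
                                            qgrid[min(length(qgrid), i + 1)]),
                            maximum = TRUE, tol = 1e-7)$maximum
    rates[ch] <- rate
    p <- .mk_marginals(rate, L, tree, post, k, n_tip)
    colnames(p) <- as.character(obs)
    rownames(p) <- nodes
    prob[[ch]] <- p
  }
  structure(list(prob = prob, rates = rates, states = state_sets,
                 tree = tree),
            class = "asr_mk")
}

## equal-rates transition probabilities: P_same and P_other for duration t
.mk_trans <- function(q, t, k) {
  e <- exp(-k * q * t)
  list(same = 1 / k + (k - 1) / k * e, other = (1 - e) / k)
}

.mk_pruning_loglik <- function(q, L, tree, post, k, n_tip) {
  elen <- numeric(n_tip + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  logscale <- 0
  for (e in seq_len(nrow(post))) {
    chd <- post[e, 2]; par <- post[e, 1]
    tp <- .mk_trans(q, elen[chd], k)
    lc <- L[chd, ]
    L[par, ] <- L[par, ] * (tp$other * sum(lc) + (tp$same - tp$other) * lc)
    m <- max(L[par, ])
    if (m > 0 && m < 1e-200) { L[par, ] <- L[par, ] / m
                               logscale <- logscale + log(m) }
  }
  lik <- mean(L[n_tip + 1L, ])
  if (lik <= 0) return(-Inf)
  log(lik) + logscale
}

## two-pass marginal probabilities at internal nodes, flat root prior
.mk_marginals <- function(q, L, tree, post, k, n_tip) {
  n_all <- n_tip + tree$Nnode
  elen <- numeric(n_all)
  elen[tree$edge[, 2]] <- tree$edge.length
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])

  ## inside pass: L[v,] = P(data below v | state at v)
  Ld <- L
  for (e in seq_len(nrow(post))) {
    chd <- post[e, 2]; par <- post[e, 1]
    tp <- .mk_trans(q, elen[chd], k)
    lc <- Ld[chd, ]
    Ld[par, ] <- Ld[par, ] * (tp$other * sum(lc) + (tp$same - tp$other) * lc)
  }
  ## outside pass: U[v,] = P(data above v | state at v) * prior
  U <- matrix(0, n_all, k)
  root <- n_tip + 1L
  U[root, ] <- 1 / k
  pre <- rev(seq_len(nrow(post)))
  for (e in pre) {
    chd <- post[e, 2]; par <- post[e, 1]
    sibs <- setdiff(children[[as.character(par)]], chd)
    above <- U[par, ]
    for (s in sibs) {
      tp <- .mk_trans(q, elen[s], k)
      ls <- Ld[s, ]
      above <- above * (tp$other * sum(ls) + (tp$same - tp$other) * ls)
    }
    tp <- .mk_trans(q, elen[chd], k)
    ## transmit down the child's own branch (symmetric rates)
    U[chd, ] <- tp$other * sum(above) + (tp$same - tp$other) * above
  }
  marg <- Ld * U
  marg <- marg[(n_tip + 1L):n_all, , drop = FALSE]
  sw <- rowSums(marg)
  marg / ifelse(sw > 0, sw, 1)
}

#' Expected character changes per branch with time-bin apportionment
#'
#' For every branch, sums over the characters scorable on it the
#' probability that parent and child states differ, taking tips at their
#' observed states (polymorphic tips uniform over their set) and internal
#' nodes at their marginal reconstruction; parent and child distributions
#' are treated independently. A character is scorable on a branch iff both
#' ends carry information for it: a tip is coded directly, an internal node
#' is supported by at least one coded descendant tip. Opportunity is branch
#' duration times the number of scorable characters (character-my). Each
#' branch's changes and opportunity are split across time bins in
#' proportion to the fraction of its duration inside each bin.
#'
#' @param asr an [asr_mk()] result.
#' @param matrix the same [character_matrix()].
#' @param tree the same [dated_tree()].
#' @param bins optional [make_bins()] result for apportionment.
#' @return object of class `branch_changes`: list with `branches` (data
#'   frame: parent, child, changes, duration, n_scorable, opportunity) and,
#'   if `bins` given, `bins` (data frame: bin, changes, opportunity).
#' @export
branch_changes <- function(asr, matrix, tree, bins = NULL) {
  stopifnot(inherits(asr, "asr_mk"))
  n_tip <- ape::Ntip(tree)
  taxon_row <- match(tree$tip.label, matrix$taxa)
  n_edge <- nrow(tree$edge)
  durs <- tree$node.ages[tree$edge[, 1]] - tree$node.ages[tree$edge[, 2]]
  if (any(durs <= 0)) stop("zero-duration branch: dating invariant violated")

  ## coded support per node per character
  coded <- matrix(FALSE, n_tip + tree$Nnode, matrix$n_char)
  coded[seq_len(n_tip), ] <- matrix$states[taxon_row, ] != ""
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(post)))
    coded[post[e, 1], ] <- coded[post[e, 1], ] | coded[post[e, 2], ]

  changes <- numeric(n_edge); n_scor <- integer(n_edge)
  for (ch in seq_len(matrix$n_char)) {
    obs <- asr$states[[ch]]
    k <- length(obs)
    if (k <= 1) next  # invariant characters cannot change
    cells <- .cell_sets(matrix$states[taxon_row, ch])
    dist_at <- function(v) {
      if (v <= n_tip) {
        s <- cells[[v]]
        p <- as.numeric(obs %in% s)
        p / sum(p)
      } else {
        asr$prob[[ch]][as.character(v), ]
      }
    }
    scor <- coded[tree$edge[, 1], ch] & coded[tree$edge[, 2], ch]
    for (e in which(scor)) {
      pp <- dist_at(tree$edge[e, 1]); pc <- dist_at(tree$edge[e, 2])
      changes[e] <- changes[e] + (1 - sum(pp * pc))
      n_scor[e] <- n_scor[e] + 1L
    }
  }
  branches <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                         changes = changes, duration = durs,
                         n_scorable = n_scor,
                         opportunity = durs * n_scor)
  out <- list(branches = branches)
  if (!is.null(bins)) {
    apport <- matrix(0, n_edge, nrow(bins))
    old_e <- tree$node.ages[tree$edge[, 1]]
    young_e <- tree$node.ages[tree$edge[, 2]]
    for (b in seq_len(nrow(bins))) {
      ov <- pmax(0, pmin(old_e, bins$old[b]) - pmax(young_e, bins$young[b]))
      apport[, b] <- ov / durs
    }
    out$bins <- data.frame(
      bin = bins$label,
      changes = as.numeric(crossprod(apport, changes)),
      opportunity = as.numeric(crossprod(apport, branches$opportunity)))
  }
  class(out) <- "branch_changes"
  out
}

#' Poisson likelihood-ratio classification of per-bin rates
#'
#' For each time bin, compares a single-rate null (one Poisson rate
#' `lambda0 = total changes / total opportunity`) against an alternative
#' with separate rates for the bin and the rest of the tree (each at its
#' maximum-likelihood estimate changes/opportunity). The statistic
#' `LRT = 2 * (l1 - l0)` is referred to a chi-squared distribution with one
#' degree of freedom; p-values are Benjamini-Hochberg adjusted across bins
#' and each bin is classed `high` or `low` (by the sign of
#' `lambda_bin - lambda0`) when the adjusted p falls below `alpha`, else
#' `ns`. Bins with zero opportunity are reported as missing.
#'
#' @param table a [branch_changes()] result with per-bin apportionment (or
#'   a data frame with columns `bin`, `changes`, `opportunity`).
#' @param alpha significance level after FDR adjustment.
#' @return data frame (class `rate_bin_report`): `bin`, `changes`,
#'   `opportunity`, `rate`, `pooled_rate`, `lrt`, `p`, `p_adj`, `class`.
#' @export
bin_rate_test <- function(table, alpha = 0.05) {
  tab <- if (inherits(table, "branch_changes")) table$bins else table
  if (is.null(tab)) stop("per-bin apportionment missing: pass `bins` to branch_changes()")
  ok <- tab$opportunity > 0
  if (sum(ok) < 2) stop("need at least 2 bins with positive opportunity")
  c_tot <- sum(tab$changes[ok]); o_tot <- sum(tab$opportunity[ok])
  lambda0 <- c_tot / o_tot
  n <- nrow(tab)
  rate <- lrt <- p <- rep(NA_real_, n)
  for (i in which(ok)) {
    cb <- tab$changes[i]; ob <- tab$opportunity[i]
    cr <- c_tot - cb; or <- o_tot - ob
    lb <- cb / ob; lr <- if (or > 0) cr / or else NA
    rate[i] <- lb
    if (or <= 0) next
    term <- function(cc, ll) if (cc > 0) cc * log(ll / lambda0) else 0
    lrt[i] <- 2 * (term(cb, lb) + term(cr, lr))
    p[i] <- stats::pchisq(lrt[i], df = 1, lower.tail = FALSE)
  }
  p_adj <- rep(NA_real_, n)
  p_adj[!is.na(p)] <- adjust_fdr(p[!is.na(p)])
  cls <- rep(NA_character_, n)
  cls[!is.na(p_adj)] <- ifelse(p_adj[!is.na(p_adj)] < alpha,
                               ifelse(rate[!is.na(p_adj)] > lambda0,
                                      "high", "low"),
                               "ns")
  out <- data.frame(bin = tab$bin, changes = tab$changes,
                    opportunity = tab$opportunity, rate = rate,
                    pooled_rate = lambda0, lrt = lrt, p = p, p_adj = p_adj,
                    class = cls, stringsAsFactors = FALSE)
  class(out) <- c("rate_bin_report", "data.frame")
  out
}

#' Summarise per-bin rates over a tree sample
#'
#' Arithmetic mean of the per-bin rate across trees (bins missing in a
#' tree are averaged over the trees that have them), with the per-tree
#' series retained for spaghetti plots.
#'
#' @param reports list of [bin_rate_test()] results (one per tree).
#' @return list (class `rate_summary`): `mean` (data frame `bin`,
#'   `mean_rate`, `n_trees`), `per_tree` (bins x trees matrix of rates).
#' @export
summarize_rates <- function(reports) {
  if (!length(reports)) stop("no reports given")
  bins <- reports[[1]]$bin
  per_tree <- vapply(reports, function(r) r$rate[match(bins, r$bin)],
                     numeric(length(bins)))
  per_tree <- matrix(per_tree, nrow = length(bins),
                     dimnames = list(bins, NULL))
  out <- list(
    mean = data.frame(bin = bins,
                      mean_rate = rowMeans(per_tree, na.rm = TRUE),
                      n_trees = rowSums(!is.na(per_tree))),
    per_tree = per_tree)
  class(out) <- "rate_summary"
  out
}

#' Discrete-character rate analysis over a sample of dated trees
#'
#' Runs ancestral state reconstruction, branch-change expectation and the
#' per-bin Poisson rate classification for each dated tree, and summarises.
#'
#' @param matrix a [character_matrix()].
#' @param trees list of [dated_tree()]s.
#' @param bins a [make_bins()] result.
#' @param alpha significance level.
#' @return list: `reports` (one `rate_bin_report` per tree), `summary`
#'   (see [summarize_rates()]).
#' @export
discrete_rates_analysis <- function(matrix, trees, bins, alpha = 0.05) {
  if (inherits(trees, "dated_tree")) trees <- list(trees)
  reports <- lapply(trees, function(tr) {
    asr <- asr_mk(matrix, tr)
    bc <- branch_changes(asr, matrix, tr, bins = bins)
    bin_rate_test(bc, alpha = alpha)
  })
  list(reports = reports, summary = summarize_rates(reports))
}
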