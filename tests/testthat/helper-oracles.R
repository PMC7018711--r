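# Independent oracles and fixture builders used across the suite.

# random discrete character matrix (unordered binary by default)
random_char_matrix <- function(n_taxa, n_char, p_missing = 0.2,
                               n_states = 2, seed = 1) {
  set.seed(seed)
  vals <- matrix(sample(0:(n_states - 1), n_taxa * n_char, replace = TRUE),
                 n_taxa, n_char)
  states <- matrix(as.character(vals), n_taxa, n_char)
  states[matrix(runif(n_taxa * n_char) < p_missing, n_taxa, n_char)] <- ""
  # keep every character coded somewhere
  for (ch in which(colSums(states != "") == 0))
    states[1, ch] <- as.character(vals[1, ch])
  rownames(states) <- paste0("t", seq_len(n_taxa))
  character_matrix(states)
}

# build a morph_dist object directly from D and C (for formula tests)
manual_dist <- function(D, C, metric = "MORD", n_char = max(C)) {
  taxa <- rownames(D)
  structure(list(D = D, C = C, metric = metric, taxa = taxa,
                 n_char = n_char), class = "morph_dist")
}

# brute-force optimal retained set: largest taxon subset with no
# undefined pair (ties broken toward larger size only)
oracle_trim_optimum <- function(D) {
  n <- nrow(D)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    sub <- D[idx, idx, drop = FALSE]
    if (!anyNA(sub[upper.tri(sub)])) best <- length(idx)
  }
  best
}

# dense nested Riemann quadrature for the outgroup-ladder posterior mean:
# joint density prod_k 1/(x_{k+1} - b_k) on b_k < x_k < x_{k+1} < t0
oracle_ladder_mean <- function(bounds, t0, n_grid = 400) {
  m <- length(bounds)
  dx <- (t0 - bounds[1]) / n_grid
  x <- bounds[1] + dx * (seq_len(n_grid) - 0.5)
  # f_k(x) = marginal (unnormalised) of divergence k evaluated by recursion
  f <- as.numeric(x > bounds[m]) / (t0 - bounds[m])
  if (m > 1) {
    for (k in (m - 1):1) {
      g <- numeric(n_grid)
      for (i in seq_len(n_grid)) {
        if (x[i] <= bounds[k]) next
        j <- which(x > x[i])
        g[i] <- sum(f[j] / (x[j] - bounds[k])) * dx
      }
      f <- g
    }
  }
  sum(x * f) / sum(f)
}

# exhaustive Mk marginal probabilities at internal nodes: enumerate every
# assignment of states to internal nodes; transition probabilities from an
# eigen-decomposed rate matrix (independent of the closed form in R/)
oracle_mk_marginals <- function(tree, tip_states, k, q) {
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  Q <- matrix(q, k, k); diag(Q) <- -(k - 1) * q
  Pmat <- function(t) {
    e <- eigen(Q)
    e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors)
  }
  durs <- tree$node.ages[tree$edge[, 1]] - tree$node.ages[tree$edge[, 2]]
  Ps <- lapply(durs, Pmat)
  nodes <- n_tip + seq_len(n_node)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_node)))
  post <- matrix(0, n_node, k)
  for (r in seq_len(nrow(grid))) {
    assign_state <- function(v) {
      if (v <= n_tip) tip_states[v] else grid[r, v - n_tip]
    }
    lik <- 1 / k   # flat root prior
    for (e in seq_len(nrow(tree$edge))) {
      sp <- assign_state(tree$edge[e, 1])
      chd <- tree$edge[e, 2]
      if (chd <= n_tip) {
        s <- tip_states[chd]
        if (is.na(s)) next   # missing tip: sums over states to 1
        lik <- lik * Ps[[e]][sp, s]
      } else {
        lik <- lik * Ps[[e]][sp, assign_state(chd)]
      }
    }
    for (v in seq_len(n_node))
      post[v, grid[r, v]] <- post[v, grid[r, v]] + lik
  }
  sweep(post, 1, rowSums(post), "/")
}

# full multivariate-normal BM likelihood with profiled root, matching the
# contrast definition: L_contrasts = L_full(mu_hat) * sqrt(2*pi/sum(Cinv))
oracle_bm_loglik <- function(tree, trait, sigma2, scalars = NULL) {
  phy <- tree; class(phy) <- "phylo"
  if (!is.null(scalars)) phy$edge.length <- phy$edge.length * scalars
  V <- ape::vcv(phy)
  x <- as.numeric(trait[rownames(V)])
  C <- sigma2 * V
  Ci <- solve(C)
  mu <- sum(Ci %*% x) / sum(Ci)
  r <- x - mu
  n <- length(x)
  full <- -0.5 * (n * log(2 * pi) +
                  as.numeric(determinant(C)$modulus) +
                  as.numeric(t(r) %*% Ci %*% r))
  full + 0.5 * log(2 * pi / sum(Ci))
}

# closed-form log evidence of the conjugate normal toy model:
# y_i ~ N(mu, s2_lik), mu ~ N(0, tau2)
oracle_normal_evidence <- function(y, s2_lik, tau2) {
  n <- length(y)
  S <- diag(s2_lik, n) + tau2
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(S)$modulus) +
          as.numeric(t(y) %*% solve(S) %*% y))
}

# small dated tree from a newick string and explicit ages
dated_from_ages <- function(newick, ages) {
  dated_tree(ape::read.tree(text = newick), ages)
}

write_tmp_nexus <- function(lines) {
  path <- tempfile(fileext = ".nex")
  writeLines(lines, path)
  path
}
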