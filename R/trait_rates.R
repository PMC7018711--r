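#' Brownian-motion log-likelihood of a continuous trait
#'
#' Gaussian log-likelihood of the tip values under Brownian motion with
#' variance `sigma2` per my, on branch lengths rescaled by per-branch
#' scalars. Evaluated by the pruning (independent contrasts) algorithm, so
#' the root state is profiled out at its maximum-likelihood value and the
#' likelihood is the product of the `n - 1` contrast densities.
#'
#' @param tree a [dated_tree()].
#' @param trait named numeric vector over the tree tips.
#' @param sigma2 Brownian variance (trait^2 per my, > 0).
#' @param scalars optional per-edge rate scalars (default 1; order of
#'   `tree$edge`).
#' @return log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, trait, sigma2, scalars = NULL) {
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  prep <- .bm_prep(tree, trait)
  if (is.null(scalars)) scalars <- rep(1, nrow(tree$edge))
  bm_contrast_loglik_cpp(prep$post_parent, prep$post_child,
                         prep$durs_post * scalars[prep$post_index],
                         prep$n_nodes, prep$n_tip, prep$tipvals, sigma2)
}

.bm_prep <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- ape::Ntip(tree)
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait values missing for: ",
         paste(setdiff(tree$tip.label, names(trait)), collapse = ", "))
  idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  durs <- if (is.null(tree$node.ages)) tree$edge.length
          else tree$node.ages[tree$edge[, 1]] - tree$node.ages[tree$edge[, 2]]
  list(post_parent = tree$edge[idx, 1], post_child = tree$edge[idx, 2],
       post_index = idx, durs_post = durs[idx],
       n_nodes = n_tip + tree$Nnode, n_tip = n_tip,
       tipvals = as.numeric(trait[tree$tip.label]))
}

#' Configuration for the variable-rates sampler
#'
#' Defaults are desk-scale: 200 000 iterations, 20 000 burn-in, thinning
#' 100. Priors: `sigma2` half-Cauchy(scale 1) on the variance; scalar
#' values lognormal(`scalar_meanlog`, `scalar_sdlog`); the number of
#' active scalars uniform on `{0, ..., n_locations}` over the branch and
#' clade locations (which makes the reversible-jump acceptance depend on
#' the likelihood and scalar-value prior only). Move weights give the
#' relative frequency of the four move types.
#'
#' @param iterations,burn_in,thinning chain shape.
#' @param sigma2_scale half-Cauchy scale of the `sigma2` prior.
#' @param scalar_meanlog,scalar_sdlog lognormal prior of scalar values.
#' @param move_weights named weights for `sigma2`, `perturb`, `add`,
#'   `delete` moves.
#' @param step_sigma2,step_scalar log-scale half-widths of the multiplier
#'   proposals.
#' @return list of class `vr_config`.
#' @export
vr_config <- function(iterations = 200000, burn_in = 20000, thinning = 100,
                      sigma2_scale = 1, scalar_meanlog = 0,
                      scalar_sdlog = 1.1,
                      move_weights = c(sigma2 = 0.3, perturb = 0.3,
                                       add = 0.2, delete = 0.2),
                      step_sigma2 = 0.7, step_scalar = 0.7) {
  stopifnot(iterations > burn_in, thinning >= 1)
  structure(list(iterations = iterations, burn_in = burn_in,
                 thinning = thinning, sigma2_scale = sigma2_scale,
                 scalar_meanlog = scalar_meanlog,
                 scalar_sdlog = scalar_sdlog,
                 move_weights = move_weights,
                 step_sigma2 = step_sigma2, step_scalar = step_scalar),
            class = "vr_config")
}

## closures defining the (possibly tempered) variable-rates model.
## Scalars live at L = E + N locations: one per branch (rescaling that
## branch alone) and one per internal node (rescaling the node's stem
## branch and every branch of its subtree with a single parameter, so
## clade-wide shifts are cheap to express). `state$r` caches the per-edge
## product of all scalars covering each edge.
.vr_model <- function(tree, trait, config, variable = TRUE) {
  prep <- .bm_prep(tree, trait)
  E <- length(prep$post_index)
  n_tip <- prep$n_tip
  n_node <- prep$n_nodes - n_tip
  L <- E + n_node
  ## edge indices covered by each location
  cover <- vector("list", L)
  for (e in seq_len(E)) cover[[e]] <- e
  kids <- split(seq_len(E), tree$edge[, 1])
  for (v in seq_len(n_node)) {
    node <- n_tip + v
    sub <- integer(0)
    stem <- which(tree$edge[, 2] == node)
    stack <- node
    while (length(stack)) {
      u <- stack[1]; stack <- stack[-1]
      ke <- kids[[as.character(u)]]
      sub <- c(sub, ke)
      stack <- c(stack, tree$edge[ke, 2][tree$edge[ke, 2] > n_tip])
    }
    cover[[E + v]] <- c(stem, sub)
  }
  sc <- config$sigma2_scale
  ml <- config$scalar_meanlog; sl <- config$scalar_sdlog
  w <- config$move_weights
  if (!variable) w <- c(sigma2 = 1, perturb = 0, add = 0, delete = 0)
  w <- w / sum(w)

  loglik <- function(state) {
    bm_contrast_loglik_cpp(prep$post_parent, prep$post_child,
                           prep$durs_post * state$r[prep$post_index],
                           prep$n_nodes, prep$n_tip, prep$tipvals,
                           state$sigma2)
  }
  logprior <- function(state) {
    lp <- log(2 / pi) + log(sc) - log(sc^2 + state$sigma2^2)
    if (variable) {
      k <- sum(state$in_set)
      lp <- lp - log(L + 1) - lchoose(L, k)
      if (k > 0)
        lp <- lp + sum(stats::dlnorm(state$values[state$in_set], ml, sl,
                                     log = TRUE))
    }
    lp
  }
  propose <- function(state) {
    mv <- sample.int(4L, 1L, prob = w)
    if (mv == 1L) {                       # sigma2 multiplier
      f <- exp(stats::runif(1, -config$step_sigma2, config$step_sigma2))
      state$sigma2 <- state$sigma2 * f
      return(list(state = state, log_h = log(f), move = "sigma2"))
    }
    k <- sum(state$in_set)
    if (mv == 2L) {                       # perturb one active scalar
      if (k == 0) return(NULL)
      i <- .sample_one(which(state$in_set))
      f <- exp(stats::runif(1, -config$step_scalar, config$step_scalar))
      state$values[i] <- state$values[i] * f
      state$r[cover[[i]]] <- state$r[cover[[i]]] * f
      return(list(state = state, log_h = log(f), move = "perturb"))
    }
    if (mv == 3L) {                       # add a scalar (prior draw)
      if (k == L) return(NULL)
      i <- .sample_one(which(!state$in_set))
      v <- stats::rlnorm(1, ml, sl)
      state$in_set[i] <- TRUE; state$values[i] <- v
      state$r[cover[[i]]] <- state$r[cover[[i]]] * v
      log_h <- (log(w["delete"]) - log(k + 1)) -
               (log(w["add"]) - log(L - k) +
                stats::dlnorm(v, ml, sl, log = TRUE))
      return(list(state = state, log_h = unname(log_h), move = "add"))
    }
    if (k == 0) return(NULL)              # delete a scalar
    i <- .sample_one(which(state$in_set))
    v <- state$values[i]
    state$in_set[i] <- FALSE; state$values[i] <- 1
    state$r[cover[[i]]] <- state$r[cover[[i]]] / v
    log_h <- (log(w["add"]) - log(L - k + 1) +
              stats::dlnorm(v, ml, sl, log = TRUE)) -
             (log(w["delete"]) - log(k))
    list(state = state, log_h = unname(log_h), move = "delete")
  }
  list(init = list(sigma2 = 1, values = rep(1, L),
                   in_set = rep(FALSE, L), r = rep(1, E)),
       loglik = loglik, logprior = logprior, propose = propose,
       E = E, L = L)
}

.sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

#' Reversible-jump MCMC for Brownian rate scalars on branches and clades
#'
#' Samples the posterior over `(sigma2, scalar set, scalar values)` for a
#' continuous trait on a dated tree. A scalar can sit on a single branch
#' (rescaling that branch's duration) or on an internal node (rescaling
#' the node's stem branch and its whole subtree with one parameter, so
#' clade-wide rate shifts are parsimonious to express); the effective rate
#' multiplier of an edge is the product of every scalar covering it. The
#' set changes dimension through add/delete moves with the lognormal value
#' prior used as the proposal, so with the uniform prior on the set size
#' the reversible-jump acceptance reduces to likelihood (and value-prior)
#' ratios. The root state is profiled out by the contrast likelihood.
#'
#' @param tree a [dated_tree()].
#' @param trait named numeric vector (e.g. log10 skull length).
#' @param config a [vr_config()].
#' @param seed integer seed (same seed and config give a bit-identical
#'   trace).
#' @return object of class `vr_posterior`: `samples` (data frame:
#'   iteration, sigma2, k, loglik), `scalar_samples` (thinned samples x
#'   edges matrix), `mean_scalars` (posterior mean scalar per edge,
#'   averaged over every post-burn-in iteration), `acceptance` (per move
#'   type), `min_ess` (smallest effective sample size across sigma2, k and
#'   loglik), `config`, `tree`.
#' @export
vr_mcmc <- function(tree, trait, config = vr_config(), seed = NULL) {
  if (stats::var(as.numeric(trait[tree$tip.label])) == 0)
    stop("degenerate trait: no variance among tips")
  if (!is.null(seed)) set.seed(seed)
  model <- .vr_model(tree, trait, config, variable = TRUE)
  res <- .mh_chain(model, config, beta = 1, n_iter = config$iterations,
                   burn_in = config$burn_in, thinning = config$thinning,
                   record_scalars = TRUE)
  ess <- c(sigma2 = .ess(res$samples$sigma2), k = .ess(res$samples$k),
           loglik = .ess(res$samples$loglik))
  structure(list(samples = res$samples,
                 scalar_samples = res$scalar_samples,
                 mean_scalars = res$mean_scalars,
                 acceptance = res$acceptance,
                 min_ess = min(ess), ess = ess,
                 final_state = res$state,
                 config = config, tree = tree),
            class = "vr_posterior")
}

#' @export
print.vr_posterior <- function(x, ...) {
  cat(sprintf(
    "Variable-rates posterior: %d samples, mean k = %.1f scaled branches\n",
    nrow(x$samples), mean(x$samples$k)))
  cat(sprintf("  sigma2 posterior median %.4g; min ESS %.0f\n",
              stats::median(x$samples$sigma2), x$min_ess))
  invisible(x)
}

## Metropolis-Hastings core shared by vr_mcmc and the stepping-stone stones
.mh_chain <- function(model, config, beta, n_iter, burn_in = 0,
                      thinning = 1, record_scalars = FALSE,
                      state = NULL) {
  if (is.null(state)) state <- model$init
  ll <- model$loglik(state); lp <- model$logprior(state)
  acc <- c(sigma2 = 0, perturb = 0, add = 0, delete = 0)
  tries <- acc
  keep_iters <- seq_len(n_iter)
  keep_iters <- keep_iters[keep_iters > burn_in &
                           (keep_iters - burn_in) %% thinning == 0]
  ns <- length(keep_iters)
  samples <- data.frame(iteration = keep_iters,
                        sigma2 = numeric(ns), k = integer(ns),
                        loglik = numeric(ns))
  has_scalars <- !is.null(model$E) && !is.null(state$r)
  scalar_samples <- if (record_scalars && has_scalars)
    matrix(NA_real_, ns, model$E) else NULL
  scalar_sum <- if (has_scalars) numeric(model$E) else numeric(0)
  n_sum <- 0L
  si <- 0L
  lls <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    prop <- model$propose(state)
    if (!is.null(prop)) {
      mv <- prop$move
      tries[mv] <- tries[mv] + 1
      ll_new <- model$loglik(prop$state)
      lp_new <- model$logprior(prop$state)
      la <- beta * (ll_new - ll) + (lp_new - lp) + prop$log_h
      if (is.finite(la) && log(stats::runif(1)) < la) {
        state <- prop$state; ll <- ll_new; lp <- lp_new
        acc[mv] <- acc[mv] + 1
      }
    }
    lls[it] <- ll
    if (has_scalars && it > burn_in) {
      scalar_sum <- scalar_sum + state$r; n_sum <- n_sum + 1L
    }
    if (si < ns && it == keep_iters[si + 1L]) {
      si <- si + 1L
      samples$sigma2[si] <- if (is.null(state$sigma2)) NA_real_ else state$sigma2
      samples$k[si] <- if (is.null(state$in_set)) NA_integer_
                       else sum(state$in_set)
      samples$loglik[si] <- ll
      if (!is.null(scalar_samples)) scalar_samples[si, ] <- state$r
    }
  }
  list(samples = samples, scalar_samples = scalar_samples,
       mean_scalars = if (n_sum > 0) scalar_sum / n_sum else state$r,
       acceptance = ifelse(tries > 0, acc / tries, NA),
       loglik_trace = lls, state = state)
}

## effective sample size from the initial positive autocorrelations
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  m <- if (length(pos)) pos[1] - 1 else length(rho)
  tau <- 1 + 2 * sum(rho[seq_len(m)])
  max(1, n / max(tau, 1))
}

#' Stepping-stone estimate of a log marginal likelihood
#'
#' Generic power-posterior ladder: temperatures `beta_j = (j/K)^(1/theta)`
#' run from the prior (`beta = 0`) to the posterior (`beta = 1`), a
#' Metropolis-Hastings chain samples each stone (warm-started from the
#' previous one), and the log evidence is the sum over stones of the log
#' mean importance ratio `exp((beta_{j+1} - beta_j) * loglik)`.
#'
#' @param model list with elements `init`, `loglik(state)`,
#'   `logprior(state)` and `propose(state)` returning
#'   `list(state, log_h, move)` or `NULL` for an impossible move (see
#'   [stepping_stone()] for the tree-model wrapper).
#' @param k_stones number of stones (>= 2).
#' @param iters_per_stone chain length per stone (the first 10% of each
#'   stone is discarded as per-stone warm-up).
#' @param theta ladder concentration (0.25 concentrates stones near the
#'   prior, where the integrand varies most).
#' @param seed integer seed.
#' @param config sampler configuration (a [vr_config()]); only the move
#'   steps are used here.
#' @param init_state optional starting state; supplying a posterior state
#'   (e.g. the `final_state` of a converged [vr_mcmc()] run) together with
#'   `descend = TRUE` runs the ladder from the posterior down to the
#'   prior, which avoids the low bias that arises when a prior-started
#'   chain fails to find high-likelihood configurations of a
#'   trans-dimensional model within a stone.
#' @param descend visit the stones from the posterior end (`beta` near 1)
#'   downward; the estimator only needs equilibrium samples at each stone,
#'   so the visiting order is free.
#' @return list: `log_evidence`, `per_stone` (data frame: stone, beta,
#'   log_ratio).
#' @export
stepping_stone_evidence <- function(model, k_stones = 100,
                                    iters_per_stone = 1000, theta = 0.25,
                                    seed = NULL, config = vr_config(),
                                    init_state = NULL, descend = FALSE) {
  if (k_stones < 2) stop("`k_stones` must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  betas <- (seq(0, k_stones) / k_stones)^(1 / theta)
  warm <- ceiling(iters_per_stone * 0.1)
  state <- if (is.null(init_state)) model$init else init_state
  log_ratios <- numeric(k_stones)
  order_j <- if (descend) rev(seq_len(k_stones)) else seq_len(k_stones)
  for (j in order_j) {
    res <- .mh_chain(model, config, beta = betas[j],
                     n_iter = iters_per_stone, state = state)
    state <- res$state
    lls <- res$loglik_trace[-seq_len(warm)]
    d <- (betas[j + 1] - betas[j]) * lls
    mx <- max(d)
    log_ratios[j] <- mx + log(mean(exp(d - mx)))
    if (!is.finite(log_ratios[j]))
      stop(sprintf("non-finite stepping-stone estimate at stone %d", j))
  }
  list(log_evidence = sum(log_ratios),
       per_stone = data.frame(stone = seq_len(k_stones),
                              beta = betas[-length(betas)],
                              log_ratio = log_ratios))
}

#' Stepping-stone marginal likelihood of a trait model on a tree
#'
#' Runs [stepping_stone_evidence()] for the homogeneous Brownian-motion
#' model (`sigma2` only) or the variable-rates model (reversible-jump over
#' branch scalars) of a trait on a dated tree.
#'
#' @param tree a [dated_tree()].
#' @param trait named numeric vector over tips.
#' @param model `"homogeneous"` or `"variable"`.
#' @param k_stones,iters_per_stone,theta ladder shape (defaults mirror a
#'   100-stone, 1000-iteration protocol).
#' @param seed integer seed.
#' @param config a [vr_config()].
#' @param init_state,descend see [stepping_stone_evidence()]: pass a
#'   posterior `final_state` from [vr_mcmc()] to run the ladder from the
#'   posterior downward (recommended for the variable model).
#' @return list as in [stepping_stone_evidence()], plus `model`.
#' @export
stepping_stone <- function(tree, trait,
                           model = c("homogeneous", "variable"),
                           k_stones = 100, iters_per_stone = 1000,
                           theta = 0.25, seed = NULL,
                           config = vr_config(), init_state = NULL,
                           descend = !is.null(init_state)) {
  model <- match.arg(model)
  m <- .vr_model(tree, trait, config, variable = model == "variable")
  out <- stepping_stone_evidence(m, k_stones = k_stones,
                                 iters_per_stone = iters_per_stone,
                                 theta = theta, seed = seed,
                                 config = config, init_state = init_state,
                                 descend = descend)
  out$model <- model
  out
}

#' Log Bayes factor between variable-rates and homogeneous models
#'
#' Uses the convention `logBF = 2 * (logZ_variable - logZ_homogeneous)`;
#' values above 5 are strong and above 10 very strong evidence for rate
#' heterogeneity.
#'
#' @param logz_variable,logz_homogeneous log marginal likelihoods.
#' @return list: `logBF`, `evidence` (`"very strong"`, `"strong"`,
#'   `"weak"`).
#' @export
bayes_factor <- function(logz_variable, logz_homogeneous) {
  stopifnot(is.finite(logz_variable), is.finite(logz_homogeneous))
  bf <- 2 * (logz_variable - logz_homogeneous)
  list(logBF = bf,
       evidence = if (bf > 10) "very strong" else if (bf > 5) "strong"
                  else "weak")
}

#' Evolutionary rates through time from branch scalars
#'
#' Cuts every branch of each tree at the time-bin boundaries and computes,
#' per bin and tree, the duration-weighted mean of the branch rate scalars
#' over the segments falling inside the bin; slices containing no branch
#' segment are missing. A grand mean across trees is added.
#'
#' @param trees list of [dated_tree()]s.
#' @param scalars list of per-edge mean scalar vectors (same order as each
#'   tree's edges), e.g. `mean_scalars` from [vr_mcmc()].
#' @param bins a [make_bins()] result.
#' @return list (class `rtt`): `per_tree` (bins x trees matrix), `mean`
#'   (data frame: bin, mean_rate, n_trees).
#' @export
rates_through_time <- function(trees, scalars, bins) {
  if (inherits(trees, "dated_tree")) { trees <- list(trees); scalars <- list(scalars) }
  stopifnot(length(trees) == length(scalars))
  per_tree <- vapply(seq_along(trees), function(i) {
    tr <- trees[[i]]; sc <- scalars[[i]]
    old_e <- tr$node.ages[tr$edge[, 1]]
    young_e <- tr$node.ages[tr$edge[, 2]]
    vapply(seq_len(nrow(bins)), function(b) {
      ov <- pmax(0, pmin(old_e, bins$old[b]) - pmax(young_e, bins$young[b]))
      if (sum(ov) == 0) return(NA_real_)
      sum(ov * sc) / sum(ov)
    }, 0)
  }, numeric(nrow(bins)))
  per_tree <- matrix(per_tree, nrow = nrow(bins),
                     dimnames = list(bins$label, NULL))
  out <- list(per_tree = per_tree,
              mean = data.frame(bin = bins$label,
                                mean_rate = rowMeans(per_tree, na.rm = TRUE),
                                n_trees = rowSums(!is.na(per_tree))))
  class(out) <- "rtt"
  out
}

#' Consensus tree with branch lengths replaced by mean rate scalars
#'
#' Builds the strict consensus of the topologies, keeps only the clades
#' (edges) present in every tree, and assigns each retained edge the
#' across-tree mean of its per-tree mean scalar; terminal edges are always
#' shared and averaged likewise.
#'
#' @param trees list of trees on the same tip set.
#' @param scalars list of per-edge scalar vectors.
#' @return a `phylo` whose `edge.length` are mean rate scalars.
#' @export
consensus_rate_tree <- function(trees, scalars) {
  stopifnot(length(trees) >= 2, length(trees) == length(scalars))
  tips <- sort(trees[[1]]$tip.label)
  for (t in trees) if (!identical(sort(t$tip.label), tips))
    stop("no shared edges: trees must share one tip set")
  clade_key <- function(tr) {
    n_tip <- ape::Ntip(tr)
    keys <- character(nrow(tr$edge))
    desc <- vector("list", n_tip + tr$Nnode)
    for (i in seq_len(n_tip)) desc[[i]] <- tr$tip.label[i]
    post <- ape::reorder.phylo(tr, "postorder")$edge
    for (e in seq_len(nrow(post)))
      desc[[post[e, 1]]] <- c(desc[[post[e, 1]]], desc[[post[e, 2]]])
    for (e in seq_len(nrow(tr$edge)))
      keys[e] <- paste(sort(desc[[tr$edge[e, 2]]]), collapse = "|")
    keys
  }
  tabs <- lapply(seq_along(trees), function(i)
    stats::setNames(scalars[[i]], clade_key(trees[[i]])))
  shared <- Reduce(intersect, lapply(tabs, names))
  if (!length(shared)) stop("no shared edges among the trees")
  means <- vapply(shared, function(k)
    mean(vapply(tabs, function(tb) tb[[k]], 0)), 0)
  cls <- lapply(trees, function(t) { class(t) <- "phylo"
                                     t$node.ages <- NULL; t })
  class(cls) <- "multiPhylo"
  cons <- ape::consensus(cls, p = 1, rooted = TRUE)
  keys <- clade_key(cons)
  if (!all(keys %in% shared))
    stop("internal error: consensus edge missing from shared set")
  cons$edge.length <- unname(means[keys])
  cons
}
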