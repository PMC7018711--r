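test_that("the contrast likelihood matches its closed form and the direct
           multivariate-normal evaluation", {
  dt <- dated_from_ages("(A,B);", c(0, 0, 1))
  expect_equal(bm_loglik(dt, c(A = 0, B = 2), 1),
               -0.5 * log(4 * pi) - 1, tolerance = 1e-12)
  expect_error(bm_loglik(dt, c(A = 0, B = 2), -1), "positive")

  set.seed(3)
  for (rep in 1:5) {
    tree <- simulate_tree(sample(4:8, 1), seed = 100 + rep)
    tv <- simulate_trait_vr(tree, sigma2 = 0.05, seed = 200 + rep)
    s2 <- runif(1, 0.01, 0.2)
    expect_equal(bm_loglik(tree, tv$trait, s2),
                 oracle_bm_loglik(tree, tv$trait, s2), tolerance = 1e-8)
    # with scalars
    sc <- runif(nrow(tree$edge), 0.2, 5)
    expect_equal(bm_loglik(tree, tv$trait, s2, scalars = sc),
                 oracle_bm_loglik(tree, tv$trait, s2, scalars = sc),
                 tolerance = 1e-8)
  }
})

test_that("unit scalars reduce to homogeneous BM and the scale identity
           holds", {
  tree <- simulate_tree(10, seed = 5)
  tv <- simulate_trait_vr(tree, sigma2 = 0.1, seed = 6)
  expect_equal(bm_loglik(tree, tv$trait, 0.1),
               bm_loglik(tree, tv$trait, 0.1,
                         scalars = rep(1, nrow(tree$edge))))
  # sigma2 -> 2 sigma2 with halved durations leaves the likelihood fixed
  half <- tree
  half$node.ages <- tree$node.ages / 2
  half$edge.length <- tree$edge.length / 2
  half$root.time <- tree$root.time / 2
  expect_equal(bm_loglik(tree, tv$trait, 0.1),
               bm_loglik(half, tv$trait, 0.2), tolerance = 1e-10)
})

test_that("the sampler trace is seed-deterministic and rejects degenerate
           traits", {
  tree <- simulate_tree(12, seed = 7)
  tv <- simulate_trait_vr(tree, sigma2 = 0.05, seed = 8)
  cfg <- vr_config(iterations = 2000, burn_in = 500, thinning = 10)
  p1 <- vr_mcmc(tree, tv$trait, cfg, seed = 9)
  p2 <- vr_mcmc(tree, tv$trait, cfg, seed = 9)
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$mean_scalars, p2$mean_scalars)
  expect_equal(nrow(p1$samples), (2000 - 500) / 10)
  flat <- setNames(rep(1, ape::Ntip(tree)), tree$tip.label)
  expect_error(vr_mcmc(tree, flat, cfg), "degenerate")
})

test_that("with the likelihood silenced the sampler returns its prior on
           the scalar-set size", {
  tree <- simulate_tree(8, seed = 11)
  tv <- simulate_trait_vr(tree, sigma2 = 1, seed = 12)
  # the scalar-set size mixes by a +/-1 random walk, so thin far past its
  # relaxation time to feed the goodness-of-fit test near-independent draws
  cfg <- vr_config(iterations = 400000, burn_in = 20000, thinning = 400)
  model <- burstlab:::.vr_model(tree, tv$trait, cfg, variable = TRUE)
  model$loglik <- function(state) 0
  set.seed(13)
  res <- burstlab:::.mh_chain(model, cfg, beta = 1, n_iter = cfg$iterations,
                              burn_in = cfg$burn_in,
                              thinning = cfg$thinning)
  L <- model$L
  counts <- tabulate(res$samples$k + 1L, nbins = L + 1)
  # uniform prior over {0..E}: chi-squared goodness of fit at alpha = 0.01
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("posterior credible intervals cover the generating sigma2", {
  hits <- 0
  for (rep in 1:30) {
    tree <- simulate_tree(25, seed = 400 + rep)
    tv <- simulate_trait_vr(tree, sigma2 = 0.05, seed = 500 + rep)
    cfg <- vr_config(iterations = 6000, burn_in = 1500, thinning = 10,
                     move_weights = c(sigma2 = 1, perturb = 0, add = 0,
                                      delete = 0))
    post <- vr_mcmc(tree, tv$trait, cfg, seed = 600 + rep)
    ci <- quantile(post$samples$sigma2, c(0.025, 0.975))
    if (ci[1] <= 0.05 && 0.05 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * 30 - 2 * sqrt(30 * 0.9 * 0.1))
})

test_that("stepping-stone recovers a closed-form conjugate evidence", {
  set.seed(17)
  y <- rnorm(6, 1, 1)
  truth <- oracle_normal_evidence(y, 1, 1)
  model <- list(
    init = list(mu = 0),
    loglik = function(s) sum(dnorm(y, s$mu, 1, log = TRUE)),
    logprior = function(s) dnorm(s$mu, 0, 1, log = TRUE),
    propose = function(s) {
      s$mu <- s$mu + runif(1, -1, 1)
      list(state = s, log_h = 0, move = "sigma2")
    })
  est <- stepping_stone_evidence(model, k_stones = 30,
                                 iters_per_stone = 600, seed = 18)
  expect_lt(abs(est$log_evidence - truth), 0.1)
  # a longer ladder reduces the discretisation bias
  coarse <- vapply(1:4, function(i)
    stepping_stone_evidence(model, k_stones = 2, iters_per_stone = 600,
                            seed = 20 + i)$log_evidence, 0)
  fine <- vapply(1:4, function(i)
    stepping_stone_evidence(model, k_stones = 30, iters_per_stone = 600,
                            seed = 30 + i)$log_evidence, 0)
  expect_lt(abs(mean(fine) - truth), abs(mean(coarse) - truth))
})

test_that("stepping stone is repeatable across seeds for the homogeneous
           tree model", {
  tree <- simulate_tree(15, seed = 41)
  tv <- simulate_trait_vr(tree, sigma2 = 0.05, seed = 42)
  cfg <- vr_config(iterations = 1000, burn_in = 100, thinning = 10)
  z <- vapply(1:3, function(i)
    stepping_stone(tree, tv$trait, "homogeneous", k_stones = 16,
                   iters_per_stone = 400, seed = 50 + i,
                   config = cfg)$log_evidence, 0)
  expect_lt(max(z) - min(z), 3 * sd(z) + 0.5)
})

test_that("log Bayes factors use the doubled-difference convention and
           evidence bands", {
  expect_equal(bayes_factor(-10, -12)$logBF, 4)
  expect_equal(bayes_factor(-5, -5)$logBF, 0)
  expect_equal(bayes_factor(-2, -5)$evidence, "strong")     # logBF = 6
  expect_equal(bayes_factor(1, -5)$evidence, "very strong") # logBF = 12
  expect_equal(bayes_factor(-4.9, -5)$evidence, "weak")
  expect_error(bayes_factor(NaN, 0))
})

test_that("rates through time slice branches by duration-weighted scalars", {
  tree <- simulate_tree(10, span = 40, youngest_age = 0, seed = 61)
  bins <- make_bins("equal", oldest = tree$root.time, youngest = 0,
                    width = tree$root.time / 4)
  flat <- rates_through_time(tree, rep(1, nrow(tree$edge)), bins)
  expect_equal(unname(flat$mean$mean_rate), rep(1, 4))

  # one branch with scalar 4 spanning two slices contributes 4 to both
  dt <- dated_from_ages("(A,B);", c(0, 0, 10))
  bins2 <- make_bins("equal", oldest = 10, youngest = 0, width = 5)
  sc <- c(4, 1)[order(dt$edge[, 2])]       # scalar 4 on the branch to A
  sc <- ifelse(dt$edge[, 2] == 1, 4, 1)
  rtt <- rates_through_time(dt, sc, bins2)
  expect_equal(unname(rtt$per_tree[, 1]), c(2.5, 2.5))
})

test_that("consensus rate trees average scalars over shared edges only", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  s1 <- rep(1, nrow(t1$edge)); s2 <- rep(3, nrow(t2$edge))
  cons <- consensus_rate_tree(list(t1, t2), list(s1, s2))
  # conflicting internal clades drop; tip edges average to 2
  expect_equal(ape::Ntip(cons), 4)
  tip_edges <- cons$edge[, 2] <= 4
  expect_equal(unname(cons$edge.length[tip_edges]), rep(2, 4))
  expect_equal(cons$Nnode, 1)

  # identical topologies: per-edge arithmetic mean everywhere
  s1b <- seq_len(nrow(t1$edge)); s2b <- s1b + 2
  cons2 <- consensus_rate_tree(list(t1, t1), list(s1b, s2b))
  expect_equal(sort(unname(cons2$edge.length)), sort(unname(s1b + 1)))
  expect_error(consensus_rate_tree(list(t1), list(s1)), "2")
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(consensus_rate_tree(list(t1, t3),
                                   list(s1, rep(1, nrow(t3$edge)))),
               "tip set")
})

test_that("a planted fast clade is recovered by the posterior scalars", {
  tree <- simulate_tree(30, seed = 71)
  # scale the clade under the first internal child of the root
  n_tip <- ape::Ntip(tree)
  root_children <- tree$edge[tree$edge[, 1] == n_tip + 1, 2]
  target <- root_children[root_children > n_tip][1]
  desc <- integer(0); stack <- target
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]; desc <- c(desc, v)
    stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  inside <- tree$edge[, 2] %in% desc
  scal <- ifelse(inside, 10, 1)
  tv <- simulate_trait_vr(tree, sigma2 = 0.02, scalars = scal, seed = 72)
  cfg <- vr_config(iterations = 12000, burn_in = 3000, thinning = 20)
  post <- vr_mcmc(tree, tv$trait, cfg, seed = 73)
  expect_gt(mean(post$mean_scalars[inside]),
            mean(post$mean_scalars[!inside]))
})
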