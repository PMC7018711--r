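#' Simulate a birth-death tree with extinct tips
#'
#' Forward birth-death simulation conditioned on the total number of tips:
#' lineages split at rate `birth` and die at rate `death`; the simulation
#' stops once the tree has `n_tips` leaves (extinct tips are retained as
#' leaves) and any lineages still alive are closed at the stopping time.
#' Runs that go extinct before reaching `n_tips` are resampled up to
#' `max_retry` times. Event times are rescaled so the root (first
#' divergence) sits `span` my before the youngest possible tip age
#' `youngest_age`; with `death = 0` every tip survives to the stopping time
#' and the tree is ultrametric at age `youngest_age`.
#'
#' @param n_tips number of leaves (>= 2).
#' @param birth,death per-lineage rates (> 0 and >= 0).
#' @param span root-to-youngest-tip duration in my.
#' @param youngest_age age (Ma) assigned to the youngest possible tip.
#' @param seed integer seed.
#' @param max_retry resampling cap for early extinction.
#' @return a [dated_tree()] with attribute `truth` (list: `seed`, `birth`,
#'   `death`, `span`).
#' @export
simulate_tree <- function(n_tips, birth = 0.1, death = 0.05, span = 160,
                          youngest_age = 0, seed = NULL, max_retry = 100) {
  stopifnot(n_tips >= 2, birth > 0, death >= 0, span > 0)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_retry)) {
    sim <- .bd_forward(n_tips, birth, death)
    if (!is.null(sim)) {
      phy <- .lineages_to_phylo(sim)
      t_root <- sim$t_end[sim$id == sim$root_lineage]
      t_stop <- max(sim$t_end)
      scale <- span / (t_stop - t_root)
      ages <- youngest_age + span - (phy$node.times - t_root) * scale
      ages[ages < 0 & ages > -1e-8] <- 0   # float noise at the youngest tip
      out <- dated_tree(.strip_times(phy), ages)
      attr(out, "truth") <- list(seed = seed, birth = birth, death = death,
                                 span = span)
      return(out)
    }
  }
  stop("tree went extinct before reaching n_tips in every attempt")
}

## forward simulation; returns lineage records or NULL on extinction
.bd_forward <- function(n_tips, birth, death) {
  id <- 1L; parent <- NA_integer_; t_start <- 0; t_end <- NA_real_
  type <- "alive"
  recs <- data.frame(id = id, parent = parent, t_start = t_start,
                     t_end = t_end, type = type, stringsAsFactors = FALSE)
  next_id <- 2L; births <- 0L; t <- 0
  repeat {
    alive <- which(recs$type == "alive")
    if (!length(alive)) return(NULL)
    if (births == n_tips - 1L) {
      # close survivors where the next event would have fallen, so no
      # branch has zero duration
      t <- t + stats::rexp(1, length(alive) * (birth + death))
      recs$t_end[alive] <- t
      recs$type[alive] <- "tip"
      break
    }
    t <- t + stats::rexp(1, length(alive) * (birth + death))
    lin <- alive[sample.int(length(alive), 1)]
    if (stats::runif(1) < birth / (birth + death)) {
      births <- births + 1L
      recs$t_end[lin] <- t
      recs$type[lin] <- "internal"
      recs <- rbind(recs, data.frame(
        id = c(next_id, next_id + 1L), parent = lin,
        t_start = t, t_end = NA_real_, type = "alive",
        stringsAsFactors = FALSE))
      next_id <- next_id + 2L
    } else {
      recs$t_end[lin] <- t
      recs$type[lin] <- "tip"
    }
  }
  recs$root_lineage <- 1L
  recs
}

.lineages_to_phylo <- function(recs) {
  tips <- recs[recs$type == "tip", ]
  ints <- recs[recs$type == "internal", ]
  ints <- ints[order(ints$t_end), ]          # root (earliest split) first
  n_tip <- nrow(tips)
  node_of <- integer(max(recs$id))
  node_of[tips$id] <- seq_len(n_tip)
  node_of[ints$id] <- n_tip + seq_len(nrow(ints))
  nonroot <- recs[!is.na(recs$parent), ]
  edge <- cbind(node_of[nonroot$parent], node_of[nonroot$id])
  times <- numeric(n_tip + nrow(ints))
  times[node_of[recs$id[!is.na(recs$t_end)]]] <-
    recs$t_end[!is.na(recs$t_end)]
  phy <- structure(list(edge = edge,
                        tip.label = paste0("t", seq_len(n_tip)),
                        Nnode = nrow(ints),
                        edge.length = times[edge[, 2]] - times[edge[, 1]]),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy$node.times <- times
  phy
}

.strip_times <- function(phy) {
  phy$node.times <- NULL
  phy
}

#' Branch rate scalars for an early-burst scenario
#'
#' Assigns scalar `r` to every branch whose midpoint age is older than
#' `cutoff_age` (default: the oldest third of the tree, i.e. two thirds of
#' the way from the youngest tip back to the root) and 1 elsewhere.
#'
#' @param tree a `dated_tree`.
#' @param r scalar for the old branches.
#' @param cutoff_age age (Ma) above which branches are scaled; default
#'   `youngest + 2/3 * (root age - youngest)`.
#' @return numeric vector, one scalar per edge of `tree`.
#' @export
early_burst_scalars <- function(tree, r = 10, cutoff_age = NULL) {
  ages <- tree$node.ages
  if (is.null(cutoff_age)) {
    youngest <- min(ages[seq_len(ape::Ntip(tree))])
    cutoff_age <- youngest + (tree$root.time - youngest) * 2 / 3
  }
  mid <- (ages[tree$edge[, 1]] + ages[tree$edge[, 2]]) / 2
  ifelse(mid > cutoff_age, r, 1)
}

#' Simulate discrete characters on a dated tree
#'
#' Characters evolve independently along branches under a symmetric Mk
#' model with `n_states` states and per-character rate(s) `rate`
#' (transitions per my between any two specific states), optionally
#' multiplied per branch by `branch_scalars`. A missingness mask then sets
#' each taxon's cells to missing independently so the expected coded
#' fraction matches that taxon's completeness target; characters that lose
#' every coded cell keep one (the invariant that every character is coded
#' somewhere is preserved).
#'
#' @param tree a `dated_tree`.
#' @param n_char number of characters.
#' @param rate scalar or per-character vector of Mk rates (> 0).
#' @param n_states states per character (>= 2).
#' @param completeness a single target fraction for all taxa, a vector of
#'   per-taxon targets (length = number of tips), or a length-2 range from
#'   which per-taxon targets are drawn uniformly (default `c(0.01, 0.95)`,
#'   the empirical spread of fossil character matrices).
#' @param branch_scalars per-edge rate multipliers (default 1).
#' @param seed integer seed.
#' @return list: `matrix` (a [character_matrix()]), `truth` (list with the
#'   unmasked tip states, internal node states, rates, per-taxon targets
#'   and seed).
#' @export
simulate_characters <- function(tree, n_char, rate = 0.005, n_states = 2,
                                completeness = c(0.01, 0.95),
                                branch_scalars = NULL, seed = NULL) {
  stopifnot(all(rate > 0), n_states >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_tip <- ape::Ntip(tree)
  rate <- rep_len(rate, n_char)
  if (is.null(branch_scalars)) branch_scalars <- rep(1, nrow(tree$edge))

  states <- matrix(NA_integer_, n_tip + tree$Nnode, n_char)
  states[n_tip + 1L, ] <- sample.int(n_states, n_char, replace = TRUE) - 1L
  ord <- .preorder_edges(tree)
  durs <- tree$node.ages[tree$edge[, 1]] - tree$node.ages[tree$edge[, 2]]
  eff <- durs * branch_scalars
  for (k in ord) {
    par <- tree$edge[k, 1]; chd <- tree$edge[k, 2]
    p_change <- (1 - exp(-n_states * rate * eff[k])) * (n_states - 1) / n_states
    change <- stats::runif(n_char) < p_change
    s <- states[par, ]
    if (any(change)) {
      shift <- sample.int(n_states - 1L, sum(change), replace = TRUE)
      s[change] <- (s[change] + shift) %% n_states
    }
    states[chd, ] <- s
  }

  targets <- if (length(completeness) == 1) rep(completeness, n_tip)
    else if (length(completeness) == n_tip) completeness
    else if (length(completeness) == 2)
      stats::runif(n_tip, completeness[1], completeness[2])
    else stop("completeness must be a scalar, a per-taxon vector, or a range")

  tip_states <- states[seq_len(n_tip), , drop = FALSE]
  mask <- matrix(stats::runif(n_tip * n_char), n_tip, n_char) > targets
  masked <- ifelse(mask, "", as.character(tip_states))
  lost <- which(colSums(masked != "") == 0)
  for (ch in lost) {
    keep <- which.max(targets)
    masked[keep, ch] <- as.character(tip_states[keep, ch])
  }
  rownames(masked) <- tree$tip.label
  list(matrix = character_matrix(masked),
       truth = list(tip_states = tip_states, node_states = states,
                    rates = rate, completeness_targets = targets,
                    branch_scalars = branch_scalars, seed = seed))
}

## edge indices ordered so parent edges are visited before child edges
.preorder_edges <- function(tree) {
  rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
}

#' Branch rate scalars for a planted fast clade
#'
#' Picks the internal node whose clade has close to `n_tips_clade` tips
#' (preferring, among candidates within +/-3 tips, the clade with the
#' largest summed branch duration, i.e. the most evidence-bearing one) and
#' assigns scalar `r` to every branch of that clade including its stem.
#'
#' @param tree a `dated_tree`.
#' @param n_tips_clade target clade size in tips.
#' @param r scalar for the clade branches.
#' @return numeric vector, one scalar per edge; attribute `clade_node`
#'   gives the chosen node.
#' @export
plant_clade_scalars <- function(tree, n_tips_clade = 10, r = 10) {
  n_tip <- ape::Ntip(tree)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  ntips <- integer(n_tip + tree$Nnode); ntips[seq_len(n_tip)] <- 1L
  for (e in seq_len(nrow(post)))
    ntips[post[e, 1]] <- ntips[post[e, 1]] + ntips[post[e, 2]]
  cands <- which(ntips >= n_tips_clade - 3 & ntips <= n_tips_clade + 3)
  cands <- cands[cands > n_tip]
  if (!length(cands)) stop("no clade close to the requested size")
  durs <- tree$node.ages[tree$edge[, 1]] - tree$node.ages[tree$edge[, 2]]
  clade_edges <- function(node) {
    desc <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]; desc <- c(desc, v)
      stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
    }
    which(tree$edge[, 2] %in% desc)
  }
  node <- cands[which.max(vapply(cands,
                                 function(v) sum(durs[clade_edges(v)]), 0))]
  scal <- rep(1, nrow(tree$edge))
  scal[clade_edges(node)] <- r
  attr(scal, "clade_node") <- node
  scal
}

#' Simulate a continuous trait under variable-rates Brownian motion
#'
#' Gaussian increments with variance `sigma2 * r * duration` per branch,
#' accumulated root to tip. Branch scalars `r` plant known rate
#' heterogeneity (see [early_burst_scalars()]).
#'
#' @param tree a `dated_tree`.
#' @param sigma2 base Brownian variance (trait^2 per my).
#' @param scalars per-edge rate scalars (default all 1).
#' @param root_state trait value at the root.
#' @param seed integer seed.
#' @return list: `trait` (named vector over tips), `truth` (list with node
#'   values, `sigma2`, `scalars`, `seed`).
#' @export
simulate_trait_vr <- function(tree, sigma2 = 1, scalars = NULL,
                              root_state = 0, seed = NULL) {
  stopifnot(sigma2 > 0)
  if (!is.null(seed)) set.seed(seed)
  n_edge <- nrow(tree$edge)
  if (is.null(scalars)) scalars <- rep(1, n_edge)
  stopifnot(length(scalars) == n_edge, all(scalars >= 0))
  n_tip <- ape::Ntip(tree)
  vals <- numeric(n_tip + tree$Nnode)
  vals[n_tip + 1L] <- root_state
  ord <- .preorder_edges(tree)
  durs <- tree$node.ages[tree$edge[, 1]] - tree$node.ages[tree$edge[, 2]]
  incs <- stats::rnorm(n_edge, 0, sqrt(sigma2 * scalars * durs))
  for (k in ord)
    vals[tree$edge[k, 2]] <- vals[tree$edge[k, 1]] + incs[k]
  trait <- vals[seq_len(n_tip)]
  names(trait) <- tree$tip.label
  list(trait = trait,
       truth = list(node_values = vals, sigma2 = sigma2, scalars = scalars,
                    seed = seed))
}

#' Simulate stratigraphic ranges around true tip ages
#'
#' For each tip, FAD and LAD are drawn uniformly between the tip's true age
#' and `min(parent age, tip age + window)`, so the range lies within the
#' tip's subtending branch and `FAD >= LAD` always holds; `window = 0`
#' collapses both to the true tip age.
#'
#' @param tree a `dated_tree`.
#' @param window maximum range width in my (>= 0).
#' @param seed integer seed.
#' @return list: `ranges` (data frame `taxon`, `fad`, `lad`), `truth`
#'   (true tip ages, seed).
#' @export
simulate_strat_ranges <- function(tree, window = 5, seed = NULL) {
  stopifnot(window >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_tip <- ape::Ntip(tree)
  parent <- integer(n_tip)
  parent[tree$edge[, 2][tree$edge[, 2] <= n_tip]] <-
    tree$edge[, 1][tree$edge[, 2] <= n_tip]
  tip_age <- tree$node.ages[seq_len(n_tip)]
  upper <- pmin(tree$node.ages[parent], tip_age + window)
  u1 <- stats::runif(n_tip, tip_age, upper)
  u2 <- stats::runif(n_tip, tip_age, upper)
  ranges <- data.frame(taxon = tree$tip.label,
                       fad = pmax(u1, u2), lad = pmin(u1, u2),
                       stringsAsFactors = FALSE)
  list(ranges = ranges,
       truth = list(tip_ages = stats::setNames(tip_age, tree$tip.label),
                    seed = seed))
}

#' Generate a complete synthetic study
#'
#' One call producing every input of the full analysis with known ground
#' truth, shaped like a Mesozoic marine-reptile dataset: a birth-death tree
#' with extinct tips spanning 160 my ending at ~91 Ma, discrete characters
#' with a 1-95% per-taxon completeness spread evolving faster (x
#' `char_burst_r`) on the oldest third of the tree, a log-scale trait with
#' planted early-burst scalars (x `trait_burst_r`), stratigraphic windows
#' per tip, and a ladder of outgroup ages older than the root.
#'
#' @param n_taxa,n_char problem size (defaults 115 taxa, 250 characters).
#' @param char_rate base Mk rate per my.
#' @param char_burst_r,trait_burst_r planted rate multipliers on branches
#'   older than the cutoff (oldest third of the tree).
#' @param sigma2 base Brownian variance for the trait (log10 units^2/my).
#' @param seed integer seed (drives every stage deterministically).
#' @return list: `tree`, `matrix`, `trait`, `ranges`, `outgroup_ages`,
#'   `bins`, and `truth` (per-stage truth records).
#' @export
simulate_scenario <- function(n_taxa = 115, n_char = 250,
                              char_rate = 0.004, char_burst_r = 5,
                              trait_burst_r = 10, sigma2 = 5e-4,
                              seed = 1) {
  tree <- simulate_tree(n_taxa, birth = 0.12, death = 0.09, span = 160,
                        youngest_age = 91.3, seed = seed)
  char_scalars <- early_burst_scalars(tree, r = char_burst_r)
  chars <- simulate_characters(tree, n_char = n_char, rate = char_rate,
                               completeness = c(0.01, 0.95),
                               branch_scalars = char_scalars,
                               seed = seed + 1)
  trait_scalars <- early_burst_scalars(tree, r = trait_burst_r)
  trait <- simulate_trait_vr(tree, sigma2 = sigma2,
                             scalars = trait_scalars, root_state = 2.5,
                             seed = seed + 2)
  ranges <- simulate_strat_ranges(tree, window = 5, seed = seed + 3)
  outgroup_ages <- tree$root.time + c(4, 9, 15, 22, 30, 40)
  list(tree = tree, matrix = chars$matrix, trait = trait$trait,
       ranges = ranges$ranges, outgroup_ages = outgroup_ages,
       bins = make_bins("equal", oldest = tree$root.time,
                        youngest = min(tree$node.ages[seq_len(n_taxa)])),
       truth = list(tree = attr(tree, "truth"), characters = chars$truth,
                    trait = trait$truth, ranges = ranges$truth,
                    char_scalars = char_scalars,
                    trait_scalars = trait_scalars, seed = seed))
}
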