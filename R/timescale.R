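#' Dated trees
#'
#' A `dated_tree` is an `ape` `phylo` tree whose tips and nodes carry
#' absolute ages in Ma: `node.ages` holds one age per tip and node (indexed
#' as in `phy$edge`), `edge.length` holds branch durations in my
#' (parent age minus child age), and `root.time` is the root age. Every
#' parent is strictly older than each of its children.
#'
#' @param phy a rooted `phylo` topology.
#' @param ages numeric vector of ages (Ma) for tips then nodes, indexed by
#'   the `phylo` node numbering.
#' @return object of class `c("dated_tree", "phylo")`.
#' @export
dated_tree <- function(phy, ages) {
  stopifnot(inherits(phy, "phylo"))
  n_all <- ape::Ntip(phy) + phy$Nnode
  if (length(ages) != n_all)
    stop("`ages` must have one entry per tip and node (", n_all, ")")
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  phy$node.ages <- ages
  phy$root.time <- ages[ape::Ntip(phy) + 1L]
  class(phy) <- c("dated_tree", "phylo")
  validate_dated_tree(phy)
  phy
}

#' Validate a dated tree
#'
#' Checks the dating invariants: finite positive ages, every parent
#' strictly older than each child (all branch durations positive).
#'
#' @param tree a `dated_tree`.
#' @param ranges optional stratigraphic range table; if given, each tip age
#'   must lie within that taxon's `[LAD, FAD]`.
#' @return `tree`, invisibly; errors describe any violation.
#' @export
validate_dated_tree <- function(tree, ranges = NULL) {
  ages <- tree$node.ages
  if (any(!is.finite(ages)) || any(ages < 0))
    stop("ages must be finite and non-negative")
  dur <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (any(dur <= 0))
    stop("every parent must be strictly older than its children; ",
         sum(dur <= 0), " branch(es) violate this")
  if (!is.null(ranges)) {
    ranges <- .check_ranges(ranges)
    tips <- tree$tip.label
    idx <- match(tips, ranges$taxon)
    ta <- ages[seq_along(tips)]
    bad <- which(!is.na(idx) &
                 (ta > ranges$fad[idx] + 1e-9 | ta < ranges$lad[idx] - 1e-9))
    if (length(bad))
      stop("tip ages outside stratigraphic range: ",
           paste(tips[bad], collapse = ", "))
  }
  invisible(tree)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("Dated tree: %d tips, root age %.2f Ma, tip ages %.2f-%.2f Ma\n",
              ape::Ntip(x), x$root.time,
              max(x$node.ages[seq_len(ape::Ntip(x))]),
              min(x$node.ages[seq_len(ape::Ntip(x))])))
  invisible(x)
}

#' Draw point tip ages from stratigraphic ranges
#'
#' Each taxon's age is drawn independently from a uniform distribution on
#' `[LAD, FAD]`.
#'
#' @param ranges stratigraphic range table (`taxon`, `fad`, `lad`).
#' @param seed integer seed.
#' @return named numeric vector of ages (Ma).
#' @export
sample_tip_dates <- function(ranges, seed = NULL) {
  ranges <- .check_ranges(ranges)
  if (!is.null(seed)) set.seed(seed)
  ages <- stats::runif(nrow(ranges), min = ranges$lad, max = ranges$fad)
  names(ages) <- ranges$taxon
  ages
}

#' Minimum branch length time-scaling
#'
#' Each node starts at the age of its oldest descendant tip, then ages are
#' propagated rootward so that every branch lasts at least `min_length` my.
#'
#' @param topology a rooted `phylo`.
#' @param tip_ages named vector of tip ages (Ma).
#' @param min_length minimum branch duration in my (> 0).
#' @return a [dated_tree()].
#' @export
mbl_date_tree <- function(topology, tip_ages, min_length = 1) {
  if (min_length <= 0) stop("`min_length` must be positive")
  phy <- topology
  n_tip <- ape::Ntip(phy)
  ages <- numeric(n_tip + phy$Nnode)
  ages[seq_len(n_tip)] <- tip_ages[phy$tip.label]
  if (anyNA(ages[seq_len(n_tip)]))
    stop("tip ages missing for: ",
         paste(phy$tip.label[is.na(tip_ages[phy$tip.label])], collapse = ", "))
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    par <- eo[k, 1]; chd <- eo[k, 2]
    ages[par] <- max(ages[par], ages[chd] + min_length)
  }
  dated_tree(phy, ages)
}

#' Bayesian node dating from successive outgroup ages
#'
#' Whole-tree extension of outgroup-constrained Bayesian node dating. For
#' each internal node, the ladder of calibrating older observations is the
#' node's own oldest descendant age followed by the max-accumulated oldest
#' ages of the successively more inclusive sister clades along the path to
#' the root, with the supplied outgroup first-appearance ages appended
#' beyond the root. Conditional on the next divergence rootward at age `y`,
#' a divergence with lower bound `b` is taken uniform on `(b, y)`; the
#' rootmost divergence is uniform between its bound and the hard upper
#' limit `t0`. Marginal posteriors are propagated inward on a discrete age
#' grid by midpoint quadrature and each node's age is its posterior mean;
#' a final postorder pass enforces parent > child by one grid step where
#' the marginal means violate it.
#'
#' @param topology rooted, binary `phylo`.
#' @param tip_ages named vector of tip ages (Ma).
#' @param outgroup_ages first-appearance ages (Ma) of successive outgroups,
#'   strictly increasing rootward.
#' @param resolution number of grid cells (>= 100).
#' @param t0 hard older bound of the grid (Ma); default oldest outgroup age
#'   plus 20 my.
#' @return a [dated_tree()].
#' @export
hedman_date_tree <- function(topology, tip_ages, outgroup_ages,
                             resolution = 1000, t0 = NULL) {
  phy <- topology
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("resolve polytomies first: topology must be rooted and binary")
  if (resolution < 100) stop("`resolution` must be at least 100")
  if (is.unsorted(outgroup_ages, strictly = TRUE))
    stop("outgroup ages must be strictly increasing rootward")
  n_tip <- ape::Ntip(phy)
  ages <- numeric(n_tip + phy$Nnode)
  ages[seq_len(n_tip)] <- tip_ages[phy$tip.label]
  if (anyNA(ages[seq_len(n_tip)])) stop("tip ages missing for some tips")
  if (is.null(t0)) t0 <- max(outgroup_ages) + 20
  if (any(outgroup_ages <= max(ages[seq_len(n_tip)])))
    warning("some outgroup ages are not older than the oldest ingroup tip")
  if (t0 <= max(c(outgroup_ages, ages[seq_len(n_tip)])))
    stop("`t0` must exceed every tip and outgroup age")

  ## oldest descendant tip age per clade
  clade_max <- ages
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    clade_max[eo[k, 1]] <- max(clade_max[eo[k, 1]], clade_max[eo[k, 2]])

  parent <- integer(n_tip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- n_tip + 1L
  children <- split(phy$edge[, 2], phy$edge[, 1])

  step <- (t0 - min(ages[seq_len(n_tip)])) / resolution
  for (nd in (n_tip + 1L):(n_tip + phy$Nnode)) {
    bounds <- clade_max[nd]
    at <- nd
    while (at != root) {
      sibs <- setdiff(children[[as.character(parent[at])]], at)
      sib_age <- max(clade_max[sibs])
      bounds <- c(bounds, max(bounds[length(bounds)], sib_age))
      at <- parent[at]
    }
    for (o in outgroup_ages)
      bounds <- c(bounds, max(bounds[length(bounds)], o))
    ages[nd] <- hedman_posterior(bounds, t0, resolution)$mean
  }
  for (k in seq_len(nrow(eo))) {
    par <- eo[k, 1]; chd <- eo[k, 2]
    if (ages[par] <= ages[chd]) ages[par] <- ages[chd] + step
  }
  dated_tree(phy, ages)
}

#' Posterior of a divergence age under an outgroup-age ladder
#'
#' Grid recursion used by [hedman_date_tree()], exposed for diagnostics and
#' oracle testing. `bounds` gives the non-decreasing lower bounds of the
#' successive divergences from the target (first) rootward (last); the
#' rootmost divergence is uniform on `(bounds[m], t0)` and each divergence
#' inward is uniform between its bound and the next divergence rootward.
#'
#' @param bounds non-decreasing numeric vector of lower bounds (Ma).
#' @param t0 hard older limit (Ma), greater than `max(bounds)`.
#' @param resolution number of grid cells.
#' @return list: `grid` (cell midpoints, ascending ages), `density`
#'   (normalised so `sum(density * step) == 1`), `mean`, `step`.
#' @export
hedman_posterior <- function(bounds, t0, resolution = 1000) {
  m <- length(bounds)
  if (is.unsorted(bounds)) stop("`bounds` must be non-decreasing")
  if (t0 <= bounds[m]) stop("`t0` must exceed the largest bound")
  lo <- bounds[1]
  dx <- (t0 - lo) / resolution
  x <- lo + dx * (seq_len(resolution) - 0.5)
  q <- as.numeric(x > bounds[m])
  q <- q / (sum(q) * dx)
  if (m > 1) {
    for (k in (m - 1):1) {
      contrib <- ifelse(x > bounds[k], q * dx / (x - bounds[k]), 0)
      tail_sums <- rev(cumsum(rev(contrib)))
      q_new <- c(tail_sums[-1], 0)        # integrate over y strictly above x
      q_new[x <= bounds[k]] <- 0
      s <- sum(q_new) * dx
      if (s <= 0) stop("degenerate posterior: check bounds and t0")
      q <- q_new / s
    }
  }
  list(grid = x, density = q, mean = sum(x * q) * dx, step = dx)
}

#' Date a sample of trees with resampled tip ages
#'
#' Batch driver mirroring the protocol of dating many posterior topologies:
#' tip ages are redrawn from their stratigraphic ranges for every tree so
#' the dated sample embeds both phylogenetic and dating uncertainty; trees
#' whose dating fails are logged and skipped, and the first `n_keep`
#' successes are retained (supply more trees than `n_keep` to oversample).
#'
#' @param trees list of `phylo` topologies (or a `multiPhylo`).
#' @param ranges stratigraphic range table for the tips.
#' @param method `"hedman"` or `"mbl"`.
#' @param outgroup_ages outgroup age ladder (required for `"hedman"`).
#' @param n_keep number of dated trees to retain (default: all that
#'   succeed).
#' @param min_length minimum branch duration for `"mbl"`.
#' @param resolution,t0 grid controls for `"hedman"`.
#' @param seed integer seed for the tip-age draws.
#' @return list of `dated_tree`s with attribute `failures` (data frame of
#'   tree index and error message).
#' @export
date_tree_sample <- function(trees, ranges, method = c("hedman", "mbl"),
                             outgroup_ages = NULL, n_keep = NULL,
                             min_length = 1, resolution = 1000, t0 = NULL,
                             seed = NULL) {
  method <- match.arg(method)
  if (method == "hedman" && is.null(outgroup_ages))
    stop("`outgroup_ages` required for the hedman method")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- list()
  fails <- data.frame(tree = integer(0), error = character(0),
                      stringsAsFactors = FALSE)
  for (i in seq_along(trees)) {
    if (!is.null(n_keep) && length(out) >= n_keep) break
    tip_ages <- sample_tip_dates(ranges)
    res <- tryCatch({
      if (method == "hedman")
        hedman_date_tree(trees[[i]], tip_ages, outgroup_ages,
                         resolution = resolution, t0 = t0)
      else
        mbl_date_tree(trees[[i]], tip_ages, min_length = min_length)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails <- rbind(fails, data.frame(tree = i,
                                       error = conditionMessage(res),
                                       stringsAsFactors = FALSE))
    } else {
      out[[length(out) + 1]] <- res
    }
  }
  if (!is.null(n_keep) && length(out) < n_keep)
    warning(sprintf("only %d of the requested %d trees dated successfully",
                    length(out), n_keep))
  attr(out, "failures") <- fails
  out
}

#' Write dated trees as Newick plus a root-age sidecar CSV
#'
#' Branch lengths in the Newick file are durations in my; absolute ages are
#' recoverable from the sidecar root ages.
#'
#' @param trees list of `dated_tree`s.
#' @param newick_path,csv_path output paths.
#' @return invisibly, the paths.
#' @export
write_dated_trees <- function(trees, newick_path, csv_path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  cls <- lapply(trees, function(t) { class(t) <- "phylo"; t })
  class(cls) <- "multiPhylo"
  ape::write.tree(cls, file = newick_path)
  utils::write.csv(
    data.frame(tree = seq_along(trees),
               root_age = vapply(trees, function(t) t$root.time, 0)),
    csv_path, row.names = FALSE)
  invisible(c(newick_path, csv_path))
}

#' Read outgroup age constraints
#'
#' CSV with columns `name`, `age` (Ma); returned ages are sorted increasing
#' rootward as required by [hedman_date_tree()].
#'
#' @param path CSV file path.
#' @return named numeric vector of ages.
#' @export
read_outgroup_ages <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("name", "age") %in% names(df)))
    stop("outgroup CSV must have columns name, age")
  ages <- sort(df$age)
  names(ages) <- df$name[order(df$age)]
  if (anyDuplicated(ages)) stop("outgroup ages must be strictly increasing")
  ages
}
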