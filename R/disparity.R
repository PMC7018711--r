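#' Per-bin disparity from pairwise distances
#'
#' Point estimate, bootstrap mean and 95% percentile confidence interval of
#' mean pairwise dissimilarity for a set of taxa. The unweighted estimate is
#' the mean of the upper-triangle distances over member pairs; the weighted
#' estimate is `sum(D * C) / sum(C)` over the same pairs, down-weighting
#' pairs compared over few characters. Bootstrapping resamples taxa with
#' replacement (500 replicates by default); pairs of resampled slots that
#' point at the same original taxon are excluded.
#'
#' @param dist a `morph_dist`.
#' @param members character vector of taxa (subset of `dist$taxa`).
#' @param weighted logical; weight pairs by comparable-character counts.
#' @param n_boot bootstrap replicates (>= 1).
#' @param seed integer seed for the bootstrap.
#' @return list (class `disparity_cell`): `n`, `estimate`, `boot_mean`,
#'   `ci_lo`, `ci_hi`, `metric`, `defined`. Bins with fewer than 2 members
#'   are flagged `defined = FALSE` with `NA` values.
#' @export
pairwise_disparity <- function(dist, members, weighted = FALSE,
                               n_boot = 500, seed = NULL) {
  stopifnot(inherits(dist, "morph_dist"), n_boot >= 1)
  missing_taxa <- setdiff(members, dist$taxa)
  if (length(missing_taxa))
    stop("members not in distance matrix: ",
         paste(missing_taxa, collapse = ", "))
  metric <- paste0(if (weighted) "weighted ", "pairwise ", dist$metric)
  if (length(members) < 2)
    return(.undefined_cell(length(members), metric))
  idx <- match(members, dist$taxa)
  D <- dist$D[idx, idx, drop = FALSE]
  C <- dist$C[idx, idx, drop = FALSE]

  est <- .pair_stat(D, C, seq_along(members), weighted)
  if (!is.null(seed)) set.seed(seed)
  boots <- replicate(n_boot, {
    s <- sample(length(members), replace = TRUE)
    .pair_stat(D, C, s, weighted)
  })
  boots <- boots[!is.na(boots)]
  if (!length(boots)) boots <- est
  structure(list(n = length(members), estimate = est,
                 boot_mean = mean(boots),
                 ci_lo = unname(stats::quantile(boots, 0.025)),
                 ci_hi = unname(stats::quantile(boots, 0.975)),
                 metric = metric, defined = TRUE),
            class = "disparity_cell")
}

## mean (or C-weighted mean) distance over pairs of the index multiset,
## excluding pairs that reference the same original taxon
.pair_stat <- function(D, C, s, weighted) {
  ds <- D[s, s, drop = FALSE]; cs <- C[s, s, drop = FALSE]
  same <- outer(s, s, `==`)
  ut <- upper.tri(ds) & !same & !is.na(ds)
  if (!any(ut)) return(NA_real_)
  if (weighted) {
    cw <- sum(cs[ut])
    if (cw == 0) return(NA_real_)
    sum(ds[ut] * cs[ut]) / cw
  } else {
    mean(ds[ut])
  }
}

.undefined_cell <- function(n, metric) {
  structure(list(n = n, estimate = NA_real_, boot_mean = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, metric = metric,
                 defined = FALSE),
            class = "disparity_cell")
}

#' Rarefied disparity at a fixed subsample size
#'
#' Repeatedly subsamples `n_sub` members without replacement, recomputes the
#' disparity metric, and summarises the replicate distribution. Used to ask
#' whether between-bin disparity differences are artefacts of sample size.
#'
#' @inheritParams pairwise_disparity
#' @param metric `"pairwise"` or `"weighted"`.
#' @param n_sub subsample size, `2 <= n_sub <= length(members)`.
#' @param reps number of subsampling replicates.
#' @return list: `n_sub`, `mean`, `ci_lo`, `ci_hi`, `reps`.
#' @export
rarefy_disparity <- function(dist, members, metric = c("pairwise", "weighted"),
                             n_sub, reps = 500, seed = NULL) {
  metric <- match.arg(metric)
  if (n_sub > length(members)) stop("n_sub exceeds the number of members")
  if (n_sub < 2) stop("n_sub must be at least 2")
  idx <- match(members, dist$taxa)
  if (anyNA(idx)) stop("members not in distance matrix")
  D <- dist$D[idx, idx, drop = FALSE]
  C <- dist$C[idx, idx, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  vals <- replicate(reps, {
    s <- sample(length(members), n_sub)
    .pair_stat(D, C, s, metric == "weighted")
  })
  vals <- vals[!is.na(vals)]
  list(n_sub = n_sub, mean = mean(vals),
       ci_lo = unname(stats::quantile(vals, 0.025)),
       ci_hi = unname(stats::quantile(vals, 0.975)),
       reps = reps)
}

#' Morphospace disparity metrics on ordination axes
#'
#' Sum of per-axis sample variances, sum of per-axis ranges, or mean
#' Euclidean distance of members to their centroid, with a taxon bootstrap
#' as in [pairwise_disparity()]. All three are invariant to translation of
#' the morphospace.
#'
#' @param ord an [morph_pcoa()] result.
#' @param members character vector of taxa.
#' @param metric `"sum_of_variances"`, `"sum_of_ranges"` or
#'   `"centroid_distance"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return a `disparity_cell` (see [pairwise_disparity()]).
#' @export
ordination_disparity <- function(ord, members,
                                 metric = c("sum_of_variances",
                                            "sum_of_ranges",
                                            "centroid_distance"),
                                 n_boot = 500, seed = NULL) {
  stopifnot(inherits(ord, "ordination"))
  metric <- match.arg(metric)
  if (!all(members %in% ord$taxa))
    stop("members not in ordination: ",
         paste(setdiff(members, ord$taxa), collapse = ", "))
  need <- if (metric == "centroid_distance") 1L else 2L
  if (length(members) < need)
    return(.undefined_cell(length(members), metric))
  X <- ord$coords[match(members, ord$taxa), , drop = FALSE]
  f <- switch(metric,
    sum_of_variances = function(M) sum(apply(M, 2, stats::var)),
    sum_of_ranges = function(M) sum(apply(M, 2, function(v) diff(range(v)))),
    centroid_distance = function(M) {
      ctr <- colMeans(M)
      mean(sqrt(rowSums(sweep(M, 2, ctr)^2)))
    })
  est <- f(X)
  if (!is.null(seed)) set.seed(seed)
  boots <- replicate(n_boot, f(X[sample(nrow(X), replace = TRUE), ,
                                 drop = FALSE]))
  structure(list(n = length(members), estimate = est,
                 boot_mean = mean(boots),
                 ci_lo = unname(stats::quantile(boots, 0.025)),
                 ci_hi = unname(stats::quantile(boots, 0.975)),
                 metric = metric, defined = TRUE),
            class = "disparity_cell")
}

#' Disparity through time
#'
#' Convenience wrapper: assigns taxa to bins and computes a disparity cell
#' per bin, returning a tidy series.
#'
#' @param dist a `morph_dist`.
#' @param ranges stratigraphic range table (see [read_strat_ranges()]).
#' @param bins a [make_bins()] result.
#' @param weighted logical, weight by comparable characters.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return data frame (class `disparity_series`): one row per bin with
#'   `bin`, `old`, `young`, `n`, `estimate`, `boot_mean`, `ci_lo`, `ci_hi`.
#' @export
disparity_through_time <- function(dist, ranges, bins, weighted = FALSE,
                                   n_boot = 500, seed = NULL) {
  members <- assign_taxa_to_bins(ranges, bins)
  members <- lapply(members, intersect, y = dist$taxa)
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    cell <- pairwise_disparity(dist, members[[i]], weighted = weighted,
                               n_boot = n_boot,
                               seed = if (is.null(seed)) NULL else seed + i)
    data.frame(bin = bins$label[i], old = bins$old[i], young = bins$young[i],
               n = cell$n, estimate = cell$estimate,
               boot_mean = cell$boot_mean,
               ci_lo = cell$ci_lo, ci_hi = cell$ci_hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("disparity_series", "data.frame")
  out
}
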