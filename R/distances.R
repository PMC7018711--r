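#' Inter-taxon morphological distance matrices
#'
#' Converts a discrete character matrix into a pairwise dissimilarity matrix
#' `D` paired with a comparable-character-count matrix `C`. A character is
#' comparable for a pair of taxa iff both taxa code it. Per-character
#' differences are 0/1 for unordered characters (equal/unequal state sets,
#' with polymorphism scored as the minimum over cross-pairs of states, so
#' overlapping sets differ by 0) and the minimum absolute state difference
#' for ordered characters.
#'
#' Metrics:
#' \describe{
#'   \item{RAW}{Euclidean norm of the per-character differences over
#'     comparable characters.}
#'   \item{GED}{generalised Euclidean distance: incomparable characters are
#'     imputed with the mean per-character difference over all comparable
#'     cells of the whole matrix before taking the Euclidean norm, so GED is
#'     always defined.}
#'   \item{GOW}{Gower: sum of differences divided by the number of
#'     comparable characters.}
#'   \item{MORD}{maximum observable rescaled distance: sum of differences
#'     divided by the summed maximum attainable difference of the comparable
#'     characters (1 for an unordered character with at least two observed
#'     states, the observed state range for an ordered character, 0 for an
#'     invariant character, which therefore contributes to neither numerator
#'     nor denominator). Bounded in `[0, 1]`.}
#' }
#' Pairs with no comparable characters are `NA` under RAW, GOW and MORD.
#'
#' @param matrix a [character_matrix()].
#' @param metric one of `"mord"`, `"gow"`, `"raw"`, `"ged"`
#'   (case-insensitive).
#' @return an object of class `morph_dist`: list with `D` (symmetric
#'   dissimilarity matrix, zero diagonal), `C` (symmetric comparable-count
#'   matrix; diagonal = number of coded characters per taxon), `metric`,
#'   `taxa` and `n_char`.
#' @examples
#' m <- character_matrix(rbind(A = c("0", "1", ""), B = c("1", "1", "0")))
#' morph_distance_matrix(m, "gow")$D
#' @export
morph_distance_matrix <- function(matrix, metric = c("mord", "gow", "raw", "ged")) {
  stopifnot(inherits(matrix, "char_matrix"))
  metric <- toupper(match.arg(tolower(metric[1]),
                              c("mord", "gow", "raw", "ged")))
  n <- length(matrix$taxa)
  if (n < 2) stop("need at least 2 taxa")

  Dsum <- matrix(0, n, n); Sq <- matrix(0, n, n)
  C <- matrix(0L, n, n); Msum <- matrix(0, n, n)
  tot_d <- 0; tot_n <- 0

  for (ch in seq_len(matrix$n_char)) {
    cells <- .cell_sets(matrix$states[, ch])
    ordered <- matrix$ordering[ch] == "ordered"
    d <- .char_diff_matrix(cells, ordered)
    cmp <- !is.na(d)
    obs <- unique(unlist(cells))
    m_c <- if (length(obs) < 2) 0
           else if (ordered) max(obs) - min(obs) else 1
    Dsum[cmp] <- Dsum[cmp] + d[cmp]
    Sq[cmp] <- Sq[cmp] + d[cmp]^2
    C <- C + cmp
    Msum[cmp] <- Msum[cmp] + m_c
    ut <- cmp & upper.tri(cmp)
    tot_d <- tot_d + sum(d[ut]); tot_n <- tot_n + sum(ut)
  }

  off <- !diag(n)
  undef <- C == 0 & off
  D <- switch(metric,
    RAW = { out <- sqrt(Sq); out[undef] <- NA_real_; out },
    GOW = { out <- Dsum / ifelse(C > 0, C, NA_real_); out[undef] <- NA_real_; out },
    MORD = {
      stopifnot(!any(Msum == 0 & Dsum > 0)) # impossible by construction
      out <- ifelse(Msum > 0, Dsum / Msum, 0)
      out[undef] <- NA_real_; out
    },
    GED = {
      gmean <- if (tot_n > 0) tot_d / tot_n else 0
      sqrt(Sq + (matrix$n_char - C) * gmean^2)
    })
  diag(D) <- 0
  dimnames(D) <- dimnames(C) <- list(matrix$taxa, matrix$taxa)
  structure(list(D = D, C = C, metric = metric, taxa = matrix$taxa,
                 n_char = matrix$n_char),
            class = "morph_dist")
}

## per-character difference matrix; NA where either cell is uncoded
.char_diff_matrix <- function(cells, ordered) {
  n <- length(cells)
  sizes <- lengths(cells)
  miss <- sizes == 0L
  v <- rep(NA_real_, n)
  single <- sizes == 1L
  v[single] <- vapply(cells[single], function(s) as.numeric(s[1]), 0)
  d <- if (ordered) abs(outer(v, v, `-`)) else (outer(v, v, `!=`)) * 1
  for (i in which(sizes > 1L)) {
    for (j in seq_len(n)) {
      if (miss[j] || i == j) next
      dij <- if (ordered) {
        min(abs(outer(cells[[i]], cells[[j]], `-`)))
      } else {
        as.numeric(!any(cells[[i]] %in% cells[[j]]))
      }
      d[i, j] <- dij; d[j, i] <- dij
    }
  }
  d[miss, ] <- NA_real_; d[, miss] <- NA_real_
  diag(d)[!miss] <- 0
  d
}

#' @export
print.morph_dist <- function(x, ...) {
  n_na <- sum(is.na(x$D[upper.tri(x$D)]))
  cat(sprintf("%s distance matrix: %d taxa, %d undefined pair(s)\n",
              x$metric, length(x$taxa), n_na))
  invisible(x)
}

#' Remove taxa until every pair of the distance matrix is defined
#'
#' Iteratively removes the taxon involved in the largest number of undefined
#' (no comparable characters) pairs; ties are broken by removing the least
#' complete taxon (fewest coded characters, read from `diag(C)`), remaining
#' ties lexicographically. The removal log records the order and reason.
#'
#' @param dist a [morph_distance_matrix()] result, possibly with `NA`
#'   entries.
#' @return list with `dist` (trimmed `morph_dist`), `removed` (character
#'   vector in removal order) and `log` (data frame: taxon, n_undefined,
#'   reason).
#' @export
trim_distance_matrix <- function(dist) {
  stopifnot(inherits(dist, "morph_dist"))
  D <- dist$D; C <- dist$C
  n <- nrow(D)
  undef <- is.na(D); diag(undef) <- FALSE
  if (all(undef[upper.tri(undef)]))
    stop("matrix fully incomparable")
  keep <- rep(TRUE, n)
  log <- data.frame(taxon = character(0), n_undefined = integer(0),
                    reason = character(0), stringsAsFactors = FALSE)
  repeat {
    u <- undef[keep, keep, drop = FALSE]
    if (!any(u)) break
    if (sum(keep) <= 2) stop("matrix fully incomparable")
    counts <- rowSums(u)
    cand <- which(counts == max(counts))
    reason <- "most undefined pairs"
    if (length(cand) > 1) {
      compl <- diag(C)[keep][cand]
      cand <- cand[compl == min(compl)]
      reason <- "tie: least complete"
    }
    if (length(cand) > 1) {
      labs <- rownames(u)[cand]
      cand <- cand[order(labs)][1]
      reason <- "tie: lexicographic"
    }
    victim <- rownames(u)[cand[1]]
    log <- rbind(log, data.frame(taxon = victim,
                                 n_undefined = max(counts),
                                 reason = reason,
                                 stringsAsFactors = FALSE))
    keep[match(victim, rownames(D))] <- FALSE
  }
  out <- dist
  out$D <- D[keep, keep, drop = FALSE]
  out$C <- C[keep, keep, drop = FALSE]
  out$taxa <- dist$taxa[keep]
  list(dist = out, removed = log$taxon, log = log)
}

#' Export D and C matrices as CSV
#'
#' Writes taxon-labelled CSV files of the dissimilarity matrix and, if
#' `c_path` is given, the comparable-character-count matrix.
#'
#' @param dist a `morph_dist`.
#' @param d_path,c_path output file paths (`c_path` optional).
#' @return invisibly, the paths written.
#' @export
write_distance_csv <- function(dist, d_path, c_path = NULL) {
  stopifnot(inherits(dist, "morph_dist"))
  utils::write.csv(dist$D, d_path, row.names = TRUE)
  if (!is.null(c_path)) utils::write.csv(dist$C, c_path, row.names = TRUE)
  invisible(c(d_path, c_path))
}
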