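#' Principal coordinates analysis of a morphological distance matrix
#'
#' Classical PCoA by Gower double-centring of `-D^2/2` followed by
#' eigendecomposition. Distance matrices derived from incomplete character
#' data are usually non-Euclidean and produce negative eigenvalues; two
#' corrections are offered. Cailliez adds the smallest constant `c` to every
#' off-diagonal distance that makes the configuration Euclidean; Lingoes
#' adds a constant to the squared off-diagonal distances
#' (`d'^2 = d^2 + 2c`, with `c` the magnitude of the most negative
#' eigenvalue). Axes whose eigenvalue magnitude is below `1e-10` times the
#' largest are dropped; coordinates are returned for positive-eigenvalue
#' axes, sorted by descending eigenvalue.
#'
#' @param dist a `morph_dist` (must contain no undefined entries; see
#'   [trim_distance_matrix()]) or a plain symmetric numeric matrix.
#' @param correction `"none"`, `"cailliez"` or `"lingoes"`.
#' @return object of class `ordination`: `coords` (taxa x axes),
#'   `eigenvalues` (for the retained axes), `all_eigenvalues` (including
#'   negatives, for diagnostics), `correction`, `constant` (the additive
#'   constant applied, 0 for `"none"`) and `taxa`.
#' @examples
#' d <- as.matrix(dist(cbind(c(0, 3, 0), c(0, 0, 4))))
#' ord <- morph_pcoa(d)
#' variance_explained(ord)
#' @export
morph_pcoa <- function(dist, correction = c("none", "cailliez", "lingoes")) {
  correction <- match.arg(correction)
  D <- if (inherits(dist, "morph_dist")) dist$D else as.matrix(dist)
  taxa <- rownames(D)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(D)))
  if (anyNA(D))
    stop("distance matrix has undefined entries; run trim_distance_matrix() first")
  n <- nrow(D)
  if (n < 2) stop("need at least 2 taxa")

  constant <- 0
  if (correction == "cailliez") {
    constant <- .cailliez_constant(D)
    if (constant > 0) {
      D <- D + constant
      diag(D) <- 0
    } else constant <- 0
  } else if (correction == "lingoes") {
    ev0 <- eigen(.gower_centre(D), symmetric = TRUE, only.values = TRUE)$values
    cmin <- min(ev0)
    if (cmin < -1e-12) {
      constant <- -cmin
      D <- sqrt(D^2 + 2 * constant)
      diag(D) <- 0
    }
  }

  B <- .gower_centre(D)
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values
  tol <- 1e-10 * max(abs(vals))
  keep <- abs(vals) > tol
  vals_kept <- vals[keep]
  pos <- which(keep & vals > 0)
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), length(pos))
  rownames(coords) <- taxa
  colnames(coords) <- paste0("axis", seq_along(pos))
  structure(list(coords = coords,
                 eigenvalues = vals[pos],
                 all_eigenvalues = vals_kept,
                 correction = correction,
                 constant = constant,
                 taxa = taxa),
            class = "ordination")
}

.gower_centre <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

## Smallest additive constant making D + c Euclidean (Cailliez 1983):
## largest real eigenvalue of the 2n x 2n block matrix
## [ 0, 2*Delta1 ; -I, -4*Delta2 ], Delta1 = centred(-D^2/2),
## Delta2 = centred(-D/2).
.cailliez_constant <- function(D) {
  n <- nrow(D)
  d1 <- .gower_centre(D)
  A2 <- -0.5 * D
  J <- diag(n) - matrix(1 / n, n, n)
  d2 <- J %*% A2 %*% J
  M <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("PCoA ordination: %d taxa, %d positive axes (correction: %s)\n",
              length(x$taxa), ncol(x$coords), x$correction))
  ve <- variance_explained(x)
  cat(sprintf("  axis 1-3 variance: %s%%\n",
              paste(sprintf("%.1f", utils::head(ve, 3)), collapse = ", ")))
  invisible(x)
}

#' Percentage of variance explained per ordination axis
#'
#' Eigenvalue of each retained (positive) axis as a percentage of the sum of
#' positive eigenvalues; negative eigenvalues of an uncorrected ordination
#' are excluded from the denominator.
#'
#' @param ord an [morph_pcoa()] result.
#' @return numeric vector of percentages summing to 100.
#' @export
variance_explained <- function(ord) {
  stopifnot(inherits(ord, "ordination"))
  pos <- ord$eigenvalues[ord$eigenvalues > 0]
  if (!length(pos)) stop("no positive eigenvalues")
  100 * ord$eigenvalues / sum(pos)
}

#' Write ordination coordinates to CSV
#'
#' @param ord an `ordination`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ordination_csv <- function(ord, path) {
  stopifnot(inherits(ord, "ordination"))
  df <- data.frame(taxon = ord$taxa, ord$coords, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
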