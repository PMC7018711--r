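test_that("binning schemes produce the expected bin counts and edges", {
  eq <- make_bins("equal", oldest = 251.3, youngest = 94, width = 10)
  expect_equal(nrow(eq), 16)
  expect_equal(eq$old[1], 251.3)
  expect_equal(eq$young[1], 241.3)
  expect_true(201.3 %in% eq$young)          # Triassic-Jurassic boundary
  expect_equal(nrow(make_bins("epoch")), 8)
  expect_equal(nrow(make_bins("equal", oldest = 30, youngest = 10,
                              width = 10)), 2)
  expect_error(make_bins("equal", width = 0), "positive")
  expect_error(make_bins("equal", oldest = 10, youngest = 20), "exceed")
})

test_that("taxa join every bin their range overlaps; boundary points go to
           the younger bin", {
  bins <- make_bins("equal", oldest = 251.3, youngest = 94, width = 10)
  ranges <- data.frame(
    taxon = c("inside", "spanning", "boundary_pt", "outside"),
    fad = c(250, 243, 201.3, 60),
    lad = c(247, 239, 201.3, 50))
  expect_warning(mem <- assign_taxa_to_bins(ranges, bins), "outside")
  hits <- function(tx) names(Filter(function(v) tx %in% v, mem))
  expect_equal(hits("inside"), "251.3-241.3")
  expect_equal(hits("spanning"), c("251.3-241.3", "241.3-231.3"))
  expect_equal(hits("boundary_pt"), "201.3-191.3")
  expect_equal(hits("outside"), character(0))
})

test_that("weighted disparity reproduces the comparable-character formula", {
  D <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  D[upper.tri(D)] <- c(0.5, 0.2, 0.4)   # (A,B), (A,C), (B,C)
  D <- D + t(D)
  C <- matrix(0L, 3, 3, dimnames = dimnames(D))
  C[upper.tri(C)] <- c(2L, 5L, 5L)
  C <- C + t(C); diag(C) <- 6L
  dist <- manual_dist(D, C)
  cell <- pairwise_disparity(dist, LETTERS[1:3], weighted = TRUE,
                             n_boot = 10, seed = 1)
  expect_equal(cell$estimate, (0.5 * 2 + 0.2 * 5 + 0.4 * 5) / 12)
  expect_equal(cell$estimate, 1 / 3)
  unw <- pairwise_disparity(dist, LETTERS[1:3], n_boot = 10, seed = 1)
  expect_equal(unw$estimate, mean(c(0.5, 0.2, 0.4)))
})

test_that("degenerate member sets behave as specified", {
  D <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  C <- matrix(4L, 3, 3); dimnames(C) <- dimnames(D)
  dist <- manual_dist(D, C)
  # identical taxa: zero disparity, zero-width interval
  cell <- pairwise_disparity(dist, LETTERS[1:3], n_boot = 50, seed = 2)
  expect_equal(cell$estimate, 0)
  expect_equal(cell$ci_lo, 0)
  expect_equal(cell$ci_hi, 0)
  # fewer than two members: flagged undefined, not an error
  u <- pairwise_disparity(dist, "A", n_boot = 10)
  expect_false(u$defined)
  expect_true(is.na(u$estimate))
  # two members: estimate equals their distance
  D2 <- D; D2["A", "B"] <- D2["B", "A"] <- 0.7
  cell2 <- pairwise_disparity(manual_dist(D2, C), c("A", "B"),
                              n_boot = 10, seed = 3)
  expect_equal(cell2$estimate, 0.7)
})

test_that("weighted and unweighted disparity coincide for constant C", {
  m <- random_char_matrix(8, 30, p_missing = 0, seed = 21)
  d <- morph_distance_matrix(m, "mord")
  w <- pairwise_disparity(d, m$taxa, weighted = TRUE, n_boot = 5, seed = 1)
  u <- pairwise_disparity(d, m$taxa, weighted = FALSE, n_boot = 5, seed = 1)
  expect_equal(w$estimate, u$estimate)
})

test_that("disparity estimates are invariant to taxon ordering", {
  m <- random_char_matrix(10, 40, p_missing = 0.2, seed = 31)
  d <- morph_distance_matrix(m, "mord")
  members <- m$taxa[1:6]
  e1 <- pairwise_disparity(d, members, n_boot = 5, seed = 1)$estimate
  e2 <- pairwise_disparity(d, rev(members), n_boot = 5, seed = 1)$estimate
  expect_equal(e1, e2)
})

test_that("the bootstrap mean approaches the point estimate", {
  m <- random_char_matrix(12, 40, p_missing = 0.1, seed = 41)
  d <- morph_distance_matrix(m, "mord")
  cell <- pairwise_disparity(d, m$taxa, n_boot = 10000, seed = 99)
  # percentile machinery: interval brackets the mean
  expect_lte(cell$ci_lo, cell$boot_mean)
  expect_gte(cell$ci_hi, cell$boot_mean)
  boot_sd <- (cell$ci_hi - cell$ci_lo) / (2 * 1.96)
  se <- boot_sd / sqrt(10000)
  expect_lt(abs(cell$boot_mean - cell$estimate), max(2 * 1.96 * se, 0.005))
})

test_that("rarefaction is exact at full sample size and unbiased at n = 2", {
  m <- random_char_matrix(9, 40, p_missing = 0.1, seed = 51)
  d <- morph_distance_matrix(m, "mord")
  full <- pairwise_disparity(d, m$taxa, n_boot = 5, seed = 1)$estimate
  r_full <- rarefy_disparity(d, m$taxa, n_sub = length(m$taxa),
                             reps = 20, seed = 2)
  expect_equal(r_full$mean, full)
  expect_equal(r_full$ci_hi - r_full$ci_lo, 0)
  # n_sub = 2 draws single pairs: expectation is the mean pairwise distance
  r2 <- rarefy_disparity(d, m$taxa, n_sub = 2, reps = 4000, seed = 3)
  ut <- d$D[upper.tri(d$D)]
  se <- sd(ut) / sqrt(4000)
  expect_lt(abs(r2$mean - mean(ut)), 4 * se + 1e-8)
  expect_error(rarefy_disparity(d, m$taxa, n_sub = 50, reps = 5),
               "exceeds")
})

test_that("morphospace metrics match hand arithmetic and are
           translation-invariant", {
  coords <- matrix(c(-1, 1), 2, 1,
                   dimnames = list(c("A", "B"), "axis1"))
  ord <- structure(list(coords = coords, eigenvalues = 2,
                        taxa = c("A", "B")), class = "ordination")
  expect_equal(ordination_disparity(ord, c("A", "B"), "sum_of_variances",
                                    n_boot = 5, seed = 1)$estimate, 2)
  expect_equal(ordination_disparity(ord, c("A", "B"), "sum_of_ranges",
                                    n_boot = 5, seed = 1)$estimate, 2)
  expect_equal(ordination_disparity(ord, c("A", "B"), "centroid_distance",
                                    n_boot = 5, seed = 1)$estimate, 1)
  # single point: variance undefined, ranges and centroid collapse to 0
  expect_false(ordination_disparity(ord, "A", "sum_of_variances",
                                    n_boot = 5)$defined)
  expect_equal(ordination_disparity(ord, "A", "centroid_distance",
                                    n_boot = 5, seed = 1)$estimate, 0)
  # translation invariance
  set.seed(61)
  X <- matrix(rnorm(24), 8, 3,
              dimnames = list(paste0("t", 1:8), paste0("axis", 1:3)))
  ordX <- structure(list(coords = X, eigenvalues = c(3, 2, 1),
                         taxa = rownames(X)), class = "ordination")
  ordY <- ordX; ordY$coords <- sweep(X, 2, c(10, -4, 2), "+")
  for (metric in c("sum_of_variances", "sum_of_ranges",
                   "centroid_distance"))
    expect_equal(
      ordination_disparity(ordX, rownames(X), metric, n_boot = 5,
                           seed = 7)$estimate,
      ordination_disparity(ordY, rownames(X), metric, n_boot = 5,
                           seed = 7)$estimate, info = metric)
})

test_that("rarefied sum of variances is stable in subsample size", {
  set.seed(71)
  X <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("t", 1:20), paste0("axis", 1:3)))
  ord <- structure(list(coords = X, eigenvalues = c(3, 2, 1),
                        taxa = rownames(X)), class = "ordination")
  sov_at <- function(n_sub) {
    set.seed(1000 + n_sub)
    mean(replicate(400, {
      s <- sample(20, n_sub)
      sum(apply(X[s, , drop = FALSE], 2, var))
    }))
  }
  v <- vapply(c(5, 10, 15, 20), sov_at, 0)
  full <- sum(apply(X, 2, var))
  expect_true(all(abs(v - full) / full < 0.1))
})

test_that("a bin mixing two morphological regimes has higher disparity than
           single-regime bins", {
  set.seed(81)
  # regime 1: characters mostly 0; regime 2: mostly 1
  s1 <- matrix(as.character(rbinom(6 * 40, 1, 0.05)), 6, 40)
  s2 <- matrix(as.character(rbinom(6 * 40, 1, 0.95)), 6, 40)
  states <- rbind(s1, s2)
  rownames(states) <- paste0("t", 1:12)
  m <- character_matrix(states)
  d <- morph_distance_matrix(m, "mord")
  one <- pairwise_disparity(d, paste0("t", 1:6), n_boot = 5, seed = 1)
  two <- pairwise_disparity(d, paste0("t", 7:12), n_boot = 5, seed = 1)
  mixed <- pairwise_disparity(d, paste0("t", c(1:3, 7:9)), n_boot = 5,
                              seed = 1)
  expect_gt(mixed$estimate, one$estimate)
  expect_gt(mixed$estimate, two$estimate)
})

test_that("disparity_through_time flags empty and singleton bins", {
  m <- random_char_matrix(8, 30, p_missing = 0, seed = 91)
  d <- morph_distance_matrix(m, "mord")
  bins <- make_bins("equal", oldest = 30, youngest = 0, width = 10)
  ranges <- data.frame(taxon = m$taxa,
                       fad = c(28, 27, 26, 25, 15, 14, 13, 4),
                       lad = c(25, 24, 23, 22, 12, 11, 11, 2))
  s <- disparity_through_time(d, ranges, bins, n_boot = 20, seed = 1)
  expect_equal(nrow(s), 3)
  expect_true(all(is.finite(s$estimate[1:2])))
  expect_true(is.na(s$estimate[3]))        # singleton bin
  expect_equal(s$n, c(4, 3, 1))
})
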