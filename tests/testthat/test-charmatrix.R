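test_that("NEXUS matrices are transcribed cell by cell", {
  path <- write_tmp_nexus(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  DIMENSIONS NTAX=2 NCHAR=3;",
    "  FORMAT SYMBOLS=\"01\" MISSING=? GAP=-;",
    "  MATRIX",
    "    A 01?",
    "    B 110",
    "  ;",
    "END;"))
  m <- read_nexus_matrix(path)
  expect_equal(m$taxa, c("A", "B"))
  expect_equal(unname(m$states["A", ]), c("0", "1", ""))
  expect_equal(unname(m$states["B", ]), c("1", "1", "0"))
  expect_equal(m$ordering, rep("unordered", 3))
})

test_that("polymorphisms, inapplicable codes and ordering blocks parse", {
  path <- write_tmp_nexus(c(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "  DIMENSIONS NCHAR=4;",
    "  FORMAT SYMBOLS=\"012\" MISSING=? GAP=-;",
    "  MATRIX",
    "    'Taxon a' (01)2-1",
    "    Taxon_b  {12}01?",
    "  ;",
    "END;",
    "BEGIN ASSUMPTIONS;",
    "  TYPESET * untitled = ord: 2 4, unord: 1 3;",
    "END;"))
  m <- read_nexus_matrix(path)
  expect_equal(unname(m$states["Taxon a", ]), c("0/1", "2", "", "1"))
  expect_equal(unname(m$states["Taxon_b", ]), c("1/2", "0", "1", ""))
  expect_equal(m$ordering,
               c("unordered", "ordered", "unordered", "ordered"))
})

test_that("malformed NEXUS fails with a line-anchored parse error", {
  path <- write_tmp_nexus(c(
    "#NEXUS",
    "BEGIN DATA;",
    "  MATRIX",
    "    A 010",
    "    B 110"))
  expect_error(read_nexus_matrix(path), "line 2.*END")
  path2 <- write_tmp_nexus(c(
    "#NEXUS", "BEGIN DATA;", "  MATRIX", "    A 01Z", "    B 110",
    "  ;", "END;"))
  expect_error(read_nexus_matrix(path2), "line 4.*'Z'")
  path3 <- write_tmp_nexus(c(
    "#NEXUS", "BEGIN DATA;", "  MATRIX", "    A 010", "    A 110",
    "  ;", "END;"))
  expect_error(read_nexus_matrix(path3), "duplicate taxon")
})

test_that("NEXUS round-trip preserves states and ordering", {
  m <- random_char_matrix(8, 20, p_missing = 0.3, n_states = 3, seed = 11)
  m$ordering[c(3, 7)] <- "ordered"
  path <- tempfile(fileext = ".nex")
  write_nexus_matrix(m, path)
  m2 <- read_nexus_matrix(path)
  expect_equal(m2$states, m$states)
  expect_equal(m2$ordering, m$ordering)
})

test_that("completeness is the coded fraction per taxon", {
  states <- rbind(part = c(rep("1", 3), rep("", 7)),
                  full = rep("0", 10))
  m <- character_matrix(states)
  expect_equal(unname(completeness(m)), c(0.3, 1.0))
})

test_that("per-character distances follow the hand-worked definitions", {
  # ordered characters with observed ranges 2 and 2
  m <- character_matrix(rbind(A = c("0", "2"), B = c("2", "2"),
                              C = c("0", "0")),
                        ordering = c("ordered", "ordered"))
  gow <- morph_distance_matrix(m, "gow")
  mord <- morph_distance_matrix(m, "mord")
  expect_equal(gow$D["A", "B"], 1.0)
  expect_equal(mord$D["A", "B"], 0.5)
  expect_equal(mord$D["B", "C"], 1.0)

  # unordered binary with a missing cell: char 2 is invariant across the
  # matrix, so it contributes to the Gower denominator but not the MORD one
  m2 <- character_matrix(rbind(A = c("0", "1", ""), B = c("1", "1", "0")))
  g2 <- morph_distance_matrix(m2, "gow")
  expect_equal(g2$D["A", "B"], 0.5)
  expect_equal(g2$C["A", "B"], 2L)
  expect_equal(morph_distance_matrix(m2, "mord")$D["A", "B"], 1.0)
})

test_that("identical taxa are at distance zero under all four metrics", {
  # GED imputes the grand mean difference into non-comparable cells, so the
  # identity holds exactly on coded characters; use fully coded twins
  states <- rbind(A = c("0", "1", "2", "1"), B = c("0", "1", "2", "1"),
                  C = c("1", "0", "2", "0"))
  m <- character_matrix(states, ordering = c("ordered", rep("unordered", 3)))
  for (metric in c("raw", "ged", "gow", "mord"))
    expect_equal(morph_distance_matrix(m, metric)$D["A", "B"], 0,
                 info = metric)
  # with shared missing cells the comparable-character metrics still agree
  states2 <- rbind(A = c("0", "1", ""), B = c("0", "1", ""),
                   C = c("1", "0", "1"))
  m2 <- character_matrix(states2)
  for (metric in c("raw", "gow", "mord"))
    expect_equal(morph_distance_matrix(m2, metric)$D["A", "B"], 0,
                 info = metric)
})

test_that("GED equals RAW on a fully coded matrix", {
  m <- random_char_matrix(6, 25, p_missing = 0, seed = 4)
  expect_equal(morph_distance_matrix(m, "ged")$D,
               morph_distance_matrix(m, "raw")$D)
})

test_that("polymorphism distance is the minimum over cross pairs", {
  m <- character_matrix(rbind(A = c("0/1", "0/3"), B = c("1", "1")),
                        ordering = c("unordered", "ordered"))
  d <- morph_distance_matrix(m, "gow")
  # char 1: sets overlap -> 0; char 2 ordered: min(|0-1|, |3-1|) = 1
  expect_equal(d$D["A", "B"], (0 + 1) / 2)
})

test_that("distance matrices are symmetric, zero-diagonal, bounded and
           invariant to taxon order; MORD == GOW for variable binary", {
  for (seed in 1:5) {
    m <- random_char_matrix(9, 30, p_missing = 0.25, seed = seed)
    # force both states observed in every character
    both <- apply(m$states, 2, function(col) {
      s <- unique(col[col != ""]); length(s) >= 2
    })
    m$states <- m$states[, both, drop = FALSE]
    m$ordering <- m$ordering[both]
    m$n_char <- sum(both)
    gow <- morph_distance_matrix(m, "gow")
    mord <- morph_distance_matrix(m, "mord")
    expect_equal(mord$D, gow$D, info = paste("seed", seed))
    for (dd in list(gow, mord)) {
      expect_equal(dd$D, t(dd$D))
      expect_equal(unname(diag(dd$D)), rep(0, nrow(dd$D)))
      expect_true(all(dd$D >= 0 & dd$D <= 1, na.rm = TRUE))
    }
    # permutation equivariance
    perm <- sample(nrow(m$states))
    mp <- character_matrix(m$states[perm, , drop = FALSE], m$ordering)
    dp <- morph_distance_matrix(mp, "mord")
    expect_equal(dp$D[m$taxa, m$taxa], mord$D)
  }
})

test_that("undefined entries appear exactly where no character is shared", {
  states <- rbind(A = c("0", "1", "", ""), B = c("", "", "1", "0"),
                  C = c("0", "1", "1", "0"))
  m <- character_matrix(states)
  d <- morph_distance_matrix(m, "mord")
  expect_true(is.na(d$D["A", "B"]))
  expect_equal(d$C["A", "B"], 0L)
  expect_false(anyNA(d$D["A", "C"]))
  # GED is defined everywhere
  expect_false(anyNA(morph_distance_matrix(m, "ged")$D))
})

test_that("trimming removes the most conflicted taxon and ties break by
           completeness then name", {
  # only pair (A, B) undefined; A less complete -> A removed
  states <- rbind(A = c("0", "", "", ""), B = c("", "1", "1", "1"),
                  C = c("0", "1", "1", "0"))
  m <- character_matrix(states)
  tr <- trim_distance_matrix(morph_distance_matrix(m, "mord"))
  expect_equal(tr$removed, "A")
  expect_equal(tr$dist$taxa, c("B", "C"))
  expect_false(anyNA(tr$dist$D))
  expect_match(tr$log$reason[1], "least complete")

  # already clean matrix is a no-op with an empty log
  clean <- morph_distance_matrix(random_char_matrix(5, 20, 0, seed = 2),
                                 "mord")
  tr2 <- trim_distance_matrix(clean)
  expect_identical(tr2$dist$D, clean$D)
  expect_equal(nrow(tr2$log), 0)
})

test_that("greedy trimming matches the brute-force optimum on small cases", {
  for (seed in 1:20) {
    m <- random_char_matrix(7, 8, p_missing = 0.55, seed = 100 + seed)
    d <- morph_distance_matrix(m, "mord")
    if (!anyNA(d$D)) next
    ut <- d$D[upper.tri(d$D)]
    if (all(is.na(ut))) {
      expect_error(trim_distance_matrix(d), "fully incomparable")
      next
    }
    tr <- tryCatch(trim_distance_matrix(d), error = function(e) e)
    if (inherits(tr, "error")) next
    retained <- length(tr$dist$taxa)
    expect_equal(retained, oracle_trim_optimum(d$D),
                 info = paste("seed", seed))
    expect_false(anyNA(tr$dist$D))
  }
})

test_that("a fully incomparable matrix is rejected", {
  states <- rbind(A = c("0", ""), B = c("", "1"))
  m <- character_matrix(states)
  expect_error(trim_distance_matrix(morph_distance_matrix(m, "mord")),
               "fully incomparable")
})
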