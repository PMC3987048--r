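test_that("block norms collapse site-state blocks correctly", {
  # diagonal-only coupling matrix: no pair signal
  G0 <- diag(3 * 21)
  expect_equal(max(block_norms(G0, "frobenius", q = 21L)), 0)

  # a single nonzero block entry scores |v| under both norms
  G1 <- matrix(0, 2 * 21, 2 * 21)
  G1[3, 21 + 5] <- -0.7; G1[21 + 5, 3] <- -0.7
  for (nm in c("frobenius", "l1")) {
    S <- block_norms(G1, nm, include_gap_state = TRUE, q = 21L)
    expect_equal(S[1, 2], 0.7)
    expect_equal(S, t(S))
    expect_equal(diag(S), c(0, 0))
  }

  # toy q = 3 blocks against direct arithmetic
  set.seed(89)
  G <- matrix(rnorm(36), 6, 6); G <- G + t(G)
  blk <- G[1:3, 4:6]
  Sf <- block_norms(G, "frobenius", include_gap_state = TRUE, q = 3L)
  Sl <- block_norms(G, "l1", include_gap_state = TRUE, q = 3L)
  expect_equal(Sf[1, 2], sqrt(sum(blk^2)), tolerance = 1e-12)
  expect_equal(Sl[1, 2], sum(abs(blk)), tolerance = 1e-12)

  # matches the loop oracle, with and without the gap state
  set.seed(97)
  Gb <- matrix(rnorm((2 * 21)^2), 42, 42); Gb <- Gb + t(Gb)
  for (nm in c("frobenius", "l1")) {
    for (inc in c(TRUE, FALSE)) {
      expect_equal(
        unclass(block_norms(Gb, nm, inc, q = 21L))[1:4],
        oracle_block_norms(Gb, 21L, nm, inc)[1:4], tolerance = 1e-12)
    }
    # norm is monotone in the included entries
    expect_true(all(block_norms(Gb, nm, TRUE, q = 21L) >=
                    block_norms(Gb, nm, FALSE, q = 21L) - 1e-12))
  }
})

test_that("average product correction has the advertised algebra", {
  # constant off-diagonal scores are fully explained by the background
  Sc <- matrix(0.4, 6, 6); diag(Sc) <- 0
  expect_equal(max(abs(apc(Sc))), 0, tolerance = 1e-12)

  # zero matrix: guarded degenerate case, no division error
  expect_equal(apc(matrix(0, 4, 4)), matrix(0, 4, 4))

  # rank-one background is annihilated exactly when the diagonal
  # participates in the means
  u <- c(1, 2, 3, 4)
  expect_equal(max(abs(apc(outer(u, u), exclude_diagonal = FALSE))), 0,
               tolerance = 1e-9)

  # under the default diagonal-excluding means the cancellation is only
  # approximate; frozen hand-derived value for u = (1,2,3,4), diag zeroed:
  # corrected[1,2] = 2 - 3 * (16/3) / (70/12) = -26/35
  S1 <- outer(u, u); diag(S1) <- 0
  expect_equal(apc(S1)[1, 2], -26 / 35, tolerance = 1e-12)

  # positive homogeneity: apc(c S) = c apc(S)
  set.seed(103)
  S <- matrix(abs(rnorm(49)), 7, 7); S <- S + t(S); diag(S) <- 0
  expect_equal(apc(3.7 * S), 3.7 * apc(S), tolerance = 1e-12)
})

test_that("contact ranking filters, sorts and maps indices", {
  n <- 6
  corrected <- matrix(0, n, n); raw <- matrix(0, n, n)
  corrected[1, 6] <- corrected[6, 1] <- 0.5
  corrected[2, 6] <- corrected[6, 2] <- 0.9
  raw[1, 6] <- raw[6, 1] <- 0.1

  # mincontsep 5 on L = 6: only (1, 6) qualifies
  cl <- rank_contacts(corrected, raw, mincontsep = 5)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$i, cl$j), c(1L, 6L))
  expect_equal(cl$raw, 0.1)

  # mincontsep 1 reports all pairs, sorted by corrected descending
  cl1 <- rank_contacts(corrected, raw, mincontsep = 1)
  expect_equal(nrow(cl1), n * (n - 1) / 2)
  expect_equal(c(cl1$i[1], cl1$j[1]), c(2L, 6L))
  expect_true(all(diff(cl1$corrected) <= 0))

  # ties break by ascending (i, j)
  tie <- matrix(1, 4, 4); diag(tie) <- 0
  clt <- rank_contacts(tie, tie, mincontsep = 1)
  expect_equal(clt$i[1:3], c(1L, 1L, 1L))
  expect_equal(clt$j[1:3], c(2L, 3L, 4L))

  # masked columns never appear; indices map to original positions
  ci <- c(2L, 5L, 9L)
  cm <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  clm <- rank_contacts(cm, cm, mincontsep = 3, column_index = ci)
  expect_true(all(c(clm$i, clm$j) %in% ci))
  expect_equal(c(clm$i[1], clm$j[1]), c(5L, 9L))  # top score 3
  # separation is measured on original positions: mincontsep 4 drops (2, 5)
  clm4 <- rank_contacts(cm, cm, mincontsep = 4, column_index = ci)
  expect_false(any(clm4$i == 2 & clm4$j == 5))
  expect_equal(nrow(clm4), 2L)
})

test_that("reported pair count matches exhaustive enumeration", {
  set.seed(107)
  for (k in 1:10) {
    L <- sample(2:12, 1)
    msep <- sample(1:6, 1)
    S <- matrix(abs(rnorm(L * L)), L); S <- S + t(S); diag(S) <- 0
    cl <- rank_contacts(S, S, mincontsep = msep)
    count <- 0
    for (i in seq_len(L)) for (j in seq_len(L)) {
      if (i < j && j - i >= msep) count <- count + 1
    }
    expect_equal(nrow(cl), count)
  }
})
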