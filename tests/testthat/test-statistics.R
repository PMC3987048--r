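test_that("single-site frequencies follow the pseudocount formula", {
  aln <- read_alignment(text = "AAAA", format = "flat")
  ws <- compute_weights(aln, 62)
  f1 <- single_frequencies(aln, ws, lambda = 0)
  expect_equal(f1[1, 1], 1)
  expect_equal(sum(f1[1, -1]), 0)

  # huge pseudocount drives everything to 1/21
  f1u <- single_frequencies(aln, ws, lambda = 1e9)
  expect_equal(max(abs(f1u - 1 / 21)), 0, tolerance = 1e-6)

  # M = 2, equal weights 1/2, lambda = 1, pscount_weight = 0, column (A, C)
  aln2 <- read_alignment(text = "AG\nCG", format = "flat")
  ws2 <- compute_weights(aln2, 0)          # one cluster of 2: w = (1/2, 1/2)
  expect_equal(ws2$w, c(0.5, 0.5))
  f12 <- single_frequencies(aln2, ws2, lambda = 1, pscount_weight = 0)
  expect_equal(f12[1, 1], (1 / 21 + 1 / 2) / 2)
  expect_equal(f12[1, 2], (1 / 21 + 1 / 2) / 2)
  expect_equal(f12[1, 3], (1 / 21) / 2)
})

test_that("pair frequencies match point-mass and oracle cases", {
  aln <- read_alignment(text = "AC", format = "flat")
  ws <- compute_weights(aln, 62)
  ft <- frequency_tables(aln, ws, lambda = 0)
  blk <- f2_block(ft, 1, 2)
  expect_equal(blk[1, 2], 1)    # (A, C)
  expect_equal(sum(blk), 1)

  set.seed(23)
  for (k in 1:5) {
    aln <- random_alignment(M = sample(3:12, 1), L = sample(2:6, 1))
    ws <- compute_weights(aln, runif(1, 20, 90))
    lambda <- sample(c(0, 0.5, 1, 3), 1)
    pw <- runif(1)
    ft <- frequency_tables(aln, ws, lambda, pw)
    or <- oracle_frequencies(aln, ws$w, lambda, pw)
    expect_equal(ft$f1, or$f1, tolerance = 1e-12)
    expect_equal(ft$f2, or$f2, tolerance = 1e-12)
    expect_equal(ft$gapfreq, or$gapfreq, tolerance = 1e-12)
  }
})

test_that("frequency tables satisfy their algebraic invariants", {
  set.seed(31)
  for (k in 1:5) {
    aln <- random_alignment(M = sample(2:15, 1), L = sample(2:6, 1),
                            gap_prob = runif(1, 0, 0.3))
    ws <- compute_weights(aln, runif(1, 30, 90))
    ft <- frequency_tables(aln, ws, lambda = sample(c(0, 1, 2), 1),
                           pscount_weight = runif(1))
    L <- aln$L
    expect_equal(rowSums(ft$f1), rep(1, L), tolerance = 1e-9)
    for (i in seq_len(L)) {
      for (j in seq_len(L)) {
        blk <- f2_block(ft, i, j)
        # marginalisation onto f1
        expect_equal(rowSums(blk), ft$f1[i, ], tolerance = 1e-9)
        # symmetry f2[i,j,a,b] = f2[j,i,b,a]
        expect_equal(blk, t(f2_block(ft, j, i)), tolerance = 1e-12)
      }
      # diagonal block is delta_ab * f1
      expect_equal(f2_block(ft, i, i), diag(ft$f1[i, ], nrow = 21),
                   tolerance = 1e-12)
    }
  }
})

test_that("gap masking uses raw weighted gap frequency with strict >", {
  aln <- read_alignment(text = "A-A-\nA-C-\nACAA", format = "flat")
  ws <- compute_weights(aln, 100)  # no identical rows: unit weights
  ft <- frequency_tables(aln, ws, lambda = 5)  # pseudocount must not matter
  expect_equal(ft$gapfreq[2], 2 / 3, tolerance = 1e-12)
  expect_equal(ft$gapfreq[4], 2 / 3, tolerance = 1e-12)
  expect_identical(gap_mask(ft, gapth = 0.5), c(TRUE, FALSE, TRUE, FALSE))
  # gapth = 1 never drops (strict >, frequency <= 1)
  all_gap <- read_alignment(text = "-A\n-C", format = "flat")
  ftg <- frequency_tables(all_gap, compute_weights(all_gap, 62))
  expect_identical(gap_mask(ftg, gapth = 1), c(TRUE, TRUE))
  expect_identical(gap_mask(ftg, gapth = 0.5), c(FALSE, TRUE))
  # apply = FALSE keeps everything
  expect_identical(gap_mask(ftg, gapth = 0.5, apply = FALSE), c(TRUE, TRUE))
  # all columns masked is an error
  gappy <- read_alignment(text = "--\n--", format = "flat")
  ftx <- frequency_tables(gappy, compute_weights(gappy, 62))
  expect_error(gap_mask(ftx, gapth = 0.5), class = "coev_no_columns")
})

test_that("covariance matrix has the contracted side and content", {
  set.seed(41)
  aln <- random_alignment(M = 12, L = 10)
  ws <- compute_weights(aln, 62)
  ft <- frequency_tables(aln, ws, lambda = 1, pscount_weight = 0.5)
  expect_equal(nrow(build_covariance(ft, cov20 = TRUE)$C), 200L)
  expect_equal(nrow(build_covariance(ft, cov20 = FALSE)$C), 210L)

  # masked columns shrink the side and are recorded in column_index
  keep <- rep(TRUE, 10); keep[c(3, 7)] <- FALSE
  cv <- build_covariance(ft, keep, cov20 = TRUE)
  expect_equal(nrow(cv$C), 160L)
  expect_equal(cv$column_index, setdiff(1:10, c(3, 7)))

  # M = 1: Bernoulli variance on the diagonal
  a1 <- read_alignment(text = "AC", format = "flat")
  ft1 <- frequency_tables(a1, compute_weights(a1, 62), lambda = 1)
  cv1 <- build_covariance(ft1)
  f <- ft1$f1[1, 1]
  expect_equal(cv1$C[1, 1], f * (1 - f), tolerance = 1e-12)
})

test_that("covariance equals the brute-force oracle", {
  set.seed(47)
  for (k in 1:4) {
    aln <- random_alignment(M = sample(3:15, 1), L = sample(2:5, 1),
                            gap_prob = 0.15)
    ws <- compute_weights(aln, 62)
    ft <- frequency_tables(aln, ws, lambda = 1, pscount_weight = runif(1))
    keep <- rep(TRUE, aln$L)
    cov20 <- k %% 2 == 0
    cv <- build_covariance(ft, keep, cov20)
    or <- oracle_covariance(ft$f1, ft$f2, keep, cov20)
    expect_equal(cv$C, or, tolerance = 1e-10)
  }
})

test_that("independent columns give near-zero covariance blocks", {
  set.seed(53)
  aln <- random_alignment(M = 2000, L = 2, gap_prob = 1 / 21)
  ws <- structure(list(w = rep(1, 2000), Meff = 2000, clustpc = 0,
                       comparison = "ge"), class = "coev_weights")
  ft <- frequency_tables(aln, ws, lambda = 0)
  cv <- build_covariance(ft)
  offblk <- cv$C[1:21, 22:42]
  expect_lt(max(abs(offblk)), 0.05)
})

test_that("off-diagonal block row sums vanish without pseudocount (q = 21)", {
  set.seed(59)
  aln <- random_alignment(M = 10, L = 5, gap_prob = 0.2)
  ws <- compute_weights(aln, 62)
  ft <- frequency_tables(aln, ws, lambda = 0)
  cv <- build_covariance(ft, cov20 = FALSE)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      blk <- cv$C[(i - 1) * 21 + 1:21, (j - 1) * 21 + 1:21]
      expect_equal(max(abs(rowSums(blk))), 0, tolerance = 1e-9)
      expect_equal(max(abs(colSums(blk))), 0, tolerance = 1e-9)
    }
  }
})
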