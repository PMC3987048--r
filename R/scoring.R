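#' Per-pair block norms of a coupling matrix
#'
#' Collapses the site-state coupling matrix to one raw score per column
#' pair: the norm of the q' x q' block `Gamma[(i, .), (j, .)]`, where
#' `q' = 20` when `include_gap_state = FALSE` (the gap row/column of each
#' block is excluded; a no-op when the matrix was built with `cov20`).
#' `"frobenius"` (sqrt of the sum of squares) is the mean-field DCA
#' convention behind corrected-norm scores; `"l1"` (sum of absolute values)
#' is the sparse-inverse-covariance convention. The result is symmetric
#' with a zero diagonal.
#'
#' @param prec A `coev_precision` (or plain matrix plus `q` attribute-free
#'   use with `q` supplied).
#' @param norm `"frobenius"` or `"l1"`.
#' @param include_gap_state Include the gap state's row/column in each
#'   block norm (only meaningful when `q = 21`).
#' @param q States per site; taken from `prec` when it is a
#'   `coev_precision`.
#' @return Square score matrix over the *kept* columns, with the
#'   `column_index` mapping attached as an attribute.
#' @export
block_norms <- function(prec, norm = c("frobenius", "l1"),
                        include_gap_state = FALSE, q = NULL) {
  norm <- match.arg(norm)
  if (inherits(prec, "coev_precision")) {
    Gamma <- prec$Gamma
    q <- prec$q
    column_index <- prec$column_index
  } else {
    Gamma <- prec
    stopifnot(!is.null(q))
    column_index <- seq_len(nrow(Gamma) %/% q)
  }
  n <- nrow(Gamma) %/% q
  stopifnot(n * q == nrow(Gamma))
  qp <- if (!include_gap_state && q == Q_STATES) q - 1L else q
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    ri <- (i - 1L) * q + seq_len(qp)
    for (j in (i + 1L):n) {
      blk <- Gamma[ri, (j - 1L) * q + seq_len(qp), drop = FALSE]
      S[i, j] <- S[j, i] <- switch(norm,
        frobenius = sqrt(sum(blk^2)),
        l1 = sum(abs(blk)))
    }
  }
  attr(S, "column_index") <- column_index
  attr(S, "norm") <- norm
  S
}

#' Average product correction
#'
#' Removes the background/phylogenetic component of a symmetric pair score
#' matrix: `corrected[i, j] = S[i, j] - rowmean_i * rowmean_j / grandmean`.
#' By default the means exclude the (zero) diagonal, matching the score
#' matrices produced by [block_norms()]; with
#' `exclude_diagonal = FALSE` the means run over whole rows and the whole
#' matrix, under which convention a rank-one matrix `u u'` is annihilated
#' exactly. A zero grand mean returns an all-zero matrix rather than
#' dividing by zero. APC is positively homogeneous: `apc(c * S) = c *
#' apc(S)` for `c > 0`.
#'
#' @param S Symmetric score matrix with zero diagonal (attributes from
#'   [block_norms()] are preserved).
#' @param exclude_diagonal Exclude the diagonal from the row and grand
#'   means (default).
#' @return Corrected score matrix, same shape and attributes, zero
#'   diagonal.
#' @export
apc <- function(S, exclude_diagonal = TRUE) {
  n <- nrow(S)
  stopifnot(n == ncol(S))
  if (n < 2L) return(S)
  if (exclude_diagonal) {
    rowm <- (rowSums(S) - diag(S)) / (n - 1)
    grand <- (sum(S) - sum(diag(S))) / (n * (n - 1))
  } else {
    rowm <- rowSums(S) / n
    grand <- sum(S) / (n * n)
  }
  out <- if (grand == 0) {
    matrix(0, n, n)
  } else {
    S - outer(rowm, rowm) / grand
  }
  diag(out) <- 0
  attributes(out)[c("column_index", "norm")] <-
    attributes(S)[c("column_index", "norm")]
  out
}

#' Rank contact scores into a reportable list
#'
#' Enumerates every unmasked column pair at sequence separation
#' `j - i >= mincontsep` (indices mapped back through the gap-column mask
#' to original 1-based target positions), sorted by descending corrected
#' score with ties broken by ascending `(i, j)` so output is byte-stable.
#'
#' @param corrected,raw Score matrices over kept columns (same shape), e.g.
#'   from [apc()] and [block_norms()].
#' @param mincontsep Minimum separation `j - i` (inclusive), `>= 1`.
#' @param column_index Kept-column to original-column mapping; defaults to
#'   the `column_index` attribute of `corrected`, else the identity.
#' @param target_residues Optional character vector of target-row symbols
#'   used to fill `res_i` / `res_j`.
#' @return A `coev_contacts` data frame with columns `i`, `res_i`, `j`,
#'   `res_j`, `raw`, `corrected`.
#' @export
rank_contacts <- function(corrected, raw, mincontsep = 5L,
                          column_index = NULL, target_residues = NULL) {
  stopifnot(mincontsep >= 1, all(dim(corrected) == dim(raw)))
  n <- nrow(corrected)
  if (is.null(column_index)) column_index <- attr(corrected, "column_index")
  if (is.null(column_index)) column_index <- seq_len(n)
  stopifnot(length(column_index) == n)

  pairs <- which(upper.tri(corrected), arr.ind = TRUE)
  oi <- column_index[pairs[, 1L]]
  oj <- column_index[pairs[, 2L]]
  ok <- (oj - oi) >= mincontsep
  oi <- oi[ok]; oj <- oj[ok]
  ki <- pairs[ok, 1L]; kj <- pairs[ok, 2L]

  res <- if (is.null(target_residues)) rep(NA_character_, max(length(oi), 1L)) else NULL
  df <- data.frame(
    i = oi,
    res_i = if (is.null(target_residues)) rep(NA_character_, length(oi))
            else target_residues[oi],
    j = oj,
    res_j = if (is.null(target_residues)) rep(NA_character_, length(oj))
            else target_residues[oj],
    raw = raw[cbind(ki, kj)],
    corrected = corrected[cbind(ki, kj)],
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$corrected, df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "mincontsep") <- mincontsep
  attr(df, "norm") <- attr(corrected, "norm")
  class(df) <- c("coev_contacts", "data.frame")
  df
}
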