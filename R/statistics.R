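## Flat site-state index: (column i, state a) -> (i-1)*21 + a + 1.
## All (L*q) x (L*q) matrices in this package use this layout
## (column-major over alignment columns, state-minor).
site_state_index <- function(cols, states = seq_len(Q_STATES)) {
  cols <- as.integer(cols)
  as.vector(vapply(cols, function(i) (i - 1L) * Q_STATES + states,
                   integer(length(states))))
}

## Effective pseudocount mass: pscount_weight interpolates between a fixed
## mass (0) and one proportional to Meff (1), the mean-field DCA convention.
lambda_effective <- function(lambda, pscount_weight, meff) {
  stopifnot(lambda >= 0, pscount_weight >= 0, pscount_weight <= 1)
  lambda * (pscount_weight * meff + (1 - pscount_weight))
}

#' Weighted, pseudocounted frequency tables
#'
#' Computes single-site frequencies `f1[i, a]`, pairwise frequencies
#' `f2[(i,a), (j,b)]` and per-column weighted gap frequencies from a weighted
#' alignment. With effective pseudocount mass
#' `lambda' = lambda * (pscount_weight * Meff + (1 - pscount_weight))`:
#' \deqn{f_1(i,a) = (\lambda'/q + \sum_m w_m [x_{mi}=a]) / (\lambda' + M_{eff})}
#' \deqn{f_2(i,j,a,b) = (\lambda'/q^2 + \sum_m w_m [x_{mi}=a][x_{mj}=b]) /
#'   (\lambda' + M_{eff})}
#' for \eqn{i \neq j}; the diagonal blocks are set to
#' \eqn{f_2(i,i,a,b) = \delta_{ab} f_1(i,a)} explicitly. Under this shared
#' scheme the pair table marginalises exactly onto the single-site table.
#' Gap frequencies are computed from the raw weighted counts, *without*
#' pseudocount, so that an all-gap column cannot sneak under a threshold
#' near 1.
#'
#' @param aln A `coev_alignment`.
#' @param ws A `coev_weights` for the same alignment.
#' @param lambda Pseudocount mass, `>= 0`.
#' @param pscount_weight Interpolation weight in `[0, 1]` between a fixed
#'   pseudocount mass (0) and one scaled by `Meff` (1).
#' @return A `coev_frequencies`: list with `f1` (L x 21), `f2`
#'   ((21 L) x (21 L), site-state layout), `gapfreq` (length L), `lambda`,
#'   `lambda_eff`, `meff`, `L`.
#' @export
frequency_tables <- function(aln, ws, lambda = 0, pscount_weight = 0) {
  stopifnot(inherits(aln, "coev_alignment"), inherits(ws, "coev_weights"),
            length(ws$w) == aln$M)
  L <- aln$L
  q <- Q_STATES
  meff <- ws$Meff
  lam <- lambda_effective(lambda, pscount_weight, meff)

  X <- alignment_indicator(aln)
  cnt1 <- as.vector(Matrix::crossprod(X, ws$w))             # length L*q
  cnt2 <- as.matrix(Matrix::crossprod(X, Matrix::Diagonal(x = ws$w) %*% X))

  f1v <- (lam / q + cnt1) / (lam + meff)
  f2 <- (lam / q^2 + cnt2) / (lam + meff)
  f1 <- t(matrix(f1v, nrow = q, ncol = L))
  for (i in seq_len(L)) {                                   # diagonal blocks
    idx <- site_state_index(i)
    f2[idx, idx] <- diag(f1[i, ], nrow = q)
  }
  gapfreq <- cnt1[site_state_index(seq_len(L), states = q)] / meff

  structure(list(f1 = f1, f2 = f2, gapfreq = gapfreq, lambda = lambda,
                 lambda_eff = lam, meff = meff, L = L),
            class = "coev_frequencies")
}

#' @rdname frequency_tables
#' @export
single_frequencies <- function(aln, ws, lambda = 0, pscount_weight = 0) {
  frequency_tables(aln, ws, lambda, pscount_weight)$f1
}

#' @rdname frequency_tables
#' @export
pair_frequencies <- function(aln, ws, lambda = 0, pscount_weight = 0) {
  frequency_tables(aln, ws, lambda, pscount_weight)$f2
}

#' Extract one q x q pair-frequency block
#'
#' @param ft A `coev_frequencies`.
#' @param i,j 1-based alignment columns.
#' @return The 21 x 21 block `f2[i, j, , ]`.
#' @export
f2_block <- function(ft, i, j) {
  ft$f2[site_state_index(i), site_state_index(j)]
}

#' Gap-column mask
#'
#' Marks columns whose weighted gap frequency (raw weighted counts, no
#' pseudocount) exceeds `gapth` strictly. Masked columns are excluded from
#' the covariance matrix and can never appear in the output contacts. With
#' `apply = FALSE` every column is kept.
#'
#' @param gapfreq Length-L weighted gap frequencies (e.g.
#'   `frequency_tables(...)$gapfreq`), or a `coev_frequencies`.
#' @param gapth Threshold in `(0, 1]`; a column is dropped when its gap
#'   frequency is `> gapth` (strict, so `gapth = 1` never drops).
#' @param apply When `FALSE`, return an all-keep mask regardless of gaps.
#' @return Logical vector, `TRUE` for kept columns.
#' @export
gap_mask <- function(gapfreq, gapth, apply = TRUE) {
  if (inherits(gapfreq, "coev_frequencies")) gapfreq <- gapfreq$gapfreq
  stopifnot(gapth > 0, gapth <= 1)
  keep <- if (apply) !(gapfreq > gapth) else rep(TRUE, length(gapfreq))
  if (!any(keep)) {
    stop_coev("no columns remain after gap masking", "coev_no_columns")
  }
  keep
}

#' Site-state covariance matrix
#'
#' Builds `C[(i,a),(j,b)] = f2[i,j,a,b] - f1[i,a] * f1[j,b]` over the kept
#' columns. With `cov20 = TRUE` one state is left out per site -- the pooled
#' gap state (code 20) -- so each site contributes 20 rows/columns and the
#' system is not overdetermined; with `cov20 = FALSE` all 21 states are
#' kept. The matrix is symmetrised as `(C + t(C)) / 2` on construction.
#'
#' @param ft A `coev_frequencies`.
#' @param keep Logical keep-mask over columns from [gap_mask()]; `NULL`
#'   keeps all.
#' @param cov20 Drop the gap state per site (20 states) instead of keeping
#'   all 21.
#' @return A `coev_covariance`: list with `C` (side `L_kept * q`), integer
#'   `column_index` mapping block index to original column, `q` (20 or 21).
#' @export
build_covariance <- function(ft, keep = NULL, cov20 = FALSE) {
  stopifnot(inherits(ft, "coev_frequencies"))
  L <- ft$L
  if (is.null(keep)) keep <- rep(TRUE, L)
  stopifnot(length(keep) == L)
  cols <- which(keep)
  qr <- if (cov20) Q_STATES - 1L else Q_STATES
  idx <- site_state_index(cols, states = seq_len(qr))
  f1v <- as.vector(t(ft$f1))          # flat site-state layout
  C <- ft$f2[idx, idx] - tcrossprod(f1v[idx])
  C <- (C + t(C)) / 2
  structure(list(C = C, column_index = cols, q = qr),
            class = "coev_covariance")
}

#' @export
print.coev_covariance <- function(x, ...) {
  cat(sprintf("<coev_covariance> side %d (%d columns x %d states)\n",
              nrow(x$C), length(x$column_index), x$q))
  invisible(x)
}
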