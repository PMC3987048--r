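#' Percentage sequence identity between two encoded rows
#'
#' Identity is counted position-by-position over the full alignment length:
#' gap-vs-gap counts as a match, gap-vs-residue as a mismatch (the gap class
#' behaves as a 21st symbol). The denominator is the full alignment length L,
#' not the pairwise ungapped length.
#'
#' @param a,b Integer-encoded rows of equal length (codes 0..20).
#' @return Identity in percent, in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  if (length(a) != length(b)) {
    stop_coev("sequences have different lengths", "coev_format_error")
  }
  100 * sum(a == b) / length(a)
}

## M x (L*21) one-hot indicator over (column, state); column-major over
## alignment columns, state-minor: flat index (i, a) -> (i-1)*21 + a + 1.
alignment_indicator <- function(aln) {
  M <- aln$M; L <- aln$L
  j <- as.vector(t(aln$encoded)) + 1L + rep((seq_len(L) - 1L) * Q_STATES,
                                            times = M)
  Matrix::sparseMatrix(i = rep(seq_len(M), each = L), j = j, x = 1,
                       dims = c(M, L * Q_STATES))
}

identity_percent_matrix <- function(aln) {
  X <- alignment_indicator(aln)
  counts <- as.matrix(Matrix::tcrossprod(X))
  100 * counts / aln$L
}

#' Identity-clustering sequence weights and effective alignment weight
#'
#' Each sequence m is weighted by `1 / n_m`, where `n_m` is the number of
#' sequences (m itself included) whose percent identity to m satisfies the
#' clustering comparison against `clustpc`. With `comparison = "ge"`
#' sequences at *exactly* the threshold identity are grouped together;
#' `"gt"` reproduces the strictly-greater grouping used by some other
#' implementations -- the two differ exactly and only on alignments holding
#' a pair at the threshold. The effective alignment weight `Meff` is the sum
#' of the weights.
#'
#' @param aln A `coev_alignment`.
#' @param clustpc Clustering threshold in percent, in `[0, 100]`.
#' @param comparison `"ge"` (group at identity >= clustpc, the default) or
#'   `"gt"` (strictly greater).
#' @return A `coev_weights`: list with `w` (length-M weights), `Meff`,
#'   `clustpc`, `comparison`.
#' @export
#' @examples
#' aln <- read_alignment(text = "ACDE\nACDE\nWYWY", format = "flat")
#' compute_weights(aln, clustpc = 62)$Meff  # duplicates collapse: 2
compute_weights <- function(aln, clustpc, comparison = c("ge", "gt")) {
  comparison <- match.arg(comparison)
  stopifnot(clustpc >= 0, clustpc <= 100)
  idm <- identity_percent_matrix(aln)
  n <- if (comparison == "ge") {
    rowSums(idm >= clustpc)
  } else {
    rowSums(idm > clustpc)
  }
  n <- pmax(n, 1)  # self-identity is 100, so n >= 1 already under "ge"
  w <- 1 / n
  structure(list(w = w, Meff = sum(w), clustpc = clustpc,
                 comparison = comparison),
            class = "coev_weights")
}

#' @export
print.coev_weights <- function(x, ...) {
  cat(sprintf("<coev_weights> M = %d, Meff = %.4g (clustpc = %g%%, %s)\n",
              length(x$w), x$Meff, x$clustpc, x$comparison))
  invisible(x)
}

#' Abort when the effective alignment weight is too small
#'
#' A redundant alignment can collapse to an effective weight near 1, in
#' which case there is no covariation signal to estimate couplings from.
#' Raises a dedicated `coev_insufficient_weight` condition (CLI exit code 2)
#' when `Meff < min_meff`; passes silently otherwise (boundary inclusive).
#'
#' @param ws A `coev_weights`.
#' @param min_meff Minimum acceptable `Meff`; default 1.5 (a single
#'   effective sequence carries no covariation signal).
#' @return `ws`, invisibly.
#' @export
check_total_weight <- function(ws, min_meff = 1.5) {
  stopifnot(inherits(ws, "coev_weights"))
  if (ws$Meff < min_meff) {
    stop_coev(sprintf(
      "insufficient total alignment weight: Meff = %.6g < required %.6g",
      ws$Meff, min_meff), "coev_insufficient_weight", meff = ws$Meff)
  }
  invisible(ws)
}
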