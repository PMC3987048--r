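#' Specify a Potts-like model with planted couplings
#'
#' Defines the pairwise distribution
#' `p(x) ~ exp(sum_i h_i(x_i) + sum_{(i,j)} beta_ij [x_i == x_j])`
#' over `q`-state sequences of length `L`: an Ising-like "same-state bonus"
#' coupling on each planted pair plus per-column field biases. This is the
#' ground truth for end-to-end tests -- planted pairs are the residue pairs
#' a contact predictor should recover.
#'
#' @param L Number of columns.
#' @param M Number of sequences to draw.
#' @param coupled_pairs Data frame with columns `i`, `j` (`i < j`) and
#'   `beta` (coupling strength `> 0`), or `NULL` for an independent model.
#' @param fields Optional L x q matrix of field biases `h_i(a)`; default 0.
#' @param q States per position (default 21, matching the encoding).
#' @param burn_in Gibbs burn-in sweeps (default `100 * L`; small models mix
#'   fast, tune down for speed).
#' @param thin Sweeps between recorded sequences (default 10).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return A `coev_planted_model`.
#' @export
planted_model <- function(L, M, coupled_pairs = NULL, fields = NULL,
                          q = Q_STATES, burn_in = 100L * L, thin = 10L,
                          seed = 1L) {
  if (is.null(coupled_pairs)) {
    coupled_pairs <- data.frame(i = integer(), j = integer(),
                                beta = numeric())
  }
  stopifnot(is.data.frame(coupled_pairs),
            all(c("i", "j", "beta") %in% names(coupled_pairs)))
  if (nrow(coupled_pairs)) {
    stopifnot(all(coupled_pairs$i < coupled_pairs$j),
              all(coupled_pairs$j <= L),
              all(is.finite(coupled_pairs$beta)))
  }
  if (is.null(fields)) fields <- matrix(0, L, q)
  stopifnot(all(dim(fields) == c(L, q)))
  if (!all(is.finite(fields))) {
    stop_coev("non-finite field parameters", "coev_degenerate_input")
  }
  structure(list(L = L, M = M, q = q, coupled_pairs = coupled_pairs,
                 fields = fields, burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "coev_planted_model")
}

#' Draw an alignment from a planted coupling model
#'
#' Single-chain, single-site Gibbs sampling: after `burn_in` full sweeps,
#' one sequence is recorded every `thin` sweeps until `M` sequences are
#' drawn. Identical seeds give identical alignments. With `q = 21` the gap
#' state is sampled like any other, so a uniform model yields roughly 1/21
#' gap symbols per column.
#'
#' @param model A `coev_planted_model`.
#' @return A `coev_alignment` (row 1 doubles as the "target" sequence).
#' @export
sample_alignment <- function(model) {
  stopifnot(inherits(model, "coev_planted_model"))
  set.seed(model$seed)
  enc <- gibbs_sample_cpp(model$L, model$q, model$fields,
                          as.integer(model$coupled_pairs$i),
                          as.integer(model$coupled_pairs$j),
                          as.numeric(model$coupled_pairs$beta),
                          model$M, model$burn_in, model$thin)
  alignment_from_encoded(enc)
}

#' Append exact or mutated duplicates of alignment rows
#'
#' Exercises the redundancy handling of the weighting stage: appends
#' `copies[m]` near-duplicates of row m, each position independently
#' resampled (uniformly over all 21 codes) with probability
#' `mutation_rate`. With rate 0 duplicates are exact, so a row copied k
#' times forms a cluster of size k + 1 at any `clustpc <= 100` under the
#' inclusive comparison. Uses the current RNG state; call `set.seed()`
#' first for reproducibility.
#'
#' @param aln A `coev_alignment`.
#' @param copies Integer vector of duplicate counts, length `M` (or a
#'   single value recycled).
#' @param mutation_rate Per-position resampling probability in `[0, 1]`.
#' @return A `coev_alignment` with the duplicates appended after the
#'   original rows.
#' @export
add_redundancy <- function(aln, copies, mutation_rate = 0) {
  stopifnot(inherits(aln, "coev_alignment"),
            mutation_rate >= 0, mutation_rate <= 1)
  copies <- rep_len(as.integer(copies), aln$M)
  if (sum(copies) == 0L) return(aln)
  extra <- list()
  for (m in seq_len(aln$M)) {
    for (k in seq_len(copies[m])) {
      row <- aln$encoded[m, ]
      if (mutation_rate > 0) {
        mut <- runif(aln$L) < mutation_rate
        row[mut] <- sample.int(Q_STATES, sum(mut), replace = TRUE) - 1L
      }
      extra[[length(extra) + 1L]] <- row
    }
  }
  alignment_from_encoded(rbind(aln$encoded, do.call(rbind, extra)))
}
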