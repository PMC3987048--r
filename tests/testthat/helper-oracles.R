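# Brute-force reference implementations, written as literal translations of
# the definitions (per-pair / per-sequence loops). They deliberately share no
# code with the vectorised production paths they check.

Q <- 21L

random_alignment <- function(M, L, gap_prob = 0.1) {
  codes <- matrix(
    ifelse(runif(M * L) < gap_prob, 20L,
           sample.int(20L, M * L, replace = TRUE) - 1L),
    nrow = M, ncol = L)
  coevcontact::read_alignment(text = paste(decode_symbols(codes),
                                           collapse = "\n"),
                              format = "flat")
}

oracle_weights <- function(aln, clustpc, comparison = "ge") {
  M <- aln$M
  n <- integer(M)
  for (m in seq_len(M)) {
    for (mp in seq_len(M)) {
      id <- 100 * sum(aln$encoded[m, ] == aln$encoded[mp, ]) / aln$L
      hit <- if (comparison == "ge") id >= clustpc else id > clustpc
      if (hit) n[m] <- n[m] + 1L
    }
  }
  w <- 1 / pmax(n, 1)
  list(w = w, Meff = sum(w), n = n)
}

oracle_frequencies <- function(aln, w, lambda = 0, pscount_weight = 0) {
  M <- aln$M; L <- aln$L
  meff <- sum(w)
  lam <- lambda * (pscount_weight * meff + (1 - pscount_weight))
  f1 <- matrix(0, L, Q)
  for (i in seq_len(L)) {
    for (a in seq_len(Q)) {
      s <- 0
      for (m in seq_len(M)) if (aln$encoded[m, i] == a - 1L) s <- s + w[m]
      f1[i, a] <- (lam / Q + s) / (lam + meff)
    }
  }
  f2 <- matrix(0, L * Q, L * Q)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      blk <- matrix(lam / Q^2, Q, Q)
      for (m in seq_len(M)) {
        a <- aln$encoded[m, i] + 1L
        b <- aln$encoded[m, j] + 1L
        blk[a, b] <- blk[a, b] + w[m]
      }
      blk <- blk / (lam + meff)
      if (i == j) blk <- diag(f1[i, ], nrow = Q)
      f2[(i - 1L) * Q + 1:Q, (j - 1L) * Q + 1:Q] <- blk
    }
  }
  gapfreq <- numeric(L)
  for (i in seq_len(L)) {
    gapfreq[i] <- sum(w[aln$encoded[, i] == 20L]) / meff
  }
  list(f1 = f1, f2 = f2, gapfreq = gapfreq)
}

oracle_covariance <- function(f1, f2, keep, cov20) {
  qr <- if (cov20) Q - 1L else Q
  cols <- which(keep)
  n <- length(cols)
  C <- matrix(0, n * qr, n * qr)
  for (bi in seq_len(n)) {
    for (bj in seq_len(n)) {
      i <- cols[bi]; j <- cols[bj]
      for (a in seq_len(qr)) {
        for (b in seq_len(qr)) {
          C[(bi - 1L) * qr + a, (bj - 1L) * qr + b] <-
            f2[(i - 1L) * Q + a, (j - 1L) * Q + b] - f1[i, a] * f1[j, b]
        }
      }
    }
  }
  (C + t(C)) / 2
}

oracle_block_norms <- function(Gamma, q, norm, include_gap_state) {
  n <- nrow(Gamma) %/% q
  qp <- if (!include_gap_state && q == Q) q - 1L else q
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      acc <- 0
      for (a in seq_len(qp)) {
        for (b in seq_len(qp)) {
          v <- Gamma[(i - 1L) * q + a, (j - 1L) * q + b]
          acc <- acc + if (norm == "frobenius") v * v else abs(v)
        }
      }
      S[i, j] <- if (norm == "frobenius") sqrt(acc) else acc
    }
  }
  S
}

oracle_precision_report <- function(pred, truth_pairs, L,
                                    n_values = c(1, 2, 5, 10),
                                    sep_values = c(4, 8, 11, 23)) {
  is_true <- function(i, j) {
    any(truth_pairs$i == i & truth_pairs$j == j)
  }
  out <- NULL
  for (sep in sep_values) {
    for (n in n_values) {
      taken_i <- c(); taken_j <- c()
      for (r in seq_len(nrow(pred))) {
        if (length(taken_i) >= floor(L / n)) break
        if (pred$j[r] - pred$i[r] > sep) {
          taken_i <- c(taken_i, pred$i[r]); taken_j <- c(taken_j, pred$j[r])
        }
      }
      k <- length(taken_i)
      prec <- if (k == 0) NA_real_ else {
        tp <- 0
        for (r in seq_len(k)) if (is_true(taken_i[r], taken_j[r])) tp <- tp + 1
        100 * tp / k
      }
      out <- rbind(out, data.frame(n = n, sep = sep, n_eval = k,
                                   precision = prec))
    }
  }
  out
}

# Minimal fixed-width PDB ATOM record writer for fixtures.
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          altloc = " ", occ = 1.00) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, sprintf(" %-3s", name), altloc, resname, chain, resno,
          x, y, z, occ, 0.0)
}
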