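#' Read per-residue contact-atom coordinates from a PDB file
#'
#' Parses standard fixed-width `ATOM` records (first model only, i.e. up to
#' the first `ENDMDL`) and returns one coordinate per residue in chain
#' order: the Cbeta atom, or the Calpha for glycine or when no Cbeta is
#' present. Alternate locations are resolved by highest occupancy, ties by
#' alphabetical altloc identifier. Residue indices in the result are
#' 1-based chain order; prediction-to-structure mapping is assumed to be
#' this identity mapping.
#'
#' @param file Path to a PDB coordinate file.
#' @param chain Chain identifier; `NULL` takes the first chain seen.
#' @return Data frame with `index`, `resno` (author numbering), `resname`,
#'   `atom`, `x`, `y`, `z`.
#' @export
read_structure <- function(file, chain = NULL) {
  lines <- readLines(file, warn = FALSE)
  end <- which(startsWith(lines, "ENDMDL"))
  if (length(end)) lines <- lines[seq_len(end[1L] - 1L)]
  lines <- lines[startsWith(lines, "ATOM")]
  if (length(lines) == 0L) {
    stop_coev("no ATOM records found", "coev_format_error")
  }
  at <- data.frame(
    name   = trimws(substr(lines, 13L, 16L)),
    altloc = substr(lines, 17L, 17L),
    resname = trimws(substr(lines, 18L, 20L)),
    chain  = substr(lines, 22L, 22L),
    resno  = as.integer(substr(lines, 23L, 26L)),
    icode  = substr(lines, 27L, 27L),
    x = as.numeric(substr(lines, 31L, 38L)),
    y = as.numeric(substr(lines, 39L, 46L)),
    z = as.numeric(substr(lines, 47L, 54L)),
    occ = suppressWarnings(as.numeric(substr(lines, 55L, 60L))),
    stringsAsFactors = FALSE
  )
  at$occ[is.na(at$occ)] <- 1
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop_coev(sprintf("chain '%s' not found in structure", chain),
              "coev_format_error")
  }
  key <- paste(at$resno, at$icode)
  keys <- unique(key)
  pick_atom <- function(sub, name) {
    cand <- sub[sub$name == name, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand <- cand[order(-cand$occ, cand$altloc), , drop = FALSE]
    cand[1L, , drop = FALSE]
  }
  out <- lapply(keys, function(k) {
    sub <- at[key == k, , drop = FALSE]
    a <- if (sub$resname[1L] == "GLY") pick_atom(sub, "CA") else {
      hit <- pick_atom(sub, "CB")
      if (is.null(hit)) pick_atom(sub, "CA") else hit
    }
    if (is.null(a)) {
      stop_coev(sprintf("residue %s %s has neither CB nor CA",
                        sub$resname[1L], trimws(k)), "coev_format_error")
    }
    a
  })
  out <- do.call(rbind, out)
  data.frame(index = seq_along(keys), resno = out$resno,
             resname = out$resname, atom = out$name,
             x = out$x, y = out$y, z = out$z, stringsAsFactors = FALSE)
}

new_contact_map <- function(pairs, L, threshold) {
  if (nrow(pairs)) {
    stopifnot(all(pairs$i < pairs$j), all(pairs$i >= 1), all(pairs$j <= L))
  }
  structure(list(L = L, pairs = pairs, threshold = threshold,
                 atom_rule = "CB, CA for glycine"),
            class = "coev_contact_map")
}

#' Derive the true contact map from residue coordinates
#'
#' Two residues are in contact when their contact-atom distance (Cbeta, or
#' Calpha for glycine) is strictly below `threshold` Angstrom -- the CASP
#' convention. A pair at exactly the threshold is *not* a contact.
#'
#' @param coords Data frame from [read_structure()] (needs `x`, `y`, `z`).
#' @param threshold Distance cutoff in Angstrom (default 8).
#' @return A `coev_contact_map`: list with `L`, `pairs` (data frame `i`,
#'   `j`, `i < j`, 1-based), `threshold`, `atom_rule`.
#' @export
contacts_from_structure <- function(coords, threshold = 8) {
  L <- nrow(coords)
  D <- as.matrix(stats::dist(coords[, c("x", "y", "z")]))
  idx <- which(upper.tri(D) & D < threshold, arr.ind = TRUE)
  new_contact_map(data.frame(i = idx[, 1L], j = idx[, 2L]), L, threshold)
}

#' Load a contact map from a two-column TSV of residue index pairs
#'
#' @param file Path to a TSV/whitespace-delimited file with columns `i`,
#'   `j` (1-based, any order per row).
#' @param L Residue count of the protein.
#' @return A `coev_contact_map`.
#' @export
read_contact_map <- function(file, L) {
  tab <- utils::read.table(file, header = FALSE,
                           col.names = c("i", "j"))[, 1:2]
  ij <- cbind(pmin(tab$i, tab$j), pmax(tab$i, tab$j))
  ij <- unique(ij)
  new_contact_map(data.frame(i = ij[, 1L], j = ij[, 2L]), L, NA_real_)
}

#' CASP-style precision of top-L/n contact predictions
#'
#' For every combination of list-length divisor `n` and separation band
#' `sep`, takes the first `floor(L / n)` predicted pairs with `j - i > sep`
#' (strict, the CASP convention -- note the predictor's own `mincontsep`
#' filter is inclusive) and reports the percentage that are true contacts.
#' A cell with no admissible pairs is reported as missing (`NA`), not 0.
#'
#' @param pred A ranked `coev_contacts` (or data frame with `i`, `j` in
#'   rank order).
#' @param truth A `coev_contact_map`.
#' @param L Target protein length; defaults to `truth$L`.
#' @param n_values Top-list divisors (default `c(1, 2, 5, 10)`).
#' @param sep_values Separation thresholds (default `c(4, 8, 11, 23)`).
#' @return A `coev_precision_report` data frame with columns `n`, `sep`,
#'   `n_eval` (pairs taken), `n_true`, `precision` (percent, `NA` when no
#'   pairs qualify).
#' @export
precision_report <- function(pred, truth, L = truth$L,
                             n_values = c(1, 2, 5, 10),
                             sep_values = c(4, 8, 11, 23)) {
  stopifnot(inherits(truth, "coev_contact_map"), is.data.frame(pred))
  true_keys <- paste(truth$pairs$i, truth$pairs$j)
  grid <- expand.grid(n = n_values, sep = sep_values)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    n <- grid$n[r]; sep <- grid$sep[r]
    cand <- pred[pred$j - pred$i > sep, , drop = FALSE]
    k <- min(floor(L / n), nrow(cand))
    if (k < 1L) {
      return(data.frame(n = n, sep = sep, n_eval = 0L, n_true = 0L,
                        precision = NA_real_))
    }
    taken <- cand[seq_len(k), , drop = FALSE]
    tp <- sum(paste(taken$i, taken$j) %in% true_keys)
    data.frame(n = n, sep = sep, n_eval = k, n_true = tp,
               precision = 100 * tp / k)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("coev_precision_report", "data.frame")
  out
}
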