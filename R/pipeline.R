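#' Parameter profiles for the two prediction families
#'
#' Returns the full run configuration for one of the three compatibility
#' profiles: `"evfold"` (mean-field DCA: dense covariance inversion over 20
#' states per site, heavy Meff-scaled pseudocount, Frobenius block norms),
#' `"psicov"` (sparse inverse covariance over 21 states with gap-column
#' masking, density-targeted graphical lasso, L1 block norms) and
#' `"psicov-sd"` ("sensible default": as `"psicov"` but a fixed
#' regularisation penalty, no density targeting). The numeric profile
#' constants are reconstructions from the cited methods -- the original
#' tool documents them only in its distribution, not in print -- and are
#' echoed into the run log for transparency. Explicit arguments to
#' [contact_pipeline()] override profile values.
#'
#' @param name `"evfold"`, `"psicov"` or `"psicov-sd"`.
#' @return A named list of parameters (a `RunConfig`).
#' @export
resolve_profile <- function(name = c("evfold", "psicov", "psicov-sd")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop_coev(
                     sprintf("unknown parameter profile '%s'", name[1L]),
                     "coev_usage_error"))
  base <- list(
    parprof = name,
    clustpc = 70, comparison = "ge",
    cov20 = TRUE,
    estimate_ivcov = FALSE,
    apply_gapth = FALSE, gapth = 0.9,
    pseudocnt = 1, pscount_weight = 1,
    density = NA_real_, rho = 0.001, icme_timeout = 1800,
    mincontsep = 5L,
    norm = "frobenius", include_gap_state = FALSE,
    min_meff = 1.5, shrink_step = 0.05,
    threads = 1L
  )
  if (name %in% c("psicov", "psicov-sd")) {
    base$clustpc <- 62
    base$cov20 <- FALSE
    base$estimate_ivcov <- TRUE
    base$apply_gapth <- TRUE
    base$pscount_weight <- 0
    base$norm <- "l1"
    base$density <- if (name == "psicov") 0.03 else NA_real_
  }
  base
}

#' Run the full contact-prediction pipeline
#'
#' Wires all stages: read/validate the alignment, clustering weights,
#' total-weight check, pseudocounted frequencies, gap-column masking,
#' covariance construction, coupling inference (shrinkage + graphical
#' lasso, or dense inversion), block norms, average product correction,
#' separation-filtered ranking and optional TSV output. The pipeline is
#' deterministic: identical input and configuration give byte-identical
#' output, independently of `threads` (accepted for interface
#' compatibility; the implementation contract is thread-count-independent
#' results).
#'
#' @param input A `coev_alignment`, a file path, or alignment text via
#'   `text`.
#' @param text Alignment content as text (alternative to a path in
#'   `input`).
#' @param format Alignment format passed to [read_alignment()].
#' @param parprof Parameter profile name; see [resolve_profile()].
#' @param ... Named overrides for any profile parameter (e.g.
#'   `clustpc = 80`, `density = 0.01`, `icme_timeout = 60`).
#' @param output Optional path; when given, contacts are written as TSV
#'   via [write_contacts()].
#' @return A `coev_run`: list with `contacts` (a `coev_contacts`),
#'   `log` (Meff, L, L_kept, shrinkage alpha, rho_final, density,
#'   per-stage times) and `config`.
#' @export
#' @examples
#' model <- planted_model(L = 12, M = 150, seed = 7,
#'                        coupled_pairs = data.frame(i = 2, j = 9, beta = 2))
#' run <- contact_pipeline(sample_alignment(model), parprof = "evfold",
#'                         mincontsep = 3)
#' head(run$contacts, 3)
contact_pipeline <- function(input, text = NULL, format = "auto",
                             parprof = "evfold", ..., output = NULL) {
  cfg <- resolve_profile(parprof)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop_coev(paste0("unknown parameter(s): ",
                     paste(unknown, collapse = ", ")), "coev_usage_error")
  }
  cfg[names(overrides)] <- overrides

  times <- c()
  tick <- local({
    last <- proc.time()[["elapsed"]]
    function(stage) {
      now <- proc.time()[["elapsed"]]
      times[[stage]] <<- now - last
      last <<- now
    }
  })

  aln <- if (inherits(input, "coev_alignment")) input else {
    read_alignment(file = if (is.null(text)) input else NULL,
                   text = text, format = format)
  }
  tick("read")

  ws <- compute_weights(aln, cfg$clustpc, cfg$comparison)
  check_total_weight(ws, cfg$min_meff)
  tick("seqw")

  ft <- frequency_tables(aln, ws, cfg$pseudocnt, cfg$pscount_weight)
  tick("pairfreq")

  keep <- gap_mask(ft$gapfreq, cfg$gapth, cfg$apply_gapth)
  cov <- build_covariance(ft, keep, cfg$cov20)
  tick("cov")

  sh <- shrink_to_positive_definite(cov, cfg$shrink_step)
  tick("shrink")

  prec <- if (cfg$estimate_ivcov) {
    if (is.na(cfg$density)) {
      glasso_estimate(sh, cfg$rho, timeout = cfg$icme_timeout)
    } else {
      glasso_with_density_target(sh, cfg$rho, cfg$density,
                                 timeout = cfg$icme_timeout)
    }
  } else {
    invert_covariance(sh)
  }
  tick("inv")

  S <- block_norms(prec, cfg$norm, cfg$include_gap_state)
  A <- apc(S)
  contacts <- rank_contacts(A, S, cfg$mincontsep,
                            target_residues = aln$target_residues)
  tick("score")

  if (!is.null(output)) write_contacts(contacts, output)

  log <- list(
    M = aln$M, L = aln$L, L_kept = length(cov$column_index),
    Meff = ws$Meff, alpha = sh$alpha,
    method = prec$method,
    rho_final = prec$rho_final, density = prec$density,
    converged = prec$converged,
    profile = cfg$parprof, stage_times = times
  )
  structure(list(contacts = contacts, log = log, config = cfg),
            class = "coev_run")
}

#' @export
print.coev_run <- function(x, ...) {
  cat(sprintf(
    "<coev_run> %s profile, %s: M = %d, L = %d (kept %d), Meff = %.4g, %d contacts\n",
    x$log$profile, x$log$method, x$log$M, x$log$L, x$log$L_kept,
    x$log$Meff, nrow(x$contacts)))
  invisible(x)
}
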