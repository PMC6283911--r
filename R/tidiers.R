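# broom-style tidy()/glance() methods for the package's fitted objects

#' Tidy a profile HMM into per-state emission rows
#'
#' @param x An `ear_phmm`.
#' @param ... Unused.
#' @return Tibble `state`, `residue`, `probability`, `log_odds`.
#' @export
tidy.ear_phmm <- function(x, ...) {
  em <- x$match_emissions
  lo <- log2(sweep(em, 2, x$background, "/"))
  tibble(
    state = rep(seq_len(nrow(em)), times = ncol(em)),
    residue = rep(colnames(em), each = nrow(em)),
    probability = as.vector(em),
    log_odds = as.vector(lo)
  ) |>
    arrange(.data$state, .data$residue)
}

#' One-row summary of a profile HMM
#'
#' @param x An `ear_phmm`.
#' @param ... Unused.
#' @return Tibble with `n_match`, `n_seqs`, `consensus`, `calibrated`,
#'   `gumbel_mu`, `gumbel_beta`.
#' @export
glance.ear_phmm <- function(x, ...) {
  tibble(
    n_match = x$n_match,
    n_seqs = x$n_seqs,
    consensus = x$consensus,
    calibrated = !is.null(x$calibration),
    gumbel_mu = x$calibration$mu %||% NA_real_,
    gumbel_beta = x$calibration$beta %||% NA_real_
  )
}

#' Tidy an iterative-search result into its candidate table
#'
#' @param x An `ear_search`.
#' @param ... Unused.
#' @return The candidates tibble (`protein_id`, `provenance`).
#' @export
tidy.ear_search <- function(x, ...) x$candidates

#' One-row summary of an iterative search
#'
#' @param x An `ear_search`.
#' @param ... Unused.
#' @return Tibble with `n_candidates`, `n_iterations`, `converged`,
#'   `evalue_cutoff`.
#' @export
glance.ear_search <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$candidates),
    n_iterations = max(x$log$iteration),
    converged = x$converged,
    evalue_cutoff = x$evalue_cutoff
  )
}

#' Tidy a network comparison into its matched ortholog pairs
#' @param x An `ear_net_comparison`.
#' @param ... Unused.
#' @return Tibble `gene_a`, `gene_b`.
#' @export
tidy.ear_net_comparison <- function(x, ...) x$pairs

#' One-row summary of a network comparison
#' @param x An `ear_net_comparison`.
#' @param ... Unused.
#' @return Tibble `n_pairs`, `n_genes_a`, `n_genes_b`.
#' @export
glance.ear_net_comparison <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_genes_a = x$n_genes_a, n_genes_b = x$n_genes_b)
}
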