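# ggplot2 views of the package's result types

#' Plot a profile HMM's match-state emissions
#'
#' Heatmap of per-state residue emission probabilities; the consensus
#' residue of each state is outlined.
#'
#' @param object An `ear_phmm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ear_phmm <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$state, y = .data$residue,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "match state", y = "residue",
                  title = sprintf("Profile emissions (consensus %s)",
                                  object$consensus)) +
    ggplot2::theme_minimal()
}

#' Plot the trajectory of an iterative EAR search
#'
#' Seed-set size and novel additions per iteration.
#'
#' @param object An `ear_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ear_search <- function(object, ...) {
  d <- object$log |>
    tidyr::pivot_longer(c("seeds_in", "novel_added"),
                        names_to = "series", values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$count,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "proteins",
                  title = "Seed expansion trajectory") +
    ggplot2::theme_minimal()
}

#' Plot cis-element enrichment results
#'
#' Bar chart of per-motif Z scores, filled by significance of the
#' calibrated (`p_raw`) statistic.
#'
#' @param result Tibble from [cis_enrichment()].
#' @param alpha Significance threshold (default 0.05).
#' @param raw Plot `z_raw` (default) instead of the platform's verbatim `z`.
#' @return A ggplot.
#' @export
plot_cis_enrichment <- function(result, alpha = 0.05, raw = TRUE) {
  result$zz <- if (raw) result$z_raw else result$z
  result$sig <- (if (raw) result$p_raw else result$p) < alpha
  ggplot2::ggplot(result, ggplot2::aes(x = stats::reorder(.data$motif, .data$zz),
                                       y = .data$zz, fill = .data$sig)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = if (raw) "Z (raw)" else "Z",
                  fill = sprintf("p < %g", alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a hit-location summary of an EAR motif scan
#'
#' Counts of hits by pattern class and positional class.
#'
#' @param hits Tibble from [scan_ear_motifs()].
#' @return A ggplot.
#' @export
plot_ear_hits <- function(hits) {
  d <- dplyr::count(hits, .data$pattern, .data$location)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$location, y = .data$n,
                                  fill = .data$pattern)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "motif location", y = "hits") +
    ggplot2::theme_minimal()
}
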