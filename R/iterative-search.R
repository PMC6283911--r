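# Iterative seed expansion: partition seeds by (pattern, location), build one
# profile per occupied subgroup, search the proteome, keep hits that pass the
# E-value cutoff AND carry a literal EAR pattern, feed novel proteins back in.

#' Partition seed proteins into (pattern, location) subgroups
#'
#' One subgroup per occupied combination of pattern class (`LxLxL`, `DLNP`)
#' and positional class (`N`, `M`, `C`), at most six. A protein with several
#' hits contributes a window to every subgroup its hits fall in.
#'
#' @param proteins Tibble with `id`, `seq` covering all seeds.
#' @param seed_ids Character vector of seed protein ids.
#' @param hits Optional precomputed hit tibble from [scan_ear_motifs()];
#'   scanned on the fly when omitted.
#' @param flank Window flank width (see [extract_seed_windows()]).
#' @return Tibble of seed windows with `pattern` and `location` keys; split
#'   by `dplyr::group_by(pattern, location)` to enumerate subgroups.
#' @export
partition_seeds <- function(proteins, seed_ids, hits = NULL, flank = 6L) {
  seeds <- filter(proteins, .data$id %in% seed_ids)
  absent <- setdiff(seed_ids, proteins$id)
  if (length(absent)) stop_earminer(sprintf("seed not in proteome: %s", absent[[1]]))
  hits <- hits %||% scan_ear_motifs(seeds)
  hits <- filter(hits, .data$protein_id %in% seed_ids)
  no_hit <- setdiff(seed_ids, hits$protein_id)
  if (length(no_hit)) {
    stop_earminer(sprintf("seed without any EAR motif: %s", no_hit[[1]]))
  }
  extract_seed_windows(seeds, hits, flank = flank) |>
    arrange(.data$pattern, .data$location, .data$protein_id, .data$start)
}

#' Build one profile HMM per seed subgroup
#'
#' @param windows Subgroup-keyed window tibble from [partition_seeds()].
#' @param background Residue background passed to [build_profile()].
#' @param flank Flank width the windows were extracted with.
#' @param pseudocount Emission/transition pseudocount.
#' @return List of `ear_phmm` objects, each tagged with its `pattern` and
#'   `location`.
#' @export
build_subgroup_profiles <- function(windows, background = NULL,
                                    flank = 6L, pseudocount = 1.0) {
  windows |>
    group_by(.data$pattern, .data$location) |>
    dplyr::group_map(function(w, key) {
      msa <- build_anchored_msa(mutate(w, pattern = key$pattern), flank = flank)
      hmm <- build_profile(msa, background = background, pseudocount = pseudocount)
      hmm$pattern <- key$pattern
      hmm$location <- key$location
      hmm
    })
}

#' Iterated profile-HMM identification of EAR proteins
#'
#' Runs the seed-expansion loop: build one profile per occupied
#' (pattern, location) subgroup from the current seeds, calibrate it, score
#' every pattern-carrying protein, keep proteins with `E < evalue_cutoff`
#' for at least one profile **and** at least one literal EAR motif, add the
#' novel ones to the seed set and repeat until no novel protein appears (or
#' `max_iter` is hit, flagged by `converged = FALSE`).
#'
#' @param proteins Proteome tibble (`id`, `seq`).
#' @param seed_ids Initial seed protein ids (must carry EAR motifs).
#' @param evalue_cutoff E-value threshold (default 0.01).
#' @param max_iter Safety cap on iterations (default 20).
#' @param seed Master seed; per-profile calibration seeds are derived from
#'   it, so results are deterministic.
#' @param flank,n_null,null_len See [extract_seed_windows()] and
#'   [calibrate()].
#' @param background Residue background (default bundled composition).
#' @return An object of class `ear_search`: list with `candidates` (tibble
#'   `protein_id`, `provenance`), `log` (per-iteration tibble), `converged`.
#' @export
hmm_iterate <- function(proteins, seed_ids, evalue_cutoff = 0.01,
                        max_iter = 20L, seed = 1L, flank = 6L,
                        n_null = 500L, null_len = 400L, background = NULL) {
  if (length(seed_ids) == 0L) stop_earminer("empty seed set")
  all_hits <- scan_ear_motifs(proteins)
  pattern_positive <- unique(all_hits$protein_id)
  no_hit <- setdiff(seed_ids, pattern_positive)
  if (length(no_hit)) {
    stop_earminer(sprintf("seed without any EAR motif: %s", no_hit[[1]]))
  }
  db_size <- nrow(proteins)
  # only pattern-positive proteins can ever pass the conjunctive filter
  scan_pool <- filter(proteins, .data$id %in% pattern_positive)

  current <- sort(unique(seed_ids))
  provenance <- tibble(protein_id = current, provenance = "seed")
  logs <- list()
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    windows <- partition_seeds(proteins, current,
                               hits = filter(all_hits, .data$protein_id %in% current),
                               flank = flank)
    profiles <- build_subgroup_profiles(windows, background = background,
                                        flank = flank)
    pass_e <- character(0)
    for (pi in seq_along(profiles)) {
      hmm <- calibrate(profiles[[pi]], n_null = n_null, null_len = null_len,
                       seed = derive_seed(seed, it, pi))
      sc <- score_sequences(hmm, scan_pool$seq)
      ev <- evalue(hmm, sc, db_size)
      pass_e <- union(pass_e, scan_pool$id[ev < evalue_cutoff])
    }
    pass_both <- intersect(pass_e, pattern_positive)
    novel <- sort(setdiff(pass_both, current))
    logs[[it]] <- tibble(
      iteration = it,
      seeds_in = length(current),
      n_profiles = length(profiles),
      hits_passing_evalue = length(pass_e),
      hits_passing_pattern = length(pass_both),
      novel_added = length(novel)
    )
    if (length(novel) == 0L) { converged <- TRUE; break }
    provenance <- bind_rows(provenance,
                            tibble(protein_id = novel,
                                   provenance = sprintf("hmm(%d)", it)))
    current <- sort(union(current, novel))
  }
  if (!converged) warn(sprintf("no convergence after %d iterations", max_iter))
  structure(list(
    candidates = arrange(provenance, .data$protein_id),
    log = bind_rows(logs),
    converged = converged,
    evalue_cutoff = evalue_cutoff,
    seed = seed
  ), class = "ear_search")
}

#' @export
print.ear_search <- function(x, ...) {
  cat(sprintf("<ear_search> %d candidate(s) after %d iteration(s)%s\n",
              nrow(x$candidates), max(x$log$iteration),
              if (x$converged) ", converged" else " (NOT converged)"))
  invisible(x)
}

#' Merge HMM-derived and ortholog-derived EAR candidates
#'
#' Union of the two candidate sources, with ortholog-derived members that
#' lack a literal EAR pattern removed. Members of both sources get
#' provenance `"both"`.
#'
#' @param hmm_result `ear_search` object (or its `candidates` tibble).
#' @param ortholog_ids Protein ids proposed by ortholog transfer.
#' @param proteins Proteome tibble; every id must resolve in it.
#' @return Tibble `protein_id`, `provenance`
#'   (`seed`/`hmm(k)`/`ortholog`/`both`).
#' @export
merge_candidates <- function(hmm_result, ortholog_ids, proteins) {
  cand <- if (inherits(hmm_result, "ear_search")) hmm_result$candidates else hmm_result
  absent <- setdiff(c(cand$protein_id, ortholog_ids), proteins$id)
  if (length(absent)) {
    stop_earminer(sprintf("candidate not in proteome: %s", absent[[1]]))
  }
  ortho <- filter(proteins, .data$id %in% ortholog_ids)
  keep <- ortho$id[purrr::map_int(ortho$seq, ~ nrow(find_ear_motifs(.x))) > 0]
  tibble(protein_id = union(cand$protein_id, keep)) |>
    left_join(cand, by = "protein_id") |>
    mutate(provenance = dplyr::case_when(
      .data$protein_id %in% keep & !is.na(.data$provenance) ~ "both",
      .data$protein_id %in% keep ~ "ortholog",
      .default = .data$provenance
    )) |>
    arrange(.data$protein_id)
}
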