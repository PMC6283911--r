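#' EAR pattern definitions
#'
#' The two EAR repression motif consensus patterns: `LxLxL` (leucines at
#' offsets 0, 2 and 4; length 5) and `DLNx[1,2]P` (`DLN`, one or two free
#' residues, then `P`; lengths 5 and 6). Free (`x`) positions match any
#' residue code including `X` and `U`; fixed positions require the exact
#' residue, so a degenerate code never satisfies a fixed position.
#'
#' @return Tibble with columns `pattern`, `regex` and `length`.
#' @export
ear_patterns <- function() {
  tibble(
    pattern = c("LxLxL", "DLNP", "DLNP"),
    regex = c("L.L.L", "DLN.P", "DLN..P"),
    length = c(5L, 5L, 6L)
  )
}

#' Find EAR motifs in one amino-acid sequence
#'
#' Scans a protein for literal `LxLxL` and `DLNx[1,2]P` matches. Every match
#' start position is reported (overlaps allowed); at a `D` admitting both a
#' 5-mer `DLNxP` and a 6-mer `DLNxxP`, both are reported.
#'
#' @param seq Amino-acid sequence string.
#' @param patterns Pattern table as from [ear_patterns()].
#' @return Tibble with columns `pattern`, `start`, `end` (1-based inclusive)
#'   and `matched`, sorted by `start` then match length.
#' @export
find_ear_motifs <- function(seq, patterns = ear_patterns()) {
  seq <- assert_aa_seq(seq)
  hits <- purrr::pmap(patterns, function(pattern, regex, length) {
    starts <- stringr::str_locate_all(seq, sprintf("(?=%s)", regex))[[1]][, "start"]
    starts <- starts[starts + length - 1L <= nchar(seq)]
    if (!base::length(starts)) return(NULL)
    tibble(pattern = pattern, start = as.integer(starts),
           end = as.integer(starts + length - 1L),
           matched = substr(rep(seq, base::length(starts)), starts, starts + length - 1L))
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble(pattern = character(), start = integer(), end = integer(),
                  matched = character()))
  }
  arrange(out, .data$start, .data$end)
}

#' Scan a whole proteome for EAR motifs
#'
#' Applies [find_ear_motifs()] to every record and classifies each hit's
#' positional class (N-terminal, Middle, C-terminal).
#'
#' @param proteins Tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param n_frac,c_frac Fractions of the protein length counted as the
#'   N-/C-terminal regions (defaults 0.25 each).
#' @return Tibble with columns `protein_id`, `pattern`, `start`, `end`,
#'   `matched`, `location`.
#' @export
scan_ear_motifs <- function(proteins, n_frac = 0.25, c_frac = 0.25) {
  stopifnot(all(c("id", "seq") %in% names(proteins)))
  rows <- purrr::map2(proteins$id, proteins$seq, function(id, seq) {
    h <- find_ear_motifs(seq)
    if (nrow(h) == 0L) return(NULL)
    h$protein_id <- id
    h$location <- classify_location(h$start, h$end, nchar(seq), n_frac, c_frac)
    h
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(protein_id = character(), pattern = character(),
                  start = integer(), end = integer(), matched = character(),
                  location = character()))
  }
  select(out, "protein_id", "pattern", "start", "end", "matched", "location")
}

#' Classify a motif hit's position within a protein
#'
#' A hit is `N`-terminal when it ends within the first `ceil(n_frac * L)`
#' residues, `C`-terminal when it starts within the last `ceil(c_frac * L)`
#' residues, and `M` (middle) otherwise. When both terminal conditions hold
#' (tiny proteins), `N` takes precedence.
#'
#' @param start,end 1-based inclusive hit coordinates (vectorised).
#' @param seq_len Protein length in residues.
#' @param n_frac,c_frac Terminal-region fractions; must satisfy
#'   `0 < n_frac`, `0 < c_frac`, `n_frac + c_frac <= 1`.
#' @return Character vector of `"N"`, `"M"` or `"C"`.
#' @export
classify_location <- function(start, end, seq_len, n_frac = 0.25, c_frac = 0.25) {
  if (n_frac <= 0 || c_frac <= 0 || n_frac + c_frac > 1) {
    stop_earminer("need 0 < n_frac, 0 < c_frac and n_frac + c_frac <= 1")
  }
  if (any(start < 1 | end > seq_len | start > end)) {
    stop_earminer("hit outside sequence bounds")
  }
  n_cut <- ceiling(n_frac * seq_len)
  c_start <- seq_len - ceiling(c_frac * seq_len) + 1
  dplyr::case_when(
    end <= n_cut ~ "N",
    start >= c_start ~ "C",
    .default = "M"
  )
}

#' Classify proteins by which EAR pattern classes they carry
#'
#' @param hits Hit tibble from [scan_ear_motifs()] (may cover many proteins).
#' @param protein_ids Optional ids to classify (defaults to those in `hits`);
#'   ids without hits are classified `none`.
#' @return Tibble with columns `protein_id` and `membership`
#'   (`LxLxL-only`, `DLNP-only`, `both` or `none`).
#' @export
classify_pattern_membership <- function(hits, protein_ids = NULL) {
  protein_ids <- protein_ids %||% unique(hits$protein_id)
  per <- hits |>
    group_by(.data$protein_id) |>
    summarise(
      has_l = any(.data$pattern == "LxLxL"),
      has_d = any(.data$pattern == "DLNP"),
      .groups = "drop"
    ) |>
    mutate(membership = dplyr::case_when(
      .data$has_l & .data$has_d ~ "both",
      .data$has_l ~ "LxLxL-only",
      .data$has_d ~ "DLNP-only"
    )) |>
    select("protein_id", "membership")
  tibble(protein_id = protein_ids) |>
    left_join(per, by = "protein_id") |>
    mutate(membership = dplyr::coalesce(.data$membership, "none"))
}
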