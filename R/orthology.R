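# Reciprocal-best-hit orthology with bootstrap support: a deliberately small
# stand-in for the inparanoid pipeline, keeping only what downstream steps
# observe (ortholog pairs above a support cutoff).

blosum62_ext <- function() {
  bl <- get_blosum62()
  m <- matrix(0, 24, 24, dimnames = list(AA_EXT, AA_EXT))
  have <- intersect(AA_EXT, rownames(bl))
  m[have, have] <- bl[have, have]
  # U (selenocysteine) scored like C; absent codes fall back to X's column
  if (!"U" %in% rownames(bl)) {
    m["U", ] <- m["C", ]; m[, "U"] <- m[, "C"]; m["U", "U"] <- m["C", "C"]
  }
  m
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

encode_aa_ext <- function(seq) {
  idx <- match(stringr::str_split_1(toupper(seq), ""), AA_EXT)
  if (anyNA(idx)) stop_earminer("invalid residue in sequence")
  idx - 1L
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps (BLOSUM62, gap open 11, gap extend 1 by
#' default, mirroring common protein-BLAST settings). Returns the optimal
#' score and the aligned residue columns of one optimal alignment.
#'
#' @param a,b Amino-acid sequence strings.
#' @param gap_open,gap_extend Affine gap parameters (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @return List with `score` and `columns` (tibble `pos_a`, `pos_b`,
#'   `res_a`, `res_b`, `subst` for each aligned residue pair).
#' @export
align_local <- function(a, b, gap_open = 11, gap_extend = 1) {
  a <- assert_aa_seq(a, "sequence a"); b <- assert_aa_seq(b, "sequence b")
  subst <- blosum62_ext()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(chartr("U", "C", a)),
    Biostrings::AAString(chartr("U", "C", b)),
    type = "local", substitutionMatrix = get_blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pat <- stringr::str_split_1(as.character(Biostrings::alignedPattern(pa)), "")
  sub <- stringr::str_split_1(as.character(Biostrings::alignedSubject(pa)), "")
  both <- pat != "-" & sub != "-"
  pos_a <- Biostrings::start(Biostrings::pattern(pa)) - 1L + cumsum(pat != "-")
  pos_b <- Biostrings::start(Biostrings::subject(pa)) - 1L + cumsum(sub != "-")
  cols <- tibble(
    pos_a = pos_a[both], pos_b = pos_b[both],
    res_a = pat[both], res_b = sub[both]
  )
  cols$subst <- subst[cbind(cols$res_a, cols$res_b)]
  list(score = max(0, Biostrings::score(pa)), columns = cols)
}

# all-vs-all local alignment scores (rows = a, cols = b)
sw_score_matrix <- function(seqs_a, seqs_b, gap_open = 11, gap_extend = 1) {
  subst <- blosum62_ext()
  ea <- lapply(seqs_a, encode_aa_ext)
  eb <- lapply(seqs_b, encode_aa_ext)
  out <- matrix(0, length(ea), length(eb))
  for (i in seq_along(ea)) {
    for (j in seq_along(eb)) {
      out[i, j] <- sw_score_cpp(ea[[i]], eb[[j]], subst, gap_open, gap_extend)
    }
  }
  out
}

# shared 4-mer counts used to restrict all-vs-all DP on large proteomes
kmer_candidate_sets <- function(seqs_a, seqs_b, k = 4L, top = 50L) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  kb <- lapply(seqs_b, kmers)
  inv <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(kb)) for (km in kb[[j]]) {
    inv[[km]] <- c(inv[[km]] %||% integer(0), j)
  }
  lapply(seqs_a, function(s) {
    hits <- unlist(lapply(kmers(s), function(km) inv[[km]] %||% integer(0)))
    if (!length(hits)) return(integer(0))
    cnt <- sort(table(hits), decreasing = TRUE)
    as.integer(names(head(cnt, top)))
  })
}

bootstrap_support <- function(cols_best, cols_runner, n_boot, seed) {
  if (is.null(cols_runner)) return(100)
  nb <- nrow(cols_best); nr <- nrow(cols_runner)
  if (nb == 0L) return(0)
  wins <- with_seed(seed, {
    s_best <- vapply(seq_len(n_boot), function(i)
      sum(cols_best$subst[sample.int(nb, nb, replace = TRUE)]), 0)
    s_run <- vapply(seq_len(n_boot), function(i)
      if (nr == 0L) 0 else
        sum(cols_runner$subst[sample.int(nr, nr, replace = TRUE)]), 0)
    sum(s_best > s_run) + 0.5 * sum(s_best == s_run)
  })
  100 * wins / n_boot
}

#' Predict orthologs between two proteomes by reciprocal best hits
#'
#' All-vs-all local alignment (BLOSUM62 11/1) gives each protein's best hit
#' in the other proteome; reciprocal best pairs become candidates. Support
#' is the percentage of `n_boot` column resamples (aligned columns drawn
#' with replacement, best pair and runner-up resampled independently, ties
#' counted half) in which the pair outscores the query's runner-up subject;
#' a query without a runner-up gets support 100. Pairs with
#' `support > support_cutoff` are returned.
#'
#' @param proteome_a,proteome_b Tibbles with `id`, `seq`.
#' @param n_boot Bootstrap resamples (default 100).
#' @param support_cutoff Minimum support, exclusive (default 60, i.e. the
#'   pair needs over 60% support).
#' @param seed Integer seed; results are deterministic given it.
#' @param gap_open,gap_extend Alignment gap parameters.
#' @param prefilter_above All-vs-all DP is restricted to the `prefilter_top`
#'   subjects sharing the most 4-mers with the query when the subject
#'   proteome exceeds this size.
#' @param prefilter_top Candidates kept per query by the prefilter.
#' @return Tibble `gene_a`, `gene_b`, `score`, `support`, sorted by
#'   `gene_a`.
#' @export
find_orthologs <- function(proteome_a, proteome_b, n_boot = 100L,
                           support_cutoff = 60, seed = 1L,
                           gap_open = 11, gap_extend = 1,
                           prefilter_above = 2000L, prefilter_top = 50L) {
  if (nrow(proteome_a) == 0L || nrow(proteome_b) == 0L) {
    stop_earminer("both proteomes must be non-empty")
  }
  ids_a <- proteome_a$id; ids_b <- proteome_b$id
  subst <- blosum62_ext()
  ea <- lapply(proteome_a$seq, encode_aa_ext)
  eb <- lapply(proteome_b$seq, encode_aa_ext)

  use_prefilter <- length(eb) > prefilter_above || length(ea) > prefilter_above
  cand <- if (use_prefilter) {
    kmer_candidate_sets(proteome_a$seq, proteome_b$seq, top = prefilter_top)
  } else {
    rep(list(seq_along(eb)), length(ea))
  }
  S <- matrix(-Inf, length(ea), length(eb), dimnames = list(ids_a, ids_b))
  for (i in seq_along(ea)) {
    for (j in cand[[i]]) {
      S[i, j] <- sw_score_cpp(ea[[i]], eb[[j]], subst, gap_open, gap_extend)
    }
  }

  # best hits with lexicographic tie-break
  best_of <- function(scores, ids) {
    mx <- max(scores)
    list(idx = which(scores == mx)[order(ids[scores == mx])][1], score = mx)
  }
  best_ab <- purrr::map(seq_along(ea), ~ best_of(S[.x, ], ids_b))
  best_ba <- purrr::map(seq_along(eb), ~ best_of(S[, .x], ids_a))

  pairs <- list()
  for (i in seq_along(ea)) {
    j <- best_ab[[i]]$idx
    if (!is.finite(best_ab[[i]]$score) || best_ab[[i]]$score <= 0) next
    if (best_ba[[j]]$idx != i) next
    # runner-up subject for query i (second-highest scoring subject)
    ord <- order(-S[i, ], ids_b)
    runner <- if (length(ord) >= 2 && is.finite(S[i, ord[2]]) && S[i, ord[2]] > 0) ord[2] else NA_integer_
    al_best <- align_local(proteome_a$seq[i], proteome_b$seq[j],
                           gap_open, gap_extend)
    al_run <- if (!is.na(runner)) {
      align_local(proteome_a$seq[i], proteome_b$seq[runner],
                  gap_open, gap_extend)
    } else NULL
    supp <- bootstrap_support(al_best$columns, al_run$columns %||% NULL,
                              n_boot, derive_seed(seed, i, j))
    pairs[[length(pairs) + 1L]] <- tibble(
      gene_a = ids_a[i], gene_b = ids_b[j],
      score = S[i, j], support = supp
    )
  }
  out <- bind_rows(pairs)
  if (nrow(out) == 0L) {
    return(tibble(gene_a = character(), gene_b = character(),
                  score = double(), support = double()))
  }
  arrange(filter(out, .data$support > support_cutoff), .data$gene_a)
}

#' Transfer EAR candidates across species through ortholog pairs
#'
#' @param pairs Tibble from [find_orthologs()].
#' @param seed_ids Species-A protein ids to transfer.
#' @return Unique species-B ids orthologous to any seed.
#' @export
transfer_candidates <- function(pairs, seed_ids) {
  sort(unique(pairs$gene_b[pairs$gene_a %in% seed_ids]))
}

#' Predict a species-B interaction network from a species-A network
#'
#' An edge is transferred when both endpoints have orthologs; many-to-many
#' mappings expand to all combinations; self-loops are dropped.
#'
#' @param network_a Edge tibble (`from`, `to`) with species-A ids.
#' @param pairs Ortholog pairs from [find_orthologs()].
#' @return Edge tibble with species-B ids (deduplicated, `from < to`).
#' @export
transfer_network <- function(network_a, pairs) {
  mapped <- network_a |>
    inner_join(pairs |> select(from = "gene_a", from_b = "gene_b"),
               by = "from", relationship = "many-to-many") |>
    inner_join(pairs |> select(to = "gene_a", to_b = "gene_b"),
               by = "to", relationship = "many-to-many") |>
    filter(.data$from_b != .data$to_b) |>
    mutate(from = pmin(.data$from_b, .data$to_b),
           to = pmax(.data$from_b, .data$to_b)) |>
    select("from", "to") |>
    distinct() |>
    arrange(.data$from, .data$to)
  mapped
}
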