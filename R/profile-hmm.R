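# Profile HMMs over EAR seed windows: anchored MSA -> profile -> local
# log2-odds scoring (Viterbi / forward) -> Gumbel-calibrated E-values.

encode_aa <- function(seq) {
  idx <- match(stringr::str_split_1(toupper(seq), ""), AA_STANDARD)
  ifelse(is.na(idx), -1L, idx - 1L)
}

#' Extract seed windows around EAR motif hits
#'
#' Cuts the motif plus `flank` residues on each side out of every hit's
#' protein; windows truncated at sequence ends record the truncation through
#' `motif_offset` (0-based start of the motif within the window).
#'
#' @param proteins Tibble with `id`, `seq`.
#' @param hits Hit tibble from [scan_ear_motifs()] (needs `protein_id`,
#'   `pattern`, `start`, `end`, `location`).
#' @param flank Residues kept on each side of the motif (default 6, i.e. up
#'   to 12 adjoining residues per window).
#' @return `hits` with added columns `window`, `motif_offset`, `motif_len`.
#' @export
extract_seed_windows <- function(proteins, hits, flank = 6L) {
  seqs <- setNames(proteins$seq, proteins$id)
  missing <- setdiff(hits$protein_id, proteins$id)
  if (length(missing)) {
    stop_earminer(sprintf("hit for unknown protein: %s", missing[[1]]))
  }
  s <- seqs[hits$protein_id]
  ws <- pmax(1L, hits$start - flank)
  we <- pmin(nchar(s), hits$end + flank)
  hits |>
    mutate(
      window = unname(substr(s, ws, we)),
      motif_offset = unname(hits$start - ws),
      motif_len = .data$end - .data$start + 1L
    )
}

#' Align seed windows of one subgroup by motif anchoring
#'
#' Rows are aligned on the motif's fixed residues: the motif occupies a fixed
#' block of columns (`5` for `LxLxL`, `6` for `DLNx[1,2]P`; 5-mer `DLNxP`
#' windows receive one gap in the second free position), flanks are padded
#' with `-` where clipped.
#'
#' @param windows Tibble from [extract_seed_windows()]; all rows must share
#'   one pattern.
#' @param flank Flank width used when the windows were extracted.
#' @return Character matrix (rows = windows, columns = alignment positions),
#'   rownames = protein ids.
#' @export
build_anchored_msa <- function(windows, flank = 6L) {
  if (nrow(windows) == 0L) stop_earminer("no windows to align")
  pat <- unique(windows$pattern)
  if (length(pat) != 1L) {
    stop_earminer(sprintf("windows mix patterns: %s", paste(pat, collapse = ", ")))
  }
  motif_block <- if (pat == "DLNP") 6L else 5L
  ncol_total <- 2L * flank + motif_block
  rows <- purrr::pmap(windows, function(window, motif_offset, motif_len, ...) {
    chars <- stringr::str_split_1(window, "")
    left <- chars[seq_len(motif_offset)]
    motif <- chars[motif_offset + seq_len(motif_len)]
    right <- chars[-seq_len(motif_offset + motif_len)]
    if (pat == "DLNP" && motif_len == 5L) {
      # D L N x [gap] P aligned against the 6-mer frame
      motif <- c(motif[1:4], "-", motif[5])
    }
    c(rep("-", flank - length(left)), left,
      motif,
      right, rep("-", flank - length(right)))
  })
  bad <- lengths(rows) != ncol_total
  if (any(bad)) stop_earminer("window wider than flank allows; re-extract with matching flank")
  msa <- do.call(rbind, rows)
  rownames(msa) <- windows$protein_id
  msa
}

#' Build a profile HMM from an anchored alignment
#'
#' Columns whose residue occupancy reaches `occupancy` become match states;
#' all-gap columns are dropped with a warning. Match emissions are
#' pseudocount-smoothed observed frequencies,
#' `(count + pseudocount * background) / (n + pseudocount)`; insert states
#' emit the background. Transition probabilities are counted from the gap
#' structure with the same pseudocount spread uniformly over each state's
#' allowed moves.
#'
#' @param msa Character matrix from [build_anchored_msa()].
#' @param background Named residue frequency vector (default: bundled
#'   average composition).
#' @param pseudocount Dirichlet pseudocount mass (default 1).
#' @param occupancy Minimum non-gap fraction for a match column (default 0.5).
#' @return An object of class `ear_phmm`.
#' @export
build_profile <- function(msa, background = NULL, pseudocount = 1.0,
                          occupancy = 0.5) {
  if (is.null(dim(msa)) || nrow(msa) == 0L) stop_earminer("empty alignment")
  background <- normalise_background(background)
  occ <- colMeans(msa != "-")
  if (any(occ == 0)) {
    warn(sprintf("dropping %d all-gap column(s)", sum(occ == 0)))
    msa <- msa[, occ > 0, drop = FALSE]
    occ <- occ[occ > 0]
  }
  is_match <- occ >= occupancy
  m <- sum(is_match)
  if (m == 0L) stop_earminer("no match columns at this occupancy")

  em <- matrix(0, nrow = m, ncol = 20, dimnames = list(NULL, AA_STANDARD))
  mcols <- which(is_match)
  for (k in seq_len(m)) {
    res <- msa[, mcols[k]]
    res <- res[res %in% AA_STANDARD]
    cnt <- table(factor(res, levels = AA_STANDARD))
    em[k, ] <- (as.numeric(cnt) + pseudocount * background) /
      (length(res) + pseudocount)
  }

  # transition counts from each row's path through the column classes
  cnt0 <- function() stats::setNames(numeric(7), c("mm", "mi", "md", "im", "ii", "dm", "dd"))
  counts <- replicate(m + 1, cnt0(), simplify = FALSE)
  pos_of_col <- cumsum(is_match)  # match-state index reached after each column
  for (r in seq_len(nrow(msa))) {
    state <- "m"; pos <- 0L
    for (cix in seq_len(ncol(msa))) {
      ch <- msa[r, cix]
      if (is_match[cix]) {
        nxt <- if (ch == "-") "d" else "m"
        counts[[pos + 1L]][paste0(state, nxt)] <-
          counts[[pos + 1L]][paste0(state, nxt)] + 1
        state <- nxt; pos <- pos_of_col[cix]
      } else if (ch != "-") {
        if (state == "d") next  # no D->I in this architecture
        counts[[pos + 1L]][paste0(state, "i")] <-
          counts[[pos + 1L]][paste0(state, "i")] + 1
        state <- "i"
      }
    }
    # exit: state -> End, counted in the position-m slot as *->"m" (match/End)
    counts[[m + 1L]][paste0(state, "m")] <- counts[[m + 1L]][paste0(state, "m")] + 1
  }

  smooth <- function(cv, allowed, pc = pseudocount) {
    tot <- sum(cv[allowed]) + pc
    p <- stats::setNames(rep(0, length(cv)), names(cv))
    p[allowed] <- (cv[allowed] + pc / length(allowed)) / tot
    p
  }
  mm <- mi <- md <- im <- ii <- dm <- dd <- rep(-Inf, m + 1)
  for (j in 0:m) {
    cv <- counts[[j + 1L]]
    last <- j == m
    aM <- if (last) c("mm", "mi") else c("mm", "mi", "md")
    pM <- smooth(cv, aM)
    mm[j + 1] <- log2(pM["mm"]); mi[j + 1] <- log2(pM["mi"])
    md[j + 1] <- if (last) -Inf else log2(pM["md"])
    aI <- c("im", "ii")
    pI <- smooth(cv, aI)
    im[j + 1] <- log2(pI["im"]); ii[j + 1] <- log2(pI["ii"])
    if (j >= 1) {
      aD <- if (last) "dm" else c("dm", "dd")
      pD <- smooth(cv, aD)
      dm[j + 1] <- log2(pD["dm"])
      dd[j + 1] <- if (last) -Inf else log2(pD["dd"])
    }
  }

  structure(list(
    n_match = m,
    match_emissions = em,
    insert_emissions = background,
    transitions = list(mm = mm, mi = mi, md = md, im = im, ii = ii,
                       dm = dm, dd = dd),
    background = background,
    consensus = paste(AA_STANDARD[apply(em, 1, which.max)], collapse = ""),
    n_seqs = nrow(msa),
    calibration = NULL
  ), class = "ear_phmm")
}

#' @export
print.ear_phmm <- function(x, ...) {
  cat(sprintf("<ear_phmm> %d match states from %d window(s); consensus %s; %s\n",
              x$n_match, x$n_seqs, x$consensus,
              if (is.null(x$calibration)) "uncalibrated"
              else sprintf("Gumbel(mu=%.2f, beta=%.2f)",
                           x$calibration$mu, x$calibration$beta)))
  invisible(x)
}

phmm_args <- function(hmm) {
  lo <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  c(list(em_lo = lo), hmm$transitions)
}

#' Score a protein sequence against a profile HMM
#'
#' Best local placement of the full profile in the sequence: flanking
#' residues are free, the profile may skip columns through delete states and
#' absorb extra residues through background-emitting insert states. The
#' score is the log2-odds (bits) of the alignment against the background
#' model; `forward` replaces the max over paths by the log-sum.
#'
#' @param hmm An `ear_phmm`.
#' @param seq Amino-acid sequence string.
#' @param mode `"viterbi"` (default, reported score) or `"forward"`.
#' @return Bitscore (double).
#' @export
score_sequence <- function(hmm, seq, mode = c("viterbi", "forward")) {
  mode <- match.arg(mode)
  seq <- assert_aa_seq(seq)
  a <- phmm_args(hmm)
  hmm_score_cpp(encode_aa(seq), a$em_lo, a$mm, a$mi, a$md, a$im, a$ii,
                a$dm, a$dd, mode == "viterbi")
}

score_sequences <- function(hmm, seqs, mode = "viterbi") {
  a <- phmm_args(hmm)
  enc <- lapply(seqs, encode_aa)
  hmm_score_batch_cpp(enc, a$em_lo, a$mm, a$mi, a$md, a$im, a$ii,
                      a$dm, a$dd, mode == "viterbi")
}

fit_gumbel_ml <- function(x) {
  beta0 <- sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.57721566 * beta0
  nll <- function(par) {
    beta <- exp(par[2])
    z <- (x - par[1]) / beta
    length(x) * log(beta) + sum(z) + sum(exp(-z))
  }
  fit <- tryCatch(
    optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead"),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$convergence != 0) {
    return(list(mu = mu0, beta = beta0, method = "moments"))
  }
  list(mu = fit$par[1], beta = exp(fit$par[2]), method = "ml")
}

#' Calibrate a profile HMM's E-value statistics
#'
#' Scores `n_null` i.i.d. background sequences of length `null_len` with the
#' Viterbi algorithm and fits a Gumbel (location/scale) to the max scores by
#' maximum likelihood; the empirical null sample is retained as a fallback.
#'
#' @param hmm An `ear_phmm`.
#' @param background Residue frequencies for the null sequences (defaults to
#'   the profile's background).
#' @param n_null Number of null sequences (>= 100).
#' @param null_len Null sequence length in residues.
#' @param seed Integer seed; the calibration is deterministic given it.
#' @return The `ear_phmm` with a `calibration` element
#'   (`mu`, `beta`, `method`, `null_scores`, `null_len`).
#' @export
calibrate <- function(hmm, background = NULL, n_null = 1000L, null_len = 400L,
                      seed = 1L) {
  if (n_null < 100L) stop_earminer("n_null must be >= 100")
  background <- normalise_background(background %||% hmm$background)
  scores <- with_seed(seed, {
    seqs <- replicate(n_null, paste(
      sample(AA_STANDARD, null_len, replace = TRUE, prob = background),
      collapse = ""), simplify = TRUE)
    score_sequences(hmm, seqs, mode = "viterbi")
  })
  if (sd(scores) < 1e-9) stop_earminer("degenerate null score variance")
  fit <- fit_gumbel_ml(scores)
  hmm$calibration <- list(mu = fit$mu, beta = fit$beta, method = fit$method,
                          null_scores = scores, null_len = null_len,
                          seed = as.integer(seed))
  hmm
}

gumbel_tail <- function(s, mu, beta) {
  # P(S >= s) for a Gumbel(mu, beta), computed stably in the far tail
  t <- exp(-(s - mu) / beta)
  -expm1(-t)
}

#' E-value of a bitscore against a calibrated profile
#'
#' `E = db_size * P(S >= bitscore)` under the profile's Gumbel null:
#' the expected number of unrelated sequences reaching the score in a search
#' of `db_size` sequences.
#'
#' @param hmm Calibrated `ear_phmm`.
#' @param bitscore Score(s) from [score_sequence()] (vectorised).
#' @param db_size Number of sequences searched.
#' @return E-value(s).
#' @export
evalue <- function(hmm, bitscore, db_size) {
  if (is.null(hmm$calibration)) stop_earminer("profile is not calibrated")
  db_size * gumbel_tail(bitscore, hmm$calibration$mu, hmm$calibration$beta)
}

#' Serialise a profile HMM to JSON
#'
#' @param hmm An `ear_phmm` (calibrated or not).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(hmm, path) {
  obj <- list(
    n_match = hmm$n_match,
    residues = AA_STANDARD,
    match_emissions = unname(apply(hmm$match_emissions, 1, as.list)),
    transitions = hmm$transitions,
    background = as.list(hmm$background),
    consensus = hmm$consensus,
    n_seqs = hmm$n_seqs,
    pattern = hmm$pattern %||% NA,
    location = hmm$location %||% NA,
    calibration = if (is.null(hmm$calibration)) NULL else
      hmm$calibration[c("mu", "beta", "method", "null_len", "seed")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a profile HMM from JSON
#'
#' @param path Path written by [write_profile_json()].
#' @return An `ear_phmm` (without the empirical null sample).
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  em <- if (is.data.frame(obj$match_emissions)) {
    as.matrix(obj$match_emissions)
  } else {
    do.call(rbind, obj$match_emissions)
  }
  colnames(em) <- obj$residues
  trans <- lapply(obj$transitions, function(v) { v[is.na(v)] <- -Inf; v })
  structure(list(
    n_match = obj$n_match,
    match_emissions = em,
    insert_emissions = unlist(obj$background),
    transitions = trans,
    background = unlist(obj$background),
    consensus = obj$consensus,
    n_seqs = obj$n_seqs,
    pattern = if (is.null(obj$pattern) || is.na(obj$pattern)) NULL else obj$pattern,
    location = if (is.null(obj$location) || is.na(obj$location)) NULL else obj$location,
    calibration = if (is.null(obj$calibration)) NULL else obj$calibration
  ), class = "ear_phmm")
}
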