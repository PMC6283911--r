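# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and closed forms only.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# exhaustive substring check of the EAR pattern definitions
oracle_ear_scan <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (s in seq_len(n)) {
    # LxLxL: length 5, L at offsets 0, 2, 4
    if (s + 4 <= n && chars[s] == "L" && chars[s + 2] == "L" && chars[s + 4] == "L") {
      hits[[length(hits) + 1]] <- data.frame(pattern = "LxLxL", start = s, end = s + 4)
    }
    # DLNxP: length 5
    if (s + 4 <= n && chars[s] == "D" && chars[s + 1] == "L" &&
        chars[s + 2] == "N" && chars[s + 4] == "P") {
      hits[[length(hits) + 1]] <- data.frame(pattern = "DLNP", start = s, end = s + 4)
    }
    # DLNxxP: length 6
    if (s + 5 <= n && chars[s] == "D" && chars[s + 1] == "L" &&
        chars[s + 2] == "N" && chars[s + 5] == "P") {
      hits[[length(hits) + 1]] <- data.frame(pattern = "DLNP", start = s, end = s + 5)
    }
  }
  if (!length(hits)) {
    return(data.frame(pattern = character(), start = integer(), end = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$end), , drop = FALSE]
}

# exhaustive path enumeration over the profile-HMM state machine; returns all
# complete-path log2 scores (every Begin offset separately)
oracle_hmm_paths <- function(hmm, seq) {
  enc <- match(strsplit(seq, "")[[1]], AA20) - 1L
  m <- hmm$n_match
  lo <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  tr <- hmm$transitions
  L <- length(enc)
  scores <- c()
  emit <- function(j, i) if (!is.na(enc[i])) lo[j, enc[i] + 1] else 0

  recurse <- function(state, j, i, acc) {
    if (j == m) {
      ex <- switch(state, m = tr$mm[m + 1], i = tr$im[m + 1], d = tr$dm[m + 1])
      scores <<- c(scores, acc + ex)
    }
    if (state == "m") {
      if (j < m && i < L) {
        recurse("m", j + 1, i + 1, acc + tr$mm[j + 1] + emit(j + 1, i + 1))
      }
      if (i < L) recurse("i", j, i + 1, acc + tr$mi[j + 1])
      if (j < m) recurse("d", j + 1, i, acc + tr$md[j + 1])
    } else if (state == "i") {
      if (j < m && i < L) {
        recurse("m", j + 1, i + 1, acc + tr$im[j + 1] + emit(j + 1, i + 1))
      }
      if (i < L) recurse("i", j, i + 1, acc + tr$ii[j + 1])
    } else if (state == "d") {
      if (j < m && i < L) {
        recurse("m", j + 1, i + 1, acc + tr$dm[j + 1] + emit(j + 1, i + 1))
      }
      if (j < m) recurse("d", j + 1, i, acc + tr$dd[j + 1])
    }
  }
  for (i0 in 0:L) recurse("m", 0L, i0, 0)
  scores
}

oracle_hmm_viterbi <- function(hmm, seq) max(oracle_hmm_paths(hmm, seq))
oracle_hmm_forward <- function(hmm, seq) {
  s <- oracle_hmm_paths(hmm, seq)
  mx <- max(s)
  mx + log2(sum(2^(s - mx)))
}

# random small profile for the enumeration tests
random_toy_profile <- function(n_match, n_rows = 3, ncols = NULL) {
  ncols <- ncols %||% n_match
  msa <- matrix(sample(AA20, n_rows * ncols, replace = TRUE), n_rows, ncols)
  # sprinkle gaps but keep occupancy above 0.5 in the first n_match columns
  if (ncols > n_match) {
    for (cix in (n_match + 1):ncols) {
      gaps <- sample(n_rows, max(1L, n_rows - 1L))
      msa[gaps, cix] <- "-"
    }
  }
  build_profile(msa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force k-clique percolation: all k-subsets, pairwise overlap, components
oracle_k_clique_modules <- function(edges, k) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  has_edge <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% key
  if (length(nodes) < k) return(list())
  subsets <- utils::combn(nodes, k, simplify = FALSE)
  cliques <- Filter(function(s) {
    prs <- utils::combn(s, 2)
    all(has_edge(prs[1, ], prs[2, ]))
  }, subsets)
  nc <- length(cliques)
  if (nc == 0) return(list())
  adj <- matrix(FALSE, nc, nc)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    adj[i, j] <- i != j && length(intersect(cliques[[i]], cliques[[j]])) == k - 1
  }
  seen <- rep(FALSE, nc)
  mods <- list()
  for (i in seq_len(nc)) {
    if (seen[i]) next
    comp <- i
    frontier <- i
    seen[i] <- TRUE
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    mods[[length(mods) + 1]] <- sort(unique(unlist(cliques[comp])))
  }
  mods
}

module_set <- function(modules_tbl) {
  if (nrow(modules_tbl) == 0) return(list())
  unname(lapply(split(modules_tbl$member, modules_tbl$module), sort))
}

set_of_sets_equal <- function(a, b) {
  norm <- function(x) sort(vapply(x, function(s) paste(sort(s), collapse = ","), ""))
  identical(norm(a), norm(b))
}

# closed-form hypergeometric upper tail by direct enumeration
oracle_hyper_tail <- function(k, q, s, N) {
  j <- k:min(q, s)
  sum(exp(lchoose(s, j) + lchoose(N - s, q - j) - lchoose(N, q)))
}
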