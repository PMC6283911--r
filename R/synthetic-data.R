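# Ground-truth generators: proteomes with implanted EAR windows, promoters
# with differential motif implantation, networks with planted k-clique
# communities, grouped expression matrices with known effects. Every
# generator is a pure function of (parameters, seed).

sample_bg <- function(n, background) {
  sample(AA_STANDARD, n, replace = TRUE, prob = background)
}

ear_fixed_positions <- function(pattern, motif_len) {
  if (pattern == "LxLxL") {
    list(pos = c(1L, 3L, 5L), res = c("L", "L", "L"))
  } else if (motif_len == 5L) {
    list(pos = c(1L, 2L, 3L, 5L), res = c("D", "L", "N", "P"))
  } else {
    list(pos = c(1L, 2L, 3L, 6L), res = c("D", "L", "N", "P"))
  }
}

#' Simulate a proteome with implanted EAR motif windows
#'
#' Background proteins are i.i.d. draws from the residue background;
#' implanted proteins carry one EAR window: a family consensus (shared
#' flanks of `flank` residues per side plus a pattern-specific motif block)
#' whose non-fixed positions are mutated independently at `divergence_rate`
#' (to a different residue); the pattern's fixed residues are never mutated,
#' so every implant contains a literal EAR motif at the planted site. The
#' implant position is drawn uniformly among positions whose N/M/C class
#' (at the default 0.25/0.25 thresholds) matches the drawn location.
#'
#' @param n Number of proteins.
#' @param n_implant Number carrying an implant (`<= n`).
#' @param length_mean Mean protein length (Poisson, floored at 60).
#' @param background_freqs Residue background (default bundled table).
#' @param pattern_mix Named weights over `LxLxL`/`DLNP` (default equal).
#' @param location_mix Named weights over `N`/`M`/`C` (default equal).
#' @param divergence_rate Per-position mutation probability of non-fixed
#'   window positions (default 0.1).
#' @param flank Flank width of the implanted window (default 6).
#' @param seed Integer seed; output is bit-for-bit reproducible from it.
#' @return List with `proteome` (tibble `id`, `seq`, `description`) and
#'   `truth` (tibble `id`, `implanted`, `pattern`, `location`,
#'   `motif_start`, `motif_end`, `window`).
#' @export
simulate_proteome <- function(n, n_implant, length_mean = 300,
                              background_freqs = NULL,
                              pattern_mix = c(LxLxL = 0.5, DLNP = 0.5),
                              location_mix = c(N = 1, M = 1, C = 1) / 3,
                              divergence_rate = 0.1, flank = 6L, seed = 1L) {
  if (n_implant > n) stop_earminer("n_implant must be <= n")
  if (any(pattern_mix < 0) || sum(pattern_mix) <= 0 ||
      !setequal(names(pattern_mix), c("LxLxL", "DLNP"))) {
    stop_earminer("pattern_mix must be nonnegative weights over LxLxL/DLNP")
  }
  if (any(location_mix < 0) || sum(location_mix) <= 0 ||
      !setequal(names(location_mix), c("N", "M", "C"))) {
    stop_earminer("location_mix must be nonnegative weights over N/M/C")
  }
  if (divergence_rate < 0 || divergence_rate > 1) {
    stop_earminer("divergence_rate must be in [0, 1]")
  }
  bg <- normalise_background(background_freqs)
  with_seed(seed, {
    lens <- pmax(60L, rpois(n, length_mean))
    seqs <- vapply(lens, function(L) paste(sample_bg(L, bg), collapse = ""), "")
    ids <- sprintf("prot%04d", seq_len(n))

    # family context: one flank consensus shared across subgroups
    flank_left <- sample_bg(flank, bg)
    flank_right <- sample_bg(flank, bg)
    motif_consensus <- list(
      LxLxL = local({ m <- sample_bg(5, bg); m[c(1, 3, 5)] <- "L"; m }),
      DLNP = local({ m <- sample_bg(6, bg); m[c(1, 2, 3)] <- c("D", "L", "N"); m[6] <- "P"; m })
    )

    implant_ix <- sample.int(n, n_implant)
    truth_rows <- vector("list", n_implant)
    for (t in seq_along(implant_ix)) {
      i <- implant_ix[t]
      L <- lens[i]
      pattern <- sample(names(pattern_mix), 1, prob = pattern_mix)
      location <- sample(names(location_mix), 1, prob = location_mix)
      motif <- motif_consensus[[pattern]]
      if (pattern == "DLNP" && runif(1) < 0.5) motif <- motif[-5]  # 5-mer DLNxP
      mlen <- length(motif)
      window <- c(flank_left, motif, flank_right)
      fixed <- ear_fixed_positions(pattern, mlen)$pos + flank
      mutable <- setdiff(seq_along(window), fixed)
      mut <- mutable[runif(length(mutable)) < divergence_rate]
      for (p in mut) {
        window[p] <- sample(setdiff(AA_STANDARD, window[p]), 1,
                            prob = bg[setdiff(AA_STANDARD, window[p])])
      }
      starts <- seq_len(L - mlen + 1)
      cls <- classify_location(starts, starts + mlen - 1L, L)
      ok <- starts[cls == location]
      ms <- if (length(ok)) sample(rep(ok, 2), 1) else sample(rep(starts, 2), 1)
      ws <- max(1L, ms - flank); we <- min(L, ms + mlen - 1L + flank)
      wseq <- window[(ws - (ms - flank) + 1):(length(window) - ((ms + mlen - 1L + flank) - we))]
      s <- stringr::str_split_1(seqs[i], "")
      s[ws:we] <- wseq
      seqs[i] <- paste(s, collapse = "")
      truth_rows[[t]] <- tibble(
        id = ids[i], pattern = pattern, location = location,
        motif_start = ms, motif_end = ms + mlen - 1L,
        window = paste(wseq, collapse = "")
      )
    }
    implant_truth <- bind_rows(truth_rows)
    if (nrow(implant_truth) == 0L) {
      implant_truth <- tibble(id = character(), pattern = character(),
                              location = character(), motif_start = integer(),
                              motif_end = integer(), window = character())
    }
    truth <- tibble(id = ids, implanted = ids %in% ids[implant_ix]) |>
      left_join(implant_truth, by = "id")
    list(
      proteome = tibble(id = ids, seq = seqs, description = ""),
      truth = truth
    )
  })
}

#' Simulate promoters with differential cis-motif implantation
#'
#' Promoters are i.i.d. nucleotides at the given GC content; motif instances
#' are implanted at Poisson counts (`rate_query` for query promoters,
#' `rate_background` otherwise) at uniform non-overlapping positions.
#'
#' @param n_query,n_background Promoter counts per class.
#' @param length Promoter length in nt (default 3000).
#' @param gc GC content of the background (default 0.35, AT-rich like plant
#'   promoters).
#' @param motif Literal motif instance to implant (default the GCC-box
#'   core `GCCGCC`).
#' @param rate_query,rate_background Expected implants per promoter.
#' @param seed Integer seed.
#' @return List with `promoters` (tibble `id`, `seq`, `class`) and `truth`
#'   (tibble `id`, `class`, `n_implanted`).
#' @export
simulate_promoters <- function(n_query, n_background, length = 3000L,
                               gc = 0.35, motif = "GCCGCC",
                               rate_query = 1, rate_background = 1,
                               seed = 1L) {
  if (nchar(motif) > length) stop_earminer("motif longer than promoter")
  if (rate_query < 0 || rate_background < 0) stop_earminer("rates must be >= 0")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  mlen <- nchar(motif)
  with_seed(seed, {
    n <- n_query + n_background
    cls <- rep(c("query", "background"), c(n_query, n_background))
    ids <- sprintf("prom%04d", seq_len(n))
    n_imp <- rpois(n, ifelse(cls == "query", rate_query, rate_background))
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- sample(names(probs), length, replace = TRUE, prob = probs)
      placed <- integer(0)
      tries <- 0L
      while (base::length(placed) < n_imp[i] && tries < 100L * max(1L, n_imp[i])) {
        tries <- tries + 1L
        p <- sample.int(length - mlen + 1L, 1)
        if (!any(abs(p - placed) < mlen)) {
          s[p:(p + mlen - 1L)] <- stringr::str_split_1(motif, "")
          placed <- c(placed, p)
        }
      }
      n_imp[i] <- base::length(placed)
      seqs[i] <- paste(s, collapse = "")
    }
    list(
      promoters = tibble(id = ids, seq = seqs, class = cls),
      truth = tibble(id = ids, class = cls, n_implanted = n_imp)
    )
  })
}

#' Simulate a network with planted k-clique communities
#'
#' Each planted module is a clique of `module_size` nodes (hence a single
#' k-clique community for any `k <= module_size`); independent noise edges
#' are added between all remaining node pairs with probability
#' `noise_edge_prob`.
#'
#' @param n_modules Number of planted modules.
#' @param module_size Nodes per module (`>= k`).
#' @param k Clique-percolation parameter the truth refers to (default 4).
#' @param noise_edge_prob Noise edge probability (default 0).
#' @param n_noise_nodes Extra background nodes (default 20).
#' @param seed Integer seed.
#' @return List with `edges` (edge tibble), `nodes` (all node ids) and
#'   `truth` (tibble `node`, `module`; `NA` module for background nodes).
#' @export
simulate_network <- function(n_modules, module_size, k = 4L,
                             noise_edge_prob = 0, n_noise_nodes = 20L,
                             seed = 1L) {
  if (module_size < k) stop_earminer("module_size must be >= k")
  with_seed(seed, {
    n_nodes <- n_modules * module_size + n_noise_nodes
    nodes <- sprintf("g%03d", seq_len(n_nodes))
    member <- rep(c(seq_len(n_modules), NA), c(rep(module_size, n_modules), n_noise_nodes))
    edges <- list()
    for (m in seq_len(n_modules)) {
      ns <- nodes[which(member == m)]
      cmb <- utils::combn(ns, 2)
      edges[[m]] <- tibble(from = cmb[1, ], to = cmb[2, ])
    }
    planted <- bind_rows(edges)
    if (noise_edge_prob > 0) {
      cmb <- utils::combn(nodes, 2)
      all_pairs <- tibble(from = cmb[1, ], to = cmb[2, ])
      pick <- runif(nrow(all_pairs)) < noise_edge_prob
      planted <- bind_rows(planted, all_pairs[pick, ]) |> distinct()
    }
    list(
      edges = arrange(planted, .data$from, .data$to),
      nodes = nodes,
      truth = tibble(node = nodes, module = member)
    )
  })
}

#' Simulate a grouped expression matrix with known effects
#'
#' Log2 expression is Gaussian around a shared baseline; the first `n_de`
#' genes get a group-A shift of `effect_size` log2 units. Values are
#' returned on the positive linear scale (suitable for [de_filter()]).
#'
#' @param n_genes Number of genes.
#' @param n_de Number of differentially expressed genes.
#' @param effect_size Group mean difference in log2 units (default 2).
#' @param sigma Within-group log2 sd (default 0.25).
#' @param samples_per_group Samples per group (default 3).
#' @param base_log2 Baseline log2 expression (default 7).
#' @param seed Integer seed.
#' @return List with `expr` (matrix, columns `a1..`, `b1..`) and `truth`
#'   (tibble `gene`, `is_de`, `effect`).
#' @export
simulate_expression <- function(n_genes, n_de, effect_size = 2, sigma = 0.25,
                                samples_per_group = 3L, base_log2 = 7,
                                seed = 1L) {
  if (n_de > n_genes) stop_earminer("n_de must be <= n_genes")
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    eff <- c(rep(effect_size, n_de), rep(0, n_genes - n_de))
    k <- samples_per_group
    a <- matrix(rnorm(n_genes * k, base_log2 + eff, sigma), n_genes, k)
    b <- matrix(rnorm(n_genes * k, base_log2, sigma), n_genes, k)
    expr <- 2^cbind(a, b)
    dimnames(expr) <- list(genes, c(paste0("a", seq_len(k)), paste0("b", seq_len(k))))
    list(expr = expr,
         truth = tibble(gene = genes, is_de = eff != 0, effect = eff))
  })
}
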