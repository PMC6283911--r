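# Co-expression network construction (PCC / mutual rank, top-N neighbours),
# exact k-clique-percolation modules and cross-species network comparison.
# Networks are undirected edge tibbles (from, to, weight), from < to.

edges_to_igraph <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = unique(c(nodes, edges$from, edges$to))
  )
  igraph::simplify(g)
}

#' Build a co-expression network from an expression matrix
#'
#' Computes the Pearson correlation coefficient (PCC) between all gene
#' pairs; the mutual rank is `MR(a,b) = sqrt(rank_a(b) * rank_b(a))`, where
#' `rank_a(b)` is b's 1-based position in a's PCC-descending neighbour list.
#' Each gene keeps its `top_n` neighbours (highest PCC, or lowest MR) and
#' the edge set is the union over genes. Ties break lexicographically by
#' gene id.
#'
#' @param expr Numeric matrix, genes in rows (rownames), samples in columns
#'   (>= 3 samples). Zero-variance genes are excluded with a warning.
#' @param method `"pcc"` (default) or `"mr"`.
#' @param top_n Neighbours kept per gene (default 300).
#' @param min_pcc Optional absolute PCC floor applied before ranking.
#' @return Edge tibble `from`, `to`, `weight` (PCC or MR of the pair).
#' @export
build_coexpression <- function(expr, method = c("pcc", "mr"), top_n = 300L,
                               min_pcc = NULL) {
  method <- match.arg(method)
  if (ncol(expr) < 3L) stop_earminer("need at least 3 samples")
  v <- apply(expr, 1, sd)
  if (any(v == 0)) {
    warn(sprintf("excluding %d zero-variance gene(s)", sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  genes <- rownames(expr)
  n <- length(genes)
  if (n < 2L) stop_earminer("need at least 2 variable genes")
  C <- cor(t(expr))
  diag(C) <- -Inf  # a gene is never its own neighbour

  # 1-based PCC-descending rank of every gene in every gene's list
  R <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    ord <- order(-C[i, ], genes)  # ties: lexicographic id
    R[i, ord] <- seq_len(n)
  }
  W <- if (method == "pcc") C else sqrt(R * t(R))

  keep_mask <- matrix(TRUE, n, n)
  if (!is.null(min_pcc)) keep_mask <- abs(C) >= min_pcc
  edges <- list()
  for (i in seq_len(n)) {
    cand <- setdiff(which(keep_mask[i, ]), i)
    if (!length(cand)) next
    ord <- if (method == "pcc") {
      cand[order(-C[i, cand], genes[cand])]
    } else {
      cand[order(W[i, cand], genes[cand])]
    }
    nb <- head(ord, top_n)
    edges[[i]] <- tibble(
      from = pmin(genes[i], genes[nb]), to = pmax(genes[i], genes[nb]),
      weight = if (method == "pcc") C[cbind(i, nb)] else W[cbind(i, nb)]
    )
  }
  bind_rows(edges) |>
    distinct(.data$from, .data$to, .keep_all = TRUE) |>
    arrange(.data$from, .data$to)
}

#' Functional modules by k-clique percolation
#'
#' Exact clique percolation: every k-clique of the network is enumerated,
#' two k-cliques are adjacent when they share k-1 nodes, and each connected
#' component of that clique graph contributes one module (the union of its
#' cliques' nodes). Modules may overlap in nodes; every module member
#' belongs to at least one k-clique.
#'
#' @param edges Edge tibble (`from`, `to`).
#' @param k Clique size (default 4; must be >= 3).
#' @return Tibble `module`, `member` (one row per module membership),
#'   modules numbered by size then lexicographic smallest member.
#' @export
k_clique_modules <- function(edges, k = 4L) {
  if (k < 3L) stop_earminer("k must be >= 3")
  if (nrow(edges) == 0L) return(tibble(module = integer(), member = character()))
  g <- edges_to_igraph(edges)
  cliq <- igraph::cliques(g, min = k, max = k)
  if (length(cliq) == 0L) return(tibble(module = integer(), member = character()))
  cl <- lapply(cliq, function(x) sort(names(x)))
  nc <- length(cl)

  # adjacency through shared (k-1)-subsets: hash each subset
  sub_env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nc)) {
    for (d in seq_len(k)) {
      key <- paste(cl[[i]][-d], collapse = "\r")
      sub_env[[key]] <- c(sub_env[[key]] %||% integer(0), i)
    }
  }
  parent <- seq_len(nc)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (key in ls(sub_env)) {
    members <- sub_env[[key]]
    if (length(members) > 1L) {
      r <- find(members[[1]])
      for (m in members[-1]) parent[find(m)] <- r
    }
  }
  comp <- vapply(seq_len(nc), find, 0L)
  mods <- split(seq_len(nc), comp)
  member_sets <- lapply(mods, function(ix) sort(unique(unlist(cl[ix]))))
  ord <- order(-lengths(member_sets),
               vapply(member_sets, `[[`, "", 1))
  bind_rows(purrr::imap(member_sets[ord], function(mem, i) {
    tibble(module = as.integer(i), member = mem)
  }))
}

#' Induced neighbourhood subnetwork around a gene
#'
#' @param edges Edge tibble.
#' @param gene Centre gene id (must be in the network).
#' @param depth Number of hops (default 1).
#' @param nodes Optional full node set (to allow isolated nodes).
#' @return List with `nodes` (within `depth` hops) and `edges` (induced
#'   subgraph edge tibble).
#' @export
neighborhood <- function(edges, gene, depth = 1L, nodes = NULL) {
  g <- edges_to_igraph(edges, nodes = nodes)
  if (!gene %in% igraph::V(g)$name) {
    stop_earminer(sprintf("gene not in network: %s", gene))
  }
  nb <- igraph::ego(g, order = depth, nodes = gene)[[1]]
  sub <- igraph::induced_subgraph(g, nb)
  el <- igraph::as_data_frame(sub, what = "edges")
  tibble_edges <- if (nrow(el)) {
    tibble(from = pmin(el$from, el$to), to = pmax(el$from, el$to)) |>
      arrange(.data$from, .data$to)
  } else tibble(from = character(), to = character())
  list(nodes = sort(names(nb)), edges = tibble_edges)
}

#' Compare two species' co-expression networks through ortholog pairs
#'
#' Reports the orthologous node pairs whose members are both present in
#' their respective networks, per-species counts, and an overlay graph with
#' solid within-species co-expression edges and dashed cross-species
#' ortholog links.
#'
#' @param net_a,net_b Edge tibbles for species A and B.
#' @param pairs Ortholog pairs (`gene_a`, `gene_b`).
#' @return List of class `ear_net_comparison` with `pairs` (tibble of
#'   matched ortholog pairs), `n_pairs`, `n_genes_a`, `n_genes_b`, and
#'   `overlay` (edge tibble with columns `from`, `to`, `type`
#'   (`coexpression_a`/`coexpression_b`/`ortholog`), `style`
#'   (`solid`/`dashed`)).
#' @export
compare_networks <- function(net_a, net_b, pairs) {
  nodes_a <- unique(c(net_a$from, net_a$to))
  nodes_b <- unique(c(net_b$from, net_b$to))
  matched <- pairs |>
    filter(.data$gene_a %in% nodes_a, .data$gene_b %in% nodes_b) |>
    distinct(.data$gene_a, .data$gene_b) |>
    arrange(.data$gene_a, .data$gene_b)
  overlay <- bind_rows(
    tibble(from = net_a$from, to = net_a$to, type = "coexpression_a",
           style = "solid"),
    tibble(from = net_b$from, to = net_b$to, type = "coexpression_b",
           style = "solid"),
    tibble(from = matched$gene_a, to = matched$gene_b, type = "ortholog",
           style = "dashed")
  )
  structure(list(
    pairs = matched,
    n_pairs = nrow(matched),
    n_genes_a = dplyr::n_distinct(matched$gene_a),
    n_genes_b = dplyr::n_distinct(matched$gene_b),
    overlay = overlay
  ), class = "ear_net_comparison")
}

#' @export
print.ear_net_comparison <- function(x, ...) {
  cat(sprintf("<ear_net_comparison> %d ortholog pair(s): %d gene(s) in A, %d in B\n",
              x$n_pairs, x$n_genes_a, x$n_genes_b))
  invisible(x)
}
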