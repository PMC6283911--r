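# Promoter cis-element enrichment with a resampled background, overlap GSEA,
# t-test/fold-change DE filtering and peak-to-gene association.

#' Extract promoter sequences for gene models
#'
#' The promoter is the `length` nucleotides upstream of the TSS, strand
#' aware: `[tss - length, tss)` on `+`; `(tss, tss + length]`
#' reverse-complemented on `-`; truncated at contig ends. The promoter id is
#' the gene id.
#'
#' @param genome Tibble with `id`, `seq` (nucleotide) as from
#'   `read_fasta(path, alphabet = "dna")`.
#' @param genes Gene-model tibble from [read_gff_genes()].
#' @param length Promoter length in nt (default 3000).
#' @return Tibble `id`, `seq` of promoter sequences.
#' @export
extract_promoters <- function(genome, genes, length = 3000L) {
  contigs <- setNames(genome$seq, genome$id)
  missing <- setdiff(genes$seq_id, genome$id)
  if (base::length(missing)) {
    stop_earminer(sprintf("contig not in genome: %s", missing[[1]]))
  }
  seqs <- purrr::pmap_chr(genes, function(gene_id, seq_id, strand, tss, ...) {
    contig <- contigs[[seq_id]]
    clen <- nchar(contig)
    if (strand == "+") {
      from <- max(1L, tss - length)
      to <- tss - 1L
      if (to < from) return("")
      substr(contig, from, to)
    } else {
      from <- tss + 1L
      to <- min(clen, tss + length)
      if (to < from) return("")
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(contig, from, to))))
    }
  })
  out <- tibble(id = genes$gene_id, seq = seqs)
  filter(out, nzchar(.data$seq))
}

#' Count motif matches across promoters
#'
#' Total number of match start positions of a motif's regular expression
#' over the given promoters; overlapping matches are all counted. Scanning
#' is single-strand by default.
#'
#' @param promoters Tibble with `id`, `seq`.
#' @param pattern Nucleotide regular expression (one motif).
#' @param both_strands Also scan the reverse complement of each promoter.
#' @return Integer total count.
#' @export
count_matches <- function(promoters, pattern, both_strands = FALSE) {
  sum(count_matches_per(promoters, pattern, both_strands))
}

count_matches_per <- function(promoters, pattern, both_strands = FALSE) {
  n <- stringr::str_count(promoters$seq, stringr::regex(sprintf("(?=%s)", pattern)))
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(promoters$seq)))
    n <- n + stringr::str_count(rc, stringr::regex(sprintf("(?=%s)", pattern)))
  }
  n
}

#' Promoter cis-element enrichment against a resampled background
#'
#' For each motif, the observed match count `x_bar` over the query genes'
#' promoters is compared with its distribution over `n_random` random gene
#' lists of the same size drawn without replacement from the universe
#' (random lists may overlap the query). Two statistics are reported:
#' the platform's verbatim `z = (x_bar - mu) / (sigma / sqrt(n))` with
#' `p = pnorm` on that scale (upper tail by default; `tail = "lower"` gives
#' the literal lower-tail reading), and the plain standardisation
#' `z_raw = (x_bar - mu) / sigma` with `p_raw`, which is the calibrated
#' null statistic (`sigma` is already the sd of the size-`n` sum, so the
#' verbatim `z` is inflated by `sqrt(n)`).
#'
#' @param query_genes Character vector of query gene ids.
#' @param universe_promoters Promoter tibble (`id`, `seq`) for the whole
#'   universe; query ids must be a subset.
#' @param motifs Motif tibble from [read_motif_table()].
#' @param n_random Number of random lists (default 1000).
#' @param seed Integer seed for the random lists.
#' @param tail `"upper"` (enrichment, default) or `"lower"` (literal pnorm).
#' @param both_strands Scan both strands.
#' @return Tibble `motif`, `x_bar`, `mu`, `sigma`, `n`, `z`, `p`, `z_raw`,
#'   `p_raw`. When `sigma = 0`: `p = 0` if `x_bar > mu`, else `1`, and `z`
#'   is `Inf`/`-Inf`.
#' @export
cis_enrichment <- function(query_genes, universe_promoters, motifs,
                           n_random = 1000L, seed = 1L,
                           tail = c("upper", "lower"), both_strands = FALSE) {
  tail <- match.arg(tail)
  if (n_random < 2L) stop_earminer("n_random must be >= 2")
  ids <- universe_promoters$id
  if (!all(query_genes %in% ids)) {
    stop_earminer("query gene without a universe promoter")
  }
  n <- length(query_genes)
  if (n > length(ids)) stop_earminer("query larger than universe")
  qidx <- match(query_genes, ids)
  rand_idx <- with_seed(seed, {
    replicate(n_random, sample.int(length(ids), n), simplify = FALSE)
  })
  res <- purrr::pmap(motifs, function(motif, pattern, ...) {
    per <- count_matches_per(universe_promoters, pattern, both_strands)
    x_bar <- sum(per[qidx])
    rnd <- vapply(rand_idx, function(ix) sum(per[ix]), 0)
    mu <- mean(rnd); sigma <- sd(rnd)
    if (sigma > 0) {
      z <- (x_bar - mu) / (sigma / sqrt(n))
      z_raw <- (x_bar - mu) / sigma
      p <- pnorm(x_bar, mu, sigma / sqrt(n), lower.tail = tail == "lower")
      p_raw <- pnorm(x_bar, mu, sigma, lower.tail = tail == "lower")
    } else {
      z <- if (x_bar > mu) Inf else if (x_bar < mu) -Inf else 0
      z_raw <- z
      p <- if (x_bar > mu) 0 else 1
      p_raw <- p
    }
    tibble(motif = motif, x_bar = x_bar, mu = mu, sigma = sigma, n = n,
           z = z, p = p, z_raw = z_raw, p_raw = p_raw)
  })
  bind_rows(res)
}

#' Overlap-based gene set enrichment
#'
#' One-sided over-representation test per gene set from the 2x2 table
#' (query-and-set, query-not-set, set-not-query, rest), after intersecting
#' each set with the universe. Fisher's exact test and the hypergeometric
#' tail give identical p-values; a chi-squared variant is available. No
#' multiple-testing correction is applied by default.
#'
#' @param query Character vector of query gene ids (subset of `universe`).
#' @param collection Gene-set tibble from [read_gmt()].
#' @param universe Character vector of universe gene ids.
#' @param test `"fisher"` (default), `"hypergeometric"` or `"chisq"`.
#' @param alpha Significance level (default 0.05).
#' @param adjust Apply Benjamini-Hochberg correction before flagging.
#' @return Tibble `set`, `overlap`, `query_size`, `set_size`,
#'   `universe_size`, `p`, `test`, `significant`. Sets disjoint from the
#'   universe are skipped with a warning.
#' @export
gsea <- function(query, collection, universe,
                 test = c("fisher", "hypergeometric", "chisq"),
                 alpha = 0.05, adjust = FALSE) {
  test <- match.arg(test)
  universe <- unique(universe)
  if (length(universe) == 0L) stop_earminer("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop_earminer("query must be a subset of the universe")
  N <- length(universe); q <- length(query)
  rows <- purrr::pmap(collection, function(set, genes, ...) {
    s_genes <- intersect(genes, universe)
    if (length(s_genes) == 0L) {
      warn(sprintf("gene set '%s' is disjoint from the universe; skipped", set))
      return(NULL)
    }
    k <- length(intersect(query, s_genes)); s <- length(s_genes)
    p <- switch(test,
      fisher = fisher.test(
        matrix(c(k, q - k, s - k, N - q - s + k), 2, 2),
        alternative = "greater")$p.value,
      hypergeometric = phyper(k - 1, s, N - s, q, lower.tail = FALSE),
      chisq = {
        tb <- matrix(c(k, q - k, s - k, N - q - s + k), 2, 2)
        pv <- suppressWarnings(chisq.test(tb, correct = FALSE)$p.value)
        # one-sided: halve when the overlap is above expectation
        if (k > q * s / N) pv / 2 else 1 - pv / 2
      })
    tibble(set = set, overlap = k, query_size = q, set_size = s,
           universe_size = N, p = p, test = test)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  pv <- if (adjust) p.adjust(out$p, "BH") else out$p
  mutate(out, significant = pv <= alpha)
}

#' Differential-expression filtering by t-test and fold change
#'
#' Per gene: two-sample equal-variance (Student) t-test between the two
#' groups and `log2fc = log2(mean_a / mean_b)` on the positive linear
#' scale. A gene is differentially expressed when `p < p_cut` and
#' `|log2fc| > lfc_cut`.
#'
#' @param expr Numeric matrix, genes in rows (rownames), samples in columns.
#' @param group_a,group_b Column names (or indices) of the two groups,
#'   >= 2 samples each.
#' @param p_cut,lfc_cut Thresholds (defaults 0.05 and 1).
#' @return Tibble `gene`, `mean_a`, `mean_b`, `t`, `p`, `log2fc`, `is_de`.
#'   Genes with a nonpositive group mean are excluded with a warning.
#' @export
de_filter <- function(expr, group_a, group_b, p_cut = 0.05, lfc_cut = 1.0) {
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) {
    stop_earminer("each group needs at least 2 samples")
  }
  ma <- rowMeans(a); mb <- rowMeans(b)
  bad <- ma <= 0 | mb <= 0
  if (any(bad)) {
    warn(sprintf("excluding %d gene(s) with nonpositive group mean", sum(bad)))
  }
  keep <- which(!bad)
  rows <- purrr::map(keep, function(i) {
    tt <- t.test(a[i, ], b[i, ], var.equal = TRUE)
    tibble(gene = rownames(expr)[i], mean_a = unname(ma[i]),
           mean_b = unname(mb[i]), t = unname(tt$statistic), p = tt$p.value,
           log2fc = unname(log2(ma[i] / mb[i])))
  })
  bind_rows(rows) |>
    mutate(is_de = .data$p < p_cut & abs(.data$log2fc) > lfc_cut)
}

#' Associate epigenetic mark peaks with genes
#'
#' A gene is associated with a mark when any of the mark's peaks overlaps
#' the strand-aware upstream window `[tss - W, tss)` (mirrored on `-`) or
#' the gene body. Peaks are 0-based half-open (BED); gene models 1-based
#' closed; all interval arithmetic is half-open internally.
#'
#' @param genes Gene-model tibble from [read_gff_genes()].
#' @param peaks Peak tibble from [read_bed()]; the `mark` (falling back to
#'   `name`) column labels the mark.
#' @param upstream_window Upstream window size W in nt (1000 for
#'   Arabidopsis, 2000 for rice/maize).
#' @return Tibble `gene_id`, `mark` (one row per associated pair).
#' @export
associate_peaks <- function(genes, peaks, upstream_window = 1000L) {
  mark <- dplyr::coalesce(peaks$mark, peaks$name, "peak")
  # gene body + upstream window as 0-based half-open intervals
  up_start <- ifelse(genes$strand == "+", genes$tss - 1L - upstream_window,
                     genes$tss)
  up_end <- ifelse(genes$strand == "+", genes$tss - 1L, genes$tss + upstream_window)
  body_start <- genes$start - 1L
  body_end <- genes$end
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    on <- peaks$seq_id == genes$seq_id[i]
    if (!any(on)) return(NULL)
    ps <- peaks$start[on]; pe <- peaks$end[on]
    hit <- (ps < up_end[i] & pe > max(0L, up_start[i])) |
           (ps < body_end[i] & pe > body_start[i])
    if (!any(hit)) return(NULL)
    tibble(gene_id = genes$gene_id[i], mark = unique(mark[on][hit]))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(tibble(gene_id = character(), mark = character()))
  arrange(out, .data$gene_id, .data$mark)
}
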