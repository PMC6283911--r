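toy_genome <- function() {
  set.seed(91)
  tibble::tibble(
    id = "chr1",
    seq = paste(sample(c("A", "C", "G", "T"), 12000, replace = TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  )
}

test_that("promoter extraction is strand-aware and truncates at contig ends", {
  genome <- toy_genome()
  genes <- tibble::tibble(
    gene_id = c("gp", "gm", "gshort"),
    seq_id = "chr1",
    strand = c("+", "-", "-"),
    start = c(5001L, 2000L, 11000L),
    end = c(6000L, 5000L, 11500L),
    tss = c(5001L, 5000L, 11500L)
  )
  pr <- extract_promoters(genome, genes, length = 3000)
  g <- genome$seq
  # + strand: 0-based [2000, 5000), i.e. 1-based 2001..5000
  expect_equal(pr$seq[pr$id == "gp"], substr(g, 2001, 5000))
  expect_equal(nchar(pr$seq[pr$id == "gp"]), 3000L)
  # - strand: (tss, tss+3000] reverse-complemented
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(pr$seq[pr$id == "gm"], rc(substr(g, 5001, 8000)))
  # truncation at contig end
  expect_equal(nchar(pr$seq[pr$id == "gshort"]), 12000L - 11500L)
  expect_error(extract_promoters(genome, dplyr::mutate(genes, seq_id = "chrX")),
               "contig")
})

test_that("minus-strand extraction mirrors the plus-strand of the mirrored gene", {
  genome <- toy_genome()
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  mirrored <- tibble::tibble(id = "mir", seq = rc(genome$seq))
  L <- nchar(genome$seq)
  tss <- 7000L
  minus <- tibble::tibble(gene_id = "g", seq_id = "chr1", strand = "-",
                          start = 6000L, end = tss, tss = tss)
  plus_mirror <- tibble::tibble(gene_id = "g", seq_id = "mir", strand = "+",
                                start = L - tss + 1L, end = L - 6000L + 1L,
                                tss = L - tss + 1L)
  p1 <- extract_promoters(genome, minus, length = 2000)$seq
  p2 <- extract_promoters(mirrored, plus_mirror, length = 2000)$seq
  expect_equal(p1, p2)
})

test_that("match counting includes overlaps and is order-invariant", {
  pr <- tibble::tibble(id = c("p1", "p2"), seq = c("TATATA", "GGTATAGG"))
  expect_equal(count_matches(pr[1, ], "TATA"), 2L)
  expect_equal(count_matches(pr, "TATA"), 3L)
  expect_equal(count_matches(pr[2:1, ], "TATA"), 3L)
  expect_equal(count_matches(pr, "CCCCC"), 0L)
  # additivity over disjoint promoter sets
  expect_equal(count_matches(pr, "TATA"),
               count_matches(pr[1, ], "TATA") + count_matches(pr[2, ], "TATA"))
  # reverse-complement scanning
  expect_equal(count_matches(tibble::tibble(id = "x", seq = "GGGGCC"), "GGCCCC",
                             both_strands = TRUE), 1L)
})

test_that("cis enrichment statistics follow the Z and p definitions", {
  sim <- simulate_promoters(20, 180, length = 400, rate_query = 3,
                            rate_background = 0.3, seed = 41)
  motifs <- tibble::tibble(motif = "GCCbox", pattern = "GCCGCC")
  query <- sim$promoters$id[sim$promoters$class == "query"]
  res <- cis_enrichment(query, sim$promoters, motifs, n_random = 300, seed = 2)
  expect_equal(res$n, 20L)
  # verbatim z is sqrt(n) times the raw standardisation
  expect_equal(res$z, res$z_raw * sqrt(res$n), tolerance = 1e-12)
  expect_lt(res$p_raw, 0.05)
  expect_lt(res$p, res$p_raw + 1e-12)  # verbatim upper-tail p is smaller
  # literal lower-tail mode is the complement
  low <- cis_enrichment(query, sim$promoters, motifs, n_random = 300, seed = 2,
                        tail = "lower")
  expect_equal(low$p, 1 - res$p, tolerance = 1e-12)
  expect_error(cis_enrichment(c(query, "nope"), sim$promoters, motifs),
               "universe")
})

test_that("null cis-enrichment p_raw is calibrated and near-uniform", {
  # expected per-list counts are kept large (~50) so the normal reference
  # distribution for the count sum is appropriate; each replicate draws a
  # fresh universe so the 200 rate estimates are independent
  motifs <- tibble::tibble(motif = "GCCbox", pattern = "GCCGCC")
  set.seed(43)
  pvals <- vapply(1:200, function(r) {
    sim <- simulate_promoters(0, 200, length = 500, rate_query = 0,
                              rate_background = 2, seed = 42000 + r)
    q <- sample(sim$promoters$id, 25)
    cis_enrichment(q, sim$promoters, motifs, n_random = 200,
                   seed = 1000 + r)$p_raw
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
  ks <- max(abs(sort(pvals) - (1:200) / 200))
  expect_lt(ks, 0.1)
})

test_that("gsea matches the closed-form hypergeometric and flags edge cases", {
  # query identical to a set of size k in universe N: p = 1 / choose(N, k)
  universe <- sprintf("g%02d", 1:20)
  coll <- tibble::tibble(set = "S", description = "d",
                         genes = list(universe[1:5]))
  res <- gsea(universe[1:5], coll, universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(res$significant)

  # fisher == hypergeometric == enumeration oracle on random tables, N <= 50
  set.seed(44)
  for (i in 1:200) {
    N <- sample(5:50, 1)
    q <- sample(1:N, 1); s <- sample(1:N, 1)
    krange <- max(0, q + s - N):min(q, s)
    k <- if (length(krange) == 1) krange else sample(krange, 1)
    pf <- fisher.test(matrix(c(k, q - k, s - k, N - q - s + k), 2, 2),
                      alternative = "greater")$p.value
    expect_equal(pf, oracle_hyper_tail(k, q, s, N), tolerance = 1e-9)
  }
  uni <- sprintf("g%02d", 1:30)
  collr <- tibble::tibble(set = "S", description = "d", genes = list(uni[1:8]))
  qry <- uni[c(1:4, 9:14)]
  expect_equal(gsea(qry, collr, uni, test = "fisher")$p,
               gsea(qry, collr, uni, test = "hypergeometric")$p,
               tolerance = 1e-12)

  # set disjoint from the universe is skipped with a warning
  disj <- tibble::tibble(set = "D", description = "d", genes = list("zz"))
  expect_warning(out <- gsea(uni[1:3], disj, uni), "disjoint")
  expect_equal(nrow(out), 0L)
  expect_error(gsea("g01", coll, character(0)), "universe")
})

test_that("DE filtering applies Student's t and the fold-change cut", {
  sim <- simulate_expression(100, 15, effect_size = 2, sigma = 0.2, seed = 45)
  res <- de_filter(sim$expr, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  # direct recomputation of t and log2fc for every gene
  for (i in seq_len(nrow(sim$expr))) {
    a <- sim$expr[i, 1:3]; b <- sim$expr[i, 4:6]
    tt <- t.test(a, b, var.equal = TRUE)
    r <- res[res$gene == rownames(sim$expr)[i], ]
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p, tt$p.value, tolerance = 1e-12)
    expect_equal(r$log2fc, log2(mean(a) / mean(b)), tolerance = 1e-12)
    expect_equal(r$is_de, tt$p.value < 0.05 && abs(log2(mean(a) / mean(b))) > 1)
  }
  # strong effect with tiny variance is called DE with log2fc ~ 2
  strong <- matrix(c(4, 4.01, 3.99, 1, 1.01, 0.99), 1,
                   dimnames = list("g", c("a1", "a2", "a3", "b1", "b2", "b3")))
  rs <- de_filter(strong, 1:3, 4:6)
  expect_equal(rs$log2fc, 2, tolerance = 1e-3)
  expect_true(rs$is_de)
  # identical groups are never DE
  same <- matrix(rep(c(5, 6, 7), 2), 1, dimnames = list("g", NULL))
  expect_false(de_filter(same, 1:3, 4:6)$is_de)
  expect_error(de_filter(sim$expr, "a1", c("b1", "b2")), "2 samples")
})

test_that("null DE positive rate matches the t-test alpha when lfc cut is off", {
  sim <- simulate_expression(4000, 0, sigma = 0.3, samples_per_group = 4,
                             seed = 46)
  res <- de_filter(sim$expr, paste0("a", 1:4), paste0("b", 1:4),
                   p_cut = 0.05, lfc_cut = 0)
  expect_lt(abs(mean(res$is_de) - 0.05), 0.015)
})

test_that("peak association honours half-open boundaries and both regions", {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), seq_id = "chr1", strand = c("+", "-"),
    start = c(5001L, 5001L), end = c(6000L, 6000L),
    tss = c(5001L, 6000L)
  )
  W <- 1000L
  # + gene: upstream 0-based [4000, 5000); peak covering [4999, 5000) hits
  peaks <- tibble::tibble(seq_id = "chr1", start = 4999L, end = 5000L,
                          name = "pk", mark = "H3K4me3")
  expect_equal(associate_peaks(genes[1, ], peaks, W)$gene_id, "gp")
  # peak ending exactly at the window start does not overlap
  peaks2 <- tibble::tibble(seq_id = "chr1", start = 3900L, end = 4000L,
                           name = "pk", mark = "m")
  expect_equal(nrow(associate_peaks(genes[1, ], peaks2, W)), 0L)
  # gene-body overlap associates regardless of upstream
  peaks3 <- tibble::tibble(seq_id = "chr1", start = 5500L, end = 5510L,
                           name = "pk", mark = "m")
  expect_equal(associate_peaks(genes[1, ], peaks3, W)$gene_id, "gp")
  # - gene: upstream is downstream in genome coordinates: [6000, 7000)
  peaks4 <- tibble::tibble(seq_id = "chr1", start = 6500L, end = 6600L,
                           name = "pk", mark = "m")
  expect_equal(associate_peaks(genes[2, ], peaks4, W)$gene_id, "gm")
})

test_that("peak association equals the brute-force overlap oracle", {
  set.seed(47)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    seq_id = sample(c("chr1", "chr2"), 100, replace = TRUE),
    strand = sample(c("+", "-"), 100, replace = TRUE),
    start = sample(2000:90000, 100)
  ) |>
    dplyr::mutate(end = start + sample(500:3000, 100, replace = TRUE),
                  tss = ifelse(strand == "+", start, end))
  peaks <- tibble::tibble(
    seq_id = sample(c("chr1", "chr2"), 500, replace = TRUE),
    start = sample(0:95000, 500)
  ) |>
    dplyr::mutate(end = start + sample(50:800, 500, replace = TRUE),
                  name = sprintf("pk%03d", 1:500),
                  mark = sample(c("H3K4me3", "H3K9me2", "DNAme"), 500, replace = TRUE))
  got <- associate_peaks(genes, peaks, 1000L)
  # O(n*m) oracle over every gene/peak combination
  want <- list()
  for (i in 1:100) {
    for (j in 1:500) {
      if (genes$seq_id[i] != peaks$seq_id[j]) next
      tss0 <- genes$tss[i] - 1L
      if (genes$strand[i] == "+") { us <- tss0 - 1000L; ue <- tss0 }
      else { us <- tss0 + 1L; ue <- tss0 + 1L + 1000L }
      bs <- genes$start[i] - 1L; be <- genes$end[i]
      ps <- peaks$start[j]; pe <- peaks$end[j]
      if ((ps < ue && pe > us) || (ps < be && pe > bs)) {
        want[[length(want) + 1]] <- data.frame(gene_id = genes$gene_id[i],
                                               mark = peaks$mark[j])
      }
    }
  }
  want <- unique(do.call(rbind, want))
  want <- want[order(want$gene_id, want$mark), ]
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$mark, want$mark)
})
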