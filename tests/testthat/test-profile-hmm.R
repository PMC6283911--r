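make_proteins <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = sprintf("p%d", seq_along(seqs)), seq = seqs)
}

test_that("seed windows clip at sequence ends and record the motif offset", {
  prot <- make_proteins(paste0("LLLAL", strrep("A", 45)))          # motif 1-5 of 50
  hits <- scan_ear_motifs(prot)
  w <- extract_seed_windows(prot, hits, flank = 6)
  expect_equal(nchar(w$window), 11L)   # left-clipped: 5 + 6
  expect_equal(w$motif_offset, 0L)

  prot2 <- make_proteins(paste0(strrep("A", 19), "LLLAL", strrep("A", 26)))  # 20-24
  w2 <- extract_seed_windows(prot2, scan_ear_motifs(prot2), flank = 6)
  expect_equal(nchar(w2$window), 17L)
  expect_equal(w2$motif_offset, 6L)

  prot3 <- make_proteins(paste0(strrep("A", 47), "LLLAL"))         # motif 48-52 of 52
  w3 <- extract_seed_windows(prot3, scan_ear_motifs(prot3), flank = 6)
  expect_equal(nchar(w3$window), 11L)  # right-clipped: 6 + 5
  expect_equal(w3$motif_offset, 6L)
})

test_that("anchored MSA aligns motif frames and pads clipped flanks", {
  prot <- make_proteins(
    paste0(strrep("A", 10), "LQLRL", strrep("G", 10)),
    paste0(strrep("C", 10), "LSLTL", strrep("H", 10))
  )
  w <- extract_seed_windows(prot, scan_ear_motifs(prot), flank = 6)
  msa <- build_anchored_msa(w, flank = 6)
  expect_equal(dim(msa), c(2L, 17L))
  expect_true(all(msa != "-"))
  expect_equal(paste(msa[1, 7:11], collapse = ""), "LQLRL")

  # 5-mer DLNxP gets exactly one gap relative to the 6-mer frame
  protd <- make_proteins(
    paste0(strrep("A", 10), "DLNQP", strrep("G", 10)),
    paste0(strrep("A", 10), "DLNQQP", strrep("G", 10))
  )
  wd <- extract_seed_windows(protd, scan_ear_motifs(protd), flank = 6)
  msad <- build_anchored_msa(wd, flank = 6)
  expect_equal(ncol(msad), 18L)
  expect_equal(sum(msad[wd$motif_len == 5L, ] == "-"), 1L)
  expect_equal(unname(msad[wd$motif_len == 5L, 11]), "-")  # second free position
  expect_equal(unname(msad[1, 12]), unname(msad[2, 12]))   # both P anchored

  # single window -> single-row alignment
  single <- build_anchored_msa(w[1, ], flank = 6)
  expect_equal(nrow(single), 1L)

  expect_error(build_anchored_msa(dplyr::bind_rows(w, wd)), "mix patterns")
})

test_that("profile emissions follow the pseudocount smoothing formula", {
  msa <- rbind(c("L", "A"), c("L", "C"))
  uniform <- setNames(rep(1 / 20, 20), AA20)
  hmm <- build_profile(msa, background = uniform, pseudocount = 1)
  expect_equal(hmm$n_match, 2L)
  # column {L,L}: P(L) = (2 + 1/20) / 3
  expect_equal(unname(hmm$match_emissions[1, "L"]), (2 + 1 / 20) / 3)
  expect_equal(unname(hmm$match_emissions[1, "A"]), (0 + 1 / 20) / 3)
  # every emission row and outgoing-transition set normalises to 1
  expect_equal(unname(rowSums(hmm$match_emissions)), rep(1, 2), tolerance = 1e-9)
  tr <- hmm$transitions
  for (j in 1:2) {
    expect_equal(2^tr$mm[j] + 2^tr$mi[j] + 2^tr$md[j], 1, tolerance = 1e-9)
    expect_equal(2^tr$im[j] + 2^tr$ii[j], 1, tolerance = 1e-9)
  }
  expect_equal(2^tr$mm[3] + 2^tr$mi[3], 1, tolerance = 1e-9)  # M_m -> {E, I_m}

  # all-gap column dropped with a warning
  expect_warning(build_profile(rbind(c("L", "-"), c("L", "-"))), "all-gap")
})

test_that("viterbi and forward match exhaustive path enumeration", {
  set.seed(11)
  for (rep in 1:100) {
    m <- sample(1:3, 1)
    hmm <- random_toy_profile(m, n_rows = sample(2:4, 1),
                              ncols = m + sample(0:1, 1))
    seq <- random_protein(sample(1:6, 1))
    expect_equal(score_sequence(hmm, seq, "viterbi"),
                 oracle_hmm_viterbi(hmm, seq), tolerance = 1e-9)
    expect_equal(score_sequence(hmm, seq, "forward"),
                 oracle_hmm_forward(hmm, seq), tolerance = 1e-9)
  }
})

test_that("forward dominates viterbi and consensus dominates random sequences", {
  set.seed(12)
  prot <- make_proteins(
    paste0(strrep("A", 8), "LQLRL", strrep("G", 8)),
    paste0(strrep("A", 8), "LQLKL", strrep("G", 8)),
    paste0(strrep("A", 8), "LQLRL", strrep("G", 8))
  )
  w <- extract_seed_windows(prot, scan_ear_motifs(prot), flank = 6)
  hmm <- build_profile(build_anchored_msa(w))
  cons_score <- score_sequence(hmm, hmm$consensus)
  for (i in 1:200) {
    s <- random_protein(nchar(hmm$consensus))
    expect_lte(score_sequence(hmm, s), cons_score)
    expect_gte(score_sequence(hmm, s, "forward") - score_sequence(hmm, s), -1e-9)
  }
})

test_that("calibration is deterministic, self-consistent, and errors sanely", {
  prot <- make_proteins(
    paste0(strrep("A", 8), "LQLRL", strrep("G", 8)),
    paste0(strrep("C", 8), "LSLRL", strrep("G", 8))
  )
  w <- extract_seed_windows(prot, scan_ear_motifs(prot), flank = 6)
  hmm <- build_profile(build_anchored_msa(w))

  c1 <- calibrate(hmm, n_null = 300, null_len = 150, seed = 5)
  c2 <- calibrate(hmm, n_null = 300, null_len = 150, seed = 5)
  expect_identical(c1$calibration, c2$calibration)

  # Gumbel tail at the empirical 95th percentile is close to 0.05
  q95 <- quantile(c1$calibration$null_scores, 0.95)
  p <- earminer:::gumbel_tail(q95, c1$calibration$mu, c1$calibration$beta)
  expect_lt(abs(p - 0.05), 0.02)

  # E-value at the null median is about db_size / 2
  med <- median(c1$calibration$null_scores)
  expect_lt(abs(evalue(c1, med, 1000) - 500), 75)

  expect_error(calibrate(hmm, n_null = 50), "n_null")
  expect_error(evalue(hmm, 10, 100), "not calibrated")
})

test_that("E-values are monotone in score, proportional to database size", {
  prot <- make_proteins(paste0(strrep("A", 8), "LQLRL", strrep("G", 8)))
  w <- extract_seed_windows(prot, scan_ear_motifs(prot), flank = 6)
  hmm <- calibrate(build_profile(build_anchored_msa(w)),
                   n_null = 200, null_len = 100, seed = 2)
  s <- seq(0, 40, by = 5)
  e <- evalue(hmm, s, 1000)
  expect_true(all(diff(e) < 0))
  expect_equal(evalue(hmm, 10, 2000), 2 * evalue(hmm, 10, 1000))
  expect_lt(evalue(hmm, 1e6, 1000), 1e-12)
})

test_that("profile JSON serialisation round-trips scores exactly", {
  prot <- make_proteins(
    paste0(strrep("A", 8), "LQLRL", strrep("G", 8)),
    paste0(strrep("C", 8), "LSLRL", strrep("G", 8))
  )
  w <- extract_seed_windows(prot, scan_ear_motifs(prot), flank = 6)
  hmm <- calibrate(build_profile(build_anchored_msa(w)),
                   n_null = 200, null_len = 100, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_profile_json(hmm, path)
  back <- read_profile_json(path)
  s <- random_protein(60)
  expect_equal(score_sequence(back, s), score_sequence(hmm, s), tolerance = 1e-12)
  expect_equal(evalue(back, 15, 500), evalue(hmm, 15, 500), tolerance = 1e-12)
})
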