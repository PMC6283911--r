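---
title: "Identifying EAR repression-motif proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying EAR repression-motif proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earminer)
library(dplyr)
```

## The problem

EAR (ERF-associated Amphiphilic Repression) motifs are short linear signals
— consensus `LxLxL` or `DLNx[1,2]P` — through which many plant transcription
factors recruit corepressors. Because the motifs are only five or six
residues long, a literal pattern match is sensitive but carries no sequence
context, while a profile model built from known family members captures the
conserved flanking context but needs a seed set. `earminer` combines both:
literal scanning defines candidates and anchors training windows; iterated
profile-HMM search expands a seed set through the proteome; reciprocal-best-hit
orthology transfers candidates across species; and a set of downstream
analytics (promoter cis-element enrichment, overlap GSEA,
differential-expression filtering, peak–gene association, co-expression
modules) annotates the resulting proteins.

## Motif scanning

`find_ear_motifs()` reports **every** match start (overlaps included); at a
`D` that begins both a 5-mer `DLNxP` and a 6-mer `DLNxxP`, both are
reported. Free (`x`) positions accept any residue code, including the
degenerate `X`/`B`/`Z`/`U`; fixed positions require the exact residue, so a
degenerate code never satisfies them. This is the conservative choice on
low-quality sequence: degeneracy can only lose motifs, never invent them.

Each hit gets a positional class. The terminal fractions are not part of the
motif definition anywhere we could find them stated, so they are parameters:
with defaults `n_frac = c_frac = 0.25`, a hit ending within the first
`ceiling(0.25 * L)` residues is `N`, one starting within the last
`ceiling(0.25 * L)` residues is `C`, everything else `M`, and `N` wins on
tiny proteins where the regions overlap. The three-way split is stable
across realistic length distributions and is recomputed per protein, so it
is invariant in distribution under length changes.

## Profile HMMs over seed windows

Training windows are the motif plus six flanking residues per side (twelve
adjoining residues in total; the per-side/total reading of "adjoining 12
residues" is ambiguous, we take total and expose `flank`). Windows are
aligned by **anchoring**, not by optimisation: the motif's fixed residues
define a fixed column frame (five columns for `LxLxL`, six for the `DLNP`
class, with 5-mer `DLNxP` windows gapped at the second free position), and
clipped flanks are padded with gaps. For windows this short and this
anchored, an alignment optimiser could only move residues *away* from the
one correspondence we know to be true.

The profile is a plan7-core model (match/insert/delete, no `I↔D`
transitions). Columns with residue occupancy ≥ 0.5 become match states.
Emissions are pseudocount-smoothed frequencies,
`(count + pc·background) / (n + pc)` with `pc = 1`; transitions are counted
from the gap structure with the same pseudocount spread uniformly over each
state's allowed moves. Subgroups with a single window still build a profile
(a near-consensus matcher); nothing in the iteration requires a minimum
seed count, and early iterations routinely have singleton subgroups.

Scoring is local-in-sequence, global-in-profile: flanking residues are free
(log-odds 0), entry and exit may pass through delete chains, insert states
emit the background (log-odds 0). The reported bitscore is the Viterbi
maximum (log2-odds); `mode = "forward"` replaces the max over paths by the
log-sum. Both are checked against exhaustive path enumeration on toy models
in the test suite, to 1e-9.

E-values come from a Gumbel fit: `calibrate()` scores `n_null` i.i.d.
background sequences of fixed length 400 — one calibration per profile,
matching the single search cutoff, rather than per-target-length
corrections — and fits location/scale by maximum likelihood (moment
estimates as fallback if the optimiser fails; the empirical sample is
retained). Then `E = db_size · P(S ≥ s)`. The choice of 400 residues
approximates a typical plant protein; because both calibration and search
use the same local scoring, the length mismatch for short/long targets is
second-order at the 0.01 cutoff used here.

## The iteration

`hmm_iterate()` is a fixed-point loop:

1. partition current seeds into (pattern, location) subgroups — at most six;
2. build and calibrate one profile per occupied subgroup (profiles are
   rebuilt from scratch each iteration, not incrementally updated);
3. score every literal-pattern-carrying protein against every profile;
4. keep proteins with `E < 0.01` for ≥ 1 profile **and** ≥ 1 literal EAR
   motif; add the novel ones to the seed set; repeat.

The pattern filter is conjunctive, so only pattern-positive proteins can
ever enter — scoring is restricted to them, which changes nothing in the
result. The seed set grows monotonically and the proteome is finite, so
termination is guaranteed; a `max_iter = 20` cap guards against oscillation
from re-calibration noise (calibration RNG is derived per profile per
iteration from the master seed, so runs are fully deterministic). The
E-value cutoff is applied per profile: any passing profile admits the
protein, mirroring a search where each family model is run independently.

Ortholog-derived candidates are merged afterwards (`merge_candidates()`),
with the same literal-pattern filter applied to them — homology without a
motif is not an EAR protein.

## Orthology

`find_orthologs()` implements reciprocal best hits with bootstrap support,
a deliberately reduced form of inparanoid-style orthology: the downstream
steps consume only ortholog *pairs* above a support cutoff, so the
inparalog-clustering layer would be unobservable here. Alignment is local
Smith–Waterman with BLOSUM62 and affine gaps 11/1 (common protein-BLAST
defaults; the upstream tool is named without parameters). Support is the
percentage of `n_boot = 100` column resamples in which the pair, resampled
independently of the query's runner-up subject, outscores it (ties count
half; no runner-up means support 100). A query facing two identical
subjects therefore sits at ~50% and falls below the >60% cutoff — exactly
the ambiguity the bootstrap is meant to flag. This column-resampling
bootstrap is our stated substitute for the original tool's procedure, which
is not reproducible from its description. Proteomes beyond ~2,000 sequences
engage a shared-4-mer prefilter (top 50 candidates per query, exact DP
decides); at tested scales the prefilter changes nothing.

## Enrichment statistics

**Cis-element enrichment.** For `n` query genes, the observed motif-match
count `x_bar` over their promoters is compared to `n_random = 1000` random
same-size gene lists drawn without replacement from the universe (lists may
overlap the query; the universe is whatever promoter set the caller
supplies). Two statistics are reported side by side:

* `z = (x_bar − mu) / (sigma / sqrt(n))` and its `pnorm` p-value — the
  platform's printed formula, kept verbatim for fidelity (upper tail by
  default; `tail = "lower"` reproduces a literal lower-tail reading);
* `z_raw = (x_bar − mu) / sigma` and `p_raw` — the plain standardisation.

These differ by `sqrt(n)`: `sigma` is already the standard deviation of the
size-`n` count sum, so dividing it by `sqrt(n)` again inflates the
statistic and makes the verbatim `p` strongly anticonservative. All
calibration claims in this package (null uniformity, type-I rate) are made
— and tested — for `p_raw`; the verbatim columns exist so results are
comparable with the platform's convention. The normal reference is
appropriate when expected per-list counts are tens or more; the calibration
tests run in that regime (expected counts ≈ 50) and the power tests at a
5× implantation rate.

Promoters default to 3,000 nt upstream of the TSS, strand-aware and
truncated at contig ends; scanning is single-strand by default
(`both_strands` available) and counts all overlapping match starts.

**GSEA.** Overlap-based over-representation per gene set: one-sided
Fisher's exact test on the 2×2 table after intersecting each set with the
universe; the hypergeometric tail is identical (asserted exhaustively in
tests) and a χ² variant is available. No multiple-testing correction is
applied by default (an optional BH flag exists) — results are flagged at
`p ≤ 0.05`.

**Differential expression.** Per gene, an equal-variance Student t-test and
`log2fc = log2(mean_a / mean_b)` on the positive linear scale;
`is_de ⇔ p < 0.05 ∧ |log2fc| > 1`. Genes with a nonpositive group mean are
excluded with a warning rather than silently log-transformed.

**Peak association.** A gene is associated with an epigenetic mark iff any
peak overlaps the strand-aware upstream window `[tss − W, tss)` (`W` =
1,000 nt for Arabidopsis-like genomes, 2,000 for rice/maize; configurable)
or the gene body. All interval arithmetic is 0-based half-open internally;
GFF3 (1-based closed) and BED (0-based half-open) are converted exactly
once, at the reader boundary.

## Networks

`build_coexpression()` computes all-pairs Pearson correlation; mutual rank
is `MR(a,b) = sqrt(rank_a(b) · rank_b(a))` on the PCC-descending neighbour
lists. Each gene keeps its `top_n = 300` neighbours (ties broken by gene id
for determinism) and the edge set is the union. An optional absolute-PCC
floor is exposed because the thresholds used by public co-expression
databases vary.

`k_clique_modules()` is exact clique percolation: all k-cliques (enumerated
via igraph), adjacency through shared (k−1)-subsets (hashed), connected
components unioned into modules. Modules may overlap; every member is in at
least one k-clique, which the tests audit on every run. Exactness is the
point — the implementation is cross-checked against brute-force subset
enumeration on small random graphs — and the practical bound (~10⁴
k-cliques) is ample for desk-scale co-expression networks.

`compare_networks()` reports the ortholog pairs present in both species'
networks and an overlay graph (solid within-species co-expression edges,
dashed cross-species ortholog links), the structure used to compare a
gene's co-expression neighbourhood with its ortholog's.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every stage has a ground truth without any
download:

* `simulate_proteome()` — i.i.d. background residues (bundled average
  composition) with EAR windows implanted at controlled pattern/location
  mixes and divergence. Implanted windows share one family-level flanking
  consensus (the motif block differs per pattern); fixed motif positions
  never mutate. This models what the iterative search actually exploits —
  conserved context around the motif within a family. It does **not** model
  domain architecture, repeat content, or compositional bias, so passing
  recovery benchmarks here demonstrates the machinery (partitioning,
  calibration, filtering, convergence), not performance on real proteomes.
* `simulate_promoters()` — i.i.d. nucleotides at AT-rich plant-like GC
  (0.35) with Poisson motif implantation at class-specific rates,
  non-overlapping placement by rejection sampling. No positional
  composition or motif clustering.
* `simulate_network()` — planted cliques plus independent noise edges; at
  zero noise the planted modules are exactly the k-clique communities.
* `simulate_expression()` — Gaussian log2 expression with a mean shift for
  the DE genes, returned on the linear scale.

Every generator is a pure function of (parameters, seed): the same seed
reproduces outputs byte-for-byte.

Benchmark scales used by the tests and the acceptance script — a
1,000-protein proteome with 50 implants at divergence 0.1 and 10 seeds,
five replicates plus ten 70%-seed resampling runs; a duplicated 200-protein
proteome for orthology; 200 null replicates at `n_random = 200` (each with
a freshly generated universe, so the replicates are independent) and 100
power replicates for enrichment — were chosen as the smallest sizes at
which the measured rates are stable, and are stated here as the package's
benchmark definition.

## Numerical and design notes

* All probability tables normalise to 1 ± 1e-9 (tested). Log-odds are base
  2 throughout; `-Inf` encodes forbidden transitions.
* Gumbel tail probabilities use `-expm1(-exp(·))` for far-tail stability.
* `σ = 0` in cis-enrichment yields `p ∈ {0, 1}` by the sign of
  `x_bar − mu`, with a signed-infinity `z` sentinel.
* Ties everywhere (best hits, neighbour ranking) break lexicographically by
  identifier, making every result order-independent and reproducible.
* The Fisher-vs-hypergeometric identity is asserted by exact arithmetic for
  every 2×2 table with `N ≤ 50`, and against `fisher.test` exhaustively to
  `N = 20` with randomised coverage to 50 (the full exhaustive sweep
  through `fisher.test` itself is disproportionately slow for a routine
  suite).

## Known limitations

* The HMM architecture is a plan7 core without the full B/E/J wing
  retractions; glocal modes and DNA models are out of scope.
* E-value calibration uses a single null length; extreme target lengths
  shift the effective E-value modestly.
* The verbatim cis-enrichment `z`/`p` columns are anticonservative by
  construction (see above); use `p_raw` for calibrated inference.
* Orthology is RBH-only: inparalog groups, synteny and tree-based methods
  are not attempted.
* Clique percolation is exact and therefore exponential in the worst case;
  it is intended for desk-scale networks, not genome-wide graphs at low
  thresholds.
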