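# earminer

Identification and downstream analysis of **EAR repression-motif proteins**
in plants.

EAR (ERF-associated Amphiphilic Repression) motifs are short linear signals
— consensus **LxLxL** or **DLNx[1,2]P** — through which plant transcription
factors recruit corepressors. `earminer` finds them and expands a seed set
of known EAR proteins through a proteome:

1. **Scan** — literal pattern matching of `LxLxL` and `DLNx[1,2]P` (all
   overlapping matches, both `DLNxP`/`DLNxxP` lengths), with each hit
   classified as N-terminal / Middle / C-terminal.
2. **Model** — seed motif windows (motif ± 6 flanking residues) are
   partitioned by (pattern, location) into up to six subgroups; each
   subgroup trains a profile HMM (anchored alignment, plan7-core states,
   pseudocount smoothing) whose E-values are calibrated by a Gumbel fit to
   null max-scores.
3. **Iterate** — score the proteome, keep proteins with `E < 0.01` for any
   profile *and* a literal EAR motif, add novel ones to the seeds, rebuild,
   repeat to convergence.
4. **Transfer** — reciprocal-best-hit orthologs (Smith–Waterman BLOSUM62
   11/1, bootstrap support > 60%) carry candidates and interaction networks
   across species.
5. **Annotate** — promoter cis-element enrichment against a resampled
   background (`Z = (X̄ − μ)/(σ/√n)` verbatim plus the calibrated raw
   standardisation), overlap GSEA (Fisher/hypergeometric/χ²),
   t-test + fold-change DE filtering, TSS-window peak association,
   PCC/mutual-rank co-expression networks and k-clique-percolation modules
   (`k = 4`).

Synthetic-data generators (`simulate_proteome()`, `simulate_promoters()`,
`simulate_network()`, `simulate_expression()`) provide ground truth for
every stage, so the whole pipeline is benchmarkable offline.

## Worked example

```r
library(earminer)
library(dplyr)

# a proteome with 50 implanted EAR windows, 10 of them used as seeds
sim <- simulate_proteome(n = 1000, n_implant = 50,
                         divergence_rate = 0.1, seed = 7)
seeds <- head(sim$truth$id[sim$truth$implanted], 10)

res <- hmm_iterate(sim$proteome, seeds, evalue_cutoff = 0.01, seed = 11)
res
#> <ear_search> 50 candidate(s) after 2 iteration(s), converged
glance(res)
#> # A tibble: 1 × 4
#>   n_candidates n_iterations converged evalue_cutoff
#>          <int>        <int> <lgl>             <dbl>
#> 1           50            2 TRUE               0.01

implanted <- sim$truth$id[sim$truth$implanted]
mean(implanted %in% res$candidates$protein_id)   # recovery
#> [1] 1
mean(!res$candidates$protein_id %in% implanted)  # false discoveries
#> [1] 0
```

All 50 implanted proteins are recovered from 10 seeds with no false
discoveries: iteration 1 trains profiles on the seeds' subgroups and pulls
in every protein whose motif context matches at `E < 0.01`; iteration 2
finds nothing novel and the loop stops. Scanning alone:

```r
find_ear_motifs("GGGDLNYYPGGGLLLALGGG")
#> # A tibble: 2 × 4
#>   pattern start   end matched
#>   <chr>   <int> <int> <chr>
#> 1 DLNP        4     9 DLNYYP
#> 2 LxLxL      13    17 LLLAL
```

A command-line front end covering all operations (scan, search, orthologs,
coexpr, modules, cis-enrich, gsea, de, peaks, simulate, ...) is installed at
`system.file("scripts", "earminer", package = "earminer")`.

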