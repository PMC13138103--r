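# pphnet

Differential **pathway topology** from gene expression, via persistent
path homology of directed pathway networks.

Classical enrichment methods treat a pathway as an unordered gene set.
`pphnet` instead asks whether the *directed wiring* of a pathway — its
feed-forward motifs, feedback cycles and signalling cascades — is
assembled differently by the co-expression structure of two conditions
(e.g. disease vs control).

For each condition, every pathway edge `u -> v` is weighted by the
correlation distance

```
d(u, v) = 1 - |rho(u, v)|
```

(Pearson correlation of the two genes' expression profiles; strong
negative co-regulation counts like strong positive). Sweeping a threshold
`f` from 0 to 1 in steps of 0.01 yields a filtration of directed graphs,
and **regular path homology** — computed with exact finite-field linear
algebra — tracks

* `beta0(f)`: the number of connected gene clusters, and
* `beta1(f)`: the number of independent *directed* cycles
  (direction-aware: a transitive triangle is filled, a feedback cycle is
  not)

at each threshold. Betti curves become persistence barcodes and
landscapes; averaged-landscape differences between conditions are tested
globally by permutation (sup-, 1- and 2-norms, BH-adjusted), and each
pathway is tested by the two-sample Kolmogorov–Smirnov statistic and
Cohen's *d* on its Betti series (5000 label permutations each, BH across
pathways). A pathway is flagged only when **all four** FDR values
(KS and *d*, dimensions 0 and 1) fall below 0.05.

Pathway networks come from KGML (KEGG) files, TSV edge lists or 0/1
adjacency matrices; expression comes from any log-scale matrix (a
`log_tpm()` helper converts raw counts).

## Worked example

The package ships a 10-gene illustrative pathway: a feedback cycle
`g1 -> g2 -> g3 -> g4 -> g1`, a bi-fan `g6, g9 -> g7, g8`, a pendant gene
`g5` and an isolated gene `g10`, plus a deterministic edge-distance table.

```r
library(pphnet)

betti_numbers(toy_network())
#> beta0 beta1
#>     3     2

persistence_pairs(toy_filtration(), dimension = 1)
#> # A tibble: 2 x 4
#>   dimension birth death essential
#> 1         1  0.38     1 TRUE
#> 2         1  0.87     1 TRUE
```

With every edge present the pathway has 3 components and 2 independent
directed cycles. The barcode shows *when* each cycle assembles: the bi-fan
completes once its slowest edge enters at `f = 0.38`, the feedback cycle
at `f = 0.87`, and both persist to `f = 1` (essential bars).

An end-to-end run on simulated data — 20-gene-scale pathways, 17 samples
per condition, two pathways rewired between conditions:

```r
st  <- simulate_pathway_study(n_pathways = 6, n_planted = 2, seed = 42)
res <- run_pph(st$expression, st$networks,
               n_perm_global = 200, n_perm_pathway = 1000, seed = 1)
res
#> <pph_result> 6 pathway(s), conditions C vs D
#>   global test: min q = 0.185
#>   significant pathways (all four q < 0.05): 2 [pw01, pw02]

dplyr::select(tidy(res), pathway_id, dimension, K, d, q_ks, q_d, significant)
#> # A tibble: 12 x 7
#>    pathway_id dimension      K       d  q_ks   q_d significant
#>  1 pw01               0 0.733   2.24   0     0     TRUE
#>  2 pw01               1 0.772  -2.56   0     0     TRUE
#>  3 pw02               0 0.871   2.70   0     0     TRUE
#>  4 pw02               1 0.871  -3.54   0     0     TRUE
#>  5 pw03               0 0.0792  0.234  0.424 0.206 FALSE
#>  6 pw03               1 0.228  -0.576  0     0.002 FALSE
#>  ...
```

The two planted pathways (`pw01`, `pw02`) are recovered: their disease
condition assembles edges and cycles much earlier, giving large KS
separation and effect sizes in both dimensions. `pw03` shows how the
four-test rule guards against partial signals: two of its four q-values
are small, so it is not flagged. Positive `d` in dimension 0 reads as
"more disconnected components in the control condition".

`tidy()` / `glance()` return the tables, `autoplot()` draws Betti curves,
barcodes and landscapes, and `run_pph(..., out_dir = )` writes the full
CSV/JSON bundle. A thin command-line front end lives at
`inst/cli/pphnet.R` (`run`, `betti`, `toy` subcommands).

## Layout

* `R/` — pathway I/O (KGML, edge lists, adjacency), expression weighting,
  the path-homology core, persistence summaries, permutation statistics,
  simulators, the `run_pph()` workflow
* `tests/testthat/` — unit, property and acceptance suites, including an
  independent exact-rank (Bareiss) oracle for the homology core
* `vignettes/pathway-topology.Rmd` — the model, its assumptions, numerical
  choices and limitations
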