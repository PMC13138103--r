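---
title: "Differential pathway topology with persistent path homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential pathway topology with persistent path homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pphnet)
```

## The problem

Enrichment-style pathway analyses treat a pathway as a bag of genes and ask
whether its members are unusually differentially expressed. They ignore the
*wiring*: KEGG pathways are directed graphs whose activations and
inhibitions encode feed-forward motifs, feedback cycles and signalling
cascades. Two conditions can share every marginal expression change and
still differ in how the pathway's genes are *co-ordinated* along those
directed edges.

`pphnet` compares the directed topology of a pathway between two
conditions (e.g. disease vs control). The co-expression structure of each
condition turns the pathway graph into a filtered object, persistent path
homology summarizes how connected components and directed cycles assemble
as co-expression weakens, and permutation statistics decide which pathways'
topological profiles differ.

## From expression to a filtration

For one condition with $n$ samples, each pathway gene is a point in
$\mathbb{R}^n$ (its expression profile). Every directed edge $u \to v$ of
the pathway receives the correlation distance

$$d(u, v) = 1 - |\rho_{uv}|,$$

with $\rho_{uv}$ the Pearson correlation of the two profiles. The absolute
value makes strong negative co-expression (inhibition) count as strongly as
positive co-expression. The filtration threshold $f$ runs from $0$ to $1$
in steps of $0.01$ (101 grid points): at threshold $f$ the subgraph
contains **all** genes and exactly the edges with $d \le f$ (comparison
tolerance $10^{-12}$, so a weight sitting on a grid value enters
deterministically). At $f = 0$ the pathway is a disconnected point cloud;
at $f = 1$ it is the full KEGG graph.

Genes without a measured profile are dropped (with their incident edges)
before weighting, and recorded; they are never imputed, because the point
cloud is defined by measured genes only. A zero-variance profile makes
$\rho$ undefined; such edges get $d = 1$ (they enter only at the last
step), with a warning — an uninformative gene should not create early
connectivity.

## Regular path homology in dimensions 0 and 1

Path homology is the digraph analogue of simplicial homology. An *allowed*
$p$-path is a vertex sequence $v_0 \to \cdots \to v_p$ walking along
directed edges. The chain spaces are $\Omega_0 = \langle V \rangle$,
$\Omega_1 = \langle E \rangle$, and

$$\Omega_2 = \{ x \in \langle A_2 \rangle : \partial x \text{ is supported
on allowed 1-paths} \},$$

where $A_2$ is the set of allowed 2-paths and
$\partial(u,v,w) = (v,w) - (u,w) + (u,v)$ (the $(u,w)$ term vanishes when
$u = w$, the irregular case). Then

$$\beta_0 = |V| - \operatorname{rank} \partial_1, \qquad
  \beta_1 = \dim \ker \partial_1 - \operatorname{rank}
  (\partial_2|_{\Omega_2}).$$

$\beta_0$ counts weakly connected components; $\beta_1$ counts independent
directed cycles *after* quotienting by the fillers in $\Omega_2$. Direction
matters: the transitive triangle and the diamond are filled
($\beta_1 = 0$), while a consistently oriented cycle of length $\ge 4$ and
the bi-fan ($g6,g9 \to g7,g8$) are not ($\beta_1 = 1$). Higher dimensions
carry little signal in gene pathways and are out of scope; the package
fixes the maximum dimension at 1.

### Exact arithmetic

Floating-point rank estimation is unreliable for homology, so all ranks and
null spaces are computed exactly over the prime field
$\mathrm{GF}(1000003)$, with boundary matrices whose entries lie in
$\{-1, 0, 1\}$. For such incidence-type matrices the $\mathrm{GF}(p)$ rank
can differ from the rational rank only if $p$ divides an invariant factor,
which does not occur for the small factors these matrices have at
$p \approx 10^6$. The test suite verifies agreement with an independent
fraction-free (Bareiss) integer elimination — i.e. exact rational ranks —
on batches of random digraphs, as well as closed-form motifs. The prime is
small enough that every intermediate double-precision product in the
vectorised elimination stays exact.

```{r toy}
betti_numbers(toy_network())
```

## Betti curves, barcodes, landscapes

Evaluating $(\beta_0, \beta_1)$ at each of the 101 thresholds gives the
Betti curves. Because only thresholds where an edge enters can change
anything, the implementation computes homology at those critical values and
extends piecewise-constantly.

The Betti series alone does not determine how features pair into bars, so
barcodes use the canonical one-parameter construction: persistent Betti
numbers $\beta(i,j) = \dim Z(G_i) - \dim(Z(G_i) \cap B(G_j))$ (valid
because the chain spaces are nested under edge inclusion) and
inclusion–exclusion multiplicities
$\mu(i,j) = \beta(i,j{-}1) - \beta(i,j) - \beta(i{-}1,j{-}1) +
\beta(i{-}1,j)$. For dimension 0 the vertex set is fixed, every component
is born at $f = 0$ and deaths follow the $\beta_0$ decrements. Features
alive at $f = 1$ are *essential*; they are recorded with death capped at
$1.0$ so landscapes stay finite (the full network is guaranteed at
$f = 1$). Dropping them instead is available via `cap_essential = FALSE`.
A heuristic `method = "curve"` pairing (each decrement kills the youngest
live bar) is kept for comparison with pipelines that only ever see the
Betti series; both modes agree on live-bar counts at every threshold.

A barcode becomes a persistence landscape
$\lambda_k(t) = k\text{-th largest of } \max(0, \min(t - b, d - t))$
over bars $(b, d)$. Landscapes are evaluated on the same 101-point grid:
births and deaths are grid-snapped, each $\lambda_k$ is 1-Lipschitz, so the
discretization error is at most half a step; the tests quantify it against
a $10\times$ finer grid. Averages and differences are pointwise and
level-wise with zero-padding of missing levels. Norms are
$\sup_k \sup_t |\lambda_k|$, $\sum_k \int |\lambda_k|$ and
$(\sum_k \int \lambda_k^2)^{1/2}$, with trapezoidal integrals — exact for
piecewise-linear integrands up to kink placement. All nonzero levels are
retained; truncation to the most dominant levels is a plotting choice only.

## Statistics

**Global test.** Per homology dimension, the observed statistic is each
norm of $\overline{PL}_D - \overline{PL}_C$, averaging landscapes across
pathways within a condition. The null pools all landscapes and reassigns
them to two groups of the original sizes; `n_perm = 1000` by default. The
p-value is the proportion of permuted statistics $\ge$ the observed one
(ties count, the valid choice), and the three norms' p-values form one BH
family per dimension. A pooled six-value family and the conservative
$(\text{count}+1)/(N+1)$ estimator are available by argument.

**Pathway-level tests.** Per pathway and dimension, the two conditions'
Betti series (101 values each) are compared with the two-sample KS
statistic $K = \sup_v |F_C(v) - F_D(v)|$ and Cohen's
$d = \mu_\Delta / s$ with $\mu_\Delta$ the control-minus-disease mean and
$s$ the pooled ($n-1$) standard deviation, $n_1 = n_2 = \tau = 101$.
Positive $d$ in dimension 0 means more disconnected components in the
control condition. Permutation p-values (default `n_perm = 5000`) pool the
$2\tau$ values and resplit; $|d|$ is used for a two-sided effect-size test.
Equal constant series give $d = 0$; unequal constant series are reported as
a signed infinite effect. BH runs across pathways within each of the four
families $\{K, d\} \times \{\beta_0, \beta_1\}$, and a pathway is
*significant* only when all four q-values fall below $\alpha = 0.05$.

Two honest caveats, verified in the test suite's calibration checks. With
tie-free statistics the permutation p-value is exactly calibrated; heavy
ties in Betti values only make it conservative. But the 101 grid values of
one pathway are *autocorrelated*, so treating them as exchangeable samples
makes the pathway-level tests sensitive to any systematic difference
between the condition curves, however small — which is why the
intersection over four tests, not any single p-value, defines
significance.

## What the simulator emulates — and what it does not

`simulate_expression()` draws profiles from a multivariate normal whose
correlation matrix carries the requested $|\rho|$ targets (positive sign;
the distance is sign-blind). Exactly singular targets such as $|\rho| = 1$
are admitted through a $10^{-10}$ ridge; indefinite target structures are
rejected rather than silently repaired. Realized correlations converge to
the targets as $n$ grows (tests check $n = 1000$ at tolerance 0.05); at
the study scale of 17 samples per condition the realized correlation of a
pair with target $\rho$ fluctuates with standard deviation roughly
$(1 - \rho^2)/4$.

That fluctuation drives the design of `simulate_pathway_study()`, the
planted-signal benchmark: 20 pathways of 8 genes, each containing a
directed 4-cycle so both dimensions are informative, 17 samples per
condition. *Null* pathways are tight co-expression modules
($|\rho| = 0.9$ in both conditions, noise $\approx 0.05$): only then do a
null pathway's two filtrations genuinely agree, so the benchmark measures
rewiring recovery rather than finite-sample correlation noise. *Planted*
pathways contrast $|\rho| = 0.05$ (control) with $0.9$ (disease), so
edges and cycles assemble much earlier in the disease filtration.

The simulator is Gaussian and stationary: it does not emulate counts,
library-size effects, outlier samples, batch structure, or the heavy-tailed
marginals of real RNA-seq. Passing tests therefore demonstrate that the
topological and inferential machinery behaves as specified under its own
model — not that any particular biological dataset will separate.

The bundled 10-gene network (`toy_network()`) carries a deterministic
synthetic weight table (`toy_edge_weights()`): only the strongest edge
($g9 \to g7$ at $d = 0.184$) and the maximum ($0.946$) are dictated by the
motivating illustration; the remaining seven values were chosen once so the
filtration reproduces the reference snapshots ($\beta_0 = 9$ at $f = 0.2$;
$\beta_0 = 7, \beta_1 = 1$ at $f = 0.4$; stable $\beta_0 = 3,
\beta_1 = 2$ from $f = 0.95$). The pendant attachment of $g5$ is
configurable because only the figure, not the text, fixes it — every
Betti summary above is provably invariant to that choice.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `step` | 0.01 | filtration step on $[0,1]$; 101 grid points |
| `n_perm_global` | 1000 | permutations for the landscape test |
| `n_perm_pathway` | 5000 | permutations per pathway-level test |
| `alpha` | 0.05 | FDR threshold in the four-test rule |
| `p` | 1000003 | prime modulus of the coefficient field |
| `n_samples` | 17 | simulator samples per condition |
| `seed` | — | one generator drives all randomness; reruns are bit-identical |

## Problem sizes

The homology core costs one exact elimination per critical threshold, and
the dimension-1 barcode one additional rank per pair of critical
thresholds; pathway graphs with a few hundred edges are comfortable on one
core. The test suite runs its stochastic checks at reduced sizes chosen as
the package's own regression scale: 100 random digraphs for oracle
equivalence, 200 replicates at 99 permutations for calibration, and
20 pathways at 200–500 permutations for the planted benchmark.

## Known limitations

* Homology dimensions $\ge 2$, non-regular path homology and
  Vietoris–Rips persistence of the raw point cloud are out of scope.
* KGML semantics beyond gene entries, relations and groups (maps,
  compounds, orthologs) are dropped, and identifier mapping is an explicit
  offline table, never a network lookup.
* The grid-snapped landscape introduces a discretization error of up to
  half a step in each norm; the closed-form tests run at that tolerance.
* Permutation p-values of 0 are reported as the numeric 0 (and fed to BH
  as such); the conservative estimator is one argument away.
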