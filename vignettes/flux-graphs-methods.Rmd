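---
title: "Flux-based graphs for metabolic networks: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-based graphs for metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxgraphs)
```

This vignette is the package's account of the science it implements: the
graph constructions, the diffusion-based community detection, the
assumptions behind them, and the design decisions taken where the design
was genuinely open.

## 1. From stoichiometry to directed flow graphs

A metabolic network of $n$ metabolites and $m$ reactions is summarised by
the stoichiometric matrix $S$, with $S_{ij}$ the net number of molecules
of metabolite $i$ produced ($>0$) or consumed ($<0$) by reaction $j$, and
the mass balance $\dot{x} = S v$ for the flux vector $v$.

The classical Reaction Adjacency Graph $A = \hat S^\top \hat S$ (boolean
$\hat S$) connects reactions that share metabolites. It is symmetric by
construction, ignores irreversibility, and its connectivity is dominated
by pool metabolites — ATP, protons, water and other cofactors that
participate in a large fraction of reactions. `build_rag()` implements it
as the baseline; its diagonal records how many metabolites each reaction
touches, and the package counts those self-loops as edges.

The flow constructions instead ask *where mass goes*. Every reaction is
unfolded into a forward and a backward column,

$$S_{2m} = [\,S,\ -S\,\mathrm{diag}(r)\,],$$

with $r$ the reversibility indicator, so the backward column of an
irreversible reaction is identically zero (such columns are dropped from
all graph node sets, which is why the blueprint graph of the bundled
*E. coli* core model has $95 + 59 = 154$ nodes). The production and
consumption splits are $S^+ = (|S_{2m}| + S_{2m})/2$ and
$S^- = (|S_{2m}| - S_{2m})/2$, with row totals $w^+_k$, $w^-_k$: the
number of molecules of metabolite $k$ produced/consumed across the whole
unfolded system.

**Normalised Flow Graph.** With no biological context beyond
stoichiometry, the probability that a molecule of metabolite $k$ chosen
uniformly at random is produced by direction $i$ and consumed by
direction $j$ is $(s^+_{ki}/w^+_k)(s^-_{kj}/w^-_k)$. Averaging over
metabolites gives the NFG weights

$$\mathcal{D}_{ij} = \frac{1}{n}\sum_k \frac{s^+_{ki}}{w^+_k}\frac{s^-_{kj}}{w^-_k}
  = \frac{1}{n}\left[(W_+^\dagger S^+)^\top (W_-^\dagger S^-)\right]_{ij}.$$

$\sum_{ij}\mathcal{D}_{ij} = (\text{metabolites both produced and
consumed})/n$, equal to 1 exactly when every metabolite has a producer
and a consumer. A cofactor consumed by 40 reactions contributes $1/w^+w^-$
per pair — the over-representation of pool metabolites is tamed by the
normalisation itself, not by deleting them.

**Mass Flow Graph.** Given a balanced flux vector ($Sv = 0$), positive
entries become forward fluxes and negative entries backward fluxes,
$v_{2m} = [(|v|+v)/2;\ (|v|-v)/2] \ge 0$. The flux at which metabolite
$k$ turns over is $j_k = (S^+ v_{2m})_k = (S^- v_{2m})_k$; equality of
the two expressions *is* the steady-state condition, and the package
verifies it (a violation is an error naming the worst metabolite, not a
silent fix-up). Each metabolite's production is then allocated to its
consumers proportionally to their consumption flux, giving

$$M(v^*) = (S^+ V^*)^\top J_v^\dagger (S^- V^*),$$

with $V^* = \mathrm{diag}(v_{2m}^*)$, $J_v = \mathrm{diag}(j)$. Weights
are in mmol/gDW/h; self-loops are kept (they are the flux of
autocatalytic reactions); reaction directions with numerically zero flux
are pruned from the node set.

**Competition and synergy graphs.** The same normalisation applied on one
side only gives the undirected
$\mathcal{D}_c = \frac1n S^{-\top}(W_-^\dagger)^2 S^-$ (two directions
consuming the same random molecule) and
$\mathcal{D}_s = \frac1n S^{+\top}(W_+^\dagger)^2 S^+$ (producing it).

**Pseudoinverse convention.** Throughout, the dagger on a diagonal matrix
is the Moore–Penrose pseudoinverse: reciprocal of non-zero entries, zero
elsewhere. Metabolites that nothing produces (or nothing consumes)
therefore contribute nothing, with no special-casing; `validate_model()`
flags them so the user knows they are there.

## 2. Flux Balance Analysis

`solve_fba()` maximises the objective flux $c^\top v$ subject to
$S v = 0$ and $v_{lb} \le v \le v_{ub}$. Because no linear-programming
package is part of this package's dependency footprint, the LP is solved
by an internal bounded-variable two-phase primal simplex
(`simplex_lp()`) with Bland's smallest-index anti-cycling rule.
Stoichiometric LPs are unforgiving: $S$ is rank-deficient (the core
model has rank 67 of 72 rows) and optima sit on highly degenerate
vertices; redundant rows are removed by QR factorisation up front and
Bland's rule guarantees termination. The solver is deterministic — the
same model yields the same vertex — and solutions are verified a
posteriori ($\max|Sv| \le 10^{-6}$ scaled, bounds to $10^{-7}$).

FBA optima are generally non-unique. The package mirrors common practice
by reporting the raw optimal vertex; an optional lexicographic second
stage (`minimize_total_flux = TRUE`) fixes the objective and minimises
$\sum_j |v_j|$ for a canonical representative. Every `flux_solution`
records which mode produced it. The choice matters downstream: the MFG
node set and hence its community structure inherit the chosen vertex
(see §5).

The four built-in growth scenarios for the core model set each available
carbon source to an uptake of 18.5 mmol/gDW/h; oxygen is unlimited
except in the anaerobic scenario (uptake bound 0); the nutrient-limited
scenario caps ammonium at 4.5 and phosphate at 3.04 mmol/gDW/h. "Rich
media" is read as the model's distributed exchange defaults with only
the stated uptakes overridden; the exact exchange set of the ethanol
scenario is under-documented upstream, so results for it should be
treated as scenario-sensitive.

## 3. PageRank centrality

`pagerank()` computes the stationary distribution of a random walk that
follows out-edges with probability $\lambda$ and teleports uniformly
with probability $1-\lambda$ (dangling nodes always teleport):

$$B = \lambda K_{out}^{-1} G + \tfrac1N\left[(1-\lambda) I + \lambda\,\mathrm{diag}(a)\right]\mathbf{1}\mathbf{1}^\top .$$

Teleportation makes the chain ergodic on directed graphs that are not
strongly connected — true of every MFG, whose exchange reactions are
sources and sinks. $\pi$ is computed by power iteration to an $L_1$
residual of $10^{-12}$ (cap $10^5$ iterations; non-convergence is an
error, not a warning). $\lambda = 0.85$ is the default everywhere, and
the stability analysis reuses the same value — one source of truth.
Percentiles use average-rank ties; each direction of a reversible
reaction carries its own score. `pathway_pagerank()` sums scores by
pathway; since $\sum\pi = 1$ the pathway totals read as shares of
random-walk occupation.

## 4. Markov Stability community detection

On the same teleporting walk, define $L = I - B$ and the transition
kernel $P(t) = e^{-tL}$. For a hard partition encoded one-hot in $H$,
the clustered autocovariance

$$R(t, H) = H^\top\!\left(\Pi P(t) - \pi\pi^\top\right) H,
\qquad \Pi = \mathrm{diag}(\pi),$$

has entries measuring how much probability flow starting in one
community is found in another after Markov time $t$, beyond chance. The
Markov Stability $r(t,H) = \mathrm{tr}\,R(t,H)$ scores how well
communities retain flow; $t$ acts as a resolution parameter. Exact
limits used as tests: $r(0)$ of the all-singleton partition is
$1 - \sum_i \pi_i^2$; the one-community partition scores 0 at every $t$;
all partitions decay to 0 as $t \to \infty$.

A note on orientation: the autocovariance is sometimes written with
$e^{-tL^\top}$ next to $\Pi$. Spelled out entrywise that variant pairs
$\pi_i$ with backward transition probabilities and does not match the
stated meaning of $R$; this package uses $\Pi P(t)$ with the
row-oriented kernel, which does, and which reproduces persistent
multiscale structure in practice.

**Optimisation.** Since the trace only sums entries within communities,
$r$ is invariant under symmetrising $F(t) = \Pi P(t) - \pi\pi^\top$, and
the maximisation over partitions is a generalised Louvain problem on
$(F + F^\top)/2$ — generalised because the null model $\pi\pi^\top$ is
already inside the matrix, which therefore carries negative entries that
off-the-shelf modularity Louvain implementations do not accept. The
optimiser (C++, `louvain_optimise()`) runs shuffled node sweeps taking
the best strictly-improving move, then aggregates and repeats. The
shuffle uses a private xorshift generator, so results are deterministic
given the seed and independent of R's RNG state. The improvement
threshold is *relative* to the magnitude of $F(t)$, because the
objective decays like $e^{-(1-\lambda)t}$ and an absolute cutoff would
freeze the optimiser at large Markov times.

**Robustness.** `scan_stability()` optimises $r$ at each time of a
log-spaced grid (default $10^{-2}$–$10^2$, 100 points) from
`n_repeats = 100` seeds, keeps the best partition, and records two
diagnostics: the ensemble mean normalised variation of information
$VI(t)$ (optimiser consistency at fixed $t$) and the cross-time matrix
$VI(t,t')$ between best partitions. $VI$ is normalised by $\log n$, so
it lies in $[0,1]$ and is a metric on partitions. After the per-time
optimisations, the best partitions are propagated to neighbouring grid
points (forward and backward re-evaluation sweeps) and kept where they
score higher — Louvain is greedy, and the partition found at one
resolution is often the better optimum next door; $VI(t)$ always
reflects the raw ensemble. `robust_partitions()` then flags times where
$VI(t)$ dips below a threshold (default 0.05) and the contiguous run of
$t'$ with $VI(t,t') <$ threshold spans at least 5 grid points. The
plateau is judged on cross-time VI rather than on the community count,
so a level whose count wobbles by one splinter community still forms a
single plateau. Both thresholds are heuristics for what one would select
by inspecting the $VI$ curves, and both are configurable.

## 5. What the scans do and do not reproduce

On the bundled core model the package reproduces the structural numbers
exactly: 72×95 model, 59 reversible reactions, RAG 95 nodes / 1,158
edges (including the 95 self-loops), NFG 154 nodes / 1,604 directed
edges, and NFG weights summing to exactly 1. The stability scans (100
repeats, default grid and thresholds) robustly yield 7 communities for
the RAG, 5 for the NFG, and 3 and 11 for the aerobic-glucose MFG.

Levels reported elsewhere for MFGs — 4 communities anaerobically, and
intermediate aerobic-glucose levels of 7, 5 and 2 — appear in our scans
as community counts but with ensemble $VI(t)$ around 0.07–0.14, above
the 0.05 dip threshold: the optimiser genuinely lands on distinct
partitions at those scales. We attribute this to FBA vertex degeneracy:
the MFG inherits the particular optimal vertex, different LP
implementations return different vertices of the same optimal face, and
we verified that the lexicographic minimum-flux vertex shifts which
levels are robust. The two constructions that do not depend on a flux
vector (RAG, NFG) are unaffected. Conclusions drawn from MFG community
structure should therefore be checked across vertices (the
`minimize_total_flux` switch exists for exactly this), and robust levels
read from the $VI$ diagnostics rather than from a single partition.

## 6. Synthetic data

`toy_network()` is an 8-reaction, 5-metabolite network with nutrient
uptake, intermediate biosynthesis, two secretion routes, one reversible
interconversion (R4) and a biomass reaction consuming X3 + 2 X4 + X5 —
large enough to exercise unfolding, FBA (its optimum, 2.5, is derivable
by hand from the steady-state balance) and every graph builder.

`random_model()` draws sparse random stoichiometries (coefficients ±1,
±2) at a requested density and reversible fraction; by default rows are
repaired so every metabolite has at least one producing and one
consuming unfolded column, the regime in which the NFG normalisation is
exactly 1. `random_balanced_flux()` samples the null space of $S$ (so
$Sv = 0$ to machine precision), projecting out components that violate
irreversibility and scaling into the bounds. These fixtures emulate the
*algebraic* structure of metabolic models — they make no attempt at
biochemical realism (no mass conservation across a reaction, no
compartments, no correlated pathway structure). Tests passing on them
certify the linear algebra and the probabilistic normalisations, not
biological conclusions; the bundled core model covers the realistic end.

Test and scan problem sizes (brute-force oracles at $n, m \le 12$,
exhaustive partition enumeration at $N \le 8$, scans at 100 grid points
× 100 repeats) are chosen so the whole suite evaluates in a few minutes
on a laptop while still separating correct from incorrect
implementations at $10^{-12}$ tolerances.

## 7. Numerical choices, in one place

- LP feasibility/optimality tolerance $10^{-9}$; pivot tolerance
  $10^{-10}$; post-hoc balance check $10^{-6}$ (scaled).
- MFG zero-flux node pruning: $|v| < 10^{-9} \max|v|$ (configurable) —
  LP vertices carry numerical dust.
- Edge weights below $10^{-15}$ are not materialised; this can affect
  edge counts and is configurable per builder.
- Matrix exponential: dense scaling-and-squaring (`Matrix::expm`);
  adequate for the ≤ few-thousand-node graphs this package targets.
- Power iteration: $L_1$ tolerance $10^{-12}$, max $10^5$ iterations.
- Louvain: relative improvement threshold $10^{-12}\,\max|F|$;
  first-best move per node; ties broken toward the lower community
  index.
- VI: natural logarithms, normalised by $\log n$; tiny negative joint
  entropies from floating point are clipped at 0.

## 8. Known limitations

- No flux variability analysis, dynamic FBA, MOMA/ROOM, or
  gene–protein–reaction rules — out of scope by design.
- The SBML reader covers Level 3 with fbc bounds/objectives (the format
  of current model repositories); kinetic-law-encoded bounds of legacy
  Level 2 files are not read.
- Markov Stability at very large Markov times operates on an objective
  decayed to the order of $10^{-9}$; partitions reported beyond the last
  robust plateau are numerically fragile and should not be interpreted.
- The bundled subsystem labels of the core model follow the standard
  pathway annotation; they feed only pathway-level aggregation, not the
  graph constructions themselves.
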