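---
title: "Methods: similarity-network drug repurposing with tuned modularity resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-network drug repurposing with tuned modularity resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddsn)
```

## The method in one page

`ddsn` operationalizes a simple pharmacological assumption: drugs that
interact with the same genes *in the same manner* tend to share therapeutic
function, so a drug embedded in a network community dominated by one
anatomical group is a candidate for repositioning into that group.

The pipeline has three stages.

1. **Projection.** Typed drug–gene interactions (drug, gene, type) form a
   bipartite graph; it is projected onto drugs with edge weight
   $w_{ij} = |\{g : \exists t,\ (D_i,g,t) \wedge (D_j,g,t)\}|$, the number of
   *distinct* genes shared in the same manner. A gene shared under two
   different matching types still counts once (the similarity is about
   genes, not gene–type pairs), and a gene touched by both drugs under
   *different* types contributes nothing.
2. **Clustering.** The weighted drug–drug similarity network (DDSN) is
   partitioned by maximizing
   $$M_\lambda(C) = \frac{1}{2a}\sum_{ij}\Big[\lambda\,w_{ij} -
     \frac{k_i k_j}{2a}\Big]\,\delta(C_i, C_j),
     \qquad a = \tfrac12\sum_{ij} w_{ij},$$
   a resolution-parameterized weighted modularity that reduces to the
   standard quantity at $\lambda = 1$ (all-in-one partition scores exactly
   0; a single unit edge between two singletons scores $-0.5$).
3. **Labeling, tuning, hints.** Each cluster is labeled with its *dominant*
   level-1 ATC letter — the letter carried by the most member drugs, each
   drug counting at most once per letter. The resolution is tuned by
   sweeping a grid and counting *confirmed repositionings* against a newer
   ATC release: drug $D_j$ in cluster $C_i$ with dominant letter $P_i$ is
   confirmed iff $P_i \notin A^1(D_j)$ in the older table and
   $P_i \in A^{c1}(D_j)$ in the newer one. At the tuned resolution, every
   drug missing its cluster's dominant letter yields a hint $(D_j, P_i)$,
   ranked by centrality.

## Resolution convention

$\lambda$ multiplies the *observed-weight* term, so dividing through by
$\lambda$ shows it is equivalent to the familiar null-model scaling with
$\gamma = 1/\lambda$: **lower $\lambda$ yields more, smaller clusters**.
This is the only convention consistent with the tuning sweep's intended
behavior (a grid from fragmenting to coarse partitions), and the package
treats $\lambda$ strictly as a parameter of the quality function, never as
a move-acceptance threshold. An asserted consequence on the planted fixture:
the cluster count at $\lambda = 0.3$ is at least the count at
$\lambda = 3.0$.

## The optimizer and its numerical choices

The optimizer is the classic two-phase greedy scheme: local moves over a
seeded random node order, then aggregation of clusters into super-nodes
(internal weight becomes a self-loop, counted twice in the degree), repeated
until no move improves $M_\lambda$. Choices that matter:

* **Gains are exact.** The gain of moving node $i$ from its cluster into
  cluster $C$ is computed as
  $$\Delta M = \frac{\lambda\,(k_{i,C} - k_{i,src})}{a}
    - \frac{k_i\,(K_C - K_{src})}{2a^2},$$
  with cluster degree totals excluding the moving node. This is an algebraic
  identity with the $M_\lambda$ difference — the test suite verifies
  agreement with a dense double-sum evaluation to $10^{-12}$ on 200 random
  (graph, partition, move) instances. Published forms of this gain differ in
  whether the node-to-cluster link term is doubled; pinning the
  implementation to the difference identity removes that ambiguity.
* **Strict positivity.** A move is accepted only when its net gain exceeds
  $10^{-12}$; tie gains (including exact zeros) never trigger a move. Among
  improving destinations the largest gain wins, ties resolved to the
  smallest cluster index, making every run a deterministic function of
  (graph, $\lambda$, seed, restarts).
* **Restarts.** The optimizer is restarted from `restarts` derived seeds
  (default 5) and the best-$M_\lambda$ partition is kept. The tuning sweep
  reuses the *same* seed/restart policy at every grid point so counts are
  comparable across $\lambda$.
* **Renumbering.** Clusters are re-indexed $0, 1, 2, \dots$ by decreasing
  size (ties: smallest member id), so `C0` is always a largest cluster.
* **Quality.** On 100 seeded random graphs of 5–8 nodes the optimizer
  attains the exhaustively enumerated optimum (restricted-growth-string
  enumeration of all partitions) within $10^{-9}$ in at least 95% of cases;
  two 4-cliques joined by a single edge split exactly at $\lambda = 1$.

Edgeless graphs have undefined modularity and are reported as all-singleton
partitions with `NA` modularity; isolated nodes stay singletons.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `resolution` ($\lambda$) | tuned over 0.1–5.0, step 0.1 | trade-off between observed weights and the degree null model; dimensionless |
| `seed` / `restarts` | 42 / 5 | optimizer determinism and restart count |
| `k` (dominant letters) | 1 | top-k cluster letters considered; `k = 1` is the algorithmic default, larger `k` is exploratory (a cluster's runner-up letter can be clinically informative) |
| `top_n` | 10 | hints kept per cluster after centrality ranking |
| `categories` | `targets` | DrugBank protein categories harvested (`targets`, `enzymes`, `carriers`, `transporters`); published interaction counts depend on this choice, so it is explicit |
| `approved_only` | `TRUE` | restrict to drugs with the `approved` group |

Ties in the tuning sweep are resolved to the **largest** $\lambda$ at the
maximum confirmed count — when several resolutions perform equally the
coarsest acceptable clustering is preferred.

Betweenness for ranking is computed with **unit edge lengths**: DDSN weights
are similarity counts, and feeding them to shortest-path algorithms as
distances would rank strongly-similar paths as long. Ranking is betweenness
descending, ties by weighted degree descending, then drug id. Clustering
always operates on the full DDSN; `largest_connected_component()` is for
reporting and export only.

Drugs with no ATC codes are retained throughout: they contribute to no
histogram letter but are eligible hint recipients (the dominant letter is
vacuously absent from an empty code set) and are flagged `no_current_atc`.

## What the synthetic generator emulates — and what it does not

`generate_fixture(fixture_spec())` plants: (i) a block structure of
4 blocks × 12 drugs with 8 genes per block, each gene carrying one fixed
interaction type (drawn from the DrugBank action vocabulary) so that block
membership, not type diversity, drives similarity; (ii) interaction
probabilities $p_{in} = 0.8$ within and $p_{out} = 0.03$ across blocks —
sparse but non-zero cross-talk, enough to connect the DDSN without hiding
the blocks; (iii) one level-1 letter per block on 75% of its drugs
(`hint_fraction = 0.25` receive a foreign letter instead, with a 0.3 chance
of a second code, emulating multi-valued ATC labels); and (iv) a "newer"
ATC table in which half of the planted hint drugs (`confirm_fraction
= 0.5`) gain their block's letter. These values were fixed once as a
realistic miniature of a curated drug database: strong but imperfect
within-class gene sharing, a minority of drugs whose coding lags their
pharmacology, and conservative label growth between releases.

The fixture deliberately does **not** reproduce real DrugBank's heavy-tailed
degree distribution, its promiscuous hub targets, gene-symbol aliasing, or
the polypharmacology that blurs cluster boundaries. Passing the recovery
tests therefore demonstrates the machinery is correct on resolvable planted
structure, not that real-data hint lists reach any particular precision.

**The planted resolution window.** With the defaults above, within-block
DDSN weight dwarfs cross-block weight until $\lambda$ grows large enough
that the $\lambda w_{ij}$ term makes merging two blocks profitable
(cross-block weight $\approx 0.4$ per pair vs. a null term of order
$K_b^2/2a^2$); the crossover sits a little above $\lambda = 3$, while below
$\lambda \approx 0.2$ blocks shatter into fragments too small to carry their
letter. The acceptance window for the tuned resolution is therefore fixed
at $[0.3, 4.0]$; empirically the sweep holds the full planted confirmation
count across roughly $0.4 \le \lambda \le 2.9$ and the largest-tie rule
reports the upper end.

## Problem sizes and runtime posture

The test suite runs entirely on generated data: exhaustive-search oracles on
graphs of 5–8 nodes (all set partitions enumerated), projection oracles up
to 30 drugs, and end-to-end sweeps on the 48-drug fixture over the full
50-point grid with 2 restarts — sizes chosen so the whole suite exercises
every claim in well under a minute of optimizer time while keeping the
oracles exact. Real DrugBank-scale networks (thousands of drugs) run in
minutes in pure R; the optimizer's inner loop is vectorized per node but not
compiled.

## Known limitations

* Gene identity is the exact trimmed polypeptide gene-name string; no alias
  resolution, so symbol drift between database releases can split a gene.
* Which DrugBank protein categories reproduce any particular published
  interaction count is not recorded in the databases themselves; counts are
  best-effort and category choice is exposed.
* Confirmation by ATC-code growth is conservative — the WHO assigns new
  codes slowly — so confirmed counts are small by construction and serve to
  *tune* the resolution rather than to measure recall.
* Single dominant letter per cluster (`k = 1`) is the algorithmic default;
  sub-cluster structure and runner-up letters are exposed (`k > 1`) but no
  automated scoring of hints against literature is attempted.
* No overlapping communities and no refinement phase (Leiden-style) — one
  drug belongs to exactly one cluster.
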