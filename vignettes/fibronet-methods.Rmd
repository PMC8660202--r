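---
title: "fibronet: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fibronet: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibronet)
```

This vignette is the package's own account of its statistics and of the
decisions taken where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The moderated two-group model

Expression values are log2 intensities, genes × samples, with each sample
labelled `case` or `control`. For gene $g$, with group means
$\bar{y}_{g1}, \bar{y}_{g2}$ and pooled within-group variance $s_g^2$ on
$df = n_1 + n_2 - 2$ degrees of freedom, the model treats the per-gene
variances as draws from a scaled inverse-chi-square prior with $d_0$ prior
degrees of freedom and prior variance $s_0^2$, giving the posterior
(shrunken) variance

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + df\, s_g^2}{d_0 + df},
\qquad
t_g = \frac{\bar{y}_{g1}-\bar{y}_{g2}}
           {\tilde{s}_g \sqrt{1/n_1 + 1/n_2}},$$

with $t_g$ referred to Student's $t$ on $d_0 + df$ degrees of freedom
(normal limit when $d_0 = \infty$). Shrinking variances towards a common
prior stabilises the denominator in small cohorts — the regime the package
targets (the emulated designs are 16 vs 13 and 19 vs 9 samples).

**Hyper-parameter estimation.** With $z_g = \log s_g^2$ (finite values
only), moment matching gives

$$\operatorname{trigamma}(d_0/2) = \max\!\big(0,\ \operatorname{var}(z) -
\operatorname{trigamma}(df/2)\big),$$

solved for $d_0$ by monotone bisection on $(0, 10^7]$; a non-positive
right-hand side means the observed spread of $z$ is no larger than pure
sampling noise and $d_0 = \infty$ (every gene uses $s_0^2$). Then

$$\log s_0^2 = \overline{z} - \psi(df/2) + \log(df/2) + \psi(d_0/2) -
\log(d_0/2),$$

dropping the last two terms in the infinite limit. This closed form is
deterministic and directly testable; the test suite verifies that, given
identical hyper-parameters, the resulting statistics agree with limma's
empirical-Bayes moderated t to $10^{-9}$, and that $d_0 = 0$ reduces
*exactly* to the ordinary pooled-variance t-test (checked against
`t.test(var.equal = TRUE)`).

**Degenerate inputs.** With $d_0 = 0$ and $s_g^2 = 0$ there is no variance
information at all: a zero fold change yields $t = 0$, $p = 1$; a nonzero
fold change is flagged `zero_variance` with `NA` p-values rather than an
invented significance.

**Gates.** A gene is `over` iff $\log_2\mathrm{FC} > 0.5$ and BH-adjusted
$P < 0.05$, `under` symmetrically; both inequalities strict, so boundary
values never pass. Fold changes are oriented case minus control. BH is the
step-up procedure (`stats::p.adjust`); an independent hand-written step-up
serves as the oracle in the tests.

## 2. Network construction

Interaction tables are STRING-style: unordered scored pairs, integer scores
auto-scaled from the 0–1000 convention, duplicate pairs collapsed keeping
the maximum, and per-channel scores (e.g. experiments / databases /
coexpression) combined as independent evidence,
$1 - \prod_c (1 - s_c)$, when no combined column is present.

Seed expansion keeps, per query: the top `shell1_max = 20` non-seed
interactors with a qualifying edge (score ≥ 0.4) to a seed, ranked by
maximum qualifying score with ties broken by ascending node id — the
metasearch engines behind such protocols do not expose their ranking, so a
deterministic, score-respecting rule is required for reproducibility — then
the top `shell2_max = 5` relative to seeds ∪ shell 1. After node selection
**all** qualifying edges among retained nodes are included (the "evidence
view"), which is what makes the downstream centrality analysis meaningful;
spokes-only graphs would make every shell node a leaf.

The merged per-tissue network starts from one expansion of all DEGs, then
repeatedly re-submits the still-isolated *inputs* (not isolated shell
nodes) as fresh seed sets, merging by node/edge union with per-node shell
the minimum over rounds, until a round adds no edge or no input is
isolated. Every productive round connects at least one isolated input, so
the loop is bounded. The shell caps are applied per query, not per merged
network — with re-seeding rounds this is the only interpretation that
keeps rounds independent of each other.

Grow-to-saturation expands a focal set with `saturation_shell1 = 50`,
no second shell, feeding new nodes back as seeds until the node set is a
fixed point, then returns the subgraph induced on the *original* inputs.
Downstream of the confidence filter all graphs are simple and unweighted;
scores survive only as edge metadata.

## 3. Centrality and the HBS rule

* **Degree** — adjacent-neighbour count.
* **Betweenness** — Brandes' BFS accumulation; fractional counting over all
  shortest paths, unordered pairs, endpoints excluded, *no normalisation*
  (the raw plugin-style score). Any affine rescaling leaves the
  classification unchanged, which the tests assert, so the normalisation
  convention cannot affect results.
* **Eigenvector** — power iteration from a uniform positive start,
  L2-normalised per step, stopping at max absolute change $< 10^{-10}$ or
  1000 iterations, output rescaled to max = 1. The iteration runs on
  $A + I$: same eigenvectors, spectrum shifted strictly positive, so
  bipartite graphs — a star is bipartite — cannot oscillate between the
  $\pm\lambda_1$ pair that defeats plain power iteration. On disconnected
  graphs the loadings concentrate on the dominant component (other
  components decay towards 0) and a warning is emitted; an edgeless graph
  is an error, since the dominant direction is undefined. Whether the
  plugin-style eigenvector is max-rescaled or L2-normalised is not
  observable downstream: only the above-average flags feed the pipeline,
  and those are scale-invariant.

A node is Hub / Bottleneck / Switch when its degree / betweenness /
eigenvector strictly exceeds the arithmetic mean over **all** nodes of the
analysed network, and HBS when all three hold. Strictness matters: in an
all-tied graph (triangle) nothing is above average and nothing is flagged,
rather than everything.

Betweenness is verified against exhaustive shortest-path enumeration on
200 random graphs of ≤ 8 nodes (exact to $10^{-9}$), the eigenvector
against the eigen-equation residual ($< 10^{-8}$) and a dense
eigendecomposition, and both against igraph as an independent
implementation.

## 4. Over-representation analysis

The test is the one-sided hypergeometric (Fisher's exact upper tail),
$P[X \ge k]$ for $k$ query hits in a term of universe-restricted size $K$,
query size $n$, universe size $N$, computed via `stats::phyper` and
verified against exhaustive enumeration of all $\binom{N}{n}$ draws for
$N \le 12$. Gene sets are flat: no ontology-graph propagation, ancestor
closure or term decorrelation — graph-aware enrichment algorithms
(whose defaults disagree with each other) are out of scope, and term ids
are opaque labels supplied by the annotation file.

The universe defaults to the intersection of the caller's background
(typically the expression matrix's genes) with the union of annotated
genes; terms are filtered to $K \in [3, 2000]$ *before* testing; BH runs
across exactly the tested terms of one query. Significance is strict at
two tiers: FDR < 0.05 for DEG-list queries, FDR < 0.001 for HBS-list
queries.

## 5. Cross-tissue overlap

Per direction (`over`, `under`, `all`), the two tissues' gene sets are
Venn-partitioned and the shared count expressed as a percentage of each
tissue's count. Display values are **truncated** (floored) to two
significant figures: this is the unique simple rule consistent with all
four published-style fractions (2/200 → "1.0", 2/44 → "4.5",
2/1075 → "0.18", 2/47 → "4.2"); round-half-up would turn 0.186 into 0.19.
Full-precision values are reported alongside. A zero denominator yields
`NA`, never an error.

For a shared annotation term, the member-overlap view intersects each
tissue's *predicted* genes with the term's members. "Predicted" is taken
to mean membership in the tissue's PPI network node set, not DEG status:
the interesting published-style observation is precisely that shared term
members need not be differentially expressed anywhere, so the inclusion
rule must admit non-DEGs. Each shared gene is flagged by where (if
anywhere) it is a DEG.

## 6. The synthetic-data generators

The generators produce the structure the pipeline assumes, from one master
seed with one derived substream per generator (adding a generator call
never perturbs another; identical configs give byte-identical output).

* **Expression** — $y_{gj} = \mu_g + \Delta_g\,[j \in \text{case}] +
  \varepsilon_{gj}$, $\varepsilon_{gj} \sim N(0, \sigma_g^2)$, with
  $\mu_g \sim N(7, 1)$ (log2-intensity scale), $\Delta_g = \pm 2$ for 50
  planted genes (signs drawn per gene), $\sigma_g = 0.5$. Cohorts default
  to 16 case / 13 control ("rectal-like"); the study-level generator adds
  a 19 / 9 "bronchial-like" tissue. A heteroscedastic option draws
  $\sigma_g$ log-uniformly in a range so variance shrinkage is genuinely
  exercised; the default is homoscedastic, under which the estimated
  $d_0$ is correctly near-infinite. Values are emitted already normalised:
  probe-level artifacts, batch effects and platform normalisation are
  deliberately not emulated, so passing tests say nothing about
  preprocessing robustness on real arrays.
* **Interactions** — preferential attachment from a complete graph on
  $m+1 = 3$ nodes, each new node attaching $m = 2$ edges with probability
  proportional to degree, to 200 nodes (edge count therefore exactly
  $3 + 2 \cdot 197 = 397$ before extras); heavy-tailed degrees like a real
  interactome, but none of its clustering, modularity or annotation bias.
  The planted hub is the highest-degree node of the grown graph and
  receives 30 extra edges to distinct non-neighbours, which guarantees
  strict degree dominance by construction (every other node gains at most
  one edge). Scores are Beta(2, 1), leaving ≈ 16% of edges below the 0.4
  confidence filter so the filter has work to do. Node ids are drawn from
  the shared gene universe so expression/network/annotation joins are
  non-trivially non-empty — one id space, as in a real gene-symbol
  analysis.
* **Annotations** — 50 terms with sizes uniform in [10, 40]; the planted
  term holds 30 genes from the planted DEG list plus random non-planted
  fillers.
* **Study level** (`simulate_study`) — the two tissues share exactly
  `n_shared_planted = 10` planted DEGs with consistent signs; one
  interaction table and one annotation set serve both tissues. The planted
  DEGs are assigned to the network's highest-degree nodes, and the planted
  term's core to the most-connected planted genes: the generator emulates
  the coupling between network centrality and functional coherence of a
  disease module — the very signal the HBS-then-enrich strategy is built
  to detect. A pipeline that computes centralities or the hypergeometric
  tail incorrectly will not recover the planted term at the strict tier.

**What the defaults imply.** At $|\Delta| = 2$, $\sigma = 0.5$, 16 vs 13,
the standardised effect is ≈ 10, so the DEG caller's sensitivity is
essentially 1 and its false-discovery proportion well under 0.10; under a
null generator (no planted genes) the mean called fraction is far below
5%. These are the operating characteristics the acceptance script
recomputes.

**A known property of shared-universe designs.** Genes planted in only one
tissue are strong true positives there and ordinary nulls in the other;
with ~80 such genes and a BH threshold lifted by ~100 true signals, one of
them occasionally (roughly a fifth of seeds) crosses both gates in the
other tissue, adding a spurious shared DEG. The tests therefore assert
what the design can guarantee: all shared planted genes are recovered in
≥ 90% of seeds and spurious shared calls average ≤ 1 per study — not that
the shared count equals the planted count exactly in every run.

## 7. Problem sizes and runtime posture

The shipped demo and the test suite run two 1000-gene tissues, 200-node
networks, and 50-term annotation sets; oracle suites use 200 random graphs
of ≤ 8 nodes, 10 seeds for operating characteristics and 20 for null
calibration and hub recovery. These sizes were chosen so the whole suite
completes in well under a minute on a single core while every check still
has statistical teeth; all of them scale up linearly through
`synthetic_config()` if heavier validation is wanted.

## 8. Limitations

* Two-group comparison only: no covariates, paired designs, contrasts or
  array weights.
* The network protocol reproduces a query discipline (confidence filter,
  shell caps, re-seeding, merge), not any specific interaction database's
  content, score calibration or homology transfer.
* Flat gene sets; no GO-DAG semantics.
* Centralities are unweighted; confidence acts only through the build-time
  filter.
* The synthetic generators validate pipeline logic, not biology: effect
  sizes are homogeneous, noise is Gaussian, and network topology is pure
  preferential attachment.
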