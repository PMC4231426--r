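---
title: "Inferring regulatory networks from knockout screens: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory networks from knockout screens: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtr)
```

This vignette documents the statistical model behind `pgtr`, the parameters
that matter, and the design decisions taken where more than one reasonable
implementation exists. The README shows the quick path; here we explain why
the pieces look the way they do.

## The inference model

The input is a complete (or partial) single-knockout screen: steady-state
expression of $n$ genes in the wild type and after each single deletion.
The inference proceeds in three stages.

### Candidate edges

Two statistics score a potential edge $i \to j$:

* the **deviation z-score** $z_{ij} = (G^{ko}_{ij} - \mu_j)/\sigma_j$, where
  $\mu_j$ and $\sigma_j$ summarize *all* measurements of gene $j$ — the $n$
  knockout values (including the self-knockout) plus the wild type. A large
  $|z_{ij}|$ says deleting $i$ moved $j$ far outside its typical range.
* the **conditional correlation** $c_{ij}$: the Pearson correlation of the
  measurement columns of $i$ and $j$ across experiments, excluding the
  experiment that knocks out $j$ itself (that value reflects the
  intervention, not regulation). Excluding the $i$-knockout as well is
  available as an option (`exclusion = "drop_i_and_j"`); the default drops
  only $j$, which retains one more observation per pair and is the
  conditioning we consider best aligned with the causal question "does $j$
  track $i$ when neither is clamped to zero through $j$".

The combined graph (`build_pg_new`) requires $|z| > \beta$, $|c| > \gamma$
and $c \cdot z < 0$. The sign rule encodes the physics of a deletion:
removing an activator of $j$ lowers $j$ (negative $z$) while the two genes
co-vary positively across the compendium (positive $c$). Edges violating the
rule are most often noise artefacts. Consequently edges inherit their sign
from the z-score alone: $z < 0 \Rightarrow$ activation, $z > 0 \Rightarrow$
repression.

The per-target standardization $Z^c_{\cdot j} = (|c_{\cdot j}| -
\text{mean})/\text{sd}$ asks whether a particular regulator correlates with
$j$ unusually strongly *relative to the other candidate regulators of $j$*;
genes differ widely in how "correlatable" they are, so a global
standardization would conflate targets. The subsequent positivity shift is a
single global offset chosen so the minimum off-diagonal entry equals
$\varepsilon = 10^{-6}$: the local-reduction weight rule multiplies two
$Z^c$ values, so all entries must be strictly positive, and a single global
shift (rather than per-column shifts) preserves the cross-column ordering.

Ranking weights $W^r = \text{minmax}(|Z| + Z^c)$ are normalized globally
over all ordered pairs. A per-gene normalization would equalize hub and
leaf targets and discard exactly the between-target information the ranking
needs.

### Transitive reduction

Perturbation effects propagate: if $i$ regulates $k$ and $k$ regulates $j$,
the screen shows an $i \to j$ edge too. An edge is *explainable* when an
alternative path could have produced the observed effect:

* **TRANSWESD** accepts a simple path with matching overall sign, at most
  $L$ edges, and bottleneck weight $w_{max}(P) < \alpha\, w_{ij}$ (strict,
  so with $\alpha < 1$ the explanation is built entirely from more-confident
  edges).
* **LTR** accepts only feed-forward loops $i \to k \to j$ with consistent
  signs and $\alpha Z^c_{ij} \le Z^c_{ik} Z^c_{kj}$ (non-strict). Here
  *large* $Z^c$ is high confidence, so candidates are processed in
  ascending $Z^c_{ij}$ — lowest-confidence edge first.
* **DR-FFL** removes any edge crossing strongly-connected-component
  boundaries that has an unsigned alternative path; it is retained as the
  historical baseline and inherits its known weakness (no reduction inside
  cycles).

Removal is iterative with an explainability re-check: before an edge is
deleted, every edge of the original graph must stay present or explainable
in the remaining graph; otherwise the candidate is kept
(`kept_explainable` in the result). With `full_check = FALSE` all decisions
are frozen against the original graph — much cheaper, occasionally wrong,
matching its intended use on large cyclic graphs.

**The LTR re-check uses paths of any length.** The 2-path rule decides
*candidacy*; the re-check instead verifies that every observed effect stays
*represented* by a sign-consistent directed path in the remaining graph. If
the re-check also insisted on 2-paths, a fully pruned graph could never
represent indirect effects whose shortest true path has three or more steps
— pruning one branch of a long cascade would always be blocked, and an
idealized noise-free screen (the transitive closure of the true network)
could never be reduced back to the truth. With the any-length re-check both
TRANSWESD and LTR reduce such closures exactly (the closure-recovery test
in the suite runs 200 random 30-node cases at 100% recovery). For the same
reason the removable set is computed once on the original graph and not
re-screened against the shrinking graph during iteration.

The closure-recovery study itself makes two choices worth stating. First,
ground-truth DAGs are transitively reduced before building the closure: a
true edge running parallel to an equally-signed true path is
indistinguishable from an indirect effect by any weight scheme that gives
all true edges similar confidence, so recovery is only well posed for
irreducible truths. Second, edge signs derive from node potentials
($s_{uv} = \phi_u \phi_v$), which makes every path between a pair carry the
same sign — the closure then has well-defined edge signs, and negative
feed-forward loops are absent by construction (which is also the regime
where signed and unsigned reduction provably coincide; the suite asserts
that equality).

### Ranking and evaluation

All $n(n-1)$ ordered pairs are ranked by $W^r$ plus a tier offset (+2 per
tier): surviving edges first, optionally edges removed during reduction as a
middle tier (`three_tier`), then everything else. Only the ordering matters;
the offset merely implements "an edge of the final graph always outranks a
non-edge". Ties are broken lexicographically by (source, target), making
every ranking a deterministic permutation.

AUPR integrates the precision–recall curve trapezoidally over a sweep of the
full ranking, anchored at (recall 0, precision 1); AUROC is computed as the
Mann–Whitney statistic. Note that challenge-specific evaluators interpolate
PR curves slightly differently; discrepancies up to about $10^{-3}$ in AUPR
are expected when cross-checking against such tools. Silver-standard scoring
restricts both lists to common nodes: predictions touching genes unknown to
the standard are not scored, and standard edges touching unmeasured genes
are dropped.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $\beta$ | z-score threshold (dimensionless) | 2.0 | two standard deviations; benchmark setting across all analyses |
| $\gamma$ | correlation (or deviation) threshold | 0.05 | small but non-zero; robust across the noise grid |
| $\alpha$ (TRANSWESD, $L=\infty$) | confidence factor | 0.95 | just below 1: explanations must be more confident than the edge |
| $\alpha$ (TRANSWESD, $L=2$) | confidence factor | 1.5 | the local variant operates in a different range |
| $\alpha$ (LTR) | multiplicative weight factor | 0.15 | benchmark setting |
| $L$ | maximum explaining-path length | $\infty$ (2 for LTR) | LTR is local by definition |
| $\varepsilon$ | $Z^c$ positivity floor | $10^{-6}$ | minimal; only strict positivity matters |
| `tier_offset` | ranking tier separation | 2 | any value above the $[0,1]$ weight range works |

Unweighted TRANSWESD is the $\alpha = \infty$ limit; unweighted LTR the
$\alpha = 0$ limit (the weight condition is dropped).

## The synthetic benchmark

`generate_topology()` draws out-degrees from a discrete power law (exponent
2.5, capped at $n/10$) and in-degrees from a geometric distribution, both
adjusted to the target edge count $nK$, and pairs stubs with a 0.7
preference for the source's module ($\lceil\sqrt n/2\rceil$ modules). This
reproduces the qualitative degree structure of transcriptional networks —
a few master regulators with large regulons, most genes regulated by a few
factors — and a modular community structure.

`simulate_knockouts()` solves $x_j = b_j \prod_i r(x_i)$ by damped
fixed-point iteration (damping 0.5, absolute tolerance $10^{-9}$, max 500
sweeps; non-convergence is an error naming the experiment). The regulation
factor is a saturating Hill response normalized so that an unregulated gene
sits at its basal level $b_j = \theta^{syn}_j/\theta^{deg}_j$: for an
activator $r(x) = (1 + aH)/(1 + a/2)$ with $H = x^m/(x^m+1)$, inhibitors
take the reciprocal; $a = 1$, $m = 1$ by default. Knockouts clamp the gene
to exactly 0 (a residual-expression knockdown mode is a natural extension
but not modelled). Biological variability perturbs $\theta^{syn}$ and
$\theta^{deg}$ once per dataset ($\mathcal N(1, \sigma_\theta)$, truncated
at 0.1 so rates stay positive at $\sigma_\theta = 0.1$); measurement noise
multiplies every reported value by $e^\nu$, $\nu \sim \mathcal N(0,
\sigma_\nu)$. The noise grid crosses both standard deviations over
$\{0.025, 0.05, 0.1\}$, labels LL…HH.

What the simulator does *not* emulate: transcription/translation dynamics
and time courses, saturation regimes far from the normalized operating
point, compensatory rewiring after deletion, batch structure, and the
detailed kinetic laws of any particular published simulator. Passing tests
on this generator therefore demonstrate correctness of the inference
machinery and the *qualitative* noise response, not absolute performance
numbers on any external compendium. One consequence of the chosen kinetics
is strong attenuation along paths: two-step effects are roughly an order of
magnitude weaker than direct ones, so at low noise the perturbation graph
is already quite clean and transitive reduction has little left to prune;
at higher measurement noise the ranking degrades smoothly.

## Numerical and degenerate-input choices

* Thresholds $\beta$, $\gamma$ and the TRANSWESD weight rule are strict
  (`>`/`<`); the LTR weight rule is non-strict (`<=`), as defined.
* Zero-variance genes (z-scores) and zero-variance pairs (correlations)
  yield 0 with a recorded warning instead of an error: one dead gene should
  not abort a genome-scale screen.
* Constant $|c|$ columns standardize to 0 before the positivity shift.
* Min-max normalization of a constant matrix returns zeros.
* All iteration orders (removal, path search, ranking ties) are
  deterministic — lexicographic in gene identifiers after the relevant
  weight key — so identical inputs give identical outputs, including the
  removal log.
* The approximate path search is a label-correcting dynamic program over
  (node, sign-parity) states minimizing bottleneck weight over walks of at
  most $L$ edges (round-indexed, so the length cap is exact; $2n$ rounds
  stand in for $L=\infty$ since a bottleneck-optimal walk never needs to
  revisit a state). It is complete — it never misses a qualifying simple
  path — but may certify with a non-simple walk; the exact mode is a pruned
  depth-first enumeration of simple paths.

## Problem sizes in the test suite

The suite exercises: exhaustive path-search cross-checks on 500 random
graphs of up to 10 nodes; curve-area cross-checks against point-by-point
integration on rankings of up to 30 pairs (tolerance $10^{-12}$); 200
closure-recovery cases at $n = 30$; ten-replicate noise-trend suites at
$n = 100$, $K = 1.5$; and five 5000-node topology draws. These sizes keep
the full suite in the low minutes on a single core while leaving each claim
statistically meaningful.

## Known limitations

* Every node must be perturbed for full-network inference; with $m < n$
  perturbations, `infer_partial_network()` infers the $m \times m$
  sub-network and reports perturbed→unperturbed candidates unpruned
  (no paths exist among unperturbed targets, so reduction cannot help).
* The exact signed path search is exponential in the worst case; it is
  intended for $L = 2$, small graphs, and closure studies. Large cyclic
  graphs should use `path_exact = FALSE` (and usually
  `full_check = FALSE`).
* Knockdown (partial loss-of-function) designs, time series, and
  multifactorial perturbations are out of scope.
* AUPR comparisons across tools require matching PR interpolation
  conventions (see above).
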