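---
title: "Methods: probabilistic mapping of lymph node metastasis pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic mapping of lymph node metastasis pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnmpath)
```

## The model

The analysis treats the involvement status of 14 anatomical lymph node
zones as a vector of binary random variables per patient and asks three
questions: how involvement is distributed regionally, which zones are
conditionally dependent, and which directed connections are consistent
and plausible enough to read as candidate metastatic routes.

The dependency structure is a discrete Bayesian network: a DAG $G$ over
the zone variables together with a conditional probability table (CPT)
per node. Structure is learned by greedy hill-climbing over the
operators add / delete / reverse edge, scored by the BIC

$$\mathrm{score}(G) = \sum_j \widehat{\ell}_j \;-\; \frac{\log n}{2}
  \sum_j q_j (k_j - 1),$$

where $\widehat{\ell}_j$ is node $j$'s maximized multinomial
log-likelihood given its parents, $k_j$ its state count and $q_j$ the
number of parent configurations. Higher is better; the score decomposes
over nodes, so the search caches local terms by (node, parent set).
Parameters are maximum-likelihood CPT entries
$(\text{count} + \alpha)/(\text{total} + \alpha k)$ with pseudo-count
$\alpha = 0$ by default. Posterior queries are answered exactly by
variable elimination with a greedy min-degree ordering; a brute-force
joint enumeration (feasible at $2^{14}$ states) is retained purely as an
independent oracle in the tests.

Edge *confidence* comes from the nonparametric bootstrap: rows are
resampled with replacement $B$ times, the structure relearned each time,
and each directed edge's frequency of appearance recorded. Edge
*relevance* comes from co-occurrence: the fraction of patients with both
zones of a pair involved. A connection is highlighted as a
high-probability route only if it passes the dual criterion — bootstrap
strength $\geq \tau$ and co-occurrence in the top $q$ fraction of the 91
zone pairs — and additionally joins anatomically adjacent zones. Zones
are then labelled by their role in the highlighted graph (hub, terminal,
intermediate, isolated) and maximal simple directed chains are reported.

Interpretation is deliberately associational: edges are conditional
dependencies in observational data, not demonstrated transit routes, and
the direction assigned to an edge is partly a convention of the score
(see below).

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `tau` | 0.6 | bootstrap edge-strength threshold; the conventional "edge present in ≥60% of resamples" confidence cut |
| `q` | 0.3 | top co-occurrence quantile; 28 of the 91 zone pairs at the default |
| `bootstrap_B` | 200 | resampling depth; frequencies stabilise well below this (checked in the tests at B = 200 vs 400) |
| `alpha` | 0 | CPT pseudo-count; 0 is pure maximum likelihood, 1 gives Laplace smoothing when zero-probability evidence must be avoided |
| `hub_min` | 3 | minimum total degree for a "hub" label; connectivity-based hub labelling needs a numeric rule and 3 is the smallest degree that cannot occur on a simple chain |
| `max_indegree` | unlimited | parent cap for the search; mainly useful for the clinical-augmented network |
| `denominator_mode` | `lnm_patients` | co-occurrence denominator; the mapping cohort is conditioned on having any metastasis, so the LN-positive subset is the natural default, with the whole-cohort variant exposed for sensitivity analysis |
| cutoffs | CA125 264.5 U/mL, HE4 148.5/122.2 U/mL (post-/premenopausal), ascites 90 mL, tumor size 100 mm, age 50 y | dichotomization constants shipped as defaults; `youden_cutoff()` re-derives data-driven thresholds when wanted |

## The synthetic generator

Real patient-level data for this analysis are not publicly deposited,
so validation runs on synthetic cohorts with known truth
(`sim_config()`, `generate_cohort()`):

* Zone involvement is sampled ancestrally from a configurable truth DAG
  in a fixed topological order (ties broken by zone id), so a seed fully
  determines the cohort. Planted routes use a leaky noisy-OR: with a
  single parent, $P(\text{child}=1\mid\text{parent}=1)$ equals the route
  strength and the off-route baseline is 0.05.
* Clinical covariates (age, menopause, parity, CA125, HE4, ascites,
  tumor size, grade, subtype, laterality, NACT) are drawn marginally
  independent, with marginal shapes chosen to resemble a plausible EOC
  surgical cohort (e.g. median tumor size ≈ 90 mm, ~19% NACT, the
  published left/right/bilateral mixture 38:50:122). They become
  dependent on zones only through explicitly planted log-odds effects.
  No joint covariate distribution is claimed.
* Resected-node counts are negative binomial per zone (para-aortic
  stations largest), forced to ≥1 in involved zones; positive counts are
  1 plus a binomial thinning of the remainder, which guarantees the
  record invariants (positive ≤ resected; involvement ⇔ ≥1 positive
  node).
* FIGO stage is assigned after zone sampling: any involvement implies
  III–IV; node-negative patients are III–IV with probability 0.36. This
  preserves the structural zero (stage I–II is node-negative by
  definition) that also dominates the published stage odds ratio.

What the generator does **not** emulate: correlated covariates,
laterality-specific zone preferences unless planted, measurement error
in node counts, or institution-specific dissection practice. Passing
tests therefore demonstrate that the machinery recovers known structure
under the stated conditions — not that real cohorts satisfy those
conditions.

## Numerical and design choices

**Deterministic tie-breaking and edge orientation.** BIC is
score-equivalent: Markov-equivalent DAGs (e.g. the chain
$3\to5\to1$ and its reversals) receive identical scores, so the
orientation of the first edge added within an equivalence class is a
pure tie. The search breaks ties deterministically — operator order add
< delete < reverse, then lexicographically by (parent, child); the
zero-padded zone names make this "smallest zone id first". Score
comparisons use a $10^{-9}$ tolerance so floating-point-equal
alternatives resolve by that order. Consequently, *which* pair enters
the model first is decided by the data (the empirically strongest
dependence), while the orientation of that tie is decided by the rule.
The reference simulation (`reference_sim_config()`) therefore plants the
chain with asymmetric strengths (entry edge 3→5 at 0.95 from a 0.65
head, continuation 5→1 at 0.75): the search then reliably enters the
chain at its head, and once 3→5 is present, 5→1 wins over 1→5 on the
score itself (the v-structure alternative costs more parameters). This
was fixed as part of the study design, verified by simulation when the
defaults were chosen, and not revisited.

**Directed vs undirected bootstrap counting.** Published network
figures draw directed edges, but whether an edge "appearing" in a
bootstrap iteration ignores orientation is ambiguous. Both conventions
are computed; the selection threshold applies to the directed frequency
and the undirected frequency is reported alongside (it always dominates
both orientations).

**Anatomical adjacency.** "Anatomically distant" is not given a formal
definition in the source analysis, so the atlas ships an explicit,
editable pair list: per-side iliac chains, iliac-to-obturator drainage,
obturator→inguinal and obturator→presacral spread, common
iliac→para-aortic and →presacral continuation, the six contralateral
pairs, and common iliac / para-aortic connections to the distant
compartment. The default list contains every connection the analysis
treats as a plausible route and excludes leaps such as external
iliac→inguinal or internal iliac→contralateral para-aortic.

**Degenerate inputs.** Zero cells in a 2×2 table are an error unless
the Haldane–Anscombe correction is requested, in which case the result
is flagged — the published FIGO odds ratio (519.75) arises from exactly
such a structural zero and is deliberately not reproduced as an
uncorrected number. Chi-square is Pearson without Yates correction (a
flag exposes the corrected variant); the stepwise entry criterion is the
likelihood-ratio test, entry-only. Unseen parent configurations at
$\alpha=0$ yield uniform CPT rows and are flagged. Inconsistent
evidence ($P(\text{evidence})=0$) is an error in `posterior_query()` and
a flagged row in `conditional_probability_report()`. Highlighted edge
sets aggregated across bootstrap networks can in principle contain a
directed cycle; `chain_report()` breaks cycles by dropping the
lowest-frequency edge with a message. Separation in logistic fits is
detected by diverging coefficients (|β| > 15) and flagged rather than
treated as non-convergence; binary candidates with separation fall back
to a corrected 2×2 test inside the stepwise loop.

**Study sizes.** The validation studies use: 20 random 4-variable
datasets of n = 300 against the 543-DAG exhaustive oracle; 50 random
networks of 3–6 nodes for inference-vs-enumeration; 10 seeds of n = 2000
for skeleton-F1 recovery of a six-edge planted network (strength 0.85
over baseline 0.05); n = 2000 for recovery of a planted conditional
probability of 0.875; and 10 seeds of 300 LN-positive patients with
B = 100 for end-to-end pathway recovery at the default
$\tau = 0.6, q = 0.3$. These sizes were chosen to keep each study's
Monte-Carlo error comfortably inside the acceptance margins.

## Known limitations

* Edge directions within a Markov-equivalence class are conventions of
  the tie-break, not biological findings; only the skeleton and the
  conditional-independence structure are identified by the data.
* The co-occurrence criterion is marginal and can admit pairs whose
  association is fully mediated by a third zone; the dual criterion
  mitigates but does not eliminate this.
* Conditioning the network cohort on "any involvement" induces weak
  negative dependence among zones; with moderate n the search can pick
  up low-confidence artefactual edges, which is precisely why the
  pathway rule demands high bootstrap frequency, top-quantile
  co-occurrence and anatomical plausibility simultaneously.
* The generator's marginally independent covariates make the
  clinical-augmented network easier than real data, where confounding
  among covariates is the norm.
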