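# lnmpath

Probabilistic mapping of lymph node metastasis (LNM) pathways in
epithelial ovarian cancer (EOC).

## The problem

Whether and where EOC spreads to regional lymph nodes drives staging
(FIGO I–II vs III–IV), surgical radicality and adjuvant treatment, yet
systematic pelvic and para-aortic lymphadenectomy carries real morbidity
and uncertain survival benefit. A risk-adapted strategy needs more than
per-station involvement rates: it needs the *joint* structure of nodal
involvement — which stations co-metastasize, which act as hubs, and along
which chains disease plausibly travels.

`lnmpath` implements that analysis for cohorts in which resected nodes
are classified into 14 anatomical zones (left/right common iliac 1–2,
external iliac 3–4, internal iliac 5–6, obturator 7–8, superficial
inguinal 9–10, para-aortic 11–12, presacral 13, distant 14):

* **Cohort statistics** — Youden-index dichotomization of continuous
  markers (CA125, HE4, ascites volume, tumor size, age), 2×2 odds ratios
  with Woolf log-normal intervals
  (`CI = exp(log OR ± 1.96·√(Σ 1/nᵢⱼ))`), Haldane–Anscombe handling of
  structural zeros, chi-square and Mann–Whitney tests, and logistic
  regression with forward stepwise (likelihood-ratio) selection.
* **Regional mapping** — node-level shares (positive nodes in a zone /
  all positive nodes), patient-level shares (patients with the zone
  involved / LN-positive patients), overall nodal positivity, per-zone
  resection summaries, laterality stratification.
* **Discrete Bayesian network engine** — hill-climbing structure search
  over DAGs scored by BIC
  (`score = Σⱼ log L̂ⱼ − (log n)/2 · Σⱼ qⱼ(kⱼ−1)`), maximum-likelihood
  CPTs with optional Laplace smoothing, exact inference by variable
  elimination, and exhaustive small-DAG enumeration as a built-in test
  oracle (1, 3, 25, 543 DAGs on 1–4 nodes).
* **Bootstrap edge confidence and co-occurrence** — the fraction of
  bootstrap-resampled structure-learning runs in which each directed edge
  appears, and the fraction of patients with both zones of a pair
  involved.
* **Pathway extraction** — a directed connection is a high-probability
  metastatic route when its bootstrap edge strength is ≥ 0.6 **and** its
  pair ranks in the top 30% of co-occurrence **and** the zones are
  anatomically adjacent; zones are then labelled hub / terminal /
  intermediate / isolated and maximal route chains reported.
* **Synthetic cohorts** — a generator with a known truth DAG, planted
  pathway strengths, covariate effects and resection-count models, so
  every stage is validated against ground truth.

Because the underlying clinical cohort is not publicly deposited, the
package ships the published summary tables it needs as plain-text inputs
and runs everything else on synthetic cohorts with known truth.

## Worked example

```r
library(lnmpath)

# a 654-patient synthetic cohort with planted routes 3->5->1 and 11->12
cfg    <- reference_sim_config(654, seed = 20260101)
cohort <- generate_cohort(cfg)

lnm   <- cohort[cohort$nact == 0 & lnm_positive(cohort), ]
zones <- lnm[, zone_names()]

edges <- bootstrap_edge_strength(zones, B = 200, seed = 1)
top   <- top_quantile_pairs(cooccurrence_matrix(lnm), q = 0.3)
paths <- extract_routes(edges, top, tau = 0.6)
paths$highlighted
#>  parent child directed_freq cooccurrence
#>       3     5          1.00         0.66
#>       5     1          1.00         0.50
#>      11    12          0.99         0.53
chain_report(paths)
#> 3 -> 5 -> 1   and   11 -> 12
```

Both planted routes — and nothing anatomically implausible — are
recovered: the left external → internal → common iliac chain and the
para-aortic pair, each present in ≥ 99% of bootstrap networks, with
co-occurrence in the top 30% of the 91 zone pairs. The published
lateralization odds ratio recomputes from its 2×2 counts as

```r
odds_ratio_2x2(table2x2(254, 110, 109, 181))
#> OR 3.83, 95% CI 2.77–5.31
```

The numbered scripts under `analysis/` run the same workflow end to end
(simulation → statistics → mapping → networks → clinical augmentation),
printing what each stage found and writing its tables under `results/`.

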