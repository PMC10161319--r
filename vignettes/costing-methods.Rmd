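---
title: "Costing risk-stratified breast screening: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing risk-stratified breast screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratcost)
```

## The costing problem

When a national breast screening programme considers stratifying screening
intensity by each woman's predicted cancer risk, the risk prediction itself
has a delivery cost: invitations must be mailed, questionnaires processed,
mammographic density measured, saliva samples genotyped, risk letters
generated and higher-risk women seen in consultation. `stratcost`
implements a bottom-up (micro-costing) model of that delivery pathway at a
woman's first screen, for three nested strategies:

* **TC** — a self-completed risk questionnaire (Tyrer-Cuzick style) alone;
* **TC_VBD** — adding an automated volumetric breast-density measurement;
* **TC_VBD_SNP** — further adding a 142-SNP polygenic test on a saliva
  sample, genotyped on array chips in batches.

Each strategy is costed in two delivery settings: as run inside a research
trial (with the implementation issues actually observed: failed image
transfers, manual density reads, aerial installation on mobile vans,
consultant-led consultations, manual administrative steps) and as it would
be run routinely in the health service (those issues resolved; nurse-led
consultations; automated letter generation; the study-specific invitation
mailing absorbed into the existing screening invitation).

## The expected-cost model

The pathway is a decision tree. Internal nodes are chance nodes whose
branches carry probability parameters (a `"~"` branch receives the residual
probability); leaves are activities, i.e. bundles of resource items. A
resource item is a quantity (minutes, sheets, stamps, measurements) priced
at a unit cost, all in 2021 GBP. For a strategy $s$ and setting $d$, the
expected per-woman cost is

$$E[C_{sd}] \;=\; \sum_{a \in \mathcal{A}_{sd}} \Pr(a \text{ fires}) \cdot c_a,$$

computed by recursive descent and accumulated over seven pathway stages
(invitation, questionnaire, density, density implementation, SNP, risk
letter, consultation). Because the model is multilinear in its parameters
— each outcome path's probability is a product of independent branch
probabilities and its cost a sum of item costs — an exhaustive enumeration
of root-to-leaf outcomes (`enumerate_outcomes()`) provides an exact
independent oracle, and the probabilistic sensitivity analysis can be
vectorised over the same path decomposition.

Chance nodes are treated as mutually independent (survey mode, follow-up,
image-transfer failure, risk category, appointment uptake). Risk-category
probabilities are strategy-specific: adding density and genotype
information moves more women into the high-risk band (1.47% under the
questionnaire alone, 5% with density, 7.4% with density and SNPs), which is
why the consultation stage grows with strategy richness.

Monetary arithmetic is kept in full double precision; rounding to 2
decimal places (money) and 4 (probabilities) happens only in report
writers.

```{r grid}
model <- paper_model()
summary(model)
```

These are the totals the package computes from its packaged fixture. In
the trial setting the questionnaire-only strategy is dominated by the risk
letter (about 41% of cost), the invitation mailing (28%) and the
consultation stage (26%):

```{r shares}
round(stage_shares(predict(model, "TC", "trial")), 1)
```

## The packaged fixture and its provenance

The fixture (`inst/extdata/bcpredict/`, regenerable with
`make_paper_fixture()`) encodes the published parameter tables of the
micro-costing study this model re-implements: every unit cost, resource
quantity and branch probability is a published point value unless flagged
otherwise. Three kinds of flags matter:

* `printed_cost_gbp` — a published per-woman cost that overrides
  recomputation. Used once: the full-batch SNP staff cost (25.25 GBP,
  where 38.39 min at 41 GBP/h would give 26.23). The published aggregate
  is kept because the published strategy totals reconcile with it.
* `assumed` — the telephone follow-up of unclear paper surveys has a
  published branch probability (0.35 per paper survey) but no published
  cost row; the fixture assumes 5 minutes of administrator time. Its
  weight in any total is only $0.05 \times 0.35 \times 2.92 \approx 0.05$
  GBP.
* `reconstructed` — rows re-created from aggregates (the consumable
  schedule, all uncertainty distributions; see below).

Two readings deserve explanation because the published tables are not
fully self-consistent:

* **Saliva collection.** The published per-woman cost column shows 0.68
  GBP against 3.5 min of nurse time at 41 GBP/h (= 2.39 GBP; 0.68 would be
  one minute). The fixture costs collection from its resource use, because
  the published strategy totals only decompose correctly with 2.39: the
  genotyping strategy's trial total minus the density strategy's total
  leaves 79.37 GBP for the SNP stage, which equals 51.73 (consumables) +
  25.25 (staff) + 2.39 (collection) almost exactly.
* **Routine-NHS delivery.** The published routine-setting totals (4.68 /
  6.64 / 86.30) are far below what removing only the density
  implementation issues would give. Their own stage shares (risk letter
  58%, consultation 23% of the questionnaire strategy) imply that in
  routine delivery the separate invitation mailing disappears into the
  existing screening invitation, letter generation is automated (no 7.5-min
  manual retrieval), and the manual risk pack is not compiled. The
  packaged `nhs` setting profile therefore excludes those items and swaps
  consultant-led for nurse-led consultations. All six strategy-by-setting
  totals then land within 1.20 GBP of the published grid.

## Genotyping batch costs

The SNP test's per-sample cost depends strongly on batch size. The model:

* an array chip costs 1,343.77 GBP and holds 48 samples; every batch
  carries one non-payable control that occupies a slot, so the optimum is
  95 payable samples + 1 control on two chips, and a 48th payable sample
  forces a second chip;
* staff time is `fixed + variable x slots`, calibrated exactly to the two
  published anchors (2,165 min for a single-sample batch; 38.39 min per
  slot at the full batch), giving 2,132.65 fixed minutes and 16.17 min per
  slot at 41 GBP/h;
* consumables are bought in whole boxes. The box-level detail is not
  published; the fixture reconstructs it as a 48-sample reagent kit
  (400 GBP per box, aligned with chip boundaries) plus a 4-sample
  preparation box (59.45 GBP), calibrated once so the full-batch per-sample
  chips-plus-consumables share equals the published 51.73 GBP. The
  48-aligned kit is what makes batches of 48-71 dearer per sample than a
  batch of 47, as the published scenario analysis describes; a purely
  linear consumable model cannot produce that shape.

```{r batch}
sched <- paper_batch_schedule()
curve <- batch_curve(sched)
curve[c(1, 47, 48, 71, 72, 95), ]
```

The curve reproduces the published qualitative shape exactly (upward jump
at 48, dearer than batch-47 through 71, below 100 GBP per sample from 72,
global minimum at 95) and the full-batch strategy cost within a pound.
One published figure is not reproducible from the published inputs: the
single-test strategy cost of 2,731.98 GBP is lower than one chip plus the
published 2,165 staff minutes at the published 41 GBP/h rate alone
(2,823.19 GBP) before any consumables or pathway cost, so any faithful
reconstruction must exceed it; ours gives 3,291 GBP because a single test
still purchases one reagent-kit box. We keep the published staff-time and
rate inputs rather than distorting them to force the printed endpoint.

## Uncertainty analysis

**Probabilistic (PSA).** Distributions are attached to parameters and the
model re-evaluated under 10,000 Monte Carlo draws (the published analysis
found that count sufficient for stability; our convergence checker
confirms it on this model). The distribution families are reconstructed,
since only the elicited ranges are published: moment-matched beta
distributions at an effective sample size of 100 for all probabilities;
uniform distributions over the elicited range for interview-derived
durations (each range's midpoint equals the point value, e.g. data entry
12.5-30 min around 21.25); point masses for tariff-like unit costs, the
chip and the consumable aggregate. Each parameter draws from its own
seeded sub-stream, so adding a parameter to the specification never
perturbs existing draws, and identical seeds give bit-identical results.
Pseudo confidence intervals are the empirical 2.5th/97.5th centiles with
type-7 quantiles (linear interpolation between order statistics) — stated
because centile conventions differ.

Because every parameter enters the expected cost multilinearly and the
reconstructed distributions are centred on the point values, PSA means
track the deterministic totals; the trial-setting means fall inside the
published pseudo-intervals. The published routine-setting PSA means sit
1-2.4 GBP *above* the same study's deterministic routine totals, which
implies right-skewed routine-setting distributions whose form is not
published; our reconstruction does not attempt to replicate that skew, and
the routine-setting comparison is reported rather than asserted.

**Deterministic (DSA).** The published informant-level analysis re-costed
the pathway once per interviewed clinical trials assistant. The
per-informant input sets are not published, so `run_dsa()` is exercised on
synthetic informants (`perturb_resource_use()`): multiplicative,
mean-corrected log-normal noise on every duration and count, the natural
family for positive, right-skewed elicited durations. Linearity of the
evaluator guarantees that overriding one item's quantity moves the total
by exactly the item's probability-weighted cost change, which the tests
assert.

## National rollout

About 240,000 women attend a first screen each year in the English
programme. `annual_programme_cost(n, uptake, cost)` scales a per-woman
cost (full uptake is the default assumption, kept as an explicit
parameter); the *value of perfect implementation* is the annual cost
difference between the strategy as delivered with trial implementation
issues and as ideally delivered, and the value of *actual* implementation
scales it by the fraction of barriers an initiative removes (a linear
model; the concept is published without a formula). With the published
per-woman costs of the density strategy (6.64 vs 21.82 GBP) the programme
costs 1.6M vs 5.2M GBP per year, so perfect implementation is worth up to
3.6M GBP per year — rounding to 0.1M GBP is presentation only.

## Synthetic models and what the tests show

`generate_random_model()` builds seeded random chance-node trees (symmetric
Dirichlet branch probabilities, uniform activity costs, configurable depth
and branching) and returns the analytic expected cost accumulated during
construction, independently of the evaluator. The test suite checks
evaluator-vs-enumeration and evaluator-vs-construction agreement to 1e-9
relative tolerance on hundreds of such models. These generators emulate
the *structure* the analysis assumes — finite independent chance nodes,
costs linear in quantities — not real elicitation data: passing tests show
the machinery is exact for this model class, not that the elicited inputs
themselves are accurate, which interview-based micro-costing cannot
guarantee (stated as a limitation in the original elicitation too).

Problem sizes used throughout the suite are the study's own: the full
fixture (24 items, 12 probabilities), 10,000 Monte Carlo iterations, the
complete 1-95 batch range, and 200 random models for the oracle property.

## Numerical conventions and edge cases

* Comparisons on money use an absolute tolerance of 0.005 GBP in tests;
  internal arithmetic is unrounded double precision.
* A chance node with no `"~"` branch must have direct probabilities
  summing to 1 within 1e-9; the residual of a `"~"` branch is clamped at
  zero (never triggered by the fixture's distributions, whose
  high+moderate risk draws stay far below 1).
* Degenerate inputs are first-class: zero quantities cost zero; a
  zero-total breakdown has no stage shares (error); empty PSA samples are
  rejected; batch sizes outside [1, 95] are rejected.
* `convergence_check()` flags a checkpoint as converged when the running
  mean moved at most 0.10 GBP (default) since the previous checkpoint; the
  first checkpoint is judged against its own half-prefix.

## Known limitations

* No health outcomes, QALYs or cost-effectiveness ratios: this is a
  costing engine, intended to feed such evaluations.
* The consumable box structure and the uncertainty-distribution families
  are reconstructions calibrated to published aggregates; quantities that
  depend on their fine structure (the single-test cost, exact crossover
  batch sizes, routine-setting PSA skew) carry that reconstruction
  uncertainty and are flagged wherever reported.
* The published single-test figure cannot be matched by any parameter
  choice consistent with the other published inputs (see above); the
  package reports the faithful value instead.
* Currency is GBP at 2021 prices throughout; `inflate()` supports
  re-basing but no currency conversion.
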