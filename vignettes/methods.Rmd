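---
title: "Disproportionality methods for FAERS adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods for FAERS adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersdispro)
```

## The statistical problem

Spontaneous-report databases such as FAERS have no denominator: they
record who reported an adverse event, not who took a drug. Signal
detection therefore works on *reporting disproportionality* — whether a
drug–event pair is reported more often than the rest of the database
would predict. For drug query $D$ and event query $E$ the deduplicated
case reports are cross-classified as $A$ (both), $B$ (drug only), $C$
(event only), $D$ (neither), and the crude reporting odds ratio is

$$\mathrm{ROR} = \frac{A/B}{C/D},\qquad
  \mathrm{se}(\ln\mathrm{ROR}) = \sqrt{\tfrac1A+\tfrac1B+\tfrac1C+\tfrac1D},$$

with the Woolf log-scale 95% interval
$\exp(\ln\mathrm{ROR} \pm 1.959964\,\mathrm{se})$ and a Wald chi-square
p-value from $(\ln\mathrm{ROR}/\mathrm{se})^2$ on 1 df. The ROR is a
reporting measure, not an incidence measure: it controls for overall
reporting volume differences between drugs, but inherits every reporting
bias in the database.

The comparison background is deliberately the **entire** analyzable
database, not the other study drugs, so each drug's estimate is
interpretable on its own and adding a drug to the study set does not
move the others' estimates.

### Covariate adjustment

Because age and sex affect both what is prescribed and what is reported,
crude RORs confound drug effects with demographic reporting patterns. The
adjusted ROR is $\exp(\beta_{\text{drug}})$ from the binomial logistic
model

$$\operatorname{logit} P(\text{event}) =
  \beta_0 + \beta_{\text{drug}}\,\text{drug} +
  \beta_{\text{sex}} I(\text{F}) + \beta_{\text{age}} I(\ge 65).$$

`cell_logit()` fits this by Newton iteration (iteratively reweighted
least squares) on counts collapsed over the observed covariate patterns,
which is likelihood-identical to a one-row-per-report fit — the test
suite asserts agreement to $10^{-6}$ on random data, and agreement with
both `stats::glm` and a brute-force quasi-Newton maximizer of an
independently coded likelihood. Convergence requires the score max-norm
below $10^{-8}$ or a relative log-likelihood change below $10^{-10}$,
within 100 iterations; standard errors come from the inverse observed
information (equal to Fisher information at the logit link). With an
empty covariate set the model is the saturated $2\times2$ logistic, so
estimate, standard error and Wald p reproduce the crude ROR *exactly* —
a useful internal consistency check that also holds in the code.

The adjustment scheme follows the stratified design: the overall grid
adjusts for sex and age band; age-stratum estimates (under-65 / 65-plus)
adjust for sex; sex-stratum estimates adjust for age band.

### Signals, stratum contrasts and multiplicity

A pair is flagged as a risk signal when aROR $\ge 2$, p $< 0.05$ and at
least 3 cases report both drug and event. The ROR and case thresholds
are inclusive, the p threshold exclusive. By default the p entering the
criterion is Holm-corrected within its *analysis surface* — the overall
drug-by-event grid is one family, the age contrasts another, the sex
contrasts a third — counting only estimable tests in the family size.
The heat-map style matrices blank a cell when the aROR falls below 2
and/or the corrected p is at or above 0.05 (`signal_p = "raw"` switches
to uncorrected Wald p for the flag itself).

Stratum aRORs are compared with the standard two-independent-estimates
contrast on the log scale,
$z = (\ln\mathrm{ROR}_a - \ln\mathrm{ROR}_b)/\sqrt{se_a^2+se_b^2}$, with
a two-sided normal p. Holm correction uses `stats::p.adjust`; the
step-down rule multiplies the $i$-th smallest p by $(m-i+1)$ and
enforces a running maximum capped at 1, so e.g.
$[0.04, 0.01, 0.03] \to [0.06, 0.03, 0.06]$, and a capped smaller p
propagates: $[0.5, 0.9] \to [1, 1]$.

## Degenerate inputs and numerical choices

* **Zero cells**: a crude table with any zero cell is flagged *not
  estimable*. No Haldane/continuity correction is applied — the ≥3-case
  gate already removes zero-$A$ pairs from signal evaluation, and
  corrections bias the ROR.
* **Sparse strata**: stratum estimates with $A < 3$ are reported not
  estimable rather than silently dropped; the gate threshold is
  configurable (`min_cases`). The pooled-table gate governs drug
  inclusion, and the same threshold is re-applied per stratum.
* **Separation**: a covariate pattern that perfectly predicts the
  outcome drives $|\beta|\to\infty$; the fitter detects non-convergence
  (score fails to vanish, or $|\beta| > 30$, i.e. an odds ratio beyond
  $e^{30}$) and the result propagates as not estimable. A singular
  information matrix at the first step is a hard error.
* **Not-estimable results** are excluded from Holm families (they
  contribute neither a rejection nor to $m$) and make any stratum
  contrast involving them not estimable.
* **Step-halving** keeps the Newton iteration's likelihood
  non-decreasing, which stabilizes near-separated fits without changing
  converged answers.

## Ingestion rules

FAERS quarterly ASCII tables are `$`-delimited with a header line. The
parser targets the post-2012Q3 layout; older LAERS-era column names are
handled by a user-supplied JSON column map (`load_dialect()`), since the
historical harmonization is not standardized. Lines whose field count
does not match the header are skipped and counted.

* **Deduplication** keeps one record per `caseid`: highest
  `caseversion`, ties broken by latest `fda_dt`, then largest
  `primaryid` — the FDA's published recommendation. The operation is
  idempotent.
* **Age** is converted to years from the unit code: DEC ×10, YR ×1,
  MON ÷12, WK ÷52.1775, DY ÷365.25, HR ÷8766. Unknown units and negative
  ages become missing with a warning. The 65-year threshold is inclusive
  (65.0 is the older band). The week/day constants differ by under one
  part in $10^3$ from any alternative calendar convention and cannot move
  a plausible age across the 65-year boundary.
* **Eligibility**: only cases with harmonizable age and sex `F`/`M` are
  analyzable; FAERS codes `UNK`/`NS`/empty are missing. Every filter
  logs in/kept/dropped counts and the assembly asserts
  `n_in = n_kept + n_dropped`.
* **Counting unit** is the deduplicated case: a case counts once per
  event query however many of its PTs match, and once per drug query
  however many mentions match.

### Drug and event matching

Drug names are normalized (uppercase, whitespace collapsed, trailing
parentheticals stripped) and matched *exactly* against a synonym
dictionary; substring matching exists behind `match_mode = "substring"`
but is off by default to avoid combination-product false positives.
Event queries match a reaction by MedDRA PT code when the mention
carries one — a code/name disagreement is reported and the code wins —
falling back to case-insensitive name matching otherwise. The five
self-defined queries (sedation; weight gain; cognitive impairment;
SIADH/hyponatraemia; hyperprolactinaemia) ship with full PT name/code
sets; the 13 standard SMQs ship as name + SMQ-code placeholders because
MedDRA membership lists are licensed and must be supplied by the user.
Synonym dictionaries for the six antipsychotics are best-effort
(generic + major brands) and fully configurable; no claim is made that
they replicate any specific mapping service.

## The synthetic generator

`simulate_faers()` emulates exactly the structure the adjusted model
assumes: sex (55% female by default), an age band (25% aged 65+, age
uniform within 18–64 / 65–95), independent drug exposures whose
prevalence may differ by sex or age band (the confounding mechanism),
and each event drawn Bernoulli with

$$\operatorname{logit} p = \beta_0 + \textstyle\sum_j \beta_j x_j +
 \beta_s I(F) + \beta_a I(65+) + \text{interactions},$$

so every conditional odds ratio is known in closed form (`$truth`).
Defaults: background event rate 2%, drug prevalence 5%, 5% of cases
carrying a stale earlier version (removed again by deduplication), 1%
missing sex and 1% missing age, role codes drawn
PS/SS/C/I = 0.70/0.10/0.15/0.05, and ages re-encoded on write in mixed
units (85% YR, plus DEC/MON/WK/DY/HR) to exercise harmonization end to
end. Event-free reports receive a filler PT from a vocabulary disjoint
from every query term, and every report carries one background drug
mention, so the $C$ and $D$ cells are always populated. Output is fully
deterministic given the seed, to the byte, in the written files.

What the generator does **not** emulate: reporting-volume time trends,
drug co-prescription structure, LLT-level coding, notoriety effects
(except the optional `period_boost`, a crude date-redraw multiplier for
one pair, off by default), or correlated missingness. Tests passing on
synthetic data therefore validate the *arithmetic* of the pipeline — not
the epidemiological fitness of the ROR for any particular real-world
question.

## Validation design and problem sizes

The package validates itself at three levels, all run routinely:

1. **Closed forms**: hand-computable crude-ROR, CI, Holm and Z examples.
2. **Independent oracles**: the IRLS fit vs `stats::glm` and vs a
   brute-force BFGS maximizer of a separately coded likelihood (sampled
   small tables, agreement to $10^{-5}$); collapsed vs expanded data;
   covariate-free fit vs crude closed form on 1000 random tables.
3. **Simulation recovery**: with sex-confounded exposure and a planted
   odds ratio of 5 at 200,000 reports, the sex-adjusted estimate lands
   within 3 standard errors of truth while the crude estimate is
   detectably biased; a planted drug-age interaction of 2 is recovered
   by the stratum ratio, with the Z-test rejecting in well over 80% of
   replicate databases; under a global null the family-wise false-signal
   rate over replicate 20,000-report databases stays inside its binomial
   envelope around 0.05 (Holm makes it conservative in practice, since a
   false signal additionally needs aROR ≥ 2); crude-ROR CIs cover the
   null in ≈95% of replicates.

Simulation sizes (20k–200k reports, 15–100 replicates depending on the
check) were chosen so Monte-Carlo noise is small relative to each
assertion's margin while the whole suite stays comfortably
desk-runnable.

## Scope and limitations

* PT-level matching only: no MedDRA hierarchy traversal, no broad-scope
  SMQ logic, no LLT→PT mapping, no multi-ingredient decomposition.
* No shrinkage-based estimators (PRR, IC/BCPNN, EBGM) and no exact
  logistic regression; the Wald inference is asymptotic and the ≥3-case
  gate is the only small-sample guard.
* Reporting odds ratios quantify reporting, not risk: stimulated
  reporting (litigation, media), channeling and under-reporting all move
  them. The period-split analysis (`split_by_period`, receipt-date
  cutover) is the built-in tool for probing such artifacts.
* Case counts from any given FAERS vintage depend on the deduplication
  details and drug-name mapping used; with identical inputs the pipeline
  is deterministic, but bit-reproducibility against other tools is not
  guaranteed.
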