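---
title: "A lifetime cost-utility model of education and exercise therapy versus total knee replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime cost-utility model of education and exercise therapy versus total knee replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oacea)
```

## The decision problem

Clinical guidelines recommend exhausting nonsurgical care -- structured
education and exercise therapy in particular -- before total knee replacement
(TKR) is considered for knee osteoarthritis. `oacea` implements a
health-system-perspective cost-utility model of that choice at national
scale: a hypothetical cohort of adults aged 45--84 who would otherwise
undergo primary TKR in one year either receives TKR in the first year (usual
care) or enters a 12-week education and exercise program with the option of
TKR later. The model combines a life table with an annual-cycle semi-Markov
cohort model and reports discounted lifetime costs (2022 A$), QALYs, and the
incremental net monetary benefit

$$\mathrm{INMB} = \lambda\,\Delta E - \Delta C,$$

at a willingness-to-pay threshold $\lambda$ of A\$28,033 per QALY
(\$19,475 at the \$0.6947/A\$ conversion used throughout). Because the
program is expected to both save money and lose QALYs (the southwest
quadrant of the cost-effectiveness plane), the ICER is ill-defined as a
decision metric and the INMB carries the conclusion; `oa_run()` suppresses
the ICER whenever both increments are negative.

## Model structure

**States.** Three alive pain states defined by the EQ-5D-5L pain domain --
no or mild, moderate, severe or extreme -- plus absorbing death. The engine
expands these with surgical status: pre-surgical (in the program),
post-primary tunnel states indexed by years since surgery
$k = 1,\dots,k_{\max}$ ($k_{\max} = 20$), and post-revision states. Our
post-revision states also retain the years-since-primary clock: the
post-surgical excess-mortality ratio is keyed to intervals since the primary
procedure, and a single lumped "chronic revision" state would leave that
ratio undefined after revision. Revision is a one-time event (no
re-revision), and hazards beyond $k_{\max}$ are held at their year-$k_{\max}$
values, matching the horizon over which registries report cumulative
revision.

**Within-cycle event order.** Death first (probability
$q(\text{age},\text{sex})$ times the excess ratio for post-surgical states,
capped at 1 with a warning), then surgery among survivors. The ordering is a
modelling choice -- it avoids charging procedures to decedents -- and is
fixed and tested rather than left implicit. The usual-care arm is the same
operator with the conversion probability set to 1 in every cycle, so the
entire surviving cohort is operated on in cycle 1.

**Pain dynamics.** The post-operative pain transition (registry 6-month
outcome) is applied once at surgery; thereafter pain is static apart from
revision effects, because no further pain dynamics are reported. Likewise
the program's pain transition (program-registry 12-month outcome) is applied
once, in cycle 1, to non-converters. A participant who converts to surgery
in a later cycle receives the post-operative transition from their current
pain state at conversion. Program conversion probabilities (0.26 in year 1,
95% CI 0.14--0.38; 0.08 per year thereafter, CI 0.03--0.21) are applied
uniformly across pain states, ages and sexes, reflecting the stated
equal-effectiveness assumption and the absence of stratified data.

**Utilities.** Post-surgical persons carry the post-operative state
utilities. Program participants carry their baseline state utility plus a
transition-specific increment $\Delta u(\text{from} \to \text{to})$; the
incremental formulation compensates for the higher baseline quality of life
of program-registry participants relative to the surgical registry. Because
mortality and conversion do not depend on pain state among pre-surgical
participants, the cohort engine carries the mass-weighted mean utility per
current pain state; the individual-level microsimulation carries each
person's exact $(\text{from}, \text{to})$ pair, and the two agree in
expectation (this is tested). Increments are held constant over time -- the
alternative (decay) has no reported basis. Revision surgery incurs a 0.28
disutility in the cycle of the event, applied to the revision event count,
and a 0.10 decrement in all subsequent cycles via the post-revision state
utility (both with an assumed SE of 25% of the mean). Treating the 0.28 as
an event-cycle decrement is an interpretation of "the cycle prior to
revision": a cohort model cannot anticipate individual revisions, and
attaching the decrement to the revision-bound mass in the event cycle is the
closest well-defined equivalent; at a 5% discount rate the difference from
true one-cycle anticipation is below 5% of an already small term.

**Mortality.** All-cause annual death probabilities by single year of age
and sex, multiplied after surgery by interval-specific excess ratios (below
1 up to about 9 years after surgery, above 1 beyond 12 years). Pre-surgical
program participants carry unadjusted population mortality, since the
adjustment is framed as mortality *following* surgery. The maximum age is
100: anyone alive then dies at the end of that cycle, so horizons are finite
without truncating accrual elsewhere.

**Economics.** Annual discounting at 5% with cycle-1 flows undiscounted
(factor $(1+r)^{-(t-1)}$): both arms incur their intervention in year 1, and
the published account states the rate but not the convention, so we fix this
one and note that the headline identities are insensitive to it. QALYs and
continuous costs accrue on half-cycle corrected (trapezoid) occupancy; event
costs -- A\$24,607 per primary TKR (public 20,955 / private 25,435),
A\$43,125 per revision (public 43,233 / private 43,078), A\$1,500 for the
program -- attach to event counts, undiscounted within their cycle. The
program fee is one-off in cycle 1 for the whole program-arm cohort
regardless of later conversion. The weighted-mean costs are stored as
independent inputs rather than derived from the public/private split: the
published weighted means are not reproducible from the printed components
and any one case-mix weighting, and the printed values take precedence.

## The cohort

`build_cohort()` sizes the eligible population per stratum (4 age bands x 2
sexes) as population times the age- and sex-specific procedure rate, then
splits each stratum over baseline pain states. Persons are continuous
masses; integer rounding happens only at rendering, so partitions are exact
and order-independent. Stratum starting age is the band midpoint (lower
bound + 5), configurable in the bundle settings.

## The synthetic input bundle

The real stratified inputs derive from registry and government sources that
are not redistributable, so `generate_input_bundle()` creates structurally
faithful synthetic bundles. Everything the publication prints as a scalar
keeps its printed value (uptake probabilities, costs, disutilities, discount
rate, threshold, exchange rate); the stratified tables are synthesized once,
with these choices:

* **Population and incidence**: 2022 Australian population magnitudes per
  band and sex; procedure rates anchored so the band totals reproduce the
  printed subgroup sizes (3,943 / 16,567 / 26,240 / 14,644; 53.9% female),
  giving a national cohort of 61,394. Per-person rates rise steeply with age
  and are nearly flat from 65--74 to 75--84.
* **Baseline mix**: Dirichlet-distributed per stratum, parameterized by
  multinomial counts emulating the ~9,889 preoperative records behind the
  published proportions; males and younger bands skew toward no/mild pain.
* **Mortality**: Gompertz schedules
  $q(a) = 1 - \exp(-A e^{ba})$ with $b$ = 0.095 (female) / 0.090 (male) and
  $A$ calibrated so life expectancy at 65 is ~22 years (female) and ~19
  (male), plausible national magnitudes. Excess ratios 0.75 (years 1--4),
  0.90 (5--9), 1.00 (10--12), 1.20 (13+).
* **Transitions**: post-surgical rows concentrate in no/mild pain (modal
  destination in every stratum); program rows improve less on average.
  Rows are multinomial draws (n = 400 surgical, 150 program per row), so the
  stored probabilities are exactly counts/total and the same counts
  parameterize the PSA Dirichlet.
* **Revision**: front-loaded annual hazards (~1.2% year 1 declining to 0.3%)
  scaled up for younger strata and males, cumulating to roughly 6--9% at 20
  years.
* **Utilities**: baseline 0.79/0.57/0.31 and post-operative 0.89/0.69/0.46
  by state, with small age/sex offsets; program increments
  $\Delta u(i \to j) = g(j) - g(i) + 0.02$ from program-registry-like levels
  $g = (0.80, 0.60, 0.37)$.

What passing tests on synthetic bundles show -- and what they do not: the
generator reproduces the *structure* of the real inputs (strata, files,
invariants, qualitative patterns), so green tests certify the pipeline's
correctness, not the published registry-driven results. The synthetic
base case saves about A\$8,800 per person, loses about 0.9 QALYs, and is
cost-effective for the first ~4 years; the published analysis, with its
(unavailable) registry inputs, reports A\$7,970, 0.43 and 9 years. The
quantities that *are* reproduced exactly are the arithmetic identities among
the printed numbers, which `consistency_report()` recomputes from the
packaged transcription of the published table.

Two special profiles support testing. `null_effect` equalizes the arms so
the lifetime QALY difference is exactly zero: both arms share a rank-one
(row-identical, hence idempotent) pain transition -- with any non-idempotent
shared matrix, later converters would re-apply the transition and break
exact symmetry -- plus equalized utilities
($\Delta u(i \to j) = u_{\text{post}}(j) - u_{\text{base}}(i)$, utilities
unstratified), unit excess ratios and no revisions. `extreme_benefit` makes
the program strictly better on utilities.

## Verification strategy

* `microsim_oracle()` simulates individuals through the identical event
  logic and must agree with the cohort engine within 3 Monte Carlo SEs per
  arm (run at n = 200,000 in the acceptance suite, ~5 s).
* `build_cycle_matrix()` materializes the expanded-state operator; tests
  check row-stochasticity to 1e-12 and that one engine step equals a
  vector-matrix product.
* Closed forms: cumulative conversion $1 - 0.74 \cdot 0.92^{\,h-1}$ with
  mortality off; trapezoid life-years under constant $q$
  $\tfrac{1}{2} + s(1 - s^{H-1})/(1-s)$ with $s = 1 - q$; trapezoid accrual
  equal to the exact integral of a linear occupancy path.
* Mass conservation per cycle and stratum to 1e-6 relative; subgroup
  partitions (state, age band, sex) sum exactly to the base case because the
  engine is linear in the initial allocation. The hospital partition does
  not sum exactly, by design: weighted-mean costs are independent inputs.

## Sensitivity analyses

The one-way analysis sweeps each input to its bounds: CI bounds for the
conversion probabilities, $\pm 1.96$ SE for surgical costs (SE 15% of the
mean) and revision disutilities (SE 25%), the stated A\$750--A\$3,000 range
for the program cost, $e^{\pm 1.96 \sigma}$ on the excess ratios
($\sigma = 0.1$ on the log scale, the default when no CI is given), an
additive shift of $\pm 1.96 \times 0.03$ on the program's utility increments
(0.03 being a typical SE for EQ-5D-derived increments; there is no published
one), and the $\pm$A\$500/year-for-5-years other-care scenario. On the
synthetic bundle the utility-increment parameter dominates the tornado, the
qualitative finding also reported for the original analysis.

The PSA redraws, per draw and with one hash-keyed RNG stream per parameter
path (so adding parameters never reshuffles existing draws): Dirichlet
baseline and transition rows from their counts; Beta conversion
probabilities moment-matched to mean and CI (SE = CI width / 3.92);
Gamma costs (program-cost SE taken as range/3.92 ≈ A\$574, the only
uncertainty statement available for it); mean-preserving log-normal excess
ratios; Gamma revision disutilities. State and incremental utilities are not
resampled -- the published input table assigns them no distribution -- so
the PSA spread here understates the dominant one-way driver; the one-way
analysis covers it. The 95% uncertainty interval is the 2.5th/97.5th
percentile of draws (the percentile-versus-normal choice is unstated in the
publication; percentiles are assumption-free). The acceptability-curve grid
is 0 to $2\lambda$ in 101 steps. Base analyses use 1,000 draws; tests use
8--40 draws since determinism and counting identities, not Monte Carlo
precision, are what they check.

## Worked example

```{r example, eval = FALSE}
inputs <- generate_input_bundle(seed = 1, profile = "registry_like")
res <- oa_run(inputs)
res
hs <- horizon_sweep(res)
attr(hs, "crossover")      # last horizon year with INMB >= 0
psa <- run_psa(inputs, n_sims = 1000, seed = 1)
psa
subgroups <- run_subgroups(inputs)
tornado <- one_way_dsa(inputs)
consistency_report()       # identities among the published printed numbers
```

## Known limitations

* The synthetic bundle reproduces structure, not registry values; absolute
  synthetic results should not be quoted as estimates for Australia.
* Pain states are static between surgical events; any true drift in pain
  over years is not modelled (none is reported to calibrate to).
* Waiting-list dynamics, contralateral or other-joint replacement,
  societal-perspective costs and EQ-5D scoring from raw responses are out of
  scope; utilities enter as numbers.
* The discounting convention (cycle 1 undiscounted) and the death-first
  event order are fixed choices; alternatives would shift absolute results
  slightly but leave every identity and invariant tested here intact.
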