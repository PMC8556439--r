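---
title: "Modeling ComX quorum-sensing dynamics in surfactin batch fermentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ComX quorum-sensing dynamics in surfactin batch fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(comxdyn)
```

## The biological problem

*Bacillus subtilis* regulates surfactin biosynthesis through the ComQXPA
quorum-sensing system. The secreted, farnesylated decapeptide pheromone ComX
accumulates with cell density; above a threshold it triggers, via the ComP
kinase and the ComA response regulator, expression from the surfactin
promoter P~srfA~. During a batch fermentation the extracellular ComX activity
(measured in Miller units, MU, with a P~srfA~-*lacZ* reporter bioassay) rises
through the exponential phase, peaks near the transition to stationary phase,
and then declines and settles — even though total extracellular endopeptidase
activity keeps rising with biomass. `comxdyn` packages a quantitative account
of that time course: a biomass-driven production/degradation model, the
machinery to calibrate it against bioassay time series, the surrounding
bioprocess calculus (yields, growth rates, specific productivities, assay
detection limits), the LC–MS mass arithmetic for the pheromone itself, and a
synthetic cultivation generator used to validate the whole chain.

## The model

Two coupled linear ordinary differential equations describe the ComX
activity $a(t)$ (MU) and the activity $E(t)$ of a putative ComX-specific
protease (CSP), driven by the cell-dry-weight curve $X(t)$ (g/L):

$$\frac{da}{dt} = b\,X(t) + d\,\frac{dX}{dt} - e\,E(t), \qquad
  \frac{dE}{dt} = f\,a(t) - g\,E(t).$$

Production has a biomass-proportional term ($b$) and a growth-rate-
proportional term ($d$); degradation is first order in the CSP activity,
which is itself produced in proportion to ComX ($f$) and decays first order
($g$). No autoinduction term is included — no positive feedback on ComX
synthesis is known for the ComQXPA system — and autodegradation and
cell-associated degradation are omitted because incubation experiments put
both below about 1 MU/h (a 6.5% activity loss over 8 h in heat-treated
supernatant; see `percent_activity_loss()`).

The calibrated parameter ranges are exposed by `comx_bounds()`:
$a_0 \in [21, 32]$ MU, $b \in [17.72, 19.95]$ (MU·L)/(g·h),
$d \in [436, 516]$ (MU·L)/g, $e \in [1.36, 1.58]$ MU/(EA·h), with
$f = 0.115$ EA/(MU·h) and $g = 0.328$ 1/h fixed. `comx_params_midpoint()`
gives the range midpoints used as defaults throughout.

Given biomass forcing, the system is linear in $(a, E)$; with constant
biomass $X$ it has the closed-form steady state

$$a_{ss} = \frac{b\,X\,g}{e\,f}, \qquad E_{ss} = \frac{f\,a_{ss}}{g},$$

implemented in `steady_state_comx()` and used as an independent check on the
numerical solver. At the default midpoints and $X = 5.4$ g/L,
$a_{ss} \approx 197$ MU — the late-plateau regime of a 40 g/L glucose batch.
The homogeneous part of the system has complex eigenvalues
($\lambda = -g/2 \pm i\sqrt{ef - g^2/4}$ when $ef > g^2/4$), i.e. a damped
oscillation with a period of roughly 17 h at the default parameters; this is
the model's echo of the oscillation tendency seen in late-cultivation ComX
measurements.

### A note on the units of $d$

The growth-associated coefficient is stated as $0.436–0.516 \times 10^3$
(MU·L)/g and is implemented literally as 436–516. Worth knowing: with a
fast logistic biomass (specific growth rate 0.52 1/h) this term alone
integrates to $d\,\Delta X \approx 2.6 \times 10^3$ MU, so the simulated
transient peak is several times higher than typically measured ComX maxima
(~150–260 MU), whereas the alternative reading $d \approx 0.48$ would place
the peak inside the measured range. Because published calibrations of this
model were made against slower, substrate-limited biomass trajectories read
from experimental data, the discrepancy only manifests with idealized fast
logistic forcing. The package keeps the literal value as the default and
treats the bounds as configuration (`comx_bounds()` can be replaced
wholesale), so either reading can be explored.

### Numerical choices

* Integration uses `deSolve::ode(method = "lsoda")` at `rtol = atol = 1e-8`;
  `lsoda` switches to a BDF scheme when the system stiffens (large $g$), in
  the spirit of the stiff solvers used for the original calibration. The
  test suite cross-checks it against an independently coded forward-Euler
  integration at $dt = 10^{-3}$ h (agreement within $10^{-3}$ relative
  sup-norm over 48 h) and against the closed-form steady state (within 0.1%
  at $t = 200$ h).
* With the default parameters and a small inoculum the raw solution can dip
  a few MU below zero early on (production is still negligible while the
  initial-protease balance decays). Outputs are clipped at zero with a
  warning when the raw solution goes below $-10^{-9}$; the solver state is
  never clipped mid-integration, so the dynamics are unaffected.
* The initial CSP activity is not observable with the azocasein assay and
  defaults to `ea0 = 0` (no ComX-induced protease at inoculation); it is an
  explicit argument everywhere.
* The ±8% sensitivity envelope (`sensitivity_envelope()`) perturbs the four
  free parameters in a full $3^4$ factorial (81 simulations) and takes the
  pointwise min/max, rather than varying one parameter at a time: the band
  is meant to cover the entire replicate cloud, and one-at-a-time variation
  underestimates combined effects.

## Parameter estimation

`fit_comx_params()` minimizes the plain (unweighted) sum of squared
residuals between simulated and measured ComX activity over the free
parameters $(a_0, b, d, e)$ within their bounds, holding $f$ and $g$ fixed —
the same free/fixed split as the published calibration. The optimizer is
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) from five deterministic
starts: the bounds midpoint plus four seeded Latin-hypercube points
(`lhs::randomLHS` under a fixed seed). The lowest residual wins, ties broken
by start order, so results are reproducible bit-for-bit for a given seed.
Estimates within $10^{-6}$ of the feasible range of a bound are flagged
`at_bounds` — the only identifiability diagnostic provided; no posterior or
profile likelihood is attempted.

`recovery_experiment()` closes the validation loop: it generates replicate
synthetic cultivations with known parameters, refits each, and reports
signed relative errors. The reference configuration (additive ComX noise of
5 MU, 25 samples over 48 h, 20 replicates) yields median absolute relative
errors below 15% for $b$, $d$ and $e$; with the noise at zero all free
parameters return to within $10^{-3}$ relative. $a_0$ is the least
identifiable parameter — it only shifts the short pre-growth transient — and
is therefore not held to the 15% bar.

## Curve fitting

Observables are smoothed with either a 4-parameter sigmoid
$y = y_0 + a/(1 + e^{-(t - t_0)/\tau})$ (`fit_sigmoid4()`) or a 3-parameter
exponential $y = y_0 + a e^{kt}$ (`fit_exp3()`), the two families used for
the original data analysis; which variable gets which family is the
caller's choice. Both fits are deterministic: the sigmoid starts from
$y_0 = \min y$, $a = \mathrm{range}(y)$, $t_0$ at the earliest half-range
crossing (ties to the earliest time), $\tau = \mathrm{range}(t)/10$, plus a
mirrored negative-amplitude start so decreasing series (glucose, ammonium)
fit without intervention; the exponential starts from log-linear
regressions with growth, decay and near-flat variants. The residual sum of
squares is checked against the flat-fit residual as an optimizer sanity
bound. `eval_fit()` returns closed-form values *and* derivatives — the ComX
model consumes $X(t)$ and $dX/dt$ analytically, never by finite
differencing.

The instantaneous specific surfactin productivity used for the
productivity–pheromone correlation is $q(t) = P'(t)/X(t)$ from these
analytic derivatives (`q_vs_comx()`), the short-interval limit of the
interval formula below; the curve is truncated at the ComX maximum, the
domain on which the correlation is interpretable. The interval form is kept
for whole-process summaries.

## Bioassay and process calculus

* **Miller units** (`miller_units()`):
  $\mathrm{MU} = 1000\,(OD_{420} - 1.75\,OD_{550})/(t\,v\,OD_{600})$ with
  $t$ the β-galactosidase reaction time in minutes and $v$ the sample volume
  in mL — the conventional Miller units; the 3–5 h bioassay pre-incubation
  is *not* $t$. Negative blank-level values are deliberately not clipped.
* **Detection limits** (`blank_statistics()`, `detection_limits()`): blanks
  are screened once (not iteratively) by excluding values with $|z| \ge 2$
  computed from the full set's mean and sample SD ($n-1$); then
  $\mathrm{LOD} = \bar m_B + 3 S_B$ and $\mathrm{LOQ} = \bar m_B + 10 S_B$,
  so $\mathrm{LOQ} - \mathrm{LOD} = 7 S_B$ exactly. Shapiro–Wilk normality
  of the retained blanks is reported (and warns below $p = 0.05$) but never
  enforced.
* **Degradation rates** (`degradation_rate()`): the negated OLS slope of
  activity versus incubation time, in MU/h; an endpoint difference-quotient
  mode is available since short two-point series are common.
* **Process metrics** (`process_metrics()`): yields
  $Y_{X/S} = \Delta m_X/\Delta m_S$, $Y_{P/S} = \Delta m_P/\Delta m_S$,
  $Y_{P/X} = \Delta m_P / \bar m_X$, specific growth rate
  $\mu = \ln(m_{X2}/m_{X1})/\Delta t$ and specific productivity
  $q = \Delta m_P/(\bar m_X\,\Delta t)$, evaluated at sampled time points
  only (no interpolation), with reference points chosen by the "≥ 90% of
  maximum" rule (`t_at_fraction()`): the earliest sampled time at which an
  observable reaches 90% of its maximum. Surfactin is converted mg/L → g/L
  before yield calculations. Replicates are summarized per replicate; no
  error-propagation theory is applied.
* **Mass arithmetic** (`monoisotopic_mass()`, `mz()`,
  `mass_conc_to_molar()`): standard monoisotopic residue masses at the
  5-decimal convention, water 18.010565 Da, proton 1.007276 Da.
  Farnesylation is a net +C15H24 (+204.18780 Da) on the tryptophan — the
  accepted chemistry of ComX prenylation. The computed doubly protonated
  ions of ADPITRQWGD are 579.78053 (unmodified) and 681.87443 m/z
  (farnesylated); the latter sits ~0.3 mDa (≈0.4 ppm) from the commonly
  quoted target 681.87470, a discrepancy attributable to differing
  mass-table conventions. No isotope envelopes, raw spectra or calibration
  curves are handled.
* **OD↔CDW**: the direction of the 3.2 correlation factor is taken as
  $\mathrm{CDW} = OD_{600}/3.2$, which maps the observed biomass maximum of
  5.4 g/L to a plausible $OD \approx 17$ and the inoculation OD of 0.1 to
  0.031 g/L; the factor lives in `conversion_config()` so it can be flipped
  if a culture's calibration differs.

## The synthetic cultivation generator

`generate_cultivation()` stands in for bioreactor runs. Its defaults encode
the 40 g/L glucose reference batch: logistic biomass from 0.031 to 5.4 g/L
at 0.52 1/h over 48 h sampled every 2 h in two replicates; glucose tied to
biomass through a constant 0.15 g/g yield (no maintenance term); surfactin
as an independent sigmoid reaching 1346.6 mg/L with half-maximum at 20 h
and shape scale 4 h, placing ~99% of the titer by 40 h, when the maximum
was observed; ComX simulated from the model at the calibration midpoints
with additive Gaussian noise (SD 5 MU, the scale of replicate scatter);
total endopeptidase activity proportional to biomass (15 ∆A/(h·mL) per
g/L, reproducing the ~81 ∆A/(h·mL) maximum near peak biomass); and
multiplicative 5% CV noise on concentrations. Every generator is a pure
function of its configuration and seed.

What it deliberately does **not** emulate: substrate-limited deceleration
(the logistic reaches capacity faster than a real 32-h growth curve — see
the note on $d$ above), the decline phase after glucose depletion, pH and
dissolved-oxygen effects, foam, the late oscillation of ComX, and any
mechanistic surfactin–ComX coupling (the correlation is left empirical, as
it was established). Passing tests therefore demonstrate that the
estimation and metrics machinery is correct *given the model class*, not
that the model captures every feature of real cultivations.

## Validation problem sizes

The shipped tests run the recovery study at 20 replicates × 25 samples,
the Euler cross-check at $dt = 10^{-3}$ h over 48 h, sigmoid-recovery
robustness at 50 seeded noisy replicates, and the generator moment checks
at $n = 10^4$ blanks — sizes at which the checks are sharp yet the full
suite completes in about a minute.

## Known limitations

* $a_0$ identifiability is weak (see above); treat its estimate as a
  nuisance parameter.
* The CSP is putative: its activity is expressed in azocasein units but was
  only partly captured by that assay, so `ea_csp` trajectories are
  model-internal quantities, comparable between runs but not directly to
  measured `ea_total`.
* The ≥ 90% rule uses sampled points only; sparse late sampling can shift
  reference times by one sampling interval and with them the yields.
* Yields assume batch operation (no feeds, no volume change).
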