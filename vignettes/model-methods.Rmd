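---
title: "Model and methods: carboplatin + ABT-737 combination therapy in tumor xenografts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenopkpd)
```

# The model

`xenopkpd` simulates the growth of an ovarian-cancer xenograft in a mouse
under combination therapy with carboplatin (a DNA-damaging platinum drug)
and ABT-737 (a BH3-mimetic that occupies the anti-apoptotic protein
Bcl-xL).  The model couples four blocks.

**Tumor populations.**  Proliferating cells $N$ (and, in resistance
scenarios, a carboplatin-resistant clone $N_r$) grow logistically with net
rate $g$ and shared carrying capacity $K$; arrested cells compete for the
same capacity, so the crowding term uses the total burden
$T = N + N_r + \int_0^\psi M\,da$.  Proliferating cells die at a rate
$\delta_N(x_B)$ that increases with free intracellular Bax, and are driven
into cell-cycle arrest by tissue carboplatin at rate $\alpha(C_t)$.
Resistant cells are never arrested but respond to ABT-737 exactly like
sensitive cells.

**Arrested compartment.**  Cells arrested by carboplatin are tracked by
the time $a$ since arrest (a McKendrick age-structured density $M(t,a)$,
advected along characteristics).  Each cohort remembers the tissue
carboplatin concentration at its moment of arrest — a proxy for the DNA
damage it sustained — and dies at rate
$$\delta_M = C_t(\text{at arrest}) \times \bigl(\delta_{M0} +
\lambda_s\,\max(x_B - x_B^{0},\,0)\bigr),$$
where $x_B^0$ is the constitutive free-Bax level.  Cells surviving to age
$\psi$ (default 24 h) recover instantaneously to the proliferating pool.
$\lambda_s$ — the sensitivity of arrested cells to drug-induced *changes*
in Bax — is the single number that quantifies the synergy between the two
drugs: ABT-737 frees Bax, which preferentially kills DNA-damaged cells
before they can recover.

**Pharmacokinetics.**  Both drugs are dosed intraperitoneally and follow
three-compartment models written in amount-conserving form (explicit
compartment volumes, pairwise-balanced mass fluxes, elimination tracked as
a cumulative integral so mass balance is testable).  For carboplatin the
chain is peritoneum, plasma/well-perfused organs, and poorly-perfused
peripheral tissue — where the tumor resides; the tissue concentration
$C_t$ drives arrest.  For ABT-737 the third compartment is intracellular,
and its balance includes the signed flux of the Bcl-xL binding reaction.

**Apoptosis network.**  A mass-action system of free Bcl-xL, free Bax,
the inert Bcl-xL·Bax heterodimer and the Bcl-xL·ABT-737 complex, with
constitutive production and first-order degradation.  Drug occupancy of
Bcl-xL releases Bax from the heterodimer; free Bax raises both
$\delta_N$ and (through $\lambda_s$) $\delta_M$.

# Parameters

All numeric defaults live in one schema file
(`inst/extdata/config-schema.json`, returned by `config_schema()`), each
with units and a one-line rationale.  The original study's supplementary
parameter tables are not available, so every default is this package's own
choice, made once, to satisfy the constraints the source describes in
prose:

* molecular weights 371.2 (carboplatin) and 813.4 (ABT-737) g/mol; mouse
  body mass 0.02 kg;
* carboplatin plasma kinetics biphasic with an elimination half-life of
  order one hour; ABT-737 circulation half-life of several hours, so daily
  dosing gives its intracellular concentration a sustained non-zero mean;
* arrest duration $\psi$ = 24 h (apoptosis of arrested cells is observed
  within 12–16 h of carboplatin exposure, which constrains the death-rate
  peak, not $\psi$ itself; flagged provisional);
* growth ($g = 0.12$/day, $K = 2000$ million cells from 50 million at
  therapy start on day 19) so that an untreated tumor roughly saturates
  over the eight-week observation window;
* pharmacodynamic constants placed so the four calibration arms sit in
  the qualitative regime the source reports: modest inhibition by
  100 mg/kg/day ABT-737 alone, substantial but non-curative inhibition by
  30 mg/kg/week carboplatin alone, strong combined inhibition, a
  U-shaped long-run burden as the carboplatin infusion duration varies
  (with remission achievable only at intermediate durations), and
  single-agent iso-effective doses reachable below 2000 mg/kg.

Because the defaults are calibrated to a *regime* rather than to digitized
data, a green test establishes internal consistency and qualitative
fidelity, never numerical agreement with the original figures.

Two functional-form choices deserve note.  The arrest rate is a Hill
function of tissue carboplatin (exponent 3 by default): the
peak-versus-duration trade-off that makes infusion duration matter needs a
saturating and reasonably sharp response, and the source states only
"increasing and saturating".  The proliferating death rate responds to the
*excess* of free Bax over its constitutive equilibrium, with baseline
turnover folded into $g$ — this makes the untreated model exactly
logistic, which the calibration of $g$ to untreated data presumes.

# Numerical method

The coupled system is solved by a fixed-step compiled core
(`src/sim_core.cpp`):

* the PK + network block is integrated with classical RK4, sub-stepped
  adaptively from a local stiffness estimate (binding rates spike after a
  bolus);
* populations advance one RK4 step per macro step with PK/network inputs
  frozen at step midpoints; because RK4 preserves linear invariants, the
  arrest outflow and the new age-0 cohort match exactly;
* the arrested density uses uniform age bins with $\Delta a = \Delta t$
  (characteristics-aligned upwind / escalator boxcar): advection is exact,
  there is no numerical diffusion, recovery is removal of the terminal
  bin, and each cohort carries its own $C_t$-at-arrest;
* bolus doses are state jumps at grid-aligned dose times; infusions enter
  through the *exact* window average of the analytic cumulative delivery
  profile, so the administered mass is exact for any step size and any
  window alignment (the alternative — restarting the solver at every
  window edge — is incompatible with a strictly uniform age grid).
  Smearing of a window edge is bounded by one step (43 s at the default
  $\Delta t = 0.005$ day).

Default steps: $\Delta t = 0.005$ day for production runs, 0.02 day inside
calibration objectives and scans (the convergence contract — halving
$\Delta t$ moves the final burden by < 0.1% — is part of the test suite).
Degenerate inputs (negative concentrations, steps not dividing $\psi$,
unreachable dose targets) raise errors rather than warnings.

# Calibration

The staged procedure mirrors the original fitting order, on weighted least
squares of log tumor size (the error bars of such data are proportional):

1. `fit_growth()` — $(g, K)$ from the untreated arm, using the logistic
   closed form;
2. `fit_abt_params()` — the maximal Bax-driven death rate from the
   ABT-737 arm, growth frozen;
3. `fit_carbo_params()` — the maximal arrest rate, the baseline
   arrested-death coefficient $\delta_{M0}$ and $\lambda_s$ jointly from
   the carboplatin and combination arms ($\lambda_s$ is identified only by
   the combination arm, exactly as the source argues).

Three identifiability decisions, each verified numerically during design:

* the *shape* constants of the arrest and death responses (half-effect
  points, Hill exponents) are held at known values by default: with
  single-dose arms the objective has an exact ridge trading them against
  the corresponding maxima (options `fit_c_half`/`fit_shape` re-enable
  them for dose-ranging data);
* $\lambda_s$ multiplies the drug-induced Bax *excess*, not total Bax;
  otherwise $\delta_{M0}$ is confounded with $\lambda_s \times$
  baseline-Bax and is unidentifiable at realistic noise;
* stages 2–3 are MAP fits: a weakly-informative quadratic penalty on
  log-parameters (weight 0.05) centred on the starting values regularizes
  the directions the data barely constrain; the optimizer is multi-start
  Nelder–Mead on smoothly box-bounded log-parameters (±1.5 log-units) with
  restart polishing, objective tolerance 1e-10.

A design-phase Monte-Carlo study (14 seeds, noise CV 0.15, 8 mice/arm)
gave maximal recovery errors of about 2% ($g$), 8% ($K$), 14% (death
maximum), 4% (arrest maximum), 10% ($\delta_{M0}$) and 27%
($\lambda_s$); the acceptance test's stated tolerances (15/15/25/25/25/50%)
were frozen from that study before fixing the test seed.  $\lambda_s$ is
the widest because the arrested-cell kill saturates at the calibration
doses, weakly informing its upward direction.

# The synthetic-data generator

`generate_study()` emulates the source protocol: four arms (vehicle,
100 mg/kg ABT-737 daily, 30 mg/kg carboplatin weekly, combination),
treatment from day 19 for four weeks, tumors measured twice weekly, eight
mice per arm, and independent mean-one multiplicative log-normal
measurement noise with CV 0.15 (the scale of the published error bars; a
free knob, not digitized).  The untreated arm is followed four extra
weeks so the growth plateau — and hence $K$ — is actually observed.  It
does **not** emulate inter-mouse growth heterogeneity (no random effects),
censoring by humane endpoints, or measurement-volume conversion error;
recovery results therefore bound what the pipeline can do under ideal
sampling assumptions, not under real xenograft variability.

# Scope and limitations

* Resistance is all-or-none; partial phenotypes, fitness costs, and
  mechanisms other than the arrest-recovery mutation route are out of
  scope.  Acquired and intrinsic scenarios are mutually exclusive unless
  explicitly combined.
* No host toxicity, spatial structure, or third drug.
* Configuration files are JSON (one schema-validated, human-editable
  file); the environment provides no YAML parser and JSON keeps the
  single-source-of-defaults property.
* The combination-index machinery assumes inhibition is monotone in each
  dose (asserted during bisection) and defines iso-effect at the end of a
  fixed four-week course starting day 19.
* Scan utilities cap steady-state searches (default 20 simulated years)
  and report non-convergence rather than truncating silently; analyses in
  the test suite use shorter caps, which is documented where it matters.
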