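---
title: "Temperature-dependent NF-kB oscillations: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-dependent NF-kB oscillations: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(nfkbtherm)
```

## The model

Under TNF-alpha stimulation, NF-kB shuttles between cytoplasm and nucleus
with a period of roughly 1.5 hours. The core of this package is a
five-variable rate model of that negative feedback: nuclear NF-kB ($N_n$)
transcribes its own inhibitor IkB (mRNA $I_m$, protein $I$), which pulls
NF-kB back out of the nucleus, while the kinase IKK -- activated by the
external TNF signal -- degrades IkB and closes the loop. IKK cycles
through neutral, active ($IKK_a$) and inactive ($IKK_i$) forms with a
fixed total pool, so the neutral form is computed as
$IKK_n = IKK_{tot} - IKK_a - IKK_i$ and the pool is conserved exactly (an
invariant the tests assert to the last bit). A20 is a constant
(constitutive expression), not a dynamical feedback.

$$
\begin{aligned}
\dot N_n &= k_{Nin}\,(N_{tot}-N_n)\,\frac{K_I}{K_I+I}
          - k_{Iin}\,I\,\frac{N_n}{K_N+N_n},\\
\dot I_m &= k_t N_n^2 - \gamma_m I_m,\qquad
\dot I = k_{tl} I_m - \alpha\,IKK_a\,(N_{tot}-N_n)\,\frac{I}{K_I+I},\\
\dot{IKK}_a &= k_a\,\mathrm{TNF}(t)\,IKK_n - k_i\,IKK_a,\qquad
\dot{IKK}_i = k_i\,IKK_a
  - k_p\,IKK_i\,\frac{k_{A20}}{k_{A20}+A20\cdot \mathrm{TNF}(t)}.
\end{aligned}
$$

`nfkb_params()` carries the fifteen reference constants (nine kinetic
rates, six temperature-independent constants), defined at 37 degrees C.
TNF is a dimensionless 0--1 drive; `forcing_protocol()` supports constant,
sinusoidal and piecewise-step TNF and constant or sinusoidal temperature.

## Temperature enters through the rates

Every kinetic rate is made temperature dependent through one of two
linearised laws around the reference temperature $T_{ref} = 310.15$ K:

* **Reaction limited (Arrhenius):** $k(T) = k_0\,(1 + S\,\Delta T/T_{ref})$,
  with $S$ the dimensionless activation scale factor. The slow,
  "impactful" rates $k_{Iin}, k_i, k_p$ use $S = 20$; the remaining slow
  rates $k_{tl}, \gamma_m, k_a$ use $S = 1$. The value 20 is a
  convention, not a measurement, so `thermal_config()` exposes $S$ per
  rate and sensitivity scans over it are supported; an all-Arrhenius
  variant (diffusion-limited rates switched to $S = 1$) preserves the
  qualitative period-temperature trend and is covered by a test.
* **Diffusion limited (Smoluchowski/Einstein--Stokes):**
  $k(T) = k_0\,(1 + \Delta T/T_{ref})$ for the fast encounter-limited
  rates $k_{Nin}, k_t, \alpha$.

Both laws are exactly linear in $\Delta T$ and strictly increasing, with
$\Delta T = 0$ an exact identity; the second law is sometimes written
with the running temperature in the denominator, but its derivation
yields a constant slope $k_0/T_{ref}$, and we use that reading for both
laws so the identity at the reference temperature is exact. Binding
constants and pool sizes ($K_I, K_N, N_{tot}, k_{A20}, IKK_{tot}, A20$)
are untouched. With time-varying temperature the scaling is applied
quasi-statically -- rates are re-evaluated from $T(t)$ inside every
derivative call -- because no relaxation dynamics for the rate constants
themselves is part of the model.

## Integration

`simulate_nfkb()` integrates with deSolve's `lsoda`
(stiffness-switching, adaptive) at rtol $10^{-8}$ / atol $10^{-10}$.
These tolerances are deliberately tight: the IKK recycling term
saturates sharply, the limit cycles are spiky, and the entrainment and
chaos analyses are sensitive to phase errors. The right-hand side is
compiled (C), with an R implementation (`nfkb_rhs()`) kept as the
readable reference; the two are cross-checked in the tests, and the
adaptive solver is checked against an independent fixed-step
fourth-order Runge--Kutta oracle at $dt = 10^{-3}$ min over a 1000-min
horizon to within $10^{-5}$ uM.

The default initial state $(0.1, 0.01, 0.5, 0.1, 0.1)$ uM is arbitrary
but admissible; all analyses discard a transient before measuring
anything. The default `transient_cut` of 2000 min covers more than
twelve periods of the slowest oscillation; analyses that sit close to a
bifurcation need far more (below).

## Measuring the oscillation

Periods come from the mean-subtracted FFT power spectrum with a
rectangular window, zero-padded to at least four times the sample count,
and the peak position refined by parabolic interpolation
(`power_spectrum()`). The dominant frequency is the maximal non-DC bin.
Relaxation-type cycles put harmonics at multiples of the fundamental;
because the fundamental dominates, taking the maximal bin is
self-consistent, and `peak_is_lowest` flags the (never observed under
defaults) case where the maximal bin is not the lowest substantial peak.
A second, spectral-free estimator -- the mean interval between prominent
peaks (`mean_peak_interval()`) -- agrees with the spectral period to
within 2% on every sustained oscillation, and the tests keep it that
way.

Amplitude is the peak-to-trough range of post-transient $N_n$;
`mean_abs_derivative()` averages $|\dot N_n|$ evaluated from the
right-hand side along the trajectory (not finite differences), the
quantity whose sharp rise against TNF locates the oscillation onset.

### Locating the Hopf onset

`hopf_threshold()` bisects on constant TNF with an amplitude criterion
of $10^{-4}$ uM at resolution $10^{-4}$. Two numerical subtleties are
handled explicitly. First, near the onset the fixed point is weakly
damped and ringing decays over tens of thousands of minutes, so each
evaluation discards a 10,000-min transient and then requires the
oscillation to be *sustained*: the maximal peak prominence in the second
half of a 20,000-min window must exceed the criterion and at least 80%
of the first-half value, which separates a limit cycle from slowly
decaying ringing and from slow monotone drift toward the fixed point.
Second, the oscillatory region is bounded in TNF: at high temperature
the limit cycle shrinks with increasing TNF and TNF = 1 can sit beyond
the upper boundary (at 39.5 degrees C the cycle at TNF = 1 has amplitude
of order $10^{-2}$ uM and is still shrinking), so the bisection bracket
must be chosen inside the oscillatory window -- the package uses
$[10^{-3}, 0.8]$ for threshold scans and the error message names the
endpoint that failed. Doubling the evaluation horizon moves the
threshold by less than $10^{-3}$, and the threshold decreases with
temperature: cooling brings oscillations on at lower TNF.

## Downstream genes

Each gene is a Hill-driven mRNA/protein pair,
$\dot m = \gamma N_n^h/(N_n^h + K^h) - \delta m$,
$\dot P = \Gamma m - \Delta P$, co-integrated against the stored
$N_n(t)$. The published analysis gives no numeric gene parameters, so
the defaults are chosen to place the two gene classes on either side of
the oscillation's dynamic range: the high-affinity gene
($K = 0.05$ uM, $h = 2$) is near-saturated except in deep troughs, the
low-affinity gene ($K = 0.8$ uM, $h = 4$) fires only near the highest
peaks, and both decay slowly against the ~100-min period
($\delta = 0.03$, $\Delta = 0.01$ min$^{-1}$; $\gamma = \Gamma = 1$) so
the protein time-averages the drive. The steady level is the protein
mean over the final 20% of the post-transient window, which must cover
ten protein half-lives. "Relative production" (the crossover analysis)
normalises each gene by its own 37-degree value; the two normalised
curves then intersect at the reference temperature by construction, and
the meaningful assertions -- which the tests make -- are that the
high-affinity curve rises with temperature, the low-affinity curve
falls, and the intersection is unique. All gene parameters are
configurable (`gene_spec()`, YAML via `read_gene_specs()`), and each
panel is run at constant temperature.

## Entrainment

With sinusoidal temperature (amplitude $A_T$, frequency $f_{tmp}$) the
system is a periodically forced oscillator. The rotation number is
$W = f_{tmp}/f_{NF\kappa B}$, measured by counting $N_n$ maxima
(prominence at least 5% of the post-transient amplitude) over exactly
200 forcing cycles after a 50-cycle transient. The raw count ratio is
what `rotation_number()` reports as `W`, but it is quantized by boundary
peaks (a true 3/1 lock counted over 200 cycles gives 200/66 = 3.03), so
lock detection uses `W_refined` -- the mean inter-peak interval divided
by the forcing period -- and attaches the nearest rational $p/q$ with
$q \le 8$ within $5\times10^{-3}$. Plateau edges are found by bisection
between locked and unlocked frequencies (`plateau_width()`); the
dominating plateaus (1/1 and 2/1) widen as $A_T$ grows, which the
property tests assert.

At the reference parameters the unforced period at 37 degrees C and
TNF = 0.5 is 108 min rather than ~100, and the integer plateaus at
$A_T = 1$ degC are wide (1/1 up to $f \approx 0.011$, 2/1 over roughly
0.013--0.0195 min$^{-1}$), which squeezes the higher-order rationals
such as 5/3 into a narrow band near 0.0125--0.013 min$^{-1}$; the
staircase is monotone and its plateau structure is what the tests pin
down.

### Multistability

Coexisting entrained cycles are counted from 40 random admissible
initial states. Comparing orbits as discrete point sets is hopeless at
any reasonable sampling -- the spiky cycles move at up to ~5 uM/min, so
discrete Hausdorff distances between same-attractor orbits are of order
0.1 uM -- and the comparison is instead exact on the grid: orbits are
sampled on a grid commensurate with the forcing period (128 samples per
period), an orbit is classified periodic when it repeats after $q \le 8$
forcing periods to within $10^{-3}$ uM, and two periodic orbits share an
attractor when some cyclic shift by whole forcing periods superposes
them pointwise to within $10^{-3}$ uM. Orbits that do not repeat within
8 forcing periods (quasiperiodic, chaotic, or unconverged) are flagged
and excluded from the limit-cycle count. Convergence to an entrained
cycle is slow -- repetition residuals are ~$10^{-2}$ after 6000 min but
~$10^{-6}$ after 20,000 min -- so the default transient is 20,000 min. In
the unforced control ($A_T = 0$) the phase is continuous rather than
quantized; orbits are then aligned at their parabolic-refined $N_n$ peak
times on a 0.02-min grid before the pointwise comparison, and exactly
one attractor is found. At $A_T = 2$ degC the demonstration frequency is
0.018 min$^{-1}$ (the 5/3-coupling frequency of the entrainment
figures), where the scan finds five or more distinct cycles -- at the
neighbouring 0.02 min$^{-1}$ only two coexist.

## Chaos

`divergence_metric()` diagnoses chaos by twin-trajectory divergence: a
reference trajectory is integrated 2000 min past the transient start, a
companion is launched from the same state with every component
multiplied by $1 + 10^{-6}$ (the relative reading of "separated by
$10^{-4}$%"; the perturbed variable is not specified, so all five
components are perturbed), and both run 5000 min. The verdict compares
the mean distance in $(N_n, I_m, I)$ space against the attractor
diameter (bounding-box diagonal of the reference orbit): chaotic when
the mean exceeds 10% of the diameter. On a regular attractor the twins
re-converge up to phase and the ratio is below $10^{-2}$; with zero
perturbation the twins are bit-identical, a determinism control the
tests keep. The 10% threshold is a design choice -- no formal criterion
accompanies the figure it reproduces -- and is guarded by an independent
largest-Lyapunov-exponent estimate (`lyapunov_exponent()`, two-trajectory
Benettin renormalisation at separation $10^{-7}$ uM every 10 min over
4000 min): on a ten-amplitude validation grid at forcing period 40 min
the divergence verdict must agree with $\lambda_1 > 2\times10^{-3}$
min$^{-1}$. The deadband reflects the estimator's resolution
($\lambda_1$ of an unforced cycle is zero along the phase direction and
estimates at ~$+10^{-3}$; entrained cycles give ~$-10^{-3}$; chaotic
forcing gives ~$+10^{-2}$), and the validation amplitudes sit in the
clearly locked (0--1) and clearly chaotic (3--5) regimes at period
40 min: between roughly 1.5 and 2.5 degC the system shows transient
chaos and long chaotic-looking episodes whose finite-horizon exponent is
genuinely ill-determined, so no validation point is placed there.

`chaos_transition_amplitude()` scans amplitudes upward (default 0--5
degC in 0.25 steps), calls an amplitude chaotic when the majority of
three seeded initial conditions diverge, and refines the first chaotic
amplitude by bisection to 0.05 degC. Fast forcing (period 40 min)
transitions near 2.2 degC, slow forcing (period 100 min) near 4.3 degC
-- both inside physiologically tolerated variation.

## Synthetic single-cell traces

`generate_trace()` emulates the three imaging protocols (single TNF
addition, double addition 40 min apart, constant-concentration flow) as
nuclear/cytoplasmic intensity-ratio series sampled every 10 min:
$r = c\,N_n/(N_{tot} - N_n + b)$ with $c = 1$, $b = 0.1$ (ratios span
~0.3--2), multiplicative lognormal noise (sigma = `noise_sd`) and a slow
lognormal random-walk drift that accumulates to `drift_sd` by the end of
the trace. Doses map to the dimensionless drive through the saturating
`tnf_from_dose()` (10 ng/ml gives 0.5, 18 ng/ml about 0.64, the 1 ng/ml
flow plateau about 0.091, above the 37-degree onset of about 0.09 and
comfortably above the 32-degree onset of about 0.05).

The sustained part of a trace is the model's limit cycle at the
protocol's TNF level and the working temperature, so the recorded
periods carry the model's real temperature dependence. The initial
transient is *not* the raw step response of the rate model: integrating
the model from a resting state through a TNF step drives the IkB mRNA
pool five-to-tenfold past its cycle range, after which the system is
refractory for hundreds of minutes and a second addition produces no
response at any dose -- a known limitation of the fixed-IKK-pool
simplification, which omits the fresh IKK recruitment behind the
experimentally enhanced post-addition peaks. The generator therefore
anchors the cycle phase 23 min after the first addition and multiplies a
Gaussian window (sigma = period/6, boost factors 1.2 and 0.8) onto the
first cycle peak following each abrupt addition; flow traces, with no
abrupt step, get no enhancement. This reproduces the protocol
phenomenology -- exactly one enhanced initial peak for single addition,
two for double, none for flow -- while leaving the period content of the
trace untouched.

What passing tests do and do not show: the round-trip tests (generator
to `extract_period()` at zero noise, cohort recovery at 5% noise, the
cold-slow/warm-fast cohort ordering) validate the *analysis pipeline*
against known ground truth with realistic sampling, noise, drift and
cohort sizes ($n = 12$ mirrors the single-addition cohort). They do not
validate the model against real imaging data, and real traces differ in
ways the generator does not emulate: cell-to-cell period heterogeneity,
photobleaching beyond a smooth drift, segmentation artefacts, and
cell division events.

## Trace analysis

`moving_average()` reproduces the classic centered smoothing convention
(even spans reduced by one, windows shrinking symmetrically at the ends,
so linear ramps are reproduced exactly); `detrend_trace()` subtracts the
span-13 smooth from the span-4 smooth, a linear operation that passes
the oscillation and suppresses intensity variations slower than the
period -- used for visualisation, while spectra are taken on the raw
mean-subtracted ratio. `extract_period()` zero-pads to at least 4096
points, takes the highest non-DC peak, requires it to clear three times
the median spectral power (otherwise a no-period result, not an error),
flags periods outside 20--600 min as implausible, and accepts an
explicit frequency band as the reproducible counterpart of manually
choosing the peak nearest the visually observed oscillation. The
reported uncertainty is the unpadded bin width $1/(n\,dt)$; round-trip
tests assert recovery within one bin in frequency space.

## Problem sizes used by the tests

The default analyses integrate 10,000 model minutes per point. The test
suite scales horizons to what each assertion needs: 8000-min windows
for period/amplitude checks, four-temperature grids for monotonicity,
60--80 forcing cycles for staircase and plateau assertions (the
acceptance checks use the full 200-cycle/50-transient protocol),
12--40 initial conditions for multistability, and a four-amplitude
Lyapunov agreement grid in the unit tests with the full ten-point grid
in the acceptance suite. The fixed-step oracle comparison runs a
million RK4 steps and is the single most expensive unit test.

## Known limitations

* The thermal laws are linearisations; far outside 32--41.5 degrees C
  they lose meaning (a reaction-limited rate with $S = 20$ would cross
  zero near $\Delta T = -15.5$ K and is clamped there).
* With the published scale factors the model's period-temperature slope
  at TNF = 0.5 is about $-7$ min/degC, shallower than the experimentally
  reported $-11.9 \pm 2.8$; the absolute periods at 32 and 37 degrees C
  do fall inside the reported experimental bands. A steeper effective
  activation ($S \approx 30$) would match all three anchors -- the
  package keeps the published defaults and exposes $S$ for sensitivity
  scans.
* A20 is constant; heat-shock pathways and delayed-feedback
  alternatives are out of scope, as are stochastic (Gillespie)
  dynamics and parameter fitting to experimental traces.
* Near bifurcation boundaries (oscillation onset, plateau edges, the
  chaotic transition) classifications depend on horizons and thresholds
  that are documented above and fixed package-wide; they are honest
  numerical conventions, not sharp mathematical boundaries.
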