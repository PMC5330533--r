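---
title: "Extracting molecular kinetic schemes from macroscopic traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting molecular kinetic schemes from macroscopic traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetrace)
```

## The problem

Many cellular measurements — whole-cell currents under voltage clamp,
G-protein-gated channel readouts under a ligand step, reporter signals in
general — are *macroscopic*: they sum the contributions of a large population
of molecules whose individual dynamics follow a Markov-chain kinetic scheme
(states = conformations or occupancies, transitions = first-order rates).
Very different schemes can produce nearly identical macroscopic traces, so
reading the scheme off the trace is a real inference problem.

`kinetrace` addresses the restricted but practically central case of systems
composed of one or two first-order processes (e.g. fast activation plus slow
inactivation). The pipeline has three stages, all exposed individually and
wrapped by `kinetrace()`:

1. **Identification** (`identify_tf`): fit an ARX difference-equation model
   to the sampled stimulus–response pair `(u, y)` by prediction-error least
   squares, select the model order, and convert the discrete model to a
   continuous transfer function `G(s)` by zero-order-hold equivalence (exact
   for step stimuli). `G(s)` is summarized by the time constants of its poles
   and zeros and its steady-state gain.
2. **Classification** (`classify_tf`): decide how the underlying first-order
   processes are arranged. Two first-order systems
   `G_i(s) = b_i/(s + omega_i)` (with `omega_i = 1/tau_i`, `b_i = k_i/tau_i`)
   can be combined in exactly three canonical ways:

   * cascade: `G = b_a b_b / ((s+w_a)(s+w_b))` — two poles, no zero;
   * feedback: `G = b_a (s+w_b) / ((s+w_a)(s+w_b+b_b))` — the zero sits at
     the slow process rate;
   * parallel: `G = ((b_a+b_b)s + b_a w_b + b_b w_a) / ((s+w_a)(s+w_b))` —
     the poles are the process rates themselves; addition vs subtraction is
     encoded by the signs of the gains.

   Pole/zero counting settles first-order, cascade and higher-order cases;
   the feedback/parallel decision is made by solving two box-constrained
   least-squares problems that match the monic coefficients `(B1, B0, A1,
   A0)` of the identified `G(s)` to each canonical form, and comparing their
   residual costs `f_valf` and `f_valp`.
3. **Conversion** (`convert_to_scheme`): map the classified `G(s)` to a
   Markov-chain scheme by closed-form rules (below), verify the scheme by
   reconstructing its transfer function, and simulate its occupancies
   (`simulate_scheme`) to overlay `gamma * z_obs(t)` on the data.

```{r example}
tr <- synth_trace("feedback", k_a = -5, k_b = 2, tau_a = 5, tau_b = 200,
                  duration = 1500)
fit <- kinetrace(tr, bounds = scheme_bounds(tau_a = c(1, 9),
                                            tau_b = c(50, 250)))
summary(fit)
```

## Model assumptions

The system is assumed causal, linear and time-invariant over the
measurement, at rest before the stimulus, non-oscillatory (all poles real
and negative), and driven by a known scalar input; the measured output is a
single state occupancy scaled by a constant `gamma` (Markov observable
equation `y = gamma * z_obs`), and total mass follows the input
(`sum_i z_i(t) = u(t)`). Time is in milliseconds and rates in 1/ms
throughout. Baselines are removed by subtracting pre-stimulus means of both
channels, so all quantities are changes relative to the pre-stimulus steady
state: the recovered rates are the rate *changes* induced by the stimulus.

## The kinetic schemes and closed-form rates

With `w = 1/tau`, `b = k/tau` and recovered process parameters
`(k_a, k_b, tau_a, tau_b)` (process a fast, b slow):

| configuration | states (input → …) | rates | gamma |
|---|---|---|---|
| first order | S1 → S2 (obs) | `s1 = w_a` | `k_a` |
| cascade | S1 → S2 → S3 (obs) | `s1 = w_a`, `s2 = w_b` | `k_a k_b` |
| feedback | S1 → S2 (obs) ⇄ S3 | `s1 = w_a`, `s2 = b_b`, `s3 = w_b` | `k_a` |
| parallel addition | S1 → S3 (obs), S1 → S2 → S3 | `s1 = (b_a+b_b)/(k_a+k_b)`, `s2 = w_a - s1`, `s3 = w_b` | `k_a + k_b` |
| parallel subtraction | S1 → S2 (obs) ⇄ S3 | `s1 = w_a`, `s2 = w_b - s3`, `s3 = (b_a w_b + b_b w_a)/(b_a + b_b)` | `(k_a+k_b) w_b / s3` |

These closed forms were re-derived and cross-checked here by exhaustive
enumeration of all mass-conserving wirings of up to four states and three
rates, requiring the scheme's transfer function to reproduce the canonical
`G(s)` exactly with strictly positive rates and occupancies in `[0, 1]`. Two
consequences of that exercise are worth stating plainly. First, for the
parallel-addition scheme the only feasible intermediate rate is
`w_a - s1` (`s1` always lies between `w_b` and `w_a` for same-sign gains, so
`w_b - s1` would be negative). Second, the parallel-subtraction scheme is
realizable only when the transfer-function zero is slower than the slow pole
(`0 < s3 < w_b`); gain pairs whose zero lands at the origin, between the
poles, or in the right half plane (`k_a + k_b = 0`, sums of gains and of
`b`'s with opposite signs, …) admit no scheme in this class, and
`convert_to_scheme()` raises an infeasible-scheme error for them — a
mis-classification signal. The subtraction scheme's observable scaling is
`(k_a+k_b) w_b / s3 = (b_a+b_b) tau_a`, the unique value compatible with the
observable equation and mass conservation (any larger magnitude would
require a fractional occupancy above 1).

`scheme_to_tf()` verifies every conversion by rebuilding `Y(s)/U(s)` from
the Laplace-transformed transition/observable/mass equations
(Faddeev–LeVerrier on the eliminated state space) and comparing it to the
classified `G(s)` over the dynamic band; `simulate_scheme()` integrates the
occupancies exactly (matrix-exponential stepping, exact for sampled inputs
held over one interval) and checks conservation and non-negativity.

## Identifiability: what the bounds do, and what they cannot do

A central and easily overlooked fact: **every** stable two-pole/one-zero
`G(s)` with the zero slower than the slow pole can be written *exactly* both
as a feedback pair and as a parallel pair. The two readings are
observationally equivalent — they generate identical traces — and only prior
knowledge about plausible process speeds and strengths (the
`scheme_bounds()` box) can separate them. `configuration_readings()` returns
both closed-form readings of an identified `G(s)` so a bounds choice can be
audited before a study: a bounds box is *discriminating* for a system when
exactly one reading falls inside it.

The classifier therefore works in two regimes. When the bounds exclude one
reading, its matching problem has a strictly positive constrained minimum
and the cost comparison (`f_valf` vs `f_valp`) decides, as the smaller-cost
rule requires. When both readings are inside the bounds, both problems reach
an exact fit (costs at numerical zero) and the cost comparison carries no
information; the classifier then commits to the reading whose parameters sit
deeper inside the prior box (largest relative margin to the box edges,
compared over the coordinates where the readings differ), flagging the
result ambiguous when the margins are within `margin_tol` of each other.
The margin rule is a tie-break, not evidence: it encodes the judgment that a
reading hugging a prior boundary (for example a recovered `tau_b` within a
few percent of the stated maximum) is less plausible than one comfortably
interior. The same logic resolves the rarer within-problem degeneracy of the
feedback form, which admits two exact pole pairings when `tau_a` priors are
loose.

For validation studies on synthetic data we therefore supply priors that are
informative enough to be discriminating (in the round-trip studies below:
`tau_a` to ±20%, `tau_b` to [0.7, 1.1]×, gains wide open). This is not a
convenience but the method's stated operating condition: with uninformative
priors the scheme is mathematically not unique, and the honest output is
"ambiguous".

## Identification details

* **Orders and selection.** ARX orders are searched over `n_a` in 1..4,
  `n_b` in 1..`n_a`. Selection is by parsimony on the *simulation*
  (output-error) misfit: among all candidates whose simulated response is
  within 10% of the best, the fewest-parameter model wins. One-step
  prediction loss is reported but deliberately not used for selection: with
  band-limited noise it rewards modelling the noise correlation and
  overfits the order.
* **Discrete→continuous.** Poles map by `p = log(z)/Ts`; the continuous
  numerator is solved from a linear system because ZOH discretization is
  linear in the numerator coefficients. Numerically negligible numerator
  terms (relative magnitude below 1e-6) are dropped — a cascade has no
  continuous zero but its discrete model always has a sampling zero — and
  pole/zero pairs closer than `prune_tol` (1%) are cancelled.
* **Noise handling.** Additive measurement noise on `y` enters the lagged
  outputs used as regressors, so ordinary least squares is biased (errors in
  variables); at the oversampling rates typical of these traces the bias is
  severe enough to corrupt the fast pole well before the noise is visible by
  eye. When the pre-stimulus window shows measurable variance the identifier
  therefore (i) low-pass filters *both* channels with a zero-phase
  Butterworth filter (applying the same discrete filter to `u` and `y`
  leaves the difference-equation relation algebraically exact, unlike
  filtering `y` alone or decimating, both of which were measured to distort
  the recovered rates), using constant padding against edge transients, and
  (ii) subtracts the analytically known autocovariance of the filtered noise
  (from the filter response and the pre-stimulus variance estimate) from the
  normal equations — bias-compensated least squares, capped just below the
  matrix-pencil singularity. On noise-free data both steps vanish and the
  estimator is exactly ordinary least squares. The filter cutoff
  (default 0.05 cycles/ms) sits about 1.5× above the 3-dB band edge of the
  widest-band canonical fixtures used here while removing ~95% of wide-band
  noise power; it is a user option for systems on other time scales.
* **lambda-hat.** The disturbance variance is estimated from the
  pre-stimulus sample variance when at least 30 pre-stimulus samples exist
  (this is also the natural sanity check: for white measurement noise the
  two must agree), otherwise from the fit residuals referred to the output
  (`residual variance / (1 + sum(alpha^2))`).

## Noise calibration and the robustness study

`add_noise()` calibrates white Gaussian noise to a target SNR defined as
`P_Y / (2 lambda BW)`: signal power over the post-stimulus window divided by
the noise power within the signal's 3-dB bandwidth (`tf_bandwidth_3db`,
peak-referenced, in cycles/sample). `snr_db()` inverts the same definition
(subtracting the known noise floor from the measured power so the round
trip is unbiased at heavy noise; the per-replicate empirical SNR scatters by
about ±1 dB at the heaviest levels from sampling alone). Brownian noise is
the cumulative sum of white increments; because its spectrum is not flat,
its target-SNR mode rescales the realized path to the requested in-band
power instead of using the flat-spectrum formula.

Note what in-band calibration implies: at a stated in-band SNR the
*per-sample* noise variance is larger by the Nyquist-to-bandwidth ratio —
about 36× for the default fixtures — which is why the estimator-level noise
handling above is load-bearing and why plain least squares fails long before
the in-band SNR looks alarming.

`noise_sweep()` runs the Monte-Carlo robustness study: `n_sim` noisy
replicates per SNR level, full pipeline on each, misclassification
probability `P_e` (any label other than the generating configuration counts
as an error, including ambiguous and higher-order outcomes) and the relative
errors of the recovered transition rates over the correctly classified runs.
With the default study conditions (generators `k_a = -5, k_b = 3, tau_a = 5,
tau_b = 100` in parallel subtraction and feedback; ideal step at 30 ms;
`Ts = 0.25` ms; duration 630 ms; bounds `tau_a` in [1, 9] ms, `tau_b` in
[50, 250] ms, gains in [-20, 20], feedback `k_b` in [0, 20]) the measured
behaviour is: error-free classification and rate errors of a few percent at
35 dB and above, rate errors growing through ~10–30% between 30 and 22 dB,
and a classification breakdown at the lowest levels. The original protocol
this package re-implements reports complete breakdown (`P_e = 1`) already at
18 dB; this implementation still recovers the correct configuration in a
substantial fraction of 18-dB runs, which we attribute to the
noise-compensated estimator — an in-band SNR of 18 dB still leaves the
signal power 63× the in-band noise power, so the information for a correct
call is demonstrably present in the trace. The breakdown *shape* (monotone
increase of `P_e` as SNR falls, errors dominated by wrong-order and
ambiguous outcomes) is reproduced.

## Study sizes used by the validation suite

The packaged tests and the acceptance script use: the full five-scheme
round-trip grid (`tau_a` in {2, 5, 10, 20} ms, `tau_b` in {50, 100, 200} ms,
gains in {-5, -1, 1, 3}, feedback restricted to positive `k_b`, parallel
subtraction restricted to realizable zeros; 436 runs), noise-free; the
two-trace discrimination pair (parallel subtraction -5/3/5/100 vs feedback
-5/2/5/200 under the shared caption bounds above); and Monte-Carlo sweeps
with 100 replicates per SNR level at 18–40 dB. Traces are sampled so the
fast process has at least 20 samples per time constant.

## Limitations

* Oscillatory (complex-pole) systems, time delays, and orders above two are
  out of scope; third-order systems are flagged as higher-order, not
  resolved.
* The feedback/parallel decision is only as good as the prior bounds; with
  uninformative bounds the configurations are provably indistinguishable
  from a single step response, and the classifier reports ambiguity rather
  than inventing a preference stronger than the margin heuristic.
* The synthetic generator emulates ideal steps, stationary white (or
  Brownian) noise and perfectly linear, time-invariant responses. Real
  traces add drift, desensitization, filtering by the recording hardware and
  non-stationary noise, none of which are modelled here; passing the
  packaged studies therefore demonstrates correctness of the algebra and
  estimator under the stated conditions, not field performance on arbitrary
  recordings.
* Gains recovered from voltage-clamp-style traces inherit the input units;
  `gamma` is reported in output units per unit fractional occupancy after
  baseline subtraction.
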