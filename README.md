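# kinetrace

Extract Markov-chain molecular kinetic schemes from macroscopic
stimulus–response traces by linear system identification.

## The problem

Whole-cell currents, receptor-signaling readouts and similar population-level
("macroscopic") measurements sum the activity of many molecules whose
individual dynamics follow a kinetic scheme: a small set of states
(conformations, binding-site occupancies) connected by first-order transition
rates. Different schemes can produce nearly identical traces, so recovering
the scheme — how many processes, how they are wired, and at what rates — is a
genuine inference problem. `kinetrace` solves it for systems built from one
or two first-order processes (e.g. fast activation plus slow inactivation of
an ion channel, or two signaling branches engaged by one ligand).

## The method

Given a uniformly sampled input/output pair `(t, u, y)` (time in ms):

1. **Identify.** Fit an ARX difference-equation model
   `y(t) + a_1 y(t-1) + ... = b_1 u(t-1) + ... + e(t)`
   by prediction-error least squares (bias-compensated against measurement
   noise, with a zero-phase pre-filter applied to both channels), select the
   order by parsimony on the simulated response, and convert to a continuous
   transfer function `G(s)` by zero-order-hold equivalence. `G(s)` is
   summarized by its pole and zero time constants and steady-state gain.
2. **Classify.** Two first-order processes `G_i(s) = b_i/(s + w_i)`
   (`w_i = 1/tau_i`, `b_i = k_i/tau_i`) combine in exactly three canonical
   ways — cascade, feedback, parallel (addition or subtraction by gain
   signs) — each with a distinct pole/zero/gain signature. After order
   checks, the feedback-vs-parallel decision minimizes two box-constrained
   quadratic matching problems and compares their costs `f_valf`, `f_valp`
   (user-supplied parameter bounds carry the discriminating information; see
   the vignette for the identifiability analysis).
3. **Convert.** Analytic rules map the classified `G(s)` to a kinetic scheme
   with `n + 1` states, strictly positive rates `sigma_k` (1/ms) and an
   observable scaling `gamma` (output units per unit occupancy), verified by
   reconstructing the scheme's transfer function and simulating the state
   occupancies against the data (mass conservation `sum z_i = u` holds by
   construction).

A synthetic-trace simulator for the five canonical schemes, calibrated
white-Gaussian/Brownian noise generation, SNR measurement (signal power over
the noise power within the 3-dB bandwidth), and Monte-Carlo robustness
sweeps are included.

## Worked example

A trace is simulated from a known scheme — two processes with gains −5 and 3
and time constants 5 ms and 100 ms combined in parallel (a fast downward
inflection followed by a slow partial recovery, the classic shape of an
activating-then-inactivating current) — and the pipeline is asked to recover
the scheme from the trace alone, with prior ranges `tau_a` in [1, 9] ms,
`tau_b` in [50, 250] ms, gains in [−20, 20]:

```r
library(kinetrace)
tr  <- synth_trace("parallel", k_a = -5, k_b = 3, tau_a = 5, tau_b = 100)
fit <- kinetrace(tr, bounds = scheme_bounds(tau_a = c(1, 9), tau_b = c(50, 250)))
fit
#> Kinetic-scheme fit
#>   G(s): 2 pole(s) tau = {5, 100} ms, 1 zero(s) tau = {242.5} ms, dc gain -2
#>   configuration: parallel_sub
#>   rates: sigma1 = 0.2, sigma2 = 0.005876, sigma3 = 0.004124, gamma = -4.85 (1/ms; gamma in output units)
#>   reconstruction misfit (rel. RMS): 6.87e-10
fit$scheme
#> Kinetic scheme (parallel_sub): 3 states
#>   S1 -> S2   sigma = 0.2 /ms
#>   S2 -> S3   sigma = 0.00587629 /ms
#>   S3 -> S2   sigma = 0.00412371 /ms
#>   observable: S2 (gamma = -4.85); input-linked: S1
```

The identified transfer function has poles exactly at the generating time
constants (5 and 100 ms) and a zero at 242.5 ms; the configuration is
parallel subtraction; `sigma1 = 0.2/ms` is the fast activation rate,
`sigma2` and `sigma3` the slow forward/backward rates whose sum is the slow
process rate `1/100 ms`; `gamma < 0` scales the observable state's occupancy
into the (downward) measured signal. The reconstruction misfit is the
relative RMS difference between `gamma * z_obs(t)` and the observed trace.
`coef()`, `predict()`, `plot()`, `residuals()` and `simulate()` work as for
other fitted-model objects; `summary()` adds the classifier costs, ARX
order, noise estimate and trace SNR.

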