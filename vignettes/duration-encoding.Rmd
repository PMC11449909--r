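---
title: "Modelling stimulus-duration encoding in pheromone-sensitive ORNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stimulus-duration encoding in pheromone-sensitive ORNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ornpulse)
```

## The scientific problem

Male moths track turbulent pheromone plumes in which odor filaments last
from milliseconds to seconds. Whether the very first neuron of the
pathway — the pheromone-sensitive olfactory receptor neuron (ORN) in the
trichoid sensillum — encodes stimulus duration is a question about the
shape of its firing response: moth ORNs respond *phasi-tonically* (a
sharp peak within ~50 ms of onset decaying to a plateau), continue firing
for on the order of a hundred milliseconds after short pulses, and
terminate abruptly — followed by a transient *inhibitory phase* and
later *rebound* activity — after long pulses. `ornpulse` implements the
full modelling chain used to dissect this behaviour:

1. receptor binding/activation kinetics that generate the local field
   potential (LFP) from the odor concentration;
2. a linear–nonlinear (LN) model that predicts the firing rate from the
   LFP through adaptation kernels on two timescales;
3. spike-train statistics (adaptive-bandwidth kernel rate estimation,
   terminating-ISI response-end detection, inhibitory/rebound phase
   comparisons);
4. a single-glomerulus antennal-lobe (AL) spiking network that asks
   whether duration information survives the first synaptic relay;
5. a passive multicompartmental model of the sensillum that links the
   receptor current to the recorded LFP, with its two inverse problems;
6. a synthetic-cohort generator that emulates single-sensillum
   recordings end to end and is itself first-class, tested code.

## Transduction: receptor kinetics and the LFP

Receptors move between unbound (R), bound (OR) and activated (OR\*)
fractions by mass action; the LFP is `beta * OR*` passed through a
first-order low-pass with time constant `tau_lfp = 10` ms. The published
constants are `k_a = 6.57e11`, `s_a = 7.36 1/s`, `k_b = 37.3`,
`s_b = 131 1/s`, `beta = -5.67` mV.

The printed units of the two ratio constants are mutually inconsistent
with the rate expressions (the binding flux `[O] k_b s_b` must be a
rate, yet `k_b` is printed dimensionless while `k_a` carries
M^-1). The package therefore ships three explicit dimensional
conventions (`transduction_params(convention = ...)`):

* `as_printed` plugs the numbers in verbatim. The binding flux is then
  ~5e-8 1/s at the modelled concentration of 1e-11 M, i.e. no response
  develops on the experimental timescale. Kept for fidelity, never
  silently "fixed".
* `swapped` puts the M^-1 on the binding constant. Onset kinetics become
  plausible, but after offset the deactivated receptors are recycled
  through the bound pool (re-activation at `k_a s_a ~ 274 1/s` beats
  unbinding at `131 1/s`), so activation decays with an effective
  ~420 ms time constant.
* `odor_activation` attaches the concentration to the *activation* step,
  consistent with the M^-1 printed on `k_a`. After offset the
  activation flux vanishes and OR\* decays at exactly `s_a` — which is
  the decisive property: the published account attributes the prolonged
  response to short stimuli specifically to the receptor time constant
  `1/s_a ≈ 135` ms. This convention is used by the generator and all
  headline computations.

All recovery analyses are convention-consistent (the same convention is
used to simulate and to refit), so the self-consistency results hold
under any of the three.

Numerically, square-pulse protocols are integrated two ways: an adaptive
explicit Runge–Kutta 5(4) pair (`deSolve`, rtol 1e-7 / atol 1e-9) with
the integration split exactly at valve edges, and a closed-form path
that propagates the linear kinetics segment-by-segment with matrix
exponentials (scaling and squaring). The two agree to ~1e-8 on test
problems; the closed-form path is unconditionally stable for arbitrarily
fast kinetics and is therefore used inside parameter fitting, where
optimizers probe extreme rate combinations.

The five-parameter fit (`fit_transduction`) minimizes the summed squared
error over the first 400 ms after onset of a 20 ms and a 200 ms LFP
trace. Rates and ratios are optimized in log space; a short
Nelder–Mead stage settles into the correct basin before the bounded
quasi-Newton (`L-BFGS-B`) polish — a pure quasi-Newton start can
overshoot into a degenerate fast-activation regime from which it cannot
recover. Trial parameter sets whose propagator overflows receive a large
finite penalty, so line searches back off rather than abort. The loss
weights every sample of both traces equally (the weighting between the
two traces is not otherwise constrained).

## The linear–nonlinear firing-rate model

The firing rate is `f(t) = max(0, c0 * LFP(t) + sum_k c_k (g_k * LFP)(t))`
with unit-area causal exponential kernels `g_k` (`tau = 0` denotes the
delta kernel, i.e. the raw LFP). The published average coefficients are
`c0 = -109.2`, `c1 = 85.8` at 31 ms and `c2 = 18.3` at 635 ms: a fast
drive off the LFP deflection attenuated by adaptation on two
timescales. `c2` is what terminates the response to long pulses sharply
and produces the inhibitory phase; with `c2` forced to 0 after fitting,
short-pulse predictions barely change while the 2 s prediction degrades
severely (the package tests quantify this as relative RMS error).

Timescale identification follows the two-stage protocol: a lasso scan
over a 20 x 17 grid of gamma kernels (time constants log-spaced
1 ms–3 s, shapes 1–5; penalty chosen by seeded 5-fold cross-validation —
the fold count is not otherwise constrained; features are standardized
by default, toggleable) followed by bounded quasi-Newton refinement of
the time constants with shapes held at 1 and coefficients solved by
inner ordinary least squares at every step. The lower bound 0 lets a
component degenerate into the delta kernel; components refined below
half a sample step are folded into `c0`.

Two numerical details matter. Discrete kernels are built from exact bin
integrals of the gamma density (`pgamma` differences), truncated at
1 - 1e-10 coverage and renormalized, so the DC gain is exactly 1 and the
kernel weights vary smoothly with `tau` (which the refinement's
finite-difference gradients require; the step size is 1e-5 s).
Convolutions run via FFT with operands padded to a 2–3–5-smooth length —
unpadded lengths with large prime factors make R's mixed-radix FFT
orders of magnitude slower. A direct O(NM) convolution oracle in the
test suite pins the production path to 1e-10.

Fitting uses the *linear* (unrectified) objective, matching the stated
least-squares procedure; the rectifier participates only in prediction.
The LFP baseline (mean over the pre-stimulus second) is subtracted
before fitting. The reference fit window is the 2 s stimulus plus the
preceding second, sampled at 1 kHz.

## Spike-train statistics

Rates are estimated by kernel density estimation: each spike becomes a
normal density with `sigma = bw/2`. The adaptive width is implemented
exactly as published: `bw_min = 10` ms before onset and
`bw_max - bw_min exp(-t/tau_KDE) + bw_min` after (`bw_max = 100` ms,
`tau_KDE = 500` ms). As printed this jumps to `bw_max` at `t = 0+` and
tends to `bw_max + bw_min = 110` ms; since the surrounding description
suggests a gradual widening, a smooth variant growing from `bw_min` to
`bw_max` is available behind `kde_config(smooth = TRUE)`, but the
printed form is the default — fidelity first.

The response end is the spike initiating the first inter-spike interval
that finishes after stimulus offset and exceeds 100 ms; the interval
after the last spike counts as unbounded, so a neuron that stops firing
during a long stimulus has its response end before the offset. A train
qualifies as a responder with at least 5 spikes in the first 100 ms
after onset (configurable; one published worked example contradicts this
criterion, so the threshold can be disabled). Inhibitory and rebound
phases are compared as spike counts per window length in 0.1–0.4 s and
1–3 s after the response end, with a paired two-tailed Wilcoxon
signed-rank test reporting the smaller rank sum `T` (exact null
distribution for n <= 25 without ties, tie-corrected normal
approximation otherwise; zero differences are dropped, the standard
convention). Dose–contrast relations use Spearman rank correlation with
tie correction.

## The antennal-lobe network

One glomerulus: 10 projection neurons (PNs) and 6 local neurons (LNs)
as leaky integrate-and-fire units with nondimensional potentials (leak
0, threshold 1, excitatory reversal 14/3, inhibitory/SK reversal -2/3),
random Bernoulli connectivity (PN->PN and PN->LN 0.75, LN->PN 0.38,
LN->LN 0.25, no self-connections) and per-PN SK gains drawn from
N(0.5, 0.2) floored at 0. PN spikes drive their own SK conductance
through a two-stage (rise/decay) cascade, producing spike-frequency
adaptation; LN spikes deliver fast and slow inhibition; every neuron
receives an independent Poisson ORN stream at 3 spikes/ms background
plus the stimulus profile scaled to a ~25 spikes/ms peak (100 ORNs).

Two modelling choices deserve emphasis. First, the synaptic increment
convention: the source text's phrase for the conductance increment is
dimensionally indeterminate because the synaptic time constants are not
published. The package uses the standard kick-and-decay convention of
this model family — each presynaptic spike adds the amplitude `S_X`
(the published table values) directly to the conductance, which then
decays exponentially. Second, the time constants themselves are
configuration fields, not published values. The defaults (membrane
20 ms, refractory 2 ms, excitatory/ORN synapses 2 ms, fast inhibition
10 ms, slow inhibition 200 ms, SK rise 35 ms / decay 100 ms) were
calibrated once, by a coarse scan, so that with the published amplitudes
the PNs show the described phenomenology: a few Hz of background
firing, a phasi-tonic stimulus response peaking near 20 Hz, and a
post-offset inhibitory dip. All analyses read these values from
`al_params()`; none are hard-coded.

Integration uses exact exponential decay for conductances and explicit
Euler for the membrane (default step 10 µs, hard cap 100 µs); ORN input
arrives as per-step Poisson counts from R's RNG, so identical seeds give
byte-identical spike output. The simulation kernel is compiled (Rcpp).
Population analyses pool PN spikes over repeated builds/runs; the
reference configuration uses 36 runs.

## The passive compartment model

Four node potentials (inner/outer dendrite, inner soma, outer auxiliary
cells) exchange five passive currents; the outer dendritic potential
`V_ed` is what the recording electrode sees. The stated resting state
(`V_ed = V_ea = -35` mV, `V_id = V_is = -62` mV) forces the offset
potentials `E_ls = -62`, `E_ld = -27`, `E_a = +35` mV — at those values
all five currents vanish identically, which the package verifies both
algebraically and by integrating for a second (drift below 1e-6 mV).
The conductance and capacitance magnitudes are not constrained by that
equilibrium and are not published; the reference set (`G_e = G_i = 1`,
`G_ls = G_ld = 0.2`, `G_a = 1`, `C_md = 0.010`, `C_ma = 0.005`,
`C_ms = 0.020` in relative units) was chosen so the dendritic node
integrates with a time constant of order 10 ms, and everything is
configurable.

Both inverse problems replace one node equation by the numerical
derivative of a target trace (central differences on a <= 0.1 ms grid;
pre-smooth noisy targets, since differentiation amplifies high
frequencies) and integrate the remaining nodes with classical RK4:
`infer_receptor_current` recovers `I_R` from a target LFP, and
`infer_adaptation_current` recovers the somatic `I_ad` from a target
somatic potential under a given `I_R`. Round trips through the forward
model recover the generating currents to well under 1% of peak. The
effective LFP kernel (`estimate_lfp_kernel`) fits a single exponential
from `I_R` to `V_ed` by one-dimensional search with inner least
squares; with the reference parameters the fitted constant is of order
10 ms with a negative gain (depolarizing receptor current deflects the
LFP downward) — a property of the chosen constants, not a universal
number.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws per-sensillum phenotypes around the published
average model and writes spike and LFP files plus a ground-truth
manifest in the package's delimited-text formats. The default
configuration mirrors the study design: 26 sensilla, the 11-duration
pulse series (3 ms–5 s), 10 kHz sampling, 1 s pre-stimulus baseline.
Generation composes the transduction model (LFP, plus additive Gaussian
measurement noise of 0.1 mV), the LN filter on the noiseless LFP, and a
renewal spike generator.

Choices that go beyond the published model, with their anchors:

* **Dose-to-concentration map.** Only the 1 ng recordings have a
  modelled concentration (1e-11 M). The map for lower doses is
  sublinear (`10 pg -> 2.5e-12`, `100 pg -> 5e-12` M), with the 100 pg
  anchor calibrated so that the model's 20 ms / 2 s LFP amplitude ratio
  matches the published average traces (~40%).
* **Background rate.** The species' spontaneous rate (0.34 Hz) plus a
  1.5 Hz residual: sustained post-stimulus activity outlasts the
  2–3 min inter-stimulus gaps of the protocols, so recorded baselines
  and short-pulse rebound windows sit at 1–2 Hz rather than at the
  nominal spontaneous rate. Both components enter *inside* the
  rectifier, so the inhibitory phase silences them.
* **Sustained activity.** After offset, a ramp
  `5 Hz * (1 - exp(-dur/1 s)) * (1 - exp(-(t - t_off)/1 s))` emulates
  the sustained activity that grows with stimulus duration; the
  published model deliberately omits it, but without it the rebound
  window after long pulses would be empty and the inhibitory-vs-rebound
  comparison degenerate.
* **Cell-to-cell variability.** A shared log-normal gain (cv 0.20) on
  all LN coefficients plus small independent per-coefficient factors
  (cv 0.02), and an independent 20% factor on `beta`. Fully independent
  jitter is unphysical here: the net steady-state gain
  `c0 + c1 + c2 = -5.1` is only ~5% of `|c0|`, so uncorrelated 20%
  scatter flips its sign for half the cohort and abolishes tonic
  responses.
* **Spike regularity.** Spikes come from a gamma-renewal process via
  time rescaling (order 4 by default, interval CV 0.5; order 1 recovers
  inhomogeneous Poisson, also available directly as thinning with an
  optional 2 ms dead time). Pure Poisson trains (CV 1) make the 100 ms
  terminating-ISI rule fire on chance gaps in the middle of the decaying
  response tail, which biases the response end early and leaks tail
  spikes into the post-end inhibitory window; strongly driven ORNs fire
  much more regularly than Poisson.

With these defaults the cohort reproduces the core duration-encoding
signatures: the median response end exceeds a 20 ms stimulus by more
than 50 ms but coincides with a 2 s offset to within 50 ms, and the
inhibitory-phase rate is significantly below the rebound rate after 2 s
pulses.

**Known limitation.** The generator is pinned to the LN prediction as
its firing rate, and the published average filter itself predicts a
shallow (~5–8 Hz deep, ~1 s long) sub-baseline suppression after *short*
pulses — the slow adaptation kernel integrates even a 20 ms LFP
deflection into a memory larger than any defensible background rate.
Real ORNs show no inhibitory phase after short stimuli, so the paired
inhibitory-vs-rebound comparison for 20 ms pulses reaches significance
on synthetic cohorts where the real data do not. This is a limitation of
the linear model (which was fitted only to the 2 s response), inherited
by construction; the corresponding expectation in the test suite
documents it as a known failure rather than hiding it. More generally,
passing cohort tests show that the *analysis chain* recovers what the
*model* generates — they cannot certify behaviour on real recordings,
whose trial-to-trial dispersion, drift and artifacts the generator does
not emulate.

## Problem sizes and reproducibility

The reference computations use: 1 kHz sampling for LN fitting (3001
samples over the 2 s stimulus plus 1 s baseline), 1 ms output steps over
400 ms windows for the transduction fit, 0.1 ms grids for compartment
inversions, 10 µs (tests: 20 µs) steps for the AL network with 36
pooled runs, and 10 kHz (tests: 5 kHz) sampling for cohort generation.
Every stochastic operation takes an explicit seed and restores the
session RNG state; identical seeds give identical outputs, including
byte-identical AL spike trains. `scripts/acceptance.R` re-derives the
headline parameter recoveries from scratch, and `validate_invariants()`
re-runs the core invariant checks inside any session.
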