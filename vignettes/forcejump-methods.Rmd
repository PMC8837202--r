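---
title: "Models and methods behind forcejump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind forcejump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcejump)
```

forcejump analyzes force-jump optical-tweezers experiments: a
protein–protein bond held on a DNA tether is alternately relaxed at a low
force (where binding can occur) and loaded at a high constant force until
it ruptures. This vignette is the package's own account of the models it
implements, the choices made where the design was genuinely open, and what
its synthetic-data validation does and does not demonstrate.

## The mechanical circuit

While the bond is intact, the tether contains two entropic springs in
parallel: the *loading* path — two 12-nt single-stranded DNA segments in
series with the bound protein pair, which we treat as a rigid body of
length $L_\mathrm{prot} = 8$ nm — and the *bridge*, the unpaired 55- or
70-nt stretch of ssDNA below it. Both springs follow the interpolated
worm-like chain (WLC) law

$$\frac{F L_p}{k_BT} = \frac14\left(1 - \frac{x}{L_c}\right)^{-2}
  - \frac14 + \frac{x}{L_c},$$

with persistence length $L_p = 1$ nm (ssDNA) and contour length
$L_c = 0.59\ \mathrm{nm} \times n_\mathrm{nt}$. We use the interpolation
formula exactly in this form — no higher-order correction terms — because
the point of the circuit model is a parameter-free *prediction* of the
rupture step, and the formula above is the one standard in this assay's
analysis tradition.

Because the proteins sit on the loading path, the bridge is pre-stretched
by $L_\mathrm{prot}$ relative to the loading coordinate $x$. Bound:
$F_\mathrm{Tot}(x) = F_\mathrm{Bridge}(x + L_\mathrm{prot}) +
F_\mathrm{Load}(x)$; unbound:
$F_\mathrm{Tot}(x) = F_\mathrm{Bridge}(x + L_\mathrm{prot})$. The summed
bound-state force–extension curve is strictly increasing, so the root is
unique; we solve it by Brent bracketing on
$[0,\,0.999\,\min(L_{c,\mathrm{loading}}, L_{c,\mathrm{bridge}} -
L_\mathrm{prot})]$ with an absolute tolerance of $10^{-9}$ nm. The rupture
step is $\Delta x = x_\mathrm{unbound} - x_\mathrm{bound}$ at equal total
force.

**Slack handling.** The WLC is an entropic spring and cannot push: we
assign zero force to negative extensions. At low total force the
pre-stretched bridge can carry the entire load with the loading strand
slack; the bound state then degenerates to the unbound geometry with
$F_\mathrm{Load} = 0$ and $\Delta x = 0$. This choice is not forced by the
equations (which are silent on $x < 0$) but by the physics, and it matches
the relaxed low-force state of the assay.

**Thermal energy.** $k_BT = 4.09$ pN·nm, i.e. 296 K (23&nbsp;°C, the
assay temperature); configurable everywhere it appears.

## Event detection

High-force plateaus are analyzed one at a time:

1. **Settling skip.** The first `skip_initial_samples` (default 5, i.e.
   25 ms at 200 Hz) are dropped. The instrument's response (~5–10 ms)
   low-passes the large position jump between force levels, so the first
   few samples of a plateau still relax toward the new level; including
   them corrupts the centering baseline below. The skipped duration is
   added back to reported lifetimes, so $\tau$ is still measured from the
   force jump. Events rupturing inside the skip window are lost; together
   with the four-sample minimum this makes the shortest observable dwell
   $c = (5+4)/200\ \mathrm{Hz} = 45$ ms (see *Truncation-aware fitting*).
2. **Centering.** The mean of the first five (post-skip) samples is
   subtracted, putting the bound level near zero.
3. **Noise.** The effective noise SD (eSD) is the median over all
   10-sample sliding windows of the within-window SD — robust to the one
   level change a plateau may contain.
4. **Decoding.** A two-state hidden Markov model with Gaussian emitters at
   0 and $+4$ eSD (both SD one eSD), initial state bound, and a transition
   matrix that only allows bound→unbound (the unbound state is absorbing)
   is decoded with the Viterbi algorithm. With this structure the decoded
   path has at most one changepoint, so Viterbi is mathematically a
   single-changepoint maximum-likelihood scan; the test suite exploits
   this by checking the dynamic program against an independently written
   exhaustive scan (500 seeded plateaus, exact index agreement). The
   per-sample transition probability `p_trans` (default $10^{-3}$) acts as
   a detection threshold, not a location parameter: tests verify the
   changepoint is invariant over `p_trans` $\in [10^{-5}, 10^{-2}]$ for
   steps $\geq 3$ eSD. Emission centers are *fixed* at 0/+4 eSD regardless
   of the true step; the step itself is re-estimated from sample means, so
   a mis-specified separation affects sensitivity, not the estimate.
5. **Extraction.** $\tau$ = (bound samples + skip)/sampling rate; $\Delta
   x$ = difference in means over an equal number of samples immediately
   before and after the changepoint (count set by the binding duration,
   limited by availability).

### Acceptance filters

Real traces drift, and the original analysis tradition relies on manual
inspection ("clearly instantaneous" changes). forcejump replaces that with
a declared, reproducible battery; every threshold is configuration:

- **Minimum 4 bound samples** (the classic four-data-point rule) and,
  symmetrically, **minimum 4 post-changepoint samples**. The latter is
  needed because a "changepoint" placed in the last 1–3 samples of a
  plateau rests on too few points for any level change to be estimated;
  in negative-control simulations such tail artifacts were the dominant
  false-event class.
- **Instantaneous-step screen.** The event's $\Delta x$, and the level
  change between 5-sample windows flanking the changepoint, must both
  exceed `min_step_esd` × eSD (default 2 — half the assumed emitter
  separation). Slow drift can accumulate enough total displacement to
  cross the decoding threshold, but produces no *local* step; a genuine
  rupture changes the level within the instrument response time. Without
  this screen, typical per-molecule drift turns most unbound plateaus
  into false events.
- **Transition span.** More than `max_transition_span` (default 3)
  consecutive samples sitting between the two levels likewise indicates a
  gradual change and rejects the event.
- **Drift screen and truncation.** If the post-rupture slope exceeds
  `drift_slope_esd_per_s` × eSD per second (default 0.5) *and* is
  statistically resolvable (>3 standard errors), the plateau is truncated
  to ±`drift_window_samples` (default 100) around the changepoint before
  the step is re-estimated; the lifetime keeps its full-plateau value.
  The 0.5 eSD/s default is deliberate: realistic drift rates are of order
  0.1–1.5 eSD/s, and a screen that only reacts above 2 eSD/s would
  almost never fire. The 3-SE gate prevents the screen from triggering on
  noisy slope estimates over short post-rupture windows.

With the default thresholds, seeded negative-control corpora (no binding,
with drift) of 2000 plateaus produced zero accepted events, and clean-step
simulations (step = 4 eSD, dwell ≥ 5 samples) were recalled at ≥95% —
both asserted in the test suite.

Plateaus that end with the system still bound are discarded rather than
right-censored: plateau durations are chosen long enough (≥5 s) that the
surviving fraction is negligible for the lifetimes of interest
($e^{-5/\bar\tau} < 0.2\%$ at the chevron peak of the default truth).

## Lifetime statistics and the catch-slip fit

Events are grouped by construct and trap force, or — after mapping through
the circuit model — by the load actually borne by the proteins, which lets
the two bridge constructs (which sample different loads at equal trap
force) be pooled on one axis. Each group reports mean ± SEM, molecule
count, and off-rate $1/\bar\tau$; the survival curve is $1 - \mathrm{ECDF}$
with the conventional terminal $0 \to 0.01$ replacement applied *only* to
the plotting copy, never to fits. Single-exponential survival fits use
free amplitude (the printed form $S = A e^{bt}$ has one), unweighted, on
the observed lifetimes only.

The catch-slip Bell model

$$\bar\tau(F)^{-1} = k_{c0}\,e^{F x_c / k_BT} + k_{s0}\,e^{F x_s / k_BT},
 \qquad x_c < 0 < x_s,$$

is fitted to mean lifetime versus load by weighted Levenberg–Marquardt
with box constraints that pin the pathway identities (preventing the
catch/slip label swap), multi-start over log-spaced distance parameters
with rate prefactors initialized from the endpoint off-rates, and
linearized-covariance 95% intervals. The critical force is the closed
form $F^* = k_BT \ln(-k_{c0} x_c / (k_{s0} x_s))/(x_s - x_c)$, which the
tests verify against a dense grid argmax.

**Weighting.** Weights are $1/\mathrm{SEM}^2$, but the SEM used for
weighting is floored at the model-implied value $\bar\tau/\sqrt{n}$ (dwell
times are exponential, whose SD equals its mean). The empirical SEM of a
group with two or three events can be arbitrarily small by chance; left
unfloored, such a group acquires near-infinite weight and visibly distorts
the fit. Single-event groups are kept (SEM reported as 0 with a flag) and
receive their model SEM in the weights.

**Truncation-aware fitting.** Discarding dwells shorter than the detection
floor $c$ inflates the observed mean of an exponential by exactly $c$
(memorylessness: $E[\tau \mid \tau > c] = c + \bar\tau$). When
`truncation_s = c` is supplied, the fit uses the observation model
$\bar\tau_\mathrm{obs}(F) = c + \bar\tau_\mathrm{model}(F)$. This matters
at high load, where $\bar\tau$ is comparable to $c$ and the uncorrected
slip branch is strongly biased. Group summaries themselves are left
uncorrected — they describe the observed events — and the correction
defaults to off.

Binding isotherms $Y = Y_\mathrm{max}[S]/(K_D + [S])$ are fitted by the
same constrained Levenberg–Marquardt; a fit whose $K_D$ lands far beyond
the titrated range (50× the top concentration) is reported as
unidentifiable rather than returned.

## The synthetic-data generator

`simulate_session()` emulates the assay's statistical structure: cycles of
a 0.5 pN low plateau and a high plateau (4–12 pN, round-robin), 5 s each
at 200 Hz. At each jump a bond is present with probability `p_bind`
(default 0.3; the per-cycle binding fraction is a free choice — it sets
only the event yield, not the kinetics). A present bond survives an
$\mathrm{Exp}(\bar\tau(F_\mathrm{Load}))$ time drawn from the ground-truth
catch-slip law at the circuit-model load, then the position steps by the
circuit-model $\Delta x$ — so simulated steps lie exactly on the model
curve before noise. On top of the ideal trace: a single-pole instrument
low-pass (7.5 ms time constant; the force jump itself is treated as
instantaneous since the real loading rate crosses a sample interval),
per-molecule linear drift with rate drawn from $N(0, 0.5^2)$ nm/s to
exercise the drift screens, and iid Gaussian position noise (default SD
1 nm — typical trap position noise at this bandwidth, which makes the
smallest default step, 55-nt bridge at 4 pN, 3.4 eSD and all others
larger).

What the generator deliberately does **not** model: low-force binding
kinetics (collapsed to one Bernoulli outcome per cycle), rebinding within
a high plateau (the decoded chain treats unbound as absorbing), bead/trap
compliance and feedback dynamics, the dsDNA handles (irrelevant to the
$\Delta x$ circuit), and non-linear or correlated noise. Passing the
end-to-end tests therefore demonstrates that the pipeline is correct and
unbiased *under its own model assumptions* — it does not certify
performance on traces whose noise or drift departs from these forms.

## Validation scale

The test suite and acceptance script size their simulations to run on one
CPU in a few minutes while keeping estimates meaningful: end-to-end
recovery uses corpora of 5 molecules × 60 cycles per construct (about 130
accepted events across 10 load levels per corpus) over 5–10 replicate
seeds, with medians compared to truth; changepoint decoding is checked on
500 random plateaus; isotherm recovery on 50 replicate titrations;
negative controls on ≥1000 plateaus; confidence-interval coverage on 200
group-level refits at 30 events per group.

## Known limitations

- Lifetimes are quantized to the 5 ms sample interval and carry a small
  positive delay (~1 sample) from the instrument low-pass; both are far
  below the truncation and statistical uncertainties at realistic event
  counts.
- The truncation correction assumes a sharp detection floor; in reality
  acceptance near the floor is probabilistic over ~1 sample.
- Linearized confidence intervals undercover mildly in the small-sample,
  strongly-correlated regime typical of Bell-model fits (the test suite
  requires ≥85% empirical coverage at nominal 95%); profile likelihood
  would be the next refinement.
- The fit treats group means as independent; events from the same
  molecule share calibration and drift environment, so molecule-level
  clustering is ignored.
- Monotone (pure-slip or pure-catch) lifetime data are refused with a
  structured error naming the missing branch rather than extrapolated.
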