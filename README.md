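# forcejump

Analysis of single-molecule **force-jump optical tweezers** experiments in
which a protein–protein bond, held in the middle of a DNA tether, is loaded
at constant force until it ruptures. Rupture is read out as a position step
Δx, and repeating the jump cycle yields a distribution of bond lifetimes at
each force. The package is aimed at single-molecule biophysicists who want a
reproducible, scriptable version of this analysis chain — including users
studying **catch bonds**, whose lifetime *increases* with tension up to a
critical force.

## What it computes

**Mechanical circuit.** The tether is two nonlinear springs in parallel: a
"loading" strand (24 nt of ssDNA in series with the inextensible bound
protein pair, length `L_prot` = 8 nm) and a ssDNA "bridge" (55 or 70 nt).
Each spring follows the interpolated worm-like chain law

    F·Lp/kBT = 1/4 (1 − x/Lc)^−2 − 1/4 + x/Lc

with Lp = 1 nm and 0.59 nm per nucleotide. Bound:
`F_Tot(x) = F_Bridge(x + L_prot) + F_Load(x)`; unbound, all force moves to
the bridge. Solving both states gives the load on the proteins `F_Load` and
the predicted rupture step `Δx` at any trap force.

**Event detection.** High-force plateaus are centered on their first five
samples, the effective noise SD (eSD) is the median of 10-sample sliding
window SDs, and a two-state hidden Markov model — Gaussian emitters at 0 and
+4 eSD, transitions allowed only bound→unbound — is decoded by the Viterbi
algorithm. The changepoint gives the bond lifetime τ; Δx is the mean level
change over equal windows before/after. Acceptance filters (minimum 4
samples on each side, an instantaneous-step screen, and a drift screen with
truncation) reject drift artifacts.

**Kinetics.** Lifetimes are pooled by construct and force (or by `F_Load`,
letting the two bridge constructs sample different loads at the same trap
force), summarized as mean ± SEM, and survival curves `S(t) = 1 − ECDF`
are fitted with single exponentials `S = A·e^{bt}`.

**Catch-slip Bell model.** Mean lifetime versus load is fitted to the
two-pathway form

    1/τ̄(F) = kc0·exp(F·xc/kBT) + ks0·exp(F·xs/kBT),   xc < 0 < xs

with weighted Levenberg–Marquardt, multi-start initialization and sign
constraints; the critical force is the closed form
`F* = kBT·ln(−kc0·xc/(ks0·xs))/(xs − xc)`. Single-site binding isotherms
`Y = Ymax·[S]/(KD + [S])` are fitted for thermophoresis titrations.

**Synthetic data.** `simulate_session()` generates complete force-jump
sessions (0.5 pN low / 4–12 pN high plateaus, 200 Hz, Gaussian noise,
per-molecule drift, single-pole instrument response) with exponential bond
lifetimes following a ground-truth catch-slip law, so every stage can be
validated end to end.

## Worked example

```r
library(forcejump)

truth <- bell_params(kc0 = 5.3, xc = -2.0, ks0 = 0.01, xs = 4.1)
print(truth)
#> Catch-slip Bell model
#>   kc0  = 5.3 1/s
#>   xc   = -2 nm
#>   ks0  = 0.01 1/s
#>   xs   = 4.1 nm
#>   critical force = 3.72 pN (kBT = 4.09 pN nm)

g55 <- tether_geometry(55)
predict_delta_x(6, g55)       # model step size at 6 pN, 55-nt bridge
#> [1] 4.769202

# simulate both constructs, detect events, pool on the load axis, refit
cfg    <- simulation_config(truth)
traces <- simulate_corpus(cfg, seed = 1)
geoms  <- list(`55` = tether_geometry(55), `70` = tether_geometry(70))
events <- do.call(rbind, lapply(traces, function(tr)
  detect_events(tr, geoms[[as.character(tr$construct)]])))
groups <- group_and_summarize(events, axis = "F_Load")
fit    <- fit_catch_slip(groups, truncation_s = 9 / 200)
print(fit)
#> Catch-slip Bell model
#>   kc0  = 6.29 +/- 4.4 1/s
#>   xc   = -1.78 +/- 1.2 nm
#>   ks0  = 0.00269 +/- 0.0073 1/s
#>   xs   = 5 +/- 1.7 nm
#>   critical force = 4.06 pN (kBT = 4.09 pN nm)
```

The recovered distance parameters and critical force agree with the
generating truth within their confidence intervals; `truncation_s` tells
the fit that dwells shorter than the 45 ms detection floor were discarded.

The same chain is available as a config-driven pipeline
(`fj_simulate()`, `fj_detect()`, `fj_fit()`, `fj_run_all()`) and as a
command-line script:

```sh
Rscript inst/cli/forcejump.R run-all --seed 1 --out out/
```

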