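---
title: "Models and methods: inferring wound chemoattractant dynamics from immune-cell tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: inferring wound chemoattractant dynamics from immune-cell tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemotaxis)
```

## The problem

Laser wounds in the translucent epithelium of a *Drosophila* pupal wing
recruit hemocytes — the fly's innate immune cells — within minutes. The
recruiting chemoattractant cannot be observed directly; what can be observed
is the cells: nuclear-labelled hemocytes tracked at roughly one frame per
minute across a few hundred micrometres of tissue for an hour or two after
wounding. This package treats those trajectories as the *measurement* of the
invisible gradient: it models cell headings as a biased persistent random
walk (BPRW), links the bias to a diffusing attractant through receptor
occupancy, and inverts the whole chain by Bayesian inference to recover the
attractant's diffusion coefficient, the duration of its active production,
and the geometry of its source.

## The heading model

A cell's displacement between consecutive frames defines a motion vector
with heading $\theta_t$. Two angles summarise each step: the turning angle
$\alpha_t = \theta_t - \theta_{t-1}$ (persistence) and the wound angle
$\beta_t = \theta_t - \phi_t$, where $\phi_t$ points from the step origin
toward the wound (bias). The BPRW gives each step a two-component mixture
density

$$f(\theta_t) \;=\; w\,V\!\big(\theta_t;\ \phi_t,\ \kappa(b)\big)
  \;+\; (1 - w)\,V\!\big(\theta_t;\ \theta_{t-1},\ \kappa(p)\big),$$

with $V$ the von Mises density. The bias $b$ and persistence $p$ are
expressed as *mean resultant lengths* — $\kappa(\cdot)$ inverts
$A(\kappa) = I_1(\kappa)/I_0(\kappa)$ — so both live on the same 0–1 scale:
0 is a uniformly random heading, 1 a deterministic one. $w$ is the per-step
probability that motion is biased rather than persistent.

Two reporting subtleties follow from the mixture form:

* **$b$ versus $w\,b$.** In a cohort with no real bias the weight $w$
  collapses to zero and $b$ becomes unidentifiable (the likelihood is flat
  along the ridge $w \to 0$). The *observed bias* $w\,b$ is identifiable in
  all regimes, so summaries that must behave at zero bias (unwounded
  controls, wave detection, prognosis) default to the composite; per-cluster
  tables expose both.
* The von Mises kernel is a package choice — the 0–1 axis semantics force a
  mean-resultant-length parameterisation but not a specific kernel. A
  wrapped-normal variant would change nothing structurally.

## Per-cluster inference

Steps are pooled into five 100-µm distance bands from the wound edge
(S1–S5) and five 20-min windows after wounding (T1–T5), both half-open.
Each cluster is fitted independently (no pooling or shrinkage) by adaptive
random-walk Metropolis on the logit scale under uniform priors; summaries
use the 5/25/50/75/95 percentile convention. Clusters under 50 usable steps
are reported as "insufficient data" rather than estimated. Distance is
measured from the wound *edge* by default (the inferred source is the
margin); centre-referenced distance is a flag.

## The attractant model

The attractant obeys 2D diffusion with diffusion coefficient $D$, released
at constant rate for a production duration $T$ after wounding, from either
the wound-margin ring (circumference $2\pi R$, strength $q$ per unit
length) or the damaged disc (area $\pi R^2$, strength per unit area). The
free-space ring solution is a single quadrature over emission age $u$:

$$C(r, t) = \int_{\max(0,\,t-T)}^{t} \frac{q R}{2 D u}
  \exp\!\Big(-\frac{r^2 + R^2}{4 D u}\Big)
  I_0\!\Big(\frac{r R}{2 D u}\Big)\, du .$$

Numerics worth knowing about:

* **Similarity caching.** The kernel depends on $(r, D u)$ only, so one
  lattice per wound radius in the variable $v = D u$ serves *every*
  $(D, T)$ proposal during MCMC; a likelihood evaluation is then pure
  interpolation (about 1 ms for 50,000 steps). Accuracy against the
  adaptive-quadrature form is ~0.5% at the reference $D$ and degrades only
  where the posterior carries no mass ($D < 20\ \mu m^2$/min).
* **Bounded solver.** Near wing margins, free space is wrong; a
  finite-difference solver on the domain mask with zero-flux boundaries
  (flux only between interior cell pairs, hence exactly conservative)
  captures attractant accumulation at boundaries. Sources deposit mass via
  fine sampling of the ring/disc geometry so the effective source matches
  the continuous one well below the grid scale. The solver is validated
  against the free-space forms (<2% far from boundaries), a
  method-of-images oracle (<3%), and linearity/conservation identities.
* **Decay.** Pure diffusion (no clearance) is the default and the model
  under which all inference runs. A first-order clearance knob exists; see
  "Desensitization" for the one place the presets use it.

## Linking field to behaviour

A cell of sensing length $\ell$ converts the local field into bias through
the receptor-occupancy difference across its body,

$$\Delta u = \ell\, \lvert\nabla C\rvert\, \frac{K_d}{(C + K_d)^2},
\qquad b_{\mathrm{eff}} = \min\!\big(b_{\max},\ b_0 + s\,\Delta u\big),$$

pointing up-gradient. $\Delta u$ vanishes both without a gradient and in
saturation ($C \gg K_d$) — the regime that makes cells near very large
wounds lose orientation. The functional form is deliberately isolated
behind one interface; the data constrain only the composite scale
$s\,\ell\,q / K_d$ at low occupancy, which is why the gradient inference
fixes the link shape constants and lets $q$ carry the scale (a posterior
over $q$ and over $s$ separately would be a ridge, not information).

## Gradient inference and model selection

The gradient fit estimates $(D, T, q, b_0, p, w)$ jointly from one or more
single-wound datasets: each step's $b_{\mathrm{eff}}$ and biased direction
come from the candidate field, and the BPRW mixture supplies the
likelihood. Fitting small and large wounds jointly shares all parameters
and lets only the wound radius differ — so margin scaling (total strength
proportional to circumference, not area) is a testable consequence, not an
assumption. Priors: $D$ uniform on $[1, 5000]$ µm²/min, $T$ uniform on
$[1, 120]$ min, $q$ log-uniform over four decades, the unit-interval
parameters uniform. Four-to-two adaptive Metropolis chains with
Gelman-Rubin and effective-sample-size diagnostics; a fit whose posterior
on $\log D$ is not much tighter than the prior (or whose chains disagree)
is flagged unidentified instead of summarised.

Margin versus disc source geometry is compared by WAIC on identical data
(Akaike-type weights), with a data-hash guard against accidentally
comparing fits of different datasets. An ABC-SMC route (per-cluster
circular-moment summaries, L2 distance, shrinking tolerances, bounded
simulation budget per generation) is provided as a likelihood-free
cross-check; it is much more expensive and correspondingly coarser, and
the package treats the tractable likelihood as primary. Measured at desk
scale, the moment-summary distance is nearly flat along a $D$–$T$ ridge
(doubling both is almost indistinguishable) and its simulation-noise floor
exceeds the $T$ signal at feasible cohort sizes, so the ABC route should
be read as a sanity check on $D$'s order of magnitude, not as an
independent estimate of $T$.

## The simulator and the stated world

The agent-based simulator closes the loop: cells start uniform in a
rounded-rectangle wing (900 × 450 µm), step once per minute with
gamma-distributed step lengths (mean 3 µm/min, shape 2 — speeds only add
realism; angles alone enter the inference), draw headings from the BPRW
using the local $b_{\mathrm{eff}}$, and reflect specularly at the domain
boundary. Scenario presets encode the modelled experiments: wound radii
27.5/55/65 µm (55/110/130 µm diameters), synchronous wound pairs 150/330/480
µm apart, sequential wounds at +90 min and +3 hr, and healer-like versus
chronic-like cohorts.

Reference constants on the relative concentration scale ($q = 1$ per µm of
margin per minute): $K_d = 0.1$ (just below the peak concentration at a
large wound's margin, so standard wounds stay sub-saturating), $s = 11$ and
$\ell = 10$ µm (the near band of a large wound peaks at
$b_{\mathrm{eff}} \approx 0.6$–0.7), $b_0 = 0.05$ (very low basal bias),
$b_{\max} = 0.85$, $p = 0.5$, $w = 0.5$. These were fixed once, before the
validation suite was written, from tabulated field profiles.

### Desensitization

Exposure to the first wound's attractant temporarily blinds cells to later
wounds; sensitivity returns between 90 min and 3 hr. The package implements
the simplest mechanism consistent with that bracket: a cell whose local
concentration exceeds a trigger becomes refractory (baseline bias only) for
$\tau = 120$ min, re-triggering if the ambient level still exceeds the
trigger at expiry.

One genuine physical obstruction surfaced here. In pure 2D diffusion
without clearance, the ambient concentration after the wave decays only
like $1/t$, staying at the same order as the wave tail — so *no* single
concentration threshold can both fire during the wave at second-wound
distances and release cells by +3 hr. The sequential-wound presets
therefore enable the clearance knob (0.03/min, half-life ≈ 23 min), which
restores a pulse-like exposure profile; with the trigger at 0.002 (relative
units) every cell within ~300 µm of the first wound is desensitized during
the first hour and resensitized by ~175 min. Two known limitations follow:
the threshold mechanism truncates each wound's *own* response shortly after
local trigger crossing (the in vivo first response is normal, so the true
mechanism is presumably adaptive rather than absolute), and clearance is
used only in these presets, never in inference.

## The synthetic-data generator

`generate_dataset()` corrupts simulator tracks the way nuclear tracking
does: isotropic Gaussian positional noise (default σ = 0.5 µm) and
per-frame detection dropout (default 2%), with tracks *split* at gaps —
interpolating across a gap would fabricate headings. A manifest (JSON)
regenerates any dataset bit-for-bit. What a green end-to-end test
establishes is therefore recovery under the model's own assumptions plus
small tracking noise; it does not establish robustness to segmentation
artefacts, z-projection errors, cell division/death, or non-stationary
baseline behaviour, none of which the generator emulates. Positional noise
visibly deflates persistence estimates (heading jitter scales as
$\sqrt{6}\,\sigma / v$), which is a real misspecification the recovery
targets absorb.

## Prognosis rule

A chronic (non-healing) wound announces itself early: hemocytes near the
wound show neither bias nor normal persistence in the first half hour. The
rule fits the BPRW to steps in the 0–100 µm band within 30 min and calls
"non-healer" only when *both* the observed bias $w\,b$ falls below 0.1 and
the persistence median falls below (baseline − 0.1) = 0.4; when both
posteriors straddle their thresholds the call is "indeterminate". The bias
threshold sits between the healthy scale (~0.2) and the chronic scale
(~0.03) measured in the reference world; the validation suite requires at
least 18 of 20 correct calls on a paired synthetic panel at these
defaults.

One wave detail is worth stating precisely: with a 30-min production
duration the near-field gradient keeps growing until production stops, so
in the simulated reference world the 0–100 µm band's bias is near-flat
across the first two 20-min windows with its pooled maximum in 20–40 min,
while bands further out peak strictly later (the outward wave). The
in-vivo observation of the strongest near-band rise within the first 20
min is reproduced as an immediate, large T1 response, not as a strict T1
maximum.

## Degenerate inputs and tie-breaks

Zero-length steps carry no heading: they are excluded from angle
likelihoods and counted separately. Cluster edges are half-open ([0, 100)
µm etc.); a step at exactly 100 µm belongs to S2. A reflected move that
cannot be resolved in four folds leaves the cell in place for that frame.
Empty clusters render as missing, never as zero. All randomness flows from
one integer seed through a deterministic stream splitter.

## Known limitations

* Free-space fields inside the inference likelihood ignore wing-boundary
  accumulation (the bounded solver exists for simulation; using it inside
  MCMC would be ~100× slower). For wounds near margins this biases $q$
  upward slightly before it biases $D$ or $T$.
* No hierarchical pooling across wings; no continuous-time likelihood; no
  Lévy or run-and-tumble variants.
* The desensitization mechanism is a threshold caricature (see above).
* Arrival at the wound is purely positional; cells do not adhere or stop.
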