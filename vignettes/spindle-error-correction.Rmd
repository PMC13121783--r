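---
title: "A stochastic spindle model of kinetochore-microtubule error correction"
author: "spindleflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic spindle model of kinetochore-microtubule error correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindleflux)
```

## The model

`spindleflux` simulates a one-dimensional metaphase spindle: two fixed
poles a spindle length apart, one pair of sister kinetochores joined by a
linker of stiffness $\kappa_1 = N\kappa$ ($\kappa$ = 0.01 pN/nm, rest
separation $x_0$ = 0.5 µm), $2N$ kinetochore microtubules (kMTs, $N$ per
pole) and $N$ antiparallel bridging-microtubule (bMT) pairs.  Every
microtubule is a rigid discrete tubulin lattice (site size $d$ = 8 nm)
anchored to its pole by a $\kappa_3$ spring; an attached kMT couples to a
sister kinetochore through a $\kappa_2$ linker.  Springs equilibrate
instantaneously relative to the 1-ms event clock, so each tick solves a
small linear balance: an attached kMT acts as a spring of stiffness
$\kappa_2\kappa_3/(\kappa_2+\kappa_3)$ anchored at its relaxed plus-end
position.  Pulling forces on a plus end are positive; pushing negative.

Poleward flux is generated microscopically: plus ends polymerize
(tubulin added with probability $v/d\,h$ per tick) while kinesin-13
depolymerases remove tubulins at the minus end.  Kinesin-13 motors bind
the lattice outside antiparallel overlaps, diffuse, are carried toward
the minus end by the lattice turnover, and while resident at the minus
end remove tubulins at rate $k_{dep}$ for up to $\tau_{end}$ before
leaving (or earlier, when a trailing motor bumps them off during a
removal).  Kinesin-5 motors bind only inside the antiparallel bMT
overlap and step toward the plus ends; NuMA crosslinks parallel bMTs.

An attached kMT grows at $v_{pol} = (v_{p0}/B)\,(1 + F/F_{p0})$; a
detached kMT and every bMT grow at $v_{p0}$.  Detachment follows the
catch–slip law
$1/\tau_{att} = k_1 e^{F/F_2}(1-e^{-F/F_1}) + k_2 e^{F/F_2} e^{-F/F_1}$
(lifetime maximal, about 50 min, near 5 pN), multiplied by the Aurora-B
tension factor $X_{detach} = 1 + A\,e^{-b\,(x - x_0)}$, which is largest
(65-fold) when the interkinetochore stretch vanishes.  A detached kMT
reattaches to either sister with rate
$k_{att}(y) = k_{att}(0)\,e^{-\alpha \kappa_2 |y|}$ in the distance $y$
from its plus end.  All events are per-entity Bernoulli trials on a fixed
step $h = 10^{-3}$ s; doubling $h$ leaves the summary statistics within
stochastic tolerance.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| $k_1, k_2$ | 6.6e-4, 7.7e-2 | 1/min | catch/slip prefactors |
| $F_1, F_2$ | 1.07, 1.86 | pN | catch/slip force scales |
| $A$, $b$ | 64, 50 | –, 1/µm | Aurora amplitude and tension sensitivity |
| $k_{att}(0)$, $\alpha$ | 100, 0.05 | 1/s, 1/pN | reattachment at contact, distance sensitivity |
| $\kappa$, $\kappa_2$, $\kappa_3$ | 0.01, 0.1, 0.1 | pN/nm | spring network |
| $v_{p0}$, $B$, $F_{p0}$ | 20, 1.15, 33.3 | nm/s, –, pN | plus-end growth law |
| $k_{dep}$, $\tau_{end}$ | 2.5, 150 | 1/s, s | minus-end removal while resident |
| kinesin-13 kon·conc, kdiff | 3e-4, 200 | 1/s per site, 1/s | lattice binding, hop rate |
| spindle length | 12 | µm | fixed pole separation |

The spring constants, the detachment-law constants, $A$, $x_0$,
$k_{att}(0)$, $\alpha$, $b$ and $v_{p0}$ are the published values.  The
motor rate tables of the source model are not available, so the motor
constants and $(B, F_{p0})$ are package defaults calibrated once against
the printed anchors: measured kMT flux $\approx$ 20 nm/s at
$v_{p0}$ = 20 nm/s, mean plus-end force $\approx$ 5 pN (which pins
$F_{p0}(B-1) = 5$ pN), and millisecond-scale reattachment after
transient detachment.  With $k_{dep} = 2.5$/s the minus end removes
exactly one flux-worth of lattice while occupied, and the binding rate
is set so the minus end is almost always occupied, with waiting motors
taking over seamlessly; this keeps the per-kMT force fluctuation near
$\pm$2 pN, matching the narrow published force distribution.  The pair
$(B, F_{p0}) = (1.15,\ 33.3)$ keeps the force anchor exact while making
the growth response shallow enough that merotelic churn can correct an
attachment before the erroneous intermediate's lengths adapt and freeze
it in.

## Numerical choices and degenerate inputs

* **Quasi-static mechanics.** No drag constants are specified; 0.1-pN/nm
  springs relax far faster than the 1-ms event clock, so positions are
  the static solution each tick.  With no attachments at all the
  kinetochores hold their previous positions.
* **Pushing forces.** The detachment law is clamped at $F = 0$ (it was
  fit to pulling data; extrapolating the catch branch to compression
  would produce unphysically long lifetimes).  The growth law uses the
  signed force with the speed floored at zero, so growth stalls at
  $F = -F_{p0}$: without this, an over-long kMT would keep growing
  against arbitrary compression and run away.
* **Aurora at compression.** $X_{detach}$ diverges for $x < x_0$; the
  stretch is clamped at zero so $X_{detach} \in [1, 1+A]$, reading the
  65-fold enhancement as the saturated zero-tension level.  Without the
  clamp, any transient compression detaches the whole spindle within
  milliseconds.
* **Minus-end residence.** A kinesin-13 at the first site neither
  diffuses away nor unbinds at the lattice off-rate; it leaves at
  $\tau_{end}$ or by bumping, which reads the residence time as governed
  by the pole-localised machinery.
* **Zero-length lattices.** A kMT shortened to its pole keeps a
  nucleation stub and may regrow (needed for the scenarios in which
  opposite-pole kMTs start at zero length).
* **Probability overflow.** Fixed rates must satisfy
  $\text{rate}\cdot h \le 0.5$; the force-dependent detachment and
  distance-dependent reattachment probabilities are capped at 1 (a kMT
  at enormous slip force simply detaches within the tick).
* **Ties.** When both sisters' reattachment trials fire in one tick the
  nearer sister wins; exact ties are resolved by a fair coin.

## Design choices where the design was open

* **Fixed poles.** The antecedent spindle-length-regulation machinery is
  out of scope; poles sit 12 µm apart.  Three consequences are accepted
  and documented: bMT length has no intrinsic stabilizer (bMT plus ends
  pause within 200 nm of the opposite pole, leaving a broad central
  overlap); kinesin-5 accumulates no load (lattice flux absorbs its
  stepping), so the simulator steps it at unloaded rates while the
  load-dependent laws remain exported and tested; and the measured flux
  cannot re-equilibrate to track $v_{p0}$ far from the calibration
  point the way a length-adaptive spindle would.
* **Single kinetochore pair.** The published monotelic/syntelic figures
  add a second, bi-oriented pair only to stabilise spindle length; with
  fixed poles that pair is mechanically decoupled, so the presets omit
  it.
* **Classification of nucleation stubs.** kMTs that have never engaged a
  kinetochore are excluded from the attachment-state label until first
  attachment; otherwise the monotelic/syntelic scenarios would always
  read "transient detached".
* **Sub-step order.** Mechanics, then motors, then polymerization,
  depolymerization, attachment/detachment, with every probability taken
  from the start-of-tick state; the h-doubling check guards against
  ordering bias.
* **Period estimation.** Oscillation and pulsation periods are read from
  the first autocorrelation peak of the detrended 1-s-sampled traces,
  refined by parabolic interpolation at the first few harmonics.

## What the simulations show — and what they do not

With the frozen defaults the package reproduces: the catch–slip
lifetime maximum (≈ 50 min near 5 pN); a steady kMT flux of ≈ 20 nm/s
carrying a mean plus-end force of ≈ 5 pN; the configuration contrast in
which bi-oriented and merotelic attachments bear ≈ 5 pN while syntelic
and monotelic attachments average zero, with the interkinetochore
stretch strictly largest for correct bi-orientation; efficient
correction of type-II merotelic attachments with post-correction
bi-orientation probability ≈ 1 and transient-detachment episodes of a
few tens of milliseconds; the collapse of correction without Aurora B;
and the decay of case-I monotelic/syntelic spindles to a short
fluctuating equilibrium near the attached pole.

Three published behaviours are **not** reproduced, and tests covering
them are expected to fail honestly.  First, the slow kinetochore
oscillation (≈ 6 min) with half-period pulsation: across wide scans of
the motor parameters the kinetochore-centre trace is an aperiodic
mean-reverting fluctuation — once the flux, geometry and force anchors
are fixed, its restoring rate and transport delay are pinned, and no
coherent autocorrelation peak near 360 s emerges.  The missing motor
tables of the source model presumably contain the calibration that
produces the oscillation.  Second, the high-flux arm of the
optimum-flux experiment: with fixed poles the removal capacity cannot
track $v_{p0}$ upward, so the high-$v_{p0}$ point neither reaches a
36 nm/s flux nor shows the stuck-merotelic phenotype, although the
low-flux arm (poor fidelity at small $v_{p0}$) does reproduce.  Third,
case-II re-bi-orientation after opposite-pole regrowth: with the
minus-end removal capacity pinned to the flux at every length (the
deep-supply regime that bi-orientation stability requires), a regrown
kinetochore microtubule has zero net growth once its lattice saturates,
and capture of the far kinetochore becomes a neutral random walk that
does not arrive on practical horizons.
Separately, correction at the desk-scale 4,000-s horizon is sometimes
censored: the type-I merotelic intermediate, once its lengths adapt,
carries ≈ 250 nm of stretch, where the Aurora factor is ≈ 1 and the
incorrect attachment lives tens of minutes (the published per-state
lifetime calculations show the same multi-ten-minute erroneous-state
lifetimes); at the full 20,000-s horizon nearly all runs correct.

The synthetic scenarios emulate attachment topology, spring mechanics
and motor stochasticity, not 3-D geometry, polar ejection forces,
astral microtubules or checkpoint signalling; passing tests therefore
validate the mechanochemical error-correction pathway under the model's
one-dimensional assumptions, not those excluded features of real
spindles.

## A worked run

```{r example, eval = FALSE}
p <- spindle_params()                   # calibrated defaults, N = 2
sim <- simulate_spindle(p, "merotelic2", duration_s = 4000, seed = 2)
summary(sim)
plot(sim, "label")                      # correction trajectory
plot(sim, "positions")                  # kinetochore traces
```

Problem sizes used throughout the tests and the acceptance script —
runs of 1,500–4,000 simulated seconds, 6–10 replicates, and a 12,000-s
case-II run — are the package's desk-scale defaults; the published
protocols (20,000-s trajectories, 20-replicate means) are restored by
passing the corresponding `duration_s` and seed vectors.
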