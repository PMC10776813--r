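---
title: "A cross-bridge model of muscle-spindle receptor potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cross-bridge model of muscle-spindle receptor potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(spindlesim)
```

## The model

A muscle spindle signals muscle stretch through the receptor potential of
its Ia afferent, which wraps the central region of specialized intrafusal
muscle fibres. `spindlesim` models one spindle as two half-sarcomeres in
parallel -- a slow, dynamic *bag1* fibre and a fast, static *bag2/chain*
fibre -- each driven by imposed length and calcium (pCa) time series, plus
a phenomenological readout that converts their stresses into the
receptor potential.

Each half-sarcomere couples two pools:

* **Thin filament.** A fraction $A(t)$ of actin sites is activated.
  Activation proceeds at $k_{on}\,\mathrm{Ca}^{2+}$ over the sites inside
  the thick/thin overlap zone $n_{ov}(L)$ (a clamped linear ramp in
  half-sarcomere length), deactivation at $k_{off}$ over activated sites
  not occupied by a cross-bridge. Inter-filament cooperativity
  ($k_{coop}$) lets bound myosin bias the balance: activation is enhanced
  in proportion to $A/n_{ov}$ and deactivation in proportion to
  $(n_{ov}-A)/n_{ov}$, so an activated, strongly bound filament stays on
  and a mostly off filament resists turning on.

* **Thick filament.** Myosin is either detached or attached with a
  cross-bridge strain $\Delta x$, resolved on a uniform strain grid.
  Attachment happens near zero strain (Gaussian window of width
  $\sqrt{c_f/k_{cb}} \approx 8.5$ nm, normalized over the grid) at a rate
  proportional to the available actin $A - cb$; detachment follows a
  piecewise cubic $g(\Delta x)$. Imposed length changes advect the whole
  bound distribution along the strain axis -- every attached head is
  strained one-for-one with the half-sarcomere.

Stress is the sum of a linear passive element (signed, slack length per
fibre) and the spring force of the bound heads,
$10^{-9}\rho_{cb}\sum_i k_{cb}(\Delta x_i + x_{ps})\,M_i$, with
$x_{ps} = 5$ nm the power-stroke displacement: a head that attaches at
zero strain is pre-strained by its stroke, and the per-bridge force
vanishes exactly at the detachment-rate minimum ($-5$ nm).

The receptor potential is
$r(t) = \left(k_{fc}F_c + k_{fb}F_b + k_{yb}\lfloor \dot F_b\rfloor_+\right)/s$
with weights 0.5, 0.4 and 0.005 and a fixed force-to-potential conversion
$s = 2\times10^5$ that puts responses in order-one arbitrary units. The
yank (force rate) is half-wave rectified: only rising bag force excites
the ending. Spike generation is not modelled.

## The detachment law and history dependence

The detachment rate is read as

$$ g(\Delta x) = \max\!\big(g_0 + c_\pm(\Delta x + 5)^3,\,0\big) + g_{off} $$

with $c_+ = 0.3$ above the breakpoint and $c_- = 0.2$ below. Above the
breakpoint the cubic grows steeply -- strongly stretched bridges are
ripped off within milliseconds. Below it the signed cubic *decreases*,
so the tuned part bottoms out at zero and detachment is left at the
fibre-specific floor $g_{off}$: 0.5 s$^{-1}$ for the bag, 10 s$^{-1}$ for
the chain. These floors are the slowest rates in the model and set its
history dependence. After a stretch--shorten cycle the surviving bridges
sit compressed far below the breakpoint, holding the fibre's stress well
below its resting value; the stress (and with it the initial burst on a
later test stretch) recovers as this pool releases, on a
$1/g_{off} \approx 2$ s timescale for the bag and 0.1 s for the chain.
This single asymmetry reproduces the qualitative phenomenology: initial
bursts abolished by an immediately preceding cycle, monotone recovery
with inter-stretch interval, monotone suppression with conditioning
amplitude, millisecond-scale chain recovery, and a concave growth of the
steady sinusoidal response with amplitude.

An alternative reading of the sub-breakpoint branch, a U-shaped
$c_-|\Delta x + 5|^3$, was implemented and rejected: it releases
compressed bridges in tens of milliseconds, which erases essentially all
history dependence (test-stretch bursts recover within 0.2 s regardless
of conditioning).

## Numerical scheme

Integration uses operator splitting per step of `dt` (default 0.1 ms):

1. **Kinetics.** Explicit Euler for $A$ (rates are a few hundred per
   second at most, so $k\,dt \lesssim 0.04$), and exponential Euler per
   strain bin for the bound distribution -- the attachment flux is frozen
   over the step and the linear detachment is integrated exactly, which
   is robust even where $g\,dt$ approaches one at the grid's stretched
   edge. The detached pool is defined as one minus the bound sum, so
   myosin conservation is structural.
2. **Advection.** The bound distribution is translated by the length
   increment with a mass-conserving linear-interpolation shift (each
   bin's mass is split between the two straddling destination bins;
   first moments are preserved exactly for in-grid shifts).

The strain grid spans $[-150, +40]$ nm at 0.25 nm. The span is strongly
asymmetric because the two sides die off very differently: stretched
bridges beyond $+15$ nm detach at over 2000 s$^{-1}$, while compressed
bridges release at the floor rate and are dragged tens of nm during a
5.6 % $L_0$ shorten (the chain's tail reaches past $-100$ nm). Mass
advected off the grid is forcibly detached and returned to the detached
pool; the integrator tracks the outermost-bin occupancy and raises an
error if it ever exceeds $10^{-6}$, so a too-narrow grid fails loudly
instead of silently losing bridges. The 0.25 nm width was fixed by a
refinement study: the detachment floor introduces a kink in the
stationary distribution, and halving bins from 0.5 nm still changed the
ramp-and-hold bag stress by 2.4 % RMS, while halving from 0.25 nm
changes it by 0.5 % (0.125 nm: 0.15 %). The test suite enforces both the
refinement bound and agreement of the compiled integrator with a pure-R
reference step to 12 digits, and the single-bin engine against the exact
closed form of the scalar two-state (Riccati) relaxation to $10^{-6}$.

Lengths are imposed directly on the half-sarcomere; there is no series
elasticity and no force balance. A slack mode (`allow_slack = TRUE`)
that caps stress at zero by letting the realized length ride the
zero-stress length is implemented but off by default: with these
kinetics the slack state self-sustains (attachment near zero strain
balances the slow release of the compressed pool, a "treadmill" that
parks the fibre at zero force indefinitely), which abolishes burst
recovery entirely. With direct length control the compressed-pool
mechanism above produces the intended recovery dynamics, and a
"slackened" fibre is simply one whose bound pool holds its stress at or
below zero until re-stretched.

## Protocols and study conditions

All shipped protocols start from zero bound myosin and zero activated
actin at the resting length $L_0 = 1300$ nm and hold for 2 s at constant
pCa 6.4 (near-passive activation, $\sim$10--12 % steady chain
activation) before any length change; protocols are generated at 10 kHz
and linearly resampled to the integrator step.

* `ramp_hold(36, 5.6)`: ramp at 36 % $L_0$/s to 5.6 % $L_0$, held to 3 s.
* `triangle_pair(12, 5.6, 5.6, isi)`: conditioning and test
  stretch--shorten triangles with a rest interval, 1 s trailing hold.
* `sinusoid_protocol(a, 1, 3)`: three raised-cosine cycles starting at
  $L_0$ and moving first into stretch, peak excursion $a$ % $L_0$
  (amplitudes are peak, not peak-to-peak).

The sweep drivers scan inter-stretch interval 0--10 s in 0.1 s steps,
conditioning amplitude 0--5.6 % $L_0$ in 0.1 % steps, and sinusoid
amplitudes 0.0016--1.6 % $L_0$ at 1 Hz. Sweeps and simulations are fully
deterministic; there is no randomness anywhere in the model.

## Feature definitions

* **Initial burst**: first interior local maximum of the receptor
  potential in the onset portion of the ramp, minus the baseline (mean
  over 0.5 s before onset; for a test stretch the pre-conditioning
  resting baseline is used so both bursts share a reference). The search
  is restricted to the first quarter of the ramp: the short-range
  stiffness transient lasts about (detachment strain)/(stretch
  amplitude) $\approx$ 10 % of the shipped ramps, and genuine onset
  bursts in this model peak at 10--15 %, whereas the delayed
  force-recovery overshoot of a strongly conditioned fibre peaks at
  50--99 % and must not be counted as a burst. Presence requires the
  magnitude to exceed 2 % of the reference (conditioning or
  unconditioned) burst.
* **Dynamic response**: least-squares line fitted from the signal's
  minimum after the burst (or ramp start if no burst) to the end of the
  ramp; the fitted rise over the fit interval is reported, with the raw
  slope alongside.
* **Dynamic index**: late-ramp peak minus the value at the end of the
  hold phase.
* **Recovery time**: first time after the test-stretch onset at which
  the signal exceeds its pre-conditioning resting value by 1 % of the
  conditioning peak above that value.

The sinusoid sweep subtracts a zero-amplitude control simulation before
taking cycle peaks, so residual equilibration drift of the resting fibre
(the compressed-release valley is still filling on the 2 s pre-hold
timescale) does not masquerade as a response at tiny amplitudes.

## A worked run

```{r ladder}
lad <- run_thin_filament_ladder()
lad
```

```{r ramp}
tr <- simulate_spindle(ramp_hold(36, 5.6))
extract_features(tr)
```

```{r plot}
plot(tr$time_s, tr$rtotal_au, type = "l", xlab = "time (s)",
     ylab = "receptor potential (a.u.)")
abline(v = c(2, 2 + 5.6 / 36), lty = 3)
```

## Known limitations

The model reproduces the study's structural and qualitative results --
chain steady-state activation near 10 %, dynamic index near 0.2,
millisecond chain versus sub-second bag recovery, monotone
burst recovery with rest interval, monotone suppression with
conditioning amplitude, and the concave sinusoid amplitude--response
curve -- but its absolute history-dependence timescales run slower than
the published ones (bag stress recovery ~0.4 s versus 0.16--0.22 s;
burst reappearance at ~5 s of rest versus 0.7 s). The reference
implementation this model descends from does not publish its solver
discretization or the normalization of the attachment flux across the
strain window, and those choices control how much bound myosin survives
a shorten and how deep it is dragged; the package's choices (attachment
window normalized over the grid, wide tracked strain range) are
documented above and kept fixed rather than fitted to the published
numbers. The cooperativity coefficient consequently has almost no
leverage on bag recovery here (the compressed pool, not actin
reactivation, is rate-limiting), whereas the published model shows a
40 % slowdown. Receptor-potential units are arbitrary; only
baseline-referenced features should be compared across models. Spiking,
mechanotransduction, gamma drive and extracellular matrix are out of
scope.
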