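---
title: "Bifurcation maps and bursting classes of the Epileptor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bifurcation maps and bursting classes of the Epileptor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dynamotype)
```

## The models

The Epileptor is a six-variable phenomenological model of focal seizure
dynamics built from three subsystems on separated time scales. The fast pair
$(x_1, y_1)$ (time scale $\tau_1 = 1$) produces the ictal oscillation:

$$
\dot x_1 = \begin{cases}
  y_1 - x_1^3 + 3x_1^2 - z + I_{rest1} & x_1 < 0\\
  y_1 + (m - x_2 + 0.6\,\alpha\,(z-4)^2)\,x_1 - z + I_{rest1} & x_1 \ge 0
\end{cases}
\qquad
\dot y_1 = y_0 - 5x_1^2 - y_1
$$

The slow variable $z$ (time scale $\tau_0 = 2857$) implements the
hysteresis-loop feedback, $\dot z = (4(x_1 - x_0) - z)/\tau_0$, where the
epileptogenicity $x_0$ places the z-nullcline relative to the resting branch.
The intermediate pair $(x_2, y_2)$ (time scale $\tau_2 = 10$) is an excitable
system past a SNIC bifurcation that produces preictal spikes and
spike-and-wave events; it is driven by $z$ and by a low-pass filtered copy
$u$ of $x_1$. The published model defines $u$ as an exponential-kernel
convolution; we carry it as a seventh state equation
$\dot u = 0.002\,x_1 - \gamma u$, $u(t_0) = 0$, which is exact for that
kernel and avoids storing history. The acceptance suite verifies the
equivalence against direct quadrature ($\le 10^{-6}$ relative) and the closed
form for constant input.

The package also implements a minimal three-variable bursting model whose
fast subsystem is a layer (fixed $\mu_2 = 0.07 > 0$) of the unfolding of the
degenerate Takens–Bogdanov (DTB) singularity, with an affine path
$(\mu_1(z), \nu(z))$ and the same hysteresis-loop slow dynamics
$\dot z = c\,(x - x_0)$. It is the generic reference against which the
Epileptor's map is compared.

## The map

Rewriting the Epileptor's fast subsystem with every coefficient explicit,

$$
\dot x = \begin{cases}\nu y + a x^3 + b x^2 + \mu & x<0\\
\nu y + \bar m x + \mu & x \ge 0\end{cases}
\qquad
\dot y = y_0 + B x^2 + N y,
$$

the pair $(\mu, \bar m)$ is what the slower variables move:
$\mu = I_{rest1} - z$ and $\bar m = 0.6\,\alpha(z-4)^2 + m - x_2$. Treating
them as bifurcation parameters gives closed-form local bifurcation curves
(`sn_curves()`, `hopf_curve()`, `tb_point()`):

* **SN$^-$** at $\mu = \nu y_0/N - \tfrac{4}{27 a^2}(b - \nu B/N)^3 = 5/27$
  with defaults: fold of the two negative-branch fixed points. The leftmost
  negative root is the interictal rest state.
* **SN$^+$** at $\mu = \nu y_0/N - N\bar m^2/(4B\nu)$, the fold of the two
  positive-branch fixed points, valid where the fold abscissa
  $\bar m N/(2\nu B)$ is nonnegative.
* **SN$^0$** at $\mu = \nu y_0/N = -1$ for $\bar m \le 0$: the two branches
  merge through the seam $x = 0$. The one-sided Jacobians disagree there, so
  this is a pseudo-fold; it still bounds the wedge and acts as a fold for
  bursting, and is labelled distinctly everywhere.
* **Hopf** on the line $\bar m = -N = 1$, valid on the upper branch where
  the determinant is positive ($\mu$ greater than the Takens–Bogdanov
  value); the negative-branch trace-zero candidates are nonnegative for the
  default coefficients, so no negative-branch Hopf exists.
* **TB** at $(\mu, \bar m, x) = (-1.05, 1, 0.1)$, where trace and
  determinant vanish together.

A point worth stating explicitly, because it is easy to get backwards: the
Jacobian trace on the upper branch is $\bar m + N = \bar m - 1$, so the
upper fixed point is **stable below** the Hopf line and **unstable above**
it, and the stable limit cycle of the supercritical Hopf lives at
$\bar m > 1$. The package's simulations confirm this directly (the canonical
seizure oscillation runs at $\bar m \approx 1.0$–$1.6$), and all region
logic follows the algebra, not intuition about plot orientation.

The saddle-homoclinic (SH) curve is global and is inferred numerically
(`build_map()`, `infer_sh_curve()`): every grid cell is probed by
integrating from the upper fixed point offset by $\epsilon$, discarding a
transient, and measuring the amplitude ($\max - \min$ of $x$) and the
dominant Hann-windowed DFT frequency. The limit-cycle frequency scales to
zero on approach to a homoclinic, so the left edge of the oscillatory band,
frequency-interpolated between cells, estimates the SH locus. On the default
grid it stems from one cell of the TB point and climbs toward the SN$^-$
line, exactly as the DTB unfolding predicts.

### Protocol constants

* `t_total = 600`, `t_discard = 300`, `epsilon = 0.05` per map cell
  (Epileptor fast subsystem); `2000/500/0.0005` for the DTB layer, whose
  dynamics are two orders of magnitude smaller in amplitude.
* Integration: `lsoda` with maximum internal step `0.1` (the piecewise
  seams are always resolved), `rtol = atol = 1e-8`, dense output sampled at
  `0.1`; model time is read as seconds so frequencies are in Hz.
* `amp_threshold = 1e-3` x-units separates "converged to a fixed point"
  from oscillation: two orders below typical cycle amplitudes.
* Frequencies are multiples of $1/(t_{total}-t_{discard})$ refined by
  quadratic interpolation of the spectral peak; the SH inference floor is
  twice that resolution.

### The five regions

Combining the analytic fixed-point census with simulated limit-cycle
detection, the mapped rectangle $\mu \in [-2, 1]$, $\bar m \in [-3, 2]$
contains exactly five attractor configurations
`(n_stable_fp, n_fp, has_lc)`: a single stable fixed point `(1,1,noLC)`;
bistability of two fixed points `(2,3,noLC)` (the wedge below the Hopf
line); bistability of rest and limit cycle `(1,3,LC)` (the seizure regime);
the wedge strip above the Hopf line left of SH where the upper focus is
unstable and no cycle survives `(1,3,noLC)`; and the regime where the limit
cycle is the only stable attractor `(0,1,LC)`. The acceptance grid is
staggered so no cell sits exactly on a curve; points within $10^{-8}$ of a
curve are tagged on-curve rather than classified.

## Classifying bursters (dynamotypes)

`detect_transitions()` builds an exact sliding max/min envelope of $x_1$
(window 50 time units — much longer than a fast period, much shorter than a
burst — computed on 1-unit blocks) and marks onsets/offsets by hysteresis
thresholds `amp_on = 0.5`, `amp_off = 0.2` in $x_1$ units. Branch jumps
excite the envelope for about one window even without oscillation, so
episodes shorter than 2.5 windows are discarded as jump transients; if
nothing longer exists, detection falls back to branch-switch events (the
envelope midline crossing the middle-branch abscissa), which is what the
depolarization-block (SN/SN) class produces. Oscillation episodes separated
by less than 250 time units are one seizure: near a SupH offset the
intermediate spikes re-cross the Hopf line several times.

`classify_burster()` then assigns the onset/offset pair:

* onset **SN** — finite-amplitude jump with a DC (baseline) shift of the
  envelope midline $> 0.5$; onset **SupH** — growth from zero without a
  shift. Cross-checked against the nearer of the SN$^-$ line and the Hopf
  line at the onset path point.
* offset **SH** — last inter-peak interval $> 1.25\times$ the median
  (period divergence); offset **SupH** — otherwise, cross-checked by
  whether the spike-smoothed path ordinate actually reaches the stable side
  of the Hopf line around the offset (it must for SupH; for SH the cycle
  still exists, so it cannot). Disagreement yields `"ambiguous"` with both
  candidates reported.

All presets start from the resting fixed point computed at $z = 3$ (with
$(x_2, y_2, u) = 0$) and the first complete burst is discarded, so nothing
depends on the arbitrary start. Preset spans (16000 time units) give five to
six analysable bursts.

### The preset registry and the two searched classes

`m = 0` with the intermediate drive on (SN/SupH), `m = 0`, `I_{rest2} = 0`
(SN/SH) and `m = -8`, `I_{rest2} = 0` (SN/SN) are the literature parameter
sets; presets use `x0 = -2`. The two inverted-curvature classes
($\alpha = -1$) have no published `m`; `inst/scripts/find_alpha_presets.R`
documents the scan-plus-bisection search that produced them.

Two findings from that search shape the registry. First, with the
intermediate drive on ($I_{rest2} = 0.45$) the spike kicks to $\bar m$
(amplitude $\approx 2$) force detectable fast oscillation from the moment of
the SN$^-$ jump at every `m`, so an observable SupH onset requires
$I_{rest2} = 0$ — the same switch the SN/SH scenario uses. With it,
`m = 0.4` (window $\approx [0.3, 0.5]$) gives a clean SupH/SH burster: no DC
shift at onset, amplitude growth over $\sim 240$ time units, period
divergence at offset.

Second, the SupH/SupH class is *not realizable* under the deterministic
noise-free protocol. The geometry demands a path peak within $\sim 0.01$
above the Hopf line (so the descending crossing happens right of the TB
point, before the SH curve), but the slow passage into the unstable sliver
is governed by the delayed-Hopf (memory) effect: the contraction accumulated
while approaching the focus must be undone before the oscillation can erupt,
which requires a peak at least $\sim 0.13$ above the line at these drift
rates and tolerances. The two requirements exclude each other: the
trajectory either passes the sliver silently (label SN/SN) or erupts late
and dies on the SH curve (label SupH/SH). Scans over
$m \in [-0.3, 4]$, $x_0 \in [-2.2, -0.45]$ and both `Irest2` settings, and
alternative placements of the z-nullcline inside the sliver (which produce
hard silent-to-tonic transitions, never bursting), found no exception. The
`suph_suph` preset therefore records the geometrically correct sliver value
(`m = -0.06`) and the classifier reports what the dynamics actually does;
the corresponding acceptance expectation is left failing rather than
papered over. A noise floor (or loose solver tolerance) would "unlock" the
class by constantly re-seeding the focus distance, but that would be a
noise-induced artifact, not the deterministic protocol this package
implements.

## The role of the epileptogenicity

With the intermediate subsystem silenced, $x_0$ does not enter the path
equations at all — it only scales $\dot z$ — so burst loops projected on
the map for different $x_0$ coincide except at the seizure-onset corner,
where the dynamic fold delay (the overshoot past SN$^-$ before the jump
completes) depends on the drift rate. Quantitatively
(`x0_sweep()`, symmetric Hausdorff distance between arc-length-resampled
loops over the bounding-box diagonal): loops for
$x_0 \in \{-2.05, -1.95, -1.85\}$ agree within $0.8\%$ away from that
corner and within $\sim 3\%$ including it, while the interictal duration
falls monotonically as $x_0$ increases (the z-nullcline moves away from the
resting branch) and, with the drive on, the intermediate spike count per
burst changes with $x_0$. Beyond $x_0 \approx -2.06$ the z-nullcline
intersects the resting branch and the whole system has a stable fixed point
— `x0_sweep()` flags such values "no bursting" instead of fabricating
durations; $x_0 = -2.2$ is such a value.

## Numerical choices and degenerate inputs

* The fixed-point cubic is solved in closed form (trigonometric /
  Cardano with a $10^{-10}$ discriminant guard) rather than iteratively, so
  roots are reliable arbitrarily close to folds; property tests compare 200
  random draws against `polyroot` counting and fold-locating bisections to
  $10^{-9}$.
* Stability at the seam $x = 0$ is "non-hyperbolic", never guessed: the
  one-sided Jacobians disagree there.
* Degenerate coefficients ($a$, $B$, $N$, or $\nu$ zero) are rejected at
  construction; the closed forms divide by them.
* Determinism: identical options give identical sampled output; the map
  builder is pure. Classifications of all presets are stable under halving
  the solver tolerances.

## What the tests do and do not show

Everything here is exercised on the deterministic, noise-free model itself:
there is no external data, so "synthetic data" means trajectories of the
published equations under the published protocol. Passing tests show the
implementation reproduces the model's bifurcation geometry and its bursting
phenomenology; they say nothing about how well the Epileptor fits clinical
recordings, about networks of coupled Epileptors, or about noise-driven
transitions, all of which are out of scope. Problem sizes were chosen so the
full suite runs in minutes on one core: 20×22 map cells at 600 time units
each, 16000-unit preset runs, 50×50 analytic census grids; all scale up
without code changes.
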