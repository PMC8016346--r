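---
title: "Delimiting muscle fibre operating ranges with fibreops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting muscle fibre operating ranges with fibreops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibreops)
```

## The scientific problem

Where a muscle's fibres sit on the active force-length curve — steep
ascending limb, shallow ascending limb, plateau or descending limb —
determines how much force they can produce at a given activation, and how
that capacity changes as the limb moves. A long-standing heuristic in
comparative biomechanics assumes that, across a joint's full range of
motion, fibres traverse 0.5–1.5 times their optimal length
$\ell_o$, which permits $\ell_o$ (an unmeasurable quantity in extinct
animals) to be back-calculated from joint excursions and moment arms.
`fibreops` implements the computational machinery needed to interrogate
that assumption in a Hill-type musculoskeletal model of a limb: MTU
parameterization, a multi-trial inverse (muscle-redundancy) solver with
simultaneous architecture tuning, a static posture battery that
circumscribes the *viable* fibre operating range over the whole joint
space, and linearity/decoupling analyses of the results. Because suitable
experimental data sets (fluoroscopic kinematics plus forceplate kinetics
plus a subject-specific model) cannot be packaged, a synthetic-data module
generates toy limbs and gait trials with known ground truth so that every
stage is testable end to end.

## The muscle–tendon model

Each actuator is a lumped Hill-type muscle-tendon unit (MTU): a contractile
fibre in series with an elastic tendon, reduced to a force along a path.
Parameterization follows standard practice:

* **Maximal isometric force** from belly mass $m$ and optimal fibre length
  $\ell_o$: $F_{max} = m\sigma/(\rho\,\ell_o)$ with
  $\sigma = 300{,}000\ \mathrm{N/m^2}$ and $\rho = 1060\ \mathrm{kg/m^3}$.
  Pennation is *not* applied here; it enters through the contraction
  geometry below, and applying it in both places would double-count it.
* **Dimensionless tendon stiffness**
  $k_T = E A_T \rho \ell_o/(m \sigma \cos\alpha_o)$, the normalized slope
  of the tendon force-strain curve. Small-bodied animals have relatively
  stiff tendons; the package default is $k_T = 100$ for every MTU (a
  first-pass value for a few-hundred-gram ground bird, where per-tendon
  estimates from $E = 1.2$ GPa span roughly 23 to over 1000 with a median
  near 114), in contrast to the human-model convention of 35.
* **Activation time constants** scale with body mass to the 1/6 power:
  from 0.015/0.060 s at 64.8 kg to 0.007/0.027 s at 0.545 kg.
* **Tendon slack length** is initialized by a least-squares first
  approximation that asks the fibre to traverse 0.5–1.5 $\ell_o$ across
  the MTU length range (`estimate_slack_length()`); the redundancy
  solver's tuning factors are the mechanism that refines it.

Pennation uses the constant-thickness model,
$\ell \sin\alpha = \ell_o \sin\alpha_o$, so the instantaneous angle is
$\alpha(\ell) = \arcsin(\ell_o \sin\alpha_o/\ell)$ and the fibre length
follows from the projected span
$\ell = \sqrt{(l_{MT} - l_T)^2 + (\ell_o\sin\alpha_o)^2}$.

### Characteristic curves and their recalibration

The four curves use the smooth, continuously differentiable forms of the
widely used differentiable Hill-model family: a three-Gaussian active
force-length curve, an exponential passive curve with strain scale 0.6, an
asinh-type force-velocity curve, and an exponential tendon force-strain
curve. Three deliberate recalibrations make the normalization anchors
exact rather than approximate, which the equilibrium inversions rely on:

* $f_{act}$ is normalized by its raw value at $\ell^* = 1$, so
  $f_{act}(1) = 1$ to machine precision.
* The force-velocity offset is re-solved so $f_v(0) = 1$ exactly (the
  published constant gives 1.002).
* The tendon curve is re-solved per $k_T$: writing
  $f_T(x) = c_3\,(e^{k'(x-1)} - 1)$ with $c_3 = 0.25$ and
  $k' = k_T/(1+c_3)$ guarantees $f_T(1) = 0$ and a local slope of exactly
  $k_T$ at the strain where $f_T = 1$, for *any* stiffness — the
  constants published for the human default of 35 do not transfer to
  $k_T = 100$. This form is also numerically robust in the rigid-tendon
  limit ($k_T \to 10^6$), where the equivalent
  $c_1 e^{k'(x - c_2)}$ parameterization underflows.

The passive curve is taken through a $C^1$ smooth one-sided ramp
(half-width $10^{-6}$ in $\ell^*$) so that $f_{pass}(1) = 0$ exactly and
$|f_{pass}| < 10^{-7}$ below optimal length, while staying continuously
differentiable for the optimizers.

Activation dynamics are first order with a smooth blend between the
activation and deactivation time constants,
$\dot a = (e - a)/\tau(e - a)$ with
$\tau = \tau_{deact} + (\tau_{act} - \tau_{deact})\,
\sigma\!\big((e-a)/0.1\big)$ and $\sigma$ a scaled tanh. This satisfies
the intended step time-scales directly (0.63 rise in $\approx\tau_{act}$,
$e$-fold decay in $\approx\tau_{deact}$) and was preferred over
activation-dependent rate factors for its symmetry and easy invertibility,
which both the generator and the solver seeding exploit.

Muscle-tendon equilibrium is expressed with tendon force as the state:
$$\big(a\,f_{act}(\ell^*)\,f_v(\tilde v) + f_{pass}(\ell^*) +
\beta\tilde v\big)\cos\alpha \;=\; F_T/F_{max},$$
with a small numerical damping $\beta = 0.01$ on the normalized fibre
velocity. The damping regularizes the velocity inversion when activation
is near zero; it is configurable and its default is small enough that
static solutions are unaffected (it multiplies $\tilde v = 0$).

## Limb geometry

MTU length is represented as a multivariate polynomial of the joint angles
the MTU crosses, and moment arms are the exact negative gradient (the
tendon-excursion definition $r_{m,k} = -\partial l_{MT}/\partial q_k$).
Polynomials preserve the two properties every downstream computation uses
— smoothness and exact, cheap derivatives — and are the standard surrogate
for 3-D wrapping-surface muscle paths. `check_tendon_excursion()` audits
the arm/length consistency numerically; it exists for imported geometries
that carry independently supplied moment-arm polynomials. Models
serialize to JSON with numbers encoded as 17-significant-digit decimal
strings, which round-trip IEEE doubles exactly, so a saved model
reproduces every evaluation bit for bit.

## The synthetic study and its ground truth

`make_toy_limb()` samples architectures with the spreads of a small ground
bird's hindlimb (pennation 0–35°, $L_S/\ell_o$ from 0.05 to 8, $F_{max}$
from 0.6 to 30 N) and guarantees a monoarticular antagonist pair about
every DOF; additional MTUs are biarticular. Neutral MTU lengths are chosen
so fibres sit just below optimal length at a moderate tendon load
mid-range, and moment arms are sized (≈ 0.16 $\ell_o$, de-rated for
biarticular muscles) so that fibre excursions over the joint ranges span
roughly the ascending limb and plateau — the region real locomotor muscles
occupy. The default trial bundle mirrors the two study conditions: a walk
at 0.39 m/s with duty factor 0.71 and a grounded run at 1.39 m/s with duty
factor 0.57 (stride times 0.55 s and 0.33 s, 101 samples per stride;
walking uses lower activation amplitudes, 0.25–0.45 versus 0.5–0.75, all
at most 0.8 to stay away from bound saturation).

When a ground-truth tuning is supplied, the limb's *geometry* (neutral
MTU lengths and moment-arm sizes) is laid out around the true,
tuning-applied architecture — a simulated animal whose anatomy is adapted
to its behaviour — while the stored muscle parameters keep the untuned
values, which play the role of mismeasured dissection estimates that the
solver's tuning factors should correct.

Ground-truth muscle drive is built from smoothed boxcar bursts aligned to
stance (agonists) or swing (antagonists), so bursts of an antagonist pair
never overlap and the minimum-activation inverse solution coincides with
the truth. One subtlety matters: the *requested* activation profile must
be realizable by the excitation-activation dynamics, since activation can
never decay faster than $a/\tau_{deact}$. `forward_generate_trial()`
therefore projects the request onto the feasible set — it inverts the
activation dynamics for the implied excitation, clamps it to $[0,1]$, and
re-integrates — and stores the *realized* activations (and the
excitations) as ground truth. The generated external moments are then
defined as exactly the muscular moments,
$M_{ext,k}(t) = \sum_m F_{T,m}(t)\, r_{m,k}(t)$ (plus optional Gaussian
noise), making the pair an exact feasible point of the redundancy problem
with zero reserve usage. State integration uses an implicit adaptive
solver (`deSolve::lsoda`, tolerances $10^{-8}/10^{-10}$), mirroring the
inverse solver's choice of tendon force as the contraction state.

What the generator does *not* emulate: measurement noise structure of real
fluoroscopy/forceplate pipelines, soft-tissue artefact, co-contraction,
fibre-type heterogeneity, history dependence, or geometry error. Passing
recovery tests on this data therefore demonstrates the *solver machinery*
is correct and well-conditioned, not that real-data inferences are
unbiased.

## The multi-trial redundancy solver

The inverse problem minimizes, over all trials jointly,
$$J = \sum_{trials}\int \Big( w_1 \textstyle\sum_m a_m^2
 + w_2 \sum_l a_{res,l}^2
 + w_3 \sum_m \big(\dot a_m^2 + \dot F_{T,m}^2\big)
 + w_4 \sum_m F_{pass,m}^2 \Big)\,dt
 + w_5 \sum_m (p_{\ell,m}-1)^2 + w_6 \sum_m (p_{L,m}-1)^2,$$
subject to excitation-activation dynamics, implicit contraction dynamics
(tendon force as the state), muscle-tendon equilibrium, collocation
continuity, and per-DOF moment balance
$\sum_m F_{T,m} r_{m,k} + a_{res,k}\,c_k = M_{ext,k}$ with reserve caps
$c_k$. Default weights are $w_1 = 2$, $w_2 = 500$, $w_3 = 1$, $w_4 = 100$,
$w_5 = 2$, $w_6 = 1$: reserves are heavily penalized so muscles do the
work; the passive-force penalty stops the tuner from parking fibres on
the descending limb where passive force is free; and slack lengths are
held less tightly than fibre lengths because they are estimates rather
than measurements. The tuning factors $p_\ell$ (on $\ell_o$) and $p_L$
(on $L_S$) are single decision variables shared across all trials, with
bounds $[0.5, 2]$ — generous relative to the tunings such models actually
need, which run from a few percent shortening to roughly +50%.

### Transcription and numerical scheme

The trial time axis is divided into `mesh` evenly spaced intervals
(default 100; the desk-scale analyses use 50) and the states are
propagated with two-stage Radau IIA collocation — third order and stiffly
accurate, which matters because the contraction dynamics are stiff for
stiff tendons. Rather than exposing states, stage values and defect
constraints to a large sparse NLP solver, the implementation *reduces*
the problem: the collocation defect equations are solved exactly by an
inner Newton iteration at every interval (eliminating activation and
tendon-force trajectories as functions of the controls), and the reserve
activations are eliminated exactly through the moment balance. What
remains is a purely bound-constrained problem in the per-node excitations
(piecewise linear in time), the initial states and the tuning factors.
This is minimized with L-BFGS-B using batched forward-difference
gradients: because every decision-vector perturbation is an independent
column, one vectorized sweep of the transcription (implemented in
compiled code, with an R reference implementation kept for trajectory
extraction and as an independent cross-check in the tests) evaluates the
objective for all ~400–800 perturbed columns at once. At the returned
solution the dynamics, equilibrium and continuity hold by construction to
the inner Newton tolerance (collocation defects are reported;
typically $<10^{-10}$), and the moment balance holds exactly up to the
reported reserve activations.

The monotone scalar inversions inside the dynamics (fibre velocity from
the damped equilibrium; static tendon force) use safeguarded Newton
iterations within maintained brackets — warm-started in closed form where
possible — rather than generic root finders, because they must be
vectorized over tens of thousands of simultaneous states and remain
smooth to ~$10^{-12}$ so that finite-difference gradients are clean.

The optimizer is seeded in three stages. First, a per-sample static
optimization computes minimum-norm activations subject to the moment
balance with bound constraints enforced properly: the unconstrained
pseudoinverse solution routinely assigns *negative* activation to
antagonists, and clamping it would silently discard part of the moment,
so an active-set loop re-solves the equality system whenever a variable
is driven outside $[0,1]$. Second, the rigid-tendon kinematics of that
pass are refined by fixed-point iterations that re-evaluate fibre
lengths and tendon-rate-corrected velocities from the previous pass's
tendon forces, accounting for tendon compliance. Third, a dynamics
inversion along the resulting force trajectory recovers consistent
activations and excitations (the activation-rate inversion solves the
blended-time-constant relation by fixed point). When tuning is enabled,
the optimization itself runs in two phases — tuning factors pinned at
one, then released — a standard continuation that enters the feasible
valley before trading architecture against it. Reserve caps default to
10% of each trial's peak absolute external moment per DOF (with a small
floor), which both encourages muscular solutions and keeps the reserve
penalty well-scaled.

## The static posture battery

`sample_poses()` draws uniform independent joint angles over each
actuated DOF's range (5,000 poses in the headline configuration), with
per-DOF overrides for fixed angles. Four simulations run at every pose,
gravity and inertia ignored:

1–2. whole-limb minimization/maximization of $\sum_m a_m^2$ subject to
moment balance about every DOF and static muscle-tendon equilibrium in
every MTU. The per-pose problem is solved in *tendon-force space*, where
the moment balance is linear and activation follows in closed form from
the equilibrium inversion; an augmented-Lagrangian loop over the
box-constrained forces (L-BFGS-B inner solves, normalized constraints)
handles the coupling. Maximization is the negated objective with three
seeded multistarts, since local optima are possible. Infeasibility is
*proven* by minimizing the squared normalized moment residual over the
force box — a convex problem — and declaring filter rule i only when its
minimum exceeds tolerance; solver failure is recorded separately.

3–4. each MTU in isolation with activation fixed at 0 or 1, solved by the
vectorized static equilibrium. Poses with $l_{MT} < L_S$ admit no
equilibrium and are flagged (filter rule ii).

Filter rule iii caps $l_{MT}$ per MTU (the headline analysis uses an
80 mm cap for one muscle whose modelled path misbehaves at extreme hip
flexion); rules apply in order i → ii → iii with the first failure
recorded, and viable-pose counts are recomputed per simulation pair.

## Post-processing

`hyperplane_fit()` implements the minimum-norm least-squares hyperplane
$\ell^* = c_1 q_1 + \dots + c_{\eta-1} q_{\eta-1} + c_\eta$ through the
Moore-Penrose pseudoinverse of the ones-augmented angle matrix, with
$r^2$, RMSE and maximum absolute error against the observations. When the
observations have zero variance, $r^2$ is reported as undefined (`NA`
with an attribute) rather than 0 or 1. Force-length regions default to
steep ascending $[0, 0.80)$, shallow ascending $[0.80, 0.95)$, plateau
$[0.95, 1.05]$ and descending $(1.05, \infty)$ — an approximate
correspondence to the divisions in common use; no canonical boundaries
exist, so they are explicit configuration. Operating-range summaries
report per-MTU viable extrema, the fibre-to-MTU range ratio (computed
within a single simulation, because pooling different activation levels
lets tendon stretch widen the fibre range beyond the MTU range and would
break the parity bound), in-vivo ranges and the fraction of the viable
range they use, and 0.02-wide histograms. Decoupling regressions are
ordinary least squares of the range ratio on pennation angle and on
relative tendon length $L_S/\ell_o$.

## Numerical choices and degenerate inputs

* Geometry floor: projected fibre span is bounded below by $10^{-6}$ m;
  fibre length below the muscle thickness is a domain error.
* Curve evaluation outside $\ell^* \in [0.2, 1.8]$ is permitted (extreme
  battery poses reach it) and counted; set
  `options(fibreops.log_extrapolation = TRUE)` to log it.
* Zero slack length is supported in static equilibrium (the force becomes
  an explicit function of geometry) but not in the dynamic solver, where
  tendon force is a state.
* The velocity bracket is $|\tilde v| \le 50$; solutions at the bracket
  edge only arise in physically meaningless states visited transiently by
  the optimizer.
* Ties and multistarts in the battery are seeded; identical seeds and
  models reproduce every record and flag exactly.
* L-BFGS-B occasionally ends with an abnormal line-search termination
  once it reaches the finite-difference noise floor; the incumbent point
  is returned with a warning and the recorded convergence code.

## Problem sizes used in the packaged analyses

The numbered scripts under `analysis/` and the test suite run the study
at desk scale, chosen so the full workflow illustrates every stage while
remaining quick to reproduce: a 2-DOF, 4-MTU limb, two trials of 101
samples, mesh 50 for the inverse solver (the headline default is 100),
and 5,000 battery poses. The parameter-recovery experiments use the same
bundle with tuning frozen (activation recovery) or with a +10%
fibre-length perturbation on one muscle (tuning recovery).

## Known limitations

* No fibre-type heterogeneity, history-dependent force
  depression/enhancement, or explicit aponeurosis model.
* The reduced transcription recovers the same optimum as an all-at-once
  collocation NLP when the inner Newton converges, but it cannot exploit
  infeasible intermediate iterates the way interior-point NLP solvers do;
  heavily redundant limbs may converge more slowly.
* Moment arms are exact gradients of the polynomial length model;
  importing inconsistent external arm data will be flagged by the
  tendon-excursion audit but not repaired.
* The battery ignores gravity and inertia by design; its "viable" ranges
  are geometric-physiological bounds, not behavioural predictions.
* Architecture tuning through the penalized objective is only weakly
  identifiable for small perturbations when fibres operate near the
  plateau: a ~10% change in one muscle's optimal fibre length alters the
  reduced objective by only ~0.01–0.02 under the default weights, because
  the active curve is nearly flat there and small passive forces can
  substitute for activation at little cost. The package's own
  parameter-recovery experiment documents this: activation recovery is
  essentially exact, while a +10% single-muscle fibre-length perturbation
  is recovered only partially (the optimizer settles near the untuned
  value, which the data themselves mildly prefer). Tuning earns its keep
  when mis-parameterization is gross enough to force reserve usage or
  infeasibility — the regime the approach was designed for — rather than
  for fine single-muscle calibration.
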