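---
title: "Methods: a planar neuromusculoskeletal simulation of macaque bipedalism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a planar neuromusculoskeletal simulation of macaque bipedalism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macaquegait)
```

## The scientific question

Japanese macaques walk bipedally on their forefeet: the calcaneal tuberosity
points backwards and upwards, the heel never touches the ground, and the
vertical ground reaction force (GRF) is single-peaked — unlike the
double-peaked human profile that accompanies efficient, pendulum-like
walking. `macaquegait` implements a forward-dynamics model of this system
and its central *virtual morphing experiment*: lowering the heel contact
point millimetre by millimetre (digitigrade toward plantigrade), re-tuning
the gait at each step, and asking how the GRF profile and the metabolic cost
of transport respond.

## Musculoskeletal model

The skeleton is a planar nine-link chain: a lumped head–arms–trunk (HAT)
segment and two hindlimbs of thigh, shank, foot (tarsometatarsal part) and
phalanges, coupled by frictionless hinges (hip, knee, ankle,
metatarsophalangeal). All segment masses, lengths, centre-of-mass fractions
and moments of inertia are the published macaque values; total mass is
10.038 kg. Generalized coordinates are the hip position, the trunk pitch and
the eight joint angles (signs: positive hip flexion, knee extension, ankle
and MP dorsiflexion; zero = adjacent segments aligned).

Passive joint elements: every joint carries a linear viscous moment
(0.109, 0.317, 0.0943, 0.01 N m s/rad at hip, knee, ankle, MP) and the knee
additionally carries the nonlinear hyperextension stop

$$T_{knee} = -k_1 \exp(-k_2 (k_3 - \theta_{knee})), \qquad
  k_1 = 1,\; k_2 = 30,\; k_3 = -0.23,$$

which engages as the knee approaches $-0.23$ rad and enforces the
macaque's bent-knee gait. No other joint limits exist in the model; gaits
that fold a joint far outside its anatomical range are eliminated by the
optimizer, not by the dynamics.

### Muscles

Ten principal muscle groups per leg (IL, GMED, VAS, TA, SOL, RF, BIFl, GAS,
EDL, FDL) are modelled as inextensible strings through origin, via and
insertion points fixed to the segments, so moment arms
($-\partial L/\partial\theta$) vary with posture. Muscle force is

$$f_m = F^{MAX}_m a_m + f^{PE}_m, \qquad
  f^{PE}_m = k_1^{PE}\left[e^{k_2^{PE}(L_m - \bar L_m)} - 1\right]$$

with the published maximal forces, $k_1^{PE} = 26$, $k_2^{PE} = 150$, and
*no* force–length, force–velocity or series-elastic (tendon) behaviour.
As printed, the PE law admits a small compressive force (bounded by
$-k_1^{PE}$) below rest length; a config flag (`clamp_nonnegative`)
restores the conventional tension-only variant.

Rest lengths $\bar L_m$ are calibrated geometrically: each muscle's rest
length equals its path length at the published reference posture (e.g. SOL
at 70° ankle dorsiflexion; GAS at knee −65°, ankle 60°), so the PE force is
exactly zero there.

**Attachment coordinates are this package's own anatomy.** The planar
attachment table is a calibrated stand-in constructed so that every
moment-arm sign matches the muscle's anatomical action across the
configured joint ranges and magnitudes are a plausible fraction (5–25%) of
the spanned segment's length. Two choices deserve mention:

* The hip extensors (GMED, BIFl) route through a pulley-like via point
  posterior to the hip, mimicking the wrap of the gluteal mass around the
  pelvis. Without it their moment arms collapse in deep hip flexion and the
  trunk folds forward irrecoverably — the bent-hip macaque posture operates
  exactly in that regime.
* The triceps surae insert slightly inferior to the foot's long axis at the
  calcaneal level, keeping the Achilles plantarflexion arm sign-stable over
  the whole ankle range used in gait.

The full table lives in the model config (`write_model_config()`) and is
user-replaceable.

### Foot–ground contact

Eight contact points per foot (six along the tarsometatarsal sole from the
heel to the metatarsal head, two under the phalanges) each carry a vertical
and a horizontal linear viscoelastic element (6000 N/m, 60 N s/m vertical;
1200 N/m, 13 N s/m horizontal). Vertical force is unilateral
(`max(0, k·pen + c·pen_rate)`); the horizontal element is a sticking
spring–damper anchored at the ground projection of the point at touchdown
— there is no Coulomb slip cap, a documented limitation of the penalty
formulation. Because the model has no interphalangeal joints, phalangeal
points are allowed to penetrate the ground force-free from toe-off until
the next sole touchdown (the swing-phase policy).

The heel morph is a single operation: `apply_heel_translation()` lowers the
most posterior sole point by up to 36 mm along the foot's plantar
direction, leaving inertia and muscle routing untouched.

## Controller

A two-layer central pattern generator. The rhythm-generation layer is a
pair of coupled phase oscillators

$$\dot\phi_R = \omega - K\sin(\phi_R - \phi_L - \pi), \qquad
  \omega = 2\pi/T,\; T = 0.747\ \mathrm{s},\; K = 1,$$

whose anti-phase state is the attractor. The pattern-formation layer maps a
leg's phase to muscle activation through a two-Gaussian mixture per muscle
(six parameters each: mixing weight γ, gain δ, peak timings μ₁, μ₂ and
widths σ₁, σ₂), normalized to its maximum on a fixed 2048-point phase grid
and scaled by δ. **The Gaussian exponent denominator is $2\sigma$, not
$2\sigma^2$** — the width parameters carry units of rad² — and the bells
are periodically extended with images at $\phi \pm 2\pi$ so the pattern is
continuous across the phase wrap (a `no_wrap`-style flag reproduces the
literal aperiodic form).

Trunk posture is stabilized by feedback through the hip uniarticular
muscles of each support leg (vertical GRF > 1 N):

$$a^{pc}_{IL} = \kappa \max(\bar\theta - \theta_{HAT}, 0), \qquad
  a^{pc}_{GMED} = \kappa \max(\theta_{HAT} - \bar\theta, 0), \qquad
  \kappa = 5.$$

Final activations are clamped to [0, 1].

**Phase resetting.** A leg's oscillator phase is reset to 0 at its
touchdown. In the integration loop a reset is accepted only when the leg's
phase is in the late half of its cycle ($\phi \ge \pi$), i.e. for genuine
post-swing contacts: with a penalty contact model, brief force chatter
around mid-stance otherwise produces spurious touchdown events whose resets
synchronize the two oscillators and convert walking into bilateral hopping
— a failure mode we observed directly in early optimization runs. Event
recognition itself uses a 1 N force threshold with a 20 ms debounce window
(both configurable).

**Soft start.** The pattern drive is multiplied by $\min(1, t/t_{ramp})$
($t_{ramp}$ = 0.4 s by default). The episode starts from quiet digitigrade
standing, and an abrupt full-amplitude stance burst at $t = 0$ launches the
model off the ground; the ramp lets it ease from standing into the limit
cycle. Posture feedback is not ramped.

## Initial conditions

The default initial state is digitigrade standing with a forward push of
0.5 m/s: right leg in an early-stance posture (hip 1.0, knee −0.8, ankle
1.1 rad; MP set so the phalanges lie flat), left leg offset into late
stance (hip −0.45, knee −0.25, ankle +0.25 rad relative to the right),
matching its oscillator phase which starts half a cycle ahead
($\phi_R = 0$, $\phi_L = \pi$). The hip height is solved so the vertical
contact springs carry exactly the body weight. Starting the two legs half a
cycle apart in both posture and phase establishes alternation from the
first step; symmetric starts reliably seed the hopping attractor instead.

## Dynamics and integration

The 11-DOF equation of motion is assembled from per-body point Jacobians
(for a planar revolute column, $J = s\,\mathrm{perp}(p - \mathrm{pivot})$;
angular rows are constant) and integrated by semi-implicit Euler at a fixed
0.1 ms step. The velocity update treats joint viscosity and the (very
stiff) knee-stop gradient implicitly on the diagonal, which keeps the
integration stable when the stop engages. The knee-stop exponent is capped
at 25 to avoid overflow in pathological postures. Verified invariants: the
free passive chain drifts < 0.1% in total mechanical energy per simulated
second, and the energy change of a muscle-driven free chain matches the
integrated fibre work to 0.5%.

A trial terminates early when the HAT centre of mass falls below 50% of
its standing height or |trunk pitch| reaches π/2 (closed thresholds,
configurable), or when a non-finite state appears.

## Gait optimization

The 60 pattern parameters (10 muscles × 6) are tuned by a real-coded
genetic algorithm minimizing

$$J = \begin{cases}
 1000\, J_{distance} & D \le 9\ \mathrm{m}\\
 w_1 J_{distance} + w_2 J_{cycle} + w_3 J_{HAT} + w_4 J_{energy}
   + w_5 J_{joint} + w_6 J_{GRF} & D > 9\ \mathrm{m}
\end{cases}$$

with $J_{distance} = 1/D$ and weights (10, 1, 0.01, 0.1, 1, 1). The
functional forms of the shaping terms are not printed in the source model,
so this package uses scale-free quadratic/normalized forms: $J_{cycle} =
(\mathrm{duty} - 0.65)^2$; $J_{HAT} = \mathrm{var}(\theta_{HAT})$;
$J_{energy}$ = gross cost of transport; $J_{joint}$ = mean squared error of
the landing leg's joint angles against a nominal touchdown posture (hip
0.87, knee −0.87, ankle 1.05, MP 0.52 rad; replaceable, weight zeroable);
$J_{GRF}$ = time-integral of braking horizontal force on the phalangeal
points while $\pi \le \phi \le 2\pi$, normalized by body weight × period.
The two-regime structure makes the search distance-first by construction.

GA design (hyperparameters are not printed in the source model): tournament
selection, BLX-α blend crossover (α = 0.5, p = 0.9), per-gene Gaussian
mutation (p = 0.1, σ = 5% of range), elitism 2, plus a 10% random-immigrant
fraction per generation — plain tournament+blend runs collapsed
prematurely (population mean J equal to best J) on this landscape. Bounds:
γ, δ ∈ [0, 1], μ ∈ [0, 2π), σ ∈ [0.01, 2] rad². Everything is driven by
the R RNG, so a seed makes runs bit-reproducible. The morphing experiment
(`run_morph_experiment()`) warm-starts each heel step from the previous
best genome; with elitism, a warm-started step can never end worse than
its initialization.

## Energetics

Contractile-element power is $p_m = F^{MAX}_m a_m \cdot (-\dot L_m)$,
accumulated at the full integration rate into positive and negative work.
PE-element power is excluded from the metabolic budget by default: the PE
spring is conservative, and charging its elastic return against metabolism
would contradict the elastic-storage mechanism the model exhibits (IL, GAS
and FDL forces are largely passive in the optimized gait). Gross metabolic
cost of transport is

$$COT = \frac{\sum_m (W^+_m/\eta^+ + |W^-_m|/\eta^-) + P_{basal} T}{M D}$$

with classic muscular efficiencies $\eta^+ = 0.25$, $\eta^- = 1.2$ and a
mass-specific basal rate of 2 W/kg. The efficiencies and basal rate are not
printed in the source model; they are declared calibration constants that
offset the absolute COT but cancel out of the morphing *trend*. Pendular
energy recovery uses the standard external-work formulation,
$R = 100\,(\sum\Delta^+E_p + \sum\Delta^+E_k - \sum\Delta^+E_{ext}) /
(\sum\Delta^+E_p + \sum\Delta^+E_k)$, over an integer number of strides.

## Analysis layer and synthetic fixtures

`gait_metrics()` reports stride-averaged cycle duration, stride length,
speed, duty factor, COT and %recovery after discarding the first two
strides (configurable); at least three complete strides must remain.
`classify_grf_profile()` stride-averages the vertical GRF over stance,
excludes the first 5% (the penalty-contact impact spike, a known modelling
artifact), and counts local maxima with prominence ≥ 5% of the profile
peak: one peak = single, two or more = double.

`make_fixture_gait()` generates seeded synthetic trials — periodic contact
events, single- or double-peaked stance GRF shapes, and a COM whose
potential and kinetic energies are anti-phase ("pendular") or in phase —
so the whole analysis layer is tested against known ground truth without
running the optimizer. The fixtures emulate periodicity, duty factor,
speed and energy phasing; they do not emulate muscle mechanics, so tests
passing on fixtures validate the *metrics*, not the simulator (the
simulator has its own invariant suite).

## What the shipped gaits do and do not reproduce

The shipped reference genomes are endpoints of staged, warm-started GA runs
(tens of thousands of evaluations). The walking solution was in fact found
through the morphing machinery itself: the plantigrade (36 mm heel-drop)
model crossed the 9 m full-objective threshold first, and the
digitigrade-foot walker was then obtained by re-optimizing while walking
the heel back down in 6 mm steps — in this model the plantigrade foot is
the easier one to walk on, which is itself consistent with the hypothesis
the experiment probes.

Running the acceptance suite against these gaits shows which published
features the model reproduces: steady-gait weight support (mean vertical
GRF within 5% of body weight), a walking duty factor near the 0.65 target,
passive-elastic dominance of the IL/GAS muscle forces, and the morphing
trends — lowering the heel reduces the cost of transport and raises
pendular %recovery by more than five percentage points. It does not
reproduce the published cadence (the phase-reset rhythm settles near 0.5 s
cycles instead of 0.71 s), the absolute cost of transport (the optimized
gait is several-fold more expensive), or the single-to-double GRF-peak
transition (both morphs walk with a moderately two-humped stance profile).
Closing those gaps would need optimization budgets well beyond the
minutes-scale runs this package's tests use, and possibly anatomical
muscle routing closer to the original 3D model than this package's planar
stand-in.

## Numerical choices and limitations

* dt = 0.1 ms everywhere; recording is subsampled (default 1–2 ms).
* Pattern normalization max on a fixed 2048-point grid (deterministic).
* Event debounce 20 ms; GRF support threshold 1 N; both shared between the
  controller and the offline event detector.
* The default problem sizes used by the shipped tests and the acceptance
  script are reduced-scale (smoke GA: population 24 × 30 generations;
  property checks on 0.3–2 s episodes); the shipped reference gaits come
  from longer warm-started searches run during development.
* Known limitations: no midtarsal break or interphalangeal joints, no
  force–length/velocity or tendon elasticity (all deliberately excluded
  from the model), no Coulomb friction cap on the horizontal contact
  element, and a planar (sagittal) world — frontal-plane balance is
  outside the model by construction.
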