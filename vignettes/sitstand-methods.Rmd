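---
title: "Simulating sit-to-stand hip joint contact forces: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sit-to-stand hip joint contact forces: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitstand)
```

## The question the simulation answers

Standing up from a chair loads the hip: the hip extensors must raise more
than half the body's mass, and every newton of extensor force presses the
femoral head into the acetabulum. How strongly the hip is loaded depends on
*how* a person stands up — in particular on how far the trunk is flexed over
the hips at seat-off, the instant the buttocks leave the chair. `sitstand`
implements a planar forward simulation that sweeps systematically over
seat-off postures, computes the hip joint contact force (HJCF) for each
resulting movement, and asks how the peak HJCF depends on the hip flexion
angle at seat-off.

Because the sweep needs thousands of movements that no experiment could
collect, every input is a model: an anthropometric body, a kinematic
template for the rise, and a muscle apparatus reduced to eight sagittal
actuators per leg.

## Body model

The body is a 2-D sagittal linkage of four rigid segments: a combined
head–arms–trunk segment (HAT), thighs, shanks and feet, mirrored and
assumed to move symmetrically so that one leg represents both. Segment
lengths, masses, centre-of-mass positions and gyration radii are fractions
of body height (1.74 m) and mass (73.8 kg), pinned in
`inst/extdata/anthropometry.csv` (Dempster-derived fractions with the arms
folded into the HAT). Masses conserve exactly: HAT + 2 × (thigh + shank +
foot) = body mass. The frame is X anterior, Y up, origin under the ankle;
the foot stays flat on the floor, so the ankle is a fixed point 0.039 × height
above the ground and the support base runs from the heel (0.06 m behind the
ankle) to the toe (heel + 0.152 × height).

## Movement generation

Seat-off postures are enumerated on a grid: the hip is held at 0.513 m
height and placed 0–40 cm behind the ankle in 1 cm steps (41 positions),
and the trunk is inclined 0–70° forward of vertical in 1° steps (71
angles), giving 41 × 71 = 2911 candidate postures. The knee follows from
two-link inverse kinematics (the anterior of the two circle intersections).
Joint angles are measured so that upright standing is (0, 0, 0): hip
flexion between trunk and thigh prolongation, knee flexion between thigh
and shank, ankle dorsiflexion as forward shank inclination.

Each posture becomes a movement by scaling all three seat-off angles with
one normalized half-cosine, `w(t) = (1 + cos(pi t / T)) / 2`, over T =
1.55 s: angles start at their seat-off values and decay smoothly to zero
(standing). The single shared waveform reproduces the stereotyped,
synchronized joint-angle decay seen in experimental rises, and makes all
derivatives analytic.

Two filters select realistic movements. A movement is *adopted* when its
seat-off angles lie in the closed ranges hip 85–145°, knee 95–120°, ankle
15–45° (an envelope widened from experimentally observed seat-off angles)
**and** the whole-body centre of mass stays horizontally within the foot
support base at every frame — not only at seat-off, since a movement whose
COM drifts outside the feet at any point could not be balanced. Adopted
movements whose seat-off hip flexion lies within 93 ± 8° — the band
reported for natural transfers — are additionally flagged *normal*. Under
the defaults this yields 732 adopted and 112 normal movements; both counts
are stable (±2) across time discretizations of 51–201 frames.

## Inverse dynamics

Joint moments come from a top-down Newton–Euler pass per leg (gravity
9.8 m/s²): half the HAT's weight and inertia load each hip, then the
thigh and shank equations yield the knee and ankle moments. Signs are hip
extension, knee extension and ankle plantarflexion positive; moments are
reported per leg, normalized by whole body mass (Nm/kg), which makes them
invariant to body mass at fixed kinematics. Velocities and accelerations
are exact analytic derivatives of the cosine trajectories, not finite
differences. The same pass yields the hip intersegmental force — the force
the pelvis applies to the femoral head before muscle forces are added.
A *static component* variant zeroes all velocities and accelerations,
isolating the gravity-only part of each moment.

The pass is verified three independent ways in the test suite: a
massless-leg reduction against the inverted-pendulum closed form
m g L sin(θ); a hand summation of gravity lever arms; and an independently
coded aggregate momentum-balance (whole-subsystem) formulation that must
agree with the recursive pass to 1e-6 on every frame.

## Muscle model

Eight muscles per leg (iliopsoas, gluteus maximus, vastus, rectus femoris,
hamstrings, tibialis anterior, soleus, gastrocnemius) act through constant
moment arms evaluated at the mean adopted seat-off posture (120° hip, 109°
knee, 35° ankle); PCSAs and arms are in `inst/extdata/muscles.csv`. Only
the contractile element is modelled: the per-frame maximum force is

F_max = k · f_ce(L) · f_v(V) · PCSA · σ,

with specific tension σ = 60 N/cm² and k = 1 except in the sensitivity
analysis. The force–length factor f_ce is a Gaussian of width 0.45 in the
fiber-length ratio, truncated to zero outside [0.5, 1.5]; the
force–velocity factor f_v is a normalized Hill hyperbola (a/F0 = 0.25,
f_v(−1) = 0, f_v(0) = 1) with a slope-continuous eccentric branch
saturating below 1.5; the maximum shortening velocity is 10 optimal fiber
lengths/s. Fiber-length ratios are quadratics in the spanned joint angles
around the reference posture (ratio 1 there), with slopes signed by
anatomical action — extensors lengthen as flexion increases — and
magnitudes chosen to keep the ratios within ≈[0.6, 1.4] over the simulated
ranges. These quadratic coefficients are a synthetic fixture: cadaver- or
model-derived curves for this 2-D reduction are not available, and the
coefficients' role is confined to scaling the optimization bounds. Passive
(parallel-elastic) force, tendon dynamics and pennation are deliberately
excluded: the moment equality constraint pins the total muscle moment, so
these refinements mostly redistribute rather than change the hip load.

## Static optimization

Each frame poses the muscle-redundancy problem

minimize J over F subject to R F = M, 0 ≤ F ≤ F_max,

with R the signed 3 × 8 moment-arm matrix and M the three joint moments.
Two convex objectives are supported: the sum of squared activations
J1 = Σ (F/F_max)² and the sum of squared stresses J2 = Σ (F/PCSA)².
Frames are independent (no activation dynamics). The solver (C++, Rcpp)
maximizes the concave dual of this diagonal-Hessian box-QP by Newton
ascent with Armijo backtracking; a bounded least-squares pass certifies
infeasibility — frames whose moments exceed what the bounded muscle forces
can produce — separately from numerical failure, and a movement with any
infeasible frame is flagged non-optimal. Feasible solutions satisfy the
moment constraints to 1e-6 Nm; the suite cross-checks the solver against a
closed-form two-muscle split, a dense brute-force search over the exactly
computed feasible intervals of 2–3-muscle reductions (1000 random
problems), and an independent QP implementation.

## Hip joint contact force

The contact force is the norm of the intersegmental force minus the pull
of the four hip-spanning muscles (iliopsoas, gluteus maximus, rectus
femoris, hamstrings) along their line-of-action unit vectors:

HJCF = ‖ v_HJF − Σ (F_n / m) ê_n ‖,

in N per kg body mass. Each ê_n points from the muscle's femoral
attachment toward its pelvic attachment — for the gluteus maximus, toward
its ischial-tuberosity via point — so muscle tension presses the joint
surfaces together. Attachment coordinates
(`inst/extdata/attachments.csv`) are a synthetic sagittal fixture; only
the unit directions matter. The sagittal model omits the gluteus medius;
`gluteus_medius_adjustment()` provides the order-of-magnitude frontal-plane
correction (≈4.1 N/kg at 11% activation).

## Sensitivity analysis

Muscle force estimates are notoriously parameter-sensitive, so the study
design re-estimates everything under perturbed parameters: for each of the
two objectives, ten random draws perturb every PCSA uniformly within ±SD,
every nonzero moment arm uniformly within ±1 cm (independently per
muscle–joint entry), and scale all normalized maximum forces by one global
k uniform in [0.5, 1.5] — 20 runs over the full adopted set, one draw
shared by all movements of a run, reproducible under a fixed seed.
Extreme arm draws (arms as short as 1.1 cm can approach zero) make some
frames infeasible; infeasible movement-runs are excluded from that run's
summaries and counted, mirroring the study's bookkeeping of non-optimal
solutions.

## Numerical and design choices

* **Time base**: 101 frames over 1.55 s (1% resolution). The adoption
  counts are discretization-robust; tests check 51 and 201 frames.
* **Closed intervals** for all angle filters; boundary postures are
  adopted.
* **Infeasibility** is a flag, never an exception, at every level
  (posture geometry, QP frame, movement, sensitivity run).
* **Determinism**: the pipeline is deterministic; the only randomness is
  the sensitivity draws under `set.seed`.
* **Problem sizes**: the full default study — 2911 postures, 732 adopted
  movements × 101 frames of inverse dynamics and QP, plus 20 sensitivity
  re-runs (≈1.5 million QP solves) — runs in about a minute on one core;
  the batch C++ solver is what makes the sensitivity sweep cheap.

## What the simulation does and does not show

The generator emulates balanced, symmetric, fixed-duration rises with a
shared cosine template; it does not emulate pre-seat-off chair loading,
asymmetric strategies, arm push-off, trunk-velocity variation, or
subject-specific anthropometry, so conclusions are about the *geometry* of
the rise, not about any individual. Quantities that average over many
adopted movements (mean seat-off angles, mean peak moments and contact
forces) are robust to the pinned fixtures; extreme-value statistics
(minima over the adopted set) sit at filter boundaries and inherit the
uncertainty of the anthropometric and support-base fixtures. The headline
relationship — peak HJCF rising approximately linearly with seat-off hip
flexion, with the minimum-load movement falling inside the normal band —
holds across all parameter perturbations in sign, with Pearson r above 0.85
in every draw and above 0.95 unperturbed.

```{r example, eval = FALSE}
# the full study at defaults (about a minute)
st <- run_full_study(study_config(n_draws_per_objective = 10, seed = 1))
print(st)
```
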