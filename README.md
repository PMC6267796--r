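# sitstand

Forward simulation of sit-to-stand (STS) movements in the sagittal plane,
built to answer one biomechanical question: **how does the hip flexion angle
at seat-off affect the hip joint contact force (HJCF) while standing up?**
Excessive cartilage stress drives hip osteoarthritis progression, and
standing up is one of the most frequent and hip-intensive tasks of daily
life, so the movement strategy that minimizes the hip load is clinically
interesting — and it cannot be found experimentally, because no subject can
perform thousands of systematically varied rises.

The package is aimed at movement scientists and biomechanists who want a
fully scripted, deterministic pipeline from posture enumeration to joint
contact force, with every model parameter exposed.

## What it computes

1. **Posture grid** — 41 hip positions × 71 trunk inclinations = 2911
   seat-off postures at a fixed 0.513 m hip height (two-link inverse
   kinematics for the knee).
2. **Kinematics** — every joint angle decays from its seat-off value to
   zero (upright standing) along one half-cosine over 1.55 s.
3. **Filters** — movements are *adopted* if seat-off angles fall in hip
   85–145° / knee 95–120° / ankle 15–45° and the whole-body COM stays over
   the feet at every frame; adopted movements with seat-off hip flexion in
   93 ± 8° are *normal*.
4. **Inverse dynamics** — per-leg Newton–Euler pass on analytic
   derivatives: hip/knee/ankle moments (Nm/kg) and the hip intersegmental
   force.
5. **Static optimization** — per frame, eight lower-limb muscle forces
   solve the convex program

   min Σₘ (F_m / F_MAX,m)²  (or Σₘ (F_m / PCSA_m)²)
   s.t. Σₘ r_{m,j} F_m = M_j  (j = hip, knee, ankle), 0 ≤ F_m ≤ F_MAX,m

   with Hill-type bounds F_MAX = k · f_ce(L̃) · f_v(L̇) · PCSA · σ,
   σ = 60 N/cm² (a batch dual-Newton QP solver in C++ handles the ~1.5
   million frame problems of a full study in seconds).
6. **Contact force** — HJCF = ‖v_HJF − Σₙ (F_n/m) êₙ‖ over the four
   hip-spanning muscles, in N per kg body mass.
7. **Sensitivity analysis** — 2 objectives × 10 random draws perturbing
   PCSA (±SD), moment arms (±1 cm) and force–length ability (k ∈
   [0.5, 1.5]), re-running everything per draw.

## Worked example

```r
library(sitstand)
st <- run_full_study(study_config(n_draws_per_objective = 2))
print(st)
#> STS study run
#>   adopted 732 movements (112 normal)
#>                                quantity        value
#>     min_abs_peak_static_hip_moment_nmkg   0.19885691
#>    min_abs_peak_static_knee_moment_nmkg   0.57964434
#>     static_ankle_moment_at_min_abs_nmkg   0.08814408
#>       min_sum_peak_hip_knee_moment_nmkg   1.78243192
#>        mean_peak_hip_moment_normal_nmkg   0.46771946
#>          sd_peak_hip_moment_normal_nmkg   0.09640682
#>        mean_peak_gmax_force_adopted_nkg  25.26096662
#>  mean_peak_hamstrings_force_adopted_nkg  21.23513511
#>  mean_peak_quadriceps_force_adopted_nkg  37.16992957
#>      mean_peak_extensor_sum_adopted_nkg  83.66603130
#>         mean_peak_gmax_force_normal_nkg  13.64889606
#>   mean_peak_hamstrings_force_normal_nkg   9.18490206
#>   mean_peak_quadriceps_force_normal_nkg  36.61983477
#>               mean_peak_hjcf_normal_nkg  23.61133907
#>                               n_adopted 732.00000000
#>                                n_normal 112.00000000
```

Reading the output: 732 of the 2911 candidate movements survive the
balance and joint-range filters, 112 of them with a "normal" seat-off hip
angle. Over the normal movements the peak hip extension moment averages
0.47 Nm/kg and the peak hip joint contact force averages 23.6 N/kg (≈2.4
body weights). The correlation table of the same study
(`st$summary$correlations`) shows the headline relationship — peak HJCF vs
seat-off hip flexion — with Pearson r = 0.97: standing up with a more
flexed hip at seat-off loads the hip joint approximately linearly more.
The movement with the smallest peak HJCF has a seat-off hip angle inside
the normal band, i.e. the natural rise is close to the hip-minimal one.

A command-line wrapper is included:

```sh
Rscript inst/cli/sitstand-cli.R run-all --out results/ --seed 1 --draws 10
Rscript inst/cli/sitstand-cli.R summarize --per-movement results/summary_per_movement.csv
```

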