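# wristdecon

Quantifying the *composition* of motor commands at the wrist — how much of
the muscle drive serves position control versus velocity control — from
surface EMG of the four wrist prime movers (ECR, ECU, FCU, FCR) and wrist
kinematics. The immediate audience is motor-control and clinical-movement
researchers who want a per-subject, per-task scalar that separates healthy
task-dependent command switching from its loss in cerebellar ataxia.

## The model

Joint torque is written two ways — from the muscles and from the movement:

    tau(t) = sum_i a_i T_i(t) = M theta''(t) + B theta'(t) + K theta(t)

with T_i the normalized muscle tensions, a_i sign-constrained
tension-to-torque weights, and M, B, K the inertial, viscous and elastic
weights of a linear viscoelastic joint. Torque itself is unmeasured, so
only *ratios* of the weights are identifiable. The package identifies the
velocity-to-position weight ratio **B/K** per subject and task by:

* **uncentered canonical correlation analysis** (`identify_task()`) —
  maximal correlation between the muscle torque and the kinematic torque,
  with no mean subtraction so the resting-posture zero is meaningful; and
* an exhaustive **(B, K) grid search with sign-constrained least squares**
  (`grid_search_bk()`) — the cross-checking route, which also shows that
  the correlation surface forms a ridge along rays of constant B/K.

Low B/K (≈ 0.17 in healthy subjects) characterizes rapid step tracking —
position-dominated commands; B/K above 1 (≈ 1.3) characterizes smooth
pursuit of a constant-speed target, where velocity must be represented
too. Patients with cerebellar ataxia keep the step value but fail to
raise the pursuit value — the two distributions overlap — and that
collapse of task-dependent switching is the quantitative readout. The
damping ratio `zeta = B / (2 sqrt(K M))` is reported alongside.

The package also provides EMG envelope extraction and 0.78 Nm-referenced
tension normalization, cosine-fit preferred directions and agonist
displacement/velocity correlations, exact Mann-Whitney group statistics,
and a model-consistent synthetic-trial generator (step tracking in 8
directions at 18°; figure-eight pursuit at 6.2°/s) so that every stage is
validated by parameter recovery without any recorded data.

## Worked example

Generate one virtual subject under the study conditions (3 × 8 step
trials, 5 pursuit trials, SNR 20 dB), run the full pipeline, and compare
the recovered ratios with the generator's ground truth:

```r
library(wristdecon)
coh <- generate_cohort(n_controls = 1, n_patients = 0, seed = 42L)
rec <- identify_cohort(coh)
rec[, c("task", "ratio_true", "ratio_est", "cc", "eigen_proportion_first")]
#>      task ratio_true ratio_est    cc eigen_proportion_first
#> 1    step      0.136     0.136 0.998                  0.997
#> 2 pursuit      1.512     1.521 0.997                  0.895
```

The step and pursuit ratios are recovered to within a percent, the
canonical correlation is near 1 (the data are model-consistent by
construction), and the first canonical pair dominates the eigenvalue sum.

Group statistics on the bundled reference cohort (per-subject B/K ratios
of 10 controls and 19 patients with cerebellar ataxia, both tasks):

```r
print(compare_groups(reference_cohort()))
#> | group | task | mean | sd | min | max | n |
#> |---|---|---|---|---|---|---|
#> | control | pursuit | 1.3 | 0.286 | 0.86 | 1.91 | 10 |
#> | control | step | 0.165 | 0.0704 | 0.03 | 0.28 | 10 |
#> | patient | pursuit | 0.537 | 0.286 | 0.2 | 1.17 | 19 |
#> | patient | step | 0.237 | 0.103 | 0.09 | 0.53 | 19 |
#>
#> Between-group tests (per task):
#>   pursuit: Mann-Whitney U = 184.0, p = 4.87e-05 (normal); t = 6.87, p = 2.21e-07
#>   step: Mann-Whitney U = 55.5, p = 0.0727 (normal); t = -1.98, p = 0.0577
#>   control: task ranges disjoint (width 0.58)
#>   patient: task ranges OVERLAP (width 0.33)
```

Reading: pursuit ratios separate the groups decisively (p ≈ 5e-5) while
step ratios do not; within controls the two tasks' distributions are
disjoint (gap 0.86 − 0.28 = 0.58) whereas within patients they overlap.

A command-line surface wraps the same workflow
(`inst/scripts/wristdecon-cli`): `simulate`, `process`, `identify-cca`,
`identify-grid`, `agonist`, `compare-groups`, `report`.

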