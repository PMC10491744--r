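# moodcpm

Connectome-based predictive modeling (CPM) of mood symptom severity from
functional connectivity matrices, for researchers studying individual-level
prediction of clinical scores — depressed mood (HDRS-5) and elevated mood
(YMRS) severity in bipolar disorder being the motivating use case — from
task-fMRI connectomes.

## The method

A subject's connectome is the symmetric matrix of Fisher-z-transformed
Pearson correlations `z_ij = atanh(r_ij)` between the time courses of
atlas nodes (368 nodes spanning cortex, subcortex, cerebellum and
brainstem; 67,528 unique edges). CPM predicts a clinical score `y` with
leave-one-out cross-validation; in each fold, on the n − 1 training
subjects:

1. every edge is correlated with `y`; edges with two-tailed `p < 0.001`
   form the **positive** (`r > 0`) and **negative** (`r < 0`) networks;
2. per-subject **network strength** is the sum of selected edge weights,
   `S+ = Σ z_e` over the positive mask (likewise `S−`);
3. ordinary least squares fits `y = β0 + β1 S+` (positive model),
   `y = β0 + β1 S−` (negative model) and `y = β0 + β1 S+ + β2 S−`
   (combined model);
4. the held-out subject's score is predicted from their strengths.

Performance is the concordance `r(ŷ, y)` and RMSE over all held-out
predictions; significance comes from a permutation test that shuffles the
score–connectome correspondence and reruns the entire pipeline
(`p_perm = (1 + #[r_null ≥ r_obs]) / (n_perm + 1)`). Edges selected in
every fold (the **consensus networks**) are interpreted through node
degrees (hub nodes), hemispheric edge types and macroscale-region pairs.
A full-sample model — masks plus coefficients — is frozen and transferred
unchanged to an independent cohort.

Because the underlying clinical fMRI data are not public, the package
ships a synthetic-cohort generator (`generate_cohort()`) that plants
known positive/negative networks with configurable per-edge effect sizes
in cohorts matching the study's structure (81 training / 43 validation
subjects, realistic score, age, gender and head-motion distributions), so
every claim the pipeline makes is checkable against ground truth.

## Worked example

The `analysis/` scripts run the whole workflow at study scale. Step 1
simulates 81 subjects over 368 nodes with a planted depressed-mood
network and one aberrant subject, then runs connectome QC:

```
Training cohort: 81 subjects, 368 nodes
HDRS-5: mean 3.23, SD 2.84, range 0-13
QC flagged 2 subject(s): S057, S080 | planted aberrant subject: S057
```

The flagged subjects (the planted one, plus one natural low-scorer caught
by the `Q1 − 1.5·IQR` fence) are excluded. Step 2 cross-validates both
targets on the remaining 79 subjects:

```
<cpm_result> target hdrs5 | n = 79 | alpha 0.001
  positive  r = 0.933, RMSE = 1.22
  negative  r = 0.921, RMSE = 1.43
  combined  r = 0.961, RMSE = 1.21
  consensus edges:  41 positive / 42 negative
```

The high concordance reflects the planted per-edge effect (r ≈ 0.5 on
80 edges), far stronger than real fMRI signal; the `ymrs` run on the same
cohort, which has no planted network, yields r ≈ 0.27 — a useful
illustration of how LOOCV concordance alone can flatter, which is exactly
why inference is by permutation. Step 3 makes the point concrete:

```
<perm_result> target hdrs5 | 1000 shuffles
  combined  observed r = 0.961, p_perm = 0.0010
<perm_result> target ymrs | 1000 shuffles
  combined  observed r = 0.273, p_perm = 0.1199
```

The planted network survives label shuffling; the apparent YMRS signal
does not. Step 4 interprets the consensus
networks and recovers the planted hubs as the highest-degree nodes:

```
positive network: 41 consensus edges; high-degree nodes:
 node_id           label hemisphere degree
      34 L_prefrontal_34       left     16
     250   R_parietal_18      right     11
...
Planted hub nodes (ground truth): positive 34, 250 | negative 144, 184
```

Step 5 freezes the full-sample model and applies it — no re-selection, no
re-fitting — to an independent 43-subject cohort with heterogeneous noise
and two missing YMRS scores:

```
HDRS-5 transfer: r = 0.934 (df = 41, p = 5.8e-20); partial r = 0.926; RMSE = 1.60; n = 43
YMRS analyzable subjects after missing-score exclusion: 41 of 43
```

See `vignettes/moodcpm-methods.Rmd` for the model, design decisions and
the generator's assumptions and limitations.

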