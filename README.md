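# dvjagree

Knee kinematics of the drop vertical jump (DVJ) and agreement analysis
between two markerless tracking devices.

The DVJ — drop from a box, land, immediately jump — is the standard field
screen for non-contact ACL injury risk: more knee valgus at landing and
less knee flexion at the deepest point of absorption mark higher-risk
movement patterns. Depth-sensor skeleton tracking makes the screen cheap
enough for mass use, but successive sensor generations do not necessarily
agree with each other. `dvjagree` implements the complete analysis chain
used to quantify that agreement, for biomechanists and sports-medicine
researchers working with skeletal joint streams:

1. **Kinematics.** Per-frame knee angles from joint positions, using the
   knee→hip vector as a femur surrogate and the knee→ankle vector as a
   tibia surrogate. The coronal (frontal-plane) angle is the deviation of
   the two X–Y projections from a straight leg, signed so that valgus is
   negative; the sagittal flexion angle is the same construction on the
   Y–Z projections, unsigned:

   θ_cor = ±(180° − ∠(P_xy f, P_xy t)),  θ_sag = 180° − ∠(P_yz f, P_yz t)

   with f = hip − knee, t = ankle − knee.
2. **Event triggers.** Initial contact (IC) at the frame the foot joint
   stops travelling downward (velocity sign change after a qualifying
   ≥ 0.10 m descent, refined on raw positions); peak coronal (PC) as the
   most-valgus angle after IC; peak sagittal (PS) as the maximal flexion
   over the whole recording.
3. **Agreement statistics.** Per parameter: Shapiro–Wilk-gated paired
   t / Wilcoxon signed-rank location tests, and the two-way
   absolute-agreement single-measure intraclass correlation ICC(A,1)
   with F test (df1 = df2 = n − 1 for two devices) and McGraw–Wong 95%
   CI, classified as poor/moderate/good/excellent at 0.5/0.75/0.9.
4. **Power.** Sample sizes for the paired t (noncentral t), Wilcoxon
   (asymptotic-relative-efficiency method) and ICC (Walter–Eliasziw–
   Donner) designs.
5. **Simulation.** A paired-device DVJ skeleton generator with exact
   ground truth (31 cm box, 30 fps, configurable anthropometry, true
   angles, between-jump variability, per-device bias/noise/dropout),
   built as an exact inverse of the angle computation so the whole
   pipeline is testable end to end.

See `vignettes/dvj-agreement-methods.Rmd` for the full model description,
conventions, and design decisions.

## Worked example

Simulate 20 jumps observed by a quiet device (3 mm joint noise) and a
noisier one (6 mm), then analyze agreement:

```r
library(dvjagree)
cfg <- dvj_sim_config(n_jumps = 20, seed = 7)
dir <- tempfile()
run_dvj_simulation(cfg,
                   noise_a = device_noise_model("azure", 0.003),
                   noise_b = device_noise_model("v2",    0.006),
                   out_dir = dir)
res <- run_dvj_analysis(file.path(dir, "azure"), file.path(dir, "v2"),
                        out_dir = file.path(dir, "report"))
print(res$agreement)
```

```
Location tests:
     parameter      mean_sd_A      mean_sd_B  difference     test      p_value
  left knee IC   -2.94 ± 2.92   -1.90 ± 3.79 -1.03947210 wilcoxon 3.299828e-01
  left knee PC   -7.86 ± 2.57  -10.17 ± 2.16  2.31583580 wilcoxon 1.907349e-05
  left knee PS 103.81 ± 16.87 103.87 ± 17.27 -0.05372016 paired_t 8.707576e-01
 right knee IC   -2.23 ± 2.95   -1.50 ± 3.11 -0.73228103 paired_t 2.380586e-01
 right knee PC   -6.40 ± 2.02   -8.85 ± 2.65  2.44784638 paired_t 4.022220e-07
 right knee PS  96.93 ± 13.02  97.50 ± 12.65 -0.57009188 paired_t 2.272114e-01

ICC(A,1):
     parameter       icc      ci_low   ci_high          F df1 df2      p_value
  left knee IC 0.4567053  0.04859889 0.7393011   2.745698  19  19 1.660867e-02
  left knee PC 0.5250514 -0.10017044 0.8316872   7.652634  19  19 2.325748e-05
  left knee PS 0.9965355  0.99127778 0.9986268 548.309250  19  19 4.375683e-22
 right knee IC 0.6001985  0.23850595 0.8182967   4.075145  19  19 1.799614e-03
 right knee PC 0.5294195 -0.09883813 0.8423355   9.527078  19  19 4.294177e-06
 right knee PS 0.9869930  0.96788922 0.9948041 156.993059  19  19 5.849706e-17
     class
      poor
  moderate
 excellent
  moderate
  moderate
 excellent
```

Reading the output: the per-frame coronal angle is only a few degrees, so
millimetre-level joint noise erodes agreement on IC/PC (poor–moderate
ICCs), while the ~100° flexion signal dwarfs the same noise (excellent
ICCs). Note the PC means: the noisier device reports systematically more
valgus PC (−10.17 vs −7.86) although neither device is biased — PC is a
post-IC *minimum*, and noisier series produce deeper extremes. The same
machinery on real paired recordings quantifies true inter-device
agreement; `write_agreement_tables()` serializes both tables as CSV.

Sample-size planning:

```r
power_table()
#>     design  n
#> 1 paired_t 34
#> 2 wilcoxon 35
#> 3      icc 66
```

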