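# epidose

EPID-based in-vivo dosimetry for external beam radiotherapy: commission the
conversion tables, reconstruct the dose actually delivered to points inside
the patient from the portal imager's transit signal, and compare it to the
treatment planning system (TPS) with clinical thresholds.

The flat-panel imager (EPID) behind the patient integrates a calibrated
signal (CU) during every beam. `epidose` converts that signal into dose at
points of interest using the *finite tissue maximum ratio* (fTMR) — the
ratio of the dose at depth of maximum dose `d_max` with a finite absorber
of thickness `t` in the beam to the dose without it — via three steps:

1. `d_epid = CU · D_calib · FC(f, t)` — CU to dose-to-water at the imager
   plane, with conversion factors `FC` commissioned per equivalent field
   size `f` and absorber thickness `t` through

   `FC = D_TPS / (D_calib · CU) · (SID/SAD)² · fTMR(t) / TMR(d_iso)`,

2. inverse square from the imager (SID) to the isocenter (SAD) and division
   by `fTMR(t)` of the absorber path along the ray,
3. inverse square from SAD to the point's source distance and
   multiplication by `TMR(f, d)` at the point's depth.

The reconstruction is the exact algebraic inverse of the commissioning
relation, so commissioning and reconstructing the same setup is the
identity — the package's central, machine-precision contract.

A bundled virtual linac (closed-form attenuation, output factors, TMR,
portal images with per-pixel ray paths) generates commissioning records,
TG-119-style multi-beam plan fixtures (AP/PA, bands, 7-beam, 9-beam) and
TPS reference doses, so the entire chain runs and is tested without any
measured data. Evaluation reports local per-beam/per-point deviations,
mean ± SD and total-dose deviation per point, 5 % plan / 8 % beam
notification thresholds, low-dose exclusion (< 10 % of the point's TPS
dose), MU-delivery sensitivity, and reproducible automatic placement of
evaluation points in the high-dose region.

## Worked example

Commission tables from a simulated measurement set, then catch a 6 %
under-delivery of a 7-beam prostate-like plan:

```r
library(epidose)

truth   <- truth_model()                  # zero-noise synthetic 6 MV beam
calib   <- calibration_config()           # 1 Gy / 100 MU, SAD 100, SID 150
records <- simulate_measurement_set(truth)
ftmr    <- derive_ftmr(records)
tmr     <- truth_tmr_table(truth)
fc      <- build_fc_table(records, simulate_tps_points(truth), calib, ftmr, tmr)
tables  <- list(ftmr = ftmr, tmr = tmr, fc = fc)

ftmr
#> <ftmr_table> ftmr-table/1
#>   fields: 6 nodes [2 .. 20]
#>   thicknesses: 5 nodes [0 .. 30]
#>   gaps: 7 nodes [20 .. 50]
#>   values: 210 cells in [0.2075, 1]

# delivered with every beam's MU cut by 6 %, plan left nominal
delivery <- make_plan("prostate", truth = truth, mu_scale = 0.94)
recon <- reconstruct_plan(delivery, tables = tables, calib = calib)
evaluate_plan(recon)
#> <deviation_report> thresholds: plan 5%, beam 8%, low-dose < 0.1 of TPS total
#>     poi mean_dev sd_dev total_dev n_used n_excluded status
#>     iso   -6.00%   0.00    -6.00%      7          0   fail
#>  rectum   -6.00%   0.00    -6.00%      7          0   fail
```

Every point reports the 6 % deficit and fails the 5 % notification
threshold; the same plan delivered as planned passes with deviations at
numerical noise. The sensitivity helper predicts the compound effect of an
MU scaling on top of a systematic baseline:

```r
mu_sensitivity(-0.6, 0.95)   # -0.6 % baseline, 5 % MU cut
#> [1] -5.57
```

## Scope

Single-point dose reconstruction on homogeneous slab phantoms. No 2-D/3-D
dose reconstruction, gamma-index, VMAT/per-segment IMRT modeling, or couch
corrections — see the methods vignette (`vignettes/transit-dosimetry.Rmd`)
for the model, its assumptions, the commissioning protocol and known
limitations.
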