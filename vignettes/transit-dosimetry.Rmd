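---
title: "EPID transit dosimetry with finite tissue maximum ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EPID transit dosimetry with finite tissue maximum ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidose)
```

## The problem

In-vivo dosimetry (IVD) verifies, during each treatment fraction, that the
dose a linac actually delivered to the patient agrees with the dose the
treatment planning system (TPS) prescribed. The electronic portal imaging
device (EPID) mounted opposite the treatment head records the transit beam
through the patient for free, without extra hardware in the beam, which
makes it an attractive IVD detector. The catch is calibration: the panel
reads out integrated *calibrated units* (CU), not dose, and the signal it
sees has been attenuated and scattered by everything between the source and
the panel.

`epidose` implements a point-dose reconstruction formalism built on the
*finite tissue maximum ratio* (fTMR): the ratio of the dose at the depth of
maximum dose (`d_max`, about 1.5 cm at 6 MV) measured with a finite absorber
of thickness `t` in the beam to the same measurement without the absorber.
Unlike a conventional TMR, the fTMR describes transmission through a finite
slab with an air gap behind it, which is exactly the transit geometry of an
EPID. Dose at a point inside the patient is recovered in three steps:

1. **CU to dose at the imager.** `d_epid = CU x D_calib x FC(f, t)`, where
   `D_calib` is the calibration dose (1 Gy per 100 MU at `d_max` for a
   10 x 10 cm^2 field at 100 cm SAD for a conventionally calibrated linac)
   and `FC` is a conversion factor commissioned per equivalent field size
   `f` and absorber thickness `t`.
2. **Projection to the isocenter plane.** Inverse square from the imager
   (at SID) to the isocenter (at SAD), and division by the fTMR of the full
   absorber path along the ray.
3. **Transfer to the point.** A second inverse-square factor from SAD to
   the point's source distance, and multiplication by the TMR at the
   point's depth (1 at `d_max` by definition).

The conversion factors are commissioned through the relation

```
FC = D_TPS / (D_calib x CU) x (SID / SAD)^2 x fTMR(t) / TMR(depth_iso)
```

and the reconstruction is the exact algebraic inverse of this relation, so
that reconstructing a commissioning setup returns the TPS dose identically.
That round-trip identity is the central contract of the package and is what
the test suite and the acceptance script measure.

### Off-isocenter points and the acquisition SID

The commissioning relation above fixes the inverse only at the isocenter
and only for the SID at which the factors were measured. Two choices close
the gap, both pinned by requiring the round trip to stay exact:

* a recorded CU is first re-referred to the commissioning SID by
  `(SID_delivery / SID_commissioning)^2` (the panel signal follows the
  inverse square law), after which the printed inverse applies unchanged.
  This makes the reconstructed dose independent of the acquisition SID,
  which the package asserts by re-simulating the same delivery at 140 and
  150 cm;
* for a point at source distance `spd` the projection carries an additional
  `(SAD / spd)^2`: the dose is first reconstructed at the isocenter
  distance and then moved to the point by inverse square.

## The lookup tables

Three tables drive the chain, all validated at construction and exact at
their grid nodes:

* **fTMR table** over (equivalent field side, absorber thickness, air gap):
  values in (0, 1], exactly 1 at `t = 0`, strictly decreasing in thickness,
  non-decreasing in field size (phantom scatter).
* **TMR table** over (field, depth): 1 at `d_max`, strictly decreasing
  beyond it. Points shallower than `d_max` (build-up region) are rejected
  rather than extrapolated - the formalism has no build-up model.
* **Conversion-factor table** over (field, thickness), stored normalized to
  1 at the reference cell (10 cm field, 5 cm absorber) with the absolute
  Gy-per-CU scale kept alongside (`fc_ref()`). Keeping the scale separate
  lets the table satisfy its normalization convention while the
  reconstruction uses absolute factors.

**Interpolation** is log-linear along thickness and depth and linear along
field size and air gap. Attenuation with depth is near-exponential, so
interpolating the logarithm is *exact* for an exponential falloff - which
is also why the package's synthetic truth model can be recovered to machine
precision between thickness nodes, a much sharper check than a tolerance
band. Field-size and gap dependence are smooth and shallow; linear
interpolation there keeps node values exact and errors second order.

**Extrapolation** is permitted up to 10% of the axis span beyond either
end, with a logged warning, and is a hard error beyond that. Oblique beams
through a 15 cm slab can present path lengths slightly beyond the thickest
commissioned absorber (30 cm); the margin covers these while still
rejecting clearly uncommissioned queries. Rectangular apertures are mapped
to the tables' square-field axis with Sterling's `4A/P` equivalent square.

## Commissioning

`simulate_measurement_set()` (or real records in the same schema) supplies
paired acquisitions: with-absorber and open-reference, per field size. The
default protocol uses square fields of 2-20 cm side, absorber thicknesses
of 5/10/20/30 cm, 100 MU, SAD 100 cm, SID 150 cm, and three
source-to-attenuator distances per thickness stepped in increments of half
the thickness (`100 - t`, `100 - t/2`, `100` cm). The third step puts the
absorber exit at the isocenter so that the commissioned air-gap axis
brackets the gaps that occur when treating phantoms centered on the
isocenter; with fewer steps, delivery-geometry gap queries can fall outside
the extrapolation margin.

Because the SSD stepping makes the observed gaps thickness-dependent, the
rectangular gap axis is the union of observed gaps and each (field,
thickness) cell is filled by a linear regression of fTMR on gap over that
cell's acquisitions - exact whenever the gap dependence is at most linear,
and exactly right for the gap-independent truth model. Duplicate setups are
averaged, with a warning when conversion factors in one cell spread by more
than 1%.

`adjust_fc_with_tps()` implements the iterative TPS-based refinement: each
cell is multiplied by `D_TPS / D_recon` for its own setup until the largest
per-cell relative change drops below `1e-4` (at most 50 iterations).
Because the reconstructed dose is linear in the cell's factor, the
iteration is a multiplicative fixed point: it converges in one step on
consistent data, absorbs a global TPS offset exactly, is idempotent at the
fixed point, and never increases the commissioning residuals. The tolerance
and cap are this package's choices; they are far below any clinically
visible effect.

## Evaluation

Deviations are *local*: `100 x (d_recon - d_tps) / d_tps` per beam and
point. Per point, the report carries the arithmetic mean and sample
standard deviation (n - 1) over non-excluded beams and the total-dose
deviation from the summed doses. The TPS-dose-weighted mean of per-beam
local deviations is algebraically identical to the deviation of the summed
doses, so a single total figure is reported; it is shown alongside the
unweighted mean because a passing mean can hide individual beams outside
threshold.

Default thresholds: 5% on the per-point total (notification level), 8% per
individual beam (warning), and beams contributing less than 10% of a
point's total TPS dose are excluded from scoring as low-dose - local
percent differences in low-dose regions are dominated by tiny absolute
differences and are not suitable evaluation points. All three are
configurable. Beams whose aperture excludes a point's projection are
reconstructed from the transmitted signal but flagged low-confidence and
excluded the same way.

`mu_sensitivity()` predicts the mean deviation when every beam's MU is
scaled: a `mu_scale` delivery compounds multiplicatively with the baseline
systematic deviation, `100 x (mu_scale x (1 + baseline/100) - 1)`, so a 5%
MU cut on a plan with a -0.6% baseline yields -5.6% at one decimal.

`auto_poi_sample()` draws a reproducible set of evaluation points (20 by
default) uniformly from the voxels receiving at least 90% of the maximum
dose on a dose grid. With no structure set in scope, the dose level stands
in for the prescription target volume; the 90% level and the count are
configurable.

## The virtual linac

The synthetic truth model makes the whole chain testable without measured
data. It is deliberately simple and fully closed-form:

* primary transmission `exp(-mu_eff(f) x path)` with
  `mu_eff(f) = mu0 (1 - k ln(f/10))`, `mu0 = 0.05 cm^-1`, `k = 0.03` -
  plausible 6 MV-like values chosen as fixtures;
* output factor `1 + 0.05 ln(f/10)`; truth TMR
  `exp(-tmr_mu(f) (d - d_max))` with `tmr_mu0 = 0.045 cm^-1`;
* portal images with per-pixel ray-box path attenuation, jaw-projected
  aperture masks, 2% out-of-field transmission, 0.5 cm pixels on a 40 cm
  panel;
* optional multiplicative Gaussian noise (default 0, so all fixture
  generation is exact and byte-reproducible); with noise, every draw is
  seeded.

Plan templates mirror the structure of the standard TG-119-style test
suite - 2-beam AP/PA (470 MU total) and bands (200 MU), 7-beam multitarget
(1043 MU) and prostate (1452 MU), 9-beam head-and-neck (2577 MU) and
C-shape (1846 MU) - delivered to a 30 x 30 x 15 cm^3 slab. Intensity
modulation is *not* modeled: a beam is a uniform jaw-defined aperture with
its own MU weight, and the C-shape template instead carries an off-axis
aperture on its gantry-0 beam so that it spares the central axis, which
reproduces the characteristic low-dose-beam behaviour at central points.
An `mu_scale` argument scales delivered MU only (plan and TPS doses stay
nominal), emulating a delivery error the chain must detect.

What passing tests therefore do **not** show about real data: the truth
model has no MLC leaf sequences or small-segment fluence, no treatment
couch (a known source of AP/PA-vs-lateral systematics), no off-axis
profile horns, no energy spectrum or panel glare, and homogeneous
water-equivalent phantoms only. Tests establish that the formalism and its
implementation are self-consistent and exactly invertible under these
conditions - the accuracy floor of the software, not of a clinic.

## Numerical choices and degenerate inputs

* Node queries short-circuit the interpolation so stored values are
  reproduced bit-exactly.
* Zero absorber thickness returns fTMR 1 without touching the table.
* `cu = 0` reconstructs 0 Gy; negative CU is an invalid-signal error;
  `d_tps = 0` makes the local deviation undefined and flags the point
  instead of scoring it.
* A ray that misses the phantom yields depth 0 with a logged warning (the
  point is treated as in air); a point in any beam's build-up region is a
  hard error.
* Problem sizes: the default commissioning set is 78 records (6 fields x
  4 thicknesses x 3 SSD steps + 6 open references), portal images are
  81 x 81 pixels, and dose grids for automatic point placement use 1 cm
  voxels over the central 10 cm cube; the full suite plus acceptance run
  completes in well under a minute on one CPU.

## Known limitations

Single points only (no 2-D/3-D dose reconstruction), no gamma-index, no
VMAT or per-segment IMRT modeling, no couch or heterogeneity corrections,
and the DICOM layer is a minimal explicit-VR little-endian subset intended
for fixture exchange rather than a general reader. The JSON fixture schemas
are the source of truth.

## A complete run

```{r pipeline}
truth <- truth_model()
calib <- calibration_config()
records <- simulate_measurement_set(truth)
ftmr <- derive_ftmr(records)
tmr <- truth_tmr_table(truth)
tps_pts <- simulate_tps_points(truth)
fc <- build_fc_table(records, tps_pts, calib, ftmr, tmr)
tables <- list(ftmr = ftmr, tmr = tmr, fc = fc)

delivery <- make_plan("prostate", truth = truth, mu_scale = 0.94)
recon <- suppressWarnings(
  reconstruct_plan(delivery, tables = tables, calib = calib),
  classes = "epidose_warning")
evaluate_plan(recon)
```

The 6% MU deficit surfaces as a -6% mean deviation at every point and
fails the 5% notification threshold, while the same plan delivered as
planned passes with deviations at the numerical-noise level. A 5% deficit
lands exactly on the threshold: the per-beam warning level of 8% leaves
headroom for exactly this kind of borderline case, which is why the report
carries the standard deviation alongside the mean.
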