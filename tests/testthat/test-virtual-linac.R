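# The synthetic-truth forward model.

test_that("CU is normalized, linear in MU, and attenuates exponentially", {
  tr <- truth_model()
  g <- beam_geometry(field_x = 10, field_y = 10, mu = 100)
  expect_equal(simulate_cu(tr, g), 1)            # open reference field
  expect_equal(simulate_cu(tr, g, mu = 200), 2)  # MU linearity
  ph <- slab_phantom(10, extent = 40)
  expect_equal(simulate_cu(tr, g, ph) / simulate_cu(tr, g), exp(-0.5),
               tolerance = 1e-12)                # mu_eff(10) * 10 = 0.5
})

test_that("the TPS stand-in reproduces the reference conditions", {
  tr <- truth_model()
  g <- beam_geometry(field_x = 10, field_y = 10, mu = 100)
  # slab thin enough that the isocenter sits exactly at d_max
  ph <- slab_phantom(3, extent = 40)
  iso <- point_of_interest("iso", c(0, 0, 0))
  expect_equal(simulate_tps_dose(tr, g, ph, iso), tr$calib$d_calib)
  expect_equal(simulate_tps_dose(tr, g, ph, iso, mu = 200),
               2 * tr$calib$d_calib)
  # build-up region is rejected
  ph2 <- slab_phantom(2, extent = 40)
  expect_error(simulate_tps_dose(tr, g, ph2, iso),
               class = "epidose_unsupported_region")
})

test_that("measurement sets have the protocol's record count", {
  tr <- truth_model()
  p1 <- default_commissioning_protocol(ssd_att_steps = 1)
  expect_length(simulate_measurement_set(tr, p1), 6 * 4 + 6)   # 30
  p2 <- default_commissioning_protocol()
  expect_length(simulate_measurement_set(tr, p2), 6 * 4 * 3 + 6)
  empty <- default_commissioning_protocol()
  empty$fields <- numeric(0)
  expect_error(simulate_measurement_set(tr, empty),
               class = "epidose_validation_error")
})

test_that("fixture generation is deterministic under a seed", {
  tr <- truth_model(noise = 0.01)
  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  write_fixture(simulate_measurement_set(tr, seed = 99), f1)
  write_fixture(simulate_measurement_set(tr, seed = 99), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and exact (noise-free) generation needs no seed at all
  tr0 <- truth_model()
  write_fixture(simulate_measurement_set(tr0), f1)
  write_fixture(simulate_measurement_set(tr0), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("plan templates mirror the published plan structure", {
  tr <- truth_model()
  totals <- c(ap_pa = 470, bands = 200, multitarget = 1043, prostate = 1452,
              head_neck = 2577, cshape = 1846)
  nbeams <- c(ap_pa = 2, bands = 2, multitarget = 7, prostate = 7,
              head_neck = 9, cshape = 9)
  for (tpl in names(totals)) {
    d <- make_plan(tpl, truth = tr)
    expect_length(d$beams, nbeams[[tpl]])
    expect_equal(sum(vapply(d$beams, `[[`, 1, "mu")), totals[[tpl]])
  }
  s <- make_plan("single_field", truth = tr, field = 10, thickness = 15)
  expect_length(s$beams, 1)
  expect_equal(s$beams[[1]]$mu, 100)
  expect_error(make_plan("vmat_arc"), class = "epidose_validation_error")
})

test_that("an MU-scaled delivery reduces the recorded signal, not the plan", {
  tr <- truth_model()
  d1 <- make_plan("prostate", truth = tr)
  d2 <- make_plan("prostate", truth = tr, mu_scale = 0.95)
  expect_equal(d2$tps$d_tps, d1$tps$d_tps)       # plan unchanged
  cu1 <- vapply(d1$images, function(im) sum(im$pixels), 1)
  cu2 <- vapply(d2$images, function(im) sum(im$pixels), 1)
  expect_equal(cu2, 0.95 * cu1, tolerance = 1e-12)
})
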