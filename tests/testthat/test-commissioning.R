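# Building fTMR and conversion-factor tables from measurement records.

make_pair <- function(field = 10, t = 10, with_dose = 0.5, open_dose = 1.0,
                      ssd_att = 90) {
  g <- function(ssd) beam_geometry(ssd_att = ssd, field_x = field,
                                   field_y = field, mu = 100)
  list(measurement_record(g(NA), 0, open_dose, 1, "open-reference"),
       measurement_record(g(ssd_att), t, with_dose, 0.5, "with-absorber"))
}

test_that("derive_ftmr takes the with/without chamber-dose ratio", {
  recs <- structure(make_pair(with_dose = 0.5, open_dose = 1.0),
                    class = "measurement_set")
  tab <- derive_ftmr(recs)
  expect_equal(ftmr_lookup(tab, 10, 10, 150 - 90 - 10), 0.5)
  expect_identical(ftmr_lookup(tab, 10, 0, 50), 1)
})

test_that("derive_ftmr recovers the simulator's closed-form attenuation", {
  fx <- ed_fixture()
  ft <- fx$ftmr
  for (f in ft$fields) {
    mu_eff <- fx$truth$mu0 * (1 - fx$truth$k * log(f / 10))
    for (t in setdiff(ft$thicknesses, 0)) {
      for (g in ft$gaps) {
        expect_equal(ftmr_lookup(ft, f, t, g), exp(-mu_eff * t),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("missing open references and duplicates are handled", {
  lone <- structure(make_pair()[2], class = "measurement_set")
  expect_error(derive_ftmr(lone), class = "epidose_pairing_error")
  # identical duplicates leave the table unchanged
  pair <- make_pair()
  dup <- structure(c(pair, pair[2]), class = "measurement_set")
  expect_equal(derive_ftmr(dup)$values, derive_ftmr(pair)$values)
})

test_that("compute_fc evaluates the commissioning relation", {
  cal <- calibration_config()
  g <- beam_geometry(field_x = 10, field_y = 10)
  expect_equal(
    compute_fc(0.8, cal, cu = 0.5, geometry = g, ftmr = 0.6, tmr = 0.9),
    0.8 / 0.5 * 2.25 * (0.6 / 0.9))
  # algebraic identity: FC = 1 when d_tps is commissioning-consistent
  d_tps <- cal$d_calib * 0.5 * (100 / 150)^2 * 0.9 / 0.6
  expect_equal(compute_fc(d_tps, cal, 0.5, g, 0.6, 0.9), 1)
  expect_error(compute_fc(0.8, cal, cu = 0, geometry = g, ftmr = 0.6, tmr = 0.9),
               class = "epidose_degenerate_input")
  expect_error(compute_fc(0.8, cal, cu = 0.5, geometry = g, ftmr = 0.6, tmr = 0),
               class = "epidose_degenerate_input")
})

test_that("build_fc_table fills the commissioning grid and normalizes", {
  fx <- ed_fixture()
  expect_identical(dim(fx$fc$values), c(6L, 4L))            # 6 fields x 4 t
  expect_equal(fc_lookup(fx$fc, fx$fc$ref_field, fx$fc$ref_thickness), 1)
  # on a commissioning grid with matched geometry every raw factor is
  # (SID/SAD)^2, so the normalized table is flat
  expect_equal(max(abs(fx$fc$values - 1)), 0, tolerance = 1e-12)
  expect_equal(fc_ref(fx$fc), (150 / 100)^2, tolerance = 1e-12)
  # dropping a TPS point leaves a named missing cell
  expect_error(
    build_fc_table(fx$records, fx$tps[-1, ], fx$calib, fx$ftmr, fx$tmr),
    class = "epidose_missing_cells")
})

test_that("TPS correction is a fixed point and absorbs a global offset", {
  fx <- ed_fixture()
  rec_fn <- make_commissioning_reconstructor(fx$records, fx$calib,
                                             fx$ftmr, fx$tmr)
  adj <- adjust_fc_with_tps(fx$fc, fx$tps, rec_fn)
  expect_true(adj$converged)
  expect_identical(adj$iterations, 1L)                      # already consistent
  expect_equal(adj$table$values, fx$fc$values, tolerance = 1e-12)
  # a 2% global TPS offset scales every cell by exactly 1.02
  tps2 <- fx$tps; tps2$d_tps <- tps2$d_tps * 1.02
  adj2 <- adjust_fc_with_tps(fx$fc, tps2, rec_fn)
  expect_equal(adj2$table$values, fx$fc$values * 1.02, tolerance = 1e-9)
  # idempotence at the fixed point
  adj3 <- adjust_fc_with_tps(adj2$table, tps2, rec_fn)
  expect_equal(adj3$table$values, adj2$table$values, tolerance = 1e-9)
  # degenerate TPS dose
  tps0 <- fx$tps; tps0$d_tps[1] <- 0
  expect_error(adjust_fc_with_tps(fx$fc, tps0, rec_fn),
               class = "epidose_degenerate_input")
})

test_that("a reconstructor that cannot match the TPS fails to converge", {
  fx <- ed_fixture()
  stubborn <- function(field, thickness, fc) 1   # ignores the table
  tps2 <- fx$tps; tps2$d_tps <- rep(2, nrow(tps2))
  err <- expect_error(adjust_fc_with_tps(fx$fc, tps2, stubborn, max_iter = 5),
                      class = "epidose_convergence_error")
  expect_true(is.matrix(err$residual))
})

test_that("the correction never worsens the commissioning residuals", {
  fx <- ed_fixture()
  rec_fn <- make_commissioning_reconstructor(fx$records, fx$calib,
                                             fx$ftmr, fx$tmr)
  # start from a table perturbed away from consistency
  fc_bad <- fx$fc
  fc_bad$values <- fc_bad$values * matrix(seq(0.95, 1.05,
                                              length.out = length(fc_bad$values)),
                                          nrow(fc_bad$values))
  resid_of <- function(fc) {
    max(vapply(seq_len(nrow(fx$tps)), function(i) {
      abs(rec_fn(fx$tps$field[i], fx$tps$thickness[i], fc) - fx$tps$d_tps[i]) /
        fx$tps$d_tps[i]
    }, numeric(1)))
  }
  before <- resid_of(fc_bad)
  adj <- adjust_fc_with_tps(fc_bad, fx$tps, rec_fn)
  expect_lt(resid_of(adj$table), before)
})
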