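# Lookup tables and geometric helpers.

test_that("equivalent square follows the 4A/P rule", {
  expect_identical(equivalent_square(10, 10), 10)
  expect_identical(equivalent_square(4, 4), 4)
  expect_equal(equivalent_square(10, 20), 2 * 200 / 30)
  expect_error(equivalent_square(0, 10), class = "epidose_invalid_geometry")
  expect_error(equivalent_square(10, -1), class = "epidose_invalid_geometry")
})

test_that("fTMR lookup is exact at nodes and log-linear in thickness", {
  tab <- ftmr_table(fields = 10, thicknesses = c(10, 20), gaps = 40,
                    values = array(c(0.58, 0.35), c(1, 2, 1)))
  expect_identical(ftmr_lookup(tab, 10, 0, 40), 1)          # no absorber
  expect_equal(ftmr_lookup(tab, 10, 10, 40), 0.58)          # node identity
  expect_equal(ftmr_lookup(tab, 10, 20, 40), 0.35)
  # log-linear midpoint: exp((ln 0.58 + ln 0.35) / 2)
  expect_equal(ftmr_lookup(tab, 10, 15, 40), sqrt(0.58 * 0.35),
               tolerance = 1e-12)
  expect_equal(round(ftmr_lookup(tab, 10, 15, 40), 4), 0.4506)
})

test_that("TMR lookup is 1 at d_max, log-linear in depth, rejects build-up", {
  tab <- tmr_table(fields = 10, depths = c(1.5, 10, 20),
                   values = matrix(c(1, 0.80, 0.55), 1, 3))
  expect_identical(tmr_lookup(tab, 10, 1.5), 1)
  expect_equal(tmr_lookup(tab, 10, 10), 0.80)
  expect_equal(tmr_lookup(tab, 10, 15), sqrt(0.80 * 0.55), tolerance = 1e-12)
  expect_equal(round(tmr_lookup(tab, 10, 15), 4), 0.6633)
  expect_error(tmr_lookup(tab, 10, 1.0), class = "epidose_unsupported_region")
})

test_that("conversion-factor lookup is bilinear and exposes its scale", {
  tab <- fc_table(fields = c(10, 20), thicknesses = c(5, 10),
                  values = matrix(c(1.0, 1.1, 1.0, 1.1), 2, 2),
                  gy_per_cu = 2.25)
  expect_equal(fc_lookup(tab, 10, 5), 1.0)                  # reference cell
  expect_equal(fc_lookup(tab, 20, 5), 1.1)
  expect_equal(fc_lookup(tab, 15, 5), 1.05)                 # linear midpoint
  expect_equal(fc_ref(tab), 2.25)
})

test_that("queries outside range plus margin fail naming the axis", {
  fx <- ed_fixture()
  err <- expect_error(ftmr_lookup(fx$ftmr, 50, 10, 40),
                      class = "epidose_out_of_range")
  expect_identical(err$axis, "field")
  expect_error(fc_lookup(fx$fc, 10, 60), class = "epidose_out_of_range")
  # within the 10% margin: extrapolated with a warning, not an error
  expect_warning(ftmr_lookup(fx$ftmr, 10, 32, 40),
                 class = "epidose_extrapolation")
})

test_that("table construction enforces the physical invariants", {
  # non-monotone in thickness
  expect_error(
    ftmr_table(10, c(5, 10), 40, array(c(0.6, 0.7), c(1, 2, 1))),
    class = "epidose_validation_error")
  # value at t = 0 must be exactly 1
  expect_error(
    ftmr_table(10, c(0, 10), 40, array(c(0.99, 0.6), c(1, 2, 1))),
    class = "epidose_validation_error")
  # fTMR above 1
  expect_error(
    ftmr_table(10, c(5, 10), 40, array(c(1.2, 0.6), c(1, 2, 1))),
    class = "epidose_validation_error")
  # decreasing with field size violates scatter monotonicity
  expect_error(
    ftmr_table(c(5, 10), 5, 40, array(c(0.8, 0.7), c(2, 1, 1))),
    class = "epidose_validation_error")
  # TMR not 1 at d_max
  expect_error(
    tmr_table(10, c(1.5, 10), matrix(c(0.98, 0.8), 1, 2)),
    class = "epidose_validation_error")
  # negative conversion factor
  expect_error(
    fc_table(10, 5, matrix(-1, 1, 1)),
    class = "epidose_validation_error")
})

test_that("lookups reproduce every stored node and stay in bounds", {
  fx <- ed_fixture()
  ft <- fx$ftmr
  for (i in seq_along(ft$fields)) {
    for (j in seq_along(ft$thicknesses)) {
      for (k in seq_along(ft$gaps)) {
        v <- ftmr_lookup(ft, ft$fields[i], ft$thicknesses[j], ft$gaps[k])
        expect_identical(v, ft$values[i, j, k])
      }
    }
  }
  set.seed(7)
  for (r in 1:50) {
    f <- runif(1, min(ft$fields), max(ft$fields))
    t <- runif(1, 0, max(ft$thicknesses))
    g <- runif(1, min(ft$gaps), max(ft$gaps))
    v <- ftmr_lookup(ft, f, t, g)
    expect_gt(v, 0); expect_lte(v, 1)
    d <- runif(1, fx$tmr$d_max, max(fx$tmr$depths))
    v2 <- tmr_lookup(fx$tmr, f, d)
    expect_gt(v2, 0); expect_lte(v2, 1)
    expect_gt(fc_lookup(fx$fc, f, runif(1, 5, 30)), 0)
  }
})
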