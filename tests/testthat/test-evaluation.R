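# Deviation reporting, thresholds, sensitivity, automatic points.

test_that("local deviation is the signed local percent difference", {
  expect_equal(local_deviation(1, 1), 0)
  expect_equal(local_deviation(0.944, 1), -5.6)
  expect_equal(local_deviation(2.12, 2), 6, tolerance = 1e-12)
  # antisymmetry of the definition
  for (a in c(0.5, 0.9, 1.3)) {
    expect_equal(local_deviation(a, 1), -100 * (1 - a) / 1)
  }
  expect_error(local_deviation(1, 0), class = "epidose_undefined_reference")
})

test_that("plan summary uses mean and sample SD over included beams", {
  rows <- data.frame(poi = "iso", dose = c(0.99, 1, 1.01), d_tps = 1,
                     deviation = c(-1, 0, 1), excluded = FALSE)
  s <- plan_summary(rows)
  expect_equal(s$mean_dev, 0)
  expect_equal(s$sd_dev, 1)                      # n - 1 denominator
  expect_equal(s$total_dev, 0)
  one <- data.frame(poi = "iso", dose = 1.02, d_tps = 1, deviation = 2,
                    excluded = FALSE)
  s1 <- plan_summary(one)
  expect_equal(s1$mean_dev, 2); expect_equal(s1$sd_dev, 0)
  allex <- transform(rows, excluded = TRUE)
  expect_error(plan_summary(allex), class = "epidose_empty_summary")
})

test_that("thresholds and low-dose exclusion flag as specified", {
  pb <- data.frame(
    beam_id = c("b1", "b2", "b3"),
    poi = "iso",
    dose = c(0.50, 0.30 * 1.081, 0.05 * 1.14),
    d_tps = c(0.50, 0.30, 0.05),
    infield = TRUE)
  pb$deviation <- local_deviation(pb$dose, pb$d_tps)
  rep <- flag_deviations(list(per_beam = pb))
  # b2 deviates 8.1% with a 35% dose share: warned, not excluded
  expect_identical(rep$per_beam$flag[2], "warn")
  expect_false(rep$per_beam$excluded[2])
  # b3 contributes < 10% of the TPS dose: excluded despite its 14% deviation
  expect_identical(rep$per_beam$flag[3], "low-dose")
  expect_true(rep$per_beam$excluded[3])
  # total deviation stays below the 5% plan threshold
  expect_lt(abs(rep$per_poi$total_dev), 5)
  expect_identical(rep$per_poi$status, "pass")
  # a 4.9% total passes at the 5% threshold, 5.1% fails
  mk <- function(dev) {
    d <- data.frame(beam_id = "b", poi = "iso", dose = 1 + dev / 100,
                    d_tps = 1, infield = TRUE)
    d$deviation <- local_deviation(d$dose, d$d_tps)
    flag_deviations(list(per_beam = d))$per_poi$status
  }
  expect_identical(mk(4.9), "pass")
  expect_identical(mk(5.1), "fail")
})

test_that("MU sensitivity compounds the baseline multiplicatively", {
  expect_equal(mu_sensitivity(0, 1), 0)
  expect_equal(mu_sensitivity(0, 0.95), -5)
  expect_equal(round(mu_sensitivity(-0.6, 0.95), 1), -5.6)
  # pure MU linearity for a zero baseline
  for (s in seq(0.8, 1.2, by = 0.05)) {
    expect_equal(mu_sensitivity(0, s), 100 * (s - 1), tolerance = 1e-12)
  }
})

test_that("automatic points sample the high-dose region reproducibly", {
  fx <- ed_fixture()
  d <- make_plan("prostate", truth = fx$truth)
  grid <- compute_dose_grid(fx$truth, d)
  pois <- auto_poi_sample(grid, n = 20, high_dose_frac = 0.90, seed = 11)
  expect_length(pois, 20)
  dmax <- max(grid$dose, na.rm = TRUE)
  for (p in pois) {
    ix <- c(match(p$position[1], grid$x), match(p$position[2], grid$y),
            match(p$position[3], grid$z))
    expect_gte(grid$dose[ix[1], ix[2], ix[3]], 0.90 * dmax)
  }
  pois2 <- auto_poi_sample(grid, n = 20, high_dose_frac = 0.90, seed = 11)
  expect_identical(lapply(pois, `[[`, "position"),
                   lapply(pois2, `[[`, "position"))
  expect_error(auto_poi_sample(grid, n = 1e6, high_dose_frac = 0.90, seed = 1),
               class = "epidose_too_few_voxels")
})

test_that("a delivered MU deficit appears one-for-one in the deviations", {
  fx <- ed_fixture()
  d <- make_plan("prostate", truth = fx$truth, mu_scale = 0.95)
  rep <- evaluate_plan(ed_reconstruct(d))
  iso <- rep$per_poi[rep$per_poi$poi == "iso", ]
  expect_equal(iso$mean_dev, -5, tolerance = 0.1)
  # a 5% deficit sits right at the plan threshold; a 6% one clearly fails
  d6 <- make_plan("prostate", truth = fx$truth, mu_scale = 0.94)
  rep6 <- evaluate_plan(ed_reconstruct(d6))
  expect_identical(rep6$per_poi$status[rep6$per_poi$poi == "iso"], "fail")
})
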