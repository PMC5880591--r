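# CU sampling, projection, and the full reconstruction chain.

test_that("radiological depth follows the ray-box geometry", {
  iso <- point_of_interest("iso", c(0, 0, 0))
  g0 <- beam_geometry(field_x = 10, field_y = 10)
  expect_equal(radiological_depth(g0, slab_phantom(30), iso), 15)
  # oblique beam through a slab normal to the vertical: 15 / cos(60 deg)
  g60 <- beam_geometry(gantry_angle = 60, field_x = 10, field_y = 10)
  expect_equal(radiological_depth(g60, slab_phantom(30, extent = 120), iso), 30,
               tolerance = 1e-12)
  # point on the source side of the slab
  above <- point_of_interest("above", c(0, 0, 40))
  expect_equal(radiological_depth(g0, slab_phantom(30), above), 0)
  # ray missing the phantom warns and returns 0
  aside <- point_of_interest("aside", c(40, 0, 0))
  expect_warning(d <- radiological_depth(g0, slab_phantom(10, extent = 20), aside),
                 class = "epidose_ray_miss")
  expect_equal(d, 0)
})

test_that("sample_cu projects with the imager magnification", {
  # pixels encode their own crossline coordinate (cm at the imager, offset
  # so the signal stays non-negative)
  n <- 81L; sp <- 0.5
  u <- (seq_len(n) - (n + 1) / 2) * sp
  img <- portal_image(matrix(u + 30, n, n, byrow = TRUE), spacing = sp,
                      sid = 150)
  g <- beam_geometry(field_x = 10, field_y = 10)
  poi <- point_of_interest("p", c(1.5, 0, 0))       # 1.5 cm lateral at SAD
  expect_equal(sample_cu(img, g, poi) - 30, 1.5 * 150 / 100, tolerance = 1e-9)
  # a uniform image returns the uniform value anywhere on the panel
  uni <- portal_image(matrix(0.7, n, n), spacing = sp, sid = 150)
  expect_equal(sample_cu(uni, g, point_of_interest("q", c(3, -4, 2))), 0.7)
  # projection beyond the panel edge
  far <- point_of_interest("far", c(15, 0, 0))      # 22.5 cm at the imager
  expect_error(sample_cu(img, g, far), class = "epidose_off_imager")
})

test_that("CU to imager-plane dose is linear with the conversion factor", {
  cal <- calibration_config()
  expect_equal(cu_to_epid_dose(0, cal, 2.4), 0)
  expect_equal(cu_to_epid_dose(0.5, cal, 2.4), 1.2)
  expect_equal(cu_to_epid_dose(1.0, cal, 2.4), 2 * cu_to_epid_dose(0.5, cal, 2.4))
  expect_error(cu_to_epid_dose(-0.1, cal, 2.4), class = "epidose_invalid_signal")
  expect_error(cu_to_epid_dose(0.5, cal, 0), class = "epidose_degenerate_input")
})

test_that("projection inverts the commissioning relation", {
  g <- beam_geometry(field_x = 10, field_y = 10)
  # at d_max the TMR contributes 1; with no absorber the fTMR contributes 1
  d1 <- project_to_poi(1, g, ftmr_val = 1, tmr_val = 1)
  expect_equal(d1, (100 / 150)^2)
  expect_equal(project_to_poi(1, g, ftmr_val = 0.5, tmr_val = 1), 2 * d1)
  # off-isocenter point: additional inverse square from SAD to the point
  expect_equal(project_to_poi(1, g, 1, 1, spd = 110),
               d1 * (100 / 110)^2)
  expect_error(project_to_poi(1, g, ftmr_val = 0, tmr_val = 1),
               class = "epidose_degenerate_input")
})

test_that("single-field deliveries round-trip through the chain", {
  fx <- ed_fixture()
  for (f in c(4, 10, 15)) {
    for (t in c(5, 15, 30)) {
      d <- make_plan("single_field", truth = fx$truth, field = f, thickness = t)
      rp <- ed_reconstruct(d)
      iso <- rp$per_beam[rp$per_beam$poi == "iso", ]
      expect_lt(abs(local_deviation(iso$dose, iso$d_tps)), 0.05)
    }
  }
})

test_that("the chain is linear in MU and in CU", {
  fx <- ed_fixture()
  iso <- point_of_interest("iso", c(0, 0, 0))
  mk <- function(mu) {
    b <- beam_geometry(field_x = 10, field_y = 10, mu = mu, id = "b1")
    ph <- slab_phantom(15, extent = 30)
    list(beams = list(b), phantom = ph, pois = list(iso),
         tps = plan_tps_doses(fx$truth, list(b), ph, list(iso)),
         images = list(simulate_portal_image(fx$truth, b, ph)))
  }
  r1 <- ed_reconstruct(mk(100))
  r2 <- ed_reconstruct(mk(200))   # MU doubled in plan and delivery
  expect_equal(r2$per_beam$dose, 2 * r1$per_beam$dose, tolerance = 1e-12)
  expect_equal(r2$per_poi$total, r1$per_beam$dose * 2, tolerance = 1e-12)
  # doubling the recorded CU alone doubles the reconstructed dose
  p <- mk(100)
  p$images[[1]]$pixels <- p$images[[1]]$pixels * 2
  r3 <- ed_reconstruct(p)
  expect_equal(r3$per_beam$dose, 2 * r1$per_beam$dose, tolerance = 1e-12)
})

test_that("reconstruction is invariant to the acquisition SID", {
  fx <- ed_fixture()
  iso <- point_of_interest("iso", c(0, 0, 0))
  ph <- slab_phantom(15, extent = 30)
  mk <- function(sid) {
    b <- beam_geometry(sid = sid, field_x = 10, field_y = 10, mu = 100, id = "b1")
    list(beams = list(b), phantom = ph, pois = list(iso),
         tps = plan_tps_doses(fx$truth, list(b), ph, list(iso)),
         images = list(simulate_portal_image(fx$truth, b, ph)))
  }
  d150 <- ed_reconstruct(mk(150))$per_beam$dose
  d140 <- ed_reconstruct(mk(140))$per_beam$dose
  expect_equal(d140, d150, tolerance = 1e-6)
})

test_that("plan integrity and build-up placement are enforced", {
  fx <- ed_fixture()
  d <- make_plan("ap_pa", truth = fx$truth)
  d$images <- d$images[1]                       # drop the PA image
  expect_error(ed_reconstruct(d), class = "epidose_plan_integrity")
  d2 <- make_plan("ap_pa", truth = fx$truth)
  shallow <- point_of_interest("shallow", c(0, 0, 7))  # 0.5 cm below surface
  expect_error(
    ed_reconstruct(d2, pois = list(shallow)),
    class = "epidose_unsupported_region")
})

test_that("multi-beam plans reconstruct their reference doses", {
  fx <- ed_fixture()
  for (tpl in c("ap_pa", "prostate", "cshape")) {
    d <- make_plan(tpl, truth = fx$truth)
    rp <- ed_reconstruct(d)
    rep <- evaluate_plan(rp)
    iso <- rep$per_poi[rep$per_poi$poi == "iso", ]
    expect_lt(abs(iso$total_dev), 0.5)
    expect_identical(iso$status, "pass")
    # totals are the per-beam sums
    for (p in rep$per_poi$poi) {
      rows <- rp$per_beam[rp$per_beam$poi == p, ]
      expect_equal(sum(rows$dose),
                   rp$per_poi$total[rp$per_poi$poi == p])
    }
  }
})
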