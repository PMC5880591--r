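# Virtual linac: a closed-form 6 MV-like forward model that generates
# commissioning records, portal images and TPS reference doses. It is the
# synthetic truth every other module is verified against: primary beam
# attenuation is exponential with a field-size-dependent effective
# coefficient, output factors and TMR follow smooth parametric forms, and
# both CU and dose are exactly linear in MU.

#' Virtual-linac truth model
#'
#' Parametric forward model of a 6 MV-like beam plus portal imager:
#' * effective attenuation `mu_eff(f) = mu0 * (1 - k * ln(f / 10))` (1/cm),
#'   decreasing with field size as phantom scatter partially compensates
#'   primary attenuation;
#' * output factor `OF(f) = 1 + of_coeff * ln(f / 10)`;
#' * truth TMR `exp(-tmr_mu(f) * (depth - d_max))` with
#'   `tmr_mu(f) = tmr_mu0 * (1 - tmr_k * ln(f / 10))`;
#' * out-of-aperture transmission, and optional multiplicative Gaussian
#'   noise on simulated signals (relative SD, default 0 so all fixtures are
#'   exact).
#'
#' @param mu0 effective linear attenuation coefficient at the 10 cm field
#'   (1/cm).
#' @param k relative decrease of `mu_eff` per ln(field/10).
#' @param of_coeff output-factor slope per ln(field/10).
#' @param tmr_mu0,tmr_k TMR falloff coefficient and its field-size slope.
#' @param transmission relative dose/CU level outside the jaw aperture.
#' @param noise relative standard deviation of multiplicative Gaussian noise.
#' @param calib the reference [calibration_config()].
#' @return an object of class `truth_model`.
#' @export
#' @examples
#' truth_model()
truth_model <- function(mu0 = 0.05, k = 0.03, of_coeff = 0.05,
                        tmr_mu0 = 0.045, tmr_k = 0.03,
                        transmission = 0.02, noise = 0,
                        calib = calibration_config()) {
  chk_num(mu0, "mu0", positive = TRUE)
  chk_num(k, "k")
  chk_num(of_coeff, "of_coeff")
  chk_num(tmr_mu0, "tmr_mu0", positive = TRUE)
  chk_num(transmission, "transmission", nonneg = TRUE)
  chk_num(noise, "noise", nonneg = TRUE)
  stopifnot(inherits(calib, "calibration_config"))
  structure(list(mu0 = mu0, k = k, of_coeff = of_coeff,
                 tmr_mu0 = tmr_mu0, tmr_k = tmr_k,
                 transmission = transmission, noise = noise, calib = calib),
            class = "truth_model")
}

.mu_eff <- function(truth, eq_field) truth$mu0 * (1 - truth$k * log(eq_field / 10))
.of <- function(truth, eq_field) 1 + truth$of_coeff * log(eq_field / 10)
.tmr_truth <- function(truth, eq_field, depth) {
  mu <- truth$tmr_mu0 * (1 - truth$tmr_k * log(eq_field / 10))
  exp(-mu * (depth - truth$calib$d_max))
}

.apply_noise <- function(x, noise, seed = NULL) {
  if (noise <= 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  x * (1 + noise * rnorm(length(x)))
}

#' Simulate the central calibrated-unit (CU) signal of a portal image
#'
#' The CU integrated over one delivery is `(mu / 100) * OF(f) *
#' exp(-mu_eff(f) * path) * (ref_sid / sid)^2`, normalized so an open
#' reference field (100 MU, reference field and SID, no absorber) reads
#' exactly 1 CU. `path` is the absorber traversal along the central axis.
#'
#' @param truth a [truth_model()].
#' @param geometry a [beam_geometry()].
#' @param phantom a [slab_phantom()] or `NULL` for an open field.
#' @param mu monitor units (defaults to `geometry$mu`).
#' @param noise,seed optional multiplicative noise and seed.
#' @return scalar CU.
#' @export
simulate_cu <- function(truth, geometry, phantom = NULL, mu = geometry$mu,
                        noise = truth$noise, seed = NULL) {
  eq <- equivalent_square(geometry$field_x, geometry$field_y)
  path <- if (is.null(phantom) || phantom$thickness == 0) 0 else {
    .beam_point_quantities(geometry, phantom, matrix(c(0, 0, 0), 1))$path
  }
  cu <- (mu / 100) * .of(truth, eq) * exp(-.mu_eff(truth, eq) * path) *
    (truth$calib$ref_sid / geometry$sid)^2
  .apply_noise(cu, noise, seed)
}

#' Simulate an integrated portal image
#'
#' Each pixel carries the attenuation along its own ray from the source
#' through the phantom to the pixel (ray-box path length), times the
#' in-aperture mask (the jaw edge projected with magnification `sid / sad`,
#' honoring the aperture center offset) with out-of-aperture transmission.
#' On the central axis this reduces to [simulate_cu()].
#'
#' @inheritParams simulate_cu
#' @param panel panel side length at the imager plane (cm).
#' @param spacing pixel spacing at the imager plane (cm).
#' @return a [portal_image()].
#' @export
simulate_portal_image <- function(truth, geometry, phantom = NULL,
                                  mu = geometry$mu, panel = 40, spacing = 0.5,
                                  noise = truth$noise, seed = NULL) {
  eq <- equivalent_square(geometry$field_x, geometry$field_y)
  open_cu <- (mu / 100) * .of(truth, eq) *
    (truth$calib$ref_sid / geometry$sid)^2
  n <- floor(panel / spacing) + 1L
  u <- (seq_len(n) - (n + 1) / 2) * spacing    # crossline, cm at imager
  v <- u                                       # inline
  # pixel positions in the fixed frame: S + sid * w + u * e1 + v * e2
  S <- .source_position(geometry)
  ax <- .beam_axes(geometry)
  grid <- expand.grid(v = v, u = u)            # column-major: rows = inline
  P <- matrix(S, nrow(grid), 3, byrow = TRUE) +
    geometry$sid * matrix(ax$w, nrow(grid), 3, byrow = TRUE) +
    grid$u %o% ax$e1 + grid$v %o% ax$e2
  path <- if (is.null(phantom) || phantom$thickness == 0) 0 else {
    .beam_point_quantities(geometry, phantom, P)$path
  }
  scale <- geometry$sad / geometry$sid
  inx <- abs(u * scale - geometry$aperture_cx) <= geometry$field_x / 2 + 1e-9
  iny <- abs(v * scale - geometry$aperture_cy) <= geometry$field_y / 2 + 1e-9
  mask <- outer(iny, inx)                      # rows = inline, cols = crossline
  px <- open_cu * exp(-.mu_eff(truth, eq) * path) *
    ifelse(mask, 1, truth$transmission)
  px <- .apply_noise(px, noise, seed)
  portal_image(matrix(px, n, n), spacing = spacing, sid = geometry$sid,
               beam_id = geometry$id)
}

# vectorized truth dose at points P (n x 3); NA where depth < d_max
.tps_dose_points <- function(truth, geometry, phantom, P, mu = geometry$mu) {
  eq <- equivalent_square(geometry$field_x, geometry$field_y)
  q <- .beam_point_quantities(geometry, phantom, P)
  ok <- !q$miss & q$depth >= truth$calib$d_max - 1e-9
  dose <- rep(NA_real_, nrow(q))
  dose[ok] <- (mu / 100) * truth$calib$d_calib * .of(truth, eq) *
    .tmr_truth(truth, eq, q$depth[ok]) *
    (truth$calib$ref_sad / q$spd[ok])^2 *
    ifelse(q$infield[ok], 1, truth$transmission)
  dose
}

#' Simulate the TPS reference dose at a point
#'
#' Stand-in for the planning-system calculation: `(mu / 100) * d_calib *
#' OF(f) * TMR_truth(f, depth) * (ref_sad / spd)^2`, times the aperture
#' transmission when the point is outside the jaw-projected field. Points in
#' the build-up region (depth < d_max) are rejected.
#'
#' @inheritParams simulate_cu
#' @param poi a [point_of_interest()].
#' @return dose in Gy.
#' @export
simulate_tps_dose <- function(truth, geometry, phantom, poi,
                              mu = geometry$mu) {
  d <- .tps_dose_points(truth, geometry, phantom,
                        matrix(poi$position, ncol = 3), mu = mu)
  if (is.na(d)) {
    ed_stop("epidose_unsupported_region",
            sprintf("point '%s' is in the build-up region or outside the phantom",
                    poi$label))
  }
  d
}

#' Default commissioning protocol
#'
#' The measurement grid used to commission the tables: square fields of 2,
#' 4, 8, 10, 15 and 20 cm side at 100 cm SAD, solid-water thicknesses of 5,
#' 10, 20 and 30 cm, the imager at 150 cm SID, 100 MU per acquisition, and
#' the source-to-attenuator distance stepped in increments of half the
#' attenuator thickness (`ssd_att = 100 - t, 100 - t/2, 100`), so the
#' commissioned air-gap range brackets the gaps that occur when treating
#' through phantoms centered on the isocenter.
#'
#' @param fields,thicknesses grid axes (cm).
#' @param ssd_att_steps number of SSD_att positions per thickness (1 to 3).
#' @param sad,sid,mu acquisition geometry and monitor units.
#' @return a list describing the protocol.
#' @export
default_commissioning_protocol <- function(fields = c(2, 4, 8, 10, 15, 20),
                                           thicknesses = c(5, 10, 20, 30),
                                           ssd_att_steps = 3,
                                           sad = 100, sid = 150, mu = 100) {
  stopifnot(length(fields) >= 1, length(thicknesses) >= 1,
            ssd_att_steps %in% 1:3)
  list(fields = fields, thicknesses = thicknesses,
       ssd_att_steps = ssd_att_steps, sad = sad, sid = sid, mu = mu)
}

#' Simulate a commissioning measurement set
#'
#' One with-absorber record per (field, thickness, SSD_att) setup plus one
#' open-reference record per field size. Chamber doses follow the truth
#' attenuation `exp(-mu_eff(f) * t)` relative to the open field; CU follows
#' [simulate_cu()]. With `noise = 0` (the default) the output is exact and
#' byte-identical across runs; with noise it is reproducible under `seed`.
#'
#' @param truth a [truth_model()].
#' @param protocol a [default_commissioning_protocol()]-style list.
#' @param noise,seed optional multiplicative noise and seed.
#' @return a list of [measurement_record()]s.
#' @export
simulate_measurement_set <- function(truth,
                                     protocol = default_commissioning_protocol(),
                                     noise = truth$noise, seed = NULL) {
  if (length(protocol$fields) == 0 || length(protocol$thicknesses) == 0) {
    ed_stop("epidose_validation_error", "empty commissioning protocol")
  }
  if (!is.null(seed)) set.seed(seed)
  recs <- list()
  for (f in protocol$fields) {
    g_open <- beam_geometry(sad = protocol$sad, sid = protocol$sid,
                            field_x = f, field_y = f, mu = protocol$mu)
    open_dose <- (protocol$mu / 100) * truth$calib$d_calib * .of(truth, f)
    recs[[length(recs) + 1L]] <- measurement_record(
      geometry = g_open, thickness = 0,
      chamber_dose = .apply_noise(open_dose, noise),
      cu = simulate_cu(truth, g_open, NULL, noise = noise),
      role = "open-reference")
    for (t in protocol$thicknesses) {
      ssd_list <- c(protocol$sad - t, protocol$sad - t / 2,
                    protocol$sad)[seq_len(protocol$ssd_att_steps)]
      for (ssd in ssd_list) {
        ph <- slab_phantom(t, extent = 40,
                           center = c(0, 0, protocol$sad - ssd - t / 2))
        g <- beam_geometry(sad = protocol$sad, sid = protocol$sid,
                           ssd_att = ssd, field_x = f, field_y = f,
                           mu = protocol$mu)
        dose <- open_dose * exp(-.mu_eff(truth, f) * t)
        recs[[length(recs) + 1L]] <- measurement_record(
          geometry = g, thickness = t,
          chamber_dose = .apply_noise(dose, noise),
          cu = simulate_cu(truth, g, ph, noise = noise),
          role = "with-absorber")
      }
    }
  }
  structure(recs, class = "measurement_set")
}

#' Simulate TPS reference doses for the commissioning grid
#'
#' One reference point per (field, thickness) cell: the planned dose at the
#' isocenter of a slab centered at the isocenter (depth t/2, distance SAD).
#'
#' @param truth a [truth_model()].
#' @param protocol a [default_commissioning_protocol()]-style list.
#' @return data frame with columns `field`, `thickness`, `d_tps`.
#' @export
simulate_tps_points <- function(truth,
                                protocol = default_commissioning_protocol()) {
  grid <- expand.grid(field = protocol$fields,
                      thickness = protocol$thicknesses)
  grid$d_tps <- vapply(seq_len(nrow(grid)), function(i) {
    f <- grid$field[i]; t <- grid$thickness[i]
    g <- beam_geometry(sad = protocol$sad, sid = protocol$sid,
                       field_x = f, field_y = f, mu = protocol$mu)
    ph <- slab_phantom(t, extent = 40)
    simulate_tps_dose(truth, g, ph, point_of_interest("iso", c(0, 0, 0)))
  }, numeric(1))
  grid
}

#' Truth TMR table
#'
#' Samples the truth model's TMR on a grid, yielding the beam-data TMR table
#' a clinic would take from its water-tank commissioning.
#'
#' @param truth a [truth_model()].
#' @param fields,depths axis vectors (cm); `depths[1]` defaults to `d_max`.
#' @return a [tmr_table()].
#' @export
truth_tmr_table <- function(truth,
                            fields = c(2, 4, 8, 10, 15, 20, 24),
                            depths = c(truth$calib$d_max,
                                       2.5, 5, 7.5, 10, 12.5, 15, 20, 25, 30, 35)) {
  vals <- outer(fields, depths, function(f, d) .tmr_truth(truth, f, d))
  tmr_table(fields, depths, vals, d_max = truth$calib$d_max)
}

# --- plan templates ---------------------------------------------------------

.plan_templates <- function() {
  a7 <- c(0, 50, 100, 150, 210, 260, 310)
  a9 <- seq(0, 320, by = 40)
  list(
    single_field = list(angles = 0, field = c(10, 10), total_mu = 100,
                        weights = 1, thickness = 15,
                        pois = list(c("iso", 0, 0, 0, "isocenter"),
                                    c("L1.5", -1.5, 0, 0, "offset"))),
    ap_pa = list(angles = c(0, 180), field = c(10, 10), total_mu = 470,
                 weights = c(1, 1), thickness = 15,
                 pois = list(c("iso", 0, 0, 0, "isocenter"),
                             c("L1.5", -1.5, 0, 0, "offset"),
                             c("LA1.5", -1.06, 0, 1.06, "offset"))),
    bands = list(angles = c(0, 180), field = c(15, 6), total_mu = 200,
                 weights = c(1, 1), thickness = 15,
                 pois = list(c("iso", 0, 0, 0, "isocenter"),
                             c("S2", 0, 2, 0, "offset"),
                             c("I2", 0, -2, 0, "offset"),
                             c("S4", 0, 4, 0, "offset"),
                             c("I4", 0, -4, 0, "offset"))),
    multitarget = list(angles = a7, field = c(12, 12), total_mu = 1043,
                       weights = c(1.15, 0.95, 1.0, 1.05, 0.9, 1.1, 0.85),
                       thickness = 15,
                       pois = list(c("iso", 0, 0, 0, "isocenter"),
                                   c("sup", 0, 2, 0, "target"),
                                   c("inf", 0, -2, 0, "target"))),
    prostate = list(angles = a7, field = c(8, 8), total_mu = 1452,
                    weights = c(1.1, 0.95, 1.05, 1.0, 0.9, 1.08, 0.92),
                    thickness = 15,
                    pois = list(c("iso", 0, 0, 0, "isocenter"),
                                c("rectum", 0, 0, -2, "OAR"))),
    head_neck = list(angles = a9, field = c(14, 14), total_mu = 2577,
                     weights = c(1.1, 0.9, 1.05, 0.95, 1.0, 1.08, 0.92, 1.02, 0.98),
                     thickness = 15,
                     pois = list(c("iso", 0, 0, 0, "isocenter"),
                                 c("cord", 0, 0, -3, "OAR"))),
    cshape = list(angles = a9, field = c(10, 10), total_mu = 1846,
                  weights = c(0.5, 1.05, 1.1, 0.95, 1.0, 1.02, 0.98, 1.08, 0.92),
                  thickness = 15, block_first = TRUE,
                  pois = list(c("iso", 0, 0, 0, "isocenter"),
                              c("cord", 0, 0, -2, "OAR")))
  )
}

#' Build a synthetic treatment plan with matching delivery fixtures
#'
#' Generates a plan from a named template (beam angles, apertures and MU
#' weights structured like the standard TG-119-style test suite: 2-beam
#' AP/PA and bands, 7-beam multitarget/prostate, 9-beam head-and-neck and
#' C-shape), together with simulated portal images of the delivery and TPS
#' reference doses at the template's points of interest. In the C-shape
#' template the gantry-0 beam carries an off-axis aperture so that it spares
#' the central axis, mimicking a beam that avoids a central organ at risk.
#'
#' `mu_scale` scales the *delivered* MU only: the plan and its TPS reference
#' doses keep the nominal MU, so a scale of 0.95 emulates a 5% delivery
#' error that the dosimetry chain should detect.
#'
#' @param template template name: `"single_field"`, `"ap_pa"`, `"bands"`,
#'   `"multitarget"`, `"prostate"`, `"head_neck"` or `"cshape"`.
#' @param truth a [truth_model()].
#' @param mu_scale delivered-MU scale factor (> 0).
#' @param field,thickness overrides for the single-field template: square
#'   field side and slab thickness (cm).
#' @param noise,seed optional image noise and seed.
#' @return an object of class `virtual_delivery`: a list with `beams`,
#'   `phantom`, `pois`, `tps` (data frame `beam_id`, `poi`, `d_tps`),
#'   `images`, `template` and `mu_scale`.
#' @export
#' @examples
#' d <- make_plan("ap_pa")
#' length(d$beams)
make_plan <- function(template, truth = truth_model(), mu_scale = 1,
                      field = 10, thickness = 15, noise = truth$noise,
                      seed = NULL) {
  tpl <- .plan_templates()[[template]]
  if (is.null(tpl)) {
    ed_stop("epidose_validation_error",
            sprintf("unknown plan template '%s'", template))
  }
  chk_num(mu_scale, "mu_scale", positive = TRUE)
  if (template == "single_field") {
    tpl$field <- c(field, field)
    tpl$thickness <- thickness
  }
  mus <- tpl$total_mu * tpl$weights / sum(tpl$weights)
  phantom <- slab_phantom(tpl$thickness, extent = 30)
  beams <- lapply(seq_along(tpl$angles), function(i) {
    cx <- 0; fx <- tpl$field[1]
    if (isTRUE(tpl$block_first) && i == 1L) { cx <- 7; fx <- 8 }
    beam_geometry(gantry_angle = tpl$angles[i], field_x = fx,
                  field_y = tpl$field[2], mu = mus[i], aperture_cx = cx,
                  id = sprintf("%s_b%02d_g%03d", template, i, round(tpl$angles[i])))
  })
  pois <- lapply(tpl$pois, function(p) {
    point_of_interest(p[1], as.numeric(p[2:4]), p[5])
  })
  tps <- plan_tps_doses(truth, beams, phantom, pois)
  if (!is.null(seed)) set.seed(seed)
  images <- lapply(beams, function(b) {
    simulate_portal_image(truth, b, phantom, mu = b$mu * mu_scale,
                          noise = noise)
  })
  structure(list(beams = beams, phantom = phantom, pois = pois, tps = tps,
                 images = images, template = template, mu_scale = mu_scale),
            class = "virtual_delivery")
}

#' TPS reference doses for a set of beams and points
#'
#' @param truth a [truth_model()].
#' @param beams list of [beam_geometry()] (or a `virtual_delivery`).
#' @param phantom a [slab_phantom()].
#' @param pois list of [point_of_interest()].
#' @return data frame with columns `beam_id`, `poi`, `d_tps` (Gy).
#' @export
plan_tps_doses <- function(truth, beams, phantom = NULL, pois) {
  if (inherits(beams, "virtual_delivery")) {
    phantom <- phantom %||% beams$phantom
    beams <- beams$beams
  }
  rows <- do.call(rbind, lapply(beams, function(b) {
    data.frame(beam_id = b$id %||% NA_character_,
               poi = vapply(pois, function(p) p$label, ""),
               d_tps = vapply(pois, function(p) {
                 simulate_tps_dose(truth, b, phantom, p)
               }, numeric(1)))
  }))
  rownames(rows) <- NULL
  rows
}

#' Truth dose grid for a delivery
#'
#' Sums the per-beam truth dose on a regular voxel grid inside the phantom;
#' used to locate the high-dose region for automatic point placement.
#' Voxels that fall in the build-up region of any beam are `NA`.
#'
#' @param truth a [truth_model()].
#' @param delivery a `virtual_delivery` from [make_plan()].
#' @param spacing voxel spacing in cm.
#' @param half_extent half side of the sampled cube around the isocenter (cm).
#' @return a list of class `dose_grid` with axis vectors `x`, `y`, `z` and a
#'   3-D `dose` array in Gy.
#' @export
compute_dose_grid <- function(truth, delivery, spacing = 1, half_extent = 5) {
  ph <- delivery$phantom
  ax <- function(lo, hi) seq(max(lo, -half_extent), min(hi, half_extent),
                             by = spacing)
  x <- ax(ph$lo[1] + 2, ph$hi[1] - 2)
  y <- ax(ph$lo[2] + 2, ph$hi[2] - 2)
  z <- ax(ph$lo[3] + 2, ph$hi[3] - 2)
  P <- as.matrix(expand.grid(x = x, y = y, z = z))
  dose <- rep(0, nrow(P))
  for (b in delivery$beams) {
    dose <- dose + .tps_dose_points(truth, b, ph, P)
  }
  structure(list(x = x, y = y, z = z,
                 dose = array(dose, c(length(x), length(y), length(z)))),
            class = "dose_grid")
}
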