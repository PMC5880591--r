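# Reconstruction: integrated portal-image CU -> dose at points of interest.
# Step 1: CU -> dose-to-water at the imager plane and depth d_max via the
# conversion factors. Step 2: inverse-square projection to the isocenter
# plane (the exact algebraic inverse of the commissioning relation).
# Step 3: transfer to the point's depth and source distance with the
# fTMR / TMR ratio and a second inverse-square factor.

#' Integrated portal image
#'
#' Calibrated-unit pixel array recorded at the imager plane, integrated over
#' the delivery of one beam. Rows run along the inline (y) direction,
#' columns along the crossline (x) direction; the panel is centered on the
#' beam axis.
#'
#' @param pixels numeric matrix of CU values (all >= 0).
#' @param spacing pixel spacing at the imager plane (cm).
#' @param sid source-to-imager distance (cm).
#' @param beam_id identifier linking the image to its beam.
#' @return an object of class `portal_image`.
#' @export
portal_image <- function(pixels, spacing, sid, beam_id = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || anyNA(pixels)) {
    ed_stop("epidose_validation_error", "'pixels' must be a numeric matrix")
  }
  if (any(pixels < 0)) {
    ed_stop("epidose_invalid_signal", "CU pixel values must be >= 0")
  }
  chk_num(spacing, "spacing", positive = TRUE)
  chk_num(sid, "sid", positive = TRUE)
  structure(list(pixels = pixels, spacing = spacing, sid = sid,
                 beam_id = beam_id),
            class = "portal_image")
}

#' @export
print.portal_image <- function(x, ...) {
  cat(sprintf("<portal_image> %d x %d px, %.2f cm spacing, SID %g cm%s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing, x$sid,
              if (is.null(x$beam_id)) "" else paste0(", beam ", x$beam_id)))
  cat(sprintf("  CU range [%.4g, %.4g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Sample the CU at a point's projection on the imager
#'
#' Projects the point of interest along its ray onto the imager plane (the
#' lateral offset is magnified by `sid` over the point's distance along the
#' beam axis) and samples the pixel array bilinearly.
#'
#' @param image a [portal_image()].
#' @param geometry the beam's [beam_geometry()].
#' @param poi a [point_of_interest()].
#' @return scalar CU.
#' @export
sample_cu <- function(image, geometry, poi) {
  q <- .beam_point_quantities(geometry, NULL, matrix(poi$position, ncol = 3))
  u <- q$o1 * image$sid / geometry$sad   # cm at the imager, crossline
  v <- q$o2 * image$sid / geometry$sad   # inline
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px); sp <- image$spacing
  ci <- u / sp + (nc + 1) / 2            # fractional column index
  ri <- v / sp + (nr + 1) / 2            # fractional row index
  if (ci < 0.5 || ci > nc + 0.5 || ri < 0.5 || ri > nr + 0.5) {
    ed_stop("epidose_off_imager",
            sprintf("projection of point '%s' (%.1f, %.1f cm) falls off the imager",
                    poi$label, u, v))
  }
  ci <- min(max(ci, 1), nc); ri <- min(max(ri, 1), nr)
  c0 <- floor(ci); r0 <- floor(ri)
  c1 <- min(c0 + 1, nc); r1 <- min(r0 + 1, nr)
  wc <- ci - c0; wr <- ri - r0
  (1 - wr) * ((1 - wc) * px[r0, c0] + wc * px[r0, c1]) +
    wr * ((1 - wc) * px[r1, c0] + wc * px[r1, c1])
}

#' Convert CU to dose-to-water at the imager plane
#'
#' `d_epid = cu * d_calib * fc`, the dose-to-water at the imager level and
#' depth of maximum dose. `fc` is the absolute conversion factor in Gy per
#' CU (normalized table value times [fc_ref()]).
#'
#' @param cu calibrated units (>= 0).
#' @param calib a [calibration_config()].
#' @param fc absolute conversion factor (Gy per CU, > 0).
#' @return dose in Gy.
#' @export
cu_to_epid_dose <- function(cu, calib, fc) {
  if (!is.numeric(cu) || length(cu) != 1 || is.na(cu) || cu < 0) {
    ed_stop("epidose_invalid_signal", "'cu' must be a non-negative number")
  }
  if (!is.numeric(fc) || fc <= 0) {
    ed_stop("epidose_degenerate_input", "'fc' must be > 0")
  }
  cu * calib$d_calib * fc
}

#' Project the imager-plane dose to a point in the phantom
#'
#' Inverts the commissioning relation: the dose at the imager plane is
#' carried to the isocenter plane with `(sad / sid_ref)^2` (the inverse of
#' the `(SID / SAD)^2` factor the conversion factors were built with), then
#' to the point's source distance with `(sad / spd)^2`, and divided by the
#' fTMR of the full absorber path and multiplied by the TMR of the point's
#' depth. For the isocenter `spd = sad` and the relation reduces to the
#' printed commissioning inverse.
#'
#' @param d_epid dose-to-water at the imager plane (Gy).
#' @param geometry the beam's [beam_geometry()].
#' @param ftmr_val fTMR of the absorber path, in (0, 1].
#' @param tmr_val TMR at the point's depth, in (0, 1].
#' @param spd source-to-point distance (cm); defaults to SAD (isocenter).
#' @param sid_ref SID at which the conversion factors are defined; defaults
#'   to the beam's SID.
#' @return dose in Gy at the point.
#' @export
project_to_poi <- function(d_epid, geometry, ftmr_val, tmr_val,
                           spd = geometry$sad, sid_ref = geometry$sid) {
  if (!is.numeric(ftmr_val) || ftmr_val <= 0 || ftmr_val > 1 + 1e-9 ||
      !is.numeric(tmr_val) || tmr_val <= 0 || tmr_val > 1 + 1e-9) {
    ed_stop("epidose_degenerate_input",
            "'ftmr_val' and 'tmr_val' must lie in (0, 1]")
  }
  chk_num(spd, "spd", positive = TRUE)
  chk_num(d_epid, "d_epid", nonneg = TRUE)
  d_epid * (geometry$sad / sid_ref)^2 * (geometry$sad / spd)^2 *
    tmr_val / ftmr_val
}

#' Reconstruct point doses for a whole plan
#'
#' Runs the full chain per beam and point: sample the CU at the point's
#' projection, re-refer it to the commissioning SID by inverse square,
#' convert to imager-plane dose with the conversion factors (indexed by the
#' equivalent square of the jaws and the full phantom path along the ray),
#' and project to the point with fTMR, TMR and inverse square. Beams whose
#' aperture excludes the point's projection are reconstructed from the
#' transmitted signal and flagged as low-confidence.
#'
#' @param plan a list with a `beams` element (list of [beam_geometry()]) and
#'   optionally `tps` (data frame `beam_id`, `poi`, `d_tps`), e.g. a
#'   `virtual_delivery` from [make_plan()].
#' @param images list of [portal_image()]s, one per beam, matched by
#'   `beam_id` (defaults to `plan$images`).
#' @param pois list of [point_of_interest()]s (defaults to `plan$pois`).
#' @param tables list with elements `ftmr`, `tmr`, `fc` (the commissioned
#'   tables).
#' @param calib a [calibration_config()].
#' @param phantom a [slab_phantom()] (defaults to `plan$phantom`).
#' @param tps optional TPS reference data frame (defaults to `plan$tps`).
#' @return an object of class `reconstructed_dose`: list with `per_beam`
#'   (data frame `beam_id`, `poi`, `cu`, `dose`, `d_tps`, `infield`,
#'   `depth`, `path`, `spd`) and `per_poi` (totals).
#' @export
reconstruct_plan <- function(plan, images = plan$images, pois = plan$pois,
                             tables, calib, phantom = plan$phantom,
                             tps = plan$tps) {
  beams <- plan$beams
  stopifnot(length(beams) >= 1, inherits(calib, "calibration_config"))
  img_ids <- vapply(images, function(im) im$beam_id %||% NA_character_, "")
  rows <- list()
  for (k in seq_along(beams)) {
    b <- beams[[k]]
    bid <- b$id %||% NA_character_
    im <- if (!is.na(bid) && bid %in% img_ids) {
      images[[match(bid, img_ids)]]
    } else if (length(images) >= k && (is.na(bid) || all(is.na(img_ids)))) {
      images[[k]]   # positional fallback when ids are absent
    } else NULL
    if (is.null(im)) {
      ed_stop("epidose_plan_integrity",
              sprintf("no portal image for beam '%s'", bid))
    }
    eq <- equivalent_square(b$field_x, b$field_y)
    for (p in pois) {
      q <- .beam_point_quantities(b, phantom, matrix(p$position, ncol = 3))
      if (q$miss[1] || q$depth[1] < calib$d_max - 1e-9) {
        ed_stop("epidose_unsupported_region",
                sprintf("point '%s' lies in the build-up region of beam '%s' (depth %.2f cm)",
                        p$label, bid, q$depth[1]))
      }
      cu <- sample_cu(im, b, p)
      cu_ref <- cu * (im$sid / tables$fc$sid)^2
      fc_abs <- fc_lookup(tables$fc, eq, q$path[1]) * fc_ref(tables$fc)
      d_epid <- cu_to_epid_dose(cu_ref, calib, fc_abs)
      dose <- project_to_poi(
        d_epid, b,
        ftmr_val = ftmr_lookup(tables$ftmr, eq, q$path[1], q$gap[1]),
        tmr_val = tmr_lookup(tables$tmr, eq, q$depth[1]),
        spd = q$spd[1], sid_ref = tables$fc$sid)
      d_tps <- NA_real_
      if (!is.null(tps)) {
        hit <- tps[tps$beam_id %in% bid & tps$poi == p$label, ]
        if (nrow(hit)) d_tps <- hit$d_tps[1]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        beam_id = bid, poi = p$label, cu = cu, dose = dose, d_tps = d_tps,
        infield = q$infield[1], depth = q$depth[1], path = q$path[1],
        spd = q$spd[1])
    }
  }
  per_beam <- do.call(rbind, rows)
  rownames(per_beam) <- NULL
  per_poi <- do.call(rbind, lapply(split(per_beam, per_beam$poi), function(d) {
    data.frame(poi = d$poi[1], total = sum(d$dose),
               total_tps = if (all(is.na(d$d_tps))) NA_real_ else
                 sum(d$d_tps, na.rm = TRUE),
               n_beams = nrow(d))
  }))
  rownames(per_poi) <- NULL
  structure(list(per_beam = per_beam, per_poi = per_poi, calib = calib),
            class = "reconstructed_dose")
}

#' @export
print.reconstructed_dose <- function(x, ...) {
  cat(sprintf("<reconstructed_dose> %d beams x %d points\n",
              length(unique(x$per_beam$beam_id)), nrow(x$per_poi)))
  print(x$per_poi, row.names = FALSE)
  invisible(x)
}
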