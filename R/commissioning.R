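# Commissioning: build fTMR and conversion-factor tables from measurement
# records, then refine the conversion factors against TPS reference doses.

#' One commissioning acquisition
#'
#' A with-absorber record pairs an ion-chamber dose at the depth of maximum
#' dose (measured behind the absorber) with the calibrated-unit reading at
#' the portal-image center; an open-reference record is the same acquisition
#' without the absorber and anchors the fTMR ratio.
#'
#' @param geometry a [beam_geometry()] (its `ssd_att` locates the absorber).
#' @param thickness absorber thickness in cm (0 for an open reference).
#' @param chamber_dose ion-chamber dose in Gy at `d_max`.
#' @param cu calibrated units read at the image center.
#' @param role `"with-absorber"` or `"open-reference"`.
#' @return an object of class `measurement_record`.
#' @export
measurement_record <- function(geometry, thickness, chamber_dose, cu,
                               role = c("with-absorber", "open-reference")) {
  stopifnot(inherits(geometry, "beam_geometry"))
  chk_num(thickness, "thickness", nonneg = TRUE)
  chk_num(chamber_dose, "chamber_dose", positive = TRUE)
  chk_num(cu, "cu", positive = TRUE)
  role <- match.arg(role)
  if (role == "open-reference" && thickness != 0) {
    ed_stop("epidose_validation_error",
            "open-reference records must have thickness = 0")
  }
  structure(list(geometry = geometry, thickness = thickness,
                 chamber_dose = chamber_dose, cu = cu, role = role),
            class = "measurement_record")
}

# flatten a record list into a data frame for grouping
.records_df <- function(records) {
  do.call(rbind, lapply(seq_along(records), function(i) {
    r <- records[[i]]
    g <- r$geometry
    data.frame(idx = i, role = r$role,
               field = equivalent_square(g$field_x, g$field_y),
               thickness = r$thickness,
               sad = g$sad, sid = g$sid, ssd_att = g$ssd_att, mu = g$mu,
               gap = ifelse(r$thickness > 0, g$sid - g$ssd_att - r$thickness,
                            NA_real_),
               chamber_dose = r$chamber_dose, cu = r$cu)
  }))
}

#' Derive an fTMR table from commissioning records
#'
#' Each with-absorber chamber dose is divided by the matching open-reference
#' chamber dose (same field size, SAD, SID and MU) to form the fTMR for its
#' (field, thickness, air gap) cell. The air gap is `sid - ssd_att -
#' thickness`. Duplicate setups are averaged. Because the SSD_att stepping
#' makes the observed gaps thickness-dependent, the rectangular gap axis is
#' the union of observed gaps; each (field, thickness) cell is filled by a
#' linear fit of fTMR against gap over that cell's acquisitions. A row of
#' exact 1s at zero thickness anchors the table.
#'
#' @param records list of [measurement_record()]s.
#' @return an [ftmr_table()] (construction re-validates monotonicity, so a
#'   non-monotone measurement set raises a table-validation error).
#' @export
derive_ftmr <- function(records) {
  df <- .records_df(records)
  wa <- df[df$role == "with-absorber", ]
  op <- df[df$role == "open-reference", ]
  if (nrow(wa) == 0) {
    ed_stop("epidose_validation_error", "no with-absorber records supplied")
  }
  fields <- sort(unique(wa$field))
  thicknesses <- c(0, sort(unique(wa$thickness)))
  gaps <- sort(unique(wa$gap))
  vals <- array(NA_real_, c(length(fields), length(thicknesses), length(gaps)))
  vals[, 1, ] <- 1
  for (i in seq_along(fields)) {
    f <- fields[i]
    for (j in seq_along(thicknesses)[-1]) {
      t <- thicknesses[j]
      rows <- wa[abs(wa$field - f) < 1e-9 & abs(wa$thickness - t) < 1e-9, ]
      if (nrow(rows) == 0) next
      ref <- op[abs(op$field - f) < 1e-9 & op$sad == rows$sad[1] &
                  op$sid == rows$sid[1] & op$mu == rows$mu[1], ]
      if (nrow(ref) == 0) {
        ed_stop("epidose_pairing_error",
                sprintf("no open-reference record for field %g cm (SAD %g, SID %g, %g MU)",
                        f, rows$sad[1], rows$sid[1], rows$mu[1]))
      }
      ratio <- rows$chamber_dose / mean(ref$chamber_dose)
      if (length(unique(rows$gap)) >= 2) {
        fit <- lm(ratio ~ gap, data = data.frame(ratio = ratio, gap = rows$gap))
        vals[i, j, ] <- pmin(1, pmax(1e-12,
          predict(fit, newdata = data.frame(gap = gaps))))
      } else {
        vals[i, j, ] <- mean(ratio)
      }
    }
  }
  if (anyNA(vals)) {
    miss <- which(is.na(vals), arr.ind = TRUE)
    cells <- unique(sprintf("(field %g, t %g)", fields[miss[, 1]],
                            thicknesses[miss[, 2]]))
    ed_stop("epidose_missing_cells",
            paste("incomplete fTMR grid; missing cells:",
                  paste(cells, collapse = ", ")))
  }
  ftmr_table(fields, thicknesses, gaps, vals)
}

#' Conversion factor for one commissioning setup
#'
#' Implements the commissioning relation
#' `FC = D_TPS / (D_calib * CU) * (SID / SAD)^2 * fTMR / TMR`,
#' where `(SID / SAD)^2` is the inverse-square correction from the imager
#' plane to the isocenter, `fTMR` is evaluated at the phantom thickness and
#' `TMR` at the isocenter depth.
#'
#' @param d_tps TPS dose at the isocenter (Gy).
#' @param calib a [calibration_config()] providing `D_calib`.
#' @param cu calibrated units at the image center (> 0).
#' @param geometry a [beam_geometry()] providing SAD and SID.
#' @param ftmr,tmr the two ratio values (> 0).
#' @return absolute conversion factor in Gy per CU.
#' @export
#' @examples
#' compute_fc(0.8, calibration_config(), cu = 0.5,
#'            geometry = beam_geometry(field_x = 10, field_y = 10),
#'            ftmr = 0.6, tmr = 0.9) # 2.4
compute_fc <- function(d_tps, calib, cu, geometry, ftmr, tmr) {
  if (!is.numeric(cu) || length(cu) != 1 || cu <= 0) {
    ed_stop("epidose_degenerate_input", "'cu' must be > 0")
  }
  if (!is.numeric(tmr) || tmr <= 0) {
    ed_stop("epidose_degenerate_input", "'tmr' must be > 0")
  }
  chk_num(d_tps, "d_tps", positive = TRUE)
  chk_num(ftmr, "ftmr", positive = TRUE)
  d_tps / (calib$d_calib * cu) * (geometry$sid / geometry$sad)^2 * ftmr / tmr
}

#' Build the conversion-factor table from records and TPS points
#'
#' Applies [compute_fc()] to every with-absorber record (the isocenter depth
#' is taken as half the phantom thickness, the standard slab setup with the
#' isocenter at mid-depth), averages duplicates per (field, thickness) cell
#' (warning when their spread exceeds 1%), and normalizes the grid so the
#' reference cell equals 1, keeping the absolute Gy-per-CU scale on the
#' table.
#'
#' @param records list of [measurement_record()]s.
#' @param tps_points data frame with `field`, `thickness`, `d_tps` columns
#'   (see [simulate_tps_points()]).
#' @param calib a [calibration_config()].
#' @param ftmr,tmr the commissioned [ftmr_table()] and [tmr_table()].
#' @return an [fc_table()].
#' @export
build_fc_table <- function(records, tps_points, calib, ftmr, tmr) {
  df <- .records_df(records)
  wa <- df[df$role == "with-absorber", ]
  fields <- sort(unique(wa$field))
  thicknesses <- sort(unique(wa$thickness))
  raw <- matrix(NA_real_, length(fields), length(thicknesses))
  missing_cells <- character()
  for (i in seq_along(fields)) {
    for (j in seq_along(thicknesses)) {
      f <- fields[i]; t <- thicknesses[j]
      rows <- wa[abs(wa$field - f) < 1e-9 & abs(wa$thickness - t) < 1e-9, ]
      tp <- tps_points[abs(tps_points$field - f) < 1e-9 &
                         abs(tps_points$thickness - t) < 1e-9, ]
      if (nrow(rows) == 0 || nrow(tp) == 0) {
        missing_cells <- c(missing_cells, sprintf("(field %g, t %g)", f, t))
        next
      }
      fcs <- vapply(seq_len(nrow(rows)), function(k) {
        g <- beam_geometry(sad = rows$sad[k], sid = rows$sid[k],
                           field_x = f, field_y = f, mu = rows$mu[k])
        compute_fc(tp$d_tps[1], calib, rows$cu[k], g,
                   ftmr = ftmr_lookup(ftmr, f, t, rows$gap[k]),
                   tmr = tmr_lookup(tmr, f, t / 2))
      }, numeric(1))
      if (length(fcs) > 1 && diff(range(fcs)) / mean(fcs) > 0.01) {
        ed_warn("epidose_duplicate_spread",
                sprintf("conversion factors at (field %g, t %g) spread by %.2f%%; using their mean",
                        f, t, 100 * diff(range(fcs)) / mean(fcs)))
      }
      raw[i, j] <- mean(fcs)
    }
  }
  if (length(missing_cells)) {
    ed_stop("epidose_missing_cells",
            paste("incomplete conversion-factor grid; missing cells:",
                  paste(missing_cells, collapse = ", ")))
  }
  ref_field <- if (calib$ref_field %in% fields) calib$ref_field else {
    fields[which.min(abs(fields - calib$ref_field))]
  }
  ref_thickness <- if (5 %in% thicknesses) 5 else min(thicknesses)
  ref_val <- raw[fields == ref_field, thicknesses == ref_thickness]
  fc_table(fields, thicknesses, raw / ref_val, gy_per_cu = ref_val,
           ref_field = ref_field, ref_thickness = ref_thickness,
           sad = wa$sad[1], sid = wa$sid[1])
}

#' Iterative TPS-based correction of the conversion factors
#'
#' Multiplies each conversion-factor cell by the ratio of the TPS dose to
#' the dose the current table reconstructs for that cell's commissioning
#' setup, and repeats until the largest per-cell relative change falls below
#' `tol`. Because the reconstructed dose is linear in the cell's factor the
#' iteration is a multiplicative fixed point: a global TPS offset is
#' absorbed exactly and the correction is idempotent at convergence.
#'
#' @param fc the [fc_table()] to correct.
#' @param tps_points data frame with `field`, `thickness`, `d_tps`.
#' @param reconstructor function `(field, thickness, fc_table) -> Gy`
#'   reconstructing the isocenter dose of a commissioning setup with a given
#'   table (see [make_commissioning_reconstructor()]).
#' @param tol convergence tolerance on the per-cell relative change.
#' @param max_iter iteration cap; exceeding it raises a convergence error
#'   carrying the residuals.
#' @return a list with `table` (corrected [fc_table()]), `residual` (matrix
#'   of final per-cell relative changes), `iterations` and `converged`.
#' @export
adjust_fc_with_tps <- function(fc, tps_points, reconstructor,
                               tol = 1e-4, max_iter = 50) {
  stopifnot(inherits(fc, "fc_table"), is.function(reconstructor))
  if (any(tps_points$d_tps <= 0)) {
    ed_stop("epidose_degenerate_input",
            "all TPS reference doses must be > 0")
  }
  resid <- matrix(NA_real_, length(fc$fields), length(fc$thicknesses))
  for (it in seq_len(max_iter)) {
    factors <- resid
    for (i in seq_along(fc$fields)) {
      for (j in seq_along(fc$thicknesses)) {
        tp <- tps_points[abs(tps_points$field - fc$fields[i]) < 1e-9 &
                           abs(tps_points$thickness - fc$thicknesses[j]) < 1e-9, ]
        if (nrow(tp) == 0) { factors[i, j] <- 1; next }
        d_rec <- reconstructor(fc$fields[i], fc$thicknesses[j], fc)
        if (!is.finite(d_rec) || d_rec <= 0) {
          ed_stop("epidose_degenerate_input",
                  sprintf("reconstruction returned %.3g for cell (field %g, t %g)",
                          d_rec, fc$fields[i], fc$thicknesses[j]))
        }
        factors[i, j] <- tp$d_tps[1] / d_rec
      }
    }
    fc$values <- fc$values * factors
    resid <- abs(factors - 1)
    if (max(resid) < tol) {
      return(list(table = fc, residual = resid, iterations = it,
                  converged = TRUE))
    }
  }
  ed_stop("epidose_convergence_error",
          sprintf("conversion-factor correction did not converge in %d iterations (max residual %.3g)",
                  max_iter, max(resid)),
          residual = resid)
}

#' Reconstructor closure for commissioning setups
#'
#' Returns a function reconstructing the isocenter dose of a (field,
#' thickness) commissioning cell from its recorded CU with a candidate
#' conversion-factor table - the hook [adjust_fc_with_tps()] iterates over.
#'
#' @param records list of [measurement_record()]s (supplies the CU).
#' @param calib a [calibration_config()].
#' @param ftmr,tmr commissioned [ftmr_table()] and [tmr_table()].
#' @return function `(field, thickness, fc_table) -> Gy`.
#' @export
make_commissioning_reconstructor <- function(records, calib, ftmr, tmr) {
  df <- .records_df(records)
  wa <- df[df$role == "with-absorber", ]
  function(field, thickness, fc) {
    rows <- wa[abs(wa$field - field) < 1e-9 &
                 abs(wa$thickness - thickness) < 1e-9, ]
    if (nrow(rows) == 0) {
      ed_stop("epidose_missing_cells",
              sprintf("no commissioning record for (field %g, t %g)",
                      field, thickness))
    }
    fcv <- fc_lookup(fc, field, thickness) * fc_ref(fc)
    d <- vapply(seq_len(nrow(rows)), function(k) {
      g <- beam_geometry(sad = rows$sad[k], sid = rows$sid[k],
                         field_x = field, field_y = field, mu = rows$mu[k])
      d_epid <- cu_to_epid_dose(rows$cu[k], calib, fcv)
      project_to_poi(d_epid, g,
                     ftmr_val = ftmr_lookup(ftmr, field, thickness, rows$gap[k]),
                     tmr_val = tmr_lookup(tmr, field, thickness / 2),
                     spd = g$sad, sid_ref = fc$sid)
    }, numeric(1))
    mean(d)
  }
}
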