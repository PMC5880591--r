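# Dosimetric lookup tables: fTMR, TMR and conversion factors.
#
# Interpolation scheme: log-linear along thickness/depth (attenuation with
# depth is near-exponential, so interpolating the logarithm is exact for an
# exponential falloff), linear along field size and air gap. Queries up to
# 10% of the axis span beyond either end are extrapolated from the edge pair
# with a warning; beyond that a hard out-of-range error names the axis.

.EXTRAP_MARGIN <- 0.10

# Locate x on an axis: bracketing indices and a linear weight. Weights
# outside [0, 1] encode extrapolation from the edge node pair.
.axis_locate <- function(axis, x, name, margin_frac = .EXTRAP_MARGIN) {
  n <- length(axis)
  if (n == 1L) return(list(i1 = 1L, i2 = 1L, w = 0))
  lo <- axis[1]; hi <- axis[n]
  span <- hi - lo
  m <- margin_frac * span
  if (x < lo - m - 1e-12 || x > hi + m + 1e-12) {
    ed_stop("epidose_out_of_range",
            sprintf("query %.4g outside the '%s' axis range [%g, %g] (+/- %.3g margin)",
                    x, name, lo, hi, m),
            axis = name)
  }
  eps <- 1e-9 * max(1, abs(span))
  if (x < lo - eps || x > hi + eps) {
    ed_warn("epidose_extrapolation",
            sprintf("extrapolating %.3g beyond the '%s' axis range [%g, %g]",
                    x, name, lo, hi))
  }
  i <- findInterval(x, axis, rightmost.closed = TRUE)
  i <- min(max(i, 1L), n - 1L)
  w <- (x - axis[i]) / (axis[i + 1] - axis[i])
  list(i1 = i, i2 = i + 1L, w = w)
}

# Interpolate between two positive values, optionally on the log scale.
# Exact-weight short circuits keep grid-node queries bit-identical to the
# stored values.
.interp_pair <- function(v1, v2, w, log_scale = FALSE) {
  if (w == 0) return(v1)
  if (w == 1) return(v2)
  if (log_scale) exp((1 - w) * log(v1) + w * log(v2)) else (1 - w) * v1 + w * v2
}

#' Finite tissue maximum ratio (fTMR) table
#'
#' The fTMR is the ratio of the dose at depth of maximum dose with a finite
#' absorber in the beam to the dose without it, under otherwise identical
#' conditions. The table is indexed by equivalent square field side (cm at
#' SAD), absorber thickness (cm) and air gap (cm, attenuator exit to imager).
#'
#' Construction enforces the physical invariants: all values in (0, 1],
#' exactly 1 at zero thickness, strictly decreasing with thickness at fixed
#' field and gap, and non-decreasing with field size (scatter) at fixed
#' thickness and gap.
#'
#' @param fields,thicknesses,gaps sorted axis vectors (cm).
#' @param values numeric array with dim `c(length(fields),
#'   length(thicknesses), length(gaps))`.
#' @return an object of class `c("ftmr_table", "dose_table")`.
#' @export
ftmr_table <- function(fields, thicknesses, gaps, values) {
  values <- .check_table_axes(
    list(field = fields, thickness = thicknesses, gap = gaps), values)
  if (any(values <= 0 | values > 1 + 1e-9)) {
    ed_stop("epidose_validation_error", "fTMR values must lie in (0, 1]")
  }
  if (any(thicknesses < 0)) {
    ed_stop("epidose_validation_error", "absorber thicknesses must be >= 0")
  }
  if (any(thicknesses == 0)) {
    if (any(abs(values[, thicknesses == 0, , drop = FALSE] - 1) > 1e-9)) {
      ed_stop("epidose_validation_error",
              "fTMR must equal 1 exactly at zero absorber thickness")
    }
  }
  # strict decrease in thickness per (field, gap) column
  if (length(thicknesses) > 1) {
    d <- apply(values, c(1, 3), diff)           # diffs along thickness
    if (any(d >= -1e-12)) {
      ed_stop("epidose_validation_error",
              "fTMR values must strictly decrease with absorber thickness")
    }
  }
  if (length(fields) > 1) {
    d <- apply(values, c(2, 3), diff)           # diffs along field size
    if (any(d < -1e-9)) {
      ed_stop("epidose_validation_error",
              "fTMR values must be non-decreasing with field size")
    }
  }
  structure(list(fields = fields, thicknesses = thicknesses, gaps = gaps,
                 values = values, version = "ftmr-table/1"),
            class = c("ftmr_table", "dose_table"))
}

#' Tissue maximum ratio (TMR) table
#'
#' Dose at depth relative to the dose at the depth of maximum dose `d_max`
#' for the same field and source-to-point distance, indexed by equivalent
#' square field side and depth. The first depth node is `d_max`, where the
#' TMR is 1 by definition; the build-up region above `d_max` is not modeled.
#'
#' @param fields,depths sorted axis vectors (cm); `depths[1]` is `d_max`.
#' @param values numeric matrix `length(fields) x length(depths)`.
#' @param d_max depth of maximum dose in cm (defaults to `depths[1]`).
#' @return an object of class `c("tmr_table", "dose_table")`.
#' @export
tmr_table <- function(fields, depths, values, d_max = depths[1]) {
  values <- .check_table_axes(list(field = fields, depth = depths), values)
  if (any(values <= 0 | values > 1 + 1e-9)) {
    ed_stop("epidose_validation_error", "TMR values must lie in (0, 1]")
  }
  if (any(depths == d_max) &&
      any(abs(values[, depths == d_max] - 1) > 1e-9)) {
    ed_stop("epidose_validation_error", "TMR must equal 1 exactly at d_max")
  }
  if (length(depths) > 1) {
    sel <- depths > d_max + 1e-12
    d <- apply(values, 1, diff)
    if (is.matrix(d)) d <- d[sel[-1] | sel[-length(sel)], , drop = FALSE]
    if (length(d) && any(d >= 1e-12)) {
      ed_stop("epidose_validation_error",
              "TMR values must strictly decrease with depth beyond d_max")
    }
  }
  structure(list(fields = fields, depths = depths, values = values,
                 d_max = d_max, version = "tmr-table/1"),
            class = c("tmr_table", "dose_table"))
}

#' Conversion-factor (FC) table
#'
#' Maps equivalent square field side and absorber thickness to the factor
#' converting portal-image calibrated units (CU) into dose-to-water at the
#' imager plane. Stored values are normalized so the reference cell equals
#' 1; the absolute scale in Gy per CU is kept in the `gy_per_cu` field
#' together with the commissioning geometry (`sad`, `sid`) at which the
#' factors were measured.
#'
#' @param fields,thicknesses sorted axis vectors (cm).
#' @param values numeric matrix `length(fields) x length(thicknesses)` of
#'   normalized factors (all > 0).
#' @param gy_per_cu absolute Gy-per-CU factor of the reference cell.
#' @param ref_field,ref_thickness the normalization cell.
#' @param sad,sid commissioning geometry (cm).
#' @param norm_tol warn if the reference cell differs from 1 by more than
#'   this commissioning fit tolerance.
#' @return an object of class `c("fc_table", "dose_table")`.
#' @export
fc_table <- function(fields, thicknesses, values, gy_per_cu = 1,
                     ref_field = 10, ref_thickness = min(thicknesses),
                     sad = 100, sid = 150, norm_tol = 0.05) {
  values <- .check_table_axes(
    list(field = fields, thickness = thicknesses), values)
  if (any(values <= 0)) {
    ed_stop("epidose_validation_error", "conversion factors must be > 0")
  }
  chk_num(gy_per_cu, "gy_per_cu", positive = TRUE)
  i <- which(fields == ref_field); j <- which(thicknesses == ref_thickness)
  if (length(i) == 1 && length(j) == 1 && abs(values[i, j] - 1) > norm_tol) {
    ed_warn("epidose_normalization",
            sprintf("reference cell (%g cm, %g cm) is %.4f, more than %g from 1",
                    ref_field, ref_thickness, values[i, j], norm_tol))
  }
  structure(list(fields = fields, thicknesses = thicknesses, values = values,
                 gy_per_cu = gy_per_cu, ref_field = ref_field,
                 ref_thickness = ref_thickness, sad = sad, sid = sid,
                 version = "fc-table/1"),
            class = c("fc_table", "dose_table"))
}

# shared axis/dim validation; returns values coerced to the right array shape
.check_table_axes <- function(axes, values) {
  for (nm in names(axes)) {
    a <- axes[[nm]]
    if (!is.numeric(a) || length(a) < 1 || anyNA(a) || is.unsorted(a, strictly = TRUE)) {
      ed_stop("epidose_validation_error",
              sprintf("'%s' axis must be strictly increasing and non-empty", nm))
    }
  }
  dims <- vapply(axes, length, 1L)
  if (length(dims) == 2L && is.null(dim(values)) &&
      length(values) == prod(dims)) {
    values <- matrix(values, dims[1], dims[2])
  }
  if (length(dims) == 3L && is.null(dim(values)) &&
      length(values) == prod(dims)) {
    values <- array(values, dims)
  }
  if (!identical(as.integer(dim(values)), as.integer(dims))) {
    ed_stop("epidose_validation_error",
            sprintf("values must have dim [%s]", paste(dims, collapse = " x ")))
  }
  if (anyNA(values)) {
    ed_stop("epidose_validation_error", "table values must not contain NA")
  }
  values
}

#' Look up an fTMR value
#'
#' Returns the stored value exactly at grid nodes; between nodes the value is
#' interpolated log-linearly in thickness and linearly in field size and air
#' gap. Axes with a single node are treated as constant.
#'
#' @param table an [ftmr_table()].
#' @param eq_field equivalent square field side (cm).
#' @param thickness absorber thickness (cm, >= 0).
#' @param air_gap attenuator-exit-to-imager distance (cm).
#' @return dimensionless fTMR in (0, 1].
#' @export
ftmr_lookup <- function(table, eq_field, thickness, air_gap) {
  stopifnot(inherits(table, "ftmr_table"))
  chk_num(thickness, "thickness", nonneg = TRUE)
  if (thickness == 0) return(1)
  lf <- .axis_locate(table$fields, eq_field, "field")
  lt <- .axis_locate(table$thicknesses, thickness, "thickness")
  lg <- .axis_locate(table$gaps, air_gap, "gap")
  v <- table$values
  # collapse thickness on the log scale, then bilinear in field and gap
  corner <- function(i, k) {
    .interp_pair(v[i, lt$i1, k], v[i, lt$i2, k], lt$w, log_scale = TRUE)
  }
  g1 <- .interp_pair(corner(lf$i1, lg$i1), corner(lf$i2, lg$i1), lf$w)
  g2 <- .interp_pair(corner(lf$i1, lg$i2), corner(lf$i2, lg$i2), lf$w)
  .interp_pair(g1, g2, lg$w)
}

#' Look up a TMR value
#'
#' Log-linear in depth, linear in field size; exactly 1 at `d_max`. Depths
#' above `d_max` (build-up region) are rejected.
#'
#' @param table a [tmr_table()].
#' @param eq_field equivalent square field side (cm).
#' @param depth depth in cm, `>= d_max`.
#' @return dimensionless TMR in (0, 1].
#' @export
tmr_lookup <- function(table, eq_field, depth) {
  stopifnot(inherits(table, "tmr_table"))
  if (depth < table$d_max - 1e-9) {
    ed_stop("epidose_unsupported_region",
            sprintf("depth %.3g cm is in the build-up region (d_max = %g cm)",
                    depth, table$d_max))
  }
  if (abs(depth - table$d_max) <= 1e-9) return(1)
  lf <- .axis_locate(table$fields, eq_field, "field")
  ld <- .axis_locate(table$depths, depth, "depth")
  v <- table$values
  col <- function(i) .interp_pair(v[i, ld$i1], v[i, ld$i2], ld$w, log_scale = TRUE)
  .interp_pair(col(lf$i1), col(lf$i2), lf$w)
}

#' Look up a normalized conversion factor
#'
#' Bilinear interpolation over field size and absorber thickness. The value
#' is normalized (1 at the reference cell); multiply by [fc_ref()] to obtain
#' the absolute Gy-per-CU factor.
#'
#' @param table an [fc_table()].
#' @param eq_field equivalent square field side (cm).
#' @param thickness absorber thickness (cm).
#' @return normalized conversion factor (> 0).
#' @export
fc_lookup <- function(table, eq_field, thickness) {
  stopifnot(inherits(table, "fc_table"))
  lf <- .axis_locate(table$fields, eq_field, "field")
  lt <- .axis_locate(table$thicknesses, thickness, "thickness")
  v <- table$values
  .interp_pair(.interp_pair(v[lf$i1, lt$i1], v[lf$i2, lt$i1], lf$w),
               .interp_pair(v[lf$i1, lt$i2], v[lf$i2, lt$i2], lf$w),
               lt$w)
}

#' Absolute Gy-per-CU scale of a conversion-factor table
#'
#' @param table an [fc_table()].
#' @return the Gy-per-CU factor of the reference cell.
#' @export
fc_ref <- function(table) {
  stopifnot(inherits(table, "fc_table"))
  table$gy_per_cu
}

#' @export
print.dose_table <- function(x, ...) {
  axes <- setdiff(names(x), c("values", "version", "d_max", "gy_per_cu",
                              "ref_field", "ref_thickness", "sad", "sid"))
  cat(sprintf("<%s> %s\n", class(x)[1], x$version))
  for (a in axes) {
    cat(sprintf("  %s: %d nodes [%g .. %g]\n", a, length(x[[a]]),
                min(x[[a]]), max(x[[a]])))
  }
  cat(sprintf("  values: %d cells in [%.4g, %.4g]\n", length(x$values),
              min(x$values), max(x$values)))
  if (!is.null(x$gy_per_cu)) {
    cat(sprintf("  reference scale: %.5g Gy/CU at (%g cm, %g cm), SAD %g / SID %g\n",
                x$gy_per_cu, x$ref_field, x$ref_thickness, x$sad, x$sid))
  }
  invisible(x)
}
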