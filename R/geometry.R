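#' Reference calibration conditions
#'
#' Holds the calibration dose and the reference geometry under which the
#' portal imager and the conversion-factor table are normalized: by default
#' 1 Gy at the depth of maximum dose for 100 MU from a 10 x 10 cm^2 field at
#' 100 cm SAD, with the imager at 150 cm SID.
#'
#' @param d_calib dose in Gy delivered at depth `d_max` per 100 MU under
#'   reference conditions (1 for a conventionally calibrated linac).
#' @param d_max reference depth of maximum dose in cm (about 1.5 cm at 6 MV).
#' @param ref_field reference square field side in cm.
#' @param ref_sad,ref_sid reference source-to-axis and source-to-imager
#'   distances in cm; `ref_sid >= ref_sad`.
#' @return an object of class `calibration_config`.
#' @export
#' @examples
#' calibration_config()
calibration_config <- function(d_calib = 1, d_max = 1.5, ref_field = 10,
                               ref_sad = 100, ref_sid = 150) {
  chk_num(d_calib, "d_calib", positive = TRUE)
  chk_num(d_max, "d_max", positive = TRUE)
  chk_num(ref_field, "ref_field", positive = TRUE)
  chk_num(ref_sad, "ref_sad", positive = TRUE)
  chk_num(ref_sid, "ref_sid", positive = TRUE)
  if (ref_sid < ref_sad) {
    ed_stop("epidose_validation_error", "'ref_sid' must be >= 'ref_sad'")
  }
  structure(list(d_calib = d_calib, d_max = d_max, ref_field = ref_field,
                 ref_sad = ref_sad, ref_sid = ref_sid),
            class = "calibration_config")
}

#' Beam geometry for one treatment or commissioning field
#'
#' Distances are in cm, angles in degrees (IEC 61217 gantry angle: 0 points
#' the beam straight down, increasing clockwise when viewed from the foot of
#' the table). The jaw field is defined at SAD; an optional aperture center
#' offset models fields deliberately blocked away from the axis.
#'
#' @param sad source-to-axis distance (cm).
#' @param sid source-to-imager distance (cm), must exceed `sad`.
#' @param ssd_att source-to-attenuator-surface distance (cm), may be `NA`
#'   when it is derived from the phantom instead.
#' @param gantry_angle gantry angle in degrees, normalized to `[0, 360)`.
#' @param field_x,field_y jaw opening (cm) at SAD, crossline and inline.
#' @param mu monitor units delivered by this beam.
#' @param energy_label free-text beam quality label, e.g. `"6MV"`.
#' @param aperture_cx,aperture_cy aperture center offset (cm) at the
#'   isocenter plane, crossline and inline.
#' @param id optional beam identifier used to match portal images.
#' @return an object of class `beam_geometry`.
#' @export
#' @examples
#' beam_geometry(field_x = 10, field_y = 10, mu = 100)
beam_geometry <- function(sad = 100, sid = 150, ssd_att = NA_real_,
                          gantry_angle = 0, field_x, field_y, mu = 100,
                          energy_label = "6MV",
                          aperture_cx = 0, aperture_cy = 0, id = NULL) {
  chk_num(sad, "sad", positive = TRUE)
  chk_num(sid, "sid", positive = TRUE)
  if (sid <= sad) {
    ed_stop("epidose_invalid_geometry", "'sid' must be greater than 'sad'")
  }
  chk_num(field_x, "field_x", positive = TRUE)
  chk_num(field_y, "field_y", positive = TRUE)
  chk_num(mu, "mu", nonneg = TRUE)
  chk_num(gantry_angle, "gantry_angle")
  gantry_angle <- gantry_angle %% 360
  structure(list(sad = sad, sid = sid, ssd_att = ssd_att,
                 gantry_angle = gantry_angle,
                 field_x = field_x, field_y = field_y, mu = mu,
                 energy_label = energy_label,
                 aperture_cx = aperture_cx, aperture_cy = aperture_cy,
                 id = id),
            class = "beam_geometry")
}

#' Rectangular water-equivalent slab phantom
#'
#' An axis-aligned box of water-equivalent material in the IEC 61217 fixed
#' frame (origin at isocenter, z up, y along the table toward the gantry).
#' `flat` puts the thickness along z (stack lying on the table); `on_side`
#' puts it along x, as used to measure lateral beams without couch effects.
#'
#' @param thickness slab thickness t in cm (>= 0; 0 means no absorber).
#' @param extent lateral extent in cm (side length of the square faces).
#' @param center box center in cm, length-3 (defaults to the isocenter).
#' @param orientation `"flat"` or `"on_side"`.
#' @return an object of class `slab_phantom` with `lo`/`hi` corner fields.
#' @export
#' @examples
#' slab_phantom(15, extent = 30)
slab_phantom <- function(thickness, extent = 30, center = c(0, 0, 0),
                         orientation = c("flat", "on_side")) {
  chk_num(thickness, "thickness", nonneg = TRUE)
  chk_num(extent, "extent", positive = TRUE)
  chk_num(center, "center", len = 3L)
  orientation <- match.arg(orientation)
  half <- if (orientation == "flat") {
    c(extent, extent, thickness) / 2
  } else {
    c(thickness, extent, extent) / 2
  }
  structure(list(thickness = thickness, extent = extent, center = center,
                 orientation = orientation,
                 lo = center - half, hi = center + half),
            class = "slab_phantom")
}

#' Point of interest in the phantom frame
#'
#' @param label short name for reporting.
#' @param position length-3 position in cm, IEC fixed frame, isocenter origin.
#' @param role one of `"isocenter"`, `"offset"`, `"target"`, `"OAR"`.
#' @return an object of class `point_of_interest`.
#' @export
#' @examples
#' point_of_interest("iso", c(0, 0, 0), "isocenter")
point_of_interest <- function(label, position,
                              role = c("isocenter", "offset", "target", "OAR")) {
  chk_num(position, "position", len = 3L)
  role <- match.arg(role)
  structure(list(label = as.character(label), position = position, role = role),
            class = "point_of_interest")
}

#' Equivalent square field side
#'
#' Maps a rectangular jaw opening onto the side of the square field with the
#' same area-to-perimeter ratio (Sterling's 4A/P rule), the standard scalar
#' used to index scatter-dependent dosimetric tables.
#'
#' @param field_x,field_y rectangle sides in cm (defined at SAD).
#' @return equivalent square side in cm.
#' @export
#' @examples
#' equivalent_square(10, 20) # 13.33
equivalent_square <- function(field_x, field_y) {
  if (!is.numeric(field_x) || !is.numeric(field_y) ||
      any(field_x <= 0) || any(field_y <= 0)) {
    ed_stop("epidose_invalid_geometry",
            "field sides must be positive for the equivalent-square mapping")
  }
  2 * field_x * field_y / (field_x + field_y)
}

# --- internal beam-frame helpers -------------------------------------------

# source position in the fixed frame for a gantry angle
.source_position <- function(geometry) {
  th <- geometry$gantry_angle * pi / 180
  geometry$sad * c(sin(th), 0, cos(th))
}

# unit vectors: w along the beam (source -> isocenter), e1 crossline, e2 inline
.beam_axes <- function(geometry) {
  th <- geometry$gantry_angle * pi / 180
  list(w = -c(sin(th), 0, cos(th)),
       e1 = c(cos(th), 0, -sin(th)),
       e2 = c(0, 1, 0))
}

# Per-point ray/box quantities for a beam and phantom. P is an n x 3 matrix.
# Returns, per point: source-to-point distance spd, distance along the beam
# axis d_axis, iso-plane lateral offsets o1/o2, in-aperture flag, the
# water-equivalent path through the box up to the point (depth), the full
# traversal (path, used as the absorber thickness), the source-to-entry
# distance ssd_eff and the exit-to-imager air gap.
.beam_point_quantities <- function(geometry, phantom, P) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  S <- .source_position(geometry)
  ax <- .beam_axes(geometry)
  D <- sweep(P, 2, S)
  spd <- sqrt(rowSums(D^2))
  U <- D / spd
  smin <- rep(-Inf, nrow(P)); smax <- rep(Inf, nrow(P))
  if (!is.null(phantom) && phantom$thickness > 0) {
    for (j in 1:3) {
      t1 <- (phantom$lo[j] - S[j]) / U[, j]
      t2 <- (phantom$hi[j] - S[j]) / U[, j]
      smin <- pmax(smin, pmin(t1, t2))
      smax <- pmin(smax, pmax(t1, t2))
    }
  } else {
    smin <- rep(NA_real_, nrow(P)); smax <- rep(NA_real_, nrow(P))
  }
  miss <- is.na(smin) | smin > smax | smax < 0
  path <- ifelse(miss, 0, pmax(0, smax - smin))
  depth <- ifelse(miss, 0, pmax(0, pmin(spd, smax) - smin))
  d_axis <- drop(D %*% ax$w)
  a1 <- drop(D %*% ax$e1)
  a2 <- drop(D %*% ax$e2)
  o1 <- a1 * geometry$sad / d_axis
  o2 <- a2 * geometry$sad / d_axis
  infield <- abs(o1 - geometry$aperture_cx) <= geometry$field_x / 2 + 1e-9 &
    abs(o2 - geometry$aperture_cy) <= geometry$field_y / 2 + 1e-9
  data.frame(spd = spd, d_axis = d_axis, o1 = o1, o2 = o2,
             infield = infield, miss = miss,
             depth = depth, path = path,
             ssd_eff = ifelse(miss, NA_real_, smin),
             gap = ifelse(miss, NA_real_, geometry$sid - smax))
}

#' Radiological depth of a point along a beam
#'
#' Water-equivalent path length from the point where the ray from the source
#' enters the phantom to the point of interest. For a beam at gantry 0 and a
#' point at the mid-plane of a flat slab this is half the slab thickness; for
#' oblique beams the path lengthens geometrically (ray-box intersection).
#'
#' @param geometry a [beam_geometry()].
#' @param phantom a [slab_phantom()].
#' @param poi a [point_of_interest()].
#' @return depth in cm; 0 (with a warning) if the ray misses the phantom, 0
#'   if the point lies on the source side of the phantom surface.
#' @export
#' @examples
#' g <- beam_geometry(field_x = 10, field_y = 10)
#' radiological_depth(g, slab_phantom(30), point_of_interest("iso", c(0, 0, 0)))
radiological_depth <- function(geometry, phantom, poi) {
  q <- .beam_point_quantities(geometry, phantom, matrix(poi$position, ncol = 3))
  if (q$miss[1]) {
    ed_warn("epidose_ray_miss",
            sprintf("ray through point '%s' misses the phantom; depth set to 0",
                    poi$label))
    return(0)
  }
  q$depth[1]
}
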