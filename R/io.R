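# Versioned JSON fixtures. Tables are single JSON documents with explicit
# axis vectors and a row-major value array; measurement records are JSON
# lines; plans bundle beams, phantom, points, TPS doses and images.

.tojson <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

# row-major flattening (last axis fastest), the layout declared by the schema
.flatten_rm <- function(a) {
  if (is.null(dim(a))) return(as.vector(a))
  as.vector(aperm(a, rev(seq_along(dim(a)))))
}
.unflatten_rm <- function(v, dims) {
  aperm(array(v, rev(dims)), rev(seq_along(dims)))
}

#' Write a fixture object to JSON
#'
#' Serializes tables (`ftmr-table/1`, `tmr-table/1`, `fc-table/1`),
#' measurement sets (`records/1`, JSON lines), deliveries/plans (`plan/1`)
#' and deviation reports (`report/1`). [read_fixture()] is its exact
#' inverse.
#'
#' @param x a `dose_table`, `measurement_set`, `virtual_delivery` or
#'   `deviation_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(x, path) UseMethod("write_fixture")

#' @export
write_fixture.dose_table <- function(x, path) {
  doc <- list(version = x$version)
  for (nm in setdiff(names(x), c("values", "version"))) doc[[nm]] <- x[[nm]]
  doc$dim <- dim(x$values) %||% length(x$values)
  doc$values <- .flatten_rm(x$values)
  writeLines(.tojson(doc), path)
  invisible(path)
}

#' @export
write_fixture.measurement_set <- function(x, path) {
  lines <- vapply(x, function(r) {
    g <- r$geometry
    .tojson(list(schema = "records/1", role = r$role,
                 thickness = r$thickness, chamber_dose = r$chamber_dose,
                 cu = r$cu,
                 geometry = list(sad = g$sad, sid = g$sid,
                                 ssd_att = g$ssd_att,
                                 gantry_angle = g$gantry_angle,
                                 field_x = g$field_x, field_y = g$field_y,
                                 mu = g$mu, energy_label = g$energy_label)))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
write_fixture.virtual_delivery <- function(x, path) {
  doc <- list(
    version = "plan/1", template = x$template, mu_scale = x$mu_scale,
    phantom = list(thickness = x$phantom$thickness, extent = x$phantom$extent,
                   center = x$phantom$center,
                   orientation = x$phantom$orientation),
    beams = lapply(x$beams, function(b) {
      b[c("sad", "sid", "ssd_att", "gantry_angle", "field_x", "field_y",
          "mu", "energy_label", "aperture_cx", "aperture_cy", "id")]
    }),
    pois = lapply(x$pois, function(p) {
      list(label = p$label, position = p$position, role = p$role)
    }),
    tps = x$tps,
    images = lapply(x$images, function(im) {
      list(beam_id = im$beam_id, sid = im$sid, spacing = im$spacing,
           nrow = nrow(im$pixels), ncol = ncol(im$pixels),
           pixels = .flatten_rm(im$pixels))
    }))
  writeLines(.tojson(doc), path)
  invisible(path)
}

#' @export
write_fixture.deviation_report <- function(x, path) {
  doc <- list(version = "report/1", thresholds = x$thresholds,
              per_beam = x$per_beam, per_poi = x$per_poi)
  writeLines(.tojson(doc), path)
  invisible(path)
}

#' Read a fixture file written by [write_fixture()]
#'
#' Detects the schema from the `version`/`schema` field, rebuilds the typed
#' object and re-validates every invariant at load, so e.g. a table with a
#' non-monotone fTMR column is rejected with a validation error.
#'
#' @param path fixture file path.
#' @return the typed object (`dose_table`, `measurement_set`,
#'   `virtual_delivery` or `deviation_report`).
#' @export
read_fixture <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    ed_stop("epidose_format_error", sprintf("'%s' is empty", path))
  }
  if (grepl('"schema"\\s*:\\s*"records/1"', lines[1])) {
    return(.read_records(lines))
  }
  doc <- tryCatch(jsonlite::fromJSON(paste(lines, collapse = "\n"),
                                     simplifyVector = TRUE),
                  error = function(e) {
                    ed_stop("epidose_format_error",
                            sprintf("cannot parse '%s' as JSON: %s", path,
                                    conditionMessage(e)))
                  })
  v <- doc$version
  if (is.null(v)) {
    ed_stop("epidose_format_error",
            sprintf("'%s' has no schema version field", path))
  }
  switch(v,
    "ftmr-table/1" = ftmr_table(doc$fields, doc$thicknesses, doc$gaps,
                                .unflatten_rm(doc$values, doc$dim)),
    "tmr-table/1" = tmr_table(doc$fields, doc$depths,
                              .unflatten_rm(doc$values, doc$dim),
                              d_max = doc$d_max),
    "fc-table/1" = fc_table(doc$fields, doc$thicknesses,
                            .unflatten_rm(doc$values, doc$dim),
                            gy_per_cu = doc$gy_per_cu,
                            ref_field = doc$ref_field,
                            ref_thickness = doc$ref_thickness,
                            sad = doc$sad, sid = doc$sid),
    "plan/1" = .read_plan(doc),
    "report/1" = structure(list(per_beam = doc$per_beam,
                                per_poi = doc$per_poi,
                                thresholds = doc$thresholds),
                           class = "deviation_report"),
    ed_stop("epidose_format_error",
            sprintf("unknown schema version '%s' in '%s'", v, path))
  )
}

.read_records <- function(lines) {
  recs <- lapply(lines[nzchar(lines)], function(ln) {
    r <- jsonlite::fromJSON(ln)
    if (!identical(r$schema, "records/1")) {
      ed_stop("epidose_format_error",
              sprintf("unexpected record schema '%s'", r$schema %||% "<none>"))
    }
    g <- r$geometry
    measurement_record(
      geometry = beam_geometry(sad = g$sad, sid = g$sid,
                               ssd_att = g$ssd_att %||% NA_real_,
                               gantry_angle = g$gantry_angle,
                               field_x = g$field_x, field_y = g$field_y,
                               mu = g$mu, energy_label = g$energy_label),
      thickness = r$thickness, chamber_dose = r$chamber_dose, cu = r$cu,
      role = r$role)
  })
  structure(recs, class = "measurement_set")
}

.read_plan <- function(doc) {
  beams <- lapply(seq_len(nrow(doc$beams)), function(i) {
    b <- doc$beams[i, ]
    beam_geometry(sad = b$sad, sid = b$sid,
                  ssd_att = b$ssd_att %||% NA_real_,
                  gantry_angle = b$gantry_angle,
                  field_x = b$field_x, field_y = b$field_y, mu = b$mu,
                  energy_label = b$energy_label,
                  aperture_cx = b$aperture_cx %||% 0,
                  aperture_cy = b$aperture_cy %||% 0, id = b$id)
  })
  pois <- lapply(seq_len(nrow(doc$pois)), function(i) {
    pos <- doc$pois$position
    pos_i <- if (is.matrix(pos)) pos[i, ] else unlist(pos[[i]])
    point_of_interest(doc$pois$label[i], pos_i, doc$pois$role[i])
  })
  images <- lapply(seq_len(nrow(doc$images)), function(i) {
    im <- doc$images[i, ]
    portal_image(.unflatten_rm(unlist(im$pixels), c(im$nrow, im$ncol)),
                 spacing = im$spacing, sid = im$sid, beam_id = im$beam_id)
  })
  ph <- doc$phantom
  structure(list(beams = beams,
                 phantom = slab_phantom(ph$thickness, ph$extent, ph$center,
                                        ph$orientation),
                 pois = pois, tps = doc$tps, images = images,
                 template = doc$template, mu_scale = doc$mu_scale),
            class = "virtual_delivery")
}

#' Export a deviation report as CSV
#'
#' Writes the per-beam rows and the per-point summary as two CSV files
#' (`<stem>_beams.csv`, `<stem>_points.csv`).
#'
#' @param report a `deviation_report`.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
write_report_csv <- function(report, stem) {
  p1 <- paste0(stem, "_beams.csv"); p2 <- paste0(stem, "_points.csv")
  write.csv(report$per_beam, p1, row.names = FALSE)
  write.csv(report$per_poi, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
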