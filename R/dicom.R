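# Minimal DICOM support (explicit VR little endian) for the RT Plan /
# RT Dose / RT Image tag subsets this package exchanges. JSON fixtures are
# the source of truth; this reader is a tolerant best-effort mapping that
# ignores unknown and private tags. The matching writers produce synthetic
# files for interoperability tests; they are not a general DICOM
# implementation.

.DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcm_value_raw <- function(vr, value) {
  if (vr %in% c("UI", "DS", "IS", "LO", "SH", "CS", "DA", "TM", "PN", "ST", "LT")) {
    s <- paste(vapply(value, function(v) {
      if (is.numeric(v)) format(v, digits = 15, scientific = FALSE) else as.character(v)
    }, ""), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2 == 1) {
      b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    }
    b
  } else if (vr == "US") {
    .u16(value)
  } else if (vr == "UL") {
    .u32(value)
  } else if (vr == "FL") {
    writeBin(as.double(value), raw(), size = 4, endian = "little")
  } else if (vr == "FD") {
    writeBin(as.double(value), raw(), size = 8, endian = "little")
  } else if (vr == "OW") {
    .u16(value)
  } else if (vr == "SQ") {
    # value: list of datasets (each a list of elements)
    do.call(c, lapply(value, function(item) {
      content <- do.call(c, lapply(item, function(el) {
        .dcm_element_raw(el$group, el$elem, el$vr, el$value)
      }))
      c(.u16(0xFFFE), .u16(0xE000), .u32(length(content)), content)
    }))
  } else {
    ed_stop("epidose_dicom_error", sprintf("unsupported VR '%s' in writer", vr))
  }
}

.dcm_element_raw <- function(group, elem, vr, value) {
  body <- .dcm_value_raw(vr, value)
  hdr <- c(.u16(group), .u16(elem), charToRaw(vr))
  if (vr %in% .DCM_LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), .u32(length(body)), body)
  } else {
    c(hdr, .u16(length(body)), body)
  }
}

.dcm_write <- function(elements, path) {
  meta <- .dcm_element_raw(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  body <- do.call(c, lapply(elements, function(el) {
    .dcm_element_raw(el$group, el$elem, el$vr, el$value)
  }))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# --- reader ----------------------------------------------------------------

.rd_u16 <- function(r, pos) {
  readBin(r[pos + 0:1], "integer", size = 2, signed = FALSE, endian = "little")
}
.rd_u32 <- function(r, pos) {
  readBin(r[pos + 0:3], "integer", size = 4, endian = "little")
}

# parse a dataset from raw bytes [from, to]; returns named list keyed
# "GGGG,EEEE" with entries list(vr, value)
.dcm_parse <- function(r, from, to) {
  out <- list()
  pos <- from
  while (pos <= to) {
    if (pos + 7 > to + 1) {
      ed_stop("epidose_dicom_error", "truncated DICOM element header")
    }
    group <- .rd_u16(r, pos); elem <- .rd_u16(r, pos + 2)
    vr <- rawToChar(r[pos + 4:5])
    if (vr %in% .DCM_LONG_VRS) {
      len <- .rd_u32(r, pos + 8); pos <- pos + 12
    } else {
      len <- .rd_u16(r, pos + 6); pos <- pos + 8
    }
    if (len < 0 || pos + len - 1 > to) {
      ed_stop("epidose_dicom_error",
              sprintf("truncated DICOM value for tag (%04X,%04X)", group, elem))
    }
    key <- sprintf("%04X,%04X", group, elem)
    val <- if (vr == "SQ") {
      .dcm_parse_items(r, pos, pos + len - 1)
    } else if (len == 0) {
      NULL
    } else {
      bytes <- r[pos:(pos + len - 1)]
      switch(vr,
        US = readBin(bytes, "integer", n = len / 2, size = 2, signed = FALSE,
                     endian = "little"),
        UL = readBin(bytes, "integer", n = len / 4, size = 4, endian = "little"),
        FL = readBin(bytes, "double", n = len / 4, size = 4, endian = "little"),
        FD = readBin(bytes, "double", n = len / 8, size = 8, endian = "little"),
        OW = readBin(bytes, "integer", n = len / 2, size = 2, signed = FALSE,
                     endian = "little"),
        OB = bytes,
        {
          s <- sub(" +$", "", rawToChar(bytes[bytes != as.raw(0)]))
          parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
          if (vr %in% c("DS", "IS", "FL", "FD")) as.numeric(parts) else parts
        })
    }
    out[[key]] <- list(vr = vr, value = val)
    pos <- pos + len
  }
  out
}

.dcm_parse_items <- function(r, from, to) {
  items <- list()
  pos <- from
  while (pos <= to) {
    group <- .rd_u16(r, pos); elem <- .rd_u16(r, pos + 2)
    if (group != 0xFFFE || elem != 0xE000) {
      ed_stop("epidose_dicom_error", "malformed sequence item")
    }
    len <- .rd_u32(r, pos + 4); pos <- pos + 8
    items[[length(items) + 1L]] <- .dcm_parse(r, pos, pos + len - 1)
    pos <- pos + len
  }
  items
}

.dcm_read_file <- function(path) {
  r <- readBin(path, raw(), n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM") {
    ed_stop("epidose_dicom_error",
            sprintf("'%s' is not a DICOM part-10 file", path))
  }
  .dcm_parse(r, 133, length(r))
}

.dcm_need <- function(ds, key, what) {
  el <- ds[[key]]
  if (is.null(el)) {
    ed_stop("epidose_missing_tag",
            sprintf("required DICOM tag (%s) %s is missing", key, what),
            tag = key)
  }
  el$value
}

#' Read a minimal DICOM RT file subset
#'
#' Maps the documented tag subsets onto this package's fixture objects:
#' * `rtimage`: RT Image SID (3002,0026), ImagePlanePixelSpacing
#'   (3002,0011), Rows/Columns, PixelData with optional rescale
#'   slope/intercept, mapped to a [portal_image()] (mm converted to cm).
#' * `rtdose`: dose grid geometry (ImagePositionPatient, PixelSpacing,
#'   GridFrameOffsetVector) and PixelData times DoseGridScaling, mapped to a
#'   `dose_grid` usable by [auto_poi_sample()].
#' * `rtplan`: BeamSequence (gantry angle, SAD, jaw positions) and the
#'   per-beam meterset from the FractionGroupSequence, mapped to a list of
#'   [beam_geometry()].
#'
#' Unknown and private tags are ignored; a missing required tag raises an
#' error naming it.
#'
#' @param path DICOM file path.
#' @param kind `"rtplan"`, `"rtdose"` or `"rtimage"`.
#' @return the mapped fixture object.
#' @export
read_dicom_subset <- function(path, kind = c("rtplan", "rtdose", "rtimage")) {
  kind <- match.arg(kind)
  ds <- .dcm_read_file(path)
  switch(kind,
    rtimage = {
      sid <- .dcm_need(ds, "3002,0026", "RT Image SID")
      sp <- .dcm_need(ds, "3002,0011", "Image Plane Pixel Spacing")
      nr <- .dcm_need(ds, "0028,0010", "Rows")
      nc <- .dcm_need(ds, "0028,0011", "Columns")
      pix <- .dcm_need(ds, "7FE0,0010", "Pixel Data")
      slope <- (ds[["0028,1053"]]$value) %||% 1
      icept <- (ds[["0028,1052"]]$value) %||% 0
      portal_image(matrix(slope * pix + icept, nr, nc, byrow = TRUE),
                   spacing = sp[1] / 10, sid = sid / 10,
                   beam_id = ds[["300A,00C8"]]$value %||% NULL)
    },
    rtdose = {
      scaling <- .dcm_need(ds, "3004,000E", "Dose Grid Scaling")
      offsets <- .dcm_need(ds, "3004,000C", "Grid Frame Offset Vector")
      ipp <- .dcm_need(ds, "0020,0032", "Image Position (Patient)")
      sp <- .dcm_need(ds, "0028,0030", "Pixel Spacing")
      nr <- .dcm_need(ds, "0028,0010", "Rows")
      nc <- .dcm_need(ds, "0028,0011", "Columns")
      nf <- as.integer(.dcm_need(ds, "0028,0008", "Number of Frames"))
      pix <- .dcm_need(ds, "7FE0,0010", "Pixel Data")
      # pixel order: frame, then row, then column (row-major per frame)
      a <- aperm(array(pix, c(nc, nr, nf)), c(1, 2, 3)) * scaling
      structure(list(x = (ipp[1] + (0:(nc - 1)) * sp[2]) / 10,
                     y = (ipp[2] + (0:(nr - 1)) * sp[1]) / 10,
                     z = (ipp[3] + offsets) / 10,
                     dose = a),
                class = "dose_grid")
    },
    rtplan = {
      beams <- .dcm_need(ds, "300A,00B0", "Beam Sequence")
      fg <- .dcm_need(ds, "300A,0070", "Fraction Group Sequence")
      refs <- fg[[1]][["300C,0004"]]$value
      mus <- setNames(
        vapply(refs, function(it) .dcm_need(it, "300A,0086", "Beam Meterset"),
               numeric(1)),
        vapply(refs, function(it) {
          as.character(.dcm_need(it, "300C,0006", "Referenced Beam Number"))
        }, ""))
      lapply(beams, function(b) {
        num <- as.character(.dcm_need(b, "300A,00C0", "Beam Number"))
        sad <- .dcm_need(b, "300A,00B4", "Source Axis Distance") / 10
        ga <- .dcm_need(b, "300A,011E", "Gantry Angle")
        jaws <- b[["300A,011A"]]$value
        fx <- 10; fy <- 10; cx <- 0; cy <- 0
        for (j in jaws %||% list()) {
          type <- .dcm_need(j, "300A,00B8", "RT Beam Limiting Device Type")
          pos <- .dcm_need(j, "300A,011C", "Leaf/Jaw Positions") / 10
          if (type %in% c("X", "ASYMX")) { fx <- diff(pos); cx <- mean(pos) }
          if (type %in% c("Y", "ASYMY")) { fy <- diff(pos); cy <- mean(pos) }
        }
        beam_geometry(sad = sad, sid = 1.5 * sad, gantry_angle = ga,
                      field_x = fx, field_y = fy,
                      mu = mus[[num]] %||% 0,
                      aperture_cx = cx, aperture_cy = cy,
                      id = paste0("beam", num))
      })
    })
}

#' Write a synthetic DICOM RT Image
#'
#' Explicit-VR little-endian writer for the tag subset
#' [read_dicom_subset()] consumes; intended for generating synthetic
#' interoperability fixtures.
#'
#' @param image a [portal_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dicom_rtimage <- function(image, path) {
  slope <- max(image$pixels) / 30000
  if (slope == 0) slope <- 1
  pix <- as.integer(round(as.vector(t(image$pixels)) / slope))
  el <- function(g, e, vr, v) list(group = g, elem = e, vr = vr, value = v)
  .dcm_write(list(
    el(0x0008, 0x0060, "CS", "RTIMAGE"),
    el(0x0028, 0x0010, "US", nrow(image$pixels)),
    el(0x0028, 0x0011, "US", ncol(image$pixels)),
    el(0x0028, 0x1052, "DS", 0),
    el(0x0028, 0x1053, "DS", slope),
    el(0x3002, 0x0011, "DS", rep(image$spacing * 10, 2)),
    el(0x3002, 0x0026, "DS", image$sid * 10),
    el(0x7FE0, 0x0010, "OW", pix)
  ), path)
}

#' Write a synthetic DICOM RT Dose
#'
#' @param grid a `dose_grid` (axes in cm, dose in Gy).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dicom_rtdose <- function(grid, path) {
  d <- grid$dose
  d[is.na(d)] <- 0
  scaling <- max(d) / 30000
  if (scaling == 0) scaling <- 1
  # frame-major (z), then rows (y), then columns (x)
  pix <- as.vector(aperm(d, c(1, 2, 3)))
  el <- function(g, e, vr, v) list(group = g, elem = e, vr = vr, value = v)
  .dcm_write(list(
    el(0x0008, 0x0060, "CS", "RTDOSE"),
    el(0x0020, 0x0032, "DS", c(grid$x[1], grid$y[1], grid$z[1]) * 10),
    el(0x0028, 0x0008, "IS", length(grid$z)),
    el(0x0028, 0x0010, "US", length(grid$y)),
    el(0x0028, 0x0011, "US", length(grid$x)),
    el(0x0028, 0x0030, "DS", c(diff(grid$y[1:2]), diff(grid$x[1:2])) * 10),
    el(0x3004, 0x000C, "DS", (grid$z - grid$z[1]) * 10),
    el(0x3004, 0x000E, "DS", scaling),
    el(0x7FE0, 0x0010, "OW", round(pix / scaling))
  ), path)
}

#' Write a synthetic DICOM RT Plan
#'
#' @param beams list of [beam_geometry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dicom_rtplan <- function(beams, path) {
  el <- function(g, e, vr, v) list(group = g, elem = e, vr = vr, value = v)
  beam_items <- lapply(seq_along(beams), function(i) {
    b <- beams[[i]]
    jaw <- function(type, lo, hi) {
      list(el(0x300A, 0x00B8, "CS", type),
           el(0x300A, 0x011C, "DS", c(lo, hi) * 10))
    }
    list(el(0x300A, 0x00C0, "IS", i),
         el(0x300A, 0x00B4, "DS", b$sad * 10),
         el(0x300A, 0x011E, "DS", b$gantry_angle),
         el(0x300A, 0x011A, "SQ",
            list(jaw("X", b$aperture_cx - b$field_x / 2,
                     b$aperture_cx + b$field_x / 2),
                 jaw("Y", b$aperture_cy - b$field_y / 2,
                     b$aperture_cy + b$field_y / 2))))
  })
  ref_items <- lapply(seq_along(beams), function(i) {
    list(el(0x300C, 0x0006, "IS", i),
         el(0x300A, 0x0086, "DS", beams[[i]]$mu))
  })
  .dcm_write(list(
    el(0x0008, 0x0060, "CS", "RTPLAN"),
    el(0x300A, 0x0070, "SQ", list(list(el(0x300C, 0x0004, "SQ", ref_items)))),
    el(0x300A, 0x00B0, "SQ", beam_items)
  ), path)
}
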