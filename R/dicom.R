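# Minimal DICOM Part-10 serialization (explicit VR little endian) for the
# three object types the toolkit needs: CT image slices, RT Structure Set,
# and grid-type RT Dose.  Only the tags this package writes are parsed back;
# round trips are covered by tests (including a pydicom cross-check).
#
# Axis mapping (one constant, see vignette): phantom cylinder axis -> DICOM z
# (slice stacking), anterior -> DICOM -y (head-first-supine convention),
# phantom x -> DICOM x.  So a phantom point (x, y, z) is written as the
# DICOM patient coordinate (x, -y, z).

UID_CT      <- "1.2.840.10008.5.1.4.1.1.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_RTDOSE  <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

.uid_env <- new.env(parent = emptyenv())
.uid_env$counter <- 0L

# Fresh UID under the UUID-derived root (2.25) plus process entropy.
new_uid <- function() {
  .uid_env$counter <- .uid_env$counter + 1L
  sprintf("2.25.%d%05d%06d", as.integer(Sys.time()) %% 100000000L,
          Sys.getpid() %% 100000L, .uid_env$counter)
}

phantom_to_dicom <- function(pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  cbind(pts[, 1], -pts[, 2], pts[, 3])
}
dicom_to_phantom <- phantom_to_dicom  # the mapping is its own inverse

# ---- low-level encoding -------------------------------------------------

pack_u16 <- function(x) {
  x <- as.integer(round(x))
  as.raw(rbind(x %% 256L, (x %/% 256L) %% 256L))
}
pack_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
               (x %/% 16777216) %% 256))
}
read_u16 <- function(r, n = 1L) readBin(r, "integer", n, size = 2L,
                                        signed = FALSE, endian = "little")
read_u32 <- function(r) {
  b <- as.integer(r[1:4])
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

format_ds <- function(x) {
  s <- sprintf("%.10g", x)
  if (any(nchar(s) > 16L)) s <- sprintf("%.8g", x)
  paste(s, collapse = "\\")
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UN", "UT")

# value: character scalar (string VRs, already backslash-joined), integer
# vector (US/UL), raw (OB/OW), or list of item element-lists (SQ).
dcm_element <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

encode_element <- function(el) {
  body <- switch(el$vr,
    US = pack_u16(el$value),
    UL = pack_u32(el$value),
    OB = , OW = as.raw(el$value),
    SQ = {
      items <- lapply(el$value, function(item) {
        content <- encode_dataset(item)
        c(pack_u16(c(0xFFFE, 0xE000)), pack_u32(length(content)), content)
      })
      do.call(c, c(items, list(raw(0))))
    },
    { # string VRs
      s <- charToRaw(as.character(el$value))
      if (length(s) %% 2L == 1L) {
        s <- c(s, if (el$vr == "UI") as.raw(0L) else charToRaw(" "))
      }
      s
    })
  if (el$vr %in% c("OB", "OW") && length(body) %% 2L == 1L) body <- c(body, as.raw(0))
  header <- c(pack_u16(c(el$group, el$element)), charToRaw(el$vr))
  if (el$vr %in% LONG_VRS) {
    c(header, as.raw(c(0, 0)), pack_u32(length(body)), body)
  } else {
    if (length(body) > 65535) stop("element too long for short-form VR ", el$vr)
    c(header, pack_u16(length(body)), body)
  }
}

encode_dataset <- function(elements) {
  key <- vapply(elements, function(e) e$group * 65536 + e$element, 0)
  elements <- elements[order(key)]
  do.call(c, lapply(elements, encode_element))
}

write_dcm_file <- function(file, sop_class, sop_instance, elements) {
  meta <- encode_dataset(list(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", sop_class),
    dcm_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", "2.25.4242424242")
  ))
  group_len <- encode_element(dcm_element(0x0002, 0x0000, "UL", length(meta)))
  body <- c(raw(128), charToRaw("DICM"), group_len, meta, encode_dataset(elements))
  ok <- tryCatch({ writeBin(body, file); TRUE }, error = function(e) FALSE)
  if (!ok) stop("I/O error writing DICOM file: ", file)
  invisible(file)
}

# ---- low-level decoding -------------------------------------------------

parse_elements <- function(r, pos, end) {
  out <- list()
  while (pos + 8 <= end) {
    group <- read_u16(r[pos + (1:2)])
    element <- read_u16(r[pos + (3:4)])
    vr <- rawToChar(r[pos + (5:6)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(r[pos + (9:12)]); data_at <- pos + 12
    } else {
      len <- read_u16(r[pos + (7:8)]); data_at <- pos + 8
    }
    bytes <- if (len > 0) r[(data_at + 1):(data_at + len)] else raw(0)
    value <- switch(vr,
      US = read_u16(bytes, len / 2L),
      UL = read_u32(bytes),
      OB = , OW = bytes,
      SQ = parse_items(bytes),
      DS = , IS = {
        s <- trimws(strsplit(rawToChar(bytes), "\\", fixed = TRUE)[[1]])
        as.numeric(s)
      },
      { v <- rawToChar(bytes[bytes != as.raw(0)]); trimws(v) })
    out[[sprintf("%04X,%04X", group, element)]] <- list(vr = vr, value = value)
    pos <- data_at + len
  }
  out
}

parse_items <- function(r) {
  items <- list(); pos <- 0L; end <- length(r)
  while (pos + 8 <= end) {
    len <- read_u32(r[pos + (5:8)])
    items[[length(items) + 1L]] <- parse_elements(r, pos + 8L, pos + 8L + len)
    pos <- pos + 8L + len
  }
  items
}

read_dcm_file <- function(file) {
  r <- readBin(file, "raw", file.info(file)$size)
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", file)
  }
  elements <- parse_elements(r, 132L, length(r))
  elements[!grepl("^0002,", names(elements))]
}

dcm_get <- function(ds, tag, required = TRUE) {
  el <- ds[[tag]]
  if (is.null(el)) {
    if (required) stop("format error: missing DICOM tag (", tag, ")")
    return(NULL)
  }
  el$value
}

# ---- CT series ----------------------------------------------------------

#' Write the pseudo-CT as a DICOM CT series
#'
#' One file per slice, stored pixel 0 with identity rescale (CT number
#' 0), per-slice Image Position (Patient) tags consistent with the spec,
#' and a shared frame-of-reference UID across the series.
#'
#' @param ct a [build_pseudo_ct()] result.
#' @param dir output directory (created if absent).
#' @return (invisibly) a list with `files`, `study_uid`, `series_uid`,
#'   `frame_uid`, `sop_instances` and `slice_z` for downstream objects.
#' @export
write_ct_series <- function(ct, dir) {
  stopifnot(inherits(ct, "pseudo_ct"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- ct$spec
  study <- new_uid(); series <- new_uid(); frame <- new_uid()
  sops <- character(spec$n_slices)
  files <- character(spec$n_slices)
  px <- pack_u16(rep(spec$fill_value, spec$matrix^2))
  for (i in seq_len(spec$n_slices)) {
    sops[i] <- new_uid()
    files[i] <- file.path(dir, sprintf("CT_%04d.dcm", i))
    ipp <- c(spec$corner, spec$corner, ct$slice_z[i])
    els <- list(
      dcm_element(0x0008, 0x0016, "UI", UID_CT),
      dcm_element(0x0008, 0x0018, "UI", sops[i]),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0010, 0x0010, "PN", "VIRTUAL^PHANTOM"),
      dcm_element(0x0010, 0x0020, "LO", "ARCQA"),
      dcm_element(0x0018, 0x0050, "DS", format_ds(spec$slice_thickness)),
      dcm_element(0x0020, 0x000D, "UI", study),
      dcm_element(0x0020, 0x000E, "UI", series),
      dcm_element(0x0020, 0x0013, "IS", as.character(i)),
      dcm_element(0x0020, 0x0032, "DS", format_ds(ipp)),
      dcm_element(0x0020, 0x0037, "DS", format_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0020, 0x0052, "UI", frame),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", spec$matrix),
      dcm_element(0x0028, 0x0011, "US", spec$matrix),
      dcm_element(0x0028, 0x0030, "DS", format_ds(rep(spec$pixel_spacing, 2))),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 0L),
      dcm_element(0x0028, 0x1052, "DS", "0"),
      dcm_element(0x0028, 0x1053, "DS", "1"),
      dcm_element(0x7FE0, 0x0010, "OW", px)
    )
    write_dcm_file(files[i], UID_CT, sops[i], els)
  }
  invisible(list(files = files, study_uid = study, series_uid = series,
                 frame_uid = frame, sop_instances = sops, slice_z = ct$slice_z))
}

#' Read back a DICOM CT series
#'
#' @param files character vector of file paths, or a directory.
#' @return list with `matrix`, `pixel_spacing`, `slice_thickness`,
#'   `corner`, `slice_z` (sorted), `frame_uid`, `sop_instances`, and
#'   `pixels` (list of integer matrices in file z order).
#' @export
read_ct_series <- function(files) {
  if (length(files) == 1L && dir.exists(files)) {
    files <- list.files(files, pattern = "\\.dcm$", full.names = TRUE)
  }
  if (length(files) == 0L) stop("no DICOM files found")
  slices <- lapply(files, read_dcm_file)
  z <- vapply(slices, function(s) dcm_get(s, "0020,0032")[3], 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  first <- slices[[1]]
  n <- dcm_get(first, "0028,0010")
  pixels <- lapply(slices, function(s) {
    matrix(read_u16(dcm_get(s, "7FE0,0010"), n * n), nrow = n)
  })
  list(matrix = n,
       pixel_spacing = dcm_get(first, "0028,0030")[1],
       slice_thickness = dcm_get(first, "0018,0050"),
       corner = dcm_get(first, "0020,0032")[1],
       slice_z = z,
       frame_uid = dcm_get(first, "0020,0052"),
       sop_instances = vapply(slices, function(s) dcm_get(s, "0008,0018"), ""),
       pixels = pixels)
}

# ---- RT Structure Set ---------------------------------------------------

#' Write a structure set as a DICOM RT Structure Set
#'
#' One region of interest per structure; contours are written as closed
#' planar polylines (the repeated closing vertex is dropped on write and
#' restored on read) in the DICOM patient frame, referencing the CT
#' series' frame of reference.
#'
#' @param structures a [build_structures()] result.
#' @param ct_ref the list returned by [write_ct_series()].
#' @param file output path.
#' @return (invisibly) `file`.
#' @export
write_rtstruct <- function(structures, ct_ref, file) {
  stopifnot(inherits(structures, "structure_set"))
  roi_items <- list(); contour_items <- list()
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    roi_items[[i]] <- list(
      dcm_element(0x3006, 0x0022, "IS", as.character(i)),
      dcm_element(0x3006, 0x0024, "UI", ct_ref$frame_uid),
      dcm_element(0x3006, 0x0026, "LO", s$name)
    )
    cs <- vector("list", length(s$slice_idx))
    for (k in seq_along(s$slice_idx)) {
      zi <- s$slice_idx[k]
      if (zi < 1L || zi > length(ct_ref$slice_z)) {
        stop("contour references a slice position absent from the CT series")
      }
      poly <- s$contours[[k]]
      if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
      pts <- phantom_to_dicom(cbind(poly, ct_ref$slice_z[zi]))
      cs[[k]] <- list(
        dcm_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", as.character(nrow(pts))),
        dcm_element(0x3006, 0x0050, "DS", format_ds(as.numeric(t(pts))))
      )
    }
    contour_items[[i]] <- list(
      dcm_element(0x3006, 0x0040, "SQ", cs),
      dcm_element(0x3006, 0x0084, "IS", as.character(i))
    )
  }
  sop <- new_uid()
  els <- list(
    dcm_element(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    dcm_element(0x0008, 0x0018, "UI", sop),
    dcm_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_element(0x0010, 0x0010, "PN", "VIRTUAL^PHANTOM"),
    dcm_element(0x0010, 0x0020, "LO", "ARCQA"),
    dcm_element(0x0020, 0x000D, "UI", ct_ref$study_uid),
    dcm_element(0x0020, 0x000E, "UI", new_uid()),
    dcm_element(0x3006, 0x0002, "SH", "ARCQA"),
    dcm_element(0x3006, 0x0020, "SQ", roi_items),
    dcm_element(0x3006, 0x0039, "SQ", contour_items)
  )
  write_dcm_file(file, UID_RTSTRUCT, sop, els)
  invisible(file)
}

#' Read back a DICOM RT Structure Set
#'
#' @param file path to the structure set.
#' @return list with one entry per ROI: `name`, `number`, and `contours`
#'   (list of closed n x 3 matrices in the phantom frame, mm).
#' @export
read_rtstruct <- function(file) {
  ds <- read_dcm_file(file)
  rois <- dcm_get(ds, "3006,0020")
  contours <- dcm_get(ds, "3006,0039")
  numbers <- vapply(contours, function(it) dcm_get(it, "3006,0084"), 0)
  out <- lapply(seq_along(rois), function(i) {
    num <- dcm_get(rois[[i]], "3006,0022")
    ci <- contours[[match(num, numbers)]]
    polys <- lapply(dcm_get(ci, "3006,0040"), function(cn) {
      pts <- matrix(dcm_get(cn, "3006,0050"), ncol = 3, byrow = TRUE)
      pts <- dicom_to_phantom(pts)
      rbind(pts, pts[1, , drop = FALSE])
    })
    list(name = dcm_get(rois[[i]], "3006,0026"), number = num, contours = polys)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# ---- RT Dose ------------------------------------------------------------

#' Dose grid container
#'
#' Absolute dose (Gy) on a regular 3D grid of voxel centers in the
#' phantom frame.
#'
#' @param grid a [grid3d()].
#' @param values nonnegative 3D array of dose (Gy), `dim = c(nx, ny, nz)`.
#' @param beam optional beam metadata attached to the grid.
#' @return object of class `dose_grid`.
#' @export
dose_grid <- function(grid, values, beam = NULL) {
  stopifnot(inherits(grid, "grid3d"))
  if (length(values) == 0L) stop("empty dose grid")
  if (!identical(dim(values), c(length(grid$x), length(grid$y), length(grid$z)))) {
    stop("dose array dimensions do not match the grid")
  }
  if (any(values < 0)) stop("dose values must be nonnegative")
  structure(list(grid = grid, values = values, beam = beam,
                 frame = "phantom"), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %d x %d x %d voxels, max %.4g Gy\n",
              length(x$grid$x), length(x$grid$y), length(x$grid$z),
              max(x$values)))
  invisible(x)
}

#' Write / read a grid-type DICOM RT Dose
#'
#' Doses are stored as 16-bit unsigned integers with
#' `DoseGridScaling = max(dose) / (2^16 - 1)`, so the reconstruction
#' `stored x scaling` is exact at the maximum and within one quantum
#' elsewhere.
#'
#' @param dose a [dose_grid()].
#' @param file output path.
#' @return `write_rtdose` returns (invisibly) `file`; `read_rtdose`
#'   returns a [dose_grid()].
#' @export
write_rtdose <- function(dose, file) {
  stopifnot(inherits(dose, "dose_grid"))
  g <- dose$grid
  mx <- max(dose$values)
  scaling <- if (mx > 0) mx / 65535 else 1
  stored <- round(dose$values / scaling)
  # DICOM rows run along -y in the phantom frame: reverse the y axis.
  ny <- length(g$y)
  px <- integer(0)
  frames <- lapply(seq_along(g$z), function(k) {
    slab <- stored[, ny:1, k]              # [x = image column, dicom row]
    as.integer(slab)                       # column-fastest == row-major pixels
  })
  px <- unlist(frames)
  corner_dicom <- c(g$x[1], -g$y[ny], g$z[1])
  sop <- new_uid()
  els <- list(
    dcm_element(0x0008, 0x0016, "UI", UID_RTDOSE),
    dcm_element(0x0008, 0x0018, "UI", sop),
    dcm_element(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_element(0x0010, 0x0010, "PN", "VIRTUAL^PHANTOM"),
    dcm_element(0x0010, 0x0020, "LO", "ARCQA"),
    dcm_element(0x0020, 0x000D, "UI", new_uid()),
    dcm_element(0x0020, 0x000E, "UI", new_uid()),
    dcm_element(0x0020, 0x0032, "DS", format_ds(corner_dicom)),
    dcm_element(0x0020, 0x0037, "DS", format_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0008, "IS", as.character(length(g$z))),
    dcm_element(0x0028, 0x0010, "US", ny),
    dcm_element(0x0028, 0x0011, "US", length(g$x)),
    dcm_element(0x0028, 0x0030, "DS",
                format_ds(c(g$spacing[["dy"]], g$spacing[["dx"]]))),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x3004, 0x0002, "CS", "GY"),
    dcm_element(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_element(0x3004, 0x000A, "CS", "PLAN"),
    dcm_element(0x3004, 0x000C, "DS", format_ds(g$z - g$z[1])),
    dcm_element(0x3004, 0x000E, "DS", format_ds(scaling)),
    dcm_element(0x7FE0, 0x0010, "OW", pack_u16(px))
  )
  write_dcm_file(file, UID_RTDOSE, sop, els)
  invisible(file)
}

#' @rdname write_rtdose
#' @export
read_rtdose <- function(file) {
  ds <- read_dcm_file(file)
  scaling <- dcm_get(ds, "3004,000E")
  nframes <- dcm_get(ds, "0028,0008")
  rows <- dcm_get(ds, "0028,0010"); cols <- dcm_get(ds, "0028,0011")
  spacing <- dcm_get(ds, "0028,0030")          # (row, col)
  ipp <- dcm_get(ds, "0020,0032")
  offsets <- dcm_get(ds, "3004,000C")
  stored <- read_u16(dcm_get(ds, "7FE0,0010"), rows * cols * nframes)
  x <- ipp[1] + (seq_len(cols) - 1) * spacing[2]
  y_dicom <- ipp[2] + (seq_len(rows) - 1) * spacing[1]
  z <- ipp[3] + offsets
  values <- array(0, dim = c(cols, rows, nframes))
  for (k in seq_len(nframes)) {
    fr <- matrix(stored[((k - 1) * rows * cols + 1):(k * rows * cols)],
                 nrow = cols)                  # [col, row] after transpose-free fill
    values[, , k] <- fr[, rows:1]              # back to ascending phantom y
  }
  g <- grid3d(x, rev(-y_dicom), z)
  dose_grid(g, values * scaling)
}
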