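# Detector-helix and phantom geometry.
#
# Phantom frame: right-handed, origin at isocenter, cylinder axis along z
# (the slice-stacking axis), anterior pole at +y.  Gantry 0 deg means the
# beam enters from anterior; the gantry angle increases from +y toward +x.
# The unfolded chart uses signed arc length from the anterior pole
# (positive toward +x by default) and a nominal axial coordinate.

#' Detector array specification
#'
#' Describes the helical diode geometry: 1386 diodes in 21 helix turns of
#' 66 (22 circuit boards of 3 per turn), all at 104 mm from the cylinder
#' axis, with a nominal 10 mm spacing between adjacent diodes along the
#' circumference and a 10 mm axial pitch per turn.
#'
#' @param n_total total diode count.
#' @param per_turn diodes per helix turn.
#' @param n_turns number of helix turns.
#' @param radius diode distance from the cylinder axis (mm).
#' @param nominal_arc_spacing chart spacing between adjacent diodes (mm).
#' @param turn_pitch axial advance per helix revolution (mm).
#' @param pcb_count circuit boards per turn (3 diodes each).
#' @param arc_positive_x if `TRUE` (default) positive chart arc maps to +x.
#' @param axial_advance `-1` (default) when the physical axial coordinate
#'   decreases as the arc coordinate increases within a turn, `+1` for the
#'   opposite handedness. The default reproduces the published chart
#'   positions of the seam-adjacent exit diodes.
#' @return An object of class `detector_array_spec`.
#' @export
detector_array_spec <- function(n_total = 1386L, per_turn = 66L, n_turns = 21L,
                                radius = 104.0, nominal_arc_spacing = 10.0,
                                turn_pitch = 10.0, pcb_count = 22L,
                                arc_positive_x = TRUE, axial_advance = -1L) {
  if (n_total != per_turn * n_turns) {
    stop(sprintf("configuration error: n_total (%d) != per_turn (%d) x n_turns (%d)",
                 n_total, per_turn, n_turns))
  }
  if (per_turn != 3L * pcb_count) {
    stop("configuration error: per_turn must equal 3 x pcb_count")
  }
  if (radius <= 0 || nominal_arc_spacing <= 0 || turn_pitch <= 0) {
    stop("radius, nominal_arc_spacing and turn_pitch must be positive")
  }
  if (!axial_advance %in% c(-1L, 1L)) stop("axial_advance must be -1 or +1")
  structure(list(n_total = as.integer(n_total), per_turn = as.integer(per_turn),
                 n_turns = as.integer(n_turns), radius = radius,
                 nominal_arc_spacing = nominal_arc_spacing,
                 turn_pitch = turn_pitch, pcb_count = as.integer(pcb_count),
                 arc_positive_x = isTRUE(arc_positive_x),
                 axial_advance = as.integer(axial_advance)),
            class = "detector_array_spec")
}

#' Build the helical detector array
#'
#' Places `per_turn` diodes per revolution at an exact angular spacing of
#' 360/`per_turn` degrees, offset by half a spacing so no diode sits on
#' the anterior or posterior pole.  The physical axial coordinate advances
#' by `turn_pitch` per revolution (a true helix); turns are stacked to
#' span `n_turns * turn_pitch` mm centered on the isocenter plane.  Chart
#' coordinates follow the nominal convention: arc at +-5, +-15, ...,
#' +-325 mm from the anterior pole and axial equal to the turn's nominal
#' position (multiples of `turn_pitch`), so the two entrance diodes of
#' the central turn sit at (-5, 0) and (5, 0).
#'
#' @param spec a [detector_array_spec()].
#' @return A `data.frame` of class `detector_array` with one row per
#'   diode: `index`, `turn` (centered, 0 = central turn), `angle_deg`
#'   (signed, from the anterior pole), `x_mm`, `y_mm`, `z_mm`, `arc_mm`,
#'   `axial_mm`.
#' @export
#' @examples
#' arr <- build_detector_array()
#' nrow(arr)                        # 1386
#' range(sqrt(arr$x_mm^2 + arr$y_mm^2))  # 104, 104
build_detector_array <- function(spec = detector_array_spec()) {
  if (!inherits(spec, "detector_array_spec")) stop("spec must be a detector_array_spec")
  j <- seq_len(spec$per_turn) - 1L                       # position along the turn
  tc <- seq_len(spec$n_turns) - 1L - (spec$n_turns - 1L) / 2  # centered turn index
  arc1 <- (j - (spec$per_turn - 1) / 2) * spec$nominal_arc_spacing
  theta1 <- arc1 / (spec$per_turn * spec$nominal_arc_spacing) * 360
  dz1 <- spec$axial_advance * ((j + 0.5) / spec$per_turn - 0.5) * spec$turn_pitch
  turn <- rep(tc, each = spec$per_turn)
  arc <- rep(arc1, times = spec$n_turns)
  theta <- rep(theta1, times = spec$n_turns)
  z <- turn * spec$turn_pitch + rep(dz1, times = spec$n_turns)
  sgn <- if (spec$arc_positive_x) 1 else -1
  out <- data.frame(
    index = seq_len(spec$n_total),
    turn = turn,
    angle_deg = theta,
    x_mm = sgn * spec$radius * sin(theta * pi / 180),
    y_mm = spec$radius * cos(theta * pi / 180),
    z_mm = z,
    arc_mm = arc,
    axial_mm = turn * spec$turn_pitch
  )
  class(out) <- c("detector_array", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Unfolded chart coordinates of a detector array
#'
#' @param array a [build_detector_array()] result.
#' @return A `data.frame` with `index`, `arc_mm`, `axial_mm`.
#' @export
chart_coordinates <- function(array) {
  stopifnot(inherits(array, "detector_array"))
  array[, c("index", "arc_mm", "axial_mm")]
}

# Wrapped angular distance in degrees, in [0, 180].
angular_distance <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Entrance/exit sampling diodes for the EEDR
#'
#' Selects the two entrance-side diodes (left and right of the beam
#' central axis) and the four exit-side diodes around the axis, by
#' smallest angular distance to the beam entry/exit pole and then
#' smallest physical axial distance from the isocenter plane.  At gantry
#' 0 this yields chart positions (-5, 0), (5, 0) on the entrance side and
#' (325, 10), (325, 0), (-325, 0), (-325, -10) on the exit side.
#'
#' @param array a [build_detector_array()] result.
#' @param gantry_angle beam gantry angle in degrees (0 = from anterior).
#' @return list with integer index vectors `entrance` (2) and `exit` (4).
#' @export
eedr_detectors <- function(array, gantry_angle = 0) {
  stopifnot(inherits(array, "detector_array"))
  pick <- function(pole, k) {
    d <- angular_distance(array$angle_deg, pole)
    cand <- which(d < min(d) + 1e-9)
    cand[order(abs(array$z_mm[cand]), array$arc_mm[cand])][seq_len(k)]
  }
  list(entrance = sort(pick(gantry_angle %% 360, 2L)),
       exit = sort(pick((gantry_angle + 180) %% 360, 4L)))
}

#' Plug-center grid of the multi-plug insert
#'
#' A 5 x 5 grid of 2 x 2 cm plug centers at 20 mm spacing, centered on
#' the phantom axis; all 25 centers lie inside the 75 mm insert radius.
#'
#' @param n points per side (odd).
#' @param spacing center-to-center spacing (mm).
#' @param insert_radius radius of the insert that must contain the grid (mm).
#' @return `data.frame` with `x_mm`, `y_mm` (transverse plane, mm).
#' @export
multiplug_grid <- function(n = 5L, spacing = 20.0, insert_radius = 75.0) {
  if (n %% 2L != 1L) stop("plug grid must have an odd number of points per side")
  v <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- expand.grid(x_mm = v, y_mm = v, KEEP.OUT.ATTRS = FALSE)
  if (max(sqrt(g$x_mm^2 + g$y_mm^2)) >= insert_radius) {
    stop("plug grid does not fit inside the insert radius")
  }
  g[order(g$y_mm, g$x_mm), , drop = FALSE]
}

#' Gantry-angle measurement series
#'
#' Full rotation starting at `start` degrees advancing by `step`
#' (wrapping at 360), with angles inside the closed `excluded` interval
#' removed.  The defaults reproduce the 174-beam attenuation series
#' (every 2 degrees, beams from 8 to 18 degrees excluded).
#'
#' @param step angle step (degrees); must divide 360.
#' @param excluded closed interval `c(lo, hi)` of excluded angles, or `NULL`.
#' @param start first angle (degrees).
#' @return numeric vector of angles in `[0, 360)`.
#' @export
#' @examples
#' length(gantry_angle_series())            # 174
#' length(gantry_angle_series(excluded = NULL))  # 180
gantry_angle_series <- function(step = 2, excluded = c(8, 18), start = 180) {
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-9) {
    stop("step must be a positive divisor of 360")
  }
  angles <- (start + step * (seq_len(round(360 / step)) - 1)) %% 360
  if (!is.null(excluded)) {
    stopifnot(length(excluded) == 2L)
    if (any(abs(excluded / step - round(excluded / step)) > 1e-9)) {
      warning("excluded interval endpoints are not aligned to the step; ",
              "removing every angle inside the interval")
    }
    lo <- excluded[1] %% 360; hi <- excluded[2] %% 360
    drop <- if (lo <= hi) angles >= lo & angles <= hi else angles >= lo | angles <= hi
    angles <- angles[!drop]
  }
  angles
}

#' Five-ring structure table
#'
#' The cylindrical phantom reduced to five concentric density regions:
#' Outer (outer acrylic shell), Complex (circuit boards and surrounding
#' low-density material), Detectors (diode layer), Inner (inner acrylic
#' shell) and Insert (acrylic plug insert), with their outer radii and
#' default relative electron densities.
#'
#' @param name,outer_radius_mm,red vectors defining the rings, outermost
#'   first; radii must be strictly decreasing and REDs positive.
#' @return `data.frame` of class `ring_structures`.
#' @export
ring_structures <- function(name = c("Outer", "Complex", "Detectors", "Inner", "Insert"),
                            outer_radius_mm = c(133.0, 110.0, 103.4, 100.0, 75.0),
                            red = c(1.130, 1.200, 1.000, 1.130, 1.130)) {
  stopifnot(length(name) == length(outer_radius_mm), length(name) == length(red))
  if (any(diff(outer_radius_mm) >= 0)) stop("ring radii must be strictly decreasing")
  if (any(red <= 0)) stop("ring REDs must be positive")
  structure(data.frame(name = as.character(name),
                       outer_radius_mm = outer_radius_mm, red = red),
            class = c("ring_structures", "data.frame"))
}

#' QA-platform objects (synthetic default outlines)
#'
#' The adjustable setup platform is modeled as six contoured objects,
#' three per side, named LtOuter, LtMiddle, LtInner, RtInner, RtMiddle,
#' RtOuter, each with a closed transverse outline, a slice range and a
#' uniform RED (default 1.350).  The published work does not print the
#' platform outlines, so the default here is a synthetic fixture: three
#' mirror-symmetric rectangles per side beneath the phantom.
#'
#' @param red relative electron density assigned to every object.
#' @param z_range axial extent `c(lo, hi)` of the objects (mm).
#' @param outlines optional named list of closed polygons (n x 2 matrices,
#'   mm) replacing the synthetic default; names must be the six platform
#'   names above.
#' @return list of class `platform_objects`; each element has `name`,
#'   `outline` (closed polygon), `z_range`, `red`.
#' @export
platform_objects <- function(red = 1.350, z_range = c(-121, 121), outlines = NULL) {
  nm <- c("LtOuter", "LtMiddle", "LtInner", "RtInner", "RtMiddle", "RtOuter")
  if (is.null(outlines)) {
    rect <- function(x0, x1, y0, y1) {
      cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
    }
    xr <- list(c(-160, -120), c(-110, -70), c(-60, -20),
               c(20, 60), c(70, 110), c(120, 160))
    outlines <- lapply(xr, function(r) rect(r[1], r[2], -175, -145))
    names(outlines) <- nm
  }
  if (!setequal(names(outlines), nm)) {
    stop("platform outlines must be named ", paste(nm, collapse = ", "))
  }
  if (red <= 0) stop("platform RED must be positive")
  objs <- lapply(nm, function(n) {
    p <- as.matrix(outlines[[n]])
    if (!all(p[1, ] == p[nrow(p), ])) stop("platform outline for ", n, " is not closed")
    if (polygon_self_intersects(p)) stop("platform outline for ", n, " self-intersects")
    list(name = n, outline = p, z_range = z_range, red = red)
  })
  names(objs) <- nm
  structure(objs, class = "platform_objects")
}
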