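# Sampling dose grids at detector and plug positions, unfolding to the
# 2D chart, normalization and calibration-dose extraction.

# Deterministic quasi-uniform unit ball: a Fibonacci-spiral half set plus
# its point reflection, so the mean over any linear field is exactly the
# center value.
unit_ball_points <- function(n = 256L) {
  stopifnot(n %% 2L == 0L)
  m <- n %/% 2L
  i <- seq_len(m) - 0.5
  phi <- (1 + sqrt(5)) / 2
  r <- (i / m)^(1 / 3)
  theta <- acos(1 - 2 * i / m)               # polar angle over the sphere
  lon <- 2 * pi * i / phi
  p <- cbind(r * sin(theta) * cos(lon), r * sin(theta) * sin(lon), r * cos(theta))
  rbind(p, -p)
}

#' Sample a dose grid at a point or over a small sphere
#'
#' With `radius = 0`, trilinear interpolation at the point.  With
#' `radius > 0`, the mean of trilinear samples over a fixed deterministic
#' quasi-uniform ball of `n_ball` points (no randomness), matching the
#' 0.25 cm sphere used for plug-point dose sampling.
#'
#' @param dose a [dose_grid()].
#' @param position length-3 point (mm, phantom frame).
#' @param radius averaging-sphere radius (mm); default 0 (point sample).
#' @param n_ball points in the averaging ball (even).
#' @return dose in Gy.
#' @export
sample_point <- function(dose, position, radius = 0, n_ball = 256L) {
  stopifnot(inherits(dose, "dose_grid"), length(position) == 3L)
  if (radius < 0) stop("radius must be nonnegative")
  pts <- if (radius == 0) {
    matrix(position, 1, 3)
  } else {
    sweep(radius * unit_ball_points(n_ball), 2, as.numeric(position), `+`)
  }
  mean(interp3(dose$grid, dose$values, pts, outside = "error"))
}

#' Sample a dose grid at every diode position
#'
#' Point (radius 0) trilinear sampling at each diode's 3D position.
#'
#' @param dose a [dose_grid()].
#' @param array a [build_detector_array()] result.
#' @param source provenance tag, `"calculated"` or `"measured-like"`.
#' @return `data.frame` of class `detector_doses` with `index`, `arc_mm`,
#'   `axial_mm`, `dose_Gy`; beam metadata (if any) carried as the `beam`
#'   attribute.
#' @export
sample_detectors <- function(dose, array, source = "calculated") {
  stopifnot(inherits(dose, "dose_grid"), inherits(array, "detector_array"))
  pts <- cbind(array$x_mm, array$y_mm, array$z_mm)
  g <- dose$grid
  out <- pts[, 1] < min(g$x) | pts[, 1] > max(g$x) |
         pts[, 2] < min(g$y) | pts[, 2] > max(g$y) |
         pts[, 3] < min(g$z) | pts[, 3] > max(g$z)
  if (any(out)) {
    stop("detectors outside the dose grid: indices ",
         paste(utils::head(array$index[out], 10), collapse = ", "),
         if (sum(out) > 10) " ..." else "")
  }
  detector_doses(array, interp3(g, dose$values, pts),
                 beam = dose$beam, source = source)
}

#' Construct a per-diode dose set
#'
#' @param array a [build_detector_array()] result.
#' @param dose_Gy numeric vector, one dose per diode (Gy).
#' @param beam optional beam metadata (list with e.g. `gantry_angle`,
#'   `field`, `mu`).
#' @param source `"calculated"` or `"measured-like"`.
#' @return `data.frame` of class `detector_doses`.
#' @export
detector_doses <- function(array, dose_Gy, beam = NULL, source = "calculated") {
  stopifnot(inherits(array, "detector_array"))
  if (length(dose_Gy) != nrow(array)) {
    stop("dose vector length must equal the detector count")
  }
  if (any(dose_Gy < 0)) stop("doses must be nonnegative")
  out <- data.frame(index = array$index, arc_mm = array$arc_mm,
                    axial_mm = array$axial_mm, dose_Gy = as.numeric(dose_Gy))
  class(out) <- c("detector_doses", "data.frame")
  attr(out, "beam") <- beam
  attr(out, "source") <- source
  out
}

#' Unfold per-diode doses to the 2D chart
#'
#' Maps each diode dose to its (arc, axial) chart coordinate, ordered by
#' (axial, arc).
#'
#' @param doses a [detector_doses()] set.
#' @param array the matching [build_detector_array()] (used for a length
#'   check only; chart coordinates travel with the doses).
#' @return `data.frame` of class `unfolded_map` with `arc_mm`,
#'   `axial_mm`, `dose_Gy`, `index`.
#' @export
unfold <- function(doses, array = NULL) {
  stopifnot(inherits(doses, "detector_doses"))
  if (!is.null(array) && nrow(array) != nrow(doses)) {
    stop("doses and array lengths differ")
  }
  out <- doses[order(doses$axial_mm, doses$arc_mm),
               c("arc_mm", "axial_mm", "dose_Gy", "index")]
  rownames(out) <- NULL
  class(out) <- c("unfolded_map", "data.frame")
  attr(out, "beam") <- attr(doses, "beam")
  out
}

#' Chart dose at given (arc, axial) positions
#'
#' Exact lookup of unfolded doses (the unfolding is a bijection, so this
#' re-fold recovers per-diode doses exactly).
#'
#' @param map an [unfold()] result.
#' @param arc_mm,axial_mm chart coordinates to look up.
#' @return numeric doses (Gy); error if a position has no diode.
#' @export
chart_dose <- function(map, arc_mm, axial_mm) {
  stopifnot(inherits(map, "unfolded_map"))
  key <- paste(map$arc_mm, map$axial_mm)
  idx <- match(paste(arc_mm, axial_mm), key)
  if (anyNA(idx)) stop("no diode at the requested chart position(s)")
  map$dose_Gy[idx]
}

#' Convert an unfolded map to a regular chart grid
#'
#' The chart is a full regular grid (one diode per (arc, axial) cell), so
#' the conversion is lossless.
#'
#' @param map an [unfold()] result.
#' @return list of class `dose_map2d`: `x` (arc values), `y` (axial
#'   values), `values` (matrix `length(x)` x `length(y)`).
#' @export
unfolded_grid <- function(map) {
  stopifnot(inherits(map, "unfolded_map"))
  xs <- sort(unique(map$arc_mm)); ys <- sort(unique(map$axial_mm))
  m <- matrix(NA_real_, length(xs), length(ys))
  m[cbind(match(map$arc_mm, xs), match(map$axial_mm, ys))] <- map$dose_Gy
  if (anyNA(m)) stop("unfolded map does not cover a full chart grid")
  structure(list(x = xs, y = ys, values = m), class = "dose_map2d")
}

#' Plot an unfolded dose chart
#' @param x an `unfolded_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.unfolded_map <- function(x, ...) {
  g <- unfolded_grid(x)
  graphics::image(g$x, g$y, g$values, xlab = "arc (mm)", ylab = "axial (mm)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Normalize per-diode doses
#'
#' Divides the dose set by a reference chosen by `mode`:
#' `entrance_mean` (mean of the two entrance-side diodes),
#' `center_point` (dose sampled on the phantom axis), or
#' `reference_beam` (an explicit `reference` value, e.g. from another
#' beam).
#'
#' @param doses a [detector_doses()] set.
#' @param mode normalization mode.
#' @param array detector array (needed for `entrance_mean`).
#' @param dose dose grid (needed for `center_point`).
#' @param reference explicit reference dose (for `reference_beam`).
#' @param gantry_angle beam angle used to pick the entrance diodes.
#' @return normalized `detector_doses`; the reference value is recorded
#'   in the `normalization` attribute.
#' @export
normalize_doses <- function(doses,
                            mode = c("entrance_mean", "center_point", "reference_beam"),
                            array = NULL, dose = NULL, reference = NULL,
                            gantry_angle = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(doses, "detector_doses"))
  ref <- switch(mode,
    entrance_mean = {
      if (is.null(array)) stop("entrance_mean normalization needs the detector array")
      sel <- eedr_detectors(array, gantry_angle)$entrance
      mean(doses$dose_Gy[match(sel, doses$index)])
    },
    center_point = {
      if (is.null(dose)) stop("center_point normalization needs the dose grid")
      sample_point(dose, c(0, 0, 0))
    },
    reference_beam = {
      if (is.null(reference)) stop("reference_beam normalization needs a reference value")
      reference
    })
  if (!is.finite(ref) || ref <= 0) stop("normalization reference must be positive")
  out <- doses
  out$dose_Gy <- doses$dose_Gy / ref
  attr(out, "normalization") <- list(mode = mode, reference = ref)
  out
}

#' Calibration dose of the reference beam
#'
#' Mean of the two entrance-side central-turn diode doses for the
#' calibration geometry (10 x 10 cm field, gantry 0, 200 MU); this value
#' is entered as the calibration dose when comparing measured and
#' calculated dose sets absolutely.
#'
#' @param doses a [detector_doses()] set from the calibration beam.
#' @param array the [build_detector_array()] used.
#' @return calibration dose (Gy).
#' @export
calibration_dose <- function(doses, array) {
  stopifnot(inherits(doses, "detector_doses"))
  beam <- attr(doses, "beam")
  if (!is.null(beam)) {
    ok <- isTRUE(all.equal(beam$gantry_angle %% 360, 0)) &&
      isTRUE(all.equal(as.numeric(beam$field), c(10, 10))) &&
      isTRUE(all.equal(beam$mu, 200))
    if (!ok) {
      warning("beam metadata is not the calibration geometry ",
              "(10 x 10 cm, gantry 0, 200 MU); value returned anyway")
    }
  }
  sel <- eedr_detectors(array, 0)$entrance
  mean(doses$dose_Gy[match(sel, doses$index)])
}
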