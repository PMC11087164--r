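# QA metrics: exit/entrance dose ratio (EEDR), monitor-unit rescaling,
# and local/global DTA and gamma-index analysis on the unfolded chart.

#' Exit/entrance dose ratio
#'
#' Mean dose over the two entrance-side diodes (chart (-5, 0), (5, 0) at
#' gantry 0) and the four exit-side diodes around the beam axis (chart
#' (325, 10), (325, 0), (-325, 0), (-325, -10)); the EEDR is the ratio
#' exit mean / entrance mean.
#'
#' @param doses a [detector_doses()] set for a beam covering the
#'   entrance/exit sampling diodes.
#' @param array the matching [build_detector_array()].
#' @param gantry_angle beam angle (degrees); the sampling diodes rotate
#'   with the beam axis (the calibration beams are gantry 0).
#' @return object of class `eedr_result`: `entrance_mean`, `exit_mean`,
#'   `eedr`.
#' @export
compute_eedr <- function(doses, array, gantry_angle = 0) {
  stopifnot(inherits(doses, "detector_doses"), inherits(array, "detector_array"))
  sel <- eedr_detectors(array, gantry_angle)
  ent <- doses$dose_Gy[match(sel$entrance, doses$index)]
  ext <- doses$dose_Gy[match(sel$exit, doses$index)]
  if (anyNA(ent) || anyNA(ext)) stop("sampling detector dose missing")
  entrance_mean <- mean(ent)
  if (entrance_mean <= 0) stop("entrance mean dose must be positive")
  structure(list(entrance_mean = entrance_mean, exit_mean = mean(ext),
                 eedr = mean(ext) / entrance_mean,
                 entrance_index = sel$entrance, exit_index = sel$exit),
            class = "eedr_result")
}

#' @export
print.eedr_result <- function(x, ...) {
  cat(sprintf("EEDR %.4f (entrance %.4f Gy, exit %.4f Gy)\n",
              x$eedr, x$entrance_mean, x$exit_mean))
  invisible(x)
}

#' Relative difference between calculated and measured EEDR
#'
#' `100 * (calculated - measured) / measured`, in percent.
#'
#' @param calculated,measured EEDR values (or `eedr_result` objects).
#' @return percent difference.
#' @export
#' @examples
#' eedr_relative_difference(0.3342, 0.3207)  # 4.2
eedr_relative_difference <- function(calculated, measured) {
  if (inherits(calculated, "eedr_result")) calculated <- calculated$eedr
  if (inherits(measured, "eedr_result")) measured <- measured$eedr
  if (measured == 0) stop("measured EEDR must be nonzero")
  100 * (calculated - measured) / measured
}

#' Rescale monitor units by the measured/calculated dose ratio
#'
#' @param measured_mean,calculated_mean mean doses (Gy) at the sampling
#'   diodes.
#' @param mu monitor units of the beam.
#' @return rescaled monitor units `mu * measured_mean / calculated_mean`.
#' @export
rescale_mu <- function(measured_mean, calculated_mean, mu) {
  if (measured_mean <= 0 || calculated_mean <= 0 || mu <= 0) {
    stop("doses and MU must be positive")
  }
  mu * measured_mean / calculated_mean
}

#' Gamma/DTA analysis criteria
#'
#' @param dose_tol dose-difference tolerance in percent (e.g. 2 or 3).
#' @param dta distance-to-agreement (mm), e.g. 2.
#' @param threshold low-dose threshold in percent of the normalization
#'   dose; points below it are excluded (default 10).
#' @param mode `"local"` (tolerance relative to each reference point's
#'   own dose) or `"global"` (relative to one normalization dose,
#'   typically the maximum reference dose).
#' @return object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol, dta, threshold = 10,
                           mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (dose_tol <= 0 || dta <= 0 || threshold <= 0) {
    stop("criteria must be strictly positive")
  }
  structure(list(dose_tol = dose_tol, dta = dta, threshold = threshold,
                 mode = mode), class = "gamma_criteria")
}

# Reference input coercion: data.frame(x, y, dose) in chart mm, or an
# unfolded map.
as_reference_points <- function(reference) {
  if (inherits(reference, "unfolded_map")) {
    data.frame(x = reference$arc_mm, y = reference$axial_mm,
               dose = reference$dose_Gy)
  } else {
    stopifnot(all(c("x", "y", "dose") %in% names(reference)))
    as.data.frame(reference)[, c("x", "y", "dose")]
  }
}

as_dose_map2d <- function(evaluated) {
  if (inherits(evaluated, "dose_map2d")) return(evaluated)
  if (inherits(evaluated, "unfolded_map")) return(unfolded_grid(evaluated))
  stop("evaluated must be a dose_map2d or an unfolded_map")
}

# Disc of search offsets with the given step and radius, including (0, 0).
search_offsets <- function(step, radius) {
  v <- seq(-radius, radius, by = step)
  g <- expand.grid(dx = v, dy = v, KEEP.OUT.ATTRS = FALSE)
  g[g$dx^2 + g$dy^2 <= radius^2 + 1e-12, ]
}

#' Gamma-index analysis
#'
#' For each reference point above the low-dose threshold, the gamma
#' index is the minimum over evaluated positions of
#' `sqrt((distance/dta)^2 + (dose_diff/dose_tol_abs)^2)`, where the
#' evaluated map is interpolated bilinearly on a search grid of step
#' `dta/10` within a radius of `3 * dta` (capping gamma at about 3).
#' In global mode the absolute dose tolerance is `dose_tol%` of the
#' normalization dose; in local mode it is `dose_tol%` of the reference
#' point's own dose.  A point passes when gamma <= 1.
#'
#' The reference is the measured-like point set at the detector chart
#' positions; the evaluated map is the calculated unfolded chart
#' (the plan dose is searched).  The threshold is applied to reference
#' doses relative to the normalization dose in both modes.
#'
#' @param reference `data.frame(x, y, dose)` in chart mm, or an
#'   [unfold()] result.
#' @param evaluated a `dose_map2d` (see [unfolded_grid()]) or an
#'   [unfold()] result.
#' @param criteria a [gamma_criteria()].
#' @param normalization normalization dose (Gy); default max reference dose.
#' @return object of class `gamma_result`: `gamma` (per evaluated
#'   point), `pass`, `pass_rate` (percent), `n_evaluated`, `criteria`.
#' @export
gamma_analysis <- function(reference, evaluated, criteria,
                           normalization = NULL) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  ref <- as_reference_points(reference)
  ev <- as_dose_map2d(evaluated)
  if (is.null(normalization)) normalization <- max(ref$dose)
  if (normalization <= 0) stop("normalization dose must be positive")
  keep <- ref$dose >= criteria$threshold / 100 * normalization
  if (!any(keep)) stop("no reference points above the low-dose threshold")
  ref <- ref[keep, , drop = FALSE]
  off <- search_offsets(criteria$dta / 10, 3 * criteria$dta)
  dist2 <- (off$dx^2 + off$dy^2) / criteria$dta^2
  tol_abs <- if (criteria$mode == "global") {
    rep(criteria$dose_tol / 100 * normalization, nrow(ref))
  } else {
    criteria$dose_tol / 100 * ref$dose
  }
  gamma <- vapply(seq_len(nrow(ref)), function(i) {
    dv <- interp2(ev$x, ev$y, ev$values, ref$x[i] + off$dx, ref$y[i] + off$dy)
    ok <- !is.na(dv)
    if (!any(ok)) return(Inf)
    sqrt(min(dist2[ok] + ((dv[ok] - ref$dose[i]) / tol_abs[i])^2))
  }, 0)
  structure(list(gamma = gamma, pass = gamma <= 1,
                 pass_rate = 100 * mean(gamma <= 1),
                 n_evaluated = nrow(ref), criteria = criteria,
                 normalization = normalization),
            class = "gamma_result")
}

#' Distance-to-agreement analysis
#'
#' A reference point passes when its dose difference at its own location
#' is within the (mode-normalized) dose tolerance, or when the evaluated
#' distribution attains the reference dose somewhere within `dta` mm
#' (detected as a dose crossing on the interpolated search disc).
#'
#' @inheritParams gamma_analysis
#' @return object of class `gamma_result` (with `pass` flags, no gamma
#'   values).
#' @export
dta_analysis <- function(reference, evaluated, criteria,
                         normalization = NULL) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  ref <- as_reference_points(reference)
  ev <- as_dose_map2d(evaluated)
  if (is.null(normalization)) normalization <- max(ref$dose)
  if (normalization <= 0) stop("normalization dose must be positive")
  keep <- ref$dose >= criteria$threshold / 100 * normalization
  if (!any(keep)) stop("no reference points above the low-dose threshold")
  ref <- ref[keep, , drop = FALSE]
  off <- search_offsets(criteria$dta / 10, criteria$dta)
  tol_abs <- if (criteria$mode == "global") {
    rep(criteria$dose_tol / 100 * normalization, nrow(ref))
  } else {
    criteria$dose_tol / 100 * ref$dose
  }
  pass <- vapply(seq_len(nrow(ref)), function(i) {
    own <- interp2(ev$x, ev$y, ev$values, ref$x[i], ref$y[i])
    if (!is.na(own) && abs(own - ref$dose[i]) <= tol_abs[i]) return(TRUE)
    dv <- interp2(ev$x, ev$y, ev$values, ref$x[i] + off$dx, ref$y[i] + off$dy)
    dv <- dv[!is.na(dv)]
    if (length(dv) == 0L) return(FALSE)
    min(dv) <= ref$dose[i] && max(dv) >= ref$dose[i]
  }, TRUE)
  structure(list(gamma = NULL, pass = pass, pass_rate = 100 * mean(pass),
                 n_evaluated = nrow(ref), criteria = criteria,
                 normalization = normalization),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("%s %s %.4g%%/%g mm (TH %g%%): pass rate %.1f%% (n = %d)\n",
              if (is.null(x$gamma)) "DTA" else "gamma",
              x$criteria$mode, x$criteria$dose_tol, x$criteria$dta,
              x$criteria$threshold, x$pass_rate, x$n_evaluated))
  invisible(x)
}
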