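# Virtual phantom assembly: pseudo-CT voxel grid, ring/platform contours,
# and the structure -> RED assignment producing a voxelized RED volume.

#' Pseudo-CT specification
#'
#' Defaults reproduce the published pseudo-CT series: 121 slices of
#' 512 x 512 pixels, 0.97658 mm pixel spacing, 2 mm slice thickness, all
#' CT numbers zero, in-plane grid centered on the axis so the isocenter
#' coincides with the geometric center of the volume.  The first-pixel
#' corner coordinate is therefore -(matrix - 1)/2 x pixel_spacing =
#' -249.51619 mm on both transverse axes.
#'
#' @param n_slices slice count.
#' @param matrix square in-plane matrix size (pixels).
#' @param pixel_spacing in-plane pixel spacing (mm).
#' @param slice_thickness slice pitch (mm).
#' @param fill_value CT number assigned to every voxel.
#' @return An object of class `pseudo_ct_spec`.
#' @export
pseudo_ct_spec <- function(n_slices = 121L, matrix = 512L,
                           pixel_spacing = 0.97658, slice_thickness = 2.0,
                           fill_value = 0L) {
  if (matrix < 2L || pixel_spacing <= 0 || slice_thickness <= 0 || n_slices < 1L) {
    stop("configuration error: invalid pseudo-CT dimensions")
  }
  corner <- -(matrix - 1) / 2 * pixel_spacing
  structure(list(n_slices = as.integer(n_slices), matrix = as.integer(matrix),
                 pixel_spacing = pixel_spacing, slice_thickness = slice_thickness,
                 corner = corner, fill_value = as.integer(fill_value)),
            class = "pseudo_ct_spec")
}

#' Build the pseudo-CT volume
#'
#' All voxels equal the spec's fill value; slices are centered on the
#' isocenter plane, spanning `+-(n_slices - 1)/2 x slice_thickness` mm.
#'
#' @param spec a [pseudo_ct_spec()].
#' @return An object of class `pseudo_ct`: the spec, the voxel-center
#'   coordinate vectors `x`, `y`, `slice_z`, and the constant fill.
#'   Pixel matrices are produced on demand by [ct_slice_matrix()].
#' @export
build_pseudo_ct <- function(spec = pseudo_ct_spec()) {
  stopifnot(inherits(spec, "pseudo_ct_spec"))
  xy <- spec$corner + (seq_len(spec$matrix) - 1) * spec$pixel_spacing
  z <- (seq_len(spec$n_slices) - (spec$n_slices + 1) / 2) * spec$slice_thickness
  structure(list(spec = spec, x = xy, y = xy, slice_z = z),
            class = "pseudo_ct")
}

#' Pixel matrix of one pseudo-CT slice
#' @param ct a [build_pseudo_ct()] result.
#' @param i slice index (1-based).
#' @return integer matrix `matrix x matrix` of CT numbers.
#' @export
ct_slice_matrix <- function(ct, i) {
  stopifnot(inherits(ct, "pseudo_ct"), i >= 1L, i <= ct$spec$n_slices)
  matrix(ct$spec$fill_value, ct$spec$matrix, ct$spec$matrix)
}

#' Build the structure set
#'
#' Each ring becomes one closed circular contour per slice (rings span
#' all phantom slices), sampled at 1 degree (360 vertices).  Platform
#' objects contribute their polygon on every slice inside their
#' configured axial range.
#'
#' @param rings a [ring_structures()] table.
#' @param platform a [platform_objects()] list, or `NULL` for none.
#' @param ct a [build_pseudo_ct()] result supplying the slice grid.
#' @return list of class `structure_set`; each structure has `name`,
#'   `type` ("ring" or "polygon"), geometry (`radius` or `outline`),
#'   `red`, `slice_idx` and `contours` (list of closed n x 2 polygons,
#'   one per slice in `slice_idx`).
#' @export
build_structures <- function(rings = ring_structures(), platform = NULL,
                             ct = build_pseudo_ct()) {
  stopifnot(inherits(rings, "ring_structures"), inherits(ct, "pseudo_ct"))
  half_extent <- min(max(abs(ct$x)), max(abs(ct$y)))
  if (any(rings$outer_radius_mm > half_extent)) {
    stop("ring radius exceeds the pseudo-CT grid extent")
  }
  ang <- (0:359) * pi / 180
  circle <- function(r) {
    p <- cbind(r * cos(ang), r * sin(ang))
    rbind(p, p[1, , drop = FALSE])
  }
  all_slices <- seq_len(ct$spec$n_slices)
  out <- lapply(seq_len(nrow(rings)), function(i) {
    poly <- circle(rings$outer_radius_mm[i])
    list(name = rings$name[i], type = "ring",
         radius = rings$outer_radius_mm[i], red = rings$red[i],
         slice_idx = all_slices,
         contours = rep(list(poly), length(all_slices)))
  })
  if (!is.null(platform)) {
    stopifnot(inherits(platform, "platform_objects"))
    out <- c(out, lapply(platform, function(p) {
      idx <- which(ct$slice_z >= p$z_range[1] & ct$slice_z <= p$z_range[2])
      list(name = p$name, type = "polygon", outline = p$outline, red = p$red,
           z_range = p$z_range, slice_idx = idx,
           contours = rep(list(p$outline), length(idx)))
    }))
  }
  names(out) <- vapply(out, `[[`, "", "name")
  structure(out, class = "structure_set")
}

#' Structure -> RED assignment table
#'
#' Ordered override table; a structure listed later wins where
#' structures overlap (rings are listed outermost first, so the
#' innermost containing ring determines each voxel).
#'
#' @param structures a [build_structures()] result.
#' @param background RED outside every structure (default 0, vacuum-like).
#' @return `data.frame` with `structure`, `red`, `priority`.
#' @export
red_table <- function(structures, background = 0.0) {
  stopifnot(inherits(structures, "structure_set"))
  out <- data.frame(structure = names(structures),
                    red = vapply(structures, `[[`, 0.0, "red"),
                    priority = seq_along(structures), row.names = NULL)
  attr(out, "background") <- background
  out
}

#' Voxelize structures into a RED volume
#'
#' Assigns each voxel the RED of the last-overriding (innermost)
#' structure containing its center; voxel centers exactly on a ring
#' boundary belong to the inner structure.  `mode = "uniform"` instead
#' assigns a single RED throughout the full cylinder (out to the
#' outermost ring radius).
#'
#' @param structures a [build_structures()] result.
#' @param table a [red_table()] (defaults to the structures' own REDs).
#' @param grid a [grid3d()] of voxel centers; defaults to the grid of the
#'   default pseudo-CT.
#' @param mode `"5layer"` (per-structure REDs) or `"uniform"`.
#' @param uniform_red RED used in uniform mode.
#' @return list of class `red_volume` with `grid` and `values`
#'   (3D array, x fastest).
#' @export
voxelize_red <- function(structures, table = red_table(structures),
                         grid = NULL, mode = c("5layer", "uniform"),
                         uniform_red = 1.130) {
  mode <- match.arg(mode)
  stopifnot(inherits(structures, "structure_set"))
  if (is.null(grid)) {
    ct <- build_pseudo_ct()
    grid <- grid3d(ct$x, ct$y, ct$slice_z)
  }
  background <- attr(table, "background")
  if (is.null(background)) background <- 0.0
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  r2 <- outer(grid$x^2, grid$y^2, `+`)           # squared radius, nx x ny
  base <- matrix(background, nx, ny)
  rings <- structures[vapply(structures, `[[`, "", "type") == "ring"]
  if (mode == "uniform") {
    rmax <- max(vapply(rings, `[[`, 0.0, "radius"))
    base[r2 <= rmax^2] <- uniform_red
  } else {
    for (s in rings) {                           # outermost first: inner wins
      base[r2 <= s$radius^2] <- table$red[match(s$name, table$structure)]
    }
  }
  values <- array(base, dim = c(nx, ny, nz))
  polys <- structures[vapply(structures, `[[`, "", "type") == "polygon"]
  if (length(polys) > 0 && mode == "5layer") {
    pxy <- expand.grid(x = grid$x, y = grid$y, KEEP.OUT.ATTRS = FALSE)
    for (s in polys) {
      inside <- point_in_polygon(pxy$x, pxy$y, s$outline)
      if (!any(inside)) next
      red <- table$red[match(s$name, table$structure)]
      zr <- s$z_range
      zidx <- which(grid$z >= zr[1] & grid$z <= zr[2])
      m <- matrix(inside, nx, ny)
      for (k in zidx) {
        slab <- values[, , k]
        slab[m] <- red
        values[, , k] <- slab
      }
    }
  }
  structure(list(grid = grid, values = values, mode = mode,
                 table = table, background = background),
            class = "red_volume")
}

#' RED volume from an explicit array
#'
#' Low-level constructor for a relative-electron-density volume; most
#' code should use [voxelize_red()].
#'
#' @param grid a [grid3d()].
#' @param values 3D RED array matching the grid.
#' @param background RED assumed outside the grid.
#' @return object of class `red_volume`.
#' @export
red_volume <- function(grid, values, background = 0.0) {
  stopifnot(inherits(grid, "grid3d"),
            identical(dim(values), c(length(grid$x), length(grid$y), length(grid$z))))
  structure(list(grid = grid, values = values, mode = "explicit",
                 table = NULL, background = background), class = "red_volume")
}

#' Uniform-RED convenience volume
#'
#' @param red the single RED assigned inside the cylinder.
#' @param grid a [grid3d()]; see [voxelize_red()].
#' @param rings ring table fixing the cylinder outer radius.
#' @return a `red_volume`.
#' @export
uniform_red_volume <- function(red = 1.130, grid = NULL, rings = ring_structures()) {
  ct <- if (is.null(grid)) build_pseudo_ct() else NULL
  if (is.null(grid)) grid <- grid3d(ct$x, ct$y, ct$slice_z)
  structures <- build_structures(rings, platform = NULL,
                                 ct = pseudo_ct_for_grid(grid))
  voxelize_red(structures, grid = grid, mode = "uniform", uniform_red = red)
}

# A pseudo_ct shim whose axes match an arbitrary grid3d (used when
# structures are built for voxelization on a non-default grid).
pseudo_ct_for_grid <- function(grid) {
  spec <- pseudo_ct_spec(n_slices = length(grid$z), matrix = length(grid$x),
                         pixel_spacing = grid$spacing[["dx"]],
                         slice_thickness = grid$spacing[["dz"]])
  structure(list(spec = spec, x = grid$x, y = grid$y, slice_z = grid$z),
            class = "pseudo_ct")
}
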