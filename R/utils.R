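# Shared numeric helpers: regular-grid containers, interpolation,
# point-in-polygon.  All coordinates are millimetres in the phantom frame
# (origin at isocenter, cylinder axis = z, anterior = +y).

#' Regular 3D grid of voxel centers
#'
#' Light container used for RED volumes and dose grids. `x`, `y`, `z` are
#' strictly increasing, evenly spaced voxel-center coordinates in mm.
#'
#' @param x,y,z numeric vectors of voxel-center coordinates (mm).
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(x, y, z) {
  for (v in list(x = x, y = y, z = z)) {
    if (length(v) < 2L || any(diff(v) <= 0)) {
      stop("grid axes must be increasing with at least 2 points")
    }
    if (max(abs(diff(v) - diff(v)[1])) > 1e-9) stop("grid axes must be evenly spaced")
  }
  structure(list(x = x, y = y, z = z,
                 spacing = c(dx = diff(x)[1], dy = diff(y)[1], dz = diff(z)[1])),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
              length(x$x), length(x$y), length(x$z),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# Symmetric grid of n centers at `spacing`, centered on 0.
grid_axis <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Trilinear interpolation on a regular grid
#'
#' @param grid a [grid3d()].
#' @param values 3D array with `dim = c(length(grid$x), length(grid$y), length(grid$z))`.
#' @param pts n x 3 matrix of query points (mm).
#' @param outside what to do outside the grid: `"error"` or a numeric fill value.
#' @return numeric vector of length `nrow(pts)`.
#' @export
interp3 <- function(grid, values, pts, outside = "error") {
  pts <- matrix(as.numeric(pts), ncol = 3)
  nx <- length(grid$x); ny <- length(grid$y); nz <- length(grid$z)
  fx <- (pts[, 1] - grid$x[1]) / grid$spacing[1]
  fy <- (pts[, 2] - grid$y[1]) / grid$spacing[2]
  fz <- (pts[, 3] - grid$z[1]) / grid$spacing[3]
  out <- fx < -1e-9 | fx > nx - 1 + 1e-9 |
         fy < -1e-9 | fy > ny - 1 + 1e-9 |
         fz < -1e-9 | fz > nz - 1 + 1e-9
  if (any(out)) {
    if (identical(outside, "error")) {
      stop(sprintf("%d point(s) outside the grid (first: index %d)",
                   sum(out), which(out)[1]))
    }
  }
  i0 <- pmin(pmax(floor(fx), 0), nx - 2); tx <- pmin(pmax(fx - i0, 0), 1)
  j0 <- pmin(pmax(floor(fy), 0), ny - 2); ty <- pmin(pmax(fy - j0, 0), 1)
  k0 <- pmin(pmax(floor(fz), 0), nz - 2); tz <- pmin(pmax(fz - k0, 0), 1)
  idx <- function(i, j, k) 1 + i + nx * (j + ny * k)
  v <- (1 - tx) * (1 - ty) * (1 - tz) * values[idx(i0,     j0,     k0)] +
       tx       * (1 - ty) * (1 - tz) * values[idx(i0 + 1, j0,     k0)] +
       (1 - tx) * ty       * (1 - tz) * values[idx(i0,     j0 + 1, k0)] +
       tx       * ty       * (1 - tz) * values[idx(i0 + 1, j0 + 1, k0)] +
       (1 - tx) * (1 - ty) * tz       * values[idx(i0,     j0,     k0 + 1)] +
       tx       * (1 - ty) * tz       * values[idx(i0 + 1, j0,     k0 + 1)] +
       (1 - tx) * ty       * tz       * values[idx(i0,     j0 + 1, k0 + 1)] +
       tx       * ty       * tz       * values[idx(i0 + 1, j0 + 1, k0 + 1)]
  if (any(out) && !identical(outside, "error")) v[out] <- as.numeric(outside)
  v
}

# Bilinear interpolation on a regular 2D grid; NA outside.
interp2 <- function(xs, ys, values, px, py) {
  nx <- length(xs); ny <- length(ys)
  fx <- (px - xs[1]) / (xs[2] - xs[1])
  fy <- (py - ys[1]) / (ys[2] - ys[1])
  out <- fx < -1e-9 | fx > nx - 1 + 1e-9 | fy < -1e-9 | fy > ny - 1 + 1e-9
  i0 <- pmin(pmax(floor(fx), 0), nx - 2); tx <- pmin(pmax(fx - i0, 0), 1)
  j0 <- pmin(pmax(floor(fy), 0), ny - 2); ty <- pmin(pmax(fy - j0, 0), 1)
  v <- (1 - tx) * (1 - ty) * values[cbind(i0 + 1, j0 + 1)] +
       tx       * (1 - ty) * values[cbind(i0 + 2, j0 + 1)] +
       (1 - tx) * ty       * values[cbind(i0 + 1, j0 + 2)] +
       tx       * ty       * values[cbind(i0 + 2, j0 + 2)]
  v[out] <- NA_real_
  v
}

# Even-odd point-in-polygon, vectorized over points. poly: n x 2, open or
# closed (a repeated last vertex is ignored). Boundary points count as inside.
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# TRUE when any two non-adjacent edges of the (open) polygon cross.
polygon_self_intersects <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1 else i + 1, ])
  ccw <- function(a, b, c) (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  intersects <- function(p1, p2, p3, p4) {
    ccw(p1, p3, p4) != ccw(p2, p3, p4) && ccw(p1, p2, p3) != ccw(p1, p2, p4)
  }
  for (i in seq_len(n - 2)) {
    for (j in seq((i + 2), n)) {
      if (i == 1 && j == n) next  # adjacent through the wrap
      s1 <- seg(i); s2 <- seg(j)
      if (intersects(s1[1, ], s1[2, ], s2[1, ], s2[2, ])) return(TRUE)
    }
  }
  FALSE
}

# 2D rotation of points (n x 2) about the origin by `deg` degrees,
# positive from +y toward +x (same sense as the gantry angle).
rotate_xy <- function(pts, deg) {
  a <- deg * pi / 180
  cbind(pts[, 1] * cos(a) + pts[, 2] * sin(a),
        -pts[, 1] * sin(a) + pts[, 2] * cos(a))
}
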