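# Fixtures and independent oracles built in code.

# Dose grid from an analytic field f(x, y, z).
make_field_grid <- function(f, x = seq(-130, 130, by = 5),
                            y = x, z = seq(-20, 20, by = 5)) {
  g <- grid3d(x, y, z)
  pts <- expand.grid(x = g$x, y = g$y, z = g$z, KEEP.OUT.ATTRS = FALSE)
  dose_grid(g, array(f(pts$x, pts$y, pts$z),
                     dim = c(length(g$x), length(g$y), length(g$z))))
}

# Coarse grids for engine work (2 mm spacing fits the 0.5 mm march).
coarse_grid <- function(z_half = 10) engine_grid(spacing = 2, z_half = z_half)

# 5-layer RED volume on a coarse grid, optionally with modified ring REDs
# or platform objects.
coarse_phantom <- function(rings = ring_structures(), platform = NULL,
                           grid = coarse_grid(), mode = "5layer",
                           uniform_red = 1.130) {
  structures <- build_structures(rings, platform, arcqa:::pseudo_ct_for_grid(grid))
  voxelize_red(structures, grid = grid, mode = mode, uniform_red = uniform_red)
}

# RED volume that is `red` absolutely everywhere (background included):
# radiological depth through it is exactly length x red.
everywhere_volume <- function(red, grid = coarse_grid()) {
  red_volume(grid, array(red, dim = c(length(grid$x), length(grid$y),
                                      length(grid$z))),
             background = red)
}

# Exact chord length of the segment p1 -> p2 inside the infinite cylinder
# x^2 + y^2 <= r^2 (axis along z).
cylinder_chord <- function(p1, p2, r) {
  d <- p2 - p1
  a <- d[1]^2 + d[2]^2
  b <- 2 * (p1[1] * d[1] + p1[2] * d[2])
  cc <- p1[1]^2 + p1[2]^2 - r^2
  disc <- b^2 - 4 * a * cc
  if (a < 1e-15 || disc <= 0) return(0)
  t1 <- (-b - sqrt(disc)) / (2 * a); t2 <- (-b + sqrt(disc)) / (2 * a)
  lo <- max(min(t1, t2), 0); hi <- min(max(t1, t2), 1)
  if (hi <= lo) return(0)
  (hi - lo) * sqrt(sum(d^2))
}

# Analytic water-equivalent depth through the 5-ring phantom: sum over
# annuli of chord x RED (rings modelled as infinite cylinders).
analytic_weq <- function(p1, p2, rings = ring_structures()) {
  radii <- c(rings$outer_radius_mm, 0)
  sum(vapply(seq_len(nrow(rings)), function(i) {
    (cylinder_chord(p1, p2, radii[i]) - cylinder_chord(p1, p2, radii[i + 1])) *
      rings$red[i]
  }, 0))
}

# Naive scalar bilinear interpolation (independent of the package's).
naive_interp2 <- function(xs, ys, m, px, py) {
  if (px < xs[1] || px > xs[length(xs)] || py < ys[1] || py > ys[length(ys)]) {
    return(NA_real_)
  }
  i <- min(max(findInterval(px, xs), 1), length(xs) - 1)
  j <- min(max(findInterval(py, ys), 1), length(ys) - 1)
  tx <- (px - xs[i]) / (xs[i + 1] - xs[i])
  ty <- (py - ys[j]) / (ys[j + 1] - ys[j])
  (1 - tx) * (1 - ty) * m[i, j] + tx * (1 - ty) * m[i + 1, j] +
    (1 - tx) * ty * m[i, j + 1] + tx * ty * m[i + 1, j + 1]
}

# Brute-force gamma oracle: plain double loop over the search disc with
# naive interpolation; same search semantics as the specification
# (step dta/10, radius 3 x dta, threshold on reference dose).
oracle_gamma <- function(ref, ev, criteria, normalization = max(ref$dose)) {
  keep <- ref$dose >= criteria$threshold / 100 * normalization
  ref <- ref[keep, , drop = FALSE]
  step <- criteria$dta / 10; radius <- 3 * criteria$dta
  offs <- seq(-radius, radius, by = step)
  gam <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    tol <- if (criteria$mode == "global") {
      criteria$dose_tol / 100 * normalization
    } else {
      criteria$dose_tol / 100 * ref$dose[i]
    }
    best <- Inf
    for (dx in offs) for (dy in offs) {
      if (dx^2 + dy^2 > radius^2 + 1e-12) next
      dv <- naive_interp2(ev$x, ev$y, ev$values, ref$x[i] + dx, ref$y[i] + dy)
      if (is.na(dv)) next
      g2 <- (dx^2 + dy^2) / criteria$dta^2 + ((dv - ref$dose[i]) / tol)^2
      if (g2 < best) best <- g2
    }
    gam[i] <- sqrt(best)
  }
  list(gamma = gam, pass_rate = 100 * mean(gam <= 1), n_evaluated = nrow(ref))
}

# Brute-force DTA oracle with the same crossing semantics.
oracle_dta <- function(ref, ev, criteria, normalization = max(ref$dose)) {
  keep <- ref$dose >= criteria$threshold / 100 * normalization
  ref <- ref[keep, , drop = FALSE]
  step <- criteria$dta / 10
  offs <- seq(-criteria$dta, criteria$dta, by = step)
  pass <- logical(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    tol <- if (criteria$mode == "global") {
      criteria$dose_tol / 100 * normalization
    } else {
      criteria$dose_tol / 100 * ref$dose[i]
    }
    own <- naive_interp2(ev$x, ev$y, ev$values, ref$x[i], ref$y[i])
    if (!is.na(own) && abs(own - ref$dose[i]) <= tol) { pass[i] <- TRUE; next }
    vals <- c()
    for (dx in offs) for (dy in offs) {
      if (dx^2 + dy^2 > criteria$dta^2 + 1e-12) next
      dv <- naive_interp2(ev$x, ev$y, ev$values, ref$x[i] + dx, ref$y[i] + dy)
      if (!is.na(dv)) vals <- c(vals, dv)
    }
    pass[i] <- length(vals) > 0 && min(vals) <= ref$dose[i] && max(vals) >= ref$dose[i]
  }
  list(pass = pass, pass_rate = 100 * mean(pass), n_evaluated = nrow(ref))
}

# 2D dose map from an analytic chart field f(arc, axial).
make_map2d <- function(f, xs = seq(-24, 24, by = 2), ys = xs) {
  structure(list(x = xs, y = ys, values = outer(xs, ys, f)),
            class = "dose_map2d")
}
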