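# Independent brute-force oracles and small fixture builders.
# These deliberately use different formulations than the package internals
# (atan2 instead of acos, per-point crossing tests instead of scanline,
# dense angle sweeps instead of rotating calipers).

# exact rectangle corners from center, long-axis angle (radians, from +x),
# long and short extents; returned unordered
rect_corners <- function(center, theta, long, short) {
  u <- c(cos(theta), sin(theta))
  n <- c(-sin(theta), cos(theta))
  rbind(center + long / 2 * u + short / 2 * n,
        center + long / 2 * u - short / 2 * n,
        center - long / 2 * u - short / 2 * n,
        center - long / 2 * u + short / 2 * n)
}

# a fresh 3-point segment model from exact corners (bypasses rasterization)
model_from_corners <- function(corners, id = 1L) {
  rect <- order_corners(corners)
  models <- list(structure(list(
    id = id, V = axis_points(rect),
    W_top = rect$corners[1:2, , drop = FALSE],
    W_end = rect$corners[3:4, , drop = FALSE],
    members = list(list(id = id, kind = "segment", rect = rect)),
    top_fork = NULL, end_fork = NULL), class = "branch_segment"))
  models[[1]]
}

# vertical-ish segment model centered at `center` with long axis rotated
# `phi` radians from straight down (y+)
vertical_model <- function(center, long = 30, short = 10, phi = 0, id = 1L) {
  model_from_corners(rect_corners(center, pi / 2 + phi, long, short), id)
}

# independent point-in-polygon: per-point even-odd crossing count with
# an explicit on-boundary test
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    # boundary
    d <- b - a
    L2 <- sum(d^2)
    if (L2 > 0) {
      t <- ((px - a[1]) * d[1] + (py - a[2]) * d[2]) / L2
      if (t >= -1e-9 && t <= 1 + 1e-9) {
        cx <- a[1] + t * d[1]; cy <- a[2] + t * d[2]
        if ((px - cx)^2 + (py - cy)^2 < 1e-14) return(TRUE)
      }
    }
    if ((a[2] > py) != (b[2] > py)) {
      xint <- a[1] + (py - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# rasterization-based IoU of two rectangles on a sub-pixel grid
raster_rect_iou <- function(ca, cb, res = 250) {
  allp <- rbind(ca, cb)
  xr <- range(allp[, 1]); yr <- range(allp[, 2])
  xs <- seq(xr[1] - 0.5, xr[2] + 0.5, length.out = res)
  ys <- seq(yr[1] - 0.5, yr[2] + 0.5, length.out = res)
  ina <- outer(xs, ys, Vectorize(function(x, y) pip_oracle(x, y, ca)))
  inb <- outer(xs, ys, Vectorize(function(x, y) pip_oracle(x, y, cb)))
  u <- sum(ina | inb)
  if (u == 0) return(0)
  sum(ina & inb) / u
}

# independent sector membership from the raw definition, using atan2
sector_oracle <- function(apex, ray, full_angle_deg, depth, px, py) {
  dx <- px - apex[1]; dy <- py - apex[2]
  r <- sqrt(dx^2 + dy^2)
  if (r == 0) return(TRUE)
  if (r > depth) return(FALSE)
  a1 <- atan2(dy, dx); a2 <- atan2(ray[2], ray[1])
  d <- abs(a1 - a2) %% (2 * pi)
  if (d > pi) d <- 2 * pi - d
  d * 180 / pi <= full_angle_deg / 2
}

# minimum-area enclosing rectangle by dense angle sweep (independent of
# the rotating-calipers path)
sweep_min_area <- function(pts, step_deg = 0.05) {
  best <- Inf
  for (th in seq(0, 90 - step_deg, by = step_deg) * pi / 180) {
    u <- c(cos(th), sin(th)); w <- c(-sin(th), cos(th))
    pu <- pts %*% u; pw <- pts %*% w
    a <- (max(pu) - min(pu)) * (max(pw) - min(pw))
    if (a < best) best <- a
  }
  best
}

# rasterize an exact rectangle (given center/angle/dims) into a mask
rect_mask <- function(image_size, center, theta, long, short) {
  rasterize_polygon(rect_corners(center, theta, long, short), image_size)
}

# small clean scene spec used across tests (3 branches keeps runtime low)
small_spec <- function(seed, ...) {
  scene_spec(image_size = c(420, 420), n_branches = 3, seed = seed, ...)
}

eval_scene <- function(scene, ...) {
  fit <- suppressMessages(reconstruct_branches(scene$instances, ...))
  gt <- scene$truth$branches
  evaluate_reconstruction(fit$chains, lapply(gt, `[[`, "mask"),
                          vapply(gt, `[[`, "diameter", FUN.VALUE = 1))
}
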