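# Planar geometry for oriented bounding rectangles and sector search regions.
#
# All geometry lives in the raster frame: 0-based coordinates, x to the
# right, y down, pixel centers at integer coordinates. Points are length-2
# numeric vectors c(x, y); point sets are n x 2 matrices.

.vlen <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .vlen(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

#' Angle between two vectors, in degrees
#'
#' Computes the unsigned angle between two non-zero planar vectors as the
#' arccosine of their normalized dot product, clamped to \[-1, 1\] before
#' taking the arccosine so floating error can never produce NaN.
#'
#' @param u,v Numeric vectors of length 2 (x, y); both must be non-zero.
#' @return Angle in degrees, in \[0, 180\].
#' @examples
#' angle_between(c(1, 0), c(0, 1))  # 90
#' angle_between(c(1, 0), c(-1, 0)) # 180
#' @export
angle_between <- function(u, v) {
  nu <- .vlen(u)
  nv <- .vlen(v)
  if (nu < .Machine$double.eps || nv < .Machine$double.eps)
    stop("angle_between() requires non-zero vectors")
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

# Shoelace area of a polygon given as an n x 2 matrix (absolute value).
.poly_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman: clip convex polygon `subj` by the half-plane to the
# left of directed edge a->b (for a counter-clockwise-in-math-coords clip
# polygon traversal this keeps the interior).
.clip_halfplane <- function(subj, a, b) {
  if (nrow(subj) == 0) return(subj)
  ex <- b[1] - a[1]; ey <- b[2] - a[2]
  side <- function(p) ex * (p[2] - a[2]) - ey * (p[1] - a[1])
  out <- matrix(numeric(0), ncol = 2)
  n <- nrow(subj)
  for (i in seq_len(n)) {
    cur <- subj[i, ]
    prv <- subj[if (i == 1) n else i - 1, ]
    sc <- side(cur); sp <- side(prv)
    if (sc <= 0) {               # inside (right of or on edge, image coords)
      if (sp > 0) {              # entering: add intersection
        t <- sp / (sp - sc)
        out <- rbind(out, prv + t * (cur - prv))
      }
      out <- rbind(out, cur)
    } else if (sp <= 0) {        # leaving: add intersection
      t <- sp / (sp - sc)
      out <- rbind(out, prv + t * (cur - prv))
    }
  }
  out
}

# Area of intersection of two convex polygons (n x 2 matrices, any winding).
.convex_intersection_area <- function(a, b) {
  # orient the clip polygon so that interior points have cross(b-a, p-a) <= 0
  x <- b[, 1]; y <- b[, 2]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (s > 0) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  out <- a
  n <- nrow(b)
  for (i in seq_len(n)) {
    out <- .clip_halfplane(out, b[i, ], b[if (i == n) 1 else i + 1, ])
    if (nrow(out) == 0) return(0)
  }
  .poly_area(out)
}

.new_rect <- function(corners) {
  v1 <- (corners[1, ] + corners[2, ]) / 2
  v3 <- (corners[3, ] + corners[4, ]) / 2
  structure(list(
    corners   = corners,
    center    = colMeans(corners),
    long_len  = .vlen(v3 - v1),
    short_len = .vlen(corners[2, ] - corners[1, ]),
    long_axis_dir = if (.vlen(v3 - v1) > .Machine$double.eps)
      .unit(v3 - v1) else c(0, 1)
  ), class = "oriented_rect")
}

#' Normalize the corner order of an oriented rectangle
#'
#' Orders the four corners clockwise (in image coordinates, y down) starting
#' from the "top" short edge, so that corners 1-2 span the top edge and
#' corners 3-4 the end edge. The top short edge is the one whose midpoint has
#' the smaller y; when the midpoints tie on y (an exactly horizontal
#' rectangle) the smaller x wins, so the top of a horizontal branch is its
#' left end. Idempotent.
#'
#' @param corners A 4 x 2 matrix of corner coordinates in any order, or an
#'   `oriented_rect`.
#' @return An `oriented_rect` with fields `corners` (ordered 4 x 2 matrix),
#'   `center`, `long_len`, `short_len`, `long_axis_dir` (unit vector from the
#'   top edge midpoint toward the end edge midpoint).
#' @export
order_corners <- function(corners) {
  if (inherits(corners, "oriented_rect")) corners <- corners$corners
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) == 4, ncol(corners) == 2)
  ctr <- colMeans(corners)
  ang <- atan2(corners[, 2] - ctr[2], corners[, 1] - ctr[1])
  cyc <- corners[order(ang), , drop = FALSE]  # visually clockwise (y down)

  elen <- sapply(1:4, function(i) .vlen(cyc[if (i == 4) 1 else i + 1, ] - cyc[i, ]))
  # opposite-edge pairs (1,3) and (2,4); the short pair carries the top edge
  pick_top <- function(pair) {
    mids <- lapply(pair, function(i) (cyc[i, ] + cyc[if (i == 4) 1 else i + 1, ]) / 2)
    o <- order(sapply(mids, `[`, 2), sapply(mids, `[`, 1))
    pair[o[1]]
  }
  l13 <- (elen[1] + elen[3]) / 2
  l24 <- (elen[2] + elen[4]) / 2
  if (abs(l13 - l24) <= 1e-9 * max(l13, l24, 1)) {
    # square: choose whichever candidate top edge sits higher / more left
    cand <- c(pick_top(c(1, 3)), pick_top(c(2, 4)))
    mids <- lapply(cand, function(i) (cyc[i, ] + cyc[if (i == 4) 1 else i + 1, ]) / 2)
    top <- cand[order(sapply(mids, `[`, 2), sapply(mids, `[`, 1))[1]]
  } else {
    top <- pick_top(if (l13 < l24) c(1, 3) else c(2, 4))
  }
  idx <- ((top - 1 + 0:3) %% 4) + 1
  .new_rect(cyc[idx, , drop = FALSE])
}

#' Minimum-area oriented bounding rectangle of a mask
#'
#' Computes the smallest-area rotated rectangle enclosing all foreground
#' pixel centers of a binary mask, by rotating calipers over the convex hull:
#' the optimal rectangle has one side collinear with a hull edge, so only
#' hull-edge orientations need be examined. Corners are returned in the
#' normalized order of [order_corners()] and may have sub-pixel coordinates.
#'
#' Degenerate masks (a single pixel, or collinear pixels) yield a rectangle
#' with zero short (and possibly long) extent; downstream consumers filter
#' these by aspect ratio.
#'
#' @param mask A logical or 0/1 numeric matrix; rows are y (down), columns x.
#'   Must contain at least one foreground pixel.
#' @return An `oriented_rect`; see [order_corners()].
#' @export
min_area_rect <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("min_area_rect() requires a non-empty mask")
  pts <- cbind(x = idx[, "col"] - 1, y = idx[, "row"] - 1)
  min_area_rect_points(pts)
}

#' @rdname min_area_rect
#' @param pts An n x 2 matrix of (x, y) points (used directly, bypassing the
#'   raster).
#' @export
min_area_rect_points <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) == 1) {
    return(order_corners(matrix(rep(pts[1, ], 4), ncol = 2, byrow = TRUE)))
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh == 2) {
    # collinear input: zero-width rectangle along the two extreme points
    a <- hull[1, ]; b <- hull[2, ]
    return(order_corners(rbind(a, a, b, b)))
  }
  best <- NULL
  best_area <- Inf
  for (i in seq_len(nh)) {
    e <- hull[if (i == nh) 1 else i + 1, ] - hull[i, ]
    len <- .vlen(e)
    if (len < 1e-12) next
    u <- e / len                 # edge direction
    w <- c(-u[2], u[1])          # normal
    pu <- hull %*% u
    pw <- hull %*% w
    area <- (max(pu) - min(pu)) * (max(pw) - min(pw))
    if (area < best_area - 1e-12) {
      best_area <- area
      best <- list(u = u, w = w, u0 = min(pu), u1 = max(pu),
                   w0 = min(pw), w1 = max(pw))
    }
  }
  corners <- with(best, rbind(
    u0 * u + w0 * w,
    u1 * u + w0 * w,
    u1 * u + w1 * w,
    u0 * u + w1 * w
  ))
  order_corners(corners)
}

#' Long-axis points of an oriented rectangle
#'
#' Returns the three points of the long median axis: the top edge midpoint,
#' the center, and the end edge midpoint. These seed the three-point branch
#' segment model.
#'
#' @param rect An `oriented_rect` (ordered; see [order_corners()]).
#' @return A 3 x 2 matrix with rows v1 (top), v2 (center), v3 (end).
#' @export
axis_points <- function(rect) {
  w <- rect$corners
  rbind((w[1, ] + w[2, ]) / 2, rect$center, (w[3, ] + w[4, ]) / 2)
}

#' Intersection-over-union of two oriented rectangles
#'
#' Exact polygon intersection area over union area, via convex clipping.
#' A zero-area rectangle gives IoU 0 by convention.
#'
#' @param a,b `oriented_rect` objects or 4 x 2 corner matrices.
#' @return IoU in \[0, 1\].
#' @export
rect_iou <- function(a, b) {
  ca <- if (inherits(a, "oriented_rect")) a$corners else as.matrix(a)
  cb <- if (inherits(b, "oriented_rect")) b$corners else as.matrix(b)
  aa <- .poly_area(ca)
  ab <- .poly_area(cb)
  if (aa <= 0 || ab <= 0) return(0)
  inter <- .convex_intersection_area(ca, cb)
  inter / (aa + ab - inter)
}

#' Build a sector search region for one side of a branch model
#'
#' The sector that bounds the search for candidate fragments beyond one
#' terminal of a branch chain. For the top side the apex is the second axis
#' point v2, the boundary rays run to the top corners w1 and w2, and the
#' center ray points from v2 through the terminal v1. For the end side the
#' apex is v(n-1), the rays run to the end corners w3 and w4, and the center
#' ray points from v(n-1) through vn. The sector depth is `factor` times the
#' local axis window: dis_top = |v1 - v3|, dis_end = |v(n-2) - vn|, so deeper
#' chains search proportionally further. For a fresh three-point model both
#' windows equal the whole axis length.
#'
#' @param model A branch segment model (list with `V`, `W_top`, `W_end`; see
#'   [build_models()]), or anything with those fields.
#' @param side `"top"` or `"end"`.
#' @param factor Depth multiplier: 3 when searching for segment candidates,
#'   1.6 for fork candidates, 5 in the relaxed secondary pass.
#' @return A `sector_spec` list: `apex`, `center_ray` (unit), `full_angle`
#'   (degrees), `depth` (px), `dis` (the axis window length).
#' @export
sector_for <- function(model, side = c("top", "end"), factor = 3) {
  side <- match.arg(side)
  V <- model$V
  n <- nrow(V)
  if (is.null(n) || n < 3) stop("sector_for() needs a chain with >= 3 axis points")
  if (side == "top") {
    apex <- V[2, ]
    w <- model$W_top
    term <- V[1, ]
    dis <- .vlen(V[1, ] - V[3, ])
  } else {
    apex <- V[n - 1, ]
    w <- model$W_end
    term <- V[n, ]
    dis <- .vlen(V[n - 2, ] - V[n, ])
  }
  structure(list(
    apex = apex,
    center_ray = .unit(term - apex),
    full_angle = angle_between(w[1, ] - apex, w[2, ] - apex),
    depth = factor * dis,
    dis = dis
  ), class = "sector_spec")
}

#' Test whether a point lies inside a sector search region
#'
#' A point is inside when its offset angle from the center ray is at most
#' half the sector's full angle and its distance from the apex is at most the
#' sector depth; both comparisons are inclusive, with a 1e-9 floating
#' tolerance. A point coincident with the apex is inside (zero distance,
#' undefined angle).
#'
#' @param spec A `sector_spec` from [sector_for()].
#' @param p Point c(x, y).
#' @param half_angle_scale Multiplier on the half angle: 1 for the primary
#'   search (offset <= S/2), 2 for the relaxed secondary search (offset <= S).
#' @return Logical.
#' @export
in_sector <- function(spec, p, half_angle_scale = 1) {
  d <- p - spec$apex
  r <- .vlen(d)
  if (r <= 1e-9) return(TRUE)
  if (r > spec$depth + 1e-9) return(FALSE)
  ang <- angle_between(d, spec$center_ray)
  ang <= half_angle_scale * spec$full_angle / 2 + 1e-7
}
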