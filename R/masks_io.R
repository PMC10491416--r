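# Reading instance masks and writing reconstruction results.
#
# Two input dialects are supported: a directory of per-instance binary PNG
# masks with a YAML/JSON manifest mapping filename -> category, and a single
# COCO-style polygon JSON listing closed polygons with a "category" key.
# Categories are "segmented" (a branch fragment) and "forked" (a
# bifurcation instance).

.LABELS <- c("segmented", "forked")

#' Construct an instance set
#'
#' Container for all detected instances of one scene: binary masks, class
#' labels and unique integer ids on a common canvas.
#'
#' @param image_size c(height, width) in pixels.
#' @param instances List of instances, each a list with `mask` (logical
#'   matrix of dim image_size), `label` ("segmented" or "forked") and `id`
#'   (integer, unique).
#' @return An `instance_set`.
#' @export
instance_set <- function(image_size, instances) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2, all(image_size > 0))
  ids <- vapply(instances, function(i) as.integer(i$id), integer(1))
  if (anyDuplicated(ids)) stop("instance ids must be unique")
  for (inst in instances) {
    if (!all(dim(inst$mask) == image_size))
      stop("instance ", inst$id, ": mask dimensions differ from image_size")
    if (!any(inst$mask)) stop("instance ", inst$id, ": empty mask")
    if (!inst$label %in% .LABELS)
      stop("instance ", inst$id, ": unknown label '", inst$label, "'")
  }
  structure(list(image_size = image_size, instances = instances),
            class = "instance_set")
}

#' @export
print.instance_set <- function(x, ...) {
  labs <- vapply(x$instances, `[[`, character(1), "label")
  cat(sprintf("<instance_set> %d x %d px, %d instances (%d segmented, %d forked)\n",
              x$image_size[1], x$image_size[2], length(x$instances),
              sum(labs == "segmented"), sum(labs == "forked")))
  invisible(x)
}

#' Rasterize a closed polygon onto a canvas
#'
#' Even-odd fill evaluated at 0-based pixel centers: a pixel is foreground
#' when its center is strictly inside the polygon by even-odd crossing
#' counting, or lies exactly on the boundary (inclusive fill).
#'
#' @param poly An n x 2 matrix of (x, y) vertices, or a flat COCO-style
#'   vector x1,y1,x2,y2,...
#' @param image_size c(height, width).
#' @return Logical matrix of dim image_size.
#' @export
rasterize_polygon <- function(poly, image_size) {
  if (is.null(dim(poly))) poly <- matrix(poly, ncol = 2, byrow = TRUE)
  h <- image_size[1]; w <- image_size[2]
  out <- matrix(FALSE, h, w)
  xs <- poly[, 1]; ys <- poly[, 2]
  x0 <- max(0L, floor(min(xs))); x1 <- min(w - 1L, ceiling(max(xs)))
  y0 <- max(0L, floor(min(ys))); y1 <- min(h - 1L, ceiling(max(ys)))
  if (x0 > x1 || y0 > y1) return(out)
  px <- rep(x0:x1, times = y1 - y0 + 1)
  py <- rep(y0:y1, each = x1 - x0 + 1)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  n <- nrow(poly)
  eps <- 1e-9
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    # even-odd ray crossing (ray toward +x)
    cross <- ((a[2] > py) != (b[2] > py))
    if (any(cross)) {
      xint <- (b[1] - a[1]) * (py - a[2]) / (b[2] - a[2]) + a[1]
      inside <- xor(inside, cross & (px < xint))
    }
    # boundary inclusion: point on segment a-b
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    len2 <- dx * dx + dy * dy
    if (len2 < eps) {
      onedge <- onedge | (abs(px - a[1]) < eps & abs(py - a[2]) < eps)
    } else {
      t <- ((px - a[1]) * dx + (py - a[2]) * dy) / len2
      perp <- abs((px - a[1]) * dy - (py - a[2]) * dx) / sqrt(len2)
      onedge <- onedge | (perp < 1e-7 & t >= -eps & t <= 1 + eps)
    }
  }
  keep <- inside | onedge
  out[cbind(py[keep] + 1L, px[keep] + 1L)] <- TRUE
  out
}

.read_manifest <- function(dir) {
  for (f in c("manifest.yaml", "manifest.yml", "manifest.json")) {
    p <- file.path(dir, f)
    if (file.exists(p)) {
      m <- if (grepl("json$", f)) jsonlite::read_json(p, simplifyVector = TRUE)
           else yaml::read_yaml(p)
      return(m)
    }
  }
  stop("no manifest (manifest.yaml/.yml/.json) found in ", dir)
}

#' Load an instance set from disk
#'
#' @param path Directory (for `format = "png_dir"`) or JSON file (for
#'   `format = "polygon_json"`).
#' @param format `"png_dir"`: a directory of per-instance binary PNG masks
#'   plus a manifest mapping each filename to its category; every PNG in the
#'   directory must have a manifest entry. `"polygon_json"`: a single JSON
#'   document with `image_size` \[height, width\] and `instances`, each with
#'   `id`, `category` and a flat COCO-style `polygon` x1,y1,x2,y2,...
#'   Polygons are rasterized with [rasterize_polygon()].
#'
#' Instances whose mask has no foreground pixel are dropped with a warning.
#'
#' @return An `instance_set`.
#' @export
load_instances <- function(path, format = c("png_dir", "polygon_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "png_dir") {
    manifest <- .read_manifest(path)
    files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE))
    if (length(files) == 0) stop("no PNG masks found in ", path)
    instances <- list()
    size <- NULL
    for (k in seq_along(files)) {
      f <- files[k]
      if (is.null(manifest[[f]]))
        stop("manifest has no entry for mask file '", f, "'")
      img <- png::readPNG(file.path(path, f))
      if (length(dim(img)) == 3) img <- img[, , 1]
      mask <- img > 0.5
      if (is.null(size)) size <- dim(mask)
      if (!all(dim(mask) == size))
        stop("mask '", f, "' has dimensions ", paste(dim(mask), collapse = "x"),
             ", expected ", paste(size, collapse = "x"))
      if (!any(mask)) {
        warning("dropping instance '", f, "': empty mask")
        next
      }
      instances[[length(instances) + 1]] <-
        list(mask = mask, label = as.character(manifest[[f]]), id = k)
    }
    instance_set(size, instances)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    size <- as.integer(doc$image_size)
    recs <- doc$instances
    instances <- list()
    for (k in seq_len(if (is.data.frame(recs)) nrow(recs) else length(recs))) {
      rec <- if (is.data.frame(recs)) lapply(recs, function(col) col[[k]])
             else recs[[k]]
      mask <- rasterize_polygon(unlist(rec$polygon), size)
      if (!any(mask)) {
        warning("dropping instance ", rec$id, ": polygon rasterizes to an empty mask")
        next
      }
      instances[[length(instances) + 1]] <-
        list(mask = mask, label = as.character(rec$category),
             id = as.integer(rec$id))
    }
    instance_set(size, instances)
  }
}

#' Save an instance set to disk
#'
#' Inverse of [load_instances()]. For `png_dir`, one binary PNG per instance
#' plus `manifest.yaml`; for `polygon_json`, instances must carry a `polygon`
#' field (as those from [generate_scene()] do).
#'
#' @param x An `instance_set`.
#' @inheritParams load_instances
#' @return `path`, invisibly.
#' @export
save_instances <- function(x, path, format = c("png_dir", "polygon_json")) {
  format <- match.arg(format)
  if (format == "png_dir") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    manifest <- list()
    for (inst in x$instances) {
      f <- sprintf("instance_%04d.png", inst$id)
      png::writePNG(inst$mask * 1, file.path(path, f))
      manifest[[f]] <- inst$label
    }
    yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  } else {
    recs <- lapply(x$instances, function(inst) {
      if (is.null(inst$polygon))
        stop("instance ", inst$id, " has no polygon outline; use format='png_dir'")
      list(id = inst$id, category = inst$label,
           polygon = as.vector(t(inst$polygon)))
    })
    jsonlite::write_json(list(image_size = x$image_size, instances = recs),
                         path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' Save reconstructed branch chains as scene JSON
#'
#' One JSON document per scene: for each chain its id, member instance ids in
#' top-to-end axis order, the merged long-axis polyline and the estimated
#' diameter in pixels. Coordinates are written at full precision so a
#' save/load round trip is exact.
#'
#' @param chains List of `branch_chain` objects (see [reconstruct_scene()]).
#' @param path Output JSON path.
#' @param image_size c(height, width); recorded in the document.
#' @return `path`, invisibly.
#' @export
save_chains <- function(chains, path, image_size = NULL) {
  recs <- lapply(chains, function(ch) list(
    id = ch$id,
    member_ids = vapply(ch$members, function(m) as.integer(m$id), integer(1)),
    member_kinds = vapply(ch$members, function(m) m$kind, character(1)),
    axis = unname(apply(ch$V, 1, function(r) c(r[1], r[2]), simplify = FALSE)),
    diameter_px = ch$diameter
  ))
  doc <- list(image_size = image_size, chains = recs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load chains written by [save_chains()]
#'
#' @param path Scene JSON path.
#' @return List with `image_size` and `chains`; each chain has `id`,
#'   `member_ids`, `member_kinds`, `V` (axis matrix) and `diameter`.
#' @export
load_chains <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  chains <- lapply(doc$chains, function(rec) {
    V <- do.call(rbind, lapply(rec$axis, function(p) c(p[[1]], p[[2]])))
    list(id = rec$id,
         member_ids = vapply(rec$member_ids, as.integer, integer(1)),
         member_kinds = vapply(rec$member_kinds, as.character, character(1)),
         V = V,
         diameter = rec$diameter_px)
  })
  list(image_size = if (is.null(doc$image_size)) NULL
                    else as.integer(unlist(doc$image_size)),
       chains = chains)
}

#' Render a color overlay of reconstructed chains
#'
#' Paints each chain's mask in a distinct hue on a black canvas, the usual
#' way reconstruction results are visualised.
#'
#' @param chains List of `branch_chain` objects with rendered masks.
#' @param image_size c(height, width).
#' @return An height x width x 3 numeric array in \[0, 1\].
#' @export
render_overlay <- function(chains, image_size) {
  h <- image_size[1]; w <- image_size[2]
  img <- array(0, dim = c(h, w, 3))
  if (length(chains) == 0) return(img)
  cols <- grDevices::hcl(h = seq(15, 375, length.out = length(chains) + 1)[-1],
                         c = 100, l = 60)
  for (i in seq_along(chains)) {
    rgb <- grDevices::col2rgb(cols[i]) / 255
    m <- chains[[i]]$mask
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- rgb[ch]
      img[, , ch] <- plane
    }
  }
  img
}
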