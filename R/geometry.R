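#' Create a region-of-interest polygon
#'
#' A ROI is a simple closed polygon given by its ordered vertices (the first
#' vertex is not repeated at the end). Coordinates are in whatever frame the
#' caller works in: nanometres for localization analysis, 0-based pixel
#' coordinates (origin top-left) for image analysis.
#'
#' @param x,y Numeric vertex coordinates (length >= 3).
#' @param compartment Compartment tag, one of `"bouton"`, `"dendrite"`,
#'   `"other"`.
#' @param cell_id Optional cell identifier.
#' @param id Optional ROI identifier; defaults to `"roi"`.
#' @return An object of class `nq_roi`: a list with a two-column `vertices`
#'   matrix plus the tags.
#' @export
#' @examples
#' r <- roi(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000), compartment = "bouton")
#' polygon_area(r)
roi <- function(x, y, compartment = c("other", "bouton", "dendrite"),
                cell_id = NA_character_, id = "roi") {
  compartment <- match.arg(compartment)
  if (length(x) != length(y) || length(x) < 3L) {
    abort("A ROI polygon needs at least 3 (x, y) vertices.")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("ROI vertices must be finite.")
  v <- cbind(x = as.numeric(x), y = as.numeric(y))
  out <- structure(
    list(vertices = v, compartment = compartment,
         cell_id = cell_id, id = id),
    class = "nq_roi"
  )
  if (polygon_area(out) <= 0) abort("ROI polygon is degenerate (zero area).")
  out
}

#' @export
print.nq_roi <- function(x, ...) {
  cat(sprintf("<nq_roi '%s'> %d vertices, compartment=%s, area=%.4g\n",
              x$id, nrow(x$vertices), x$compartment, polygon_area(x)))
  invisible(x)
}

roi_vertices <- function(roi) {
  if (inherits(roi, "nq_roi")) return(roi$vertices)
  if (is.matrix(roi) && ncol(roi) >= 2) return(roi[, 1:2, drop = FALSE])
  if (is.data.frame(roi)) return(cbind(roi$x, roi$y))
  abort("Expected an `nq_roi`, a two-column matrix, or a data frame with x/y.")
}

#' Polygon area by the shoelace formula
#'
#' @param poly An [roi()] object, two-column matrix, or data frame with
#'   `x`/`y` columns.
#' @return The absolute enclosed area, in squared input units.
#' @export
polygon_area <- function(poly) {
  v <- roi_vertices(poly)
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_bbox <- function(poly) {
  v <- roi_vertices(poly)
  c(xmin = min(v[, 1]), xmax = max(v[, 1]),
    ymin = min(v[, 2]), ymax = max(v[, 2]))
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Vectorized over query points. Points lying on a polygon edge or vertex
#' count as inside.
#'
#' @param px,py Numeric vectors of query coordinates.
#' @param poly Polygon as in [polygon_area()].
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  v <- roi_vertices(poly)
  vx <- v[, 1]; vy <- v[, 2]
  nv <- length(vx)
  scale <- max(diff(range(vx)), diff(range(vy)), 1)
  eps <- 1e-9 * scale
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary test: |cross product| small and within the segment's bbox
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    seg_len <- sqrt((xj - xi)^2 + (yj - yi)^2)
    within <- px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    on_edge <- on_edge | (abs(cross) <= eps * max(seg_len, eps) & within)
    # even-odd crossing count for a ray towards +x
    denom <- yj - yi
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / denom
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside | on_edge
}

# Rasterize a ROI to a logical pixel mask. Pixels are indexed in 0-based
# half-open convention: pixel (row i, col j) of the matrix covers
# [j-1, j) x [i-1, i) and has centre (j - 0.5, i - 0.5).
rasterize_roi <- function(roi, nrow_img, ncol_img) {
  bb <- polygon_bbox(roi)
  cols <- max(1L, floor(bb["xmin"] + 0.5)):min(ncol_img, ceiling(bb["xmax"] + 0.5))
  rows <- max(1L, floor(bb["ymin"] + 0.5)):min(nrow_img, ceiling(bb["ymax"] + 0.5))
  mask <- matrix(FALSE, nrow_img, ncol_img)
  if (length(cols) == 0 || length(rows) == 0) return(mask)
  grid <- expand.grid(row = rows, col = cols)
  inside <- point_in_polygon(grid$col - 0.5, grid$row - 0.5, roi)
  mask[cbind(grid$row, grid$col)] <- inside
  mask
}

# Binary dilation with a (2k+1) x (2k+1) square structuring element,
# implemented by shift-OR; used for the 2-px background exclusion ring.
dilate_mask <- function(mask, k = 2L) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -k:k) {
    for (dc in -k:k) {
      if (dr == 0 && dc == 0) next
      src_r <- max(1, 1 - dr):min(nr, nr - dr)
      src_c <- max(1, 1 - dc):min(nc, nc - dc)
      out[src_r + dr, src_c + dc] <- out[src_r + dr, src_c + dc] | mask[src_r, src_c]
    }
  }
  out
}

# distance between two polygons' vertex sets is an upper bound; for pooled
# placement we only need the conservative bbox gap, checked exactly on x.
min_bbox_gap_x <- function(bb1, bb2) {
  max(bb1["xmin"] - bb2["xmax"], bb2["xmin"] - bb1["xmax"])
}
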