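#' Observation windows for point-pattern analysis
#'
#' A window is either an axis-aligned rectangle (for which the isotropic
#' Ripley edge correction has an exact closed form) or one or more simple
#' polygons (edge correction by numeric arc sampling). Multi-polygon windows
#' arise from [pool_rois()].
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds.
#' @return An object of class `nq_window`.
#' @export
#' @examples
#' w <- window_rect(0, 1000, 0, 1000)
#' window_area(w)
window_rect <- function(xmin, xmax, ymin, ymax) {
  if (!(xmax > xmin && ymax > ymin)) abort("Window must have positive area.")
  structure(list(type = "rect",
                 rect = c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)),
            class = "nq_window")
}

#' @rdname window_rect
#' @param poly A polygon ([roi()], matrix, or data frame), or a list of them.
#' @export
window_poly <- function(poly) {
  polys <- if (is.list(poly) && !inherits(poly, "nq_roi") && !is.data.frame(poly)) {
    lapply(poly, roi_vertices)
  } else {
    list(roi_vertices(poly))
  }
  areas <- vapply(polys, function(v) polygon_area(v), numeric(1))
  if (any(areas <= 0)) abort("Window polygons must have positive area.")
  structure(list(type = "poly", polys = polys), class = "nq_window")
}

as_window <- function(w) {
  if (inherits(w, "nq_window")) return(w)
  if (inherits(w, "nq_roi")) return(window_poly(w))
  if (is.numeric(w) && length(w) == 4) return(window_rect(w[1], w[2], w[3], w[4]))
  if (is.matrix(w) || is.data.frame(w)) return(window_poly(w))
  abort("Cannot interpret `window`; use window_rect(), window_poly(), or an nq_roi.")
}

#' @rdname window_rect
#' @param window An `nq_window` (or anything [roi()]-like coercible to one).
#' @export
window_area <- function(window) {
  w <- as_window(window)
  if (w$type == "rect") {
    unname((w$rect["xmax"] - w$rect["xmin"]) * (w$rect["ymax"] - w$rect["ymin"]))
  } else {
    sum(vapply(w$polys, polygon_area, numeric(1)))
  }
}

window_bbox <- function(window) {
  w <- as_window(window)
  if (w$type == "rect") return(w$rect)
  bbs <- vapply(w$polys, function(v) polygon_bbox(v), numeric(4))
  c(xmin = min(bbs["xmin", ]), xmax = max(bbs["xmax", ]),
    ymin = min(bbs["ymin", ]), ymax = max(bbs["ymax", ]))
}

point_in_window <- function(px, py, window) {
  w <- as_window(window)
  if (w$type == "rect") {
    r <- w$rect
    return(px >= r["xmin"] & px <= r["xmax"] & py >= r["ymin"] & py <= r["ymax"])
  }
  inside <- logical(length(px))
  for (v in w$polys) inside <- inside | point_in_polygon(px, py, v)
  inside
}

#' @export
print.nq_window <- function(x, ...) {
  if (x$type == "rect") {
    cat(sprintf("<nq_window rect> [%g, %g] x [%g, %g]\n",
                x$rect["xmin"], x$rect["xmax"], x$rect["ymin"], x$rect["ymax"]))
  } else {
    cat(sprintf("<nq_window poly> %d polygon(s), area=%.4g\n",
                length(x$polys), window_area(x)))
  }
  invisible(x)
}

#' Uniform random points in a window
#'
#' Rejection sampling from the bounding box for polygonal windows.
#'
#' @param n Number of points.
#' @param window An `nq_window` (or coercible).
#' @return Tibble with `x`, `y`.
#' @export
runif_in_window <- function(n, window) {
  w <- as_window(window)
  bb <- window_bbox(w)
  if (n == 0) return(tibble(x = numeric(0), y = numeric(0)))
  if (w$type == "rect") {
    return(tibble(x = runif(n, bb["xmin"], bb["xmax"]),
                  y = runif(n, bb["ymin"], bb["ymax"])))
  }
  xs <- numeric(0); ys <- numeric(0)
  # acceptance rate = area ratio; draw in batches until filled
  rate <- max(window_area(w) / ((bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"])), 1e-3)
  while (length(xs) < n) {
    m <- ceiling((n - length(xs)) / rate) + 10L
    cx <- runif(m, bb["xmin"], bb["xmax"])
    cy <- runif(m, bb["ymin"], bb["ymax"])
    keep <- point_in_window(cx, cy, w)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  tibble(x = xs[seq_len(n)], y = ys[seq_len(n)])
}
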