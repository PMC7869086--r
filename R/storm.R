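#' Filter localization points by a ROI polygon
#'
#' Retains localizations strictly inside or on the boundary of the ROI
#' (even-odd rule, boundary inclusive). Any z coordinate is carried through
#' but ignored by the 2-D test.
#'
#' @param points Localization tibble with `x_nm`/`y_nm` (or `x`/`y`) columns.
#' @param roi An [roi()] polygon in the same coordinate frame.
#' @return The subset of `points` falling in the ROI.
#' @export
points_in_roi <- function(points, roi) {
  if (!inherits(roi, "nq_roi")) roi <- roi_vertices(roi)
  xy <- point_xy(points)
  points[point_in_polygon(xy$x, xy$y, roi), , drop = FALSE]
}

#' Localization density of a ROI, with per-image normalization
#'
#' Density is the number of localization points (NLP) inside the ROI divided
#' by the ROI area converted to square microns. The image density is the NLP
#' of the whole field (all points of the channel within `image_bounds`)
#' divided by the field area; the normalized density is their ratio, a
#' dimensionless quantity that cancels image-to-image variability in
#' immunostaining/imaging efficiency.
#'
#' @param points Localizations of one channel, nm coordinates.
#' @param roi An [roi()] polygon, nm coordinates.
#' @param image_bounds Field of view as [window_rect()] or
#'   `c(xmin, xmax, ymin, ymax)` in nm; defaults to the bounding box of
#'   `points` when omitted (with a warning, since that underestimates empty
#'   margins).
#' @param image_points Optional full localization table used for the image
#'   density (defaults to `points`); pass the unfiltered table when `points`
#'   was already ROI-filtered.
#' @return One-row tibble: `roi_id`, `compartment`, `nlp`, `area_um2`,
#'   `density` (NLP per um^2), `image_density`, `normalized_density`.
#' @export
roi_density <- function(points, roi, image_bounds = NULL, image_points = points) {
  if (!inherits(roi, "nq_roi")) {
    roi <- roi(roi_vertices(roi)[, 1], roi_vertices(roi)[, 2])
  }
  if (is.null(image_bounds)) {
    warn("`image_bounds` missing; using the bounding box of the points.")
    xy_all <- point_xy(image_points)
    image_bounds <- c(min(xy_all$x), max(xy_all$x), min(xy_all$y), max(xy_all$y))
  }
  bounds <- as_window(image_bounds)
  inside <- points_in_roi(points, roi)
  nlp <- nrow(inside)
  area_um2 <- polygon_area(roi) * 1e-6
  density <- nlp / area_um2
  xyi <- point_xy(image_points)
  n_img <- sum(point_in_window(xyi$x, xyi$y, bounds))
  image_density <- n_img / (window_area(bounds) * 1e-6)
  normalized <- if (image_density > 0) density / image_density else NA_real_
  if (image_density == 0) warn("Image density is 0; normalized density undefined (NA).")
  tibble(roi_id = roi$id, compartment = roi$compartment, cell_id = roi$cell_id,
         nlp = nlp, area_um2 = area_um2, density = density,
         image_density = image_density, normalized_density = normalized)
}

#' Pool far-apart ROIs into a single point pattern
#'
#' Translates each (points, window) pair rigidly onto a horizontal grid such
#' that the minimum distance between any two ROI polygons exceeds `r_max`.
#' Because no inter-ROI pair can then enter the Ripley sums, analysing the
#' pooled pattern as one pattern aggregates the within-ROI structure of all
#' ROIs.
#'
#' @param roisets A list where each element is a `list(points = <tibble>,
#'   window = <window/roi>)`.
#' @param r_max The maximal Ripley radius the pooled pattern will be analysed
#'   with (nm; default 1000).
#' @param gap Gap inserted between consecutive ROI bounding boxes; default
#'   `r_max + 1` so that the inter-polygon distance strictly exceeds `r_max`.
#' @return A list with `points` (tibble with `x`, `y`, `set`), `window`
#'   (multi-polygon [window_poly()]), and `min_separation` (the smallest
#'   bounding-box gap actually realised).
#' @export
pool_rois <- function(roisets, r_max = 1000, gap = r_max + 1) {
  if (length(roisets) == 0) abort("`roisets` must contain at least one ROI.")
  polys <- list()
  pts <- vector("list", length(roisets))
  x_cursor <- 0
  bbs <- list()
  for (k in seq_along(roisets)) {
    set <- roisets[[k]]
    w <- as_window(set$window)
    poly <- if (w$type == "rect") {
      r <- w$rect
      cbind(x = r[c("xmin", "xmax", "xmax", "xmin")],
            y = r[c("ymin", "ymin", "ymax", "ymax")])
    } else {
      if (length(w$polys) != 1) abort("Each pooled ROI must be a single polygon.")
      w$polys[[1]]
    }
    bb <- polygon_bbox(poly)
    dx <- x_cursor - bb["xmin"]
    dy <- -bb["ymin"]
    poly_t <- poly
    poly_t[, 1] <- poly[, 1] + dx
    poly_t[, 2] <- poly[, 2] + dy
    xy <- point_xy(set$points)
    pts[[k]] <- tibble(x = xy$x + dx, y = xy$y + dy, set = k)
    polys[[k]] <- poly_t
    bbs[[k]] <- polygon_bbox(poly_t)
    x_cursor <- x_cursor + (bb["xmax"] - bb["xmin"]) + gap
  }
  min_sep <- Inf
  if (length(bbs) > 1) {
    for (k in seq_len(length(bbs) - 1)) {
      min_sep <- min(min_sep, bbs[[k + 1]]["xmin"] - bbs[[k]]["xmax"])
    }
  }
  if (length(bbs) > 1 && min_sep <= r_max) {
    abort("Pooled ROI separation did not exceed r_max; increase `gap`.")
  }
  list(points = dplyr::bind_rows(pts), window = window_poly(polys),
       min_separation = unname(min_sep))
}

#' Pointwise CSR envelope for the centred L function
#'
#' Simulates `n_sims` binomial (fixed-n CSR) patterns in the window, computes
#' `L(r) - r` for each with [ripley_k_l()], and returns the pointwise
#' extremes. An observed `L(r) - r` escaping the envelope indicates departure
#' from spatial randomness at that scale.
#'
#' @inheritParams ripley_k_l
#' @param n_points Number of points per simulated pattern.
#' @param n_sims Number of CSR simulations (default 199). `n_sims = 0`
#'   returns an empty envelope with a warning.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `r`, `lo`, `hi` (extremes of `L - r`) and
#'   attribute `n_sims`.
#' @export
csr_envelope <- function(window, n_points, n_sims = 199, r_max = 1000,
                         n_r = 100, r_grid = NULL, seed = NULL,
                         correction = "isotropic", n_arc = 720) {
  if (n_points < 2) abort("`n_points` must be at least 2.")
  if (!is.null(seed)) set.seed(seed)
  w <- as_window(window)
  if (is.null(r_grid)) r_grid <- seq(r_max / n_r, r_max, length.out = n_r)
  if (n_sims == 0) {
    warn("`n_sims` = 0: returning an empty envelope.")
    out <- tibble(r = r_grid, lo = NA_real_, hi = NA_real_)
    attr(out, "n_sims") <- 0L
    return(out)
  }
  lmr <- matrix(NA_real_, nrow = n_sims, ncol = length(r_grid))
  for (s in seq_len(n_sims)) {
    pts <- runif_in_window(n_points, w)
    res <- suppressWarnings(
      ripley_k_l(pts, w, r_max = r_max, r_grid = r_grid,
                 correction = correction, n_arc = n_arc)
    )
    lmr[s, ] <- res$l - res$r
  }
  out <- tibble(r = r_grid,
                lo = apply(lmr, 2, min),
                hi = apply(lmr, 2, max))
  attr(out, "n_sims") <- as.integer(n_sims)
  out
}
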