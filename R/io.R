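#' Read and write localization tables
#'
#' The canonical CSV layout is `x_nm,y_nm,z_nm,channel`. A reader shim also
#' accepts the `"x [nm]"`-style headers exported by common localization
#' software, mapping them onto the canonical names.
#'
#' @param path CSV file path.
#' @return A localization tibble.
#' @export
read_localizations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  nm <- names(df)
  map <- c("x [nm]" = "x_nm", "y [nm]" = "y_nm", "z [nm]" = "z_nm",
           "X" = "x_nm", "Y" = "y_nm", "Z" = "z_nm")
  hit <- nm %in% names(map)
  names(df)[hit] <- unname(map[nm[hit]])
  if (!all(c("x_nm", "y_nm") %in% names(df))) {
    abort("Localization file must provide x_nm/y_nm (or 'x [nm]'/'y [nm]') columns.")
  }
  if (!"z_nm" %in% names(df)) df$z_nm <- 0
  if (!"channel" %in% names(df)) df$channel <- "ch1"
  as_tibble(df)
}

#' @rdname read_localizations
#' @param points Localization tibble to write.
#' @export
write_localizations <- function(points, path) {
  readr::write_csv(points[, intersect(c("x_nm", "y_nm", "z_nm", "channel"),
                                      names(points))], path)
  invisible(path)
}

#' Read and write ROI polygons as GeoJSON
#'
#' ROIs are stored as a GeoJSON `FeatureCollection` of `Polygon` features;
#' the `compartment`, `cell_id` and `id` tags travel in the feature
#' properties. Coordinates are in the analysis frame (nm for STORM, pixels
#' for images).
#'
#' @param path GeoJSON file path.
#' @return A list of [roi()] objects.
#' @export
read_rois_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("Expected a GeoJSON FeatureCollection.")
  }
  purrr::map(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      abort("All ROI features must be GeoJSON Polygons.")
    }
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    # GeoJSON closes the ring by repeating the first vertex
    if (length(xs) > 3 && xs[1] == xs[length(xs)] && ys[1] == ys[length(ys)]) {
      xs <- xs[-length(xs)]; ys <- ys[-length(ys)]
    }
    pr <- f$properties
    roi(xs, ys,
        compartment = pr$compartment %||% "other",
        cell_id = pr$cell_id %||% NA_character_,
        id = pr$id %||% "roi")
  })
}

#' @rdname read_rois_geojson
#' @param rois List of [roi()] objects to write.
#' @export
write_rois_geojson <- function(rois, path) {
  if (inherits(rois, "nq_roi")) rois <- list(rois)
  features <- purrr::map(rois, function(r) {
    v <- rbind(r$vertices, r$vertices[1, , drop = FALSE])
    ring <- purrr::map(seq_len(nrow(v)), function(i) c(v[i, 1], v[i, 2]))
    list(type = "Feature",
         properties = list(id = r$id, compartment = r$compartment,
                           cell_id = r$cell_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write expression tables
#'
#' CSV layout: cells as rows, genes as columns, first column `cell_id`.
#' The MatrixMarket layout is a sparse triplet `matrix.mtx` (genes x cells)
#' with `genes.tsv` and `cells.tsv` sidecars, one symbol/id per line.
#' Both readers return the long tibble (`cell_id`, `gene`, `count`) used
#' throughout the package, with explicit zeros.
#'
#' @param path CSV file path.
#' @return Long expression tibble.
#' @export
read_expression_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "cell_id") abort("First column must be `cell_id`.")
  tidyr::pivot_longer(df, -"cell_id", names_to = "gene", values_to = "count")
}

#' @rdname read_expression_csv
#' @param expression Long expression tibble to write.
#' @export
write_expression_csv <- function(expression, path) {
  wide <- tidyr::pivot_wider(expression[, c("cell_id", "gene", "count")],
                             names_from = "gene", values_from = "count",
                             values_fill = 0)
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname read_expression_csv
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @export
read_expression_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readr::read_lines(file.path(dir, "genes.tsv"))
  cells <- readr::read_lines(file.path(dir, "cells.tsv"))
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    abort("matrix.mtx dimensions do not match the genes/cells sidecars.")
  }
  dense <- as.matrix(m)
  tibble(cell_id = rep(cells, each = length(genes)),
         gene = rep(genes, times = length(cells)),
         count = as.numeric(dense))
}

#' @rdname read_expression_csv
#' @export
write_expression_mtx <- function(expression, dir) {
  wide <- tidyr::pivot_wider(expression[, c("cell_id", "gene", "count")],
                             names_from = "gene", values_from = "count",
                             values_fill = 0)
  cells <- wide$cell_id
  m <- t(as.matrix(wide[, -1, drop = FALSE]))  # genes x cells
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), file.path(dir, "matrix.mtx"))
  readr::write_lines(rownames(m), file.path(dir, "genes.tsv"))
  readr::write_lines(cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read and write cutoff tables as YAML
#'
#' @param path YAML file path with `cb1:` (region -> cutoff) and `genes:`
#'   (gene -> cutoff) maps.
#' @return A [cutoff_table()].
#' @export
read_cutoffs_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cutoff_table(cb1 = unlist(y$cb1), genes = unlist(y$genes))
}

#' @rdname read_cutoffs_yaml
#' @param cutoffs A [cutoff_table()] to write.
#' @export
write_cutoffs_yaml <- function(cutoffs, path) {
  yaml::write_yaml(list(cb1 = as.list(cutoffs$cb1),
                        genes = as.list(cutoffs$genes)), path)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' @param path Text file path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  x[nzchar(x)]
}

#' Read and write 16-bit grayscale TIFF images
#'
#' Images are numeric matrices in counts (0..65535); the TIFF layer stores
#' them as 16-bit unsigned samples.
#'
#' @param path TIFF file path.
#' @return Integer intensity matrix.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(img) <- "integer"
  img
}

#' @rdname read_image_tiff
#' @param image Numeric/integer matrix of counts in 0..65535.
#' @export
write_image_tiff <- function(image, path) {
  if (any(image < 0) || any(image > 65535)) abort("Image counts must be in 0..65535.")
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
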