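#' Region and gene cutoff table for enrichment classification
#'
#' @param cb1 Named numeric vector of CB1 enrichment cutoffs per region.
#' @param genes Named numeric vector of positivity cutoffs per gene channel.
#' @return A list of class `cutoff_table`.
#' @export
cutoff_table <- function(cb1, genes = c(Necab1 = 2, Necab2 = 2)) {
  if (any(cb1 <= 0) || any(genes <= 0)) abort("All cutoffs must be > 0.")
  if (is.null(names(cb1)) || is.null(names(genes))) {
    abort("Cutoff vectors must be named (regions / genes).")
  }
  structure(list(cb1 = cb1, genes = genes), class = "cutoff_table")
}

#' Default region cutoffs for strong/weak CB1 classification
#'
#' The CB1 enrichment cutoffs derived from the bimodal per-region enrichment
#' distributions: HC-CA1 2, HC-CA3 4.5, HC-DG 3, SS-CTX 3, BLA 5. Gene
#' positivity cutoffs default to 2 (the gene-level cutoffs are not published;
#' configurable).
#'
#' @return A [cutoff_table()].
#' @export
default_cutoffs <- function() {
  cutoff_table(
    cb1 = c("HC-CA1" = 2, "HC-CA3" = 4.5, "HC-DG" = 3, "SS-CTX" = 3, "BLA" = 5),
    genes = c(Necab1 = 2, Necab2 = 2)
  )
}

#' Compute per-cell enrichment values from an image and cell ROIs
#'
#' Enrichment of a cell is the mean pixel intensity inside its ROI divided
#' by the mean intensity of the background region. The default background is
#' the complement of the union of all cell ROIs dilated by 2 pixels (square
#' structuring element); an explicit background polygon can be supplied
#' instead. Pixels belong to a polygon by the pixel-centre test in 0-based,
#' origin-top-left, half-open pixel coordinates.
#'
#' @param image 2-D numeric intensity matrix (rows = y, columns = x).
#' @param cell_rois List of [roi()] polygons in pixel coordinates.
#' @param background Optional explicit background [roi()] polygon; default
#'   NULL uses the dilated-complement rule.
#' @param region Region label attached to all cells (default `NA`).
#' @param channel Channel label attached to the values (default `"ch1"`).
#' @return A long [CellQuantTable][classify_cells] tibble: `cell_id`,
#'   `region`, `channel`, `enrichment`, plus `roi_mean`, `background_mean`,
#'   `n_pixels`.
#' @export
compute_enrichment <- function(image, cell_rois, background = NULL,
                               region = NA_character_, channel = "ch1") {
  if (!is.matrix(image) || !is.numeric(image)) abort("`image` must be a numeric matrix.")
  nr <- nrow(image); nc <- ncol(image)
  masks <- lapply(cell_rois, function(r) {
    bb <- polygon_bbox(r)
    if (bb["xmin"] < 0 || bb["ymin"] < 0 || bb["xmax"] > nc || bb["ymax"] > nr) {
      abort(sprintf("ROI '%s' extends beyond the image bounds.", r$id %||% "?"))
    }
    rasterize_roi(r, nr, nc)
  })
  if (is.null(background)) {
    union_mask <- Reduce(`|`, masks, matrix(FALSE, nr, nc))
    bg_mask <- !dilate_mask(union_mask, 2L)
  } else {
    bg_mask <- rasterize_roi(background, nr, nc)
  }
  if (!any(bg_mask)) abort("Background region is empty.")
  bg_mean <- mean(image[bg_mask])
  if (bg_mean == 0) abort("Background mean intensity is 0; enrichment undefined.")
  rows <- purrr::map2_dfr(cell_rois, masks, function(r, m) {
    npix <- sum(m)
    if (npix == 0) {
      abort(sprintf("ROI '%s' covers no pixel centres.", r$id %||% "?"))
    }
    roi_mean <- mean(image[m])
    tibble(cell_id = r$id %||% NA_character_, region = region,
           channel = channel, enrichment = roi_mean / bg_mean,
           roi_mean = roi_mean, background_mean = bg_mean, n_pixels = npix)
  })
  rows
}

#' Classify cells into strong/weak CB1 groups and per-gene positivity
#'
#' A cell is "strong" when its CB1-channel enrichment is greater than or
#' equal to the cutoff of its region (the boundary is inclusive by default;
#' configurable), and positive for a gene when that channel's enrichment
#' meets the gene cutoff. Classification is deterministic.
#'
#' @param quant Long CellQuantTable tibble: `cell_id`, `region`, `channel`,
#'   `enrichment`.
#' @param cutoffs A [cutoff_table()]; default [default_cutoffs()].
#' @param cb1_channel Name of the CB1 channel (default `"Cnr1"`).
#' @param boundary `"inclusive"` (>= cutoff is strong/positive, default) or
#'   `"exclusive"` (strictly >).
#' @return Tibble with one row per cell and gene channel: `cell_id`,
#'   `region`, `cb1_enrichment`, `cb1_class` (`"strong"`/`"weak"`), `gene`,
#'   `enrichment`, `positive`.
#' @export
#' @examples
#' quant <- tibble::tibble(
#'   cell_id = rep("c1", 2), region = "HC-CA1",
#'   channel = c("Cnr1", "Necab1"), enrichment = c(2.0, 3.1)
#' )
#' classify_cells(quant)  # enrichment 2.0 at cutoff 2 -> strong
classify_cells <- function(quant, cutoffs = default_cutoffs(),
                           cb1_channel = "Cnr1",
                           boundary = c("inclusive", "exclusive")) {
  boundary <- match.arg(boundary)
  need <- c("cell_id", "region", "channel", "enrichment")
  if (!all(need %in% names(quant))) {
    abort("`quant` needs cell_id, region, channel, enrichment columns.")
  }
  if (any(quant$enrichment <= 0)) abort("Enrichment values must be > 0.")
  unknown <- setdiff(unique(quant$region), names(cutoffs$cb1))
  if (length(unknown) > 0) {
    abort(sprintf("No CB1 cutoff for region(s): %s", paste(unknown, collapse = ", ")))
  }
  ge <- if (boundary == "inclusive") `>=` else `>`
  cb1 <- quant %>%
    dplyr::filter(.data$channel == cb1_channel) %>%
    mutate(cb1_class = ifelse(ge(.data$enrichment,
                                 unname(cutoffs$cb1[.data$region])),
                              "strong", "weak")) %>%
    select("cell_id", "region", cb1_enrichment = "enrichment", "cb1_class")
  if (nrow(cb1) == 0) abort(sprintf("No '%s' channel rows found.", cb1_channel))
  genes <- quant %>% dplyr::filter(.data$channel != cb1_channel)
  unknown_g <- setdiff(unique(genes$channel), names(cutoffs$genes))
  if (length(unknown_g) > 0) {
    abort(sprintf("No positivity cutoff for gene channel(s): %s",
                  paste(unknown_g, collapse = ", ")))
  }
  genes %>%
    mutate(positive = ge(.data$enrichment,
                         unname(cutoffs$genes[.data$channel]))) %>%
    select("cell_id", gene = "channel", "enrichment", "positive") %>%
    dplyr::inner_join(cb1, by = "cell_id") %>%
    select("cell_id", "region", "cb1_enrichment", "cb1_class", "gene",
           "enrichment", "positive")
}

#' Co-expression summary per region and CB1 class
#'
#' Counts, per (region, CB1 class) stratum, the cells positive for each
#' gene, for all genes jointly ("both" for the usual two-gene panel) and
#' for none. Fractions are retained unrounded; `pct` is `100 * frac`.
#' Empty strata yield `NA` percentages with a warning rather than 0.
#'
#' @param classified Output of [classify_cells()].
#' @return Tibble `region`, `cb1_class`, `n_cells`, `target` (each gene,
#'   `"all"`, `"none"`), `n_positive`, `frac`, `pct`.
#' @export
coexpression_summary <- function(classified) {
  need <- c("cell_id", "region", "cb1_class", "gene", "positive")
  if (!all(need %in% names(classified))) {
    abort("`classified` must come from classify_cells().")
  }
  genes <- sort(unique(classified$gene))
  per_cell <- classified %>%
    tidyr::pivot_wider(id_cols = c("cell_id", "region", "cb1_class"),
                       names_from = "gene", values_from = "positive")
  strata <- tidyr::expand_grid(
    region = unique(per_cell$region),
    cb1_class = c("strong", "weak")
  )
  out <- purrr::pmap_dfr(strata, function(region, cb1_class) {
    sub <- per_cell[per_cell$region == region & per_cell$cb1_class == cb1_class, ]
    n <- nrow(sub)
    targets <- c(genes, "all", "none")
    npos <- vapply(targets, function(tg) {
      if (n == 0) return(NA_integer_)
      flags <- switch(tg,
        all = Reduce(`&`, lapply(genes, function(g) sub[[g]])),
        none = Reduce(`&`, lapply(genes, function(g) !sub[[g]])),
        sub[[tg]])
      sum(flags)
    }, integer(1))
    npos <- unname(npos)
    tibble(region = region, cb1_class = cb1_class, n_cells = n,
           target = targets, n_positive = npos,
           frac = if (n == 0) NA_real_ else npos / n,
           pct = if (n == 0) NA_real_ else 100 * npos / n)
  })
  if (any(out$n_cells == 0)) {
    warn("Empty (region, class) stratum; percentages reported as NA.")
  }
  out
}
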