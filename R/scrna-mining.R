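#' Normalize expression to the mean total copy number per cell
#'
#' Single-cell copy numbers carry a cell-specific mRNA harvesting
#' (capture) bias: every gene of a cell is scaled by the same unknown
#' efficiency factor. Rescaling each cell's values by `Tbar / T_c`, where
#' `T_c` is the cell's total copy number and `Tbar` the dataset mean total,
#' equalizes all per-cell totals at `Tbar` and thereby removes the
#' multiplicative bias (absolute scale remains identified only up to the
#' mean capture efficiency).
#'
#' Cells with a zero total are dropped with a warning. Normalizing an
#' already-normalized table is a no-op (all totals already equal `Tbar`).
#'
#' @param expression Long tibble with columns `cell_id`, `gene`, and the
#'   value column named by `value_col` (default `"count"`). Include explicit
#'   zero rows if total copy numbers should count all genes.
#' @param value_col Name of the value column.
#' @return A tibble with the same columns where the value column has been
#'   replaced by its normalized version; attribute `mean_total` carries
#'   `Tbar`. Every retained cell's total equals `Tbar` to within 1e-9
#'   relative.
#' @export
#' @examples
#' ex <- tibble::tibble(cell_id = rep(c("a", "b"), each = 2),
#'                      gene = rep(c("g1", "g2"), 2),
#'                      count = c(10, 90, 150, 150))
#' normalize_expression(ex)  # totals 100 and 300 -> both rescaled to 200
normalize_expression <- function(expression, value_col = "count") {
  if (!all(c("cell_id", "gene", value_col) %in% names(expression))) {
    abort(sprintf("`expression` needs cell_id, gene and '%s' columns.", value_col))
  }
  vals <- expression[[value_col]]
  if (any(vals < 0)) abort("Expression values must be non-negative.")
  totals <- expression %>%
    group_by(.data$cell_id) %>%
    summarise(total = sum(.data[[value_col]]), .groups = "drop")
  if (all(totals$total == 0)) abort("All cells have zero total copy number.")
  zero <- totals$cell_id[totals$total == 0]
  if (length(zero) > 0) {
    warn(sprintf("Dropping %d cell(s) with zero total copy number.", length(zero)))
  }
  keep <- dplyr::filter(totals, .data$total > 0)
  t_bar <- mean(keep$total)
  out <- expression %>%
    dplyr::inner_join(keep, by = "cell_id") %>%
    mutate(!!value_col := .data[[value_col]] * t_bar / .data$total) %>%
    select(-"total")
  attr(out, "mean_total") <- t_bar
  attr(out, "layer") <- "normalized"
  out
}

#' Gate marker-high cells per region, with Grubbs outlier control
#'
#' Within each brain region, retains cells whose marker copy number strictly
#' exceeds `threshold_frac` times the region's maximum marker value (the
#' "10%-of-max" gate with the default `threshold_frac = 0.1`), then applies
#' `grubbs_iterations` rounds of a two-sided Grubbs test at `grubbs_alpha`
#' to the retained marker values, removing the flagged outlier after each
#' significant round. Regions with fewer than 3 retained cells skip the
#' Grubbs step with a warning (the test is undefined below n = 3).
#'
#' @param expression Long expression tibble (`cell_id`, `gene`, value
#'   column); raw or normalized.
#' @param cell_meta Tibble with `cell_id`, `region`, and (if
#'   `class_filter` is used) `cell_class`.
#' @param marker Marker gene symbol (default `"Cnr1"`).
#' @param threshold_frac Fraction of the per-region maximum (default 0.1).
#' @param grubbs_alpha Grubbs significance level (default 0.05).
#' @param grubbs_iterations Number of Grubbs rounds (default 1).
#' @param class_filter Optional class annotation (e.g. `"GABAergic"`)
#'   applied to `cell_meta` before gating, mirroring the sample-annotation
#'   pre-filter.
#' @param value_col Value column name (default `"count"`).
#' @return Tibble of retained cells: `cell_id`, `region`, `marker_value`,
#'   with attribute `audit`, a tibble logging every Grubbs removal
#'   (`region`, `cell_id`, `value`, `iteration`, `G`, `G_crit`).
#' @export
select_marker_high_cells <- function(expression, cell_meta, marker = "Cnr1",
                                     threshold_frac = 0.1, grubbs_alpha = 0.05,
                                     grubbs_iterations = 1,
                                     class_filter = NULL, value_col = "count") {
  check_number(threshold_frac, "threshold_frac", lower = 1e-12, upper = 1 - 1e-12)
  check_number(grubbs_alpha, "grubbs_alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_number(grubbs_iterations, "grubbs_iterations", lower = 0)
  if (!marker %in% expression$gene) {
    abort(sprintf("Marker '%s' not present in the expression table.", marker))
  }
  meta <- cell_meta
  if (!is.null(class_filter)) {
    if (!"cell_class" %in% names(meta)) {
      abort("`cell_meta` needs a cell_class column for class filtering.")
    }
    meta <- dplyr::filter(meta, .data$cell_class == class_filter)
  }
  mk <- expression %>%
    dplyr::filter(.data$gene == marker) %>%
    dplyr::inner_join(select(meta, "cell_id", "region"), by = "cell_id") %>%
    rename(marker_value = !!value_col)

  audit <- list()
  gated <- mk %>%
    group_by(.data$region) %>%
    dplyr::filter(.data$marker_value > threshold_frac * max(.data$marker_value)) %>%
    ungroup()

  for (reg in unique(gated$region)) {
    for (it in seq_len(grubbs_iterations)) {
      idx <- which(gated$region == reg)
      if (length(idx) < 3) {
        warn(sprintf("Region '%s': fewer than 3 retained cells; skipping Grubbs.", reg))
        break
      }
      gt <- grubbs_test(gated$marker_value[idx], alpha = grubbs_alpha)
      if (is.na(gt$outlier_index)) break
      out_row <- idx[gt$outlier_index]
      audit[[length(audit) + 1]] <- tibble(
        region = reg, cell_id = gated$cell_id[out_row],
        value = gated$marker_value[out_row], iteration = it,
        G = gt$statistic, G_crit = gt$critical)
      gated <- gated[-out_row, ]
    }
  }
  out <- select(gated, "cell_id", "region", "marker_value")
  attr(out, "audit") <- if (length(audit)) dplyr::bind_rows(audit) else
    tibble(region = character(0), cell_id = character(0), value = numeric(0),
           iteration = integer(0), G = numeric(0), G_crit = numeric(0))
  attr(out, "marker") <- marker
  out
}

#' Rank candidate genes over a gated cell population
#'
#' For each gene of a candidate list (e.g. all GO "calcium-binding"
#' annotated genes), computes the detection fraction -- the fraction of
#' gated cells with a normalized level of at least 1 copy -- and the mean
#' normalized level, then ranks by detection fraction, breaking ties by
#' mean level and then lexicographically by gene symbol.
#'
#' @param expression Normalized long expression tibble.
#' @param gated_cells Character vector of gated cell ids (or the tibble
#'   returned by [select_marker_high_cells()]).
#' @param gene_list Character vector of candidate gene symbols (non-empty,
#'   all present in the table).
#' @param detect_at Detection threshold in normalized copies (default 1).
#' @param value_col Value column name.
#' @return Tibble `gene`, `detection_fraction`, `mean_level`, `rank`.
#' @export
rank_candidate_genes <- function(expression, gated_cells, gene_list,
                                 detect_at = 1, value_col = "count") {
  if (is.data.frame(gated_cells)) gated_cells <- gated_cells$cell_id
  if (length(gated_cells) == 0) abort("The gated cell set is empty.")
  if (length(gene_list) == 0) abort("`gene_list` must not be empty.")
  missing <- setdiff(gene_list, unique(expression$gene))
  if (length(missing) > 0) {
    abort(sprintf("Genes not in the expression table: %s",
                  paste(missing, collapse = ", ")))
  }
  expression %>%
    dplyr::filter(.data$cell_id %in% gated_cells, .data$gene %in% gene_list) %>%
    group_by(.data$gene) %>%
    summarise(detection_fraction = mean(.data[[value_col]] >= detect_at),
              mean_level = mean(.data[[value_col]]), .groups = "drop") %>%
    arrange(desc(.data$detection_fraction), desc(.data$mean_level), .data$gene) %>%
    mutate(rank = row_number())
}

#' Spearman correlations between two gene sets
#'
#' Spearman's rank correlation (average ranks for ties) between every pair
#' of genes from `genes_a` x `genes_b` over a cell subset, with p-values
#' from the t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`, flagged
#' approximate for n < 10. Zero-variance genes yield a missing coefficient
#' with a warning.
#'
#' @param expression Long expression tibble (normalized recommended).
#' @param genes_a,genes_b Character vectors of gene symbols.
#' @param cells Optional cell-id subset (default: all cells in the table);
#'   at least 3 cells required.
#' @param value_col Value column name.
#' @return Tibble `gene_a`, `gene_b`, `rho`, `p_value`, `n`, `approx`.
#' @export
correlate_genes <- function(expression, genes_a, genes_b, cells = NULL,
                            value_col = "count") {
  if (is.data.frame(cells)) cells <- cells$cell_id
  cells <- cells %||% unique(expression$cell_id)
  if (length(cells) < 3) abort("Correlation needs at least 3 cells.")
  genes <- union(genes_a, genes_b)
  wide <- expression %>%
    dplyr::filter(.data$cell_id %in% cells, .data$gene %in% genes) %>%
    tidyr::pivot_wider(id_cols = "cell_id", names_from = "gene",
                       values_from = dplyr::all_of(value_col))
  missing <- setdiff(genes, names(wide))
  if (length(missing) > 0) {
    abort(sprintf("Genes not in the expression table: %s",
                  paste(missing, collapse = ", ")))
  }
  n <- nrow(wide)
  sds <- vapply(genes, function(g) sd(wide[[g]]), numeric(1))
  if (any(sds == 0)) {
    warn(sprintf("Zero-variance gene(s) in the subset: %s; correlations reported as NA.",
                 paste(genes[sds == 0], collapse = ", ")))
  }
  grid <- tidyr::expand_grid(gene_a = genes_a, gene_b = genes_b)
  res <- purrr::pmap_dfr(grid, function(gene_a, gene_b) {
    if (sds[[gene_a]] == 0 || sds[[gene_b]] == 0) {
      return(tibble(gene_a = gene_a, gene_b = gene_b, rho = NA_real_,
                    p_value = NA_real_, n = n, approx = TRUE))
    }
    rho <- cor(wide[[gene_a]], wide[[gene_b]], method = "spearman")
    p <- if (abs(rho) >= 1) 0 else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tt), df = n - 2)
    }
    tibble(gene_a = gene_a, gene_b = gene_b, rho = rho, p_value = p,
           n = n, approx = n < 10)
  })
  res
}
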