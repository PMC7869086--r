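#' Bouton distribution index (BDI)
#'
#' Summarizes where an interneuron's axonal boutons fall relative to the
#' CA1 pyramidal-cell layer. In the default `count_ratio` mode
#' `BDI = N_SP / (N_SO + N_SR)`; in `density_ratio` mode the counts are
#' first normalized by the layer areas,
#' `BDI = (N_SP / A_SP) / ((N_SO + N_SR) / (A_SO + A_SR))`, which corrects
#' for the layers' very different thicknesses. A zero denominator with a
#' positive numerator gives `Inf` (an axon arbor entirely confined to the
#' pyramidal layer). The mode used is recorded in the output.
#'
#' @param boutons Tibble with a `layer` column over `SP`/`SO`/`SR` and
#'   optionally `cell_id` (one BDI is computed per cell).
#' @param mode `"count_ratio"` (default) or `"density_ratio"`.
#' @param layer_areas Named areas `c(SP=, SO=, SR=)`, required for
#'   `density_ratio`.
#' @return Tibble `cell_id`, `n_sp`, `n_so`, `n_sr`, `bdi`, `mode`,
#'   `targeting_class`.
#' @export
#' @examples
#' b <- tibble::tibble(layer = c(rep("SP", 60), rep("SO", 25), rep("SR", 15)))
#' compute_bdi(b)  # BDI = 60/40 = 1.5 -> perisomatic
compute_bdi <- function(boutons, mode = c("count_ratio", "density_ratio"),
                        layer_areas = NULL) {
  mode <- match.arg(mode)
  if (nrow(boutons) == 0) abort("BDI is undefined for an empty bouton map.")
  if (!"layer" %in% names(boutons)) abort("`boutons` needs a `layer` column.")
  bad <- setdiff(unique(boutons$layer), c("SP", "SO", "SR"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown layer label(s): %s", paste(bad, collapse = ", ")))
  }
  if (mode == "density_ratio") {
    if (is.null(layer_areas) || !all(c("SP", "SO", "SR") %in% names(layer_areas))) {
      abort("`density_ratio` mode requires layer_areas named over SP, SO, SR.")
    }
    if (any(layer_areas <= 0)) abort("Layer areas must be positive.")
  }
  if (!"cell_id" %in% names(boutons)) boutons$cell_id <- "cell1"
  boutons %>%
    group_by(.data$cell_id) %>%
    summarise(n_sp = sum(.data$layer == "SP"),
              n_so = sum(.data$layer == "SO"),
              n_sr = sum(.data$layer == "SR"), .groups = "drop") %>%
    mutate(
      bdi = if (mode == "count_ratio") {
        ifelse(.data$n_so + .data$n_sr == 0, Inf,
               .data$n_sp / (.data$n_so + .data$n_sr))
      } else {
        num <- .data$n_sp / layer_areas[["SP"]]
        den <- (.data$n_so + .data$n_sr) / (layer_areas[["SO"]] + layer_areas[["SR"]])
        ifelse(den == 0, Inf, num / den)
      },
      mode = mode,
      targeting_class = classify_targeting(.data$bdi)
    )
}

#' Classify axonal targeting from the BDI
#'
#' `BDI > 1` marks a perisomatically targeting cell (axon arbor mainly in
#' the stratum pyramidale); `BDI < 0.5` a dendritically targeting cell
#' (arbor spread over strata oriens and radiatum); values in between --
#' including exactly 0.5 and exactly 1, which the strict inequalities leave
#' unassigned -- are "ambiguous" (the morphologically mixed cells omitted
#' from further analysis).
#'
#' @param bdi Numeric vector of BDI values (may include `Inf`).
#' @return Character vector: `"perisomatic"`, `"dendritic"`, `"ambiguous"`.
#' @export
classify_targeting <- function(bdi) {
  if (any(is.na(bdi)) || any(bdi < 0)) abort("BDI values must be >= 0 (or Inf).")
  case_when(
    bdi > 1 ~ "perisomatic",
    bdi < 0.5 ~ "dendritic",
    TRUE ~ "ambiguous"
  )
}
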