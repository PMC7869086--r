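#' Synthetic single-cell expression configuration
#'
#' Defines a ground-truthed generator for a cells-by-genes copy-number
#' matrix. Counts for gene *g* in a cell of type *t* are drawn from a
#' negative binomial with mean `efficiency * mean(t, g)` and size
#' (dispersion) parameter `dispersion(t, g)`; `poisson = TRUE` (or an
#' infinite dispersion) selects the Poisson limit. The per-cell harvesting
#' efficiency is drawn log-uniformly from `efficiency_range` and multiplies
#' every gene mean of that cell -- exactly the capture bias that per-cell
#' copy-number normalization must remove.
#'
#' @param profiles Tibble with columns `cell_type`, `gene`, `mean`,
#'   `dispersion` (negative-binomial size; larger = closer to Poisson).
#' @param n_cells Named integer vector: cells per `cell_type`.
#' @param efficiency_range Length-2 positive vector `c(lo, hi)`, `lo <= hi`.
#' @param coexpression_rules Optional tibble `gene`, `cell_type`, `p_pos`:
#'   the probability that a cell of that type expresses the gene at all
#'   (negative cells get mean 0 for that gene).
#' @param regions Optional named character vector mapping cell types to brain
#'   region labels (default `"HC-CA1"` for all).
#' @param classes Optional named character vector mapping cell types to a
#'   class annotation (default `"GABAergic"`), mirroring the sample
#'   annotation used to pre-filter interneurons.
#' @param poisson Use the Poisson limit for all genes.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A validated config object (class `scrna_sim_config`).
#' @seealso [sim_expression()]
#' @export
scrna_sim_config <- function(profiles, n_cells, efficiency_range = c(0.5, 2),
                             coexpression_rules = NULL, regions = NULL,
                             classes = NULL, poisson = FALSE, seed = 1L) {
  profiles <- as_tibble(profiles)
  need <- c("cell_type", "gene", "mean", "dispersion")
  if (!all(need %in% names(profiles)) || nrow(profiles) == 0) {
    abort("`profiles` must be a non-empty tibble with cell_type, gene, mean, dispersion.")
  }
  if (any(profiles$mean < 0)) abort("Profile means must be >= 0.")
  if (any(profiles$dispersion <= 0)) abort("Dispersions must be > 0 (Inf = Poisson).")
  types <- unique(profiles$cell_type)
  if (is.null(names(n_cells)) || !all(names(n_cells) %in% types)) {
    abort("`n_cells` must be a named vector over the profiled cell types.")
  }
  if (any(n_cells < 1)) abort("`n_cells` entries must be >= 1.")
  if (length(efficiency_range) != 2 || efficiency_range[1] <= 0 ||
      efficiency_range[1] > efficiency_range[2]) {
    abort("`efficiency_range` must satisfy 0 < lo <= hi.")
  }
  if (!is.null(coexpression_rules)) {
    coexpression_rules <- as_tibble(coexpression_rules)
    if (!all(c("gene", "cell_type", "p_pos") %in% names(coexpression_rules))) {
      abort("`coexpression_rules` needs gene, cell_type, p_pos columns.")
    }
    if (any(coexpression_rules$p_pos < 0 | coexpression_rules$p_pos > 1)) {
      abort("Positivity probabilities must lie in [0, 1].")
    }
  }
  regions <- regions %||% setNames(rep("HC-CA1", length(types)), types)
  classes <- classes %||% setNames(rep("GABAergic", length(types)), types)
  structure(list(profiles = profiles, n_cells = n_cells,
                 efficiency_range = as.numeric(efficiency_range),
                 coexpression_rules = coexpression_rules,
                 regions = regions, classes = classes,
                 poisson = isTRUE(poisson), seed = as.integer(seed)),
            class = "scrna_sim_config")
}

#' Synthetic in situ hybridization configuration
#'
#' Defines a ground-truthed generator of per-cell enrichment values. A cell
#' is a strong-CB1 interneuron with probability `p_strong`; its CB1-channel
#' enrichment is `cutoff * exp(N(location, scale))` with the positive law for
#' strong cells and the negative law for weak cells, so the location
#' parameters are expressed in units of `scale` away from the classification
#' cutoff. Each profiled gene is truly positive with probability
#' `p_pos[gene]` (strong cells) or `p_pos_weak[gene]` (weak cells, default
#' 0), and its enrichment is drawn the same way around the gene cutoff.
#'
#' With the default laws (`location = +/- 5 * scale`, `scale = 0.25`) the
#' probability mass on the correct side of the cutoff is `pnorm(5) > 0.9999997`,
#' comfortably beyond the 0.999 guaranteed-separation margin the generator
#' promises, so downstream classification recovers the truth for every cell
#' at realistic sample sizes.
#'
#' @param region Brain region label (e.g. `"HC-CA1"`).
#' @param n_cells Number of cells.
#' @param p_strong Probability a cell is a strong-CB1 interneuron.
#' @param p_pos Named probabilities that a strong cell is positive per gene.
#' @param p_pos_weak Same for weak cells (defaults to 0 for every gene).
#' @param cutoff CB1 enrichment cutoff; default looked up per region from
#'   [default_cutoffs()].
#' @param gene_cutoffs Named positivity cutoffs per gene (default 2).
#' @param law_pos,law_neg Lognormal parameters `c(location, scale)` of the
#'   enrichment relative to the relevant cutoff for truly
#'   positive/strong vs. negative/weak draws.
#' @param cb1_channel Channel name used for the CB1 signal (default
#'   `"Cnr1"`).
#' @param seed Integer seed.
#' @return A validated config (class `ish_sim_config`).
#' @seealso [sim_ish_table()], [sim_ish_image()]
#' @export
ish_sim_config <- function(region = "HC-CA1", n_cells = 100, p_strong = 0.5,
                           p_pos = c(Necab1 = 0.92, Necab2 = 1),
                           p_pos_weak = NULL, cutoff = NULL,
                           gene_cutoffs = NULL,
                           law_pos = c(location = 1.25, scale = 0.25),
                           law_neg = c(location = -1.25, scale = 0.25),
                           cb1_channel = "Cnr1", seed = 1L) {
  check_number(n_cells, "n_cells", lower = 0)
  check_prob(p_strong, "p_strong")
  if (length(p_pos) == 0 || is.null(names(p_pos))) {
    abort("`p_pos` must be a named probability vector (one entry per gene).")
  }
  for (g in names(p_pos)) check_prob(p_pos[[g]], paste0("p_pos[", g, "]"))
  p_pos_weak <- p_pos_weak %||% setNames(rep(0, length(p_pos)), names(p_pos))
  for (g in names(p_pos_weak)) check_prob(p_pos_weak[[g]], paste0("p_pos_weak[", g, "]"))
  if (is.null(cutoff)) {
    ct <- default_cutoffs()
    if (!region %in% names(ct$cb1)) {
      abort(sprintf("No default CB1 cutoff for region '%s'; supply `cutoff`.", region))
    }
    cutoff <- ct$cb1[[region]]
  }
  check_number(cutoff, "cutoff", lower = 1e-12)
  gene_cutoffs <- gene_cutoffs %||% setNames(rep(2, length(p_pos)), names(p_pos))
  if (any(gene_cutoffs <= 0)) abort("Gene cutoffs must be > 0.")
  for (law in list(law_pos, law_neg)) {
    if (length(law) != 2 || law[["scale"]] <= 0) {
      abort("Enrichment laws need c(location, scale) with scale > 0.")
    }
  }
  sep_pos <- law_pos[["location"]] / law_pos[["scale"]]
  sep_neg <- -law_neg[["location"]] / law_neg[["scale"]]
  if (pnorm(min(sep_pos, sep_neg)) < 0.999) {
    warn("Enrichment laws put < 99.9% mass on the correct side of the cutoff; classification recovery is no longer guaranteed.")
  }
  structure(list(region = region, n_cells = as.integer(n_cells),
                 p_strong = p_strong, p_pos = p_pos, p_pos_weak = p_pos_weak,
                 cutoff = cutoff, gene_cutoffs = gene_cutoffs,
                 law_pos = law_pos, law_neg = law_neg,
                 cb1_channel = cb1_channel, seed = as.integer(seed)),
            class = "ish_sim_config")
}

#' Synthetic point-process configuration
#'
#' CSR (homogeneous Poisson) or Thomas cluster process inside a window.
#' Intensities are per square micron; coordinates are nanometres.
#'
#' @param window Observation window (nm): [window_rect()], [window_poly()]
#'   or an [roi()].
#' @param process `"CSR"` or `"Thomas"`.
#' @param intensity Points per um^2 (CSR) or parent intensity kappa per um^2
#'   (Thomas).
#' @param offspring_mean Expected offspring per parent (Thomas only).
#' @param offspring_sigma Gaussian offspring spread in nm (Thomas only).
#' @param seed Integer seed.
#' @return A validated config (class `point_process_config`).
#' @seealso [sim_localizations()]
#' @export
point_process_config <- function(window, process = c("CSR", "Thomas"),
                                 intensity, offspring_mean = NULL,
                                 offspring_sigma = NULL, seed = 1L) {
  process <- match.arg(process)
  w <- as_window(window)
  if (window_area(w) <= 0) abort("Window area must be positive.")
  check_number(intensity, "intensity", lower = 0)
  if (intensity <= 0) abort("`intensity` must be > 0.")
  if (process == "Thomas") {
    check_number(offspring_mean %||% NA_real_, "offspring_mean", lower = 1e-12)
    check_number(offspring_sigma %||% NA_real_, "offspring_sigma", lower = 1e-12)
  }
  structure(list(window = w, process = process, intensity = intensity,
                 offspring_mean = offspring_mean,
                 offspring_sigma = offspring_sigma, seed = as.integer(seed)),
            class = "point_process_config")
}

#' Synthetic bouton-map configuration
#'
#' @param n_boutons Number of boutons (>= 1; the bouton distribution index is
#'   undefined for an empty map).
#' @param layer_probs Named probabilities over the CA1 layers `SP` (stratum
#'   pyramidale), `SO` (oriens) and `SR` (radiatum); must sum to 1.
#' @param seed Integer seed.
#' @return A validated config (class `bouton_sim_config`).
#' @seealso [sim_bouton_map()]
#' @export
bouton_sim_config <- function(n_boutons, layer_probs = c(SP = 0.6, SO = 0.2, SR = 0.2),
                              seed = 1L) {
  check_number(n_boutons, "n_boutons", lower = 1)
  if (!setequal(names(layer_probs), c("SP", "SO", "SR"))) {
    abort("`layer_probs` must be named over SP, SO, SR.")
  }
  if (any(layer_probs < 0) || abs(sum(layer_probs) - 1) > 1e-9) {
    abort("`layer_probs` must be non-negative and sum to 1 (within 1e-9).")
  }
  structure(list(n_boutons = as.integer(n_boutons),
                 layer_probs = layer_probs[c("SP", "SO", "SR")],
                 seed = as.integer(seed)),
            class = "bouton_sim_config")
}
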