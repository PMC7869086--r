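# shared truth draw for the ISH generators
draw_ish_truth <- function(config) {
  n <- config$n_cells
  ids <- if (n > 0) sprintf("cell%04d", seq_len(n)) else character(0)
  strong <- runif(n) < config$p_strong
  rln <- function(is_pos, cutoff) {
    loc <- ifelse(is_pos, config$law_pos[["location"]], config$law_neg[["location"]])
    sc <- ifelse(is_pos, config$law_pos[["scale"]], config$law_neg[["scale"]])
    cutoff * exp(rnorm(length(is_pos), loc, sc))
  }
  cb1_enr <- rln(strong, config$cutoff)
  genes <- names(config$p_pos)
  gene_rows <- list()
  for (g in genes) {
    p <- ifelse(strong, config$p_pos[[g]], config$p_pos_weak[[g]] %||% 0)
    positive <- runif(n) < p
    gene_rows[[g]] <- tibble(cell_id = ids, gene = g, positive = positive,
                             enrichment = rln(positive, config$gene_cutoffs[[g]]))
  }
  list(cells = tibble(cell_id = ids, region = config$region,
                      cb1_true = ifelse(strong, "strong", "weak"),
                      cb1_enrichment = cb1_enr),
       genes = dplyr::bind_rows(gene_rows))
}

#' Generate a ground-truthed per-cell ISH enrichment table
#'
#' Emulates the classified cell populations of a multiplex fluorescent ISH
#' quantification: every cell carries a strong/weak CB1 truth label and
#' per-gene positivity truths, with enrichment values sampled from the
#' configured lognormal laws on the appropriate side of each cutoff.
#'
#' @param config An [ish_sim_config()].
#' @return A list of class `ish_sim`:
#'   * `quant`: long [CellQuantTable][classify_cells] input tibble
#'     `cell_id`, `region`, `channel`, `enrichment` (CB1 channel plus one
#'     channel per gene);
#'   * `cells`: truth tibble `cell_id`, `region`, `cb1_true`,
#'     `cb1_enrichment`;
#'   * `positivity`: truth tibble `cell_id`, `gene`, `positive`.
#' @export
#' @examples
#' cfg <- ish_sim_config(region = "HC-CA1", n_cells = 50, p_strong = 1,
#'                       p_pos = c(Necab1 = 0.92, Necab2 = 1), seed = 3)
#' sim <- sim_ish_table(cfg)
#' head(sim$quant)
sim_ish_table <- function(config) {
  if (!inherits(config, "ish_sim_config")) abort("`config` must be an ish_sim_config.")
  set.seed(config$seed)
  truth <- draw_ish_truth(config)
  quant <- dplyr::bind_rows(
    truth$cells %>%
      mutate(channel = config$cb1_channel, enrichment = .data$cb1_enrichment) %>%
      select("cell_id", "region", "channel", "enrichment"),
    truth$genes %>%
      mutate(region = config$region, channel = .data$gene) %>%
      select("cell_id", "region", "channel", "enrichment")
  ) %>% arrange(.data$cell_id, .data$channel)
  structure(list(quant = quant,
                 cells = truth$cells,
                 positivity = select(truth$genes, "cell_id", "gene", "positive"),
                 config = config),
            class = "ish_sim")
}

#' @export
print.ish_sim <- function(x, ...) {
  cat(sprintf("<ish_sim> %d cells, region %s (seed %d)\n",
              nrow(x$cells), x$config$region, x$config$seed))
  invisible(x)
}

#' Render a synthetic 16-bit ISH image with cell ROIs and truth
#'
#' End-to-end fixture for enrichment recovery from pixels: nuclei are
#' rendered as disks whose per-pixel Poisson mean is `background_mean *
#' truth enrichment`, on a Poisson background of mean `background_mean`,
#' so the in-ROI mean over the background mean equals the truth enrichment
#' in expectation. One channel is rendered per call.
#'
#' @param config An [ish_sim_config()] (supplies cell truths and laws).
#' @param width,height Image size in pixels (each >= 64).
#' @param nucleus_radius Disk radius in pixels.
#' @param background_mean Poisson mean of the background, in counts.
#' @param channel Which channel's truth enrichment to render: the CB1
#'   channel (default) or one of the configured gene names.
#' @param max_tries Placement retries per cell before a geometry error.
#' @return A list of class `ish_image_sim`: `image` (integer matrix, 16-bit
#'   range), `rois` (list of [roi()] 24-gons in pixel coordinates, 0-based,
#'   origin top-left), and `truth` (tibble `cell_id`, `cb1_true`,
#'   `enrichment`, `cx`, `cy`).
#' @export
sim_ish_image <- function(config, width = 256, height = 256,
                          nucleus_radius = 8, background_mean = 200,
                          channel = NULL, max_tries = 1000) {
  if (!inherits(config, "ish_sim_config")) abort("`config` must be an ish_sim_config.")
  if (width < 64 || height < 64) abort("Image dimensions must be at least 64 x 64.")
  channel <- channel %||% config$cb1_channel
  set.seed(config$seed)
  truth <- draw_ish_truth(config)
  n <- nrow(truth$cells)
  enr <- if (channel == config$cb1_channel) {
    truth$cells$cb1_enrichment
  } else {
    if (!channel %in% names(config$p_pos)) {
      abort(sprintf("Unknown channel '%s'.", channel))
    }
    dplyr::filter(truth$genes, .data$gene == channel)$enrichment
  }

  # place non-overlapping nuclei away from the border
  margin <- nucleus_radius + 3
  min_sep <- 2 * nucleus_radius + 4
  cx <- numeric(0); cy <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      px <- runif(1, margin, width - margin)
      py <- runif(1, margin, height - margin)
      if (length(cx) == 0 || all((cx - px)^2 + (cy - py)^2 >= min_sep^2)) {
        cx <- c(cx, px); cy <- c(cy, py); placed <- TRUE; break
      }
    }
    if (!placed) {
      abort(sprintf("Could not place %d non-overlapping nuclei after %d tries per cell.",
                    n, max_tries))
    }
  }

  img <- matrix(rpois(height * width, background_mean), nrow = height, ncol = width)
  # pixel (row i, col j) centre is (j - 0.5, i - 0.5) in 0-based image coords
  colc <- matrix(rep(seq_len(width) - 0.5, each = height), nrow = height)
  rowc <- matrix(rep(seq_len(height) - 0.5, times = width), nrow = height)
  rois <- vector("list", n)
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  for (i in seq_len(n)) {
    inside <- (colc - cx[i])^2 + (rowc - cy[i])^2 <= nucleus_radius^2
    img[inside] <- rpois(sum(inside), background_mean * enr[i])
    rois[[i]] <- roi(cx[i] + nucleus_radius * cos(ang),
                     cy[i] + nucleus_radius * sin(ang),
                     id = truth$cells$cell_id[i],
                     cell_id = truth$cells$cell_id[i])
  }
  storage.mode(img) <- "integer"
  img[img > 65535L] <- 65535L
  structure(list(image = img, rois = rois,
                 truth = mutate(truth$cells, enrichment = enr,
                                cx = c(cx, numeric(0))[seq_len(n)],
                                cy = c(cy, numeric(0))[seq_len(n)],
                                channel = channel),
                 config = config),
            class = "ish_image_sim")
}
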