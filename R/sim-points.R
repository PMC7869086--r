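#' Generate a synthetic localization table (CSR or Thomas process)
#'
#' CSR: the point count is Poisson(`intensity` x area) and positions are
#' uniform in the window. Thomas: parents form a Poisson process in the
#' window's bounding box dilated by `4 * offspring_sigma` (so clusters whose
#' parents fall just outside still contribute, avoiding edge thinning);
#' each parent gets a Poisson(`offspring_mean`) number of Gaussian offspring
#' with spread `offspring_sigma`, and offspring falling outside the window
#' are discarded.
#'
#' @param config A [point_process_config()]; coordinates nm, intensities
#'   per um^2.
#' @param channel Channel tag attached to all points.
#' @return A localization tibble `x_nm`, `y_nm`, `z_nm` (0), `channel`
#'   with attribute `window`. May be empty for tiny intensities.
#' @export
#' @examples
#' cfg <- point_process_config(window_rect(0, 2000, 0, 2000), "CSR",
#'                             intensity = 100, seed = 1)
#' nrow(sim_localizations(cfg))  # ~ Poisson(400)
sim_localizations <- function(config, channel = "ch1") {
  if (!inherits(config, "point_process_config")) {
    abort("`config` must be a point_process_config.")
  }
  set.seed(config$seed)
  w <- config$window
  area_um2 <- window_area(w) * 1e-6
  if (config$process == "CSR") {
    n <- rpois(1, config$intensity * area_um2)
    pts <- runif_in_window(n, w)
  } else {
    sig <- config$offspring_sigma
    bb <- window_bbox(w)
    ext <- c(bb["xmin"] - 4 * sig, bb["xmax"] + 4 * sig,
             bb["ymin"] - 4 * sig, bb["ymax"] + 4 * sig)
    ext_area_um2 <- (ext[2] - ext[1]) * (ext[4] - ext[3]) * 1e-6
    n_par <- rpois(1, config$intensity * ext_area_um2)
    px <- runif(n_par, ext[1], ext[2])
    py <- runif(n_par, ext[3], ext[4])
    n_off <- rpois(n_par, config$offspring_mean)
    ox <- rnorm(sum(n_off), rep(px, n_off), sig)
    oy <- rnorm(sum(n_off), rep(py, n_off), sig)
    keep <- point_in_window(ox, oy, w)
    pts <- tibble(x = ox[keep], y = oy[keep])
  }
  out <- tibble(x_nm = pts$x, y_nm = pts$y, z_nm = 0, channel = channel)
  attr(out, "window") <- w
  out
}

#' Generate a synthetic bouton map
#'
#' Assigns each bouton a CA1 layer label by a multinomial draw over
#' `layer_probs`; coordinates are uniform within a per-layer depth band
#' (SO above, SP in the middle, SR below) purely for plotting -- only the
#' layer labels enter the bouton distribution index.
#'
#' @param config A [bouton_sim_config()].
#' @param cell_id Cell identifier attached to all boutons.
#' @return A bouton tibble `cell_id`, `x_um`, `y_um`, `layer`.
#' @export
sim_bouton_map <- function(config, cell_id = "cell1") {
  if (!inherits(config, "bouton_sim_config")) {
    abort("`config` must be a bouton_sim_config.")
  }
  set.seed(config$seed)
  n <- config$n_boutons
  layer <- sample(names(config$layer_probs), n, replace = TRUE,
                  prob = config$layer_probs)
  bands <- list(SO = c(0, 100), SP = c(100, 150), SR = c(150, 350))
  y <- vapply(layer, function(l) runif(1, bands[[l]][1], bands[[l]][2]), numeric(1))
  tibble(cell_id = cell_id, x_um = runif(n, 0, 200), y_um = unname(y),
         layer = layer)
}
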