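# Independent oracles and small fixtures shared across tests.

# Naive O(n^2) Ripley K without edge correction: valid reference whenever all
# circles of radius <= r_max around the points lie inside the window.
naive_k <- function(points, area, r_grid) {
  x <- points$x %||% points$x_nm
  y <- points$y %||% points$y_nm
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  vapply(r_grid, function(r) {
    area / (n * (n - 1)) * sum(d <= r & upper.tri(d)) * 2
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Grubbs decision recomputed directly from the definition: max studentized
# deviate against the t-based critical value.
grubbs_oracle <- function(x, alpha = 0.05) {
  n <- length(x)
  s <- sd(x)
  if (s == 0) return(NA_integer_)
  g <- max(abs(x - mean(x))) / s
  tcrit <- qt(1 - alpha / (2 * n), df = n - 2)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  if (g > gcrit) which.max(abs(x - mean(x))) else NA_integer_
}

# small two-type expression config used by several mining tests
mixture_config <- function(seed, n_cb1 = 100, n_pyr = 200, poisson = TRUE,
                           efficiency = c(0.9, 1.1)) {
  profiles <- dplyr::bind_rows(
    tibble::tibble(cell_type = "cb1_int",
                   gene = c("Cnr1", "Necab1", "Necab2", "Pvalb"),
                   mean = c(50, 25, 30, 0), dispersion = 10),
    tibble::tibble(cell_type = "pyramidal",
                   gene = c("Cnr1", "Necab1", "Necab2", "Pvalb"),
                   mean = c(2, 0.5, 0.5, 0.2), dispersion = 10)
  )
  scrna_sim_config(profiles,
                   n_cells = c(cb1_int = n_cb1, pyramidal = n_pyr),
                   efficiency_range = efficiency,
                   poisson = poisson, seed = seed)
}
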