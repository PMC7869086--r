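make_expr <- function(values, region = "R1") {
  n <- length(values)
  list(expression = tibble::tibble(cell_id = sprintf("c%02d", 1:n), gene = "Cnr1",
                                   count = values),
       cells = tibble::tibble(cell_id = sprintf("c%02d", 1:n), region = region,
                              cell_class = "GABAergic"))
}

test_that("normalization rescales every cell's total to the dataset mean", {
  ex <- tibble::tibble(cell_id = rep(c("a", "b"), each = 2),
                       gene = rep(c("g1", "g2"), 2),
                       count = c(10, 90, 150, 150))
  out <- normalize_expression(ex)
  # totals 100 and 300, Tbar = 200: value 10 in the first cell -> 20
  expect_equal(out$count[out$cell_id == "a" & out$gene == "g1"], 20)
  totals <- dplyr::summarise(dplyr::group_by(out, cell_id), t = sum(count))$t
  expect_true(all(abs(totals - 200) <= 1e-9 * 200))
  # identity when all totals already equal; idempotence
  again <- normalize_expression(out)
  expect_equal(again$count, out$count, tolerance = 1e-12)
  # zero-total cells dropped with a warning; all-zero errors
  ex0 <- dplyr::bind_rows(ex, tibble::tibble(cell_id = "z", gene = c("g1", "g2"),
                                             count = 0))
  expect_warning(out0 <- normalize_expression(ex0), "zero total")
  expect_false("z" %in% out0$cell_id)
  expect_error(normalize_expression(dplyr::mutate(ex, count = 0)), "zero total")
})

test_that("normalization removes the harvesting-efficiency bias", {
  prof <- tibble::tibble(cell_type = "t", gene = sprintf("g%02d", 1:10),
                         mean = c(50, 25, 30, 40, 8, 15, 10, 6, 3, 13),
                         dispersion = 5)
  cfg <- scrna_sim_config(prof, n_cells = c(t = 4000),
                          efficiency_range = c(0.5, 2), seed = 31)
  sim <- sim_expression(cfg)
  norm <- normalize_expression(sim$expression)
  totals <- dplyr::summarise(dplyr::group_by(norm, cell_id), t = sum(count))
  t_bar <- attr(norm, "mean_total")
  # every retained total equals Tbar: the efficiency factor is gone
  expect_true(all(abs(totals$t - t_bar) <= 1e-9 * t_bar))
  # per-gene means match profile truth rescaled to the realized mean total
  got <- dplyr::summarise(dplyr::group_by(norm, gene), m = mean(count))
  expected <- prof$mean / sum(prof$mean) * t_bar
  expect_true(all(abs(got$m[match(prof$gene, got$gene)] - expected) / expected < 0.05))
})

test_that("marker gate uses a strict fraction-of-max inequality per region", {
  ex <- make_expr(c(50, 4, 6, 5))
  kept <- suppressWarnings(
    select_marker_high_cells(ex$expression, ex$cells, marker = "Cnr1",
                             grubbs_iterations = 0))
  # max 50 -> cutoff 5; 4 excluded, 6 included, exactly 5 excluded
  expect_setequal(kept$cell_id, c("c01", "c03"))
})

test_that("gating is per region and respects the class pre-filter", {
  expr <- tibble::tibble(cell_id = sprintf("c%02d", 1:6), gene = "Cnr1",
                         count = c(100, 20, 5, 40, 30, 3))
  meta <- tibble::tibble(cell_id = sprintf("c%02d", 1:6),
                         region = rep(c("A", "B"), each = 3),
                         cell_class = c("GABAergic", "GABAergic", "pyramidal",
                                        "GABAergic", "GABAergic", "GABAergic"))
  kept <- suppressWarnings(
    select_marker_high_cells(expr, meta, grubbs_iterations = 0,
                             class_filter = "GABAergic"))
  # region A: max 100 (c03 excluded by class), cutoff 10 -> c01, c02
  # region B: max 40, cutoff 4 -> c04, c05 in; c06 (3) out
  expect_setequal(kept$cell_id, c("c01", "c02", "c04", "c05"))
})

test_that("identical marker values retain everyone and Grubbs removes none", {
  ex <- make_expr(rep(7, 8))
  kept <- select_marker_high_cells(ex$expression, ex$cells, marker = "Cnr1")
  expect_equal(nrow(kept), 8)
  expect_equal(nrow(attr(kept, "audit")), 0)
})

test_that("Grubbs removal matches the formula oracle and is logged", {
  vals <- c(20, 22, 25, 21, 23, 24, 26, 90)
  ex <- make_expr(vals)
  kept <- select_marker_high_cells(ex$expression, ex$cells, marker = "Cnr1",
                                   grubbs_iterations = 1)
  oidx <- grubbs_oracle(vals[vals > 9])  # gate keeps all (cutoff 9)
  expect_false("c08" %in% kept$cell_id)
  audit <- attr(kept, "audit")
  expect_equal(audit$cell_id, "c08")
  expect_gt(audit$G, audit$G_crit)
  expect_equal(which(vals == 90), oidx)
})

test_that("gate monotonicity and scale invariance hold across random draws", {
  for (s in 1:10) {
    set.seed(s)
    vals <- rpois(30, 20) + 1
    ex <- make_expr(vals)
    k1 <- suppressWarnings(select_marker_high_cells(ex$expression, ex$cells,
                                                    threshold_frac = 0.1,
                                                    grubbs_iterations = 0))
    k2 <- suppressWarnings(select_marker_high_cells(ex$expression, ex$cells,
                                                    threshold_frac = 0.3,
                                                    grubbs_iterations = 0))
    expect_true(all(k2$cell_id %in% k1$cell_id))
    exs <- make_expr(vals * 17.3)
    k3 <- suppressWarnings(select_marker_high_cells(exs$expression, exs$cells,
                                                    threshold_frac = 0.1,
                                                    grubbs_iterations = 0))
    expect_setequal(k1$cell_id, k3$cell_id)
  }
})

test_that("candidate ranking orders by detection fraction with documented ties", {
  expr <- tidyr::expand_grid(cell_id = c("a", "b", "c"),
                             gene = c("g1", "g2", "g3", "g4")) %>%
    dplyr::mutate(count = dplyr::case_when(
      gene == "g1" ~ 5,                      # detected everywhere
      gene == "g2" ~ c(2, 0, 0)[match(cell_id, c("a", "b", "c"))],
      gene == "g3" ~ 0,                      # absent
      gene == "g4" ~ 9                       # detected everywhere, higher mean
    ))
  rk <- rank_candidate_genes(expr, c("a", "b", "c"), c("g1", "g2", "g3", "g4"))
  expect_equal(rk$gene[rk$rank == 1], "g4")  # ties on fraction broken by mean
  expect_equal(rk$gene[rk$rank == 2], "g1")
  expect_equal(rk$detection_fraction[rk$gene == "g3"], 0)
  expect_equal(rk$rank[rk$gene == "g3"], 4)
  expect_error(rank_candidate_genes(expr, c("a"), character(0)), "empty")
  expect_error(rank_candidate_genes(expr, character(0), "g1"), "empty")
})

test_that("marker genes outrank decoys in a ground-truthed screen", {
  hits <- 0
  for (s in 1:20) {
    decoys <- sprintf("decoy%02d", 1:48)
    prof <- dplyr::bind_rows(
      tibble::tibble(cell_type = "cb1_int",
                     gene = c("Necab1", "Necab2", decoys),
                     mean = c(25, 30, rep(0.3, 48)), dispersion = 5),
      tibble::tibble(cell_type = "pyramidal",
                     gene = c("Necab1", "Necab2", decoys),
                     mean = c(0.3, 0.3, rep(0.3, 48)), dispersion = 5)
    )
    cfg <- scrna_sim_config(prof, n_cells = c(cb1_int = 60, pyramidal = 60),
                            seed = 100 + s)
    sim <- sim_expression(cfg)
    norm <- suppressWarnings(normalize_expression(sim$expression))
    gated <- sim$cells$cell_id[sim$cells$cell_type == "cb1_int"]
    rk <- rank_candidate_genes(norm, gated, c("Necab1", "Necab2", decoys))
    if (all(rk$rank[rk$gene %in% c("Necab1", "Necab2")] <= 2)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("Spearman correlations hit the exact limits and the expected signs", {
  expr <- tibble::tibble(
    cell_id = rep(sprintf("c%d", 1:8), times = 3),
    gene = rep(c("A", "B", "C"), each = 8),
    count = c(1:8, (1:8)^2, 8:1)  # B monotone in A, C reversed
  )
  res <- correlate_genes(expr, "A", c("B", "C"))
  expect_equal(res$rho[res$gene_b == "B"], 1)
  expect_equal(res$rho[res$gene_b == "C"], -1)
  expect_equal(res$p_value, c(0, 0))
  expect_error(correlate_genes(expr, "A", "B", cells = c("c1", "c2")), "at least 3")
  # zero variance flagged as missing
  expr0 <- dplyr::mutate(expr, count = ifelse(gene == "C", 5, count))
  expect_warning(res0 <- correlate_genes(expr0, "A", "C"), "Zero-variance")
  expect_true(is.na(res0$rho))
})

test_that("Pvalb anti-correlates with Necab genes in mixed populations", {
  neg <- 0
  for (s in 1:20) {
    prof <- dplyr::bind_rows(
      tibble::tibble(cell_type = "cb1_int", gene = c("Necab1", "Pvalb"),
                     mean = c(25, 0.1), dispersion = 5),
      tibble::tibble(cell_type = "pvalb_int", gene = c("Necab1", "Pvalb"),
                     mean = c(0.3, 60), dispersion = 5)
    )
    cfg <- scrna_sim_config(prof, n_cells = c(cb1_int = 60, pvalb_int = 60),
                            seed = 300 + s)
    sim <- sim_expression(cfg)
    res <- correlate_genes(sim$expression, "Necab1", "Pvalb")
    if (res$rho < 0) neg <- neg + 1
  }
  expect_gte(neg, 19)
})
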