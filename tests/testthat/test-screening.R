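make_summaries <- function(deltas_by_gene, b_deltas_by_gene = NULL) {
  rows <- do.call(rbind, lapply(names(deltas_by_gene), function(gene) {
    dg <- deltas_by_gene[[gene]]
    db <- if (is.null(b_deltas_by_gene)) rep(0.1, length(dg)) else
      b_deltas_by_gene[[gene]]
    data.frame(
      line_id = paste0(gene, "_E", seq_along(dg)), gene_id = gene,
      event_id = paste0("E", seq_along(dg)), material_class = "OE",
      trait = "normal kernel number", year = 2018,
      g = 10 + dg, b = db, nonlinear = 0,
      delta_g = dg, delta_b = db, stringsAsFactors = FALSE
    )
  }))
  wt <- data.frame(line_id = "WT", gene_id = "WT", event_id = "E0",
                   material_class = "WT", trait = "normal kernel number",
                   year = 2018, g = 10, b = 0, nonlinear = 0,
                   delta_g = 0, delta_b = 0, stringsAsFactors = FALSE)
  rbind(rows, wt)
}

test_that("quadrant classification follows delta signs with ties to the plus side", {
  s <- make_summaries(list(A = c(2), B = c(-1), C = c(1), D = c(-2)),
                      list(A = c(0.1), B = c(-0.1), C = c(-0.3), D = c(0.2)))
  out <- classify_quadrants(s)
  lab <- stats::setNames(out$quadrant, out$line_id)
  expect_equal(unname(lab["A_E1"]), "g+b+")
  expect_equal(unname(lab["B_E1"]), "g-b-")
  expect_equal(unname(lab["C_E1"]), "g+b-")
  expect_equal(unname(lab["D_E1"]), "g-b+")
  # the WT itself is an exact tie, labelled g+b+ and flagged
  expect_equal(unname(lab["WT"]), "g+b+")
  expect_true(out$tie[out$line_id == "WT"])
  expect_false(any(out$tie[out$line_id != "WT"]))
})

test_that("per-year selection applies the >= 3 events rule with strict inequality", {
  s <- make_summaries(list(
    keep = c(1, 2, 0.5),      # 3 events above WT
    drop = c(1, 2, -0.5),     # only 2 above
    edge = c(1, 2, 0)         # exact tie is not strictly above
  ))
  res <- select_candidates_per_year(s, "normal kernel number")
  expect_equal(res$genes, "keep")
  tab <- res$table[order(res$table$gene_id), ]
  expect_equal(tab$n_events, c(3, 3, 3))
  expect_equal(tab$n_events_g_above_wt[tab$gene_id == "edge"], 2)
  expect_true(all(tab$n_events_gb_above_wt <= tab$n_events_g_above_wt))
  expect_true(all(tab$n_events_g_above_wt <= tab$n_events))
})

test_that("combining years partitions the union into disjoint categories", {
  res <- combine_years(c("a", "b", "c"), c("b", "d", "e", "f"))
  expect_equal(unname(res$sizes["both_years"]), 1)
  expect_equal(unname(res$sizes["first_year_only"]), 2)
  expect_equal(unname(res$sizes["second_year_only"]), 3)
  expect_equal(unname(res$sizes["total"]), 6)
  expect_equal(sum(res$sizes[1:3]), unname(res$sizes["total"]))

  disjoint <- combine_years(c("a", "b", "c"), c("d", "e", "f", "g"))
  expect_equal(unname(disjoint$sizes["total"]), 7)
  expect_equal(unname(disjoint$sizes["both_years"]), 0)

  same <- combine_years(c("a", "b"), c("a", "b"))
  expect_equal(unname(same$sizes["both_years"]), 2)
  expect_equal(unname(same$sizes["first_year_only"]), 0)
  expect_equal(unname(same$sizes["second_year_only"]), 0)
})

test_that("advantage filter removes marginal genes and is the identity at zero", {
  s <- make_summaries(list(
    strong = c(8, 9, 10),
    weak = c(0.01, 0.02, 0.03)
  ))
  cand <- c("strong", "weak")
  all_kept <- advantage_filter(s, cand, "normal kernel number",
                               min_delta_g_sd = 0)
  expect_equal(all_kept$genes, cand)
  filt <- advantage_filter(s, cand, "normal kernel number",
                           min_delta_g_sd = 0.25)
  expect_equal(filt$genes, "strong")
  expect_equal(unname(filt$margins["strong"]), 9)
})

test_that("screening is monotone in both thresholds", {
  sim <- planted_signal_experiment(n_genes = 60, n_planted = 8, seed = 55)
  fit <- fit_fw_ols(sim$records, "normal kernel number")
  s <- wt_relative(line_plasticity(fit, sim$records, year = 2018))
  prev <- NULL
  for (me in 1:4) {
    genes <- select_candidates_per_year(s, "normal kernel number",
                                        min_events = me)$genes
    if (!is.null(prev)) expect_true(all(genes %in% prev))
    prev <- genes
  }
  base <- select_candidates_per_year(s, "normal kernel number")$genes
  prev <- NULL
  for (th in c(0, 0.1, 0.25, 0.5, 1)) {
    genes <- advantage_filter(s, base, "normal kernel number",
                              min_delta_g_sd = th)$genes
    if (!is.null(prev)) expect_true(all(genes %in% prev))
    prev <- genes
  }
})

test_that("planted signal genes are recovered end to end", {
  sim <- planted_signal_experiment(n_genes = 100, n_planted = 10, seed = 19)
  fit <- fit_fw_ols(sim$records, "normal kernel number")
  s <- wt_relative(line_plasticity(fit, sim$records, year = 2018))
  sel <- select_candidates_per_year(s, "normal kernel number")
  adv <- advantage_filter(s, sel$genes, "normal kernel number")
  background <- setdiff(unique(s$gene_id[s$line_id != "WT"]), sim$planted)
  expect_gte(mean(sim$planted %in% adv$genes), 0.9)
  expect_gte(mean(!background %in% adv$genes), 0.9)
})

test_that("supporting trait check reports deltas and flags negatives", {
  s <- rbind(
    make_summaries(list(A = c(2, 3, 4), B = c(1, 1, 1))),
    within(make_summaries(list(A = c(1, 1, 1), B = c(-2, -2, -2))),
           trait <- "ear length")
  )
  rep <- supporting_trait_check(s, c("A", "B"), traits = "ear length")
  expect_true(all(rep$evaluated))
  expect_false(rep$flagged[rep$gene_id == "A"])
  expect_true(rep$flagged[rep$gene_id == "B"])

  # missing fit -> not evaluated, not flagged
  rep2 <- supporting_trait_check(s, c("A", "B"),
                                 traits = "number of kernels per row")
  expect_false(any(rep2$evaluated))
  expect_false(any(rep2$flagged))
})

test_that("correlated component traits move with the primary trait", {
  # kernel number gain driven by kernels-per-row gain: simulate the
  # component trait and derive kernel number from it
  d <- population_design(10, 3, years = 2018)
  sim <- simulate_dataset(d, truth_config(mu = 30, sd_g = 3, sd_h = 3,
                                          sigma = 0.5), seed = 7,
                          trait_name = "number of kernels per row")
  kpr <- sim$records
  kn <- kpr
  kn$trait <- "normal kernel number"
  kn$value <- 16 * kpr$value # 16 rows per ear
  records <- rbind(kpr, kn)
  fits <- lapply(c("number of kernels per row", "normal kernel number"),
                 function(tr) fit_fw_ols(records, tr))
  s <- wt_relative(do.call(rbind, lapply(fits, line_plasticity,
                                         records = records, year = 2018)))
  by_line <- split(s, s$line_id)
  for (d2 in by_line) {
    expect_equal(sign(d2$delta_g[1]), sign(d2$delta_g[2]))
  }
})
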