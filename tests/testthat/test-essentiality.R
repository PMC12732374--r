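# Helper: an expression matrix marking given genes expressed in a chosen
# number of models (log2(TPM+1) scale; expressed = TPM >= 1 -> >= 1.0).
make_expr <- function(genes, models, expressed_counts) {
  v <- matrix(0, length(genes), length(models),
              dimnames = list(genes, models))
  for (i in seq_along(genes)) {
    if (expressed_counts[i] > 0) v[i, seq_len(expressed_counts[i])] <- 5
  }
  df <- as.data.frame(t(v))
  names(df) <- genes
  df <- cbind(ModelID = models, df)
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path)
  read_expression_matrix(path, scale = "log2tpm")
}

test_that("expression filter retains genes expressed in at least 5% of models", {
  models <- sprintf("M%02d", 1:28)
  dep <- make_dep(matrix(0.5, 3, 28), genes = c("g2of28", "g1of28", "gSilent"),
                  models = models)
  expr <- make_expr(c("g2of28", "g1of28", "gSilent"), models, c(2L, 1L, 0L))
  kept <- filter_by_expression(dep, expr, filter_config())
  expect_equal(rownames(kept), "g2of28")       # 2/28 = 7.1% >= 5%
  # stricter reading: tolerate at most 5% silent models
  strict <- filter_by_expression(dep, expr,
                                 filter_config(expression_rule = "silent_max"))
  expect_equal(nrow(strict), 0L)
  # genes absent from the expression matrix are dropped with a message
  expr2 <- make_expr(c("g2of28", "g1of28"), models, c(28L, 28L))
  expect_message(filter_by_expression(dep, expr2, filter_config()),
                 "absent from the expression")
  # disjoint model sets are an error
  expr3 <- make_expr("g2of28", sprintf("X%02d", 1:4), 4L)
  expect_error(filter_by_expression(dep, expr3, filter_config()),
               "no models shared")
})

test_that("missingness filter drops genes with > 20% missing scores", {
  v <- matrix(0.4, 3, 28)
  v[1, 1:6] <- NA   # 6/28 = 21.4% > 20% -> dropped
  v[2, 1:5] <- NA   # 5/28 = 17.9% -> retained
  dep <- make_dep(v, genes = c("gMiss6", "gMiss5", "gFull"))
  kept <- filter_by_missingness(dep, filter_config())
  expect_setequal(rownames(kept), c("gMiss5", "gFull"))
})

test_that("per-gene summaries use non-missing medians and a strict cutoff", {
  v <- matrix(c(0.9, 0.8, 0.1,
                0.5, 0.5, NA,
                NA, NA, NA), 3, 3, byrow = TRUE)
  dep <- make_dep(v, genes = c("gA", "gBound", "gEmpty"))
  s <- summarize_gene(dep, "gA", colnames(dep))
  expect_equal(s$median_dependency, 0.8)
  expect_equal(s$fraction_essential, 2 / 3)
  expect_equal(s$n_scored, 3L)
  # values at the cutoff do not count as essential (strictly greater)
  sb <- summarize_gene(dep, "gBound", colnames(dep))
  expect_equal(sb$fraction_essential, 0)
  expect_equal(sb$n_scored, 2L)
  # even-count median is the mean of the central pair
  expect_equal(summarize_gene(dep, "gA", colnames(dep)[1:2])$median_dependency,
               0.85)
  expect_error(summarize_gene(dep, "gEmpty", colnames(dep)), "no scored")
})

test_that("essential calls honor the cutoff, the essentiality floor and the common-essential exclusion", {
  ann <- tibble::tibble(model_id = sprintf("M%02d", 1:10),
                        subtype = rep(c("iCCA", "eCCA"), c(7, 3)),
                        display_name = sprintf("M%02d", 1:10))
  v <- rbind(rep(0.9, 10),             # planted essential everywhere
             rep(0.8, 10),             # high but on the common list
             c(rep(0.9, 1), rep(0.05, 9)),  # high in 1/10 lines: below 10% floor
             rep(0.1, 10))             # background
  dep <- make_dep(v, genes = c("gEss", "gCommon", "gRare", "gBg"),
                  models = ann$model_id)
  rec <- call_essential(dep, ann, "iCCA", gene_set("ce", "gCommon"))
  expect_equal(rec$gene[rec$is_essential], "gEss")
  expect_true(rec$is_common_essential[rec$gene == "gCommon"])
  expect_false(rec$is_essential[rec$gene == "gCommon"])
  # records sorted by descending median dependency
  expect_equal(rec$gene[1], "gEss")
  expect_error(call_essential(dep, ann, "noSuchSubtype", gene_set("ce", "x")),
               "no models annotated")
})

test_that("planted subtype-essential genes are called exactly on a synthetic screen", {
  cfg <- simulation_config(n_genes = 100, n_pan_essential = 5,
                           n_i_essential = 10, n_e_essential = 0,
                           n_shared_essential = 0, n_fsg_decoys = 10,
                           seed = 101L)
  sim <- simulate_screen(cfg)
  dep <- filter_by_missingness(
    filter_by_expression(sim$dependency, sim$expression, filter_config()),
    filter_config())
  rec <- call_essential(dep, sim$annotations, "iCCA", sim$common_essential)
  planted <- sim$truth$gene[sim$truth$role == "i_essential"]
  expect_setequal(rec$gene[rec$is_essential], planted)
})

test_that("raising thresholds never enlarges the essential set", {
  sim <- simulate_screen(simulation_config(seed = 5L))
  base_cfg <- filter_config()
  rec0 <- call_essential(sim$dependency, sim$annotations, "iCCA",
                         sim$common_essential, base_cfg)
  set0 <- rec0$gene[rec0$is_essential]
  for (cfg in list(filter_config(essential_cutoff = 0.7),
                   filter_config(min_fraction_essential = 0.5))) {
    rec <- call_essential(sim$dependency, sim$annotations, "iCCA",
                          sim$common_essential, cfg)
    expect_true(all(rec$gene[rec$is_essential] %in% set0))
  }
})

test_that("expression and missingness filters commute and summaries ignore model order", {
  sim <- simulate_screen(simulation_config(n_genes = 120, seed = 9L))
  cfg <- filter_config()
  a <- filter_by_missingness(filter_by_expression(sim$dependency,
                                                  sim$expression, cfg), cfg)
  b <- filter_by_expression(filter_by_missingness(sim$dependency, cfg),
                            sim$expression, cfg)
  expect_setequal(rownames(a), rownames(b))

  models <- colnames(sim$dependency)
  g <- rownames(sim$dependency)[1]
  s1 <- summarize_gene(sim$dependency, g, models)
  s2 <- summarize_gene(sim$dependency, g, sample(models))
  expect_equal(s1, s2)
})

test_that("the published summary table partitions into 19/16 essential FSGs, 9 shared, 10+7 subtype-only", {
  part <- partition_essential_fsgs(fsg_table1())
  expect_equal(part$n_icca, 19L)
  expect_equal(part$n_ecca, 16L)
  expect_equal(part$n_shared, 9L)
  expect_equal(part$n_icca_only, 10L)
  expect_equal(part$n_ecca_only, 7L)
  expect_true(all(c("GPX4", "CHMP5") %in% part$icca_only))
  expect_true(all(c("PARL", "ZMYND8") %in% part$ecca_only))
  expect_true("SLC3A2" %in% part$shared)
  # under the strictly-greater rule the genes printing exactly 0.5 drop out
  strict <- partition_essential_fsgs(fsg_table1(), comparison = ">")
  expect_equal(strict$n_icca, 18L)  # ARF6 prints a rounded 0.50
})

test_that("FSG intersection flags membership and the filtered view respects both flags", {
  ann <- tibble::tibble(model_id = sprintf("M%d", 1:4),
                        subtype = rep("iCCA", 4), display_name = sprintf("M%d", 1:4))
  dep <- make_dep(rbind(rep(0.9, 4), rep(0.9, 4), rep(0.1, 4)),
                  genes = c("gFsgEss", "gEssOnly", "gFsgBg"),
                  models = ann$model_id)
  rec <- intersect_fsg(call_essential(dep, ann, "iCCA", gene_set("ce", "none")),
                       gene_set("fsg", c("gFsgEss", "gFsgBg")))
  view <- essential_fsgs(rec)
  expect_equal(view$gene, "gFsgEss")
  expect_equal(essential_fsgs(intersect_fsg(rec, gene_set("fsg", "ZZZ")))$gene,
               character(0))
  cats <- scatter_categories(rec)
  expect_equal(cats$category[match(c("gFsgEss", "gEssOnly", "gFsgBg"), cats$gene)],
               c("essential_fsg", "essential", "below_threshold"))
})
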