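test_that("exact rank-sum p matches hand enumeration on the canonical cases", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5), mode = "exact")
  expect_equal(w$p_value, 0.2)   # only the observed split attains rank sum 6
  expect_equal(w$p_mode, "exact")
  # symmetric null: identical multisets give p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2), c(2, 1, 2), mode = "exact")$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  expect_error(wilcoxon_rank_sum(c(1, NA), c(2, 3)), "missing values")
})

test_that("exact p equals the full-enumeration oracle, with and without ties", {
  set.seed(2024)
  for (i in 1:60) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:(12 - n1), 1)
    pair <- if (i %% 2 == 0) {
      random_tied_pair(n1, n2)
    } else {
      list(x = rnorm(n1), y = rnorm(n2))
    }
    p_impl <- wilcoxon_rank_sum(pair$x, pair$y, mode = "exact")$p_value
    expect_equal(p_impl, oracle_wilcoxon_p(pair$x, pair$y), tolerance = 1e-12)
  }
})

test_that("exact p agrees with stats::wilcox.test on untied samples", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1))
    expect_equal(wilcoxon_rank_sum(x, y, mode = "exact")$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("normal approximation tracks the exact test on the 22-vs-6 design", {
  set.seed(77)
  for (i in 1:25) {
    x <- runif(22); y <- runif(6)
    pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
    pn <- wilcoxon_rank_sum(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
  # auto mode: choose(28, 6) = 376740 exceeds the default cap
  expect_equal(wilcoxon_rank_sum(runif(22), runif(6))$p_mode, "normal-approx")
  expect_equal(wilcoxon_rank_sum(runif(22), runif(6),
                                 enumeration_cap = 4e5)$p_mode, "exact")
})

test_that("rank-sum p is invariant under strictly increasing transforms", {
  set.seed(8)
  x <- runif(6); y <- runif(5)
  p0 <- wilcoxon_rank_sum(x, y, mode = "exact")$p_value
  for (f in list(function(v) v^3, function(v) exp(4 * v), function(v) log(v + 1))) {
    expect_equal(wilcoxon_rank_sum(f(x), f(y), mode = "exact")$p_value, p0)
  }
})

test_that("Hedges' g follows the pooled-SD formula with small-sample correction", {
  h <- hedges_g(c(0.9, 0.8, 0.7), c(0.2, 0.3))
  expect_equal(h$correction_j, 1 - 3 / 11)
  expect_equal(h$pooled_sd, sqrt(0.025 / 3), tolerance = 1e-12)
  expect_equal(h$g, 4.3818, tolerance = 1e-4)
  # J for the 22-vs-6 design
  expect_equal(hedges_g(rnorm(22), rnorm(6))$correction_j, 1 - 3 / 103)
  # identical groups
  expect_equal(hedges_g(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6))$g, 0)
  # degenerate inputs
  expect_equal(hedges_g(c(1, 1), c(1, 1))$g, 0)
  expect_error(hedges_g(c(1, 1), c(2, 2)), "degenerate")
  expect_error(hedges_g(1, c(2, 3)), "at least 2")
})

test_that("g is shift/scale invariant and antisymmetric; sign follows the mean difference", {
  set.seed(12)
  x <- runif(9); y <- runif(5)
  g0 <- hedges_g(x, y)$g
  expect_equal(hedges_g(x + 3, y + 3)$g, g0)
  expect_equal(hedges_g(2.5 * x, 2.5 * y)$g, g0)
  expect_equal(hedges_g(y, x)$g, -g0)
  expect_equal(sign(g0), sign(mean(x) - mean(y)))
})

test_that("differential essentiality labels planted directions and records skipped genes", {
  ann <- tibble::tibble(model_id = sprintf("M%02d", 1:12),
                        subtype = rep(c("iCCA", "eCCA"), c(8, 4)),
                        display_name = sprintf("M%02d", 1:12))
  set.seed(3)
  v <- rbind(c(runif(8, 0.75, 0.9), runif(4, 0.1, 0.25)),   # iCCA-selective
             c(runif(8, 0.1, 0.25), runif(4, 0.75, 0.9)),   # eCCA-selective
             c(0.30, 0.40, 0.35, 0.45, 0.32, 0.42, 0.37, 0.47,
               0.31, 0.41, 0.36, 0.46),                     # no difference
             c(0.9, rep(NA, 7), 0.8, 0.7, 0.6, 0.5))        # 1 scored iCCA model
  dep <- make_dep(v, genes = c("gI", "gE", "gNull", "gSparse"),
                  models = ann$model_id)
  res <- differential_essentiality(dep, ann, cfg = volcano_config())
  expect_equal(res$selectivity[res$gene == "gI"], "iCCA-selective")
  expect_equal(res$selectivity[res$gene == "gE"], "eCCA-selective")
  expect_equal(res$selectivity[res$gene == "gNull"], "none")
  skipped <- attr(res, "skipped")
  expect_equal(skipped$gene, "gSparse")
  expect_match(skipped$reason, "fewer than 2")
  expect_false("gSparse" %in% res$gene)
  # sorted by ascending p and BH q-values present
  expect_equal(res$p_value, sort(res$p_value))
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"))
  # swapping group labels negates g and preserves p
  swapped <- differential_essentiality(dep, ann, group_i = "eCCA",
                                       group_e = "iCCA")
  m <- match(res$gene, swapped$gene)
  expect_equal(swapped$g[m], -res$g)
  expect_equal(swapped$p_value[m], res$p_value)
})

test_that("volcano classification applies >= to |g| and strict < to p", {
  cmp <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        g = c(0.8, 2, -0.9, 0.5),
                        p_value = c(0.049, 0.06, 0.01, 0.001),
                        q_value = stats::p.adjust(c(0.049, 0.06, 0.01, 0.001), "BH"),
                        p_mode = "exact")
  v <- classify_volcano(cmp)
  expect_equal(v$selectivity, c("iCCA-selective", "none", "eCCA-selective", "none"))
  expect_equal(v$neg_log10_p, -log10(cmp$p_value))
  counts <- attr(v, "class_counts")
  expect_equal(as.integer(counts[c("iCCA-selective", "eCCA-selective", "none")]),
               c(1L, 1L, 2L))
  # empty input
  v0 <- classify_volcano(cmp[0, ])
  expect_equal(nrow(v0), 0L)
})

test_that("planted differential genes are recovered exactly in a 200-gene screen", {
  cfg <- simulation_config(n_genes = 200, n_pan_essential = 10,
                           n_i_essential = 2, n_e_essential = 2,
                           n_shared_essential = 0, n_fsg_decoys = 20)
  hits <- 0L
  for (seed in 1:20) {
    cfg$seed <- seed
    out <- run_synthetic_pipeline(cfg)
    sel <- out$differential$comparisons
    called_i <- sel$gene[sel$selectivity == "iCCA-selective"]
    called_e <- sel$gene[sel$selectivity == "eCCA-selective"]
    truth_i <- out$sim$truth$gene[out$sim$truth$role == "i_essential"]
    truth_e <- out$sim$truth$gene[out$sim$truth$role == "e_essential"]
    if (setequal(called_i, truth_i) && setequal(called_e, truth_e)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 18L)
})
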