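# Per-gene two-group comparison between subtypes: exact Wilcoxon rank-sum
# p-value, Hedges' g with small-sample bias correction, and joint
# effect-size / significance classification for volcano-style reporting.

#' Volcano classification configuration
#'
#' @param g_threshold Minimum absolute Hedges' g for a selective call
#'   (default 0.8; the comparison is `>=`).
#' @param p_threshold Maximum p-value for a selective call (default 0.05;
#'   the comparison is strict `<`).
#' @param test_mode Wilcoxon mode passed to [wilcoxon_rank_sum()].
#' @param enumeration_cap Largest number of group assignments for which
#'   `"auto"` uses the exact test (default 200000). The 22-vs-6 design has
#'   choose(28, 6) = 376740 assignments, so raising the cap to 4e5 makes
#'   the default design exact.
#' @return A `volcano_config` list.
#' @export
volcano_config <- function(g_threshold = 0.8, p_threshold = 0.05,
                           test_mode = c("auto", "exact", "normal"),
                           enumeration_cap = 200000) {
  test_mode <- match.arg(test_mode)
  if (g_threshold <= 0) abort("g_threshold must be > 0")
  if (p_threshold <= 0 || p_threshold >= 1) abort("p_threshold must lie in (0, 1)")
  structure(list(g_threshold = g_threshold, p_threshold = p_threshold,
                 test_mode = test_mode, enumeration_cap = enumeration_cap),
            class = "volcano_config")
}

# The exact null distribution depends only on (n1, multiset of ranks),
# so repeated tests on the same design (e.g. thousands of untied genes
# at 22 vs 6) reuse one enumeration.
.rank_sum_cache <- new.env(parent = emptyenv())

# Exact null distribution of the (doubled) rank sum of group 1 under
# random assignment of the pooled mid-ranks: a generating-function count
# over all choose(N, n1) assignments. r2 holds mid-ranks doubled to
# integers. Returns P(sum of doubled ranks == s) for s = 0..sum(r2) as a
# vector of counts.
rank_sum_counts <- function(r2, n1) {
  key <- paste0(n1, ":", paste(sort(r2), collapse = ","))
  hit <- .rank_sum_cache[[key]]
  if (!is.null(hit)) return(hit)
  total <- sum(r2)
  # counts[j + 1, s + 1] = number of j-subsets of the items seen so far
  # with doubled-rank sum s
  counts <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  counts[1L, 1L] <- 1
  for (r in r2) {
    jmax <- n1
    for (j in jmax:1L) {
      counts[j + 1L, (r + 1L):(total + 1L)] <-
        counts[j + 1L, (r + 1L):(total + 1L)] + counts[j, 1L:(total + 1L - r)]
    }
  }
  out <- counts[n1 + 1L, ]
  if (length(ls(.rank_sum_cache)) >= 256L) {
    rm(list = ls(.rank_sum_cache), envir = .rank_sum_cache)
  }
  .rank_sum_cache[[key]] <- out
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact mode enumerates the null distribution of the rank sum over all
#' `choose(n_x + n_y, n_x)` group assignments, with mid-ranks for ties, via
#' a generating-function count (polynomial time, exactly equivalent to
#' full enumeration). The two-sided p is twice the smaller tail,
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`. Normal mode uses the
#' large-sample approximation with tie-corrected variance and continuity
#' correction. `"auto"` chooses exact when the number of assignments is at
#' most `enumeration_cap`, else normal.
#'
#' @param x,y Numeric vectors (no missing values; remove them upstream).
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @param enumeration_cap Assignment-count cap for `"auto"`.
#' @return List: `p_value`, `p_mode` (`"exact"` or `"normal-approx"`),
#'   `statistic` (rank sum of `x`).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal"),
                              enumeration_cap = 200000) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) abort("missing values must be removed upstream")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  ranks <- rank(c(x, y))
  W <- sum(ranks[seq_len(n1)])
  if (mode == "auto") {
    mode <- if (choose(N, n1) <= enumeration_cap) "exact" else "normal"
  }
  if (mode == "exact") {
    r2 <- as.integer(round(2 * ranks))
    counts <- rank_sum_counts(r2, n1)
    total <- choose(N, n1)
    w2 <- as.integer(round(2 * W))
    p_lo <- sum(counts[seq_len(w2 + 1L)]) / total
    p_hi <- sum(counts[(w2 + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    list(p_value = p, p_mode = "exact", statistic = W)
  } else {
    mu <- n1 * (N + 1) / 2
    tie_sizes <- table(ranks)
    tie_adj <- sum(tie_sizes^3 - tie_sizes)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_adj / (N * (N - 1)))
    if (sigma2 <= 0) {
      return(list(p_value = 1, p_mode = "normal-approx", statistic = W))
    }
    d <- W - mu
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    list(p_value = p, p_mode = "normal-approx", statistic = W)
  }
}

#' Hedges' g standardized effect size
#'
#' Standardized mean difference `(mean(x) - mean(y)) / sp` with the pooled
#' standard deviation `sp = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`
#' (sample SDs, n-1 denominators), multiplied by the small-sample bias
#' correction `J = 1 - 3 / (4 (n1 + n2) - 9)`. With the subtype
#' convention used here, positive g means greater essentiality in the
#' first (iCCA) group.
#'
#' @param x,y Numeric vectors, each of length >= 2, no missing values.
#' @return List: `n_i`, `n_e`, `mean_i`, `mean_e`, `sd_i`, `sd_e`,
#'   `pooled_sd`, `correction_j`, `g`. When both groups are constant and
#'   equal, `g = 0`; constant pooled values with unequal means are a
#'   degenerate input and raise an error.
#' @export
hedges_g <- function(x, y) {
  if (anyNA(x) || anyNA(y)) abort("missing values must be removed upstream")
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) abort("each group needs at least 2 values")
  m1 <- mean(x); m2 <- mean(y)
  s1 <- sd(x); s2 <- sd(y)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  if (sp == 0) {
    if (isTRUE(all.equal(m1, m2))) {
      g <- 0
    } else {
      abort("zero pooled SD with unequal means: degenerate input")
    }
  } else {
    g <- J * (m1 - m2) / sp
  }
  list(n_i = n1, n_e = n2, mean_i = m1, mean_e = m2, sd_i = s1, sd_e = s2,
       pooled_sd = sp, correction_j = J, g = g)
}

selectivity_label <- function(g, p, cfg, group_i = "iCCA", group_e = "eCCA") {
  ifelse(!is.na(g) & !is.na(p) & abs(g) >= cfg$g_threshold & p < cfg$p_threshold,
         ifelse(g > 0, paste0(group_i, "-selective"),
                paste0(group_e, "-selective")),
         "none")
}

#' Per-gene differential essentiality between two subtypes
#'
#' For each candidate gene, compares the non-missing dependency scores of
#' the two subtype groups with [wilcoxon_rank_sum()] and [hedges_g()],
#' assigns a selectivity label from the joint effect-size/significance
#' rule, and adds Benjamini-Hochberg q-values across the tested genes.
#' Genes with fewer than two scored models in either group are recorded as
#' skipped (attribute `"skipped"`), not silently dropped.
#'
#' @param dep A `dep_matrix`.
#' @param annotations Model-annotation tibble.
#' @param genes Candidate gene symbols (default: all genes in `dep`). The
#'   intended universe is the union of the per-subtype essential FSG
#'   lists; passing all genes is an exploratory mode.
#' @param cfg A [volcano_config()].
#' @param group_i,group_e Subtype labels for the first (positive-g) and
#'   second group.
#' @return Tibble sorted by ascending p-value: `gene`, group sizes, means,
#'   SDs, `pooled_sd`, `correction_j`, `g`, `p_value`, `q_value`,
#'   `p_mode`, `selectivity`. Attribute `"skipped"` holds a tibble of
#'   skipped genes with reasons.
#' @export
differential_essentiality <- function(dep, annotations, genes = NULL,
                                      cfg = volcano_config(),
                                      group_i = "iCCA", group_e = "eCCA") {
  genes <- genes %||% rownames(dep)
  missing_genes <- setdiff(genes, rownames(dep))
  genes <- intersect(genes, rownames(dep))
  mod_i <- intersect(annotations$model_id[annotations$subtype == group_i],
                     colnames(dep))
  mod_e <- intersect(annotations$model_id[annotations$subtype == group_e],
                     colnames(dep))
  if (length(mod_i) == 0L || length(mod_e) == 0L) {
    abort("both subtype groups must contain at least one model")
  }
  m <- unclass(dep)
  rows <- vector("list", length(genes))
  skipped <- list()
  for (idx in seq_along(genes)) {
    gname <- genes[idx]
    xi <- m[gname, mod_i]; xi <- xi[!is.na(xi)]
    xe <- m[gname, mod_e]; xe <- xe[!is.na(xe)]
    if (length(xi) < 2L || length(xe) < 2L) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        gene = gname,
        reason = sprintf("fewer than 2 scored models in a group (%d vs %d)",
                         length(xi), length(xe)))
      next
    }
    es <- hedges_g(xi, xe)
    wt <- wilcoxon_rank_sum(xi, xe, mode = cfg$test_mode,
                            enumeration_cap = cfg$enumeration_cap)
    rows[[idx]] <- tibble::tibble(
      gene = gname, n_i = es$n_i, n_e = es$n_e,
      mean_i = es$mean_i, mean_e = es$mean_e,
      sd_i = es$sd_i, sd_e = es$sd_e,
      pooled_sd = es$pooled_sd, correction_j = es$correction_j,
      g = es$g, p_value = wt$p_value, p_mode = wt$p_mode)
  }
  for (gname in missing_genes) {
    skipped[[length(skipped) + 1L]] <- tibble::tibble(
      gene = gname, reason = "not present in dependency matrix")
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L) {
    out$q_value <- p.adjust(out$p_value, method = "BH")
    out$selectivity <- selectivity_label(out$g, out$p_value, cfg,
                                         group_i, group_e)
    out <- out[order(out$p_value, out$gene, method = "radix"), ]
  } else {
    out <- tibble::tibble(gene = character(), n_i = integer(), n_e = integer(),
                          mean_i = double(), mean_e = double(),
                          sd_i = double(), sd_e = double(),
                          pooled_sd = double(), correction_j = double(),
                          g = double(), p_value = double(),
                          p_mode = character(), q_value = double(),
                          selectivity = character())
  }
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

#' Volcano table and class counts
#'
#' Reclassifies a set of group comparisons at the thresholds in `cfg` and
#' emits the plot-ready table (effect size, -log10 p, selectivity) plus
#' per-class counts as attribute `"class_counts"`.
#'
#' @param comparisons Tibble from [differential_essentiality()].
#' @param cfg A [volcano_config()].
#' @param group_i,group_e Subtype labels (as in
#'   [differential_essentiality()]).
#' @return Tibble: `gene`, `g`, `p_value`, `q_value`, `neg_log10_p`,
#'   `selectivity`, `p_mode`.
#' @export
classify_volcano <- function(comparisons, cfg = volcano_config(),
                             group_i = "iCCA", group_e = "eCCA") {
  if (nrow(comparisons) == 0L) {
    out <- tibble::tibble(gene = character(), g = double(),
                          p_value = double(), q_value = double(),
                          neg_log10_p = double(), selectivity = character(),
                          p_mode = character())
    attr(out, "class_counts") <- c(none = 0L)
    return(out)
  }
  out <- tibble::tibble(
    gene = comparisons$gene, g = comparisons$g,
    p_value = comparisons$p_value, q_value = comparisons$q_value,
    neg_log10_p = -log10(comparisons$p_value),
    selectivity = selectivity_label(comparisons$g, comparisons$p_value, cfg,
                                    group_i, group_e),
    p_mode = comparisons$p_mode)
  attr(out, "class_counts") <- table(out$selectivity)
  out
}
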