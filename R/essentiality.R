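# Filter cascade and per-subtype essential-gene calling.
#
# The cascade mirrors standard dependency-screen practice: (1) drop genes
# without transcriptional activity (a dependency score for an unexpressed
# gene is uninterpretable), (2) drop genes with sparse dependency coverage,
# (3) call a gene essential in a subtype when its median dependency exceeds
# the cutoff, it is essential in at least a minimum fraction of lines, and
# it is not a pan-cancer common essential.

#' Filtering configuration for essential-gene calling
#'
#' @param min_expressed_fraction Minimum fraction of models in which a gene
#'   must be expressed to be retained (default 0.05).
#' @param expressed_threshold Expression level, on the TPM scale, at or
#'   above which a gene counts as expressed in a model (default 1 TPM,
#'   i.e. log2(TPM+1) >= 1).
#' @param max_missing_fraction Maximum tolerated fraction of missing
#'   dependency scores per gene (default 0.20); genes strictly above it are
#'   dropped.
#' @param essential_cutoff Dependency score above which a single line
#'   counts as dependent on the gene, and the median cutoff for the
#'   essential call (default 0.5).
#' @param min_fraction_essential Minimum fraction of lines that must be
#'   dependent for the essential call (default 0.10).
#' @param expression_rule `"expressed_min"` retains genes expressed in at
#'   least `min_expressed_fraction` of models (default); `"silent_max"` is
#'   the stricter reading that tolerates at most that fraction of silent
#'   models.
#' @param min_fraction_scope Whether the `min_fraction_essential` floor is
#'   evaluated over `"all"` annotated models jointly (default) or per
#'   `"subtype"`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_expressed_fraction = 0.05,
                          expressed_threshold = 1,
                          max_missing_fraction = 0.20,
                          essential_cutoff = 0.5,
                          min_fraction_essential = 0.10,
                          expression_rule = c("expressed_min", "silent_max"),
                          min_fraction_scope = c("all", "subtype")) {
  expression_rule <- match.arg(expression_rule)
  min_fraction_scope <- match.arg(min_fraction_scope)
  for (f in c(min_expressed_fraction, max_missing_fraction,
              min_fraction_essential)) {
    if (!is.numeric(f) || f < 0 || f > 1) abort("fractions must lie in [0, 1]")
  }
  if (essential_cutoff <= 0 || essential_cutoff >= 1) {
    abort("essential_cutoff must lie in (0, 1)")
  }
  if (expressed_threshold < 0) abort("expressed_threshold must be >= 0")
  structure(list(min_expressed_fraction = min_expressed_fraction,
                 expressed_threshold = expressed_threshold,
                 max_missing_fraction = max_missing_fraction,
                 essential_cutoff = essential_cutoff,
                 min_fraction_essential = min_fraction_essential,
                 expression_rule = expression_rule,
                 min_fraction_scope = min_fraction_scope),
            class = "filter_config")
}

# Threshold on the scale the expression matrix is stored in.
expressed_threshold_on_scale <- function(cfg, scale) {
  switch(scale,
         log2tpm = log2(cfg$expressed_threshold + 1),
         cfg$expressed_threshold)
}

#' Filter dependency genes by transcriptional activity
#'
#' Restricts both matrices to their common models, then retains genes
#' expressed (at or above `expressed_threshold` TPM) in at least
#' `min_expressed_fraction` of those models (or, under the
#' `"silent_max"` rule, silent in at most that fraction). Genes with
#' dependency data but absent from the expression matrix cannot be
#' verified and are dropped with a message.
#'
#' @param dep A `dep_matrix`.
#' @param expr An `expr_matrix`.
#' @param cfg A [filter_config()].
#' @return The filtered `dep_matrix`, restricted to the common models.
#' @export
filter_by_expression <- function(dep, expr, cfg = filter_config()) {
  models <- intersect(colnames(dep), colnames(expr))
  if (length(models) == 0L) abort("no models shared between dependency and expression matrices")
  dep <- subset_models(dep, models)
  missing_expr <- setdiff(rownames(dep), rownames(expr))
  if (length(missing_expr) > 0L) {
    inform(sprintf("dropped %d gene(s) absent from the expression matrix",
                   length(missing_expr)))
    dep <- subset_genes(dep, setdiff(rownames(dep), missing_expr))
  }
  e <- unclass(expr)[rownames(dep), models, drop = FALSE]
  thr <- expressed_threshold_on_scale(cfg, attr(expr, "scale"))
  frac_expressed <- rowMeans(!is.na(e) & e >= thr)
  keep <- if (cfg$expression_rule == "expressed_min") {
    frac_expressed >= cfg$min_expressed_fraction
  } else {
    frac_expressed >= 1 - cfg$min_expressed_fraction
  }
  subset_genes(dep, keep)
}

#' Filter dependency genes by missingness
#'
#' Drops genes whose fraction of missing dependency scores across the
#' retained models strictly exceeds `max_missing_fraction`.
#'
#' @inheritParams filter_by_expression
#' @return The filtered `dep_matrix`.
#' @export
filter_by_missingness <- function(dep, cfg = filter_config()) {
  frac_missing <- rowMeans(is.na(unclass(dep)))
  subset_genes(dep, frac_missing <= cfg$max_missing_fraction)
}

#' Summarize one gene's dependency over a set of models
#'
#' @param dep A `dep_matrix`.
#' @param gene Gene symbol.
#' @param models Model ids to summarize over.
#' @param cfg A [filter_config()] (supplies `essential_cutoff`).
#' @return One-row tibble: `gene`, `median_dependency` (over non-missing
#'   entries), `fraction_essential` (share of non-missing entries strictly
#'   above the cutoff), `n_scored`.
#' @export
summarize_gene <- function(dep, gene, models, cfg = filter_config()) {
  if (!gene %in% rownames(dep)) abort(sprintf("gene '%s' not in matrix", gene))
  v <- unclass(dep)[gene, models]
  v <- v[!is.na(v)]
  if (length(v) == 0L) abort(sprintf("gene '%s' has no scored models", gene))
  tibble::tibble(gene = gene,
                 median_dependency = median(v),
                 fraction_essential = mean(v > cfg$essential_cutoff),
                 n_scored = length(v))
}

# Vectorized per-gene summaries over a model subset; genes with zero
# scored models get NA summaries rather than an error.
summarize_all_genes <- function(dep, models, cfg) {
  m <- unclass(dep)[, models, drop = FALSE]
  n_scored <- rowSums(!is.na(m))
  med <- apply(m, 1L, median, na.rm = TRUE)
  med[n_scored == 0L] <- NA_real_
  frac <- rowSums(!is.na(m) & m > cfg$essential_cutoff)
  frac <- ifelse(n_scored > 0L, frac / n_scored, NA_real_)
  tibble::tibble(gene = rownames(m), median_dependency = unname(med),
                 fraction_essential = unname(frac),
                 n_scored = unname(n_scored))
}

#' Call essential genes within one subtype
#'
#' Computes per-gene median dependency and fraction-essential over the
#' subtype's models and applies the essential rule: median strictly above
#' the cutoff, at least `min_fraction_essential` of lines dependent
#' (evaluated over all annotated models or per subtype, per
#' `min_fraction_scope`), and not annotated as a common essential.
#'
#' @param dep A `dep_matrix` that has already passed the expression and
#'   missingness filters.
#' @param annotations Model-annotation tibble from
#'   [read_model_annotations()].
#' @param subtype Subtype label to stratify on (e.g. `"iCCA"`).
#' @param common_essentials A [gene_set()] (or character vector) of
#'   pan-cancer common-essential genes; these are flagged and excluded
#'   from the essential call.
#' @param cfg A [filter_config()].
#' @return Tibble of per-gene records, sorted by descending median
#'   dependency: `gene`, `subtype`, `median_dependency`,
#'   `fraction_essential`, `n_scored`, `is_essential`,
#'   `is_common_essential`, `is_fsg` (NA until [intersect_fsg()]).
#' @export
call_essential <- function(dep, annotations, subtype, common_essentials,
                           cfg = filter_config()) {
  sub_models <- intersect(annotations$model_id[annotations$subtype == subtype],
                          colnames(dep))
  if (length(sub_models) == 0L) {
    abort(sprintf("no models annotated as '%s' in the matrix", subtype))
  }
  rec <- summarize_all_genes(dep, sub_models, cfg)
  rec$subtype <- subtype
  rec$is_common_essential <- rec$gene %in% as_members(common_essentials)

  if (cfg$min_fraction_scope == "all") {
    all_models <- intersect(annotations$model_id, colnames(dep))
    floor_frac <- summarize_all_genes(dep, all_models, cfg)$fraction_essential
  } else {
    floor_frac <- rec$fraction_essential
  }
  rec$is_essential <- !is.na(rec$median_dependency) &
    rec$median_dependency > cfg$essential_cutoff &
    !is.na(floor_frac) & floor_frac >= cfg$min_fraction_essential &
    !rec$is_common_essential
  rec$is_fsg <- NA
  rec <- rec[order(-rec$median_dependency, rec$gene, method = "radix"), ]
  rec[, c("gene", "subtype", "median_dependency", "fraction_essential",
          "n_scored", "is_essential", "is_common_essential", "is_fsg")]
}

#' Flag ferroptosis-suppressor membership on essentiality records
#'
#' @param records Tibble from [call_essential()].
#' @param fsg A [gene_set()] (or character vector) of ferroptosis
#'   suppressor genes.
#' @return `records` with `is_fsg` set.
#' @export
intersect_fsg <- function(records, fsg) {
  records$is_fsg <- records$gene %in% as_members(fsg)
  records
}

#' Essential ferroptosis suppressor genes
#'
#' The filtered view: records that are both essential and FSG members.
#'
#' @param records Tibble from [intersect_fsg()].
#' @return The subset of `records` with `is_essential & is_fsg`.
#' @export
essential_fsgs <- function(records) {
  records[records$is_essential & records$is_fsg %in% TRUE, , drop = FALSE]
}

#' Scatter-plot classification of essentiality records
#'
#' Assigns each gene the category used in median-vs-fraction scatter
#' plots: `common_essential` (excluded up front), `essential_fsg`,
#' `essential` (essential but not an FSG), or `below_threshold`.
#'
#' @param records Tibble from [intersect_fsg()].
#' @return `records` plus a `category` column.
#' @export
scatter_categories <- function(records) {
  records$category <- ifelse(records$is_common_essential, "common_essential",
                      ifelse(records$is_essential & records$is_fsg %in% TRUE,
                             "essential_fsg",
                      ifelse(records$is_essential, "essential",
                             "below_threshold")))
  records
}
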