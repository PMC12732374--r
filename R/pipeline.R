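# Orchestration of the full prioritization workflow: filters ->
# per-subtype essential calls -> FSG intersection -> differential
# essentiality over the essential-FSG union. Stage gene counts are
# tracked throughout so runs on real DepMap exports can be compared
# against published narrative counts.

#' Prioritize essential ferroptosis suppressor genes per subtype
#'
#' Runs the filter cascade (expression, then missingness) on the
#' dependency matrix restricted to the annotated models, calls essential
#' genes within each subtype, flags FSG membership, and reports stage
#' counts.
#'
#' @param dep A `dep_matrix`.
#' @param expr An `expr_matrix`.
#' @param annotations Model-annotation tibble.
#' @param common_essentials [gene_set()] of common-essential genes.
#' @param fsg [gene_set()] of ferroptosis suppressor genes.
#' @param cfg A [filter_config()].
#' @param subtypes Subtype labels to stratify on.
#' @return List: `records` (per-subtype tibbles with all flags),
#'   `essential_fsg` (per-subtype filtered views), `shared`,
#'   `icca_only`, `ecca_only` style partition (named by subtype),
#'   `stage_counts` tibble, `filtered_dep` (the matrix after both
#'   filters; its genes are the natural ORA universe).
#' @export
prioritize_essential_fsgs <- function(dep, expr, annotations,
                                      common_essentials, fsg,
                                      cfg = filter_config(),
                                      subtypes = c("iCCA", "eCCA")) {
  models <- intersect(annotations$model_id,
                      intersect(colnames(dep), colnames(expr)))
  if (length(models) == 0L) abort("no annotated models with both profiles")
  dep <- subset_models(dep, models)
  n_input <- nrow(dep)
  dep <- filter_by_expression(dep, expr, cfg)
  n_expressed <- nrow(dep)
  dep <- filter_by_missingness(dep, cfg)
  n_covered <- nrow(dep)

  records <- lapply(subtypes, function(st) {
    intersect_fsg(call_essential(dep, annotations, st, common_essentials, cfg),
                  fsg)
  })
  names(records) <- subtypes
  ess_fsg <- lapply(records, essential_fsgs)
  ess_sets <- lapply(ess_fsg, function(r) r$gene)
  shared <- Reduce(intersect, ess_sets)
  only <- lapply(subtypes, function(st) setdiff(ess_sets[[st]],
                                                unlist(ess_sets[setdiff(subtypes, st)])))
  names(only) <- subtypes

  stage_counts <- tibble::tibble(
    stage = c("input", "expression_filter", "missingness_filter",
              paste0("essential_", subtypes),
              paste0("essential_fsg_", subtypes)),
    n_genes = unname(c(n_input, n_expressed, n_covered,
                       vapply(records, function(r) sum(r$is_essential), integer(1L)),
                       vapply(ess_fsg, nrow, integer(1L)))))
  list(records = records, essential_fsg = ess_fsg,
       essential_fsg_genes = ess_sets, shared = shared, only = only,
       stage_counts = stage_counts, filtered_dep = dep,
       models = models, config = cfg)
}

#' Differential essentiality over the essential-FSG union
#'
#' Convenience wrapper: takes the output of
#' [prioritize_essential_fsgs()], forms the candidate universe as the
#' union of the per-subtype essential-FSG lists, and runs
#' [differential_essentiality()] plus [classify_volcano()].
#'
#' @param prioritized Output of [prioritize_essential_fsgs()].
#' @param annotations Model-annotation tibble.
#' @param cfg A [volcano_config()].
#' @param candidates Optional explicit candidate gene vector (overrides
#'   the essential-FSG union; pass all genes for exploration).
#' @return List: `comparisons`, `volcano` (with `"class_counts"`
#'   attribute), `candidates`.
#' @export
differential_fsgs <- function(prioritized, annotations,
                              cfg = volcano_config(), candidates = NULL) {
  candidates <- candidates %||%
    sort(unique(unlist(prioritized$essential_fsg_genes)))
  comparisons <- differential_essentiality(prioritized$filtered_dep,
                                           annotations, candidates, cfg)
  list(comparisons = comparisons,
       volcano = classify_volcano(comparisons, cfg),
       candidates = candidates)
}

#' Run the full pipeline on a simulated screen
#'
#' One-call convenience for benchmarking and tests: simulate, prioritize,
#' test differential essentiality, and score recovery against the
#' planted truth.
#'
#' @param sim_cfg A [simulation_config()].
#' @param filter_cfg A [filter_config()].
#' @param volcano_cfg A [volcano_config()].
#' @return List: `sim`, `prioritized`, `differential`, `recovery`.
#' @export
run_synthetic_pipeline <- function(sim_cfg = simulation_config(),
                                   filter_cfg = filter_config(),
                                   volcano_cfg = volcano_config()) {
  sim <- simulate_screen(sim_cfg)
  prioritized <- prioritize_essential_fsgs(sim$dependency, sim$expression,
                                           sim$annotations,
                                           sim$common_essential, sim$fsg,
                                           filter_cfg)
  diff <- differential_fsgs(prioritized, sim$annotations, volcano_cfg)
  recovery <- score_recovery(prioritized$records, diff$comparisons, sim$truth)
  list(sim = sim, prioritized = prioritized, differential = diff,
       recovery = recovery)
}
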