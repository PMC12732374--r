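# Synthetic dependency-screen generator with planted gene roles, so that
# every pipeline stage is testable without DepMap downloads, plus
# recovery scoring of pipeline calls against the planted truth.
#
# Dependency probabilities live in [0, 1], so the background and
# essential score distributions are Beta; the defaults put background
# mass well below the 0.5 essentiality cutoff (Beta(1.2, 8), median
# ~0.11) and essential mass well above it (Beta(8, 2), median ~0.82),
# mimicking DepMap's normalization of scores against non-essential and
# pan-essential reference gene sets. Group sizes default to the 22
# intrahepatic vs 6 extrahepatic design of the CCA screen compendium.

#' Configuration for the synthetic screen generator
#'
#' @param n_genes Total genes (default 500).
#' @param n_models_i,n_models_e Models per subtype (defaults 22 iCCA,
#'   6 eCCA).
#' @param n_pan_essential Genes essential in every model and listed as
#'   common essentials (default 20).
#' @param n_i_essential,n_e_essential Genes essential only in the
#'   iCCA / eCCA subtype (defaults 10 and 7).
#' @param n_shared_essential Genes essential in both subtypes but not on
#'   the common-essential list (default 9).
#' @param n_fsg_decoys Background genes added to the FSG list as decoys
#'   (default 30).
#' @param missing_rate Probability that any dependency entry is masked
#'   missing-at-random (default 0.05).
#' @param silent_gene_fraction Fraction of genes transcribed at zero TPM
#'   in every model (default 0.03); drawn from the background pool.
#' @param background_shape,essential_shape Beta shape pairs `c(a, b)` for
#'   the background and essential dependency distributions.
#' @param expression_meanlog,expression_sdlog Log-normal parameters for
#'   TPM of expressed genes (defaults give a median of ~20 TPM).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 500,
                              n_models_i = 22, n_models_e = 6,
                              n_pan_essential = 20,
                              n_i_essential = 10, n_e_essential = 7,
                              n_shared_essential = 9,
                              n_fsg_decoys = 30,
                              missing_rate = 0.05,
                              silent_gene_fraction = 0.03,
                              background_shape = c(1.2, 8),
                              essential_shape = c(8, 2),
                              expression_meanlog = 3,
                              expression_sdlog = 1,
                              seed = 1L) {
  n_silent <- round(silent_gene_fraction * n_genes)
  n_planted <- n_pan_essential + n_i_essential + n_e_essential +
    n_shared_essential + n_fsg_decoys + n_silent
  if (n_planted > n_genes) abort("planted gene counts exceed n_genes")
  if (missing_rate < 0 || missing_rate > 1 ||
      silent_gene_fraction < 0 || silent_gene_fraction > 1) {
    abort("rates must lie in [0, 1]")
  }
  if (any(background_shape <= 0) || any(essential_shape <= 0)) {
    abort("Beta shape parameters must be > 0")
  }
  structure(list(n_genes = n_genes, n_models_i = n_models_i,
                 n_models_e = n_models_e,
                 n_pan_essential = n_pan_essential,
                 n_i_essential = n_i_essential,
                 n_e_essential = n_e_essential,
                 n_shared_essential = n_shared_essential,
                 n_fsg_decoys = n_fsg_decoys,
                 missing_rate = missing_rate,
                 silent_gene_fraction = silent_gene_fraction,
                 background_shape = background_shape,
                 essential_shape = essential_shape,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a DepMap-like dependency screen with planted structure
#'
#' Draws a gene x model dependency matrix in which background genes follow
#' the background Beta distribution in every model, pan-essential and
#' shared-essential genes follow the essential Beta in every model, and
#' subtype-essential genes follow the essential Beta only in their
#' subtype; entries are then masked missing-at-random. Expression is
#' log-normal TPM (stored as log2(TPM+1)), with silent genes fixed at
#' zero TPM. The FSG set is all planted subtype/shared-essential genes
#' plus background decoys; the common-essential set is the pan-essential
#' genes. The run is bit-reproducible from `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List: `dependency` (`dep_matrix`), `expression`
#'   (`expr_matrix`, log2(TPM+1)), `annotations` (tibble), `fsg`
#'   ([gene_set()]), `common_essential` ([gene_set()]), `truth` (tibble
#'   of `gene`, `role`, `fsg_member`).
#' @export
simulate_screen <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  n_models <- cfg$n_models_i + cfg$n_models_e
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  models <- c(sprintf("SIM-I%03d", seq_len(cfg$n_models_i)),
              sprintf("SIM-E%03d", seq_len(cfg$n_models_e)))
  subtype <- rep(c("iCCA", "eCCA"), c(cfg$n_models_i, cfg$n_models_e))
  is_i <- subtype == "iCCA"

  n_silent <- round(cfg$silent_gene_fraction * cfg$n_genes)
  role <- rep("background", cfg$n_genes)
  cuts <- cumsum(c(cfg$n_pan_essential, cfg$n_shared_essential,
                   cfg$n_i_essential, cfg$n_e_essential, cfg$n_fsg_decoys,
                   n_silent))
  role[seq_len(cuts[1L])] <- "pan_essential"
  if (cuts[2L] > cuts[1L]) role[(cuts[1L] + 1L):cuts[2L]] <- "shared_essential"
  if (cuts[3L] > cuts[2L]) role[(cuts[2L] + 1L):cuts[3L]] <- "i_essential"
  if (cuts[4L] > cuts[3L]) role[(cuts[3L] + 1L):cuts[4L]] <- "e_essential"
  decoy <- logical(cfg$n_genes)
  if (cuts[5L] > cuts[4L]) decoy[(cuts[4L] + 1L):cuts[5L]] <- TRUE
  if (cuts[6L] > cuts[5L]) role[(cuts[5L] + 1L):cuts[6L]] <- "silent"

  # essential-distribution indicator per (gene, model)
  ess <- matrix(FALSE, cfg$n_genes, n_models)
  ess[role %in% c("pan_essential", "shared_essential"), ] <- TRUE
  ess[role == "i_essential", is_i] <- TRUE
  ess[role == "e_essential", !is_i] <- TRUE

  dep <- matrix(rbeta(cfg$n_genes * n_models,
                      cfg$background_shape[1L], cfg$background_shape[2L]),
                cfg$n_genes, n_models)
  n_ess <- sum(ess)
  dep[ess] <- rbeta(n_ess, cfg$essential_shape[1L], cfg$essential_shape[2L])
  if (cfg$missing_rate > 0) {
    dep[runif(length(dep)) < cfg$missing_rate] <- NA_real_
  }

  tpm <- matrix(rlnorm(cfg$n_genes * n_models,
                       cfg$expression_meanlog, cfg$expression_sdlog),
                cfg$n_genes, n_models)
  tpm[role == "silent", ] <- 0

  gene_info <- tibble::tibble(symbol = genes,
                              entrez = seq_len(cfg$n_genes) + 1000L)
  dependency <- new_value_matrix(dep, gene_info, models, "dep_matrix")
  expression <- new_value_matrix(log2(tpm + 1), gene_info, models,
                                 "expr_matrix")
  attr(expression, "scale") <- "log2tpm"

  annotations <- tibble::tibble(model_id = models, subtype = subtype,
                                display_name = models)
  fsg_members <- c(genes[role %in% c("i_essential", "e_essential",
                                     "shared_essential")],
                   genes[decoy])
  truth <- tibble::tibble(gene = genes, role = role,
                          fsg_member = genes %in% fsg_members)
  list(dependency = dependency, expression = expression,
       annotations = annotations,
       fsg = gene_set("synthetic_fsg", fsg_members),
       common_essential = gene_set("synthetic_common_essential",
                                   genes[role == "pan_essential"]),
       truth = truth)
}

#' Write a simulated screen as the five input file dialects plus truth
#'
#' Emits files that parse back unchanged through the reader functions:
#' dependency and expression CSVs (models on rows), a model-metadata CSV,
#' single-column common-essential and FSG lists, and a truth TSV.
#'
#' @param sim Output of [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths.
#' @export
write_screen_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dependency = file.path(dir, "dependency.csv"),
             expression = file.path(dir, "expression_log2tpm.csv"),
             models = file.path(dir, "models.csv"),
             common_essential = file.path(dir, "common_essentials.csv"),
             fsg = file.path(dir, "fsg_list.csv"),
             truth = file.path(dir, "truth.tsv"))
  write_dependency_matrix(sim$dependency, paths[["dependency"]])
  write_expression_matrix(sim$expression, paths[["expression"]])
  readr::write_csv(data.frame(ModelID = sim$annotations$model_id,
                              Subtype = sim$annotations$subtype,
                              CellLineName = sim$annotations$display_name),
                   paths[["models"]], progress = FALSE)
  readr::write_csv(data.frame(Gene = sim$common_essential$members),
                   paths[["common_essential"]], progress = FALSE)
  readr::write_csv(data.frame(symbol = sim$fsg$members,
                              role = "suppressor"),
                   paths[["fsg"]], progress = FALSE)
  write_result_table(sim$truth, paths[["truth"]], sort_by = "gene")
  paths
}

recovery_row <- function(task, subtype, truth_pos, called_pos, universe) {
  tp <- length(intersect(truth_pos, called_pos))
  fp <- length(setdiff(called_pos, truth_pos))
  fn <- length(setdiff(truth_pos, called_pos))
  tn <- length(universe) - tp - fp - fn
  tibble::tibble(
    task = task, subtype = subtype,
    n_truth = length(truth_pos), n_called = length(called_pos),
    sensitivity = if (length(truth_pos) > 0L) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
    fdp = if (tp + fp > 0L) fp / (tp + fp) else 0)
}

#' Score pipeline calls against the planted truth
#'
#' Computes sensitivity, specificity and false-discovery proportion for
#' (a) the per-subtype essential calls (truth positives: genes planted as
#' essential in that subtype, i.e. subtype-essential or shared-essential;
#' pan-essential genes count as negatives because the pipeline excludes
#' them as common essentials) and (b) the selectivity labels (truth
#' positives: the subtype-only essential genes, with matching direction).
#' Genes dropped by upstream filters count as negative calls.
#'
#' @param essential Named list of [call_essential()] tibbles, e.g.
#'   `list(iCCA = ..., eCCA = ...)`.
#' @param comparisons Tibble from [differential_essentiality()] (may be
#'   `NULL` to skip selectivity scoring).
#' @param truth Truth tibble from [simulate_screen()].
#' @return Tibble with one row per task/subtype: `sensitivity`,
#'   `specificity`, `fdp`, truth/call counts.
#' @export
score_recovery <- function(essential, comparisons, truth) {
  universe <- truth$gene
  called_genes <- unique(c(unlist(lapply(essential, function(r) r$gene)),
                           if (!is.null(comparisons)) comparisons$gene))
  if (length(setdiff(called_genes, universe)) > 0L) {
    abort("called genes outside the truth universe")
  }
  role_pos <- list(iCCA = c("i_essential", "shared_essential"),
                   eCCA = c("e_essential", "shared_essential"))
  rows <- lapply(names(essential), function(st) {
    rec <- essential[[st]]
    recovery_row("essential_call", st,
                 truth_pos = truth$gene[truth$role %in% role_pos[[st]]],
                 called_pos = rec$gene[rec$is_essential],
                 universe = universe)
  })
  if (!is.null(comparisons)) {
    sel_pos <- list(iCCA = "i_essential", eCCA = "e_essential")
    for (st in names(sel_pos)) {
      lab <- paste0(st, "-selective")
      rows[[length(rows) + 1L]] <- recovery_row(
        "selectivity", st,
        truth_pos = truth$gene[truth$role %in% sel_pos[[st]]],
        called_pos = comparisons$gene[comparisons$selectivity == lab],
        universe = universe)
    }
  }
  dplyr::bind_rows(rows)
}
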