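# Readers and writers for the DepMap-style file dialects and for pipeline
# output tables. DepMap CSVs place models on rows and genes on columns; the
# internal representation is always gene x model, transposed once at read
# time. TSV is used for every output to avoid quoting ambiguity in symbols.

DEP_NA_STRINGS <- c("", "NA", "NaN")

new_value_matrix <- function(values, gene_info, model_ids, class) {
  stopifnot(nrow(values) == nrow(gene_info), ncol(values) == length(model_ids))
  dimnames(values) <- list(gene_info$symbol, model_ids)
  structure(values, gene_info = gene_info, class = c(class, "matrix", "array"))
}

subset_genes <- function(mat, keep) {
  gi <- attr(mat, "gene_info")
  cls <- class(mat)[1L]
  idx <- if (is.character(keep)) match(keep, rownames(mat)) else which(keep)
  out <- unclass(mat)[idx, , drop = FALSE]
  m <- new_value_matrix(out, gi[idx, , drop = FALSE], colnames(mat), cls)
  if (cls == "expr_matrix") attr(m, "scale") <- attr(mat, "scale")
  m
}

subset_models <- function(mat, models) {
  cls <- class(mat)[1L]
  out <- unclass(mat)[, models, drop = FALSE]
  m <- new_value_matrix(out, attr(mat, "gene_info"), models, cls)
  if (cls == "expr_matrix") attr(m, "scale") <- attr(mat, "scale")
  m
}

read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, na = DEP_NA_STRINGS, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        name_repair = "minimal", progress = FALSE)
  if (ncol(df) < 2L) abort(sprintf("'%s': expected a model-id column plus gene columns", path))
  model_ids <- df[[1L]]
  if (anyDuplicated(model_ids)) abort(sprintf("'%s': duplicate model ids", path))
  gene_info <- parse_gene_labels(names(df)[-1L])
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(!is.na(raw) & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("'%s': non-numeric value '%s' for gene %s, model %s",
                  path, raw[bad[1L, , drop = FALSE]],
                  gene_info$symbol[bad[1L, 2L]], model_ids[bad[1L, 1L]]))
  }
  values <- t(num)  # models-on-rows source -> gene x model
  list(values = values, gene_info = gene_info, model_ids = model_ids)
}

#' Read a CRISPR gene-dependency matrix
#'
#' Parses a DepMap-dialect CSV (models on rows, genes on columns, headers
#' either bare symbols or `"SYMBOL (ENTREZ)"`) into a gene x model matrix of
#' dependency probabilities. Empty cells, `NA` and `NaN` become missing
#' values. Every present value must lie in `[0, 1]`.
#'
#' @param path Path to the CSV file.
#' @return A `dep_matrix`: numeric gene x model matrix with a `gene_info`
#'   attribute (tibble of `symbol`, `entrez`).
#' @export
read_dependency_matrix <- function(path) {
  parsed <- read_matrix_csv(path)
  v <- parsed$values
  bad <- which(!is.na(v) & (v < 0 | v > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "dependency value %.4g outside [0, 1] for gene %s, model %s",
      v[bad[1L, 1L], bad[1L, 2L]],
      parsed$gene_info$symbol[bad[1L, 1L]],
      parsed$model_ids[bad[1L, 2L]]))
  }
  new_value_matrix(v, parsed$gene_info, parsed$model_ids, "dep_matrix")
}

#' Read a gene-expression matrix
#'
#' Same dialect as [read_dependency_matrix()] but for expression values,
#' which must be nonnegative. The scale of the stored values is recorded as
#' an attribute and used by the expression filter to place its threshold.
#'
#' @param path Path to the CSV file.
#' @param scale One of `"log2tpm"` (log2(TPM+1), the DepMap protein-coding
#'   TPM file), `"tpm"`, or `"counts"`.
#' @return An `expr_matrix` with attributes `gene_info` and `scale`.
#' @export
read_expression_matrix <- function(path, scale = c("log2tpm", "tpm", "counts")) {
  scale <- match.arg(scale)
  parsed <- read_matrix_csv(path)
  v <- parsed$values
  if (any(!is.na(v) & v < 0)) abort(sprintf("'%s': negative expression values", path))
  m <- new_value_matrix(v, parsed$gene_info, parsed$model_ids, "expr_matrix")
  attr(m, "scale") <- scale
  m
}

write_matrix_csv <- function(mat, path) {
  gi <- attr(mat, "gene_info")
  df <- as.data.frame(t(unclass(mat)))
  names(df) <- format_gene_labels(gi)
  df <- cbind(ModelID = colnames(mat), df)
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a dependency matrix in the DepMap CSV dialect
#'
#' Inverse of [read_dependency_matrix()]: models on rows, genes on columns,
#' missing entries as empty cells. Round-trips values at full precision.
#'
#' @param dep A `dep_matrix`.
#' @param path Output path.
#' @export
write_dependency_matrix <- function(dep, path) write_matrix_csv(dep, path)

#' Write an expression matrix in the DepMap CSV dialect
#'
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(expr, path) write_matrix_csv(expr, path)

#' Read model metadata and map models to subtypes
#'
#' Reads a cell-line metadata table (e.g. the DepMap model file), keeps the
#' model-id and subtype columns, and maps raw subtype labels onto the
#' two-group design. Rows whose label maps to neither group are dropped with
#' a message, so only annotated models reach the stratified analysis.
#'
#' @param path Path to the CSV/TSV metadata file.
#' @param subtype_column Name of the column carrying the raw subtype label.
#' @param subtype_mapping Named character vector mapping raw labels to
#'   `"iCCA"` / `"eCCA"` (or other two-group labels).
#' @param model_id_column Name of the model-id column (default `"ModelID"`).
#' @param display_name_column Optional column with a human-readable name.
#' @return Tibble with `model_id`, `subtype`, `display_name`.
#' @export
read_model_annotations <- function(path, subtype_column, subtype_mapping,
                                   model_id_column = "ModelID",
                                   display_name_column = NULL) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, na = DEP_NA_STRINGS,
                          show_col_types = FALSE, progress = FALSE)
  for (col in c(model_id_column, subtype_column)) {
    if (!col %in% names(df)) abort(sprintf("'%s': missing column '%s'", path, col))
  }
  if (nrow(df) == 0L) {
    warn(sprintf("'%s': no model rows", path))
    return(tibble::tibble(model_id = character(), subtype = character(),
                          display_name = character()))
  }
  raw <- as.character(df[[subtype_column]])
  mapped <- unname(subtype_mapping[raw])
  keep <- !is.na(mapped)
  if (any(!keep)) {
    inform(sprintf("dropped %d model(s) with subtype labels outside the mapping",
                   sum(!keep)))
  }
  display <- if (!is.null(display_name_column) && display_name_column %in% names(df)) {
    as.character(df[[display_name_column]])
  } else {
    as.character(df[[model_id_column]])
  }
  out <- tibble::tibble(model_id = as.character(df[[model_id_column]]),
                        subtype = mapped, display_name = display)[keep, ]
  if (anyDuplicated(out$model_id)) abort(sprintf("'%s': duplicate model ids", path))
  out
}

#' Read a gene set from a delimited file
#'
#' Accepts tab- or comma-separated tables with a symbol column and an
#' optional role/category column (the FerrDb export layout: one row per
#' gene with a role such as driver/suppressor/marker).
#'
#' @param path Path to the file.
#' @param name Name for the resulting set (default: file name).
#' @param role_filter If given, keep only rows whose role column equals this
#'   value (case-insensitive).
#' @param symbol_column,role_column Column names; auto-detected among common
#'   spellings when `NULL`.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL, role_filter = NULL,
                          symbol_column = NULL, role_column = NULL) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, na = DEP_NA_STRINGS,
                          show_col_types = FALSE, progress = FALSE)
  symbol_column <- symbol_column %||%
    intersect(c("symbol", "Symbol", "gene", "Gene", "GeneSymbol"), names(df))[1L]
  if (is.null(symbol_column) || is.na(symbol_column)) {
    abort(sprintf("'%s': no symbol column found", path))
  }
  if (!is.null(role_filter)) {
    role_column <- role_column %||%
      intersect(c("role", "Role", "category", "Category", "type", "Type"),
                names(df))[1L]
    if (is.null(role_column) || is.na(role_column)) {
      abort(sprintf("'%s': role_filter given but no role column found", path))
    }
    df <- df[tolower(as.character(df[[role_column]])) == tolower(role_filter), ]
  }
  members <- unique(as.character(df[[symbol_column]]))
  members <- members[!is.na(members) & nzchar(members)]
  if (length(members) == 0L) {
    abort(sprintf("'%s': no gene symbols left after filtering", path))
  }
  gene_set(name %||% basename(path), members)
}

#' Read a single-column gene list
#'
#' For files like the DepMap common-essential export: a header line followed
#' by one gene label per row, labels either bare symbols or
#' `"SYMBOL (ENTREZ)"`.
#'
#' @param path Path to the file.
#' @param name Name for the resulting set.
#' @return A [gene_set()] keyed by symbol.
#' @export
read_gene_list <- function(path, name = NULL) {
  df <- readr::read_csv(path, na = DEP_NA_STRINGS, show_col_types = FALSE,
                        progress = FALSE)
  labels <- as.character(df[[1L]])
  labels <- labels[!is.na(labels) & nzchar(labels)]
  if (length(labels) == 0L) abort(sprintf("'%s': empty gene list", path))
  gene_set(name %||% basename(path), parse_gene_labels(labels)$symbol)
}

#' Read gene-set collections in GMT format
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a result table as TSV with an embedded configuration header
#'
#' All pipeline outputs go through this writer: tab-separated, full numeric
#' precision, deterministic row order (the caller's sort key), and a comment
#' block recording the effective configuration so that runs are auditable.
#' List columns are collapsed with `";"`.
#'
#' @param records Data frame of homogeneous records (may be empty).
#' @param path Output path.
#' @param sort_by Optional column name(s) defining the row order.
#' @param descending Sort direction for the first key.
#' @param config Optional named list written as `# key: value` header lines.
#' @export
write_result_table <- function(records, path, sort_by = NULL,
                               descending = FALSE, config = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!is.null(sort_by) && nrow(records) > 0L) {
    keys <- lapply(sort_by, function(k) records[[k]])
    ord <- do.call(order, c(keys, list(decreasing = descending,
                                       method = "radix")))
    records <- records[ord, , drop = FALSE]
  }
  for (j in seq_along(records)) {
    if (is.list(records[[j]])) {
      records[[j]] <- vapply(records[[j]], paste, character(1L), collapse = ";")
    }
  }
  hdr <- c(sprintf("# generated_by: fsgdep %s", as.character(packageVersion("fsgdep"))),
           if (!is.null(config)) {
             vapply(names(config), function(k) {
               sprintf("# %s: %s", k, paste(format(config[[k]]), collapse = " "))
             }, character(1L))
           })
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a table written by [write_result_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble (comment header lines are skipped).
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
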