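# The published per-subtype summary of essential ferroptosis suppressor
# genes in cholangiocarcinoma cell lines: median dependency score and
# fraction of lines with dependency > 0.5, for 26 genes, printed at two
# decimals. Used as a desk-scale input fixture for the partition logic.

#' Published essential-FSG summary table
#'
#' Median dependency scores and fraction-essential values for the 26
#' ferroptosis suppressor genes called essential in intrahepatic (iCCA)
#' and/or extrahepatic (eCCA) cholangiocarcinoma cell models, as printed
#' (two decimals) in the source study of DepMap CCA screens.
#'
#' @return Tibble with columns `gene`, `median_icca`, `fraction_icca`,
#'   `median_ecca`, `fraction_ecca`.
#' @export
fsg_table1 <- function() {
  tibble::tribble(
    ~gene,     ~median_icca, ~fraction_icca, ~median_ecca, ~fraction_ecca,
    "MED1",    0.90, 0.73, 0.73, 0.67,
    "SLC3A2",  0.80, 0.82, 0.68, 0.67,
    "FXN",     0.75, 0.82, 0.87, 0.83,
    "SKP2",    0.71, 0.72, 0.77, 0.67,
    "TYMS",    0.71, 0.55, 0.86, 0.67,
    "RICTOR",  0.63, 0.64, 0.56, 0.67,
    "ADAR",    0.60, 0.59, 0.58, 0.67,
    "ZC3H13",  0.58, 0.64, 0.61, 0.50,
    "AHCY",    0.54, 0.50, 0.64, 0.67,
    "GPX4",    0.77, 0.64, 0.32, 0.16,
    "CHMP5",   0.76, 0.73, 0.11, 0.33,
    "UBIAD1",  0.73, 0.68, 0.38, 0.50,
    "PTPMT1",  0.65, 0.68, 0.49, 0.50,
    "SETD2",   0.59, 0.68, 0.46, 0.33,
    "SDHD",    0.59, 0.50, 0.17, 0.16,
    "UBR5",    0.55, 0.50, 0.14, 0.16,
    "METTL17", 0.52, 0.50, 0.40, 0.33,
    "FECH",    0.52, 0.55, 0.40, 0.33,
    "ARF6",    0.50, 0.50, 0.25, 0.16,
    "KLF5",    0.47, 0.45, 0.80, 0.67,
    "FOXM1",   0.36, 0.18, 0.74, 0.67,
    "IGF1R",   0.22, 0.31, 0.71, 0.67,
    "TEAD1",   0.39, 0.45, 0.67, 0.67,
    "PARL",    0.26, 0.09, 0.64, 0.67,
    "ZMYND8",  0.10, 0.18, 0.61, 0.67,
    "SREBF1",  0.16, 0.31, 0.52, 0.50
  )
}

#' Partition a two-subtype median-dependency table into essential-FSG sets
#'
#' Applies the median-dependency rule to each subtype's median column and
#' partitions the genes into shared, iCCA-only and eCCA-only essential
#' sets. On values printed at two decimals the comparison defaults to
#' `>=`, because a gene whose unrounded median exceeds the cutoff can print
#' exactly at it; on unrounded data use `comparison = ">"`, matching the
#' strictly-greater definition of essentiality.
#'
#' @param tbl Tibble with columns `gene`, `median_icca`, `median_ecca`
#'   (e.g. [fsg_table1()]).
#' @param cutoff Median-dependency cutoff (default 0.5).
#' @param comparison `">="` (printed, rounded values) or `">"` (raw values).
#' @return List with the gene vectors `icca`, `ecca`, `shared`,
#'   `icca_only`, `ecca_only` and their counts `n_icca`, `n_ecca`,
#'   `n_shared`, `n_icca_only`, `n_ecca_only`.
#' @export
partition_essential_fsgs <- function(tbl, cutoff = 0.5,
                                     comparison = c(">=", ">")) {
  comparison <- match.arg(comparison)
  cmp <- match.fun(comparison)
  icca <- tbl$gene[cmp(tbl$median_icca, cutoff)]
  ecca <- tbl$gene[cmp(tbl$median_ecca, cutoff)]
  shared <- intersect(icca, ecca)
  list(icca = icca, ecca = ecca, shared = shared,
       icca_only = setdiff(icca, ecca), ecca_only = setdiff(ecca, icca),
       n_icca = length(icca), n_ecca = length(ecca),
       n_shared = length(shared),
       n_icca_only = length(setdiff(icca, ecca)),
       n_ecca_only = length(setdiff(ecca, icca)))
}
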