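# Independent oracles, kept deliberately separate from the package's own
# algorithms: the rank-sum oracle enumerates every group assignment
# explicitly (combn), whereas the implementation uses a generating-function
# count; the ORA oracle is Fisher's exact test on the 2x2 overlap table.

# Two-sided rank-sum p by explicit enumeration of all choose(N, n1)
# assignments of the pooled mid-ranks.
oracle_wilcoxon_p <- function(x, y) {
  ranks <- rank(c(x, y))
  n1 <- length(x)
  N <- length(ranks)
  W <- sum(ranks[seq_len(n1)])
  subs <- utils::combn(N, n1)
  sums <- colSums(matrix(ranks[subs], nrow = n1))
  min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
}

# Random sample pair with ties, for rank-test property checks.
random_tied_pair <- function(n1, n2, n_levels = 5) {
  list(x = sample(seq_len(n_levels), n1, replace = TRUE) / 2,
       y = sample(seq_len(n_levels), n2, replace = TRUE) / 2)
}

# A small dependency matrix from explicit values (genes x models).
make_dep <- function(values, genes = NULL, models = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(models)) models <- sprintf("M%02d", seq_len(ncol(values)))
  df <- as.data.frame(t(values))
  names(df) <- genes
  df <- cbind(ModelID = models, df)
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  read_dependency_matrix(path)
}
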