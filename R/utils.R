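#' @importFrom rlang %||% abort warn inform
#' @importFrom stats median p.adjust phyper pnorm rbeta rlnorm runif sd
#' @importFrom utils packageVersion
NULL

# Parse DepMap-style gene column labels: either a bare symbol or
# "SYMBOL (ENTREZ)". Returns a tibble(symbol, entrez).
parse_gene_labels <- function(labels) {
  labels <- trimws(labels)
  m <- regmatches(labels, regexec("^(.*?)\\s*\\(([^()]*)\\)$", labels))
  symbol <- character(length(labels))
  entrez <- rep(NA_integer_, length(labels))
  for (i in seq_along(labels)) {
    if (length(m[[i]]) == 3L) {
      sym <- m[[i]][2L]
      ent <- m[[i]][3L]
      if (!nzchar(sym) || !grepl("^[0-9]+$", ent)) {
        abort(sprintf("malformed gene column label: '%s' (column %d)",
                      labels[i], i))
      }
      symbol[i] <- sym
      entrez[i] <- as.integer(ent)
    } else {
      if (!nzchar(labels[i])) {
        abort(sprintf("empty gene column label at column %d", i))
      }
      symbol[i] <- labels[i]
    }
  }
  if (anyDuplicated(symbol)) {
    dup <- unique(symbol[duplicated(symbol)])
    abort(sprintf("duplicate gene symbol(s) after parsing: %s",
                  paste(dup, collapse = ", ")))
  }
  ent_present <- entrez[!is.na(entrez)]
  if (anyDuplicated(ent_present)) {
    abort("duplicate entrez ids after parsing")
  }
  tibble::tibble(symbol = symbol, entrez = entrez)
}

format_gene_labels <- function(gene_info) {
  ifelse(is.na(gene_info$entrez),
         gene_info$symbol,
         sprintf("%s (%d)", gene_info$symbol, gene_info$entrez))
}

#' Construct a gene set
#'
#' A named collection of unique gene symbols, the container used for the
#' ferroptosis-suppressor list, the common-essential list, and ORA
#' collections.
#'
#' @param name Set name.
#' @param members Character vector of gene symbols; duplicates are collapsed.
#' @return An object of class `gene_set`: a list with `name` and `members`.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  members <- members[nzchar(members) & !is.na(members)]
  if (length(members) == 0L) {
    abort(sprintf("gene set '%s' has no members", name))
  }
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}

as_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}
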