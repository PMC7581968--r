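#' Read a regions-by-genes expression matrix
#'
#' Accepts the published compiled-atlas layout: a TSV (or CSV) whose rows are
#' cortical regions and whose columns are gene symbols, with the region
#' identifier in the first column (id or name). Genes with zero variance
#' across regions are dropped; NA entries are an error.
#'
#' @param file path to the table.
#' @param parc optional [parcellation()]; when given, rows are checked to be
#'   a subset of its left cortical regions and ordered to match.
#' @return numeric matrix (regions x genes) with region rownames.
#' @export
read_expression_matrix <- function(file, parc = NULL) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  tab <- read.delim(file, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rn <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  if (anyNA(m)) stop2("expression matrix contains NA entries")
  sdv <- apply(m, 2, sd)
  if (any(sdv == 0)) {
    message("dropping ", sum(sdv == 0), " zero-variance genes")
    m <- m[, sdv > 0, drop = FALSE]
  }
  if (!is.null(parc)) {
    left <- parc[cortical_idx(parc, "left"), ]
    key <- if (all(rn %in% left$name)) left$name else
      as.character(left$region_id)
    if (!all(rn %in% key))
      stop2("expression rows are not a subset of left cortical regions")
    m <- m[key[key %in% rn], , drop = FALSE]
  }
  m
}
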