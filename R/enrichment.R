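#' Cell-type specificity matrix from single-cell expression
#'
#' Specificity of gene `g` for cell type `c` is the mean expression of `g`
#' in cells of type `c` divided by the sum of those means over all cell
#' types, so each expressed gene's specificities sum to 1. Computing the
#' per-type mean first makes the result invariant to any one cell's library
#' size rescaling. Genes expressed nowhere are dropped.
#'
#' @param cell_by_gene nonnegative cells-by-genes expression matrix
#'   (column names = gene symbols).
#' @param cell_labels character vector of cell-type labels, one per cell
#'   (at least 2 distinct types).
#' @return a genes-by-cell-types specificity matrix (rows sum to 1).
#' @export
build_specificity <- function(cell_by_gene, cell_labels) {
  cell_by_gene <- as.matrix(cell_by_gene)
  if (any(cell_by_gene < 0)) stop2("expression must be nonnegative")
  if (length(cell_labels) != nrow(cell_by_gene))
    stop2("one cell label per row is required")
  if (length(unique(cell_labels)) < 2) stop2("at least 2 cell types required")
  sums <- rowsum(cell_by_gene, cell_labels)
  means <- sums / as.vector(table(cell_labels)[rownames(sums)])
  s <- t(means)                     # genes x types
  tot <- rowSums(s)
  s <- s[tot > 0, , drop = FALSE]
  s / rowSums(s)
}

#' Expression-weighted cell-type enrichment (EWCE)
#'
#' Tests whether a target gene list has higher mean cell-type specificity
#' than random gene lists matched on transcript length and GC content. The
#' observed statistic per cell type is the mean specificity of the target
#' genes. Bootstrap lists are drawn within joint length-by-GC strata
#' (quintile-by-quintile bins by default), matching the target's per-stratum
#' counts; a stratum with too few candidate genes is merged into its
#' length-bin margin (and finally the whole background) with a warning.
#' `p = (1 + #\{bootstrap mean >= observed\}) / (1 + n_boot)` per cell type,
#' BH-corrected across cell types; `sd_from_mean` is the distance of the
#' observed mean from the bootstrap mean in bootstrap standard deviations.
#'
#' @param target character vector of target gene symbols (subset of the
#'   specificity matrix rows with metadata).
#' @param spec specificity matrix from [build_specificity()].
#' @param meta data.frame with rownames = gene symbols and columns `length`
#'   (transcript length, bp) and `gc` (GC fraction).
#' @param n_boot number of bootstrap lists (default 100000; at least 1000).
#' @param seed RNG seed.
#' @param n_bins number of quantile bins per covariate (default 5).
#' @return data.frame of class `ewce_result`: `cell_type`, `observed`,
#'   `boot_mean`, `boot_sd`, `sd_from_mean`, `p`, `q`.
#' @export
ewce <- function(target, spec, meta, n_boot = 1e5, seed = 1, n_bins = 5) {
  if (n_boot < 1000) stop2("n_boot must be >= 1000")
  genes <- intersect(rownames(spec), rownames(meta))
  target <- unique(target)
  if (length(target) < 5) stop2("target list needs at least 5 genes")
  if (!all(target %in% genes))
    stop2("target genes missing from specificity matrix or metadata: ",
          paste(head(setdiff(target, genes), 5), collapse = ", "))
  if (any(meta[genes, "length"] <= 0)) stop2("transcript lengths must be > 0")
  if (any(meta[genes, "gc"] <= 0 | meta[genes, "gc"] >= 1))
    stop2("GC content must be in (0, 1)")

  qbin <- function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  lb <- qbin(meta[genes, "length"])
  gb <- qbin(meta[genes, "gc"])
  stratum <- paste(lb, gb, sep = ":")
  names(stratum) <- names(lb) <- genes

  tgt_strat <- table(stratum[target])
  set.seed(seed)
  n_types <- ncol(spec)
  boot_sum <- matrix(0, n_boot, n_types)
  for (s in names(tgt_strat)) {
    cnt <- tgt_strat[[s]]
    pool <- genes[stratum == s]
    if (length(pool) < 2 * cnt) {
      warning("stratum ", s, " has too few candidates; merging into its ",
              "length bin")
      pool <- genes[sub(":.*", "", stratum) == sub(":.*", "", s)]
      if (length(pool) < 2 * cnt) pool <- genes
    }
    idx <- vapply(seq_len(n_boot), function(i) sample(pool, cnt),
                  character(cnt))
    idx <- matrix(idx, nrow = cnt)
    sp <- spec[as.vector(idx), , drop = FALSE]
    grp <- rep(seq_len(n_boot), each = cnt)
    boot_sum <- boot_sum + rowsum(sp, grp)
  }
  boot_mean_mat <- boot_sum / length(target)
  obs <- colMeans(spec[target, , drop = FALSE])
  bm <- colMeans(boot_mean_mat)
  bs <- apply(boot_mean_mat, 2, sd)
  p <- vapply(seq_len(n_types), function(k)
    (1 + sum(boot_mean_mat[, k] >= obs[k])) / (1 + n_boot), numeric(1))
  out <- data.frame(cell_type = colnames(spec), observed = as.numeric(obs),
                    boot_mean = bm, boot_sd = bs,
                    sd_from_mean = (obs - bm) / bs,
                    p = p, q = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ewce_result", "data.frame")
  out
}

#' Hypergeometric gene-list overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between two gene lists drawn from a common background universe.
#'
#' @param list_a,list_b character vectors of gene symbols.
#' @param background size of the background universe (integer), or the
#'   universe itself as a character vector.
#' @return list: `overlap`, `expected`, `p` (uncorrected upper tail,
#'   including the observed count).
#' @export
hypergeom_overlap <- function(list_a, list_b, background) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  if (is.character(background)) {
    universe <- unique(background)
    if (!all(list_a %in% universe) || !all(list_b %in% universe))
      stop2("lists must be subsets of the background universe")
    background <- length(universe)
  }
  if (background < length(list_a) + length(list_b) -
      length(intersect(list_a, list_b)))
    stop2("background smaller than the union of the lists")
  k <- length(intersect(list_a, list_b))
  m <- length(list_a); nn <- background - m; kk <- length(list_b)
  list(overlap = k,
       expected = kk * m / background,
       p = phyper(k - 1, m, nn, kk, lower.tail = FALSE))
}

#' Hypergeometric annotation-set enrichment with BH correction
#'
#' Generic annotation enrichment of a target gene list against named gene
#' sets (e.g. GO biological processes read from a GMT file): per-set
#' upper-tail hypergeometric test with Benjamini-Hochberg correction across
#' sets. This is a plain hypergeometric+BH procedure, not the g:SCS
#' correction used by the g:Profiler service. Columns mirror the usual
#' reporting: `B` = genes in the set (within the universe), `N` = query
#' size, `b` = intersection.
#'
#' @param target character vector of query gene symbols.
#' @param annotation_sets named list of character vectors.
#' @param background universe size (integer) or universe gene vector.
#' @return data.frame `set`, `B`, `N`, `b`, `p`, `q`, ordered by `q`.
#' @export
annotation_enrichment <- function(target, annotation_sets, background) {
  target <- unique(target)
  universe <- if (is.character(background)) unique(background) else NULL
  bg <- if (is.null(universe)) background else length(universe)
  res <- lapply(names(annotation_sets), function(nm) {
    s <- unique(annotation_sets[[nm]])
    if (!is.null(universe)) s <- intersect(s, universe)
    b <- length(intersect(target, s))
    p <- phyper(b - 1, length(s), bg - length(s), length(target),
                lower.tail = FALSE)
    data.frame(set = nm, B = length(s), N = length(target), b = b, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param file path.
#' @return character vector (empty lines dropped).
#' @export
read_gene_list <- function(file) {
  x <- trimws(readLines(file))
  x[nzchar(x)]
}

#' Read annotation gene sets from a GMT file
#'
#' @param file path to a GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(file) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop2("reading GMT files requires the fgsea package")
  fgsea::gmtPathways(file)
}
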