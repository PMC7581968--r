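#' Bootstrap variability of PLS gene weights
#'
#' Resamples regions with replacement, refits the PLS model, takes the
#' component at the originally chosen index and aligns its sign to the
#' original by the correlation between the bootstrap score vector and the
#' original scores on the resampled regions (removing the reflection
#' ambiguity of PLS components). The per-gene standard error is the standard
#' deviation of the aligned bootstrap weights and `z = weight / SE`.
#' A degenerate resample (component collapse) is redrawn, at most 10 times.
#'
#' @param X expression matrix used for the fit.
#' @param y loss map used for the fit.
#' @param fit a [pls_fit()].
#' @param n_boot number of bootstrap resamples (at least 100).
#' @param seed RNG seed.
#' @return data.frame of class `pls_bootstrap`: `gene`, `weight`, `se`, `z`.
#' @export
bootstrap_weights <- function(X, y, fit, n_boot = 1000, seed = 1) {
  if (is.data.frame(y)) y <- y$loss
  if (n_boot < 100) stop2("n_boot must be >= 100")
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  bw <- matrix(NA_real_, length(fit$genes), n_boot,
               dimnames = list(fit$genes, NULL))
  orig_scores <- fit$scores[, fit$chosen]
  for (b in seq_len(n_boot)) {
    for (try in seq_len(10)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(refit_pls(X[idx, , drop = FALSE], y[idx],
                               fit$n_components),
                     error = function(e) NULL)
      if (!is.null(fb) && fb$n_components >= fit$chosen) break
      fb <- NULL
    }
    if (is.null(fb)) stop2("bootstrap component collapsed repeatedly")
    wb <- numeric(length(fit$genes))
    names(wb) <- fit$genes
    wb[fb$genes] <- fb$weights[, fit$chosen]
    sgn <- sign(cor(fb$scores[, fit$chosen], orig_scores[idx]))
    if (is.na(sgn) || sgn == 0) sgn <- 1
    bw[, b] <- sgn * wb
  }
  se <- apply(bw, 1, sd)
  w <- fit$weights[, fit$chosen]
  out <- data.frame(gene = fit$genes, weight = as.numeric(w),
                    se = as.numeric(se),
                    z = as.numeric(w) / as.numeric(se),
                    stringsAsFactors = FALSE)
  class(out) <- c("pls_bootstrap", "data.frame")
  out
}

#' Rank genes by PLS weight with spin-null significance
#'
#' Each gene's weight on the chosen component is tested against its own
#' spin-null weight distribution (two-sided, via absolute value), with
#' Benjamini-Hochberg correction across genes. FDR survivors are split by
#' weight sign — downweighted (negative: lower expression where connectivity
#' loss is greater) and upweighted (positive) — and ranked by absolute weight
#' within each direction.
#'
#' @param fit a [pls_fit()].
#' @param boot output of [bootstrap_weights()].
#' @param spin output of [spin_pvalue()] (provides the spin-null weights).
#' @param fdr FDR threshold for survivorship (default 0.05).
#' @return data.frame of class `gene_ranking`: `gene`, `weight`, `se`, `z`,
#'   `p`, `q`, `direction`, `survives`, `rank` (within direction, survivors
#'   only).
#' @export
rank_genes <- function(fit, boot, spin, fdr = 0.05) {
  w <- fit$weights[, fit$chosen]
  nw <- spin$null_weights
  if (is.null(nw)) stop2("spin result carries no null weights")
  n_perm <- ncol(nw)
  exceed <- rowSums(abs(nw) >= abs(w), na.rm = TRUE)
  p <- (1 + exceed) / (1 + n_perm)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene = names(w), weight = as.numeric(w),
                    se = boot$se[match(names(w), boot$gene)],
                    z = boot$z[match(names(w), boot$gene)],
                    p = p, q = q,
                    direction = ifelse(w < 0, "downweighted", "upweighted"),
                    survives = q < fdr,
                    stringsAsFactors = FALSE)
  out$rank <- NA_integer_
  for (dir in c("downweighted", "upweighted")) {
    k <- which(out$survives & out$direction == dir)
    out$rank[k[order(-abs(out$weight[k]))]] <- seq_along(k)
  }
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Extract the top fraction of ranked survivor genes in one direction
#'
#' The top-`frac` cut (default 20%) of FDR-surviving genes, ranked by
#' absolute weight, as used for downstream enrichment analyses;
#' `floor(frac * n_survivors)` genes are returned.
#'
#' @param ranking a [rank_genes()] result.
#' @param direction `"downweighted"` or `"upweighted"`.
#' @param frac fraction of survivors to keep (default 0.2; 0.1/0.3/0.5 are
#'   the robustness settings).
#' @return character vector of gene symbols.
#' @export
top_genes <- function(ranking, direction = c("downweighted", "upweighted"),
                      frac = 0.2) {
  direction <- match.arg(direction)
  k <- ranking[ranking$survives & ranking$direction == direction, ]
  k <- k[order(k$rank), ]
  head(k$gene, floor(frac * nrow(k)))
}
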