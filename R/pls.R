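#' Partial least squares regression of gene expression on a regional loss map
#'
#' Fits a univariate-response PLS model (NIPALS) relating the regions-by-
#' genes expression matrix to the regional white-matter loss map. Components
#' maximise covariance between expression projections and the loss map;
#' `r2[k]` is the incremental proportion of response variance explained by
#' component `k` (scores are mutually orthogonal, so these sum to the total
#' R-squared). The component used for gene ranking is the one explaining the
#' most response variance — an index chosen by the data, not fixed a priori.
#' Each component is oriented so its region scores correlate positively with
#' the loss map; "upweighted" genes then have higher expression where loss is
#' greater.
#'
#' Genes with zero variance across regions are dropped. Expression columns
#' are z-scored across regions before fitting (`scale = TRUE`).
#'
#' @param X regions-by-genes numeric matrix (column names = gene symbols),
#'   or an object with an `expression` element.
#' @param y numeric loss vector aligned to rows of `X`, or the data.frame
#'   returned by [regional_loss()].
#' @param n_components number of components to extract (capped at
#'   `min(nrow(X) - 1, 10)`).
#' @param scale z-score each gene across regions first (default `TRUE`).
#' @return an object of class `pls_fit`: `weights` (genes x K, unit norm),
#'   `scores` (regions x K), `loadings`, `r2` (per component), `chosen`
#'   (index of the max-R2 component), plus centering/scaling info.
#' @export
pls_fit <- function(X, y, n_components = 5, scale = TRUE) {
  if (is.data.frame(y)) y <- setNames(y$loss, y$name)
  X <- as.matrix(X)
  if (nrow(X) < 10) stop2("at least 10 regions are required")
  if (nrow(X) != length(y)) stop2("rows of X must align with y")
  if (anyNA(X) || anyNA(y)) stop2("X and y must be NA-free")
  n_components <- min(n_components, nrow(X) - 1, 10)

  sdv <- apply(X, 2, sd)
  drop <- sdv == 0
  if (any(drop)) {
    message("dropping ", sum(drop), " zero-variance genes")
    X <- X[, !drop, drop = FALSE]
    sdv <- sdv[!drop]
  }
  xc <- colMeans(X)
  Xs <- sweep(X, 2, xc)
  if (scale) Xs <- sweep(Xs, 2, sdv, "/")
  yc <- mean(y)
  ys <- y - yc
  ssy <- sum(ys^2)

  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  P <- matrix(0, p, n_components)
  r2 <- numeric(n_components)
  Xk <- Xs
  k_used <- 0
  for (k in seq_len(n_components)) {
    w <- crossprod(Xk, ys)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(ssy))) break
    w <- w / nw
    tk <- Xk %*% w
    tt <- sum(tk^2)
    if (tt < 1e-24) break
    if (sum(tk * ys) < 0) { w <- -w; tk <- -tk }
    pk <- crossprod(Xk, tk) / tt
    Xk <- Xk - tcrossprod(tk, pk)
    W[, k] <- w
    Tm[, k] <- tk
    P[, k] <- pk
    r2[k] <- if (ssy > 0) (sum(tk * ys))^2 / (tt * ssy) else 0
    k_used <- k
  }
  if (ssy == 0) stop2("response has zero variance")
  if (k_used == 0) {
    # response orthogonal to every gene: a null fit, zero variance explained
    W <- matrix(0, p, 1, dimnames = list(colnames(X), NULL))
    Tm <- matrix(0, n, 1, dimnames = list(rownames(X), NULL))
    P <- W
    r2 <- 0
    k_used <- 1L
  }
  W <- W[, seq_len(k_used), drop = FALSE]
  Tm <- Tm[, seq_len(k_used), drop = FALSE]
  P <- P[, seq_len(k_used), drop = FALSE]
  r2 <- r2[seq_len(k_used)]
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Tm) <- rownames(X)

  structure(list(weights = W, scores = Tm, loadings = P, r2 = r2,
                 chosen = which.max(r2), n_components = k_used,
                 x_center = xc, x_scale = if (scale) sdv else NULL,
                 y_center = yc, genes = colnames(X),
                 regions = rownames(X)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("PLS fit:", length(x$genes), "genes,", length(x$regions), "regions,",
      x$n_components, "components\n")
  cat("  response variance explained:",
      paste(sprintf("%.3f", x$r2), collapse = " "), "\n")
  cat("  chosen component:", x$chosen, "\n")
  invisible(x)
}

#' Region (ROI) weights of the chosen PLS component
#'
#' @param fit a [pls_fit()].
#' @return data.frame `region`, `score` for the chosen component (scores are
#'   zero-mean because the fit is centred).
#' @export
roi_weights <- function(fit) {
  data.frame(region = fit$regions,
             score = as.numeric(fit$scores[, fit$chosen]),
             stringsAsFactors = FALSE)
}

# refit helper used by spins and bootstrap: same standardisation policy
refit_pls <- function(X, y, n_components) {
  suppressMessages(pls_fit(X, y, n_components = n_components, scale = TRUE))
}
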