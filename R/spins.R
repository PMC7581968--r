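#' Spatial spin permutations of a parcellated cortical map
#'
#' Generates spatial null permutations by rotating the parcel centroids on
#' the sphere with uniformly random rotations and matching each original
#' parcel to a rotated parcel by greedy one-to-one nearest-neighbour
#' assignment (shortest geodesic first). Each permutation is therefore a
#' bijection of regions that approximately preserves the map's spatial
#' autocorrelation while breaking its alignment with any predictor.
#'
#' @param centroids matrix of unit-norm centroid coordinates (regions x 3),
#'   rownames = region names, one per modelled cortical region.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed; the spin set is deterministic given the seed.
#' @return an object of class `spin_set`: integer matrix (regions x n_perm);
#'   column `j` maps region `i` to the source region whose value it receives.
#' @export
make_spins <- function(centroids, n_perm = 1000, seed = 1) {
  centroids <- as.matrix(centroids)
  nrm <- sqrt(rowSums(centroids^2))
  if (any(abs(nrm - 1) > 1e-6)) stop2("centroids must be unit-norm")
  if (anyDuplicated(round(centroids, 10)) > 0)
    stop2("duplicate centroids")
  n <- nrow(centroids)
  set.seed(seed)
  perms <- matrix(0L, n, n_perm)
  for (j in seq_len(n_perm)) {
    R <- random_rotation()
    rot <- centroids %*% t(R)
    perms[, j] <- greedy_assign(centroids, rot)
  }
  rownames(perms) <- rownames(centroids)
  structure(perms, class = c("spin_set", "matrix"))
}

#' Uniformly random 3D rotation matrix
#'
#' Drawn from the Haar measure on SO(3) via QR decomposition of a Gaussian
#' matrix with sign fixing.
#'
#' @return a 3x3 rotation matrix (orthogonal, determinant +1).
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# one-to-one assignment: original region i <- rotated region j,
# greedily pairing the globally closest free (i, j) pairs first
greedy_assign <- function(orig, rot) {
  n <- nrow(orig)
  d <- acos(pmax(pmin(tcrossprod(orig, rot), 1), -1))
  ord <- order(d)
  map <- integer(n)
  used_i <- logical(n)
  used_j <- logical(n)
  left <- n
  for (k in ord) {
    i <- (k - 1) %% n + 1
    j <- (k - 1) %/% n + 1
    if (!used_i[i] && !used_j[j]) {
      map[i] <- j
      used_i[i] <- TRUE
      used_j[j] <- TRUE
      left <- left - 1
      if (left == 0) break
    }
  }
  map
}

# refit the PLS under every spin of y; returns the null distribution of the
# selection statistic (max component R2) and the spin-chosen component's
# gene weights, reused by spin_pvalue() and rank_genes()
spin_null <- function(fit, X, y, spins) {
  if (is.data.frame(y)) y <- y$loss
  n_perm <- ncol(spins)
  null_r2 <- numeric(n_perm)
  null_w <- matrix(NA_real_, length(fit$genes), n_perm,
                   dimnames = list(fit$genes, NULL))
  for (j in seq_len(n_perm)) {
    fs <- refit_pls(X, y[spins[, j]], fit$n_components)
    null_r2[j] <- max(fs$r2)
    null_w[fs$genes, j] <- fs$weights[, fs$chosen]
  }
  list(null_r2 = null_r2, null_weights = null_w, n_perm = n_perm)
}

#' Spin-permutation p value for the chosen PLS component
#'
#' Refits the PLS model with the loss map spun by each spatial permutation
#' and compares the observed response variance explained by the chosen
#' component against the null distribution of the same selection statistic
#' (the maximum component R-squared, matching how the component is chosen).
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param fit a [pls_fit()].
#' @param X the expression matrix used for the fit.
#' @param y the loss map used for the fit (vector or [regional_loss()] output).
#' @param spins a [make_spins()] spin set on the same region set.
#' @return list: `p`, `observed_r2`, `null_r2`, and `null_weights`
#'   (genes x n_perm, the spin-null gene weight distributions consumed by
#'   [rank_genes()]).
#' @export
spin_pvalue <- function(fit, X, y, spins) {
  sn <- spin_null(fit, X, y, spins)
  obs <- fit$r2[fit$chosen]
  p <- (1 + sum(sn$null_r2 >= obs)) / (1 + sn$n_perm)
  list(p = p, observed_r2 = obs, null_r2 = sn$null_r2,
       null_weights = sn$null_weights)
}
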