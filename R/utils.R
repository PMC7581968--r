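#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate coef cor cor.test dist lm median na.omit
#'   p.adjust pchisq phyper plogis pnorm pt qnorm quantile rbeta rbinom
#'   rlnorm rnorm runif sd setNames uniroot var
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Evenly spread points on the unit sphere (Fibonacci lattice)
#'
#' Deterministic quasi-uniform point set used for synthetic parcel centroids.
#'
#' @param n number of points.
#' @return an `n x 3` matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

# great-circle angle between rows of two unit-vector matrices
geodesic_angle <- function(a, b) {
  d <- rowSums(a * b)
  acos(pmin(1, pmax(-1, d)))
}

check_square_symmetric <- function(w, tol = 1e-6, what = "matrix") {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop2(what, " must be a square matrix")
  if (anyNA(w)) stop2(what, " contains NA/NaN entries")
  asym <- max(abs(w - t(w)))
  if (asym > tol)
    stop2(what, " is asymmetric (max |A - t(A)| = ", format(asym),
          ", tolerance ", format(tol), ")")
  invisible(asym)
}
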