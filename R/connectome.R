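#' Subject-level structural connectome
#'
#' Wraps a symmetric, nonnegative, zero-diagonal weighted connectivity matrix
#' over a parcellation together with subject metadata. No threshold is applied
#' to the weights at any point.
#'
#' @param weights square numeric matrix, nodes ordered as in `parc`.
#' @param parc a [parcellation()].
#' @param subject_id subject identifier.
#' @param group one of `"control"`, `"pd_high"`, `"pd_low"`.
#' @param age age in years.
#' @param sex `"male"` or `"female"`.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, parc, subject_id, group,
                       age = NA_real_, sex = NA_character_) {
  if (nrow(weights) != nrow(parc))
    stop2("matrix dimension (", nrow(weights),
          ") does not match parcellation size (", nrow(parc), ")")
  check_square_symmetric(weights, tol = 1e-9, what = "connectivity matrix")
  if (any(weights < 0)) stop2("connectivity weights must be nonnegative")
  group <- match.arg(group, c("control", "pd_high", "pd_low"))
  diag(weights) <- 0
  dimnames(weights) <- list(parc$name, parc$name)
  structure(list(subject_id = as.character(subject_id), group = group,
                 weights = weights,
                 covariates = list(age = age, sex = sex)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("Connectome", x$subject_id, "(", x$group, "):",
      nrow(x$weights), "nodes, density",
      sprintf("%.1f%%", connectome_density(x)), "\n")
  invisible(x)
}

#' Load a connectivity matrix into a connectome
#'
#' Accepts either a dense matrix file (TSV/CSV with a header row of region
#' names) or a long-format edge table with columns
#' `region_a`, `region_b`, `weight`. Near-symmetric input (numerical noise
#' below 1e-6) is symmetrised by averaging with its transpose; larger
#' asymmetry is an error.
#'
#' @param file path to the matrix file, or a numeric matrix.
#' @param parc a [parcellation()].
#' @param subject_id,group,age,sex subject metadata (see [connectome()]).
#' @return a [connectome()].
#' @export
load_connectome <- function(file, parc, subject_id, group,
                            age = NA_real_, sex = NA_character_) {
  w <- if (is.matrix(file)) file else read_connectivity_matrix(file, parc)
  if (nrow(w) != nrow(parc) || ncol(w) != nrow(parc))
    stop2("matrix dimension (", nrow(w), "x", ncol(w),
          ") does not match parcellation size (", nrow(parc), ")")
  if (anyNA(w)) stop2("connectivity matrix contains NA/NaN entries")
  if (any(w < 0)) stop2("connectivity weights must be nonnegative")
  asym <- max(abs(w - t(w)))
  if (asym >= 1e-6)
    stop2("connectivity matrix is asymmetric (max |A - t(A)| = ",
          format(asym), "); refusing to symmetrise")
  w <- (w + t(w)) / 2
  connectome(w, parc, subject_id, group, age, sex)
}

#' Read a dense or long-format connectivity matrix
#'
#' @param file path; TSV or CSV. A file whose header contains columns
#'   `region_a`, `region_b`, `weight` is treated as a long-format edge table;
#'   anything else as a dense matrix with a header row of region names.
#' @param parc a [parcellation()] fixing node order.
#' @return a numeric matrix in parcellation node order.
#' @export
read_connectivity_matrix <- function(file, parc) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  hdr <- strsplit(readLines(file, n = 1), sep)[[1]]
  if (all(c("region_a", "region_b", "weight") %in% hdr)) {
    ed <- read.delim(file, sep = sep, stringsAsFactors = FALSE)
    n <- nrow(parc)
    w <- matrix(0, n, n)
    ia <- match(ed$region_a, parc$name)
    ib <- match(ed$region_b, parc$name)
    if (anyNA(ia) || anyNA(ib))
      stop2("edge table names unknown to the parcellation")
    w[cbind(ia, ib)] <- ed$weight
    w[cbind(ib, ia)] <- ed$weight
    w
  } else {
    m <- as.matrix(read.delim(file, sep = sep, check.names = FALSE))
    storage.mode(m) <- "double"
    m
  }
}

#' Connectome density
#'
#' Fraction of off-diagonal unordered region pairs with nonzero weight,
#' reported as a percentage.
#'
#' @param x a [connectome()] or a square weight matrix.
#' @return density in percent, in \[0, 100\].
#' @export
connectome_density <- function(x) {
  w <- if (inherits(x, "connectome")) x$weights else x
  n <- nrow(w)
  ut <- upper.tri(w)
  100 * sum(w[ut] > 0) / sum(ut)
}

#' Arithmetic group-mean connectome
#'
#' @param connectomes list of [connectome()] objects on one parcellation.
#' @param group optional group to average over (default: all supplied).
#' @return a weight matrix (mean of the group's matrices).
#' @export
group_mean_weights <- function(connectomes, group = NULL) {
  if (!is.null(group))
    connectomes <- Filter(function(cx) cx$group == group, connectomes)
  if (!length(connectomes)) stop2("no connectomes to average")
  Reduce(`+`, lapply(connectomes, `[[`, "weights")) / length(connectomes)
}
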