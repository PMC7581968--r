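#' Module partition of the cortical connectome
#'
#' @param labels integer module labels, named by cortical region name.
#' @param gamma resolution parameter used (or `NA`).
#' @param provenance one of `"louvain_consensus"`, `"random_null"`, `"user"`.
#' @param module_hemisphere optional named character vector mapping module id
#'   (as character) to `"left"`/`"right"`. When absent, hemispheres are
#'   derived from the parcellation at classification time and modules are
#'   required to be hemisphere-pure. Random-null partitions carry their own
#'   (arbitrary, balanced) assignment because their modules deliberately
#'   ignore anatomy.
#' @return an object of class `module_partition`.
#' @export
module_partition <- function(labels, gamma = NA_real_,
                             provenance = c("user", "louvain_consensus",
                                            "random_null"),
                             module_hemisphere = NULL) {
  provenance <- match.arg(provenance)
  labels <- setNames(as.integer(labels), names(labels))
  if (anyNA(labels)) stop2("every cortical region must have a module label")
  structure(list(labels = labels,
                 gamma = gamma,
                 n_modules = length(unique(labels)),
                 provenance = provenance,
                 module_hemisphere = module_hemisphere),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition (", x$provenance, "): ", x$n_modules, " modules over ",
      length(x$labels), " cortical regions",
      if (!is.na(x$gamma)) paste0(", gamma = ", x$gamma), "\n", sep = "")
  invisible(x)
}

cortical_graph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

louvain_once <- function(g, gamma) {
  igraph::membership(igraph::cluster_louvain(g, resolution = gamma))
}

#' Consensus Louvain partition of the cortical connectome
#'
#' Runs the Louvain community-detection algorithm `n_runs` times on the
#' group-averaged cortical connectivity matrix, builds the co-assignment
#' (agreement) matrix across runs, thresholds it at its off-diagonal mean and
#' re-clusters the thresholded agreement graph, iterating until all runs
#' agree (at most `max_iter` consensus iterations). Deterministic given
#' `seed`.
#'
#' @param group_mean square cortical weight matrix (group average), or a full
#'   parcellation-sized matrix together with `parc` to extract the cortical
#'   submatrix.
#' @param parc optional [parcellation()]; when given, the cortical submatrix
#'   of `group_mean` is used and labels are named by region name.
#' @param gamma Louvain resolution parameter (default 1.0).
#' @param n_runs number of Louvain runs entering the consensus (default 1000).
#' @param seed RNG seed.
#' @param max_iter maximum consensus iterations.
#' @return a [module_partition()] with provenance `"louvain_consensus"`.
#' @export
louvain_consensus <- function(group_mean, parc = NULL, gamma = 1.0,
                              n_runs = 1000, seed = 1, max_iter = 20) {
  if (!is.null(parc)) {
    k <- cortical_idx(parc)
    group_mean <- group_mean[k, k]
    dimnames(group_mean) <- list(parc$name[k], parc$name[k])
  }
  if (n_runs < 1) stop2("n_runs must be >= 1")
  g <- cortical_graph(group_mean)
  if (igraph::components(g)$no > 1)
    warning("cortical graph is disconnected; components are partitioned ",
            "separately")
  set.seed(seed)
  runs <- replicate(n_runs, louvain_once(g, gamma))
  runs <- matrix(runs, ncol = n_runs)
  for (it in seq_len(max_iter)) {
    if (all_runs_equal(runs)) break
    co <- coassignment(runs)
    thr <- mean(co[upper.tri(co)])
    co[co <= thr] <- 0
    diag(co) <- 0
    gc2 <- cortical_graph(co)
    runs <- matrix(replicate(n_runs, louvain_once(gc2, 1.0)), ncol = n_runs)
  }
  lab <- canonical_labels(runs[, 1])
  names(lab) <- rownames(group_mean)
  module_partition(lab, gamma = gamma, provenance = "louvain_consensus")
}

all_runs_equal <- function(runs) {
  if (ncol(runs) == 1) return(TRUE)
  ref <- canonical_labels(runs[, 1])
  all(apply(runs[, -1, drop = FALSE], 2,
            function(r) identical(canonical_labels(r), ref)))
}

# relabel modules by first appearance so label values are comparable
canonical_labels <- function(lab) {
  as.integer(match(lab, unique(lab)))
}

coassignment <- function(runs) {
  n <- nrow(runs)
  co <- matrix(0, n, n)
  for (j in seq_len(ncol(runs))) {
    m <- outer(runs[, j], runs[, j], "==")
    co <- co + m
  }
  co / ncol(runs)
}

#' Split mixed-hemisphere modules into hemisphere-pure submodules
#'
#' Community detection on connectomes with strong homotopic connectivity can
#' return modules straddling the midline; connection-type classification
#' requires hemisphere-pure modules. This splits every module at the midline
#' (a module wholly within one hemisphere is kept as is) and relabels
#' modules consecutively, left hemisphere first.
#'
#' @param partition a [module_partition()].
#' @param parc the [parcellation()] supplying hemisphere membership.
#' @return a [module_partition()] with hemisphere-pure modules.
#' @export
split_by_hemisphere <- function(partition, parc) {
  hemi <- parc$hemisphere[match(names(partition$labels), parc$name)]
  if (anyNA(hemi)) stop2("partition regions unknown to the parcellation")
  key <- paste(hemi, partition$labels)
  ord <- unique(key[order(match(hemi, c("left", "right")),
                          partition$labels)])
  lab <- setNames(match(key, ord), names(partition$labels))
  module_partition(lab, gamma = partition$gamma,
                   provenance = partition$provenance)
}

#' Random-partition null for the module layout
#'
#' Generates a random undirected weighted graph with the same number of nodes
#' and edges as the group-averaged cortical connectome (weights shuffled from
#' the observed nonzero weights), partitions it with the Louvain algorithm at
#' the same resolution, and returns the resulting module allocation. Because
#' these modules ignore anatomy, the partition carries an arbitrary balanced
#' pseudo-hemisphere assignment of modules (alternating by module size) so
#' that connection-type classification can be replicated under the null.
#'
#' @inheritParams louvain_consensus
#' @return a [module_partition()] with provenance `"random_null"`.
#' @export
random_partition_null <- function(group_mean, parc = NULL, gamma = 1.0,
                                  seed = 1) {
  if (!is.null(parc)) {
    k <- cortical_idx(parc)
    group_mean <- group_mean[k, k]
    dimnames(group_mean) <- list(parc$name[k], parc$name[k])
  }
  n <- nrow(group_mean)
  wts <- group_mean[upper.tri(group_mean)]
  wts <- wts[wts > 0]
  set.seed(seed)
  g <- igraph::sample_gnm(n, length(wts), directed = FALSE)
  igraph::E(g)$weight <- sample(wts)
  lab <- canonical_labels(louvain_once(g, gamma))
  names(lab) <- rownames(group_mean)
  mods <- sort(unique(lab))
  sizes <- tabulate(lab)[mods]
  ord <- mods[order(-sizes, mods)]
  hemi <- setNames(rep(c("left", "right"), length.out = length(ord)),
                   as.character(ord))
  module_partition(lab, gamma = gamma, provenance = "random_null",
                   module_hemisphere = hemi[as.character(mods)])
}
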