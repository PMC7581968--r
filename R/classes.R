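#' Enumerate connection classes from a module partition
#'
#' Connections are classified into four kinds: `interhemispheric` (left
#' module to right module), `intrahemispheric` (two distinct modules in the
#' same hemisphere), `intramodular` (within one module) and
#' `subcortical_cortical` (a hemisphere's subcortical block of six deep grey
#' structures to an ipsilateral module). With `mL` left and `mR` right
#' modules this yields `mL*mR + choose(mL,2) + choose(mR,2) + (mL+mR) +
#' (mL+mR)` classes — 44 in the default study layout of 4 + 4 modules.
#'
#' Modules must be hemisphere-pure (all member regions in one hemisphere)
#' unless the partition carries its own pseudo-hemisphere assignment (the
#' random-partition null does). Ordering is deterministic: left before right,
#' ascending module id.
#'
#' @param partition a [module_partition()].
#' @param parc a [parcellation()].
#' @return a data.frame of class `connection_classes` with columns `label`,
#'   `kind`, `endpoint_a`, `endpoint_b`, carrying the member node index sets
#'   as attribute `node_sets`.
#' @export
enumerate_connection_classes <- function(partition, parc) {
  ctx <- cortical_idx(parc)
  lab <- partition$labels[parc$name[ctx]]
  if (anyNA(lab))
    stop2("partition does not label every cortical region of the parcellation")

  if (is.null(partition$module_hemisphere)) {
    hemi_of <- tapply(parc$hemisphere[ctx], lab, unique, simplify = FALSE)
    mixed <- names(hemi_of)[lengths(hemi_of) > 1]
    if (length(mixed))
      stop2("modules mix hemispheres: ", paste(mixed, collapse = ", "),
            " (hemisphere-pure modules are required)")
    mod_hemi <- vapply(hemi_of, identity, character(1))
  } else {
    mod_hemi <- partition$module_hemisphere
  }

  mods <- sort(as.integer(names(mod_hemi)))
  mod_hemi <- mod_hemi[as.character(mods)]
  mL <- mods[mod_hemi == "left"]
  mR <- mods[mod_hemi == "right"]

  node_sets <- lapply(mods, function(m) ctx[lab == m])
  names(node_sets) <- paste0("m", mods)
  node_sets$sc_left <- subcortical_block(parc, "left")
  node_sets$sc_right <- subcortical_block(parc, "right")

  rows <- list()
  for (a in mL) for (b in mR)
    rows[[length(rows) + 1]] <- c(kind = "interhemispheric",
                                  endpoint_a = paste0("m", a),
                                  endpoint_b = paste0("m", b))
  for (hm in list(mL, mR)) {
    if (length(hm) >= 2)
      for (i in seq_len(length(hm) - 1)) for (j in (i + 1):length(hm))
        rows[[length(rows) + 1]] <- c(kind = "intrahemispheric",
                                      endpoint_a = paste0("m", hm[i]),
                                      endpoint_b = paste0("m", hm[j]))
  }
  for (m in c(mL, mR))
    rows[[length(rows) + 1]] <- c(kind = "intramodular",
                                  endpoint_a = paste0("m", m),
                                  endpoint_b = paste0("m", m))
  for (m in mL)
    rows[[length(rows) + 1]] <- c(kind = "subcortical_cortical",
                                  endpoint_a = "sc_left",
                                  endpoint_b = paste0("m", m))
  for (m in mR)
    rows[[length(rows) + 1]] <- c(kind = "subcortical_cortical",
                                  endpoint_a = "sc_right",
                                  endpoint_b = paste0("m", m))

  cls <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  cls$label <- ifelse(cls$endpoint_a == cls$endpoint_b,
                      paste0("intra_", cls$endpoint_a),
                      paste0(sub("subcortical_cortical", "sc", cls$kind),
                             "_", cls$endpoint_a, "_", cls$endpoint_b))
  cls$label <- sub("^interhemispheric", "inter", cls$label)
  cls$label <- sub("^intrahemispheric", "intrahemi", cls$label)
  cls <- cls[, c("label", "kind", "endpoint_a", "endpoint_b")]
  attr(cls, "node_sets") <- node_sets
  class(cls) <- c("connection_classes", "data.frame")
  cls
}

#' Summed connection strength per connection class
#'
#' For each class, the sum of edge weights over unordered node pairs spanning
#' the class's two endpoint sets (within-set pairs counted once). Cortical-
#' cortical edges partition exactly across the interhemispheric,
#' intrahemispheric and intramodular classes, so those strengths sum to the
#' total cortical edge weight.
#'
#' @param x a [connectome()] or a weight matrix.
#' @param classes output of [enumerate_connection_classes()].
#' @return named numeric vector of strengths (one per class label).
#' @export
class_strengths <- function(x, classes) {
  w <- if (inherits(x, "connectome")) x$weights else x
  sets <- attr(classes, "node_sets")
  groups <- names(sets)
  memb <- matrix(0, nrow(w), length(groups),
                 dimnames = list(NULL, groups))
  for (g in groups) memb[sets[[g]], g] <- 1
  block <- t(memb) %*% w %*% memb
  s <- mapply(function(a, b) {
    if (a == b) block[a, a] / 2 else block[a, b]
  }, classes$endpoint_a, classes$endpoint_b)
  setNames(as.numeric(s), classes$label)
}

#' Per-class connection lengths and edge-level class labels
#'
#' Computes, for every class, the unweighted mean of the pairwise streamline
#' (or surrogate geodesic) lengths over the class's member region pairs, and
#' exports the edge-level records used for length-loss correlations. Pairs
#' are restricted to connected ones when a weight matrix is supplied,
#' otherwise to pairs with nonzero length.
#'
#' @param length_matrix symmetric nonnegative region-by-region length matrix.
#' @param classes output of [enumerate_connection_classes()].
#' @param weights optional weight matrix defining which pairs are connected.
#' @return list with `class_means` (data.frame `label`, `kind`,
#'   `mean_length`, `n_pairs`) and `edges` (data.frame `region_a`,
#'   `region_b`, `length`, `label`, `kind`).
#' @export
class_lengths <- function(length_matrix, classes, weights = NULL) {
  check_square_symmetric(length_matrix, tol = 1e-9, what = "length matrix")
  if (any(length_matrix < 0)) stop2("lengths must be nonnegative")
  keep <- if (is.null(weights)) length_matrix > 0 else weights > 0
  sets <- attr(classes, "node_sets")
  edges <- vector("list", nrow(classes))
  means <- numeric(nrow(classes))
  npairs <- integer(nrow(classes))
  for (i in seq_len(nrow(classes))) {
    a <- sets[[classes$endpoint_a[i]]]
    b <- sets[[classes$endpoint_b[i]]]
    if (identical(classes$endpoint_a[i], classes$endpoint_b[i])) {
      pr <- which(upper.tri(length_matrix)[a, a, drop = FALSE], arr.ind = TRUE)
      ij <- cbind(a[pr[, 1]], a[pr[, 2]])
    } else {
      ij <- as.matrix(expand.grid(a, b))
    }
    ok <- keep[ij]
    ij <- ij[ok, , drop = FALSE]
    len <- length_matrix[ij]
    means[i] <- if (length(len)) mean(len) else NA_real_
    npairs[i] <- length(len)
    edges[[i]] <- data.frame(region_a = ij[, 1], region_b = ij[, 2],
                             length = len,
                             label = rep(classes$label[i], nrow(ij)),
                             kind = rep(classes$kind[i], nrow(ij)),
                             stringsAsFactors = FALSE)
  }
  list(class_means = data.frame(label = classes$label, kind = classes$kind,
                                mean_length = means, n_pairs = npairs,
                                stringsAsFactors = FALSE),
       edges = do.call(rbind, edges))
}

#' Cohort-level connection-class strength table
#'
#' @param connectomes list of [connectome()] objects.
#' @param classes output of [enumerate_connection_classes()].
#' @return long data.frame: `subject_id`, `group`, `age`, `sex`, `label`,
#'   `kind`, `strength`.
#' @export
class_strength_table <- function(connectomes, classes) {
  rows <- lapply(connectomes, function(cx) {
    s <- class_strengths(cx, classes)
    data.frame(subject_id = cx$subject_id, group = cx$group,
               age = cx$covariates$age, sex = cx$covariates$sex,
               label = names(s), kind = classes$kind, strength = as.numeric(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Topological distance (shortest weighted path length)
#'
#' Shortest-path distance on the connectome with edge lengths taken as the
#' reciprocal of connection weight, so strong connections are topologically
#' short. Unreachable pairs are reported as `NA`.
#'
#' @param x a [connectome()] or weight matrix.
#' @return symmetric matrix of shortest weighted path lengths.
#' @export
topological_distance <- function(x) {
  w <- if (inherits(x, "connectome")) x$weights else x
  len <- w
  len[w > 0] <- 1 / w[w > 0]
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  d[is.infinite(d)] <- NA_real_
  dimnames(d) <- dimnames(w)
  d
}
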