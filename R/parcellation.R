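#' Parcellation data model
#'
#' A parcellation is the node universe of the connectome: a table of brain
#' regions with a 0-based contiguous `region_id`, a `name`, a `hemisphere`
#' (`"left"`/`"right"`), a `region_class` (`"cortical"`/`"subcortical"`) and,
#' for cortical regions, a unit-norm spherical centroid (`x`, `y`, `z`) on the
#' per-hemisphere inflated sphere. The default study layout is 360 cortical
#' regions (180 per hemisphere) plus 19 subcortical regions, 379 in total.
#'
#' @param regions a data.frame with columns `region_id`, `name`, `hemisphere`,
#'   `region_class` and (for cortical rows) `x`, `y`, `z`.
#' @return an object of class `parcellation` (a validated data.frame).
#' @export
parcellation <- function(regions) {
  need <- c("region_id", "name", "hemisphere", "region_class")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop2("parcellation is missing columns: ", paste(miss, collapse = ", "))
  if (!all(c("x", "y", "z") %in% names(regions)))
    regions$x <- regions$y <- regions$z <- NA_real_
  regions <- regions[order(regions$region_id),
                     c(need, "x", "y", "z")]
  ids <- regions$region_id
  if (anyDuplicated(ids) || !identical(as.integer(ids),
                                       seq_len(nrow(regions)) - 1L))
    stop2("region ids must be unique and contiguous from 0")
  if (!all(regions$hemisphere %in% c("left", "right")))
    stop2("hemisphere must be 'left' or 'right'")
  if (!all(regions$region_class %in% c("cortical", "subcortical")))
    stop2("region_class must be 'cortical' or 'subcortical'")
  ctx <- regions$region_class == "cortical"
  cen <- as.matrix(regions[ctx, c("x", "y", "z")])
  if (anyNA(cen) || any(!is.finite(cen)))
    stop2("every cortical region needs a finite centroid")
  nrm <- sqrt(rowSums(cen^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop2("cortical centroids must have unit norm (tolerance 1e-6)")
  rownames(regions) <- NULL
  class(regions) <- c("parcellation", "data.frame")
  regions
}

#' @export
print.parcellation <- function(x, ...) {
  ctx <- sum(x$region_class == "cortical")
  cat("Parcellation:", nrow(x), "regions (", ctx, "cortical,",
      nrow(x) - ctx, "subcortical )\n")
  invisible(x)
}

#' Read a parcellation from lookup and centroid tables
#'
#' The lookup table is a TSV with columns `region_id`, `name`, `hemisphere`,
#' `class`; centroids are a TSV with columns `region_id`, `x`, `y`, `z`
#' (cortical regions only).
#'
#' @param lookup_file path to the lookup TSV.
#' @param centroid_file path to the centroid TSV, or `NULL` if none.
#' @return a [parcellation()].
#' @export
read_parcellation <- function(lookup_file, centroid_file = NULL) {
  tab <- read.delim(lookup_file, stringsAsFactors = FALSE)
  if ("class" %in% names(tab) && !"region_class" %in% names(tab))
    names(tab)[names(tab) == "class"] <- "region_class"
  if (!is.null(centroid_file)) {
    cen <- read.delim(centroid_file, stringsAsFactors = FALSE)
    tab <- merge(tab, cen[, c("region_id", "x", "y", "z")],
                 by = "region_id", all.x = TRUE, sort = TRUE)
  }
  parcellation(tab)
}

# the six ipsilateral deep grey structures forming a hemisphere's
# subcortical block for connection-type classification
SUBCORTICAL_BLOCK <- c("thalamus", "caudate", "putamen", "pallidum",
                       "accumbens", "ventraldc")

#' Region indices (1-based) of a hemisphere's subcortical block
#'
#' The block comprises the six ipsilateral deep grey structures (thalamus,
#' caudate, putamen, pallidum, nucleus accumbens, ventral diencephalon);
#' other subcortical regions are carried in the parcellation but excluded
#' from connection-type classification.
#'
#' @param parc a [parcellation()].
#' @param hemisphere `"left"` or `"right"`.
#' @return integer row indices into `parc`.
#' @export
subcortical_block <- function(parc, hemisphere) {
  base <- sub("^(left|right)[_. ]", "", tolower(parc$name))
  which(parc$region_class == "subcortical" &
          parc$hemisphere == hemisphere &
          base %in% SUBCORTICAL_BLOCK)
}

cortical_idx <- function(parc, hemisphere = NULL) {
  k <- parc$region_class == "cortical"
  if (!is.null(hemisphere)) k <- k & parc$hemisphere == hemisphere
  which(k)
}
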