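# Independent brute-force oracles used across the suite.

# Floyd-Warshall all-pairs shortest paths on an edge-length matrix
# (0 = no edge, lengths otherwise)
fw_distances <- function(len) {
  n <- nrow(len)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[len > 0] <- len[len > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d[is.infinite(d)] <- NA_real_
  d
}

# Benjamini-Hochberg step-up, written from the definition
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# exact upper-tail hypergeometric by enumeration of all overlap values
hyper_upper_enum <- function(k, size_a, size_b, background) {
  ks <- 0:min(size_a, size_b)
  probs <- choose(size_a, ks) * choose(background - size_a, size_b - ks) /
    choose(background, size_b)
  sum(probs[ks >= k])
}

# count classes per kind, including zero-count kinds
kind_counts <- function(cls) {
  kinds <- c("interhemispheric", "intrahemispheric", "intramodular",
             "subcortical_cortical")
  vapply(kinds, function(k) sum(cls$kind == k), integer(1))
}

# brute-force connection-class counts for mL left / mR right modules
class_counts_brute <- function(mL, mR) {
  mods <- data.frame(id = seq_len(mL + mR),
                     hemi = rep(c("left", "right"), c(mL, mR)))
  inter <- intra <- 0
  for (i in seq_len(nrow(mods) - 1)) for (j in (i + 1):nrow(mods)) {
    if (mods$hemi[i] == mods$hemi[j]) intra <- intra + 1 else inter <- inter + 1
  }
  c(interhemispheric = inter, intrahemispheric = intra,
    intramodular = mL + mR, subcortical_cortical = mL + mR)
}

# Moran's I with inverse-angular-distance weights on the sphere
morans_i <- function(values, cen) {
  ang <- acos(pmax(pmin(tcrossprod(cen), 1), -1))
  w <- 1 / ang
  diag(w) <- 0
  w[is.infinite(w)] <- 0
  z <- values - mean(values)
  n <- length(z)
  (n / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
}

# small test fixtures -------------------------------------------------------

small_config <- function(...) {
  generator_config(n_regions_per_hemisphere = 30L, n_subcortical = 14L, ...)
}

# mid-size config preserving study-scale per-class edge counts for the
# replicate-based recovery properties
mid_config <- function(...) {
  generator_config(n_regions_per_hemisphere = 60L, n_subcortical = 14L, ...)
}

toy_parcellation <- function(n_per_hemi = 4, n_sub = 0) {
  cfg <- generator_config(n_regions_per_hemisphere = as.integer(n_per_hemi),
                          n_subcortical = as.integer(n_sub),
                          n_modules_per_hemisphere = 2L)
  make_parcellation(cfg)
}
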