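#' Synthetic study configuration
#'
#' Defaults describe the emulated cohort study: 180 cortical regions per hemisphere
#' plus 19 subcortical regions (379 in total), 4 cortical modules per
#' hemisphere, group sizes 34 controls / 67 high visual performers / 33 low
#' visual performers, and connection-strength attenuation in the low-
#' performing group confined to interhemispheric (20%) and subcortical-
#' cortical (10%) connections. Noise has two components: a
#' per-subject global streamline-count factor (log-normal, sdlog 0.2, i.e. a
#' between-subject coefficient of variation of about 20% in total connection
#' weight) and independent per-edge noise (log-normal, sdlog 0.25). At these
#' levels the planted attenuation yields group t statistics of a realistic
#' magnitude (roughly 2-5) for affected connection classes while unaffected
#' classes stay at the null.
#'
#' @param ... overrides for any default field.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_regions_per_hemisphere = 180L,
    n_subcortical = 19L,
    n_modules_per_hemisphere = 4L,
    n_controls = 34L, n_pd_high = 67L, n_pd_low = 33L,
    attenuation = c(interhemispheric = 0.2, subcortical_cortical = 0.1,
                    intrahemispheric = 0, intramodular = 0),
    edge_noise_sd = 0.25,      # per-edge log-normal sdlog
    subject_noise_sd = 0.2,    # per-subject global log-normal sdlog
    target_density = 0.6,      # expected fraction of nonzero pairs
    base_scale = 100,          # weight scale of the shortest connections
    weight_decay = 0.6,        # distance decay scale of base weights
    module_boost = 2,          # within-module weight multiplier
    presence_decay = 0.8,      # distance scale of the edge-presence logit
    length_scale_mm = 50,      # mm per unit of embedded distance
    n_genes = 500L, n_signal_genes = 30L,
    signal_strength = 0.7,     # mixing of the loss map into signal genes
    expr_lengthscale = 0.3,    # spatial autocorrelation scale (radians)
    n_cell_types = 6L, cells_per_type = 40L,
    marker_boost = 25,         # signal-gene boost in their cell type; with 6
                               # types this puts their specificity near 0.8

    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop2("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$n_controls >= 3, cfg$n_pd_high >= 3, cfg$n_pd_low >= 3,
            all(cfg$attenuation >= 0), all(cfg$attenuation < 1),
            cfg$expr_lengthscale > 0,
            cfg$n_signal_genes <= cfg$n_genes)
  class(cfg) <- "generator_config"
  cfg
}

SUBCORTICAL_NAMES <- c(SUBCORTICAL_BLOCK, "hippocampus", "amygdala",
                       "cerebellum")

#' Synthetic parcellation with spherical centroids
#'
#' Cortical centroids are a Fibonacci lattice on each hemisphere's unit
#' sphere (the right hemisphere mirrored in x), so modules defined as
#' contiguous azimuthal sectors are hemisphere-pure by construction.
#' Subcortical regions are appended without centroids: paired deep grey
#' structures (thalamus, caudate, putamen, pallidum, accumbens, ventral
#' diencephalon, then hippocampus, amygdala, cerebellum) and, for an odd
#' count, a midline brainstem (carried as left, excluded from the
#' subcortical block).
#'
#' @param config a [generator_config()].
#' @return a [parcellation()] (default layout: 379 regions, 360 cortical).
#' @export
make_parcellation <- function(config = generator_config()) {
  nh <- config$n_regions_per_hemisphere
  cen <- fibonacci_sphere(nh)
  regions <- data.frame(
    region_id = seq_len(2 * nh) - 1L,
    name = c(sprintf("L_ctx_%03d", seq_len(nh)),
             sprintf("R_ctx_%03d", seq_len(nh))),
    hemisphere = rep(c("left", "right"), each = nh),
    region_class = "cortical",
    x = c(cen[, 1], -cen[, 1]), y = c(cen[, 2], cen[, 2]),
    z = c(cen[, 3], cen[, 3]),
    stringsAsFactors = FALSE)
  ns <- config$n_subcortical
  if (ns == 0) return(parcellation(regions))
  npairs <- ns %/% 2
  nm <- rep(SUBCORTICAL_NAMES, length.out = npairs)
  nm <- make.unique(nm, sep = "_")
  sub <- data.frame(
    region_id = 2L * nh + seq_len(2 * npairs) - 1L,
    name = paste0(rep(c("left_", "right_"), npairs), rep(nm, each = 2)),
    hemisphere = rep(c("left", "right"), npairs),
    region_class = "subcortical",
    x = NA_real_, y = NA_real_, z = NA_real_,
    stringsAsFactors = FALSE)
  if (ns %% 2 == 1)
    sub <- rbind(sub, data.frame(region_id = 2L * nh + 2L * npairs,
                                 name = "brainstem", hemisphere = "left",
                                 region_class = "subcortical",
                                 x = NA_real_, y = NA_real_, z = NA_real_,
                                 stringsAsFactors = FALSE))
  parcellation(rbind(regions, sub))
}

# azimuthal sector labels (1..n_modules) for unit-sphere centroids
sector_labels <- function(cen, n_modules) {
  theta <- atan2(cen[, 2], cen[, 1])
  findInterval(theta, seq(-pi, pi, length.out = n_modules + 1),
               rightmost.closed = TRUE)
}

#' Planted module partition of a synthetic parcellation
#'
#' Modules are the contiguous azimuthal sectors used by the generator: left
#' hemisphere modules get ids `1..m`, right `m+1..2m`.
#'
#' @param parc a [make_parcellation()] parcellation.
#' @param config the matching [generator_config()].
#' @return a [module_partition()] with provenance `"user"`.
#' @export
planted_partition <- function(parc, config = generator_config()) {
  m <- config$n_modules_per_hemisphere
  li <- cortical_idx(parc, "left")
  ri <- cortical_idx(parc, "right")
  labL <- sector_labels(as.matrix(parc[li, c("x", "y", "z")]), m)
  labR <- sector_labels(as.matrix(parc[ri, c("x", "y", "z")]), m) + m
  lab <- setNames(c(labL, labR), parc$name[c(li, ri)])
  module_partition(lab, gamma = NA_real_, provenance = "user")
}

# physical 3D positions: hemisphere spheres offset left/right, subcortical
# clustered between and below them
region_positions <- function(parc) {
  pos <- matrix(NA_real_, nrow(parc), 3)
  ctx <- parc$region_class == "cortical"
  off <- ifelse(parc$hemisphere == "left", -1, 1)
  pos[ctx, ] <- as.matrix(parc[ctx, c("x", "y", "z")]) +
    cbind(off[ctx], 0, 0)
  # deep grey structures cluster below and between the hemispheres; their
  # lateral (x) extent is small relative to the cortical span, as in anatomy
  sub <- which(!ctx)
  if (length(sub)) {
    ring <- fibonacci_sphere(length(sub)) %*% diag(c(0.1, 0.25, 0.25))
    pos[sub, ] <- cbind(0.05 * off[sub], 0, -0.9) + ring
  }
  pos
}

# connection-kind matrix under the planted partition (NA = unclassified)
planted_kind_matrix <- function(parc, config) {
  n <- nrow(parc)
  part <- planted_partition(parc, config)
  lab <- rep(NA_integer_, n)
  lab[match(names(part$labels), parc$name)] <- part$labels
  hemi <- parc$hemisphere
  ctx <- parc$region_class == "cortical"
  blkL <- subcortical_block(parc, "left")
  blkR <- subcortical_block(parc, "right")
  blk <- rep(NA_character_, n)
  blk[blkL] <- "left"; blk[blkR] <- "right"

  kind <- matrix(NA_character_, n, n)
  cc <- outer(ctx, ctx, "&")
  same_hemi <- outer(hemi, hemi, "==")
  same_mod <- outer(lab, lab, "==")
  kind[cc & !same_hemi] <- "interhemispheric"
  kind[cc & same_hemi & !same_mod] <- "intrahemispheric"
  kind[cc & same_hemi & same_mod] <- "intramodular"
  sc <- outer(!is.na(blk), ctx, "&") & outer(blk, hemi, "==")
  kind[sc | t(sc)] <- "subcortical_cortical"
  kind
}

#' Simulate a cohort of structural connectomes
#'
#' Base connection weights decay exponentially with the Euclidean distance
#' between embedded region positions (two offset hemisphere spheres with a
#' deep subcortical cluster), with a within-module weight boost, so
#' intramodular connections are short and strong while interhemispheric and
#' subcortical-cortical connections are long and weak. Edge presence is
#' Bernoulli with a distance-decaying probability calibrated so the expected
#' density matches `target_density`. Per-subject weights are the base
#' weights times a global subject factor and independent per-edge
#' multiplicative log-normal noise (weights stay nonnegative). In the
#' `pd_low` group, edges are attenuated by the configured per-kind fractions
#' under the planted module partition. Ages and sex ratios are drawn from
#' the emulated cohort's group demographics.
#'
#' @param config a [generator_config()].
#' @param parc optional parcellation (defaults to
#'   `make_parcellation(config)`).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list: `connectomes` (list of [connectome()]), `lengths`
#'   (region-by-region mm distance matrix), `parcellation`, `config`.
#' @export
make_cohort <- function(config = generator_config(), parc = NULL,
                        seed = config$seed) {
  if (is.null(parc)) parc <- make_parcellation(config)
  n <- nrow(parc)
  pos <- region_positions(parc)
  D <- as.matrix(dist(pos))
  lengths <- D * config$length_scale_mm
  diag(lengths) <- 0

  base <- config$base_scale * exp(-D / config$weight_decay)
  kind <- planted_kind_matrix(parc, config)
  base[kind %in% "intramodular"] <- config$module_boost *
    base[kind %in% "intramodular"]
  diag(base) <- 0

  ut <- upper.tri(D)
  cal <- function(a) mean(plogis(a - D[ut] / config$presence_decay)) -
    config$target_density
  a0 <- uniroot(cal, c(-20, 20))$root
  pedge <- plogis(a0 - D / config$presence_decay)

  att <- matrix(1, n, n)
  for (kd in names(config$attenuation)) {
    f <- config$attenuation[[kd]]
    if (f > 0) att[kind %in% kd] <- 1 - f
  }

  groups <- rep(c("control", "pd_high", "pd_low"),
                c(config$n_controls, config$n_pd_high, config$n_pd_low))
  demo <- list(control = c(66.4, 9.3, 0.457),
               pd_high = c(62.2, 7.2, 0.478),
               pd_low = c(68.7, 7.3, 0.636))
  set.seed(seed)
  nu <- sum(ut)
  connectomes <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    w <- matrix(0, n, n)
    subj <- exp(rnorm(1, 0, config$subject_noise_sd))
    e <- exp(rnorm(nu, 0, config$edge_noise_sd))
    present <- rbinom(nu, 1, pedge[ut])
    w[ut] <- base[ut] * subj * e * present
    if (g == "pd_low") w[ut] <- w[ut] * att[ut]
    w <- w + t(w)
    d <- demo[[g]]
    connectomes[[i]] <- connectome(
      w, parc, sprintf("%s_%02d", g, i), g,
      age = rnorm(1, d[1], d[2]),
      sex = if (runif(1) < d[3]) "male" else "female")
  }
  list(connectomes = connectomes, lengths = lengths, parcellation = parc,
       config = config)
}

# smooth Gaussian random fields on the sphere: von Mises-Fisher kernel
# smoothing of white noise, column-standardised
smooth_fields <- function(cen, n_fields, lengthscale) {
  kappa <- 1 / lengthscale^2
  ang <- tcrossprod(cen)                 # cos(angle) for unit vectors
  K <- exp(kappa * (ang - 1))            # stabilised vMF kernel
  K <- K / rowSums(K)
  f <- K %*% matrix(rnorm(nrow(cen) * n_fields), nrow(cen))
  f <- sweep(f, 2, colMeans(f))
  sweep(f, 2, apply(f, 2, sd), "/")
}

#' Simulate regional gene expression, gene metadata and single-cell data
#'
#' Noise genes are spatially autocorrelated Gaussian random fields on the
#' cortical sphere (von Mises-Fisher kernel smoothing of white noise, with
#' the configured length-scale). Signal genes mix the standardised loss map
#' into such a field with weight `signal_strength`, half positively
#' (upweighted-like) and half negatively (downweighted-like). Transcript
#' lengths are log-normal and GC content Beta-distributed. The cell-by-gene
#' table gives signal genes elevated expression in one designated cell type
#' (the first, "oligodendrocyte"), so cell-type enrichment of recovered
#' genes can be validated against a known truth.
#'
#' @param config a [generator_config()].
#' @param loss_map [regional_loss()] output (or numeric vector) on the
#'   modelled hemisphere's cortical regions.
#' @param parc the parcellation the loss map lives on.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param hemisphere modelled hemisphere (default `"left"`).
#' @return list: `expression` (regions x genes), `meta` (data.frame
#'   `length`, `gc`; rownames = genes), `cell_by_gene` (cells x genes),
#'   `cell_labels`, `signal_genes`, `signal_sign` (+1 upweighted-like /
#'   -1 downweighted-like), `signal_cell_type`.
#' @export
make_expression <- function(config = generator_config(), loss_map, parc,
                            seed = config$seed, hemisphere = "left") {
  y <- if (is.data.frame(loss_map)) loss_map$loss else as.numeric(loss_map)
  rows <- cortical_idx(parc, hemisphere)
  if (length(y) != length(rows))
    stop2("loss map must cover the modelled hemisphere's cortical regions")
  cen <- as.matrix(parc[rows, c("x", "y", "z")])
  ng <- config$n_genes
  nsig <- config$n_signal_genes
  alpha <- config$signal_strength

  set.seed(seed)
  fields <- smooth_fields(cen, ng, config$expr_lengthscale)
  genes <- sprintf("GENE%04d", seq_len(ng))
  colnames(fields) <- genes
  sig_idx <- sample.int(ng, nsig)
  sig_sign <- rep(c(1, -1), length.out = nsig)
  ys <- as.numeric(scale(y))
  for (k in seq_len(nsig)) {
    j <- sig_idx[k]
    fields[, j] <- alpha * sig_sign[k] * ys +
      sqrt(1 - alpha^2) * fields[, j]
  }
  expression <- fields + 5          # arbitrary positive baseline
  rownames(expression) <- parc$name[rows]

  meta <- data.frame(length = rlnorm(ng, meanlog = 7.5, sdlog = 0.8),
                     gc = rbeta(ng, 20, 21),
                     row.names = genes)

  types <- c("oligodendrocyte", "astrocyte", "microglia",
             "neuron_excitatory", "neuron_inhibitory", "opc",
             "endothelial", "pericyte")[seq_len(config$n_cell_types)]
  n_cells <- config$n_cell_types * config$cells_per_type
  cell_labels <- rep(types, each = config$cells_per_type)
  mu <- rlnorm(ng, meanlog = 1, sdlog = 0.5)
  cbg <- matrix(rlnorm(n_cells * ng, meanlog = 0, sdlog = 0.4),
                n_cells, ng) * rep(mu, each = n_cells)
  colnames(cbg) <- genes
  cbg[cell_labels == types[1], sig_idx] <-
    cbg[cell_labels == types[1], sig_idx] * config$marker_boost

  list(expression = expression, meta = meta, cell_by_gene = cbg,
       cell_labels = cell_labels,
       signal_genes = genes[sig_idx], signal_sign = sig_sign,
       signal_cell_type = types[1])
}
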