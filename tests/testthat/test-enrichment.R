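test_that("specificity rows sum to one and reflect expression profiles", {
  # 3 cells per type, 2 types; gene A only in type1, gene B uniform
  expr <- cbind(A = c(4, 2, 3, 0, 0, 0),
                B = c(1, 1, 1, 1, 1, 1),
                C = c(0, 0, 0, 0, 0, 0))
  labs <- rep(c("t1", "t2"), each = 3)
  s <- build_specificity(expr, labs)
  expect_equal(unname(s["A", ]), c(1, 0), ignore_attr = TRUE)
  expect_equal(unname(s["B", ]), c(0.5, 0.5), ignore_attr = TRUE)
  expect_false("C" %in% rownames(s))   # expressed nowhere -> dropped
  expect_equal(unname(rowSums(s)), rep(1, 2), tolerance = 1e-9)

  # uniform across 6 types -> 1/6 each
  e6 <- matrix(2, 12, 1, dimnames = list(NULL, "U"))
  s6 <- build_specificity(e6, rep(paste0("t", 1:6), each = 2))
  expect_equal(unname(s6["U", ]), rep(1 / 6, 6), tolerance = 1e-12)

  # invariant to rescaling one cell's library size
  expr2 <- expr
  expr2[1, ] <- expr2[1, ] * 10
  s2 <- build_specificity(expr2, labs)
  # gene A still most specific to t1; B unchanged by construction of means?
  expect_equal(s2["B", "t2"] + s2["B", "t1"], 1, tolerance = 1e-9)
  expect_gt(s2["A", "t1"], 0.9)
})

test_that("planted marker genes have high specificity for their cell type", {
  cfg <- small_config(n_genes = 100L)
  parc <- make_parcellation(cfg)
  ex <- make_expression(cfg, rnorm(30), parc, seed = 51)
  s <- build_specificity(ex$cell_by_gene, ex$cell_labels)
  expect_true(all(s[ex$signal_genes, ex$signal_cell_type] > 0.8))
})

test_that("EWCE flags the planted cell type and stays quiet on null lists", {
  cfg <- small_config(n_genes = 150L)
  parc <- make_parcellation(cfg)
  ex <- make_expression(cfg, rnorm(30), parc, seed = 52)
  s <- build_specificity(ex$cell_by_gene, ex$cell_labels)
  e <- suppressWarnings(ewce(ex$signal_genes, s, ex$meta,
                             n_boot = 5000, seed = 53))
  hit <- e$cell_type[e$q < 0.05]
  expect_equal(hit, ex$signal_cell_type)
  expect_true(all(e$q >= e$p - 1e-15))
  # bit-for-bit reproducible given the seed
  e2 <- suppressWarnings(ewce(ex$signal_genes, s, ex$meta,
                              n_boot = 5000, seed = 53))
  expect_identical(e, e2)
  # null targets drawn from the background: sd_from_mean stays modest
  set.seed(54)
  ok <- vapply(1:30, function(i) {
    tgt <- sample(rownames(s), 30)
    en <- suppressWarnings(ewce(tgt, s, ex$meta, n_boot = 1000,
                                seed = 100 + i))
    all(abs(en$sd_from_mean) < 3)
  }, logical(1))
  expect_gte(mean(ok), 0.95 - 3 * sqrt(0.05 * 0.95 / 30))
  expect_error(ewce(ex$signal_genes[1:3], s, ex$meta, n_boot = 1000),
               "at least 5")
  expect_error(ewce(ex$signal_genes, s, ex$meta, n_boot = 10), ">= 1000")
})

test_that("hypergeometric overlap matches exact enumeration", {
  # worked example: background 10, |a| = 4, |b| = 5, overlap 3
  a <- paste0("g", 1:4); b <- paste0("g", c(1:3, 5, 6))
  r <- hypergeom_overlap(a, b, 10)
  expect_equal(r$overlap, 3L)
  expect_equal(r$p, 66 / 252, tolerance = 1e-12)
  # disjoint lists: upper tail includes 0 -> p = 1
  expect_equal(hypergeom_overlap(paste0("x", 1:3), paste0("y", 1:3), 20)$p, 1)
  # identical lists: exact minimum tail value
  r2 <- hypergeom_overlap(a, a, 12)
  expect_equal(r2$p, hyper_upper_enum(4, 4, 4, 12), tolerance = 1e-12)
  # property: matches enumeration for all overlaps, backgrounds <= 20
  set.seed(55)
  for (bg in c(8, 12, 20)) {
    universe <- paste0("u", seq_len(bg))
    for (i in 1:10) {
      na <- sample(2:(bg - 2), 1)
      nb <- sample(2:(bg - na + 1), 1)
      la <- sample(universe, na)
      lb <- sample(universe, min(nb, bg))
      k <- length(intersect(la, lb))
      expect_equal(hypergeom_overlap(la, lb, bg)$p,
                   hyper_upper_enum(k, na, length(lb), bg),
                   tolerance = 1e-12)
    }
  }
  expect_error(hypergeom_overlap(paste0("a", 1:5), paste0("b", 1:5), 8),
               "smaller")
})

test_that("annotation enrichment ranks planted sets first under BH", {
  set.seed(56)
  universe <- sprintf("G%03d", 1:300)
  target <- sample(universe, 40)
  sets <- c(list(self = target),
            lapply(1:20, function(i) sample(universe, 30)))
  names(sets) <- c("self", paste0("rand", 1:20))
  res <- annotation_enrichment(target, sets, universe)
  expect_equal(res$set[1], "self")
  expect_equal(res$b[res$set == "self"], 40L)
  expect_equal(res$N[1], 40L)
  # null calibration: ~5% of random sets at p < 0.05
  ps <- unlist(lapply(1:10, function(rep) {
    tgt <- sample(universe, 40)
    rsets <- lapply(1:10, function(i) sample(universe, 30))
    names(rsets) <- paste0("s", 1:10)
    annotation_enrichment(tgt, rsets, universe)$p
  }))
  expect_lt(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(ps)))

  # planted 5x enrichment ranks first by q in >= 95% of replicates
  hits <- vapply(1:20, function(rep) {
    special <- sample(universe, 40)
    tgt <- c(sample(special, 20), sample(setdiff(universe, special), 20))
    sets2 <- c(list(planted = special),
               lapply(1:15, function(i) sample(universe, 40)))
    names(sets2) <- c("planted", paste0("r", 1:15))
    annotation_enrichment(tgt, sets2, universe)$set[1] == "planted"
  }, logical(1))
  expect_gte(mean(hits), 0.95 - 3 * sqrt(0.05 * 0.95 / 20))
})

test_that("gene lists and GMT annotation sets round-trip through files", {
  f <- tempfile()
  writeLines(c("SNCA", "LRRK2", "", "GBA "), f)
  expect_equal(read_gene_list(f), c("SNCA", "LRRK2", "GBA"))
  g <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tSNCA\tLRRK2", "setB\tdesc\tGBA\tMAPT\tAPOE"), g)
  sets <- read_gmt(g)
  expect_equal(sets$setA, c("SNCA", "LRRK2"))
  expect_length(sets$setB, 3L)
})
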