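make_strength_fixture <- function(n_ctl = 10, n_pat = 8, seed = 1) {
  set.seed(seed)
  subj <- c(sprintf("c%02d", seq_len(n_ctl)), sprintf("p%02d", seq_len(n_pat)))
  grp <- rep(c("control", "pd_low"), c(n_ctl, n_pat))
  labs <- c("A", "B")
  do.call(rbind, lapply(seq_along(subj), function(i)
    data.frame(subject_id = subj[i], group = grp[i],
               age = rnorm(1, 65, 5),
               sex = sample(c("male", "female"), 1),
               label = labs, kind = c("interhemispheric", "intramodular"),
               strength = rnorm(2, 100, 10), stringsAsFactors = FALSE)))
}

test_that("wm loss is the tanh of the control-referenced z", {
  tab <- make_strength_fixture()
  ctl <- tab[tab$group == "control" & tab$label == "A", ]
  mu <- mean(ctl$strength); sdv <- sd(ctl$strength)
  # plant patients at exact z offsets
  tab$strength[tab$group == "pd_low" & tab$label == "A"] <-
    mu + c(0, -sdv, 2 * sdv, 1, -2, 3, 0.5, -0.5)
  loss <- wm_loss(tab)
  pa <- loss[loss$group == "pd_low" & loss$label == "A", ]
  expect_equal(pa$loss[1], 0)                    # at control mean
  expect_equal(pa$loss[2], tanh(1))              # 1 SD below -> 0.76159...
  expect_equal(pa$loss[3], tanh(-2))             # 2 SD above -> -0.96403...
  expect_true(all(abs(loss$loss) < 1))
  # strictly decreasing in strength
  o <- order(pa$strength)
  expect_true(all(diff(pa$loss[o]) < 0))
})

test_that("zero-variance classes are excluded with a warning", {
  tab <- make_strength_fixture()
  tab$strength[tab$label == "B"] <- 7
  expect_warning(loss <- wm_loss(tab), "zero-variance")
  expect_false("B" %in% loss$label)
  expect_error(wm_loss(tab[tab$subject_id %in% c("c01", "c02", "p01"), ]),
               "3 control")
})

test_that("contrasts reduce to the pooled t without covariates and flip sign", {
  cfg <- small_config()
  parc <- make_parcellation(cfg)
  coh <- make_cohort(cfg, parc, seed = 13)
  cls <- enumerate_connection_classes(planted_partition(parc, cfg), parc)
  tab <- class_strength_table(coh$connectomes, cls)
  tab <- tab[tab$label %in% unique(tab$label)[1:5], ]

  ct <- contrast_classes(tab, covariates = character(0))
  for (lb in unique(tab$label)) {
    d <- tab[tab$label == lb & tab$group %in% c("pd_high", "pd_low"), ]
    tt <- t.test(strength ~ group, data = d, var.equal = TRUE)
    expect_equal(abs(ct$t[ct$label == lb]), abs(tt$statistic[[1]]),
                 tolerance = 1e-9)
  }
  ct_flip <- contrast_classes(tab, groups = c("pd_low", "pd_high"),
                              covariates = character(0))
  expect_equal(ct_flip$beta, -ct$beta, tolerance = 1e-9)
  expect_equal(abs(ct_flip$t), abs(ct$t), tolerance = 1e-9)
  # q is BH and never below p
  expect_true(all(ct$q >= ct$p - 1e-15))
  expect_equal(ct$q, bh_stepup(ct$p))
})

test_that("mixed-model contrast agrees with the fixed fit in direction", {
  skip_if_not_installed("lmerTest")
  cfg <- small_config()
  parc <- make_parcellation(cfg)
  coh <- make_cohort(cfg, parc, seed = 14)
  cls <- enumerate_connection_classes(planted_partition(parc, cfg), parc)
  tab <- class_strength_table(coh$connectomes, cls)
  fx <- contrast_classes(tab)
  mx <- suppressMessages(contrast_classes(tab, method = "mixed"))
  inter <- fx$kind == "interhemispheric"
  expect_true(all(sign(mx$beta[inter]) == sign(fx$beta[inter])))
})

test_that("composite loss sums a kind's classes and separates groups", {
  tab <- make_strength_fixture()
  loss <- wm_loss(tab)
  loss$loss[loss$subject_id == "p01"] <- c(0.3, -0.1)
  loss$kind <- "interhemispheric"
  comp <- composite_loss(loss, "interhemispheric")
  expect_equal(comp$composite[comp$subject_id == "p01"], 0.2)

  cfg <- small_config()
  parc <- make_parcellation(cfg)
  coh <- make_cohort(cfg, parc, seed = 15)
  cls <- enumerate_connection_classes(planted_partition(parc, cfg), parc)
  full <- wm_loss(class_strength_table(coh$connectomes, cls))
  cm <- composite_loss(full, "interhemispheric")
  wt <- stats::wilcox.test(cm$composite[cm$group == "pd_low"],
                           cm$composite[cm$group == "pd_high"],
                           alternative = "greater")
  expect_lt(wt$p.value, 0.01)
  att <- ifelse(cm$group == "pd_low", 0.2, 0)
  expect_gt(spearman_cor(cm$composite, att)$rho, 0)
})

test_that("spearman matches the rank formula and handles monotone cases", {
  x <- c(-3, -1, 0, 2, 5, 7)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # 8-point toy against the brute-force rank formula (no ties)
  set.seed(17)
  a <- rnorm(8); b <- rnorm(8)
  rho_brute <- 1 - 6 * sum((rank(a) - rank(b))^2) / (8 * (8^2 - 1))
  expect_equal(spearman_cor(a, b)$rho, rho_brute, tolerance = 1e-12)
  expect_error(spearman_cor(1:3, 1:3), "length")
})

test_that("summary t test matches raw-sample computation", {
  set.seed(18)
  x <- rnorm(40); y <- rnorm(25, 0.5)
  st <- summary_t_test(mean(x), sd(x), 40, mean(y), sd(y), 25)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(st$t, tt$statistic[[1]], tolerance = 1e-9)
  expect_equal(st$p, tt$p.value, tolerance = 1e-9)
  expect_equal(summary_t_test(5, 1, 10, 5, 2, 12)$t, 0)
  expect_error(summary_t_test(1, 0, 5, 2, 1, 5), "positive")
})

test_that("chi-squared on 2x2 tables matches the classical test", {
  # perfectly proportional table -> statistic 0
  expect_equal(chi2_2x2(10, 20, 5, 10, yates = FALSE)$statistic, 0)
  expect_error(chi2_2x2(-1, 2, 3, 4), "nonnegative")
  r <- chi2_2x2(3, 7, 8, 2, yates = TRUE)
  ref <- suppressWarnings(chisq.test(matrix(c(3, 7, 8, 2), 2, byrow = TRUE),
                                     correct = TRUE))
  expect_equal(r$statistic, ref$statistic[[1]])
})

test_that("BH correction agrees with a brute-force step-up on random p", {
  set.seed(19)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("normality screen reports a Shapiro-Wilk W per class", {
  tab <- make_strength_fixture(n_ctl = 15, n_pat = 15)
  ns <- normality_screen(tab)
  expect_equal(nrow(ns), 2L)
  expect_true(all(ns$W > 0 & ns$W <= 1))
})
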