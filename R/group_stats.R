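#' Control-referenced white-matter loss scores
#'
#' Normalises each subject's class strength to the control distribution
#' (z-score) and transforms it as `loss = tanh(-z)`, so higher scores mean
#' greater connection loss and scores are bounded in (-1, 1). Classes with
#' zero variance among controls are excluded with a warning.
#'
#' @param strengths long table from [class_strength_table()].
#' @param control_group group label identifying controls (default
#'   `"control"`); at least 3 controls are required.
#' @return `strengths` with added columns `z` and `loss`.
#' @export
wm_loss <- function(strengths, control_group = "control") {
  ctl <- strengths[strengths$group == control_group, ]
  if (length(unique(ctl$subject_id)) < 3)
    stop2("at least 3 control subjects are required")
  mu <- tapply(ctl$strength, ctl$label, mean)
  sdv <- tapply(ctl$strength, ctl$label, sd)
  bad <- names(sdv)[sdv <= 0 | !is.finite(sdv)]
  if (length(bad)) {
    warning("excluding zero-variance classes: ", paste(bad, collapse = ", "))
    strengths <- strengths[!strengths$label %in% bad, ]
  }
  strengths$z <- (strengths$strength - mu[strengths$label]) /
    sdv[strengths$label]
  strengths$loss <- tanh(-strengths$z)
  strengths
}

#' Composite white-matter loss score for one connection kind
#'
#' Sum of a subject's loss scores over all classes of the given kind (e.g.
#' the composite interhemispheric loss score).
#'
#' @param loss output of [wm_loss()].
#' @param class_kind one of the four connection kinds.
#' @return data.frame `subject_id`, `group`, `composite`.
#' @export
composite_loss <- function(loss, class_kind) {
  sub <- loss[loss$kind == class_kind, ]
  if (!nrow(sub)) stop2("no classes of kind ", class_kind)
  agg <- aggregate(loss ~ subject_id + group, data = sub, FUN = sum)
  names(agg)[3] <- "composite"
  agg[order(agg$subject_id), ]
}

#' Per-connection group contrasts with covariates and FDR
#'
#' Fits, for every connection class, a linear model
#' `strength ~ group + age + sex` over the two contrasted groups and reports
#' the group coefficient, its t statistic and two-sided p value, with
#' Benjamini-Hochberg FDR correction across all classes tested. A mixed
#' variant (`method = "mixed"`) fits, per connection kind, a model with a
#' per-class group effect and a subject random intercept shared across the
#' kind's classes (requires lmerTest).
#'
#' @param strengths long table from [class_strength_table()].
#' @param groups length-2 character vector; the second level's coefficient is
#'   reported (default `c("pd_high", "pd_low")`).
#' @param covariates covariate column names (default `c("age", "sex")`).
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @param method `"fixed"` (default) or `"mixed"`.
#' @return data.frame of class `contrast_result`: `label`, `kind`, `beta`,
#'   `t`, `p`, `q`, `significant`.
#' @export
contrast_classes <- function(strengths, groups = c("pd_high", "pd_low"),
                             covariates = c("age", "sex"), fdr = 0.05,
                             method = c("fixed", "mixed")) {
  method <- match.arg(method)
  d <- strengths[strengths$group %in% groups, ]
  if (length(unique(d$subject_id[d$group == groups[1]])) < 2 ||
      length(unique(d$subject_id[d$group == groups[2]])) < 2)
    stop2("at least 2 subjects per group are required")
  for (cv in covariates)
    if (anyNA(d[[cv]])) stop2("covariate '", cv, "' has missing values")
  d$group <- factor(d$group, levels = groups)
  labs <- unique(d$label)
  kinds <- d$kind[match(labs, d$label)]
  fml <- stats::reformulate(c("group", covariates), response = "strength")

  if (method == "fixed") {
    res <- t(vapply(labs, function(lb) {
      fit <- lm(fml, data = d[d$label == lb, ])
      cf <- coef(fit)
      if (anyNA(cf))
        stop2("rank-deficient design for class ", lb, "; collinear terms: ",
              paste(names(cf)[is.na(cf)], collapse = ", "))
      sm <- summary(fit)$coefficients
      row <- grep("^group", rownames(sm))
      sm[row, c("Estimate", "t value", "Pr(>|t|)")]
    }, numeric(3)))
  } else {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      stop2("method = 'mixed' requires the lmerTest package")
    res <- matrix(NA_real_, length(labs), 3,
                  dimnames = list(labs, NULL))
    for (kd in unique(kinds)) {
      dk <- d[d$kind == kd, ]
      dk$label <- factor(dk$label)
      mfml <- stats::reformulate(
        c("0", "label", "label:group", covariates, "(1 | subject_id)"),
        response = "strength")
      fit <- lmerTest::lmer(mfml, data = dk)
      sm <- summary(fit)$coefficients
      for (lb in levels(dk$label)) {
        row <- grep(paste0("^label", lb, ":group"), rownames(sm))
        res[lb, ] <- sm[row, c("Estimate", "t value", "Pr(>|t|)")]
      }
    }
  }
  out <- data.frame(label = labs, kind = kinds,
                    beta = res[, 1], t = res[, 2], p = res[, 3],
                    stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  rownames(out) <- NULL
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Regional white-matter loss map for one connection kind
#'
#' For each cortical region of the modelled hemisphere, sums connection
#' weights from the region to the kind's partner set (the ipsilateral
#' subcortical block, the contralateral cortex, or the rest of the
#' ipsilateral cortex), z-scores the sums against controls, applies the
#' `tanh(-z)` loss transform and averages across the target patient group,
#' giving one loss score per region — the response vector for the PLS
#' analysis.
#'
#' @param connectomes list of [connectome()] objects.
#' @param parc the [parcellation()].
#' @param class_kind `"subcortical_cortical"`, `"interhemispheric"` or
#'   `"intrahemispheric"`.
#' @param hemisphere modelled hemisphere (default `"left"`, matching
#'   expression-data availability).
#' @param target_group patient group averaged into the map (default
#'   `"pd_low"`).
#' @param control_group reference group (default `"control"`).
#' @return data.frame `region_id`, `name`, `loss` (one row per modelled
#'   cortical region).
#' @export
regional_loss <- function(connectomes, parc,
                          class_kind = c("interhemispheric",
                                         "subcortical_cortical",
                                         "intrahemispheric"),
                          hemisphere = "left",
                          target_group = "pd_low",
                          control_group = "control") {
  class_kind <- match.arg(class_kind)
  rows <- cortical_idx(parc, hemisphere)
  other <- setdiff(c("left", "right"), hemisphere)
  partner <- switch(class_kind,
    subcortical_cortical = subcortical_block(parc, hemisphere),
    interhemispheric = cortical_idx(parc, other),
    intrahemispheric = cortical_idx(parc, hemisphere))
  # diagonal is zero, so for intrahemispheric the self pair contributes nothing
  scores <- vapply(connectomes, function(cx) {
    rowSums(cx$weights[rows, partner, drop = FALSE])
  }, numeric(length(rows)))
  grp <- vapply(connectomes, `[[`, character(1), "group")
  ctl <- scores[, grp == control_group, drop = FALSE]
  if (ncol(ctl) < 3) stop2("at least 3 control subjects are required")
  mu <- rowMeans(ctl)
  sdv <- apply(ctl, 1, sd)
  if (any(sdv <= 0)) stop2("zero control variance for some regions")
  z <- (scores - mu) / sdv
  loss <- tanh(-z)
  tgt <- loss[, grp == target_group, drop = FALSE]
  data.frame(region_id = parc$region_id[rows], name = parc$name[rows],
             loss = rowMeans(tgt), stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Tie-corrected Spearman correlation with a t-approximation p value.
#'
#' @param x,y numeric vectors of equal length (at least 5).
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 5)
    stop2("x and y must have equal length >= 5")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-sample pooled-variance t test from summary statistics
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
summary_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop2("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop2("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param a,b first row of the table (e.g. cases with/without the feature).
#' @param c,d second row.
#' @param yates apply the Yates continuity correction (default `TRUE`).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_2x2 <- function(a, b, c, d, yates = TRUE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop2("cells must be nonnegative integers")
  ct <- suppressWarnings(
    stats::chisq.test(matrix(cells, 2, 2, byrow = TRUE), correct = yates))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Shapiro-Wilk normality diagnostic per connection class
#'
#' Reported as a screening diagnostic (not a gate) for the z-normalisation.
#'
#' @param strengths long table from [class_strength_table()].
#' @return data.frame `label`, `W`, `p`.
#' @export
normality_screen <- function(strengths) {
  labs <- unique(strengths$label)
  res <- t(vapply(labs, function(lb) {
    s <- strengths$strength[strengths$label == lb]
    sw <- stats::shapiro.test(s)
    c(unname(sw$statistic), sw$p.value)
  }, numeric(2)))
  data.frame(label = labs, W = res[, 1], p = res[, 2],
             stringsAsFactors = FALSE)
}
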