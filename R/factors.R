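#' Theil-Sen slope estimator
#'
#' Robust trend: the median of all pairwise slopes (reported for
#' visualization alongside correlation statistics).
#'
#' @param x,y numeric vectors.
#' @return list(slope, intercept).
#' @export
theilSen <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    slopes <- c(slopes, dy[dx != 0] / dx[dx != 0])
  }
  s <- median(slopes)
  list(slope = s, intercept = median(y - s * x))
}

#' Demographic / hair factor-analysis battery
#'
#' For each factor against a per-session outcome (e.g. ROI quality or BCI
#' accuracy): binary factors (sex; hair length binarized none/short vs
#' medium/long) are tested with a Wilcoxon rank-sum test; ordinal or
#' continuous factors with Pearson, Spearman and Kendall correlations (the
#' Kendall p-value is the reported raw p); a Theil-Sen slope is attached for
#' plotting. Raw p-values are Benjamini-Hochberg corrected over the battery.
#' A separate mass-univariate one-way ANOVA per factor reports sum of
#' squares, F, and variance explained (SS_factor / SS_total); within one
#' multi-factor (sequential) ANOVA table the factor and residual
#' percentages sum to 100.
#'
#' @param outcome numeric per-session outcome.
#' @param factors per-session factor data.frame (columns as in
#'   [readFactorsTable()] plus alertness/age).
#' @param which character vector of factor columns to test; defaults to the
#'   available standard battery.
#' @return list(correlations = data.frame(factor, kind, statistic-set,
#'   p_raw, p_fdr), anova = per-factor one-way table,
#'   anova_joint = sequential multi-factor table).
#' @export
factorBattery <- function(outcome, factors,
                          which = intersect(
                            c("age", "sex", "ethnicity", "hair_color",
                              "hair_density", "hair_length", "alertness"),
                            names(factors))) {
  stopIfNot(sd(outcome, na.rm = TRUE) > 0,
            "outcome is constant; statistics undefined")
  rows <- list()
  for (f in which) {
    v <- factors[[f]]
    if (f == "hair_length") {
      # none/short vs medium/long (binarized)
      g <- ifelse(factors$hair_length_ord >= 2, "medium_long", "none_short")
      rows[[f]] <- wilcoxRow(f, outcome, g)
    } else if (f == "sex") {
      rows[[f]] <- wilcoxRow(f, outcome, v)
    } else {
      xv <- switch(f,
        hair_color = factors$hair_color_ord,
        hair_density = factors$hair_density_ord,
        ethnicity = ethnicityRank(factors),
        as.numeric(v))
      ok <- is.finite(xv) & is.finite(outcome)
      pr <- suppressWarnings(cor.test(xv[ok], outcome[ok], method = "pearson"))
      sp <- suppressWarnings(cor.test(xv[ok], outcome[ok], method = "spearman"))
      kd <- suppressWarnings(cor.test(xv[ok], outcome[ok], method = "kendall"))
      ts <- theilSen(xv[ok], outcome[ok])
      rows[[f]] <- data.frame(
        factor = f, kind = "correlation",
        pearson_r = unname(pr$estimate), spearman_rho = unname(sp$estimate),
        kendall_tau = unname(kd$estimate), wilcoxon_w = NA_real_,
        theil_sen_slope = ts$slope, p_raw = kd$p.value, n = sum(ok))
    }
  }
  cors <- do.call(rbind, rows)
  rownames(cors) <- NULL
  cors$p_fdr <- p.adjust(cors$p_raw, method = "BH")

  anovaFactors <- intersect(which, c("hair_length", "hair_color",
                                     "hair_density", "ethnicity", "sex", "age"))
  av <- lapply(anovaFactors, function(f) {
    g <- anovaGroups(f, factors)
    ok <- !is.na(g) & is.finite(outcome)
    fit <- anova(lm(outcome[ok] ~ g[ok]))
    data.frame(factor = f, ss = fit$`Sum Sq`[1], df = fit$Df[1],
               f_statistic = fit$`F value`[1], p = fit$`Pr(>F)`[1],
               variance_explained = 100 * fit$`Sum Sq`[1] / sum(fit$`Sum Sq`))
  })
  av <- do.call(rbind, av)
  if (!is.null(av)) av$p_fdr <- p.adjust(av$p, method = "BH")

  hairSet <- intersect(anovaFactors, c("hair_length", "hair_color", "hair_density"))
  joint <- NULL
  if (length(hairSet) >= 2) {
    gs <- lapply(hairSet, anovaGroups, factors = factors)
    ok <- Reduce(`&`, lapply(gs, function(g) !is.na(g))) & is.finite(outcome)
    dat <- data.frame(y = outcome[ok])
    for (i in seq_along(hairSet)) dat[[hairSet[i]]] <- gs[[i]][ok]
    fit <- anova(lm(stats::as.formula(
      paste("y ~", paste(hairSet, collapse = " + "))), data = dat))
    joint <- data.frame(
      term = rownames(fit), ss = fit$`Sum Sq`, df = fit$Df,
      f_statistic = fit$`F value`, p = fit$`Pr(>F)`,
      variance_explained = 100 * fit$`Sum Sq` / sum(fit$`Sum Sq`))
    rownames(joint) <- NULL
  }
  list(correlations = cors, anova = av, anova_joint = joint)
}

wilcoxRow <- function(f, outcome, g) {
  ok <- !is.na(g) & is.finite(outcome)
  gl <- sort(unique(g[ok]))
  stopIfNot(length(gl) == 2, paste(f, "is not binary in this cohort"))
  x1 <- outcome[ok & g == gl[1]]; x2 <- outcome[ok & g == gl[2]]
  exact <- length(x1) <= 20 && length(x2) <= 20 &&
    !any(duplicated(c(x1, x2)))
  wt <- suppressWarnings(wilcox.test(x1, x2, exact = exact, correct = TRUE))
  data.frame(factor = f, kind = "wilcoxon",
             pearson_r = NA_real_, spearman_rho = NA_real_,
             kendall_tau = NA_real_, wilcoxon_w = unname(wt$statistic),
             theil_sen_slope = NA_real_, p_raw = wt$p.value, n = sum(ok))
}

# Grouping variable for the ANOVA: unordered categories; age in 4 bins.
anovaGroups <- function(f, factors) {
  v <- factors[[f]]
  if (f == "age") {
    return(cut(as.numeric(v), breaks = c(-Inf, 30, 40, 50, Inf),
               labels = c("<30", "30-40", "40-50", ">50")))
  }
  if (f == "hair_length") {
    return(factor(ifelse(factors$hair_length_ord >= 2,
                         "medium_long", "none_short")))
  }
  factor(v)
}

# Ethnicity rank ordered by the cohort's mean hair-occlusion severity
# (self-reported hair factors averaged per ethnicity, higher = more
# occlusive), mirroring a lightness-style ordinal coding.
ethnicityRank <- function(factors) {
  sev <- hairSeverity(factors)
  mt <- tapply(sev, factors$ethnicity, mean, na.rm = TRUE)
  ord <- names(sort(mt))
  match(factors$ethnicity, ord)
}

#' Ceiling analysis of performance vs alertness
#'
#' Bins sessions by alertness (1-10), keeps the top `top_frac` performers in
#' each bin, and reports the Kendall correlation and Theil-Sen trend on the
#' retained subset (a probe for a performance ceiling rising with
#' alertness). Empty bins are skipped; `top_frac = 1` reduces to the
#' full-sample statistics.
#'
#' @param performance per-session accuracies.
#' @param alertness per-session alertness (1-10).
#' @param top_frac fraction retained per bin.
#' @return list(subset = data.frame(alertness, performance),
#'   kendall_tau, p, trend = Theil-Sen fit on the subset).
#' @export
ceilingAnalysis <- function(performance, alertness, top_frac = 0.2) {
  ok <- is.finite(performance) & is.finite(alertness)
  performance <- performance[ok]; alertness <- alertness[ok]
  keep <- logical(length(performance))
  for (a in sort(unique(alertness))) {
    idx <- which(alertness == a)
    ntop <- max(1L, ceiling(top_frac * length(idx)))
    keep[idx[order(performance[idx], decreasing = TRUE)[seq_len(ntop)]]] <- TRUE
  }
  sub <- data.frame(alertness = alertness[keep], performance = performance[keep])
  kd <- suppressWarnings(cor.test(sub$alertness, sub$performance,
                                  method = "kendall"))
  list(subset = sub, kendall_tau = unname(kd$estimate), p = kd$p.value,
       trend = theilSen(sub$alertness, sub$performance))
}
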