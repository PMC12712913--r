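# Group-comparison battery: Shapiro-Wilk normality gate, then either one-way
# ANOVA with Dunnett's test versus control (all groups normal) or
# Kruskal-Wallis with two-sided Dunn's post-hoc versus control (otherwise).
# Levene's test is computed as an advisory homogeneity check.

signif_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = TRUE)
}

#' Dunn's rank-based post-hoc comparisons versus a control group
#'
#' Standard Dunn z statistics on the pooled ranks with tie correction:
#' `z = (Rbar_i - Rbar_ctrl) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_ctrl))`
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided normal
#' p-values, adjusted over the versus-control comparisons.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @param control control group label.
#' @param adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"bonferroni"` over the versus-control family).
#' @return data.frame: `group`, `z`, `p`, `p_adj`.
#' @export
dunn_vs_control <- function(values, groups, control, adjust = "bonferroni") {
  groups <- as.character(groups)
  if (!control %in% groups) stopf("control group '%s' not present", control)
  N <- length(values)
  r <- rank(values)
  tie_t <- table(values)
  TIE <- sum(tie_t^3 - tie_t) / (12 * (N - 1))
  rb <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  others <- setdiff(names(rb), control)
  z <- vapply(others, function(g)
    (rb[[g]] - rb[[control]]) /
      sqrt((N * (N + 1) / 12 - TIE) * (1 / ns[[g]] + 1 / ns[[control]])),
    numeric(1L))
  p <- 2 * pnorm(-abs(z))
  data.frame(group = others, z = unname(z), p = unname(p),
             p_adj = pmin(1, stats::p.adjust(p, method = adjust)),
             row.names = NULL)
}

#' Compare experimental groups against a control
#'
#' Implements the normality-gated battery: Shapiro-Wilk per group (alpha
#' 0.05); if every group is consistent with normality, a one-way ANOVA with
#' Dunnett's multiple-comparison test versus the control; otherwise a
#' Kruskal-Wallis omnibus with two-sided Dunn's post-hoc versus the control
#' (Bonferroni-adjusted). Levene's homogeneity test is reported as advisory
#' only. Significance stars follow the 0.05 / 0.01 / 0.001 / 0.0001
#' convention.
#'
#' @param g either a named list of numeric samples (names are group labels)
#'   or a data.frame with `group` and `value` columns.
#' @param alpha gate level for the Shapiro-Wilk test (default 0.05).
#' @param control control group label (default `"CON"`).
#' @return object of class `stat_report`: list with `normality` (per-group
#'   Shapiro p), `levene_p`, `test` (`"anova_dunnett"` or
#'   `"kruskal_dunn"`), `statistic`, `omnibus_p`, `comparisons` (data.frame
#'   group, estimate/z, p_adj, stars).
#' @export
compare_groups <- function(g, alpha = 0.05, control = "CON") {
  if (is.data.frame(g)) {
    d <- data.frame(group = as.character(g$group), value = as.numeric(g$value))
  } else {
    if (is.null(names(g))) stopf("group samples must be named")
    d <- data.frame(group = rep(names(g), lengths(g)),
                    value = as.numeric(unlist(g)))
  }
  if (!control %in% d$group) stopf("control group '%s' not present", control)
  ns <- table(d$group)
  if (length(ns) < 2L) stopf("need at least 2 groups")
  if (any(ns < 3L))
    stopf("every group needs n >= 3 (got %s)",
          paste(sprintf("%s=%d", names(ns), ns), collapse = ", "))

  sw <- vapply(split(d$value, d$group), function(v) {
    if (length(unique(v)) == 1L) return(0)  # degenerate: clearly non-normal
    shapiro.test(v)$p.value
  }, numeric(1L))
  d$group <- stats::relevel(factor(d$group), ref = control)
  lev_p <- tryCatch(car::leveneTest(value ~ group, data = d)[1, "Pr(>F)"],
                    error = function(e) NA_real_)

  if (all(sw > alpha)) {
    fit <- aov(value ~ group, data = d)
    at <- summary(fit)[[1]]
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    gs <- summary(glht_fit)
    comparisons <- data.frame(
      group = sub(" - .*$", "", names(gs$test$coefficients)),
      estimate = unname(gs$test$coefficients),
      statistic = unname(gs$test$tstat),
      p_adj = unname(as.numeric(gs$test$pvalues)), row.names = NULL)
    test <- "anova_dunnett"
    statistic <- at[["F value"]][1L]
    omnibus_p <- at[["Pr(>F)"]][1L]
  } else {
    kw <- kruskal.test(value ~ group, data = d)
    dn <- dunn_vs_control(d$value, as.character(d$group), control)
    comparisons <- data.frame(group = dn$group, estimate = NA_real_,
                              statistic = dn$z, p_adj = dn$p_adj,
                              row.names = NULL)
    test <- "kruskal_dunn"
    statistic <- unname(kw$statistic)
    omnibus_p <- kw$p.value
  }
  comparisons$stars <- as.character(signif_stars(comparisons$p_adj))
  structure(list(normality = sw, levene_p = lev_p, test = test,
                 statistic = statistic, omnibus_p = omnibus_p,
                 control = control, comparisons = comparisons),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s (omnibus statistic %.3g, p = %.4g)\n",
              x$test, x$statistic, x$omnibus_p))
  cat("  Shapiro-Wilk p:",
      paste(sprintf("%s %.3g", names(x$normality), x$normality),
            collapse = ", "), "\n")
  if (!is.na(x$levene_p))
    cat(sprintf("  Levene homogeneity p (advisory): %.3g\n", x$levene_p))
  cat(sprintf("  comparisons vs %s:\n", x$control))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
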