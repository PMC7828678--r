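# Reporting statistics: per-organ group comparisons with Holm-Sidak
# correction, rank correlation of the tumor/liver ratio against DAR, and
# one-way ANOVA with Tukey HSD for immunoreactivity comparisons.

#' Holm-Sidak step-down adjustment of p-values
#'
#' Ordered raw p-values p_(i) are adjusted to 1 - (1 - p_(i))^(m - i + 1)
#' and made monotone by a running maximum; adjusted values never fall below
#' the raw ones and are capped at 1.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
p_adjust_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Per-organ two-group t tests with Holm-Sidak correction
#'
#' Unpaired two-tailed t tests per organ between two conjugate groups,
#' with the Holm-Sidak step-down multiplicity adjustment across organs.
#' Welch's unequal-variance form is the default; the pooled-variance
#' Student form is available by flag. Organs with zero variance in both
#' groups are flagged rather than tested.
#'
#' @param data biodistribution data frame (`conjugate`, `organ`,
#'   `pct_ia_per_g`, optionally restricted to one time point beforehand).
#' @param group_a,group_b conjugate labels to compare.
#' @param organs organs to test; defaults to all present in both groups.
#' @param var_equal use the pooled-variance Student t test.
#' @return data frame of class `group_comparison`: `organ`, `mean_a`,
#'   `mean_b`, `t`, `df`, `p`, `p_adj`, `undefined` (zero-variance flag),
#'   `method`.
#' @export
holm_sidak_ttests <- function(data, group_a, group_b, organs = NULL,
                              var_equal = FALSE) {
  a <- data[data$conjugate == group_a, ]
  b <- data[data$conjugate == group_b, ]
  if (is.null(organs)) organs <- intersect(unique(a$organ), unique(b$organ))
  res <- lapply(organs, function(o) {
    xa <- a$pct_ia_per_g[a$organ == o]
    xb <- b$pct_ia_per_g[b$organ == o]
    if (length(xa) < 2L || length(xb) < 2L)
      stop("need at least 2 observations per group for organ ", o, call. = FALSE)
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      ident <- isTRUE(all.equal(mean(xa), mean(xb)))
      return(data.frame(organ = o, mean_a = mean(xa), mean_b = mean(xb),
                        t = if (ident) 0 else NA_real_, df = NA_real_,
                        p = if (ident) 1 else NA_real_, undefined = !ident))
    }
    tt <- stats::t.test(xa, xb, var.equal = var_equal)
    data.frame(organ = o, mean_a = mean(xa), mean_b = mean(xb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, undefined = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- p_adjust_holm_sidak(out$p[ok])
  out$method <- if (var_equal) "student_holm_sidak" else "welch_holm_sidak"
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Spearman correlation of tumor/liver ratio against DAR
#'
#' Rank correlation with average-rank tie handling; the p-value is exact
#' (permutation null) for eight or fewer pairs without ties, asymptotic
#' otherwise.
#'
#' @param ratios tumor/liver concentration (or dose) ratio per conjugate.
#' @param dars matching DAR values.
#' @return list with `rho` and `p`.
#' @export
spearman_ratio_vs_dar <- function(ratios, dars) {
  stopifnot(length(ratios) == length(dars))
  if (length(ratios) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(ratios) == 0 || stats::sd(dars) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(ratios, dars, method = "spearman",
                    exact = length(ratios) <= 8L))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param values numeric response (e.g. immunoreactive-fraction replicates).
#' @param groups factor or character of group labels, >= 2 groups with
#'   >= 2 replicates each.
#' @return list with `f` (F statistic), `p` (ANOVA p-value), and `tukey`
#'   (data frame: comparison, diff, p_adj).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("need at least 2 replicates per group", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}
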