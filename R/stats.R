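#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA (equal-variance F test) across groups, the
#' omnibus test used for all three assays.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length (>= 2 non-empty groups).
#' @return List with `F`, `p`, `df_between`, `df_within`, and `degenerate`
#'   (`TRUE` when within-group variance is zero while means differ).
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_fmt("need >= 2 groups")
  if (any(table(groups) == 0L)) stop_fmt("empty group")
  df_within <- length(values) - nlevels(groups)
  if (df_within < 1L) stop_fmt("no residual degrees of freedom")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  Fval <- tab[["F value"]][1L]
  pval <- tab[["Pr(>F)"]][1L]
  msb <- tab[["Mean Sq"]][1L]
  msw <- tab[["Mean Sq"]][2L]
  # zero within-group variance with unequal means: F is meaningless
  degenerate <- msb > 0 && (msw == 0 || msw < .Machine$double.eps * msb)
  if (degenerate) {
    Fval <- Inf
    pval <- 0
  }
  list(F = Fval, p = pval, df_between = nlevels(groups) - 1L,
       df_within = df_within, degenerate = degenerate)
}

#' Pairwise group comparisons with multiplicity correction
#'
#' Tukey's honest significant difference (default) or Bonferroni-adjusted
#' pooled-variance t tests.
#'
#' @param values numeric response vector.
#' @param groups group labels.
#' @param method "tukey" or "bonferroni".
#' @return Symmetric matrix of adjusted p values with `NA` diagonal,
#'   dimnames = group levels; attribute `"method"` records the correction.
#' @export
pairwise_adjusted <- function(values, groups, method = c("tukey", "bonferroni")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_fmt("need >= 2 groups")
  lev <- levels(groups)
  p <- matrix(NA_real_, nlevels(groups), nlevels(groups),
              dimnames = list(lev, lev))
  if (method == "tukey") {
    hsd <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
    pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
    for (k in seq_along(pairs)) {
      a <- pairs[[k]][1L]; b <- pairs[[k]][2L]
      p[a, b] <- p[b, a] <- hsd[k, "p adj"]
    }
  } else {
    pt <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)$p.value
    for (a in rownames(pt)) for (b in colnames(pt)) {
      if (!is.na(pt[a, b])) p[a, b] <- p[b, a] <- pt[a, b]
    }
  }
  attr(p, "method") <- method
  p
}

#' Significance stars
#'
#' The star convention used in the figures: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `****` p < 0.0001; "ns" otherwise.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep("ns", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[!is.na(p) & p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' Omnibus + pairwise comparison of analysis cells
#'
#' Convenience wrapper tying [one_way_anova()] and [pairwise_adjusted()]
#' together into the long-format comparison table used in reports.
#'
#' @param df per-sample data.frame with a `cell` column.
#' @param value_col value column name.
#' @param method correction method for [pairwise_adjusted()].
#' @return List with `anova` (the omnibus result) and `pairwise`
#'   (data.frame `group1, group2, p_adj, stars`).
#' @export
compare_groups <- function(df, value_col, method = "tukey") {
  values <- df[[value_col]]
  groups <- df$cell
  aov_res <- one_way_anova(values, groups)
  pmat <- pairwise_adjusted(values, groups, method)
  lev <- rownames(pmat)
  pairs <- utils::combn(lev, 2L)
  pairwise <- data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    p_adj = pmat[cbind(pairs[1L, ], pairs[2L, ])],
    stringsAsFactors = FALSE)
  pairwise$stars <- significance_stars(pairwise$p_adj)
  list(anova = aov_res, pairwise = pairwise, method = method)
}
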