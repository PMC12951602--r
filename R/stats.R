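#' Non-parametric group comparisons
#'
#' Two unpaired groups are compared with a Mann-Whitney test, paired data
#' with a Wilcoxon signed-rank test, and three or more groups with a
#' Kruskal-Wallis omnibus test followed by Dunn's pairwise rank-sum
#' comparisons. Effect directions (difference of group medians) are
#' recorded with every pairwise result.
#'
#' @param values Numeric vector of observations.
#' @param group Factor or vector of group labels, same length.
#' @param paired Use the Wilcoxon signed-rank test (two groups of equal
#'   length, matched order).
#' @param p_adjust Multiplicity adjustment for Dunn's pairwise p-values
#'   (default `"holm"`).
#' @return List with `omnibus` (data.frame `method`, `statistic`,
#'   `p_value`) and `pairwise` (data.frame with one row per comparison).
#' @export
group_compare <- function(values, group, paired = FALSE,
                          p_adjust = "holm") {
  group <- factor(group)
  stopifnot(length(values) == length(group), nlevels(group) >= 2)
  lev <- levels(group)
  med <- tapply(values, group, median)
  if (nlevels(group) == 2) {
    w <- wilcox.test(values[group == lev[1]], values[group == lev[2]],
                     paired = paired, exact = FALSE)
    omni <- data.frame(
      method = if (paired) "wilcoxon_signed_rank" else "mann_whitney",
      statistic = unname(w$statistic), p_value = w$p.value)
    pw <- data.frame(group1 = lev[1], group2 = lev[2],
                     statistic = unname(w$statistic), p_value = w$p.value,
                     p_adjusted = w$p.value,
                     direction = unname(sign(med[1] - med[2])),
                     median_diff = unname(med[1] - med[2]))
    return(list(omnibus = omni, pairwise = pw))
  }
  if (paired) stop("paired comparisons support exactly two groups")
  kw <- kruskal.test(values, group)
  omni <- data.frame(method = "kruskal_wallis",
                     statistic = unname(kw$statistic),
                     p_value = kw$p.value)
  pw <- dunn_test(values, group, p_adjust = p_adjust)
  pw$direction <- sign(med[pw$group1] - med[pw$group2])
  pw$median_diff <- med[pw$group1] - med[pw$group2]
  rownames(pw) <- NULL
  list(omnibus = omni, pairwise = pw)
}

#' Dunn's pairwise rank-sum test
#'
#' Post-hoc comparisons after a Kruskal-Wallis test: z statistics from the
#' difference of mean ranks over the pooled ranking, with the standard tie
#' correction.
#'
#' @inheritParams group_compare
#' @return data.frame with columns `group1`, `group2`, `z`, `statistic`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, group, p_adjust = "holm") {
  group <- factor(group)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, group, mean)
  n <- tabulate(group)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(group)
  pairs <- utils::combn(seq_along(lev), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z <- (rbar[i] - rbar[j]) / se
    data.frame(group1 = lev[i], group2 = lev[j], z = unname(z),
               statistic = unname(z),
               p_value = 2 * pnorm(-abs(unname(z))))
  }))
  out$p_adjusted <- p.adjust(out$p_value, method = p_adjust)
  rownames(out) <- NULL
  out
}
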