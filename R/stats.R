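#' Choose a two-group test by per-group normality
#'
#' Shapiro-Wilk is run on each group; Welch's t-test is used only when both
#' groups are consistent with normality (p >= `alpha_norm` in both),
#' otherwise the Mann-Whitney U test. Groups too small for the normality
#' test (n < 3) force the rank test with a warning.
#'
#' @param group_a,group_b Numeric vectors.
#' @param alpha_norm Normality alpha (default 0.05).
#' @return `"welch"` or `"mann_whitney"`.
#' @export
route_test <- function(group_a, group_b, alpha_norm = 0.05) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    warning("Group with n < 3: Mann-Whitney U test forced", call. = FALSE)
    return("mann_whitney")
  }
  p_of <- function(x) {
    if (length(unique(x)) == 1L) return(0) # degenerate: not normal
    stats::shapiro.test(x)$p.value
  }
  if (p_of(group_a) >= alpha_norm && p_of(group_b) >= alpha_norm) {
    "welch"
  } else {
    "mann_whitney"
  }
}

#' Welch's unequal-variance t-test
#'
#' Two-sided, Welch-Satterthwaite degrees of freedom. Two constant groups
#' with equal means return statistic 0 and p = 1 rather than an error.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List with `statistic`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(statistic = 0, df = NA_real_, p = 1))
    }
    return(list(statistic = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null distribution when the smaller group has n <= 8 and there are
#' no ties; tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param group_a,group_b Numeric vectors.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`, default)
#'   the exact null.
#' @return List with `U` (statistic for group A) and `p`.
#' @export
mann_whitney <- function(group_a, group_b, exact = NULL) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  if (is.null(exact)) {
    exact <- !ties && min(length(group_a), length(group_b)) <= 8
  }
  if (identical(unique(group_a), unique(group_b)) &&
      length(unique(c(group_a, group_b))) == 1L) {
    return(list(U = length(group_a) * length(group_b) / 2, p = 1))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis statistic across k >= 3 groups, followed by
#' Dunn's z-tests on mean ranks for all k(k-1)/2 pairs, with the pairwise
#' p-values adjusted within the family (Benjamini-Hochberg by default).
#'
#' @param groups Named list of >= 3 numeric vectors (each n >= 2).
#' @param adjust Adjustment for the pairwise family (default `"BH"`).
#' @return List with `statistic`, `df`, `p` (omnibus) and `pairwise`
#'   (tibble: `group_a`, `group_b`, `z`, `p`, `p_adj`).
#' @export
kruskal_dunn <- function(groups, adjust = "BH") {
  if (length(groups) < 3) {
    stop("Fewer than 3 groups: use the two-group path ",
         "(route_test/welch_t/mann_whitney)", call. = FALSE)
  }
  stopifnot(all(lengths(groups) >= 2))
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  kw <- stats::kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  n_tot <- length(x)
  tie_sizes <- table(x)
  tie_corr <- sum(tie_sizes^3 - tie_sizes) / (12 * (n_tot - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2)
  pw <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) *
                 (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    tibble::tibble(group_a = a, group_b = b, z = z,
                   p = 2 * stats::pnorm(-abs(z)))
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adj <- adjust_p(pw$p, method = adjust)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pw)
}

#' Multiplicity adjustment
#'
#' Benjamini-Hochberg step-up (with monotonicity enforcement), Bonferroni
#' or Holm, capped at 1. Applied per contrast across all lipids.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"`, `"bonferroni"` or `"holm"`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_p <- function(p, method = c("BH", "bonferroni", "holm")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Fold change between two groups
#'
#' Ratio of group means with the second group as reference, plus its log2;
#' antisymmetric in log2 under a group swap.
#'
#' @param group_a,group_b Numeric vectors; `group_b` is the reference.
#' @return List with `fc` and `log2fc` (`NA` with a warning when the
#'   reference mean is not positive).
#' @export
fold_change <- function(group_a, group_b) {
  mb <- mean(group_b, na.rm = TRUE)
  if (!is.finite(mb) || mb <= 0) {
    warning("Nonpositive reference mean: fold change undefined",
            call. = FALSE)
    return(list(fc = NA_real_, log2fc = NA_real_))
  }
  fc <- mean(group_a, na.rm = TRUE) / mb
  list(fc = fc, log2fc = log2(fc))
}

#' Correlation between two continuous variables
#'
#' Pearson product-moment or Spearman rank correlation with a two-sided
#' test. Spearman is the rank-transform Pearson with midrank ties.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"spearman"` (default, matching the pipeline's standard
#'   choice) or `"pearson"`.
#' @return List with `estimate` and `p`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Zero variance: correlation undefined", call. = FALSE)
    return(list(estimate = NA_real_, p = NA_real_))
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE)
  )
  list(estimate = unname(ht$estimate), p = ht$p.value)
}
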