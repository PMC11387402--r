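#' Differential lipid abundance between two strata
#'
#' The per-lipid two-group engine: for every lipid row, missing values are
#' dropped (logged, never imputed), the test is routed by per-group
#' Shapiro-Wilk normality (Welch's t when both groups pass, Mann-Whitney U
#' otherwise), the fold change is the ratio of group means (group A over
#' reference group B), and raw p-values are adjusted across all lipids of
#' the contrast by Benjamini-Hochberg (Bonferroni and Holm also reported).
#'
#' @param abundance Abundance table: data frame with a `lipid` column (or
#'   first column holding lipid names) and one column per sample.
#' @param samples_a,samples_b Sample column names of the two strata;
#'   `samples_b` is the reference.
#' @param groups Length-2 character vector naming the strata (A, B).
#' @param alpha_norm Normality alpha for test routing.
#' @param log_transform Test on log2 abundances instead of raw (fold
#'   changes are always computed on the raw scale).
#' @return A `lipid_comparison` tibble: `lipid`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `median_a`, `median_b`, `fc`, `log2fc`, `test`, `p`,
#'   `p_bh`, `p_bonferroni`, `p_holm`. Attributes: `groups`, `skipped`
#'   (lipids with fewer than 2 usable values in a group, excluded from
#'   testing).
#' @export
#' @examples
#' ab <- tibble::tibble(lipid = c("LPC(24:0)", "LPC(26:0)"),
#'                      s1 = c(1, 2), s2 = c(1.1, 2.2),
#'                      s3 = c(0.5, 0.9), s4 = c(0.6, 1.1))
#' compare_lipids(ab, c("s1", "s2"), c("s3", "s4"))
compare_lipids <- function(abundance, samples_a, samples_b,
                           groups = c("A", "B"), alpha_norm = 0.05,
                           log_transform = FALSE) {
  stopifnot(is.data.frame(abundance), length(groups) == 2)
  lipid_col <- if ("lipid" %in% names(abundance)) "lipid" else names(abundance)[1]
  miss <- setdiff(c(samples_a, samples_b), names(abundance))
  if (length(miss) > 0) {
    stop("Sample column(s) not in abundance table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lipids <- as.character(abundance[[lipid_col]])
  mat_a <- as.matrix(abundance[, samples_a, drop = FALSE])
  mat_b <- as.matrix(abundance[, samples_b, drop = FALSE])

  one <- function(i) {
    a <- mat_a[i, ]; b <- mat_b[i, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    base <- tibble::tibble(
      lipid = lipids[i], n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b),
      median_a = stats::median(a), median_b = stats::median(b)
    )
    if (length(a) < 2 || length(b) < 2) {
      return(dplyr::mutate(base, fc = NA_real_, log2fc = NA_real_,
                           test = NA_character_, p = NA_real_))
    }
    fcr <- suppressWarnings(fold_change(a, b))
    ta <- if (log_transform) log2(a) else a
    tb <- if (log_transform) log2(b) else b
    test <- suppressWarnings(route_test(ta, tb, alpha_norm = alpha_norm))
    p <- if (test == "welch") welch_t(ta, tb)$p else mann_whitney(ta, tb)$p
    dplyr::mutate(base, fc = fcr$fc, log2fc = fcr$log2fc, test = test,
                  p = p)
  }
  out <- dplyr::bind_rows(lapply(seq_along(lipids), one))
  tested <- !is.na(out$p)
  out$p_bh <- out$p_bonferroni <- out$p_holm <- NA_real_
  out$p_bh[tested] <- adjust_p(out$p[tested], "BH")
  out$p_bonferroni[tested] <- adjust_p(out$p[tested], "bonferroni")
  out$p_holm[tested] <- adjust_p(out$p[tested], "holm")
  skipped <- out$lipid[!tested]
  if (length(skipped) > 0) {
    message(length(skipped), " lipid(s) excluded from testing ",
            "(fewer than 2 usable values in a group)")
  }
  attr(out, "groups") <- groups
  attr(out, "skipped") <- skipped
  class(out) <- c("lipid_comparison", class(out))
  out
}

#' Volcano classification of a lipid comparison
#'
#' Labels every tested lipid `elevated` (FC above the threshold and
#' significant), `lower` (FC below the reciprocal threshold and
#' significant) or `ns`, using the FDR-adjusted p-value by default.
#'
#' @param comparison A `lipid_comparison` from [compare_lipids()].
#' @param fc_thresh Fold-change threshold (default 1.5; lower means
#'   FC < 1/1.5).
#' @param p_thresh Significance threshold (default 0.05).
#' @param on_adjusted Use the BH-adjusted p (default) rather than raw p.
#' @return The comparison with an added `label` column (class
#'   `lipid_volcano`); `counts` attribute holds the (elevated, lower)
#'   totals, also available via [glance()].
#' @export
classify_volcano <- function(comparison, fc_thresh = 1.5, p_thresh = 0.05,
                             on_adjusted = TRUE) {
  stopifnot(inherits(comparison, "lipid_comparison") ||
              all(c("fc", "p", "p_bh") %in% names(comparison)))
  p_use <- if (on_adjusted) comparison$p_bh else comparison$p
  label <- dplyr::case_when(
    is.na(comparison$fc) | is.na(p_use) ~ "ns",
    comparison$fc > fc_thresh & p_use < p_thresh ~ "elevated",
    comparison$fc < 1 / fc_thresh & p_use < p_thresh ~ "lower",
    TRUE ~ "ns"
  )
  out <- dplyr::mutate(comparison, label = label)
  attr(out, "thresholds") <- c(fc = fc_thresh, p = p_thresh)
  attr(out, "counts") <- c(elevated = sum(label == "elevated"),
                           lower = sum(label == "lower"))
  class(out) <- unique(c("lipid_volcano", class(comparison)))
  out
}

#' Two-stratum volcano analysis in one call
#'
#' Convenience wrapper running [compare_lipids()] then
#' [classify_volcano()].
#'
#' @inheritParams compare_lipids
#' @inheritParams classify_volcano
#' @return A `lipid_volcano` tibble (see [classify_volcano()]).
#' @export
volcano <- function(abundance, samples_a, samples_b, groups = c("A", "B"),
                    fc_thresh = 1.5, p_thresh = 0.05, on_adjusted = TRUE,
                    alpha_norm = 0.05, log_transform = FALSE) {
  comparison <- compare_lipids(abundance, samples_a, samples_b,
                               groups = groups, alpha_norm = alpha_norm,
                               log_transform = log_transform)
  classify_volcano(comparison, fc_thresh = fc_thresh, p_thresh = p_thresh,
                   on_adjusted = on_adjusted)
}

#' @export
#' @rdname lipid_comparison-tidiers
#' @method tidy lipid_comparison
tidy.lipid_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), c("lipid_volcano", "lipid_comparison"))
  tibble::as_tibble(out)
}

#' Tidiers for lipid comparisons
#'
#' `tidy()` returns the per-lipid results as a plain tibble; `glance()`
#' summarizes the contrast in one row (lipids tested, test usage, and for
#' volcano-classified results the elevated/lower counts).
#'
#' @param x A `lipid_comparison` or `lipid_volcano` object.
#' @param ... Unused.
#' @name lipid_comparison-tidiers
#' @export
#' @method glance lipid_comparison
glance.lipid_comparison <- function(x, ...) {
  counts <- attr(x, "counts")
  tibble::tibble(
    n_lipids = nrow(x),
    n_tested = sum(!is.na(x$p)),
    n_welch = sum(x$test == "welch", na.rm = TRUE),
    n_mann_whitney = sum(x$test == "mann_whitney", na.rm = TRUE),
    n_elevated = if (is.null(counts)) NA_integer_ else unname(counts["elevated"]),
    n_lower = if (is.null(counts)) NA_integer_ else unname(counts["lower"])
  )
}

#' Volcano plot of a classified lipid comparison
#'
#' @param object A `lipid_volcano` from [classify_volcano()] or
#'   [volcano()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change vs -log10 p, colored by label.
#' @export
#' @method autoplot lipid_volcano
autoplot.lipid_volcano <- function(object, ...) {
  thr <- attr(object, "thresholds")
  df <- tidy.lipid_comparison(object)
  df <- df[!is.na(df$p), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p),
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-log2(thr["fc"]), log2(thr["fc"])),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(elevated = "#c0392b", lower = "#2980b9", ns = "grey70")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
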