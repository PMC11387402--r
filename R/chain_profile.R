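#' LOESS fit on a grid
#'
#' Tricube-weighted local polynomial regression (the smoother behind the
#' chain-length trend curves). With span 1, degree 1 and exactly collinear
#' data the fit reproduces the line.
#'
#' @param x,y Numeric vectors; at least `degree + 2` distinct x values.
#' @param span Smoothing span in (0, 1].
#' @param degree Local polynomial degree (1 or 2).
#' @param grid Evaluation points; defaults to the sorted distinct x.
#' @return Tibble with columns `x` (grid) and `fitted`.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 2, grid = NULL) {
  stopifnot(length(x) == length(y), span > 0, span <= 1,
            degree %in% c(1, 2))
  if (length(unique(x)) < degree + 2) {
    stop("Too few distinct x values for a degree-", degree, " LOESS fit",
         call. = FALSE)
  }
  if (is.null(grid)) grid <- sort(unique(x))
  fit <- suppressWarnings(
    stats::loess(y ~ x, data = data.frame(x = x, y = y), span = span,
                 degree = degree, surface = "direct",
                 control = stats::loess.control(iterations = 1))
  )
  tibble::tibble(x = grid,
                 fitted = unname(stats::predict(fit,
                                                newdata = data.frame(x = grid))))
}

#' Chain-length trend of a differential comparison within a lipid class
#'
#' Plots (as data) the log2 fold change of each lipid of a class against
#' its total acyl-chain length, with a LOESS trend curve over the integer
#' carbon numbers present and a monotone-increase statistic (Spearman
#' correlation of the fitted curve with chain length).
#'
#' @param results A `lipid_comparison` (or any data frame with `lipid` and
#'   `log2fc` columns).
#' @param class_code Lipid class to profile (e.g. `"LPC"`).
#' @param span,degree LOESS parameters (defaults 0.75, 2).
#' @return A `chain_trend` list: `class_code`, `points` (tibble `lipid`,
#'   `n`, `d`, `log2fc`), `fit` (tibble `x`, `fitted`), `span`, `degree`,
#'   `spearman_fit`. With fewer than 3 lipids of the class the trend is
#'   empty (no fit) and a warning is raised.
#' @export
chain_trend <- function(results, class_code, span = 0.75, degree = 2) {
  stopifnot(all(c("lipid", "log2fc") %in% names(results)))
  parsed <- parse_lipid_name_safe(results$lipid)
  keep <- parsed$valid & parsed$class_code == class_code &
    !is.na(results$log2fc)
  points <- tibble::tibble(
    lipid = results$lipid[keep], n = parsed$n[keep], d = parsed$d[keep],
    log2fc = results$log2fc[keep]
  )
  out <- list(class_code = class_code, points = points, fit = NULL,
              span = span, degree = degree, spearman_fit = NA_real_)
  class(out) <- "chain_trend"
  if (nrow(points) < 3) {
    warning("Fewer than 3 ", class_code,
            " lipids in results: no trend fitted", call. = FALSE)
    return(out)
  }
  out$fit <- loess_fit(points$n, points$log2fc, span = span,
                       degree = degree)
  if (nrow(out$fit) >= 3 && stats::sd(out$fit$fitted) > 0) {
    out$spearman_fit <- suppressWarnings(
      stats::cor(out$fit$fitted, out$fit$x, method = "spearman")
    )
  }
  out
}

#' Chain length by unsaturation heatmap matrix of log2 fold changes
#'
#' One cell per (total carbons, total double bonds) composition present in
#' the comparison for the class; cell values are the comparison's log2
#' fold changes exactly (no smoothing). Duplicate compositions violate
#' sum-composition uniqueness and are an error.
#'
#' @inheritParams chain_trend
#' @return A `saturation_heatmap` list: `class_code`, `cells` (tibble `n`,
#'   `d`, `log2fc`).
#' @export
saturation_heatmap <- function(results, class_code) {
  stopifnot(all(c("lipid", "log2fc") %in% names(results)))
  parsed <- parse_lipid_name_safe(results$lipid)
  keep <- parsed$valid & parsed$class_code == class_code &
    !is.na(results$log2fc)
  cells <- tibble::tibble(n = parsed$n[keep], d = parsed$d[keep],
                          log2fc = results$log2fc[keep])
  dup <- duplicated(cells[, c("n", "d")])
  if (any(dup)) {
    stop("Duplicate (carbons, double bonds) compositions in class ",
         class_code, ": ",
         paste(lipid_name(class_code, cells$n[dup], cells$d[dup]),
               collapse = ", "), call. = FALSE)
  }
  out <- list(class_code = class_code, cells = cells)
  class(out) <- "saturation_heatmap"
  out
}

#' @export
#' @method autoplot chain_trend
autoplot.chain_trend <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$n, y = .data$log2fc)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$d)),
                        alpha = 0.8) +
    ggplot2::labs(x = "Total chain length (carbons)",
                  y = "log2 fold change", colour = "Double bonds",
                  title = object$class_code) +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    p <- p + ggplot2::geom_line(data = object$fit,
                                ggplot2::aes(x = .data$x,
                                             y = .data$fitted),
                                inherit.aes = FALSE, linewidth = 1)
  }
  p
}

#' @export
#' @method autoplot saturation_heatmap
autoplot.saturation_heatmap <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$n, y = .data$d,
                               fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b", midpoint = 0) +
    ggplot2::labs(x = "Total chain length (carbons)",
                  y = "Total double bonds", fill = "log2 FC",
                  title = object$class_code) +
    ggplot2::theme_minimal()
}
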