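#' Fit an exponential-decay trend to post-transplant biomarker
#' trajectories
#'
#' Models the pooled concentration course after hematopoietic stem cell
#' transplantation as `C(t) = P + (C0 - P) * exp(-k * t)`: baseline `C0`,
#' plateau `P` (the level the biomarker settles at, typically still above
#' the healthy reference limit) and decay rate `k` (per month). Fitted by
#' Levenberg-Marquardt nonlinear least squares on all points pooled
#' across patients.
#'
#' @param series An [hct_series()] (or data frame with `months`, `value`).
#' @return An `hct_fit` list: `fit` (the `nls` object), `coefficients`
#'   (named vector `C0`, `P`, `k`), `data`.
#' @export
fit_hct_decay <- function(series) {
  stopifnot(all(c("months", "value") %in% names(series)),
            nrow(series) >= 4)
  d <- data.frame(months = series$months, value = series$value)
  start <- list(
    C0 = mean(d$value[d$months == min(d$months)]),
    P = max(min(d$value), 1e-6),
    k = 0.1
  )
  fit <- minpack.lm::nlsLM(
    value ~ P + (C0 - P) * exp(-k * months), data = d, start = start,
    lower = c(C0 = 0, P = 0, k = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  out <- list(fit = fit, coefficients = stats::coef(fit), data = d)
  class(out) <- "hct_fit"
  out
}

#' @export
#' @rdname hct_fit-tidiers
#' @method tidy hct_fit
tidy.hct_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                 std.error = s[, "Std. Error"],
                 statistic = s[, "t value"], p.value = s[, "Pr(>|t|)"])
}

#' Tidiers for post-transplant decay fits
#'
#' `tidy()` returns the parameter table; `glance()` one row with the
#' estimates, the decay half-life (months) and the residual standard
#' error.
#'
#' @param x An `hct_fit`.
#' @param ... Unused.
#' @name hct_fit-tidiers
#' @export
#' @method glance hct_fit
glance.hct_fit <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    baseline = unname(co["C0"]), plateau = unname(co["P"]),
    k = unname(co["k"]), half_life = log(2) / unname(co["k"]),
    sigma = summary(x$fit)$sigma, n = nrow(x$data)
  )
}

#' Group mean concentration at each post-transplant timepoint
#'
#' @param series An [hct_series()] or data frame with `months`, `value`.
#' @return Tibble `months`, `n`, `mean`, `min`, `max`.
#' @export
hct_timepoint_means <- function(series) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(series), .data$months),
    n = dplyr::n(), mean = mean(.data$value), min = min(.data$value),
    max = max(.data$value), .groups = "drop"
  )
}

#' @export
#' @method autoplot hct_fit
autoplot.hct_fit <- function(object, ...) {
  grid <- tibble::tibble(
    months = seq(min(object$data$months), max(object$data$months),
                 length.out = 200)
  )
  grid$value <- stats::predict(object$fit, newdata = grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$months, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#c0392b", linewidth = 1) +
    ggplot2::labs(x = "Months post transplant",
                  y = "Concentration") +
    ggplot2::theme_minimal()
}
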