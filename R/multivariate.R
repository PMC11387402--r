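#' Principal component scores of an abundance table
#'
#' Samples are observations, lipids are variables. Abundances are
#' log2-transformed by default (a small offset guards zeros) and centered
#' before singular value decomposition; constant lipid rows are dropped
#' with a warning.
#'
#' @param abundance Abundance table (`lipid` column + sample columns).
#' @param log2_transform,center,scale. Preprocessing toggles.
#' @param ncomp Number of components to keep (default 2).
#' @return A `lipid_pca` list: `scores` (tibble `sample`, `PC1`, ...),
#'   `loadings`, `explained_variance` (per component, fractions summing
#'   to 1 over all components), `ncomp`.
#' @export
pca_scores <- function(abundance, log2_transform = TRUE, center = TRUE,
                       scale. = FALSE, ncomp = 2) {
  m <- abundance_matrix(abundance, log2_transform = log2_transform)
  stopifnot(ncol(m) >= 3, nrow(m) >= 2) # >= 3 samples, >= 2 lipids
  const <- apply(m, 1, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant lipid row(s) dropped", call. = FALSE)
    m <- m[!const, , drop = FALSE]
  }
  fit <- stats::prcomp(t(m), center = center, scale. = scale.)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(ncomp, ncol(fit$x))
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores <- tibble::add_column(scores, sample = colnames(m), .before = 1L)
  out <- list(scores = scores, loadings = fit$rotation[, seq_len(k), drop = FALSE],
              explained_variance = ev, ncomp = k)
  class(out) <- "lipid_pca"
  out
}

#' Partial least squares discriminant analysis scores
#'
#' PLS-DA of the (log2) abundance matrix against one-hot group labels,
#' via mixOmics. Used, like PCA, to visualize group separation of the
#' lipidome; no cross-validated classification is attempted.
#'
#' @param abundance Abundance table (`lipid` column + sample columns).
#' @param labels Group label per sample column (character/factor, in
#'   column order).
#' @param ncomp Number of components (default 2).
#' @param log2_transform Log2-transform abundances first (default TRUE).
#' @return A `lipid_plsda` list: `scores` (tibble `sample`, `group`,
#'   `comp1`, ...), `ncomp`.
#' @export
plsda_scores <- function(abundance, labels, ncomp = 2,
                         log2_transform = TRUE) {
  if (!requireNamespace("mixOmics", quietly = TRUE)) {
    stop("plsda_scores() needs the mixOmics package", call. = FALSE)
  }
  m <- abundance_matrix(abundance, log2_transform = log2_transform)
  stopifnot(length(labels) == ncol(m))
  const <- apply(m, 1, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant lipid row(s) dropped", call. = FALSE)
    m <- m[!const, , drop = FALSE]
  }
  fit <- mixOmics::plsda(t(m), factor(labels), ncomp = ncomp)
  scores <- tibble::as_tibble(fit$variates$X)
  names(scores) <- paste0("comp", seq_len(ncol(scores)))
  scores <- tibble::add_column(scores, sample = colnames(m),
                               group = as.character(labels), .before = 1L)
  out <- list(scores = scores, ncomp = ncomp)
  class(out) <- "lipid_plsda"
  out
}

# lipid x sample numeric matrix from an abundance table
abundance_matrix <- function(abundance, log2_transform = FALSE,
                             offset = NULL) {
  lipid_col <- if ("lipid" %in% names(abundance)) "lipid" else names(abundance)[1]
  m <- as.matrix(abundance[, setdiff(names(abundance), lipid_col),
                           drop = FALSE])
  rownames(m) <- as.character(abundance[[lipid_col]])
  if (log2_transform) {
    if (is.null(offset)) {
      pos <- m[is.finite(m) & m > 0]
      offset <- if (length(pos)) min(pos) / 2 else 1e-12
    }
    m <- log2(m + offset)
  }
  m
}

#' @export
#' @method autoplot lipid_pca
autoplot.lipid_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  ev <- round(100 * object$explained_variance[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour)) {
    df$group <- colour
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$group))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("PC1 (", ev[1], "%)"),
                  y = paste0("PC2 (", ev[2], "%)")) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot lipid_plsda
autoplot.lipid_plsda <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$comp1, y = .data$comp2,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Component 1", y = "Component 2", colour = NULL) +
    ggplot2::theme_minimal()
}
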