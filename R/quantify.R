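#' Internal-standard semi-quantification of annotated features
#'
#' Converts peak areas to semi-quantitative abundances by dividing each
#' analyte area by the area of its class internal standard in the same
#' sample and scaling by the internal-standard plasma concentration
#' (amount spiked / plasma volume). The result is reported in arbitrary
#' units (A.U.): ratios between samples and groups are exact even though
#' per-class response factors are not calibrated.
#'
#' @param features Data frame with `feature_id` plus per-sample area
#'   columns (all non-reserved columns are treated as samples).
#' @param hits Annotation hits from [annotate_features()] or
#'   [features_from_names()]; only accepted hits are quantified.
#' @param is_areas Data frame `class_code` plus the same sample columns,
#'   holding the internal-standard peak area per class and sample.
#' @param is_specs Internal-standard specifications,
#'   see [internal_standards()].
#' @return An abundance table: tibble with `lipid` plus sample columns,
#'   attributes `units = "A.U."`, `provenance` (lipid -> internal standard
#'   used) and `flagged_samples` (samples with missing/zero IS area per
#'   class, whose abundances are set `NA`, never zero-filled).
#' @export
semiquantify <- function(features, hits, is_areas, is_specs) {
  acc <- hits[hits$accepted & !is.na(hits$name), ]
  stopifnot(nrow(acc) > 0)
  reserved <- c("feature_id", "name", "mz", "polarity", "rt")
  sample_ids <- setdiff(names(features), reserved)
  stopifnot(length(sample_ids) > 0,
            all(sample_ids %in% names(is_areas)))
  miss <- setdiff(unique(acc$class_code), is_specs$class_code)
  if (length(miss) > 0) {
    stop("No internal-standard spec for class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(unique(acc$class_code), is_areas$class_code)
  if (length(miss) > 0) {
    stop("No internal-standard areas for class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  area_mat <- as.matrix(features[match(acc$feature_id, features$feature_id),
                                 sample_ids, drop = FALSE])
  is_mat <- as.matrix(is_areas[match(acc$class_code, is_areas$class_code),
                               sample_ids, drop = FALSE])
  bad_is <- is.na(is_mat) | is_mat <= 0
  is_mat[bad_is] <- NA_real_
  conc <- is_specs$is_amount_nmol[match(acc$class_code,
                                        is_specs$class_code)] /
    is_specs$plasma_volume_uL[match(acc$class_code, is_specs$class_code)]
  ab <- sweep(area_mat / is_mat, 1L, conc, `*`)

  flagged <- tibble::tibble(
    class_code = rep(acc$class_code, times = length(sample_ids)),
    sample = rep(sample_ids, each = nrow(acc))
  )[as.vector(bad_is), ]
  flagged <- dplyr::distinct(flagged)
  if (nrow(flagged) > 0) {
    warning("Internal-standard area missing or zero for ",
            nrow(flagged), " (class, sample) pair(s); abundances set NA",
            call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(ab))
  names(out) <- sample_ids
  out <- tibble::add_column(out, lipid = acc$name, .before = 1L)
  attr(out, "units") <- "A.U."
  attr(out, "provenance") <- tibble::tibble(
    lipid = acc$name, class_code = acc$class_code,
    is_species = is_specs$is_species[match(acc$class_code,
                                           is_specs$class_code)]
  )
  attr(out, "flagged_samples") <- flagged
  out
}

#' Isotope-dilution concentration from a labeled-standard area ratio
#'
#' Targeted quantification against a stable-isotope-labeled internal
#' standard: `conc = (analyte area / labeled area) * (amount / volume)`,
#' converted to the requested unit. With 0.01 nmol of standard in 10 uL of
#' plasma, a ratio of 1 corresponds to 1 umol/L.
#'
#' @param analyte_area,labeled_is_area Peak areas (vectorized); the labeled
#'   area must be positive.
#' @param is_amount_nmol Amount of labeled standard per extraction (nmol).
#' @param plasma_volume_uL Plasma volume extracted (uL).
#' @param unit Output unit, `"nmol/L"` (targeted lyso-lipid assays) or
#'   `"umol/L"` (total fatty-acid assays).
#' @return Concentration(s) in the requested unit.
#' @export
#' @examples
#' isotope_dilution_conc(0.072, 1, 0.01, 10) # 72 nmol/L
isotope_dilution_conc <- function(analyte_area, labeled_is_area,
                                  is_amount_nmol, plasma_volume_uL,
                                  unit = c("nmol/L", "umol/L")) {
  unit <- match.arg(unit)
  if (any(labeled_is_area <= 0) || anyNA(labeled_is_area)) {
    stop("Labeled internal-standard area must be positive", call. = FALSE)
  }
  stopifnot(is_amount_nmol > 0, plasma_volume_uL > 0,
            all(analyte_area >= 0))
  conc_mmol_L <- (analyte_area / labeled_is_area) *
    (is_amount_nmol / plasma_volume_uL)
  convert_conc(conc_mmol_L, from = "mmol/L", to = unit)
}

#' Convert between molar concentration units
#'
#' @param value Numeric vector.
#' @param from,to One of `"nmol/L"`, `"umol/L"`, `"mmol/L"`.
#' @return Converted values; conversions compose to identity.
#' @export
convert_conc <- function(value, from, to) {
  scale <- c("nmol/L" = 1e-9, "umol/L" = 1e-6, "mmol/L" = 1e-3)
  if (!from %in% names(scale) || !to %in% names(scale)) {
    stop("Unknown concentration unit", call. = FALSE)
  }
  value * scale[[from]] / scale[[to]]
}
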