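#' Annotate LC-MS features by accurate mass
#'
#' Looks every feature up in an m/z catalog within a ppm tolerance and
#' (optionally) a per-class retention-time window, records all candidate
#' identities, and accepts exactly one per feature: smallest absolute ppm
#' error, ties broken by adduct priority order (the catalog's adduct order)
#' and then lexicographic species name. Features with no candidate are kept
#' and flagged unannotated, never dropped.
#'
#' @param features Data frame with columns `feature_id`, `mz`, `polarity`
#'   and optionally `rt` (minutes); other columns (e.g. per-sample areas)
#'   are ignored here and may be joined back by `feature_id`.
#' @param catalog An `mz_catalog` from [build_catalog()].
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @param rt_windows Optional data frame `class_code`, `rt_min`, `rt_max`;
#'   when supplied and the feature has an `rt`, candidates of a listed class
#'   must fall inside the class window (classes without a window always
#'   pass).
#' @return Tibble of annotation hits: `feature_id`, `name`, `class_code`,
#'   `n`, `d`, `adduct`, `mz_catalog`, `ppm_error`, `accepted`. Unannotated
#'   features appear with `NA` identity and `accepted = FALSE`.
#' @export
annotate_features <- function(features, catalog, tol_ppm = 5,
                              rt_windows = NULL) {
  stopifnot(is.data.frame(features), tol_ppm > 0,
            all(c("feature_id", "mz", "polarity") %in% names(features)))
  priority <- attr(catalog, "adduct_priority")
  if (is.null(priority)) priority <- unique(catalog$adduct)
  cat_pols <- unique(catalog$polarity)
  has_rt <- "rt" %in% names(features)

  one <- function(i) {
    f <- features[i, ]
    none <- tibble::tibble(
      feature_id = f$feature_id, name = NA_character_,
      class_code = NA_character_, n = NA_integer_, d = NA_integer_,
      adduct = NA_character_, mz_catalog = NA_real_, ppm_error = NA_real_,
      accepted = FALSE
    )
    if (!f$polarity %in% cat_pols) {
      warning("Feature ", f$feature_id, ": polarity '", f$polarity,
              "' not covered by the catalog adduct set; skipped",
              call. = FALSE)
      return(none)
    }
    cand <- query_catalog(catalog, f$mz, tol_ppm, polarity = f$polarity)
    if (!is.null(rt_windows) && has_rt && !is.na(f$rt) && nrow(cand) > 0) {
      w <- rt_windows[match(cand$class_code, rt_windows$class_code), ]
      inside <- is.na(w$class_code) | (f$rt >= w$rt_min & f$rt <= w$rt_max)
      cand <- cand[inside, ]
    }
    if (nrow(cand) == 0L) return(none)
    ord <- order(abs(cand$ppm_error), match(cand$adduct, priority),
                 cand$name)
    cand <- cand[ord, ]
    tibble::tibble(
      feature_id = f$feature_id, name = cand$name,
      class_code = cand$class_code, n = cand$n, d = cand$d,
      adduct = cand$adduct, mz_catalog = cand$mz,
      ppm_error = cand$ppm_error,
      accepted = seq_len(nrow(cand)) == 1L
    )
  }
  dplyr::bind_rows(lapply(seq_len(nrow(features)), one))
}

#' Pre-annotated features from a name-keyed abundance table
#'
#' Supplementary-style tables carry lipid names rather than m/z values; this
#' bypasses mass lookup and turns each parseable row into a feature with an
#' accepted identity. Unparseable row labels go to a rejects report and the
#' remaining rows are processed.
#'
#' @param named_table Data frame whose first column holds lipid names and
#'   whose remaining columns are per-sample values.
#' @return List with elements `features` (tibble: `feature_id`, `name`,
#'   sample columns), `hits` (tibble in the [annotate_features()] layout,
#'   all accepted, `ppm_error = 0`), and `rejects` (character vector of
#'   unparseable labels).
#' @export
features_from_names <- function(named_table) {
  stopifnot(is.data.frame(named_table), ncol(named_table) >= 1L)
  labels <- as.character(named_table[[1]])
  parsed <- parse_lipid_name_safe(labels)
  rejects <- labels[!parsed$valid]
  keep <- parsed$valid
  features <- tibble::as_tibble(named_table[keep, , drop = FALSE])
  names(features)[1] <- "name"
  features <- tibble::add_column(features,
                                 feature_id = features$name, .before = 1L)
  hits <- tibble::tibble(
    feature_id = features$feature_id,
    name = lipid_name(parsed$class_code[keep], parsed$n[keep],
                      parsed$d[keep]),
    class_code = parsed$class_code[keep],
    n = parsed$n[keep], d = parsed$d[keep],
    adduct = NA_character_, mz_catalog = NA_real_, ppm_error = 0,
    accepted = TRUE
  )
  list(features = features, hits = hits, rejects = rejects)
}
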