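#' Patient metadata schema
#'
#' The cohort functions take a data frame with one row per patient:
#' `patient_id`, `sex` (`"male"`/`"female"`), `age` (years at sampling),
#' `cald` (cerebral ALD, logical), `ai` (adrenal insufficiency, logical),
#' `edss` (0-10, `NA` allowed), optional `scd` (spinal-cord disease,
#' logical), optional `hct`/`months_post_hct`, optional `xci_fraction`
#' (fraction of cells expressing the variant allele, 0-1) and `sample_id`.
#'
#' @param cohort Data frame to validate.
#' @return The cohort, invisibly, after validation.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("patient_id", "sex", "age") %in% names(cohort)))
  stopifnot(all(cohort$sex %in% c("male", "female")),
            all(cohort$age >= 0))
  if ("edss" %in% names(cohort)) {
    e <- cohort$edss[!is.na(cohort$edss)]
    stopifnot(all(e >= 0 & e <= 10))
  }
  if ("xci_fraction" %in% names(cohort)) {
    x <- cohort$xci_fraction[!is.na(cohort$xci_fraction)]
    stopifnot(all(x >= 0 & x <= 1))
  }
  invisible(cohort)
}

new_strata <- function(rows, exclusions) {
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- exclusions
  class(out) <- c("ald_strata", class(out))
  out
}

stratum_row <- function(name, contrast, predicate, members, ages) {
  tibble::tibble(
    stratum = name, contrast = contrast, predicate = predicate,
    patient_ids = list(members), n = length(members),
    mean_age = if (length(ages)) mean(ages) else NA_real_,
    age_min = if (length(ages)) min(ages) else NA_real_,
    age_max = if (length(ages)) max(ages) else NA_real_
  )
}

#' Stratify male ALD patients by cerebral disease, adrenal function and
#' spinal-cord severity
#'
#' Encodes the natural-history-informed grouping used for the male cohort:
#' cerebral ALD present/absent (absent additionally restricted to age > 55,
#' since leukodystrophy rarely develops later), adrenal insufficiency
#' analogously, and spinal-cord severity with severe defined as EDSS > 6
#' (any age) against mild (EDSS <= 6) restricted to age > 55. Age bounds
#' are strict (`> 55`) and EDSS exactly 6 is mild. Patients lacking an EDSS
#' score are excluded from the spinal-cord contrast only, and recorded in
#' the `exclusions` attribute.
#'
#' @param cohort Patient metadata (male rows are selected; supplying
#'   females is an error to surface mixed inputs early).
#' @param age_cut Age threshold in years (default 55, strict).
#' @param edss_cut EDSS severity threshold (default 6; severe is `> 6`).
#' @return An `ald_strata` tibble: `stratum`, `contrast`, `predicate`,
#'   `patient_ids` (list), `n`, `mean_age`, `age_min`, `age_max`, with an
#'   `exclusions` attribute (tibble `patient_id`, `contrast`, `reason`).
#' @export
stratify_males <- function(cohort, age_cut = 55, edss_cut = 6) {
  validate_cohort(cohort)
  m <- cohort[cohort$sex == "male", ]
  if ("group" %in% names(m)) { # healthy controls are not stratified
    m <- m[!m$group %in% c("control", "female_control"), ]
  }
  stopifnot(nrow(m) > 0, all(c("cald", "ai", "edss") %in% names(m)))
  has_edss <- !is.na(m$edss)
  excl <- tibble::tibble(
    patient_id = m$patient_id[!has_edss],
    contrast = "spinal_cord",
    reason = "missing EDSS"
  )
  if (nrow(excl) > 0) {
    message(nrow(excl), " male patient(s) excluded from the spinal-cord ",
            "contrast (missing EDSS)")
  }
  grab <- function(sel) list(m$patient_id[sel], m$age[sel])
  rows <- list(
    with_pred("CALD", "cerebral", "cald", grab(m$cald)),
    with_pred("noCALD_all", "cerebral", "!cald", grab(!m$cald)),
    with_pred("noCALD_gt55", "cerebral", sprintf("!cald & age > %g", age_cut),
              grab(!m$cald & m$age > age_cut)),
    with_pred("AI", "adrenal", "ai", grab(m$ai)),
    with_pred("noAI_all", "adrenal", "!ai", grab(!m$ai)),
    with_pred("noAI_gt55", "adrenal", sprintf("!ai & age > %g", age_cut),
              grab(!m$ai & m$age > age_cut)),
    with_pred("mild_gt55", "spinal_cord",
              sprintf("edss <= %g & age > %g", edss_cut, age_cut),
              grab(has_edss & m$edss <= edss_cut & m$age > age_cut)),
    with_pred("severe", "spinal_cord", sprintf("edss > %g", edss_cut),
              grab(has_edss & m$edss > edss_cut))
  )
  new_strata(rows, excl)
}

with_pred <- function(name, contrast, predicate, members_ages) {
  stratum_row(name, contrast, predicate, members_ages[[1]],
              members_ages[[2]])
}

#' Stratify female ALD patients by spinal-cord disease severity
#'
#' Spinal-cord disease is rare before the fourth decade, so only women
#' over `age_min` years enter the contrast. Severity is operationalized
#' either by EDSS threshold (`rule = "edss"`, severe is EDSS > 6; the
#' default) or by a recorded spinal-cord-disease flag (`rule = "scd"`,
#' requiring an `scd` column).
#'
#' @param cohort Patient metadata.
#' @param age_min Minimum age, strict (default 40).
#' @param rule `"edss"` or `"scd"`.
#' @param edss_cut EDSS severity threshold (default 6).
#' @return An `ald_strata` tibble with strata `mild` and `severe`
#'   (contrast `"spinal_cord_female"`).
#' @export
stratify_females <- function(cohort, age_min = 40,
                             rule = c("edss", "scd"), edss_cut = 6) {
  rule <- match.arg(rule)
  validate_cohort(cohort)
  f <- cohort[cohort$sex == "female" & cohort$age > age_min, ]
  if ("group" %in% names(f)) {
    f <- f[!f$group %in% c("control", "female_control"), ]
  }
  stopifnot(nrow(f) > 0)
  if (rule == "edss") {
    stopifnot("edss" %in% names(f))
    known <- !is.na(f$edss)
    severe <- known & f$edss > edss_cut
    mild <- known & f$edss <= edss_cut
    pred_sev <- sprintf("age > %g & edss > %g", age_min, edss_cut)
    pred_mild <- sprintf("age > %g & edss <= %g", age_min, edss_cut)
    reason <- "missing EDSS"
  } else {
    stopifnot("scd" %in% names(f))
    known <- !is.na(f$scd)
    severe <- known & f$scd
    mild <- known & !f$scd
    pred_sev <- sprintf("age > %g & scd", age_min)
    pred_mild <- sprintf("age > %g & !scd", age_min)
    reason <- "missing spinal-cord-disease status"
  }
  excl <- tibble::tibble(patient_id = f$patient_id[!known],
                         contrast = "spinal_cord_female", reason = reason)
  if (nrow(excl) > 0) {
    message(nrow(excl), " female patient(s) excluded from the severity ",
            "contrast (", reason, ")")
  }
  rows <- list(
    stratum_row("mild", "spinal_cord_female", pred_mild,
                f$patient_id[mild], f$age[mild]),
    stratum_row("severe", "spinal_cord_female", pred_sev,
                f$patient_id[severe], f$age[severe])
  )
  new_strata(rows, excl)
}

#' Extract member patient ids of a stratum
#'
#' @param strata An `ald_strata` tibble.
#' @param name Stratum name.
#' @return Character vector of patient ids.
#' @export
stratum_members <- function(strata, name) {
  i <- match(name, strata$stratum)
  if (is.na(i)) stop("No stratum named '", name, "'", call. = FALSE)
  strata$patient_ids[[i]]
}

#' Assemble post-transplant biomarker trajectories
#'
#' Organizes longitudinal biomarker measurements of transplanted patients
#' into per-patient trajectories sorted by months post transplant.
#' Baseline is `months == 0`; a patient with follow-up but no baseline is
#' retained and reported in the `missing_baseline` attribute.
#'
#' @param series Data frame with columns `patient_id`, `months`, `value`.
#' @return Tibble sorted by patient then months, class `hct_series`, with
#'   a `missing_baseline` attribute listing patient ids lacking a baseline.
#' @export
hct_series <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("patient_id", "months", "value") %in% names(series)),
            all(series$months >= 0))
  out <- dplyr::arrange(tibble::as_tibble(series), .data$patient_id,
                        .data$months)
  base <- tapply(out$months, out$patient_id, function(m) any(m == 0))
  nobase <- names(base)[!base]
  if (length(nobase) > 0) {
    message(length(nobase), " patient(s) have follow-up samples but no ",
            "baseline: ", paste(nobase, collapse = ", "))
  }
  attr(out, "missing_baseline") <- nobase
  class(out) <- c("hct_series", class(out))
  out
}
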