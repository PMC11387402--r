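#' Simulation configuration for a synthetic ALD lipidomics study
#'
#' Bundles every parameter of the synthetic cohort and data generator.
#' Defaults encode the study conditions the analysis is designed for:
#' stratified male (n = 92 plus 12 controls) and female (n = 65 plus 12
#' controls) cohorts, a chain-length-dependent VLCFA enrichment of the ALD
#' lipidome (`log2FC(n, d, group) = beta_group * max(0, n - n0_class) *
#' s(d)` with saturation damping `s(d) = max(0, 1 - d/d_max)` and
#' class-specific hinge `n0` = 20/40/60 carbons for 1/2/3-radyl classes),
#' log-normal measurement noise, a linear coupling between X-inactivation
#' and plasma LPC(26:0) calibrated to a population Pearson r of 0.79, and
#' a post-transplant exponential decay from a 435 nmol/L baseline toward a
#' plateau above the 72 nmol/L healthy upper reference limit (12- and
#' 24-month group means near 219 and 190 nmol/L).
#'
#' @param seed Master seed; all stage seeds derive from it
#'   deterministically.
#' @param ... Named overrides of any default listed below.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # cohort sizes (male stratification engineered to the study's Table-1
    # style counts: CALD 24 of whom 3 aged > 55, noCALD 68 of whom 21
    # aged > 55, adrenal insufficiency 50, severe spinal-cord 15, mild
    # > 55 17; females: 54 of 65 aged > 40, split 28 mild / 26 severe)
    n_control_male = 12L, n_control_female = 12L,
    n_cald = 24L, n_nocald = 68L, n_nocald_gt55 = 21L, n_cald_gt55 = 3L,
    n_ai_cald = 19L, n_ai_nocald = 31L, n_ai_nocald_gt55 = 3L,
    n_severe = 15L, n_severe_cald = 5L, n_mild_gt55 = 17L,
    n_female = 65L, n_female_young = 11L, n_female_mild = 28L,
    n_female_severe = 26L,
    # lipidome
    lipid_grid = NULL, # NULL -> default_lipid_grid()
    baseline_meanlog = 0, baseline_sdlog = 1,
    beta = c(control = 0, noCALD = 0.12, CALD = 0.18),
    noise_cv = 0.2,
    ppm_jitter_sd = 1,
    # targeted LPC(26:0) (nmol/L): healthy log-normal with 97.5th
    # percentile at the 72 nmol/L upper reference limit; patient-group
    # means in the range reported for stratified ALD cohorts
    lpc26_control_medianlog = log(36), lpc26_control_sdlog = 0.35,
    lpc26_group_mean = c(control = 40, noCALD = 395, CALD = 600,
                         female_mild = 235, female_severe = 337),
    lpc26_sdlog = 0.35,
    # total C26:0 (umol/L) coupled to LPC(26:0) on the log scale; noise
    # is derived at generation time so the population log-scale
    # correlation (~ Spearman for a bivariate log-normal) hits the target
    c26_intercept_log = log(3.5), c26_slope = 0.45,
    c26_target_spearman = 0.7,
    # female X-inactivation coupling
    xci_n = 28L, xci_target_r = 0.79, xci_slope = 500,
    xci_intercept = 100,
    # post-transplant decay C(t) = P + (C0 - P) exp(-k t)
    hct_n = 12L, hct_timepoints = c(0, 6, 12, 24),
    hct_baseline_mean = 435, hct_baseline_sdlog = 0.18,
    hct_plateau_mean = 185.5, hct_plateau_sdlog = 0.1,
    hct_k = 0.167, hct_k_sdlog = 0.2, hct_noise_cv = 0.06,
    control_upper_lpc26 = 72
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("Unknown simulation parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  stopifnot(all(cfg$beta >= 0), cfg$noise_cv > 0, cfg$hct_k > 0,
            cfg$hct_plateau_mean > 0,
            cfg$hct_plateau_mean > cfg$control_upper_lpc26,
            cfg$hct_baseline_mean > cfg$hct_plateau_mean,
            cfg$xci_target_r > 0, cfg$xci_target_r < 1, cfg$xci_slope > 0)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic 32-bit child seed per simulation stage
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_child_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stage))
  force(code)
}

#' Default simulated lipid grid
#'
#' Sum-composition grid of six plasma lipid classes with class-specific
#' VLCFA hinge (`n0`) and saturation cutoff (`d_max`): chain lengths where
#' ALD enrichment begins at > 20 carbons for single-chain classes
#' (LPC, CE), > 40 for two-chain (PC, DG, SM) and > 60 for TG.
#'
#' @return Tibble `class_code`, `n`, `d`, `n0`, `d_max`, `lipid`.
#' @export
default_lipid_grid <- function() {
  spec <- list(
    LPC = list(n = 16:30, d = 0:2, n0 = 20, d_max = 2),
    CE  = list(n = 14:26, d = 0:2, n0 = 20, d_max = 2),
    PC  = list(n = seq(30, 48, 2), d = 0:4, n0 = 40, d_max = 7),
    DG  = list(n = seq(28, 44, 2), d = 0:4, n0 = 40, d_max = 7),
    SM  = list(n = seq(30, 42, 2), d = 0:2, n0 = 40, d_max = 7),
    TG  = list(n = seq(42, 66, 2), d = 0:6, n0 = 60, d_max = 7)
  )
  out <- purrr::imap(spec, function(s, code) {
    g <- tidyr::expand_grid(n = s$n, d = s$d)
    tibble::tibble(class_code = code, n = g$n, d = g$d, n0 = s$n0,
                   d_max = s$d_max)
  })
  out <- dplyr::bind_rows(out)
  out$lipid <- lipid_name(out$class_code, out$n, out$d)
  out
}

# planted log2 fold change of one lipid for a given effect size
planted_log2fc <- function(beta, n, n0, d, d_max) {
  beta * pmax(0, n - n0) * pmax(0, 1 - d / d_max)
}

#' Simulate a stratified ALD patient cohort
#'
#' Generates patient metadata with the configured stratum sizes: male ALD
#' patients with cerebral-ALD, adrenal-insufficiency and EDSS attributes
#' engineered so the stratification rules reproduce the configured counts;
#' female patients split by spinal-cord severity above age 40; healthy
#' male and female controls. Severe patients carry EDSS > 6 and a
#' spinal-cord-disease flag, so both female severity rules agree on
#' synthetic cohorts. Twelve male cerebral-ALD patients are flagged as
#' transplanted.
#'
#' @param config A [simulation_config()].
#' @return Cohort tibble (see [validate_cohort()]) with columns
#'   `patient_id`, `sample_id`, `sex`, `age`, `group` (`control`, `CALD`,
#'   `noCALD`, `female`, `female_control`), `cald`, `ai`, `edss`, `scd`,
#'   `hct`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  with_child_seed(config$seed, "cohort", {
    rage <- function(n, lo, hi) round(stats::runif(n, lo, hi), 1)

    # --- males with ALD ---
    n_cald <- config$n_cald
    cald_age <- c(rage(n_cald - config$n_cald_gt55, 6, 55),
                  rage(config$n_cald_gt55, 56, 73))
    n_noc <- config$n_nocald
    noc_age <- c(rage(n_noc - config$n_nocald_gt55, 9, 55),
                 rage(config$n_nocald_gt55, 56, 74))
    males <- tibble::tibble(
      patient_id = sprintf("M%03d", seq_len(n_cald + n_noc)),
      sex = "male",
      age = c(cald_age, noc_age),
      group = rep(c("CALD", "noCALD"), c(n_cald, n_noc)),
      cald = rep(c(TRUE, FALSE), c(n_cald, n_noc))
    )
    # adrenal insufficiency: configured counts within CALD, young noCALD
    # and old noCALD
    resample <- function(x, k) x[sample.int(length(x), k)]
    males$ai <- FALSE
    males$ai[resample(which(males$cald), config$n_ai_cald)] <- TRUE
    young_noc <- which(!males$cald & males$age <= 55)
    old_noc <- which(!males$cald & males$age > 55)
    males$ai[resample(young_noc,
                      config$n_ai_nocald - config$n_ai_nocald_gt55)] <- TRUE
    males$ai[resample(old_noc, config$n_ai_nocald_gt55)] <- TRUE
    # spinal-cord severity: severe (EDSS > 6) split between CALD (young)
    # and noCALD so that mild patients aged > 55 reach the configured
    # count; everyone else mild (EDSS <= 6)
    males$edss <- round(stats::runif(nrow(males), 0, 6) * 2) / 2
    sev_cald <- resample(which(males$cald & males$age <= 55),
                         config$n_severe_cald)
    n_sev_old <- (config$n_nocald_gt55 + config$n_cald_gt55) -
      config$n_mild_gt55
    sev_old <- resample(old_noc, n_sev_old)
    sev_young_noc <- resample(young_noc,
                              config$n_severe - config$n_severe_cald -
                                n_sev_old)
    severe_idx <- c(sev_cald, sev_old, sev_young_noc)
    males$edss[severe_idx] <- round(stats::runif(length(severe_idx),
                                                 6.5, 9) * 2) / 2
    males$scd <- males$edss > 6
    males$hct <- FALSE
    males$hct[utils::head(which(males$cald), config$hct_n)] <- TRUE

    # --- females with ALD ---
    nf <- config$n_female
    f_age <- c(rage(config$n_female_young, 18, 40),
               rage(nf - config$n_female_young, 41, 78))
    females <- tibble::tibble(
      patient_id = sprintf("F%03d", seq_len(nf)),
      sex = "female", age = f_age, group = "female",
      cald = FALSE, ai = FALSE
    )
    # among women aged > 40: configured mild/severe split (severe EDSS
    # > 6 and spinal-cord disease flagged); younger women mild
    females$edss <- round(stats::runif(nf, 0, 6) * 2) / 2
    old_f <- which(females$age > 40)
    sev_f <- resample(old_f, config$n_female_severe)
    females$edss[sev_f] <- round(stats::runif(length(sev_f), 6.5, 9) * 2) / 2
    females$scd <- females$edss > 6
    females$hct <- FALSE

    controls <- tibble::tibble(
      patient_id = c(sprintf("CM%02d", seq_len(config$n_control_male)),
                     sprintf("CF%02d", seq_len(config$n_control_female))),
      sex = rep(c("male", "female"),
                c(config$n_control_male, config$n_control_female)),
      age = rage(config$n_control_male + config$n_control_female, 18, 70),
      group = rep(c("control", "female_control"),
                  c(config$n_control_male, config$n_control_female)),
      cald = FALSE, ai = FALSE, edss = NA_real_, scd = NA, hct = FALSE
    )
    out <- dplyr::bind_rows(males, females, controls)
    out$sample_id <- out$patient_id
    validate_cohort(out)
    out
  })
}

#' Simulate a semi-quantitative lipid abundance table
#'
#' Log-normal per-lipid baselines shared across samples, a planted
#' chain-length/unsaturation effect per group (`log2FC = beta_group *
#' max(0, n - n0) * s(d)`), and multiplicative log-normal measurement
#' noise at the configured CV. The planted truth travels with the table.
#'
#' @param config A [simulation_config()].
#' @param sample_groups Named character vector: sample id -> effect group
#'   (a name of `config$beta`).
#' @return Abundance tibble (`lipid` + sample columns) with attributes
#'   `truth` (tibble `lipid`, `class_code`, `n`, `d`, and one
#'   `log2fc_<group>` column per effect group) and `units = "A.U."`.
#' @export
simulate_abundance <- function(config, sample_groups) {
  stopifnot(!is.null(names(sample_groups)),
            all(sample_groups %in% names(config$beta)))
  grid <- config$lipid_grid %||% default_lipid_grid()
  with_child_seed(config$seed, "abundance", {
    base_meanlog <- stats::rnorm(nrow(grid), config$baseline_meanlog,
                                 config$baseline_sdlog)
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    l2fc <- vapply(names(config$beta), function(g) {
      planted_log2fc(config$beta[[g]], grid$n, grid$n0, grid$d,
                     grid$d_max)
    }, numeric(nrow(grid)))
    eff <- l2fc[, sample_groups, drop = FALSE] # lipid x sample
    vals <- exp(
      matrix(base_meanlog, nrow(grid), length(sample_groups)) +
        log(2) * eff +
        matrix(stats::rnorm(nrow(grid) * length(sample_groups), 0, sdlog),
               nrow(grid))
    )
    colnames(vals) <- names(sample_groups)
    out <- tibble::as_tibble(as.data.frame(vals))
    out <- tibble::add_column(out, lipid = grid$lipid, .before = 1L)
    truth <- tibble::tibble(lipid = grid$lipid,
                            class_code = grid$class_code,
                            n = grid$n, d = grid$d)
    for (g in names(config$beta)) {
      truth[[paste0("log2fc_", g)]] <- l2fc[, g]
    }
    attr(out, "truth") <- truth
    attr(out, "units") <- "A.U."
    out
  })
}

#' Simulate a feature-level table from an abundance table
#'
#' Maps each lipid to its protonated catalog m/z with Gaussian ppm jitter
#' and converts abundances back to peak areas through per-class, per-sample
#' internal-standard areas with log-normal instrument drift, so the full
#' annotate-and-semiquantify path can be exercised end to end.
#'
#' @param config A [simulation_config()].
#' @param abundance Abundance table from [simulate_abundance()] (lipid
#'   names must exist in the catalog's classes).
#' @param templates Class templates, defaults to
#'   [lipid_class_templates()].
#' @return List: `features` (tibble `feature_id`, `mz`, `polarity` +
#'   sample area columns), `is_areas` (tibble `class_code` + sample
#'   columns), `catalog` (the `mz_catalog` used).
#' @export
simulate_features <- function(config, abundance,
                              templates = lipid_class_templates()) {
  parsed <- parse_lipid_name(abundance$lipid)
  tpl <- templates[templates$class_code %in% unique(parsed$class_code), ]
  catalog <- build_catalog(tpl)
  entry <- catalog[catalog$adduct == "[M+H]+", ]
  idx <- match(abundance$lipid, entry$name)
  if (anyNA(idx)) {
    stop("Lipid(s) not in catalog: ",
         paste(utils::head(abundance$lipid[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  }
  samples <- setdiff(names(abundance), "lipid")
  is_specs <- internal_standards(tpl)
  with_child_seed(config$seed, "features", {
    mz <- entry$mz[idx] *
      (1 + stats::rnorm(length(idx), 0, config$ppm_jitter_sd) * 1e-6)
    is_areas_mat <- matrix(
      stats::rlnorm(nrow(is_specs) * length(samples), log(1e6), 0.3),
      nrow(is_specs), length(samples)
    )
    is_conc <- is_specs$is_amount_nmol / is_specs$plasma_volume_uL
    row_of <- match(parsed$class_code, is_specs$class_code)
    ab <- as.matrix(abundance[, samples, drop = FALSE])
    areas <- ab / is_conc[row_of] * is_areas_mat[row_of, , drop = FALSE]
    features <- tibble::as_tibble(as.data.frame(areas))
    names(features) <- samples
    features <- tibble::add_column(
      features,
      feature_id = sprintf("F%04d", seq_along(mz)),
      mz = mz, polarity = "positive", .before = 1L
    )
    is_areas <- tibble::as_tibble(as.data.frame(is_areas_mat))
    names(is_areas) <- samples
    is_areas <- tibble::add_column(is_areas,
                                   class_code = is_specs$class_code,
                                   .before = 1L)
    list(features = features, is_areas = is_areas, catalog = catalog)
  })
}

#' Simulate the X-inactivation / LPC(26:0) coupling
#'
#' Draws X-inactivation fractions (toward the variant allele) uniformly on
#' (0, 1) and couples plasma LPC(26:0) linearly with Gaussian noise whose
#' variance is calibrated so the population Pearson correlation equals the
#' configured target: `sigma = slope * sd(x) * sqrt(1/r^2 - 1)`.
#'
#' @param config A [simulation_config()].
#' @param n Number of patients (default from config, 28).
#' @param rep_seed Optional replicate index mixed into the stage seed.
#' @param sigma Noise standard deviation; `NULL` (default) derives it
#'   from the configured target correlation, 0 gives a perfectly linear
#'   coupling.
#' @return Tibble `patient_id`, `xci_fraction`, `lpc26` with attribute
#'   `population_r`.
#' @export
simulate_xci <- function(config = simulation_config(), n = config$xci_n,
                         rep_seed = 0L, sigma = NULL) {
  r <- config$xci_target_r
  sd_x <- sqrt(1 / 12) # Uniform(0,1)
  if (is.null(sigma)) {
    sigma <- config$xci_slope * sd_x * sqrt(1 / r^2 - 1)
  } else {
    stopifnot(sigma >= 0)
  }
  with_child_seed(config$seed + rep_seed, "xci", {
    x <- stats::runif(n)
    y <- config$xci_intercept + config$xci_slope * x +
      stats::rnorm(n, 0, sigma)
    out <- tibble::tibble(patient_id = sprintf("F%03d", seq_len(n)),
                          xci_fraction = x, lpc26 = pmax(y, 1))
    attr(out, "population_r") <- r
    out
  })
}

#' Simulate post-transplant LPC(26:0) trajectories
#'
#' Per-patient exponential decay `C_i(t) = P_i + (C0_i - P_i) exp(-k_i t)`
#' with log-normal patient random effects on baseline, plateau and rate,
#' plateaus kept strictly above the configured healthy upper reference
#' limit, and multiplicative measurement noise.
#'
#' @param config A [simulation_config()].
#' @param n_patients,timepoints Cohort shape (defaults 12 patients at 0,
#'   6, 12, 24 months).
#' @param rep_seed Optional replicate index mixed into the stage seed.
#' @return An [hct_series()] tibble with attribute `truth` (tibble
#'   `patient_id`, `C0`, `P`, `k`).
#' @export
simulate_hct <- function(config = simulation_config(),
                         n_patients = config$hct_n,
                         timepoints = config$hct_timepoints,
                         rep_seed = 0L) {
  stopifnot(config$hct_baseline_mean > config$hct_plateau_mean)
  with_child_seed(config$seed + rep_seed, "hct", {
    meanlog <- function(m, s) log(m) - s^2 / 2
    C0 <- stats::rlnorm(n_patients,
                        meanlog(config$hct_baseline_mean,
                                config$hct_baseline_sdlog),
                        config$hct_baseline_sdlog)
    P <- pmax(stats::rlnorm(n_patients,
                            meanlog(config$hct_plateau_mean,
                                    config$hct_plateau_sdlog),
                            config$hct_plateau_sdlog),
              config$control_upper_lpc26 * 1.05)
    C0 <- pmax(C0, P * 1.2)
    k <- stats::rlnorm(n_patients,
                       meanlog(config$hct_k, config$hct_k_sdlog),
                       config$hct_k_sdlog)
    sdlog_noise <- sqrt(log(1 + config$hct_noise_cv^2))
    grid <- tidyr::expand_grid(i = seq_len(n_patients), months = timepoints)
    mu <- P[grid$i] + (C0[grid$i] - P[grid$i]) * exp(-k[grid$i] * grid$months)
    value <- mu * stats::rlnorm(nrow(grid), -sdlog_noise^2 / 2, sdlog_noise)
    out <- hct_series(tibble::tibble(
      patient_id = sprintf("H%02d", grid$i), months = grid$months,
      value = value
    ))
    attr(out, "truth") <- tibble::tibble(
      patient_id = sprintf("H%02d", seq_len(n_patients)),
      C0 = C0, P = P, k = k
    )
    out
  })
}

#' Simulate a complete synthetic ALD study
#'
#' One call producing every dataset the pipeline consumes: the stratified
#' cohort, the male lipidome abundance table (cerebral/non-cerebral ALD
#' and controls) with its planted truth, targeted LPC(26:0) and total
#' C26:0 vectors coupled on the log scale, the female X-inactivation
#' pairs, and the post-transplant trajectories. Regeneration from the
#' same configuration is bit-identical.
#'
#' @param config A [simulation_config()].
#' @return A `sim_study` list: `config`, `cohort`, `abundance`, `truth`,
#'   `targeted` (tibble `patient_id`, `group`, `lpc26`, `c26`), `xci`,
#'   `hct`.
#' @export
simulate_ald_study <- function(config = simulation_config()) {
  cohort <- simulate_cohort(config)
  males <- cohort[cohort$sex == "male" &
                    cohort$group %in% c("control", "CALD", "noCALD"), ]
  sample_groups <- stats::setNames(males$group, males$sample_id)
  abundance <- simulate_abundance(config, sample_groups)

  with_targeted <- cohort[cohort$group %in%
                            names(config$lpc26_group_mean) |
                            (cohort$sex == "female" & cohort$age > 40), ]
  grp <- ifelse(with_targeted$group == "female",
                ifelse(with_targeted$scd, "female_severe", "female_mild"),
                with_targeted$group)
  grp[grp == "female_control"] <- "control"
  targeted <- with_child_seed(config$seed, "targeted", {
    mu <- config$lpc26_group_mean[grp]
    sdl <- config$lpc26_sdlog
    lpc26 <- ifelse(
      grp == "control",
      stats::rlnorm(length(mu), config$lpc26_control_medianlog,
                    config$lpc26_control_sdlog),
      stats::rlnorm(length(mu), log(mu) - sdl^2 / 2, sdl)
    )
    r26 <- config$c26_target_spearman
    c26_sd <- config$c26_slope * stats::sd(log(lpc26)) *
      sqrt(1 / r26^2 - 1)
    c26 <- exp(config$c26_intercept_log +
                 config$c26_slope * (log(lpc26) - log(300)) +
                 stats::rnorm(length(mu), 0, c26_sd))
    tibble::tibble(patient_id = with_targeted$patient_id, group = grp,
                   lpc26 = lpc26, c26 = c26)
  })

  xci <- simulate_xci(config)
  cohort$xci_fraction <- NA_real_
  cohort$xci_fraction[match(xci$patient_id, cohort$patient_id)] <-
    xci$xci_fraction

  out <- list(config = config, cohort = cohort, abundance = abundance,
              truth = attr(abundance, "truth"), targeted = targeted,
              xci = xci, hct = simulate_hct(config))
  class(out) <- "sim_study"
  out
}
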