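#' Built-in adduct ion definitions
#'
#' Electron-mass-corrected adduct shifts for the default positive and
#' negative electrospray adducts. The shift of \[M+H\]+ is exactly the proton
#' mass; cationized adducts subtract, and anionized adducts add, one
#' electron mass.
#'
#' @return Tibble with columns `adduct`, `polarity`, `charge`, `shift` (Da).
#' @export
#' @examples
#' adduct_table()
adduct_table <- function() {
  em <- element_masses()
  e <- electron_mass()
  tibble::tibble(
    adduct = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-", "[M+HCOO]-"),
    polarity = c("positive", "positive", "positive", "negative", "negative"),
    charge = c(1L, 1L, 1L, -1L, -1L),
    shift = c(
      proton_mass(),
      em[["N"]] + 4 * em[["H"]] - e,
      em[["Na"]] - e,
      -(em[["H"]] - e),
      em[["C"]] + em[["H"]] + 2 * em[["O"]] + e
    )
  )
}

default_class_config_path <- function() {
  system.file("extdata", "lipid_classes.yaml", package = "lipidald",
              mustWork = TRUE)
}

#' Load lipid class templates from a YAML configuration
#'
#' Each template defines a lipid class by its sum-composition formula rule
#' `C(n + carbon_offset) H(2n + hydrogen_offset - 2d)` plus fixed heteroatom
#' counts, the radyl grid over which the class is expanded, its adduct set,
#' and the class internal standard (species, nmol spiked per extraction,
#' plasma volume).
#'
#' @param path Path to a class-template YAML file; defaults to the built-in
#'   configuration covering 16 plasma lipid classes with the internal
#'   standards of a 20 uL plasma extraction.
#' @return Tibble with one row per class: `class_code`, `radyl_count`,
#'   `carbon_offset`, `hydrogen_offset`, `fixed` (list of heteroatom
#'   counts), `carbon_min`, `carbon_max`, `db_min`, `db_max`, `adducts`
#'   (list of adduct names), `is_species`, `is_amount_nmol`,
#'   `plasma_volume_uL`.
#' @export
#' @examples
#' templates <- lipid_class_templates()
#' templates[templates$class_code == "LPC", ]
lipid_class_templates <- function(path = default_class_config_path()) {
  cfg <- yaml::read_yaml(path)
  vol <- cfg$plasma_volume_uL
  stopifnot(is.numeric(vol), vol > 0)
  all_adducts <- c(cfg$adducts$positive, cfg$adducts$negative)
  known <- adduct_table()$adduct
  if (!all(all_adducts %in% known)) {
    stop("Unknown adduct(s) in config: ",
         paste(setdiff(all_adducts, known), collapse = ", "), call. = FALSE)
  }
  out <- purrr::imap(cfg$classes, function(cl, code) {
    stopifnot(
      cl$radyl_count >= 1, cl$radyl_count <= 4,
      cl$carbon_range[1] >= 2 * cl$radyl_count,
      cl$internal_standard$amount_nmol > 0
    )
    tibble::tibble(
      class_code = code,
      radyl_count = as.integer(cl$radyl_count),
      carbon_offset = as.integer(cl$carbon_offset),
      hydrogen_offset = as.integer(cl$hydrogen_offset),
      fixed = list(unlist(cl$fixed)),
      carbon_min = as.integer(cl$carbon_range[1]),
      carbon_max = as.integer(cl$carbon_range[2]),
      db_min = as.integer(cl$db_range[1]),
      db_max = as.integer(cl$db_range[2]),
      adducts = list(all_adducts),
      is_species = cl$internal_standard$species,
      is_amount_nmol = cl$internal_standard$amount_nmol,
      plasma_volume_uL = vol
    )
  })
  dplyr::bind_rows(out)
}

#' Elemental formula of one sum-composition species of a class
#'
#' Applies a template's formula rule at total carbons `n` and total double
#' bonds `d`. A rule yielding a negative element count (outside the
#' chemically valid region) is an invalid-template error naming the pair.
#'
#' @param template One-row template tibble (a row of
#'   [lipid_class_templates()]).
#' @param n,d Total radyl carbons and total double bonds.
#' @return Formula string.
#' @export
#' @examples
#' tpl <- lipid_class_templates()
#' class_formula(tpl[tpl$class_code == "LPC", ], 26, 0) # "C34H70NO7P"
class_formula <- function(template, n, d) {
  stopifnot(nrow(template) == 1L)
  counts <- c(
    C = n + template$carbon_offset,
    H = 2L * n + template$hydrogen_offset - 2L * d
  )
  counts <- c(counts, template$fixed[[1]])
  if (any(counts < 0)) {
    stop("Invalid template ", template$class_code, " at (", n, ":", d,
         "): negative element count", call. = FALSE)
  }
  formula_string(counts)
}

#' Internal standard specifications from the class templates
#'
#' @param templates Template tibble from [lipid_class_templates()].
#' @return Tibble with columns `class_code`, `is_species`, `is_amount_nmol`,
#'   `plasma_volume_uL`, `is_conc` (amount/volume, nmol/uL = mmol/L).
#' @export
internal_standards <- function(templates = lipid_class_templates()) {
  dplyr::mutate(
    dplyr::select(templates, "class_code", "is_species", "is_amount_nmol",
                  "plasma_volume_uL"),
    is_conc = .data$is_amount_nmol / .data$plasma_volume_uL
  )
}
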