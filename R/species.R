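#' Parse lipid names into sum-composition keys
#'
#' Understands sum-composition names (`"PC(44:2)"`), per-chain names summed
#' over chains (`"TG(14:0/14:0/14:0)"`, sphingoid prefixes as in
#' `"SM(d18:1/12:0)"`), isotope-label prefixes (`"D7-CE(16:0)"`) and
#' acyl-position isomer prefixes (`"1-acyl LPC(26:0)"`), which are preserved
#' as tags.
#'
#' @param names Character vector of lipid names.
#' @return Tibble with one row per name: `name`, `class_code`, `n` (total
#'   carbons), `d` (total double bonds), `isomer` (e.g. `"1-acyl"` or `NA`),
#'   `label` (isotope label or `NA`).
#' @seealso [lipid_name()] for the inverse.
#' @export
#' @examples
#' parse_lipid_name(c("PC(44:2)", "TG(14:0/14:0/14:0)", "D4-LPC(26:0)"))
parse_lipid_name <- function(names) {
  out <- parse_lipid_name_safe(names)
  if (any(!out$valid)) {
    bad <- out$name[!out$valid][1]
    stop("Cannot parse lipid name: '", bad, "'", call. = FALSE)
  }
  out$valid <- NULL
  out
}

# Vectorized non-throwing parser; adds a `valid` column.
parse_lipid_name_safe <- function(names) {
  stopifnot(is.character(names))
  one <- function(name) {
    bad <- tibble::tibble(name = name, class_code = NA_character_,
                          n = NA_integer_, d = NA_integer_,
                          isomer = NA_character_, label = NA_character_,
                          valid = FALSE)
    if (is.na(name)) return(bad)
    x <- trimws(name)
    isomer <- NA_character_
    m <- regmatches(x, regexec("^([12]-acyl)[ -]+(.*)$", x))[[1]]
    if (length(m)) {
      isomer <- m[2]
      x <- m[3]
    }
    label <- NA_character_
    m <- regmatches(x, regexec("^(D\\d+|13C\\d+)-(.*)$", x))[[1]]
    if (length(m)) {
      label <- m[2]
      x <- m[3]
    }
    m <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9]*)\\(([^()]+)\\)$", x))[[1]]
    if (!length(m)) return(bad)
    class_code <- m[2]
    chains <- strsplit(m[3], "/", fixed = TRUE)[[1]]
    cm <- regmatches(chains, regexec("^[dtm]?(\\d+):(\\d+)$", chains))
    if (length(chains) == 0L || any(lengths(cm) != 3L)) return(bad)
    n <- sum(vapply(cm, function(z) as.integer(z[2]), integer(1)))
    d <- sum(vapply(cm, function(z) as.integer(z[3]), integer(1)))
    tibble::tibble(name = name, class_code = class_code, n = n, d = d,
                   isomer = isomer, label = label, valid = TRUE)
  }
  dplyr::bind_rows(lapply(names, one))
}

#' Display name of a sum-composition species
#'
#' @param class_code,n,d Class code, total carbons, total double bonds
#'   (vectorized).
#' @return Character vector `"CLASS(n:d)"`.
#' @export
lipid_name <- function(class_code, n, d) {
  sprintf("%s(%d:%d)", class_code, as.integer(n), as.integer(d))
}

#' Expand a lipid class template into sum-composition species
#'
#' Replaces the radyl slots of the class's generic formula with every
#' (total carbons, total double bonds) pair on the declared grid and
#' computes each species' elemental formula and neutral monoisotopic mass.
#'
#' @param template One-row tibble from [lipid_class_templates()].
#' @param masses Element mass table, see [element_masses()].
#' @return Tibble with columns `class_code`, `n`, `d`, `name`, `formula`,
#'   `neutral_mass` (Da); one row per grid point, names unique.
#' @export
#' @examples
#' tpl <- lipid_class_templates()
#' lpc <- expand_class(tpl[tpl$class_code == "LPC", ])
#' lpc[lpc$n == 26 & lpc$d == 0, ]
expand_class <- function(template, masses = element_masses()) {
  stopifnot(nrow(template) == 1L,
            template$carbon_max >= template$carbon_min,
            template$db_max >= template$db_min)
  grid <- tidyr::expand_grid(
    n = seq.int(template$carbon_min, template$carbon_max),
    d = seq.int(template$db_min, template$db_max)
  )
  grid$class_code <- template$class_code
  grid$name <- lipid_name(template$class_code, grid$n, grid$d)
  grid$formula <- vapply(
    seq_len(nrow(grid)),
    function(i) class_formula(template, grid$n[i], grid$d[i]),
    character(1)
  )
  grid$neutral_mass <- vapply(grid$formula, monoisotopic_mass, numeric(1),
                              masses = masses, USE.NAMES = FALSE)
  dplyr::select(grid, "class_code", "n", "d", "name", "formula",
                "neutral_mass")
}

#' m/z of an adduct ion of a neutral species
#'
#' `m/z = (neutral_mass + shift) / |charge|` with electron-mass-corrected
#' shifts; for \[M+H\]+ the shift is the proton mass (1.007276 Da).
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), > 0.
#' @param adduct Adduct name from [adduct_table()], or a one-row data frame
#'   with `shift` and `charge` columns.
#' @return m/z value(s).
#' @export
#' @examples
#' adduct_mz(635.48899, "[M+H]+") # 636.4963
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(all(neutral_mass > 0))
  if (is.character(adduct)) {
    tab <- adduct_table()
    idx <- match(adduct, tab$adduct)
    if (anyNA(idx)) {
      stop("Unknown adduct: ", paste(adduct[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    adduct <- tab[idx, ]
  }
  if (any(adduct$charge == 0)) stop("Adduct charge must be nonzero",
                                    call. = FALSE)
  (neutral_mass + adduct$shift) / abs(adduct$charge)
}

#' Build an m/z catalog over a set of lipid class templates
#'
#' Expands every template and crosses the species with the class adduct
#' set, producing one catalog entry per (species, adduct) combination,
#' sorted by m/z and queryable with a ppm window.
#'
#' @param templates Template tibble ([lipid_class_templates()]), one or
#'   more rows.
#' @param masses Element mass table.
#' @return An `mz_catalog`: tibble with columns `class_code`, `n`, `d`,
#'   `name`, `formula`, `neutral_mass`, `adduct`, `polarity`, `charge`,
#'   `mz`, sorted by `mz`. The adduct priority order (for annotation
#'   tie-breaks) is stored in the `adduct_priority` attribute.
#' @export
#' @examples
#' tpl <- lipid_class_templates()
#' cat <- build_catalog(tpl[tpl$class_code == "LPC", ])
build_catalog <- function(templates, masses = element_masses()) {
  stopifnot(nrow(templates) >= 1L)
  atab <- adduct_table()
  entries <- purrr::map(seq_len(nrow(templates)), function(i) {
    tpl <- templates[i, ]
    sp <- expand_class(tpl, masses = masses)
    ad <- atab[match(tpl$adducts[[1]], atab$adduct), ]
    tidyr::crossing(sp, ad) |>
      dplyr::mutate(mz = adduct_mz(.data$neutral_mass,
                                   data.frame(shift = .data$shift,
                                              charge = .data$charge)))
  })
  out <- dplyr::bind_rows(entries)
  if (anyDuplicated(paste(out$name, out$adduct))) {
    dup <- unique(paste(out$name, out$adduct)[duplicated(paste(out$name, out$adduct))])
    stop("Duplicate (species, adduct) catalog entries: ",
         paste(utils::head(dup, 5), collapse = "; "), call. = FALSE)
  }
  out <- dplyr::arrange(
    dplyr::select(out, "class_code", "n", "d", "name", "formula",
                  "neutral_mass", "adduct", "polarity", "charge", "mz"),
    .data$mz
  )
  attr(out, "adduct_priority") <- atab$adduct
  class(out) <- c("mz_catalog", class(out))
  out
}

#' Query an m/z catalog with a ppm window
#'
#' Returns exactly the catalog entries of the requested polarity whose m/z
#' lies within `tol_ppm` parts per million of the query, equivalent to a
#' linear scan but using binary search on the sorted catalog.
#'
#' @param catalog An `mz_catalog` from [build_catalog()].
#' @param mz Query m/z (scalar).
#' @param tol_ppm Tolerance in ppm (> 0).
#' @param polarity `"positive"`, `"negative"`, or `NULL` for both.
#' @return Tibble of matching entries with an added signed `ppm_error`
#'   column (observed minus catalog, in ppm of the catalog m/z).
#' @export
query_catalog <- function(catalog, mz, tol_ppm, polarity = NULL) {
  stopifnot(length(mz) == 1L, mz > 0, tol_ppm > 0)
  lo <- mz * (1 - tol_ppm * 1e-6)
  hi <- mz * (1 + tol_ppm * 1e-6)
  i_lo <- findInterval(lo, catalog$mz)
  # findInterval counts entries <= lo; an entry exactly at lo is in-window
  start <- if (i_lo >= 1L && catalog$mz[i_lo] >= lo) i_lo else i_lo + 1L
  end <- findInterval(hi, catalog$mz)
  hits <- if (end < start) catalog[0, ] else catalog[start:end, ]
  hits <- tibble::as_tibble(hits)
  if (!is.null(polarity)) hits <- hits[hits$polarity == polarity, ]
  hits$ppm_error <- (mz - hits$mz) / hits$mz * 1e6
  hits[abs(hits$ppm_error) <= tol_ppm, ]
}
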