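#' Read an abundance table (lipids in rows, samples in columns)
#'
#' Accepts the supplementary-data layout: first column lipid names, header
#' row sample ids, TSV or CSV (delimiter sniffed). Lines starting with `#`
#' are provenance comments and skipped. Duplicate lipid rows and
#' decimal-comma number dialects are rejected with explicit errors.
#'
#' @param path File path.
#' @return Tibble with `lipid` plus numeric sample columns.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  delim <- sniff_delim(path)
  x <- readr::read_delim(path, delim = delim, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "lipid"
  dup <- unique(x$lipid[duplicated(x$lipid)])
  if (length(dup) > 0) {
    stop("Duplicate lipid row(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(names(x), "lipid")) {
    if (is.character(x[[col]])) {
      if (any(grepl("^-?\\d+,\\d+$", x[[col]]))) {
        stop("Column '", col, "' uses a decimal-comma dialect; ",
             "use '.' as the decimal separator", call. = FALSE)
      }
      x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
    }
  }
  x
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 25L, warn = FALSE)
  first <- first[!startsWith(first, "#")][1]
  if (is.na(first)) stop("Empty file: ", path, call. = FALSE)
  if (grepl("\t", first)) return("\t")
  if (grepl(";", first) && !grepl(",", first)) {
    stop("Semicolon-delimited (decimal-comma dialect) input is not ",
         "supported; use '.' as the decimal separator with TSV or CSV",
         call. = FALSE)
  }
  ","
}

#' Read patient metadata
#'
#' CSV/TSV with the [validate_cohort()] column schema; logical columns
#' (`cald`, `ai`, `scd`, `hct`) are coerced from TRUE/FALSE or 0/1.
#'
#' @param path File path.
#' @return Validated cohort tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  x <- readr::read_delim(path, delim = sniff_delim(path), comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("cald", "ai", "scd", "hct"), names(x))) {
    x[[col]] <- as.logical(x[[col]])
  }
  validate_cohort(x)
  tibble::as_tibble(x)
}

#' Check that abundance samples and metadata agree
#'
#' @param abundance Abundance tibble (`lipid` + sample columns).
#' @param cohort Metadata with a `sample_id` column.
#' @return Invisibly, the common sample ids; any mismatch is an error
#'   listing the difference in both directions.
#' @export
check_samples <- function(abundance, cohort) {
  ab <- setdiff(names(abundance), "lipid")
  meta <- cohort$sample_id
  only_ab <- setdiff(ab, meta)
  only_meta <- setdiff(meta, ab)
  if (length(only_ab) || length(only_meta)) {
    stop("Sample id mismatch. In table only: ",
         paste(only_ab, collapse = ", "),
         "; in metadata only: ", paste(only_meta, collapse = ", "),
         call. = FALSE)
  }
  invisible(ab)
}

#' Write a result table as TSV with a provenance header
#'
#' The header comment records the package version, the configuration hash
#' and the seed, so reruns of deterministic stages with the same
#' configuration produce byte-identical files.
#'
#' @param x Data frame.
#' @param path Output path (written atomically via a temp file).
#' @param config Optional object whose [rlang::hash()] is recorded.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, config = NULL, seed = NULL) {
  header <- sprintf(
    "# lipidald %s | config_hash=%s | seed=%s",
    as.character(utils::packageVersion("lipidald")),
    if (is.null(config)) "none" else rlang::hash(config),
    if (is.null(seed)) "none" else format(seed)
  )
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "w")
  writeLines(header, con)
  close(con)
  df <- as.data.frame(x)
  list_cols <- vapply(df, is.list, logical(1))
  df[list_cols] <- lapply(df[list_cols], function(col) {
    vapply(col, function(v) paste(v, collapse = ";"), character(1))
  })
  readr::write_tsv(df, tmp, append = TRUE, col_names = TRUE, na = "")
  file.rename(tmp, path)
  invisible(path)
}

#' Write / read an m/z catalog as TSV
#'
#' @param catalog An `mz_catalog`.
#' @param path File path.
#' @name catalog-io
#' @return `write_catalog()` returns the path invisibly; `read_catalog()`
#'   an `mz_catalog` tibble.
#' @export
write_catalog <- function(catalog, path) {
  write_results(catalog, path, config = attr(catalog, "adduct_priority"))
}

#' @rdname catalog-io
#' @export
read_catalog <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  x <- dplyr::arrange(x, .data$mz)
  attr(x, "adduct_priority") <- adduct_table()$adduct
  class(x) <- c("mz_catalog", class(x))
  x
}

#' Read a run configuration YAML
#'
#' Validates threshold ranges and that referenced files exist.
#'
#' @param path YAML file with optional fields `templates`, `abundance`,
#'   `metadata`, `tol_ppm`, `alpha_norm`, `adjust`, `fc_thresh`,
#'   `p_thresh`, `log_transform`, `seed`.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(tol_ppm = 5, alpha_norm = 0.05, adjust = "BH",
                   fc_thresh = 1.5, p_thresh = 0.05,
                   log_transform = FALSE, seed = 1L)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  stopifnot(cfg$tol_ppm > 0, cfg$alpha_norm > 0, cfg$alpha_norm < 1,
            cfg$fc_thresh > 0, cfg$p_thresh > 0, cfg$p_thresh <= 1)
  for (f in intersect(c("templates", "abundance", "metadata"),
                      names(cfg))) {
    if (!file.exists(cfg[[f]])) {
      stop("Configured ", f, " file does not exist: ", cfg[[f]],
           call. = FALSE)
    }
  }
  cfg
}
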