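# Registry schemas, readers/writers, reference code sets, and PDMP cleaning.

# Column dictionaries for the four linked tables plus demographics. Dates are
# ISO-8601; diagnosis/multiple-cause code lists are ";"-separated strings.
registry_schemas <- list(
  fills = list(
    cols = c("patient_id", "prescriber_id", "fill_date", "drug_base",
             "combination_ingredient", "strength_per_unit", "quantity",
             "days_supply", "long_acting"),
    date = "fill_date",
    num  = c("strength_per_unit", "quantity", "days_supply"),
    lgl  = "long_acting"
  ),
  spans = list(
    cols = c("patient_id", "start_date", "end_date", "plan"),
    date = c("start_date", "end_date"), num = character(0), lgl = character(0)
  ),
  claims = list(
    cols = c("patient_id", "service_date", "setting", "diagnosis_codes"),
    date = "service_date", num = character(0), lgl = character(0)
  ),
  deaths = list(
    cols = c("patient_id", "death_date", "underlying_cause",
             "multiple_causes", "literal_text"),
    date = "death_date", num = character(0), lgl = character(0)
  ),
  demographics = list(
    cols = c("patient_id", "age_years", "gender", "race_ethnicity",
             "urbanization"),
    date = character(0), num = "age_years", lgl = character(0)
  )
)

#' Default morphine-milligram-equivalent conversion table
#'
#' Per-ingredient MME-per-mg factors following the CDC conversion reference
#' (hydrocodone 1.0, oxycodone 1.5, codeine 0.15, tramadol 0.1, morphine 1.0,
#' hydromorphone 4.0). The `other` row is a unit placeholder for ingredients
#' outside the enumerated set. Shipped as an editable CSV under
#' `inst/extdata/mme_conversion.csv`.
#'
#' @param path Optional path to an alternative two-column CSV
#'   (`drug_base`, `mme_factor`).
#' @return A tibble with columns `drug_base` and `mme_factor`.
#' @export
default_mme_table <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "mme_conversion.csv", package = "opioidcohort")
  tab <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("drug_base", "mme_factor") %in% names(tab)),
            all(tab$mme_factor > 0))
  tab
}

#' Default opioid-overdose code set
#'
#' Underlying-cause codes (X40-X44, X60-X64, X85, Y10-Y14), opioid T-code
#' prefixes (T40.0-T40.4, T40.6) for multiple causes of death and for
#' non-fatal ED/inpatient diagnoses, and a lowercase literal-text term list
#' for death-certificate free text. Shipped as editable YAML.
#'
#' @param path Optional path to an alternative YAML code-set file.
#' @return A list with elements `name`, `underlying_cause_codes`, `t_codes`,
#'   `nonfatal_dx_prefixes`, `literal_terms` (codes normalized).
#' @export
default_code_set <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "overdose_codes.yaml", package = "opioidcohort")
  cs <- yaml::read_yaml(path)
  needed <- c("underlying_cause_codes", "t_codes", "nonfatal_dx_prefixes",
              "literal_terms")
  missing <- setdiff(needed, names(cs))
  if (length(missing) > 0) {
    stop("code set is missing: ", paste(missing, collapse = ", "))
  }
  for (f in c("underlying_cause_codes", "t_codes", "nonfatal_dx_prefixes")) {
    cs[[f]] <- normalize_icd(cs[[f]])
  }
  cs$literal_terms <- tolower(cs$literal_terms)
  cs
}

#' Published cohort margins used as generator defaults
#'
#' Per-drug-group counts for every covariate level, taken from a statewide
#' linked-registry study of opioid-naive adults first prescribed short-acting
#' hydrocodone or oxycodone (2015-2017). These margins parameterize the
#' synthetic generator's covariate distributions and the worked examples.
#'
#' @return A tibble with columns `covariate`, `level`, `hydrocodone_n`,
#'   `oxycodone_n`.
#' @export
reference_margins <- function() {
  readr::read_csv(
    system.file("extdata", "reference_margins.csv", package = "opioidcohort"),
    show_col_types = FALSE)
}

parse_table <- function(path, table) {
  schema <- registry_schemas[[table]]
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(schema$cols, names(raw))
  if (length(missing) > 0) {
    stop("missing required column '", missing[1], "' in ", table, " file: ",
         path, call. = FALSE)
  }
  raw <- raw[schema$cols]
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  out <- raw
  for (col in schema$date) {
    parsed <- as.Date(raw[[col]], format = "%Y-%m-%d")
    bad <- is.na(parsed) & !is.na(raw[[col]])
    reason[is.na(reason) & bad] <- paste0("unparseable ", col)
    out[[col]] <- parsed
  }
  for (col in schema$num) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(parsed) & !is.na(raw[[col]])
    reason[is.na(reason) & bad] <- paste0("non-numeric ", col)
    out[[col]] <- parsed
  }
  for (col in schema$lgl) {
    parsed <- as.logical(raw[[col]])
    bad <- is.na(parsed) & !is.na(raw[[col]])
    reason[is.na(reason) & bad] <- paste0("non-logical ", col)
    out[[col]] <- parsed
  }
  bad_id <- is.na(out$patient_id) | out$patient_id == ""
  reason[is.na(reason) & bad_id] <- "missing patient_id"
  rejects <- tibble::tibble(table = table, row = which(!is.na(reason)),
                            reason = reason[!is.na(reason)])
  list(data = tibble::as_tibble(out[is.na(reason), , drop = FALSE]),
       rejects = rejects)
}

#' Read the linked registry tables
#'
#' Reads the four linked CSV tables (prescription fills, enrollment spans,
#' encounter claims, death records) plus patient demographics, validating
#' each against its column dictionary. Rows that fail type validation
#' (unparseable dates, non-numeric quantities, missing patient ids) are
#' collected in a reject log rather than silently dropped.
#'
#' @param paths Named list or character vector with elements `fills`,
#'   `spans`, `claims`, `deaths`, `demographics` giving file paths.
#' @return A list with typed tibbles `fills`, `spans`, `claims`, `deaths`,
#'   `demographics`, and a `rejects` tibble (`table`, `row`, `reason`).
#' @export
read_registry <- function(paths) {
  needed <- names(registry_schemas)
  missing <- setdiff(needed, names(paths))
  if (length(missing) > 0) {
    stop("paths must name files for: ", paste(missing, collapse = ", "))
  }
  parsed <- lapply(needed, function(tb) {
    if (!file.exists(paths[[tb]])) stop("file not found: ", paths[[tb]])
    parse_table(paths[[tb]], tb)
  })
  names(parsed) <- needed
  out <- lapply(parsed, `[[`, "data")
  out$rejects <- dplyr::bind_rows(lapply(parsed, `[[`, "rejects"))
  out
}

#' Write registry tables to a directory
#'
#' @param tables Named list of tibbles (as from [read_registry()] or
#'   [generate_population()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_registry <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  keep <- intersect(names(registry_schemas), names(tables))
  paths <- vapply(keep, function(tb) {
    p <- file.path(dir, paste0(tb, ".csv"))
    readr::write_csv(tables[[tb]], p, progress = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Clean prescription-monitoring fills
#'
#' Applies the standard PDMP cleaning rules: removes exact duplicate rows,
#' fills missing a prescriber id, implausible quantities (fewer than 4
#' tablets, or at/above a high-percentile cutoff computed once over the full
#' input), and days' supply below 0 or above 90. The quantity cutoff is
#' frozen from the first pass so that cleaning is idempotent; pass
#' `quantity_cap` to reuse a previously computed cutoff.
#'
#' @param fills Tibble of prescription fills.
#' @param quantity_cap_percentile Percentile (fraction) used for the upper
#'   quantity cutoff; default 0.99, computed over all input fills.
#' @param quantity_cap Optional explicit cutoff overriding the percentile.
#' @return A list with `fills` (kept rows), `removed` (dropped rows with a
#'   `reason` column), `removal_log` (counts per reason), and `quantity_cap`
#'   (the cutoff used).
#' @export
clean_fills <- function(fills, quantity_cap_percentile = 0.99,
                        quantity_cap = NULL) {
  reasons <- c("duplicate", "missing_prescriber", "quantity", "days_supply")
  if (nrow(fills) == 0) {
    return(list(fills = fills, removed = dplyr::mutate(fills, reason = character(0)),
                removal_log = tibble::tibble(reason = character(0), n = integer(0)),
                quantity_cap = quantity_cap %||% NA_real_))
  }
  cap <- quantity_cap %||%
    as.numeric(quantile(fills$quantity, quantity_cap_percentile,
                        na.rm = TRUE, names = FALSE))
  key_cols <- c("patient_id", "prescriber_id", "fill_date", "drug_base",
                "combination_ingredient", "strength_per_unit", "quantity",
                "days_supply")
  reason <- rep(NA_character_, nrow(fills))
  dup <- duplicated(fills[intersect(key_cols, names(fills))])
  reason[dup] <- "duplicate"
  no_rx <- is.na(fills$prescriber_id) | fills$prescriber_id == ""
  reason[is.na(reason) & no_rx] <- "missing_prescriber"
  bad_qty <- is.na(fills$quantity) | fills$quantity < 4 | fills$quantity >= cap
  reason[is.na(reason) & bad_qty] <- "quantity"
  bad_ds <- is.na(fills$days_supply) | fills$days_supply < 0 |
    fills$days_supply > 90
  reason[is.na(reason) & bad_ds] <- "days_supply"
  removed <- fills[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  log <- dplyr::count(removed, .data$reason, name = "n")
  list(fills = fills[is.na(reason), , drop = FALSE],
       removed = removed,
       removal_log = log,
       quantity_cap = cap)
}
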