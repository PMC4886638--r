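#' Well-level plate table schema
#'
#' Maps the canonical fluorplex column names onto the column names used in a
#' delimited plate export. The canonical long format has one row per well and
#' analyte: `patient_id`, `tissue`, `condition`, `plate`, `analyte`,
#' `well_role` (one of `"sample"`, `"standard"`, `"blank"`), `standard_level`
#' (integer 1-8, standards only), `fluorescence` (median fluorescence
#' intensity, strictly positive), `concentration` (pg/ml, may be missing) and
#' `censor_status` (one of `"in_range"`, `"extrapolated"`, `"oor_low"`,
#' `"oor_high"`, `"unset"`).
#'
#' @param ... Named overrides, e.g. `fluorescence = "MFI"` if the file calls
#'   the signal column `MFI`.
#' @return Named character vector mapping canonical names to file columns.
#' @export
#' @examples
#' plate_schema(fluorescence = "MFI", patient_id = "subject")
plate_schema <- function(...) {
  schema <- c(
    patient_id = "patient_id", tissue = "tissue", condition = "condition",
    plate = "plate", analyte = "analyte", well_role = "well_role",
    standard_level = "standard_level", fluorescence = "fluorescence",
    concentration = "concentration", censor_status = "censor_status"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(schema))
    if (length(bad)) {
      stop("unknown schema field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    schema[names(dots)] <- dots
  }
  schema
}

.censor_levels <- c("in_range", "extrapolated", "oor_low", "oor_high", "unset")
.role_levels <- c("sample", "standard", "blank")

#' Validate a well-level plate table
#'
#' Checks the structural invariants of the long plate format: all required
#' columns present, `fluorescence` present and strictly positive on every row,
#' `well_role` and `censor_status` drawn from their allowed vocabularies,
#' `standard_level` present exactly on standard wells, and `concentration`
#' absent exactly where `censor_status` marks the row as out of range or unset.
#'
#' @param ds A data frame in the canonical plate format (see [plate_schema()]).
#' @return `ds` as a tibble, invisibly unchanged, if valid. Otherwise an error
#'   listing offending row numbers.
#' @export
validate_plate_data <- function(ds) {
  required <- names(plate_schema())
  missing_cols <- setdiff(required, names(ds))
  if (length(missing_cols)) {
    stop("plate table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ds <- tibble::as_tibble(ds)
  if (nrow(ds) == 0L) {
    return(ds)
  }
  problems <- character()
  bad_fl <- which(!is.finite(ds$fluorescence) | ds$fluorescence <= 0)
  if (length(bad_fl)) {
    problems <- c(problems, paste0(
      "non-positive or missing fluorescence in row(s): ",
      paste(utils::head(bad_fl, 10L), collapse = ", "),
      if (length(bad_fl) > 10L) sprintf(" (and %d more)", length(bad_fl) - 10L) else ""
    ))
  }
  bad_role <- which(!ds$well_role %in% .role_levels)
  if (length(bad_role)) {
    problems <- c(problems, paste0(
      "invalid well_role in row(s): ", paste(utils::head(bad_role, 10L), collapse = ", ")
    ))
  }
  bad_cs <- which(!ds$censor_status %in% .censor_levels)
  if (length(bad_cs)) {
    problems <- c(problems, paste0(
      "invalid censor_status in row(s): ", paste(utils::head(bad_cs, 10L), collapse = ", ")
    ))
  }
  is_std <- ds$well_role == "standard"
  bad_std <- which(is_std & is.na(ds$standard_level) |
                     !is_std & !is.na(ds$standard_level))
  if (length(bad_std)) {
    problems <- c(problems, paste0(
      "standard_level must be present exactly on standard wells; row(s): ",
      paste(utils::head(bad_std, 10L), collapse = ", ")
    ))
  }
  conc_absent <- is.na(ds$concentration)
  should_be_absent <- ds$censor_status %in% c("oor_low", "oor_high", "unset")
  bad_conc <- which(conc_absent != should_be_absent)
  if (length(bad_conc)) {
    problems <- c(problems, paste0(
      "concentration must be missing exactly where censor_status is ",
      "oor_low/oor_high/unset; row(s): ",
      paste(utils::head(bad_conc, 10L), collapse = ", ")
    ))
  }
  if (length(problems)) {
    stop("invalid plate table:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(ds)
}

#' Read a long-format plate table
#'
#' Reads a delimited well-level export (CSV with header, UTF-8, empty fields
#' for missing numbers), renames columns according to `schema`, fills optional
#' columns that the file omits (`standard_level`, `concentration`,
#' `censor_status`) and validates the result.
#'
#' @param path Path to a delimited text file.
#' @param schema Column-name map from [plate_schema()].
#' @return A validated tibble of well records.
#' @export
read_plate_table <- function(path, schema = plate_schema()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  optional <- c("standard_level", "concentration", "censor_status")
  missing_cols <- setdiff(schema[!names(schema) %in% optional], names(raw))
  if (length(missing_cols)) {
    stop("file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  present <- schema[schema %in% names(raw)]
  ds <- dplyr::rename(raw, !!!setNames(as.list(unname(present)), names(present)))
  if (!"standard_level" %in% names(ds)) ds$standard_level <- NA_integer_
  if (!"concentration" %in% names(ds)) ds$concentration <- NA_real_
  if (!"censor_status" %in% names(ds)) ds$censor_status <- "unset"
  ds$censor_status[is.na(ds$censor_status)] <- "unset"
  ds <- dplyr::mutate(
    ds,
    dplyr::across(c("patient_id", "tissue", "condition", "plate", "analyte",
                    "well_role", "censor_status"), as.character),
    standard_level = as.integer(.data$standard_level),
    fluorescence = as.numeric(.data$fluorescence),
    concentration = as.numeric(.data$concentration)
  )
  ds <- ds[names(plate_schema())]
  if (nrow(ds) == 0L) {
    warning("plate table at ", path, " has zero data rows", call. = FALSE)
    return(tibble::as_tibble(ds))
  }
  validate_plate_data(ds)
  tibble::as_tibble(ds)
}

#' Write a plate table to CSV
#'
#' Inverse of [read_plate_table()]: missing numeric values become empty fields
#' so that a write/read round trip reproduces the table.
#'
#' @param ds Plate table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(ds, path) {
  readr::write_csv(tibble::as_tibble(ds)[names(plate_schema())], path, na = "")
  invisible(path)
}

#' Summarise the experimental design of a plate dataset
#'
#' Computes, over sample wells only, the patient-reading count per
#' (analyte, tissue, condition) design cell, the number of distinct nonempty
#' Plate:Condition:Tissue groups (the grouping behind the plate-group random
#' intercept of the differential model), and the sets of patients observed in
#' more than one tissue (paired samples).
#'
#' @param ds Plate table.
#' @param aggregate Average duplicate wells into one observation per
#'   sample x analyte before counting (default `TRUE`, matching the modelling
#'   pipeline).
#' @return An object of class `design_summary`: a list with `cell_counts`
#'   (tibble analyte/tissue/condition/n), `plate_group_count` (integer) and
#'   `paired_patients` (tibble patient_id/n_tissues/tissues).
#' @export
design_summary <- function(ds, aggregate = TRUE) {
  ds <- tibble::as_tibble(ds)
  samples <- dplyr::filter(ds, .data$well_role == "sample")
  if (nrow(samples) == 0L) stop("no sample wells in dataset", call. = FALSE)
  if (aggregate) samples <- aggregate_duplicates(samples)
  cell_counts <- dplyr::count(
    samples, .data$analyte, .data$tissue, .data$condition, name = "n"
  )
  plate_groups <- dplyr::distinct(samples, .data$plate, .data$condition, .data$tissue)
  paired <- samples |>
    dplyr::distinct(.data$patient_id, .data$tissue) |>
    dplyr::summarise(
      n_tissues = dplyr::n(),
      tissues = paste(sort(.data$tissue), collapse = "+"),
      .by = "patient_id"
    ) |>
    dplyr::filter(.data$n_tissues > 1L)
  structure(
    list(
      cell_counts = cell_counts,
      plate_group_count = nrow(plate_groups),
      paired_patients = paired,
      n_patients = dplyr::n_distinct(samples$patient_id),
      n_samples = nrow(dplyr::distinct(
        samples, .data$patient_id, .data$tissue, .data$condition, .data$plate
      )),
      n_analytes = dplyr::n_distinct(samples$analyte)
    ),
    class = "design_summary"
  )
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Plate design summary\n")
  cat("  analytes:            ", x$n_analytes, "\n")
  cat("  patients:            ", x$n_patients, "\n")
  cat("  samples:             ", x$n_samples, "\n")
  cat("  plate:condition:tissue groups:", x$plate_group_count, "\n")
  cat("  paired patients:     ", nrow(x$paired_patients), "\n")
  invisible(x)
}

#' Average duplicate wells
#'
#' Collapses replicate sample wells to one observation per
#' patient x tissue x condition x plate x analyte by the arithmetic mean of the
#' fluorescence (and of any available concentrations). `censor_status` is reset
#' to `"unset"` where rows disagreed; re-derive it with [map_dataset()].
#'
#' @param ds Plate table (only sample wells are aggregated; standards and
#'   blanks pass through untouched).
#' @return Plate table with one row per sample entity and analyte.
#' @export
aggregate_duplicates <- function(ds) {
  ds <- tibble::as_tibble(ds)
  samples <- dplyr::filter(ds, .data$well_role == "sample")
  others <- dplyr::filter(ds, .data$well_role != "sample")
  agg <- samples |>
    dplyr::summarise(
      fluorescence = mean(.data$fluorescence),
      concentration = if (all(is.na(.data$concentration))) NA_real_ else
        mean(.data$concentration, na.rm = TRUE),
      censor_status = if (dplyr::n_distinct(.data$censor_status) == 1L)
        .data$censor_status[1L] else "unset",
      standard_level = NA_integer_,
      .by = c("patient_id", "tissue", "condition", "plate", "analyte", "well_role")
    )
  dplyr::bind_rows(agg[names(plate_schema())], others[names(plate_schema())])
}

#' Drop analytes with under-filled design cells
#'
#' The global mixed model needs at least `min_per_cell` non-missing responses
#' in every (analyte, tissue, condition) design cell to avoid a rank-deficient
#' fixed-effect design. On complete fluorescence data nothing is dropped; on
#' concentration data, analytes whose low-abundance wells were censored out of
#' range can lose whole cells and are removed from the concentration analysis
#' only.
#'
#' @param ds Plate table.
#' @param response `"fluorescence"` or `"concentration"`: which response's
#'   missingness defines an empty cell.
#' @param min_per_cell Minimum non-missing responses required per design cell.
#' @return A list with `kept` (character vector of analytes), `dropped`
#'   (character vector) and `offending_cells` (tibble of under-filled cells
#'   with their counts).
#' @export
filter_estimable_analytes <- function(ds,
                                      response = c("fluorescence", "concentration"),
                                      min_per_cell = 1L) {
  response <- match.arg(response)
  ds <- tibble::as_tibble(ds)
  samples <- dplyr::filter(ds, .data$well_role == "sample")
  analytes <- sort(unique(samples$analyte))
  if (min_per_cell <= 0L) {
    return(list(kept = analytes, dropped = character(),
                offending_cells = tibble::tibble(
                  analyte = character(), tissue = character(),
                  condition = character(), n = integer())))
  }
  design_pairs <- dplyr::distinct(samples, .data$tissue, .data$condition)
  grid <- tidyr::crossing(analyte = analytes, design_pairs)
  counts <- samples |>
    dplyr::summarise(
      n = sum(!is.na(.data[[response]])),
      .by = c("analyte", "tissue", "condition")
    )
  cells <- grid |>
    dplyr::left_join(counts, by = c("analyte", "tissue", "condition")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  offending <- dplyr::filter(cells, .data$n < min_per_cell)
  dropped <- sort(unique(offending$analyte))
  list(
    kept = setdiff(analytes, dropped),
    dropped = dropped,
    offending_cells = offending
  )
}

#' Samples per plate under a well budget
#'
#' How many samples fit on one plate when each sample uses `replicates` wells
#' and the standard curve (if run on that plate) consumes
#' `n_standards + n_blanks` well groups. Running duplicate wells on a 96-well
#' plate yields 39 samples alongside an 8-point standard curve plus blank, and
#' 47 samples when the analysis is fluorescence-only and needs no curve.
#'
#' @param wells Wells on the plate (divisible by `replicates`).
#' @param replicates Wells per sample (and per standard/blank group).
#' @param include_standard_curve Reserve wells for the standard series?
#' @param n_standards Number of standard dilution levels.
#' @param n_blanks Number of blank groups.
#' @return Integer sample capacity.
#' @export
#' @examples
#' plate_capacity(96, 2, include_standard_curve = TRUE)   # 39
#' plate_capacity(96, 2, include_standard_curve = FALSE)  # 47
plate_capacity <- function(wells = 96L, replicates = 2L,
                           include_standard_curve = TRUE,
                           n_standards = 8L, n_blanks = 1L) {
  if (wells %% replicates != 0L) {
    stop("wells (", wells, ") must be divisible by replicates (", replicates, ")",
         call. = FALSE)
  }
  capacity <- wells %/% replicates - n_blanks -
    if (include_standard_curve) n_standards else 0L
  if (capacity < 0L) {
    stop("standard curve and blanks exceed the plate's well budget", call. = FALSE)
  }
  as.integer(capacity)
}
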