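#' Default column layout of the tabular exchange format
#'
#' The exchange "workbook" has three logical sections -- study metadata,
#' observation-variable definitions, and long-format data rows -- stored
#' either as three CSV/TSV files in a directory (`study.csv`,
#' `variables.csv`, `data.csv`; the writable dialect) or as three sheets of
#' an `.xlsx` file (readable when the readxl package is installed).  Column
#' headers are not hard-coded: this layout object maps logical field names to
#' the headers actually present, so files using different header spellings
#' can be read by passing an adapted layout.
#'
#' @return A nested list with elements `study`, `variables`, `data`, each a
#'   named character vector `logical_name = column_header`.
#' @export
default_layout <- function() {
  list(
    study = c(genebank = "genebank", campaign_year = "campaign_year",
              location_name = "location_name", latitude = "latitude",
              longitude = "longitude", seasonal_type = "seasonal_type",
              start_date = "start_date", end_date = "end_date"),
    variables = c(trait_code = "trait_code", trait_label = "trait_label",
                  unit = "unit", plausible_min = "plausible_min",
                  plausible_max = "plausible_max", method_note = "method_note"),
    data = c(institute_code = "institute_code", genus = "genus",
             accession_number = "accession_number",
             campaign_year = "campaign_year", location_name = "location_name",
             seasonal_type = "seasonal_type", trait_code = "trait_code",
             value = "value")
  )
}

.miappe_error <- function(msg) {
  stop(structure(class = c("miappe_format_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# read one logical section from a workbook path
.read_section <- function(path, section) {
  if (dir.exists(path)) {
    for (ext in c("csv", "tsv")) {
      f <- file.path(path, paste0(section, ".", ext))
      if (file.exists(f)) {
        sep <- if (ext == "csv") "," else "\t"
        return(utils::read.table(f, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE,
                                 colClasses = "character",
                                 check.names = FALSE, quote = "\"",
                                 fileEncoding = "UTF-8"))
      }
    }
    .miappe_error(sprintf("mandatory sheet '%s' not found in workbook '%s'",
                          section, path))
  }
  if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!file.exists(path))
      .miappe_error(sprintf("workbook '%s' does not exist", path))
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx workbooks requires the readxl package", call. = FALSE)
    sheets <- readxl::excel_sheets(path)
    hit <- sheets[tolower(sheets) == tolower(section)]
    if (!length(hit))
      .miappe_error(sprintf("mandatory sheet '%s' not found in workbook '%s'",
                            section, path))
    df <- readxl::read_excel(path, sheet = hit[1], col_types = "text")
    return(as.data.frame(df, stringsAsFactors = FALSE))
  }
  .miappe_error(sprintf("workbook '%s' does not exist (expected a directory of CSV/TSV files or an .xlsx file)",
                        path))
}

.pick_columns <- function(df, map, section, required) {
  out <- list()
  for (logical in names(map)) {
    header <- map[[logical]]
    if (!header %in% names(df)) {
      if (logical %in% required)
        .miappe_error(sprintf("sheet '%s' is missing mandatory column '%s'",
                              section, header))
      out[[logical]] <- rep(NA_character_, nrow(df))
    } else out[[logical]] <- as.character(df[[header]])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a phenotyping exchange workbook
#'
#' Reads the three sections described in [default_layout()] and assembles a
#' long-format [phenotype_dataset()].  Value cells that are empty or the
#' literal token `"NA"` denote absent measurements and are dropped silently;
#' any other non-numeric token is logged as a skip (attribute `"skipped"` on
#' the result, plus a message) and the row is excluded -- records are never
#' invented, so the output never has more records than input data rows.
#' Conflicting study metadata for the same campaign (two different seasonal
#' types or coordinate sets for one genebank x year x location) raises an
#' identity-conflict error.
#'
#' @param path Workbook directory (CSV/TSV triplet) or `.xlsx` file.
#' @param layout Column layout, see [default_layout()].
#' @return A [phenotype_dataset()] with attribute `"skipped"` (data frame of
#'   skipped rows and reasons, possibly empty).
#' @export
read_workbook <- function(path, layout = default_layout()) {
  study_raw <- .read_section(path, "study")
  vars_raw <- .read_section(path, "variables")
  data_raw <- .read_section(path, "data")

  study <- .pick_columns(study_raw, layout$study, "study",
                         required = c("genebank", "campaign_year"))
  study$campaign_year <- as.integer(.num_or_na(study$campaign_year))
  study$latitude <- .num_or_na(study$latitude)
  study$longitude <- .num_or_na(study$longitude)

  dup_key <- paste(study$genebank, study$campaign_year, study$location_name)
  if (anyDuplicated(dup_key)) {
    for (k in unique(dup_key[duplicated(dup_key)])) {
      rows <- study[dup_key == k, c("seasonal_type", "latitude", "longitude")]
      if (nrow(unique(rows)) > 1L)
        stop(structure(class = c("miappe_identity_error", "error", "condition"),
                       list(message = sprintf(
                         "conflicting study metadata for campaign '%s'", k),
                         call = NULL)))
    }
    study <- study[!duplicated(dup_key), , drop = FALSE]
  }

  vars <- .pick_columns(vars_raw, layout$variables, "variables",
                        required = c("trait_code", "unit"))
  traits <- data.frame(trait_code = vars$trait_code,
                       trait_label = ifelse(is.na(vars$trait_label),
                                            vars$trait_code, vars$trait_label),
                       unit = vars$unit,
                       plausible_min = .num_or_na(vars$plausible_min),
                       plausible_max = .num_or_na(vars$plausible_max),
                       method_note = ifelse(is.na(vars$method_note), "",
                                            vars$method_note),
                       stringsAsFactors = FALSE)

  d <- .pick_columns(data_raw, layout$data, "data",
                     required = c("institute_code", "genus",
                                  "accession_number", "campaign_year",
                                  "trait_code", "value"))
  skipped <- data.frame(row = integer(0), reason = character(0))
  raw_value <- trimws(d$value)
  absent <- is.na(raw_value) | raw_value == "" | raw_value == "NA"
  value <- .num_or_na(raw_value)
  bad <- !absent & is.na(value)
  if (any(bad)) {
    skipped <- rbind(skipped, data.frame(row = which(bad),
                                         reason = "NON_NUMERIC_VALUE"))
    message(sum(bad), " data row(s) skipped: non-numeric value")
  }
  bad_year <- is.na(.num_or_na(d$campaign_year))
  if (any(bad_year & !absent & !bad)) {
    skipped <- rbind(skipped, data.frame(row = which(bad_year & !absent & !bad),
                                         reason = "BAD_YEAR"))
    message(sum(bad_year & !absent & !bad), " data row(s) skipped: unparseable year")
  }
  keep <- !absent & !bad & !bad_year
  records <- data.frame(
    institute_code = d$institute_code[keep],
    genus = d$genus[keep],
    accession_number = d$accession_number[keep],
    campaign_year = as.integer(.num_or_na(d$campaign_year[keep])),
    location_name = d$location_name[keep],
    seasonal_type = ifelse(is.na(d$seasonal_type[keep]), "unclassified",
                           d$seasonal_type[keep]),
    trait_code = d$trait_code[keep],
    value = value[keep],
    stringsAsFactors = FALSE
  )
  # replicate index distinguishes duplicate (accession, year, trait) keys
  full_key <- paste(records$institute_code, records$genus,
                    records$accession_number, records$campaign_year,
                    records$trait_code, sep = "|")
  records$replicate <- stats::ave(seq_along(full_key), full_key,
                                  FUN = seq_along)

  ds <- phenotype_dataset(records, traits = traits, studies = study,
                          provenance = paste0("read_workbook:", path))
  attr(ds, "skipped") <- skipped
  ds
}

#' Validate a phenotype dataset
#'
#' Pure reporting operation enumerating structural issues: empty identifier
#' triplet fields, out-of-range coordinates or campaign years, trait codes
#' missing from the catalogue, duplicate record keys without distinct
#' replicate indices, and non-finite values.  The dataset is not modified;
#' calling twice yields identical reports.
#'
#' @param ds A [phenotype_dataset()].
#' @return A `validation_report` data frame with columns `code`, `context`,
#'   `message`; zero rows when the dataset is fully valid.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "phenotype_dataset"))
  r <- ds$records
  issues <- list()
  add <- function(code, rows, msg) {
    if (length(rows))
      issues[[length(issues) + 1L]] <<- data.frame(
        code = code, context = paste0("record ", rows), message = msg,
        stringsAsFactors = FALSE)
  }
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  add("MISSING_INSTITUTE", which(blank(r$institute_code)),
      "institute code is empty")
  add("MISSING_GENUS", which(blank(r$genus)), "genus is empty")
  add("MISSING_ACCESSION", which(blank(r$accession_number)),
      "accession number is empty")
  add("YEAR_RANGE",
      which(!is.na(r$campaign_year) &
              (r$campaign_year < 1900 |
                 r$campaign_year > as.integer(format(Sys.Date(), "%Y")))),
      "campaign year outside [1900, current year]")
  add("UNKNOWN_TRAIT", which(!r$trait_code %in% ds$traits$trait_code),
      "trait code not in the catalogue")
  add("NONFINITE_VALUE", which(!is.finite(r$value)), "value is not finite")
  key <- paste(accession_key(ds), r$campaign_year, r$trait_code, r$replicate,
               sep = "|")
  add("DUPLICATE_KEY", which(duplicated(key)),
      "duplicate (accession, year, trait, replicate) key")
  if (!is.null(ds$studies)) {
    s <- ds$studies
    bad_lat <- which(!is.na(s$latitude) & abs(s$latitude) > 90)
    bad_lon <- which(!is.na(s$longitude) & abs(s$longitude) > 180)
    if (length(bad_lat))
      issues[[length(issues) + 1L]] <- data.frame(
        code = "COORD_RANGE", context = paste0("study ", bad_lat),
        message = "latitude outside [-90, 90]", stringsAsFactors = FALSE)
    if (length(bad_lon))
      issues[[length(issues) + 1L]] <- data.frame(
        code = "COORD_RANGE", context = paste0("study ", bad_lon),
        message = "longitude outside [-180, 180]", stringsAsFactors = FALSE)
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(code = character(0), context = character(0),
               message = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}

# full-precision numeric formatting for CSV round-trips
.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write a curated workbook
#'
#' Writes the outlier-corrected records, the trait catalogue, the study
#' metadata, the per-accession BLUE table and the curation report to a
#' workbook directory (`data.csv`, `variables.csv`, `study.csv`, `blues.csv`,
#' `report.json`).  Numeric cells are written with 17 significant digits so
#' that reading the workbook back reproduces the values bit-for-bit; column
#' order is fixed.
#'
#' @param ds Curated [phenotype_dataset()].
#' @param blues BLUE table from [predict_blues()] (may be `NULL` or empty;
#'   an empty `blues.csv` with headers is still written).
#' @param report A `curation_report` (or `NULL`).
#' @param path Output directory; created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_curated <- function(ds, blues, report, path) {
  stopifnot(inherits(ds, "phenotype_dataset"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", path),
                call. = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(path, name)
    utils::write.table(df, f, sep = ",", row.names = FALSE, qmethod = "double",
                       fileEncoding = "UTF-8")
    files <<- c(files, f)
  }
  rec <- ds$records[, c("institute_code", "genus", "accession_number",
                        "campaign_year", "location_name", "seasonal_type",
                        "trait_code", "value"), drop = FALSE]
  rec$value <- .fmt_num(rec$value)
  wr(rec, "data.csv")
  tr <- ds$traits
  tr$plausible_min <- .fmt_num(tr$plausible_min)
  tr$plausible_max <- .fmt_num(tr$plausible_max)
  wr(tr, "variables.csv")
  st <- ds$studies
  if (is.null(st))
    st <- data.frame(genebank = character(0), campaign_year = integer(0),
                     location_name = character(0), latitude = numeric(0),
                     longitude = numeric(0), seasonal_type = character(0),
                     start_date = character(0), end_date = character(0))
  wr(st, "study.csv")
  if (is.null(blues))
    blues <- data.frame(institute_code = character(0), genus = character(0),
                        accession_number = character(0), blue = numeric(0),
                        se = numeric(0))
  b <- blues
  b$blue <- .fmt_num(b$blue)
  b$se <- .fmt_num(b$se)
  wr(b, "blues.csv")
  if (!is.null(report)) {
    f <- file.path(path, "report.json")
    rep_out <- report
    rep_out$logs <- lapply(rep_out$logs, function(l)
      l[c("rule", "records_in", "records_out", "records_removed")])
    jsonlite::write_json(unclass(rep_out), f, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE, force = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read back a written BLUE table
#'
#' @param path Workbook directory written by [write_curated()].
#' @return Data frame with columns `institute_code`, `genus`,
#'   `accession_number`, `blue`, `se`.
#' @export
read_blues <- function(path) {
  f <- file.path(path, "blues.csv")
  if (!file.exists(f)) .miappe_error(sprintf("no blues.csv in '%s'", path))
  b <- utils::read.table(f, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  b$blue <- .num_or_na(b$blue)
  b$se <- .num_or_na(b$se)
  b
}
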