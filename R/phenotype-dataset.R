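#' Phenotype dataset container
#'
#' A `phenotype_dataset` holds long-format regeneration phenotype records for
#' one genebank collection, together with the trait catalogue and the study
#' (campaign) metadata.  Each record is one measurement of one trait on one
#' accession in one campaign year.  Accessions are identified by the standard
#' triplet FAO-WIEWS institute code + genus + accession number.
#'
#' @param records Data frame with columns `institute_code`, `genus`,
#'   `accession_number`, `campaign_year`, `trait_code`, `value`; optional
#'   columns `location_name`, `seasonal_type`, `replicate`.
#' @param traits Trait catalogue data frame as returned by [core_traits()]
#'   (columns `trait_code`, `trait_label`, `unit`, `plausible_min`,
#'   `plausible_max`, `method_note`).
#' @param studies Optional study-metadata data frame with columns `genebank`,
#'   `campaign_year`, `location_name`, `latitude`, `longitude`,
#'   `seasonal_type`, `start_date`, `end_date`.
#' @param provenance Free-text source tag.
#' @return A `phenotype_dataset` object.
#' @examples
#' rec <- data.frame(institute_code = "XXX001", genus = "Triticum",
#'                   accession_number = c("A1", "A1", "A2"),
#'                   campaign_year = c(2001L, 2002L, 2001L),
#'                   trait_code = "PH", value = c(90, 95, 110))
#' ds <- phenotype_dataset(rec)
#' n_records(ds)
#' @export
phenotype_dataset <- function(records, traits = core_traits(), studies = NULL,
                              provenance = "") {
  required <- c("institute_code", "genus", "accession_number",
                "campaign_year", "trait_code", "value")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("records is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$campaign_year <- as.integer(records$campaign_year)
  records$value <- as.numeric(records$value)
  if (is.null(records$location_name)) records$location_name <- NA_character_
  if (is.null(records$seasonal_type)) records$seasonal_type <- "unclassified"
  if (is.null(records$replicate)) records$replicate <- 1L
  canon <- c(required[1:4], "location_name", "seasonal_type",
             "trait_code", "value", "replicate")
  canon <- unique(c(canon, names(records)))
  records <- records[, canon, drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(records = records, traits = traits, studies = studies,
         provenance = provenance),
    class = "phenotype_dataset"
  )
}

#' @export
print.phenotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<phenotype_dataset: %d records, %d accessions, %d campaign years, %d trait(s)>\n",
    n_records(x), n_accessions(x), length(unique(x$records$campaign_year)),
    length(unique(x$records$trait_code))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Accession identity key
#'
#' Collapses the FAO-WIEWS institute code, genus and accession number into a
#' single key string; equality of accessions is defined on this triplet.
#'
#' @param x A `phenotype_dataset` or a records data frame.
#' @return Character vector of keys, one per record.
#' @export
accession_key <- function(x) {
  r <- if (inherits(x, "phenotype_dataset")) x$records else x
  paste(r$institute_code, r$genus, r$accession_number, sep = "|")
}

#' @rdname phenotype_dataset
#' @param ds A `phenotype_dataset`.
#' @export
n_records <- function(ds) nrow(ds$records)

#' @rdname phenotype_dataset
#' @export
n_accessions <- function(ds) length(unique(accession_key(ds)))

#' Incidence queries
#'
#' `years_per_accession()` returns, for every accession, the number of
#' distinct campaign years with at least one record; `points_per_year()`
#' returns the number of records per campaign year.  These drive the
#' connectivity filter and the mean replication term of the heritability
#' formula.
#'
#' @param ds A `phenotype_dataset`.
#' @return A named integer vector.
#' @export
years_per_accession <- function(ds) {
  key <- accession_key(ds)
  if (!length(key)) return(integer(0))
  tab <- tapply(ds$records$campaign_year, key,
                function(y) length(unique(y)))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @rdname years_per_accession
#' @export
points_per_year <- function(ds) {
  if (!n_records(ds)) return(integer(0))
  tab <- table(ds$records$campaign_year)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# internal: keep a logical subset of records, preserving metadata
subset_records <- function(ds, keep) {
  out <- ds
  out$records <- ds$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}
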