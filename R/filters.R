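#' Filter log
#'
#' Every filtering stage returns a `filter_log` alongside the filtered
#' dataset.  The log reconciles exactly with the dataset sizes
#' (`records_in - records_removed == records_out`) and records a per-record
#' removal reason, so that retention percentages in the summary tables can be
#' reproduced from the logs alone.
#'
#' @param rule Name of the filtering rule.
#' @param records_in,records_out Record counts before/after.
#' @param accessions_removed,years_removed Entities that lost all records.
#' @param removed Data frame of removed records with a `reason` column.
#' @return A `filter_log` object.
#' @keywords internal
new_filter_log <- function(rule, records_in, records_out,
                           accessions_removed, years_removed, removed) {
  structure(
    list(rule = rule,
         records_in = records_in,
         records_out = records_out,
         records_removed = records_in - records_out,
         accessions_removed = accessions_removed,
         years_removed = years_removed,
         removed = removed),
    class = "filter_log"
  )
}

#' @export
print.filter_log <- function(x, ...) {
  cat(sprintf("<filter_log %s: %d -> %d records (-%d); -%d accessions, -%d years>\n",
              x$rule, x$records_in, x$records_out, x$records_removed,
              length(x$accessions_removed), length(x$years_removed)))
  invisible(x)
}

# internal: build a log comparing a dataset before/after a logical keep mask
.log_from_mask <- function(ds, keep, rule, reason) {
  before_acc <- unique(accession_key(ds))
  before_yrs <- unique(ds$records$campaign_year)
  out <- subset_records(ds, keep)
  removed <- ds$records[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!keep] else removed$reason <- character(0)
  rownames(removed) <- NULL
  log <- new_filter_log(
    rule, n_records(ds), n_records(out),
    accessions_removed = setdiff(before_acc, unique(accession_key(out))),
    years_removed = setdiff(before_yrs, unique(out$records$campaign_year)),
    removed = removed
  )
  list(dataset = out, log = log)
}

#' Plausibility (range) trimming
#'
#' Removes records whose value falls outside the trait's plausibility window
#' (bounds inclusive): 5--250 cm for plant height, 50--250 days for heading
#' date, 5--100 g for thousand kernel weight in the core presets.  These are
#' deliberately lax screens against recording errors, applied before any
#' model-based curation.
#'
#' @param ds A [phenotype_dataset()].
#' @param trait A [trait_definition()] or trait code resolved against the
#'   dataset catalogue; defaults to the single trait present in `ds`.
#' @return List with elements `dataset` (filtered) and `log`
#'   (a `filter_log`; removal reason `OUT_OF_RANGE`).
#' @examples
#' sim <- simulate_dataset(simulation_params(20, 6, seed = 1))
#' apply_range_filter(sim$dataset)$log
#' @export
apply_range_filter <- function(ds, trait = NULL) {
  stopifnot(inherits(ds, "phenotype_dataset"))
  if (is.null(trait)) {
    codes <- unique(ds$records$trait_code)
    if (length(codes) != 1L)
      stop("dataset holds several traits; pass `trait` explicitly", call. = FALSE)
    trait <- codes
  }
  trait <- .resolve_trait(ds, trait)
  v <- ds$records$value
  relevant <- ds$records$trait_code == trait$code
  keep <- !relevant | (is.finite(v) & v >= trait$plausible_min &
                         v <= trait$plausible_max)
  .log_from_mask(ds, keep, rule = "range",
                 reason = rep("OUT_OF_RANGE", length(keep)))
}

#' Connectivity filtering of accessions and campaigns
#'
#' Removes all records of accessions tested in fewer than
#' `min_years_per_accession` distinct years, and all campaigns represented by
#' fewer than `min_points_per_year` records, iterating the two rules until a
#' fixed point: removing a sparse campaign can strand an accession in a single
#' year and vice versa, and the fixed point is the only order-independent
#' result.  The stricter `strict_plus_one` switch raises both thresholds by
#' one, a setting used occasionally to raise the average connectivity of a
#' poorly connected collection.
#'
#' An empty output is a legal result (some collections retain no analysable
#' data); it is flagged via `attr(result$dataset, "empty_after_filter")`.
#'
#' @param ds A [phenotype_dataset()].
#' @param min_years_per_accession Minimum distinct test years per accession
#'   (default 2: single-year accessions are excluded).
#' @param min_points_per_year Minimum records per campaign (default 2:
#'   single-point campaigns are excluded).
#' @param strict_plus_one If `TRUE`, both thresholds are increased by one.
#' @return List with elements `dataset` and `log` (removal reasons
#'   `LOW_CONNECTIVITY_ACCESSION` / `LOW_CONNECTIVITY_YEAR`).
#' @export
apply_connectivity_filter <- function(ds, min_years_per_accession = 2L,
                                      min_points_per_year = 2L,
                                      strict_plus_one = FALSE) {
  stopifnot(inherits(ds, "phenotype_dataset"),
            min_years_per_accession >= 1, min_points_per_year >= 1)
  ky <- min_years_per_accession + as.integer(strict_plus_one)
  kp <- min_points_per_year + as.integer(strict_plus_one)

  rec <- ds$records
  keep <- rep(TRUE, nrow(rec))
  reason <- rep(NA_character_, nrow(rec))
  key <- accession_key(ds)
  repeat {
    changed <- FALSE
    idx <- which(keep)
    if (!length(idx)) break
    ny <- tapply(rec$campaign_year[idx], key[idx],
                 function(y) length(unique(y)))
    bad_acc <- names(ny)[ny < ky]
    if (length(bad_acc)) {
      hit <- keep & key %in% bad_acc
      reason[hit] <- "LOW_CONNECTIVITY_ACCESSION"
      keep[hit] <- FALSE
      changed <- TRUE
    }
    idx <- which(keep)
    if (length(idx)) {
      np <- table(rec$campaign_year[idx])
      bad_yr <- as.integer(names(np)[np < kp])
      if (length(bad_yr)) {
        hit <- keep & rec$campaign_year %in% bad_yr
        reason[hit] <- "LOW_CONNECTIVITY_YEAR"
        keep[hit] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  res <- .log_from_mask(ds, keep, rule = "connectivity", reason = reason)
  if (n_records(res$dataset) == 0L)
    attr(res$dataset, "empty_after_filter") <- TRUE
  res
}
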