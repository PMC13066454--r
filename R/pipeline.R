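#' Pipeline configuration
#'
#' Bundles every tunable of the per-collection, per-trait curation analysis.
#' Defaults reproduce the standard settings: plausibility bounds from the
#' trait definition, single-year accessions and single-point campaigns
#' excluded, standardized-CV threshold 3.5 for campaign removal, Holm
#' familywise level 0.05 for point removal, and the unweighted mean of the
#' year-specific residual variances as the error variance entering the
#' heritability formula.
#'
#' @param trait Trait code or [trait_definition()].
#' @param label Dataset label used in reports and summary tables.
#' @param min_years_per_accession,min_points_per_year,strict_plus_one
#'   Connectivity thresholds, see [apply_connectivity_filter()].
#' @param cv_threshold Standardized-CV cutoff for campaign removal.
#' @param alpha Holm familywise level for point removal.
#' @param sigma2_e_summary How to collapse the year-specific residual
#'   variances into the single error variance of the heritability formula:
#'   `"mean"` (unweighted, default), `"weighted"` (by records per year) or
#'   `"median"`.
#' @param outlier_stages Set `FALSE` to skip the campaign- and point-level
#'   outlier stages (used for sensitivity comparisons).
#' @param compute_blues Set `FALSE` to skip the final BLUE table.
#' @param seed Seed for any stochastic diagnostics (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(trait = "PH", label = "dataset",
                            min_years_per_accession = 2L,
                            min_points_per_year = 2L,
                            strict_plus_one = FALSE,
                            cv_threshold = 3.5, alpha = 0.05,
                            sigma2_e_summary = c("mean", "weighted", "median"),
                            outlier_stages = TRUE,
                            compute_blues = TRUE,
                            seed = NULL) {
  sigma2_e_summary <- match.arg(sigma2_e_summary)
  stopifnot(cv_threshold > 0, alpha > 0, alpha < 1)
  structure(
    list(trait = trait, label = label,
         min_years_per_accession = as.integer(min_years_per_accession),
         min_points_per_year = as.integer(min_points_per_year),
         strict_plus_one = isTRUE(strict_plus_one),
         cv_threshold = cv_threshold, alpha = alpha,
         sigma2_e_summary = sigma2_e_summary,
         outlier_stages = isTRUE(outlier_stages),
         compute_blues = isTRUE(compute_blues),
         seed = seed),
    class = "pipeline_config"
  )
}

#' Mean number of test years per accession
#'
#' The replication term \eqn{\bar N_Y} of the entry-mean heritability
#' formula: the arithmetic mean, over accessions, of the number of distinct
#' campaign years with data.  Computed on the post-curation dataset.
#'
#' @param ds A non-empty [phenotype_dataset()].
#' @return A scalar \eqn{\ge 1}.
#' @export
mean_years_per_accession <- function(ds) {
  stopifnot(inherits(ds, "phenotype_dataset"))
  if (!n_records(ds)) stop("dataset is empty", call. = FALSE)
  mean(years_per_accession(ds))
}

#' Entry-mean heritability
#'
#' \deqn{h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_e / \bar N_Y}}
#' where \eqn{\sigma^2_G} is the accession variance, \eqn{\sigma^2_e} the
#' error variance and \eqn{\bar N_Y} the mean number of test years per
#' accession.  Under heterogeneous errors \eqn{\sigma^2_e} is a summary of
#' the year-specific variances (unweighted mean by default).
#'
#' @param components Variance components from a random-genotype [fit_reml()]
#'   (list with `sigma2_G` and `sigma2_e_by_year`), or a list with `sigma2_G`
#'   and a scalar `sigma2_e`.
#' @param n_bar Mean years per accession, \eqn{\ge 1}.
#' @param summary Collapse rule for the year-specific variances: `"mean"`,
#'   `"weighted"` or `"median"`; for `"weighted"` supply `weights`.
#' @param weights Optional per-year record counts (named like
#'   `sigma2_e_by_year`) for the weighted summary.
#' @return Heritability in `[0, 1]`; 0 with a warning when all variances are
#'   zero.
#' @examples
#' heritability(list(sigma2_G = 4, sigma2_e = 1), n_bar = 2)  # 0.8889
#' @export
heritability <- function(components, n_bar,
                         summary = c("mean", "weighted", "median"),
                         weights = NULL) {
  summary <- match.arg(summary)
  stopifnot(is.numeric(n_bar), length(n_bar) == 1L, n_bar >= 1)
  s2G <- components[["sigma2_G"]]
  if (is.null(s2G)) stop("components$sigma2_G required (random-genotype fit)",
                         call. = FALSE)
  s2e <- if (!is.null(components[["sigma2_e"]])) components[["sigma2_e"]] else {
    v <- components[["sigma2_e_by_year"]]
    if (is.null(v)) stop("components must carry sigma2_e or sigma2_e_by_year",
                         call. = FALSE)
    switch(summary,
           mean = mean(v),
           median = stats::median(v),
           weighted = {
             if (is.null(weights)) stop("weights required for weighted summary",
                                        call. = FALSE)
             stats::weighted.mean(v, w = weights[names(v)])
           })
  }
  if (s2G <= 0 && s2e <= 0) {
    warning("all variance components are zero; heritability defined as 0")
    return(0)
  }
  h2 <- s2G / (s2G + s2e / n_bar)
  min(max(h2, 0), 1)
}

# internal: curation report skeleton
.curation_report <- function(label, raw_points, raw_accessions) {
  structure(
    list(label = label, status = "ok",
         raw_points = raw_points, raw_accessions = raw_accessions,
         kept_points = NA_integer_, kept_accessions = NA_integer_,
         points_kept_pct = NA_real_, accessions_kept_pct = NA_real_,
         heritability = NA_real_, n_bar_years = NA_real_,
         components = NULL, converged = NA, logs = list()),
    class = "curation_report"
  )
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report %s: %s>\n", x$label, x$status))
  cat(sprintf("  raw: %d points / %d accessions\n", x$raw_points,
              x$raw_accessions))
  if (x$status == "no_data") {
    cat("  no data points remained after filtering and outlier correction\n")
  } else {
    cat(sprintf("  kept: %d points (%.1f%%) / %d accessions (%.1f%%)\n",
                x$kept_points, x$points_kept_pct,
                x$kept_accessions, x$accessions_kept_pct))
    cat(sprintf("  heritability: %.3f  (N_bar_Y = %.2f)\n",
                x$heritability, x$n_bar_years))
  }
  invisible(x)
}

#' Run the full curation and validation pipeline on one dataset slice
#'
#' Executes, in order, on a single genebank x seasonal-type x trait slice:
#' plausibility trimming, connectivity filtering, campaign-level outlier
#' removal by standardized CV (with a connectivity re-check, since removing a
#' campaign can strand accessions in a single year), a fixed-genotype refit
#' with Holm-based point flagging and removal (again followed by a
#' connectivity re-check), a final random-genotype fit for variance
#' components, entry-mean heritability, and BLUEs from a fixed-genotype fit
#' of the curated data.  Every removal is logged and the report reconciles
#' exactly with the dataset sizes.  If any stage empties the dataset the
#' report is returned in the explicit `"no_data"` state; model
#' non-convergence is flagged in the report but does not abort.
#'
#' @param ds A [phenotype_dataset()] holding a single trait slice.
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `curated` (dataset), `blues` (data
#'   frame), `report` (`curation_report`), `flags`, `campaign_scores`.
#' @examples
#' sim <- simulate_dataset(simulation_params(80, 6, seed = 7))
#' res <- run_pipeline(sim$dataset, pipeline_config("PH", label = "demo"))
#' res$report
#' @export
run_pipeline <- function(ds, config = pipeline_config()) {
  stopifnot(inherits(ds, "phenotype_dataset"),
            inherits(config, "pipeline_config"))
  report <- .curation_report(config$label, n_records(ds), n_accessions(ds))
  logs <- list()
  empty_result <- function(report) {
    report$status <- "no_data"
    report$kept_points <- 0L
    report$kept_accessions <- 0L
    report$points_kept_pct <- 0
    report$accessions_kept_pct <- 0
    report$logs <- logs
    list(curated = NULL, blues = NULL, report = report,
         flags = NULL, campaign_scores = NULL) |>
      structure(class = "pipeline_result")
  }

  # 1. plausibility trimming
  st <- apply_range_filter(ds, config$trait)
  logs$range <- st$log
  cur <- st$dataset

  # 2. connectivity filter
  st <- apply_connectivity_filter(cur, config$min_years_per_accession,
                                  config$min_points_per_year,
                                  config$strict_plus_one)
  logs$connectivity <- st$log
  cur <- st$dataset
  if (!n_records(cur)) return(empty_result(report))

  scores <- NULL
  flags <- NULL
  fit_fixed <- NULL
  if (config$outlier_stages) {
    # steps I-IV: campaign-level removal by standardized CV
    scores <- tryCatch(campaign_cv_scores(cur), error = function(e) e)
    if (inherits(scores, "error")) {
      report$status <- "fit_failed"
      report$logs <- logs
      return(structure(list(curated = cur, blues = NULL, report = report,
                            flags = NULL, campaign_scores = NULL),
                       class = "pipeline_result"))
    }
    st <- drop_outlier_campaigns(cur, scores, config$cv_threshold)
    logs$campaign_cv <- st$log
    cur <- st$dataset
    if (!n_records(cur)) return(empty_result(report))
    if (st$log$records_removed > 0) {
      st <- apply_connectivity_filter(cur, config$min_years_per_accession,
                                      config$min_points_per_year,
                                      config$strict_plus_one)
      logs$connectivity_after_campaign <- st$log
      cur <- st$dataset
      if (!n_records(cur)) return(empty_result(report))
    }

    # steps V-VII: fixed-genotype refit, Holm flagging, point removal
    fit_fixed <- tryCatch(
      fit_reml(cur, model_spec("fixed", "random")), error = function(e) e)
    if (inherits(fit_fixed, "error")) {
      report$status <- "fit_failed"
      report$logs <- logs
      return(structure(list(curated = cur, blues = NULL, report = report,
                            flags = NULL, campaign_scores = scores),
                       class = "pipeline_result"))
    }
    flags <- flag_outlier_points(fit_fixed, config$alpha)
    if (any(flags$flagged)) {
      keep <- !flags$flagged
      res <- .log_from_mask(cur, keep, rule = "point_outliers",
                            reason = rep("POINT_OUTLIER", length(keep)))
      logs$point_outliers <- res$log
      cur <- res$dataset
      fit_fixed <- NULL  # curated data changed; refit for BLUEs below
      if (!n_records(cur)) return(empty_result(report))
      st <- apply_connectivity_filter(cur, config$min_years_per_accession,
                                      config$min_points_per_year,
                                      config$strict_plus_one)
      logs$connectivity_after_points <- st$log
      cur <- st$dataset
      if (!n_records(cur)) return(empty_result(report))
    }
  }

  # final random-genotype fit: variance components and heritability
  fit_random <- tryCatch(
    fit_reml(cur, model_spec("random", "random")), error = function(e) e)
  if (inherits(fit_random, "error")) {
    report$status <- "fit_failed"
    report$logs <- logs
    return(structure(list(curated = cur, blues = NULL, report = report,
                          flags = flags, campaign_scores = scores),
                     class = "pipeline_result"))
  }
  n_bar <- mean_years_per_accession(cur)
  wts <- points_per_year(cur)
  h2 <- heritability(fit_random$components, n_bar,
                     summary = config$sigma2_e_summary, weights = wts)

  blues <- NULL
  if (config$compute_blues) {
    if (is.null(fit_fixed))
      fit_fixed <- tryCatch(fit_reml(cur, model_spec("fixed", "random")),
                            error = function(e) NULL)
    if (!is.null(fit_fixed) && !inherits(fit_fixed, "error"))
      blues <- predict_blues(fit_fixed)
  }

  report$kept_points <- n_records(cur)
  report$kept_accessions <- n_accessions(cur)
  report$points_kept_pct <- 100 * report$kept_points / report$raw_points
  report$accessions_kept_pct <- 100 * report$kept_accessions / report$raw_accessions
  report$heritability <- h2
  report$n_bar_years <- n_bar
  report$components <- fit_random$components
  report$converged <- fit_random$converged &&
    (is.null(fit_fixed) || fit_fixed$converged)
  report$logs <- logs

  structure(list(curated = cur, blues = blues, report = report,
                 flags = flags, campaign_scores = scores),
            class = "pipeline_result")
}

#' Summary table over several curation reports
#'
#' One row per dataset slice with the raw counts, retention percentages
#' (one decimal), heritability and mean years per accession, sorted by label.
#' Slices in the `"no_data"` state appear with `NA` retention and
#' heritability, mirroring how collections without surviving data are
#' reported.
#'
#' @param reports List of `curation_report` objects (or `pipeline_result`s).
#' @return A data frame.
#' @export
summarize_collections <- function(reports) {
  cols <- c("dataset", "data_points", "accessions", "points_kept_pct",
            "accessions_kept_pct", "heritability", "n_bar_years", "status")
  if (!length(reports)) {
    out <- as.data.frame(stats::setNames(
      list(character(0), integer(0), integer(0), numeric(0), numeric(0),
           numeric(0), numeric(0), character(0)), cols))
    return(out)
  }
  rows <- lapply(reports, function(r) {
    if (inherits(r, "pipeline_result")) r <- r$report
    no_data <- !identical(r$status, "ok")
    data.frame(
      dataset = r$label,
      data_points = r$raw_points,
      accessions = r$raw_accessions,
      points_kept_pct = if (no_data) NA_real_ else round(r$points_kept_pct, 1),
      accessions_kept_pct = if (no_data) NA_real_ else round(r$accessions_kept_pct, 1),
      heritability = if (no_data) NA_real_ else round(100 * r$heritability, 1),
      n_bar_years = if (no_data) NA_real_ else round(r$n_bar_years, 2),
      status = r$status,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dataset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
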