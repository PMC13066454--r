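#' Parameters for the regeneration-data simulator
#'
#' The simulator emulates the structure of historical genebank regeneration
#' records: a strongly right-skewed number of test years per accession (most
#' accessions are regenerated in only one or two campaigns), additive
#' accession and year effects, year-specific residual noise, and optional
#' injected contamination (shifted single points and variance-inflated
#' campaigns).  The generating model is
#' \deqn{y_{ij} = \mu + g_i + a_j + e_{ij}}
#' with \eqn{g_i \sim N(0, \sigma^2_G)}, \eqn{a_j \sim N(0, \sigma^2_A)} and
#' \eqn{e_{ij} \sim N(0, \sigma^2_{e,j})}.
#'
#' @param n_accessions Number of accessions.
#' @param n_years Number of campaign years (>= 2).
#' @param replication_profile Probability vector over the number of distinct
#'   test years per accession; entry k is the probability of exactly k years.
#'   The default is right-skewed over 1--5 years.  A profile longer than
#'   `n_years` is truncated and renormalized with a warning.
#' @param trait Trait code (`"HD"`, `"PH"`, `"TKW"`) or a
#'   [trait_definition()]; sets the scale presets for `mu` and the variance
#'   defaults.
#' @param mu Collection mean on the trait scale; defaults to the trait preset.
#' @param sigma2_G Accession (genetic) variance.
#' @param sigma2_A Year variance.
#' @param sigma_e_by_year Per-year residual standard deviations; recycled to
#'   `n_years`.
#' @param point_outlier_rate Fraction of records turned into point outliers by
#'   [inject_outliers()].
#' @param point_outlier_shift Size of the point-outlier shift, as a multiple
#'   of the local residual SD \eqn{\sigma_{e,j}}; sign is a fair coin.
#' @param n_outlier_campaigns Number of campaigns whose residuals are redrawn
#'   with inflated variance by [inject_outliers()].
#' @param campaign_outlier_inflation Residual-variance multiplier for outlier
#'   campaigns.
#' @param seed Integer seed; every simulator operation is reproducible
#'   given the same parameters.
#' @return A `simulation_params` object.
#' @export
simulation_params <- function(n_accessions,
                              n_years = 20L,
                              replication_profile = c(0.55, 0.25, 0.10, 0.05, 0.05),
                              trait = "PH",
                              mu = NULL,
                              sigma2_G = NULL,
                              sigma2_A = NULL,
                              sigma_e_by_year = NULL,
                              point_outlier_rate = 0,
                              point_outlier_shift = 8,
                              n_outlier_campaigns = 0L,
                              campaign_outlier_inflation = 25,
                              seed = 1L) {
  stopifnot(n_accessions >= 1, n_years >= 2)
  preset <- if (is.character(trait) && trait %in% names(.trait_presets))
    .trait_presets[[trait]] else NULL
  trait_def <- .resolve_trait(list(traits = core_traits()), trait)
  if (is.null(mu)) mu <- if (!is.null(preset)) preset$mu else 100
  if (is.null(sigma2_G)) sigma2_G <- if (!is.null(preset)) preset$sigma2_G else 1
  if (is.null(sigma2_A)) sigma2_A <- if (!is.null(preset)) preset$sigma2_A else 1
  if (is.null(sigma_e_by_year))
    sigma_e_by_year <- if (!is.null(preset)) preset$sigma_e else 1
  sigma_e_by_year <- rep_len(as.numeric(sigma_e_by_year), n_years)
  if (any(replication_profile < 0) || sum(replication_profile) <= 0)
    stop("replication_profile must be non-negative with positive sum",
         call. = FALSE)
  if (abs(sum(replication_profile) - 1) > 1e-8)
    replication_profile <- replication_profile / sum(replication_profile)
  if (length(replication_profile) > n_years) {
    warning("replication_profile longer than n_years: truncating and renormalizing")
    replication_profile <- replication_profile[seq_len(n_years)]
    replication_profile <- replication_profile / sum(replication_profile)
  }
  stopifnot(sigma2_G >= 0, sigma2_A >= 0, all(sigma_e_by_year >= 0),
            point_outlier_rate >= 0, point_outlier_rate <= 1,
            n_outlier_campaigns >= 0, campaign_outlier_inflation >= 0)
  structure(
    list(n_accessions = as.integer(n_accessions),
         n_years = as.integer(n_years),
         replication_profile = replication_profile,
         trait = trait_def, mu = mu, sigma2_G = sigma2_G, sigma2_A = sigma2_A,
         sigma_e_by_year = sigma_e_by_year,
         point_outlier_rate = point_outlier_rate,
         point_outlier_shift = point_outlier_shift,
         n_outlier_campaigns = as.integer(n_outlier_campaigns),
         campaign_outlier_inflation = campaign_outlier_inflation,
         seed = as.integer(seed)),
    class = "simulation_params"
  )
}

# internal: draw the accession x year incidence; assumes RNG state is set
.draw_incidence <- function(params) {
  k <- sample.int(length(params$replication_profile), params$n_accessions,
                  replace = TRUE, prob = params$replication_profile)
  acc <- rep.int(seq_len(params$n_accessions), k)
  yrs <- unlist(lapply(k, function(ki)
    sample.int(params$n_years, ki, replace = FALSE)), use.names = FALSE)
  data.frame(accession = acc, year = yrs)
}

#' Sample the accession-by-year incidence structure
#'
#' Draws, for each accession, a number of distinct test years from the
#' replication profile (the field reality being that most accessions are
#' regenerated in only one or two campaigns), then assigns that many distinct
#' years uniformly at random, one record per accession per year.
#'
#' @param params A [simulation_params()] object.
#' @return Data frame with columns `accession` (integer index) and `year`
#'   (integer index), one row per (accession, year) pair.
#' @export
sample_incidence <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  .draw_incidence(params)
}

#' Simulate a regeneration phenotype dataset with known truth
#'
#' Generates records from the additive two-way model with year-specific
#' residual noise (see [simulation_params()]) and returns both the dataset and
#' a `synthetic_truth` object recording every draw, so that downstream
#' estimators can be validated against ground truth.  Values are not clipped
#' to the trait's plausibility window.
#'
#' @param params A [simulation_params()] object.
#' @return A list with elements `dataset` (a [phenotype_dataset()]) and
#'   `truth` (a `synthetic_truth`: per-accession effects `g`, per-year effects
#'   `a`, residuals `e`, the generating parameters, and empty outlier labels).
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  inc <- .draw_incidence(params)
  g <- stats::rnorm(params$n_accessions, 0, sqrt(params$sigma2_G))
  a <- stats::rnorm(params$n_years, 0, sqrt(params$sigma2_A))
  e <- stats::rnorm(nrow(inc), 0, params$sigma_e_by_year[inc$year])
  y <- params$mu + g[inc$accession] + a[inc$year] + e

  years <- 2000L + inc$year  # calendar labels for the campaign index
  records <- data.frame(
    institute_code = "SYN001",
    genus = "Triticum",
    accession_number = sprintf("ACC%06d", inc$accession),
    campaign_year = years,
    location_name = "Synthetic station",
    seasonal_type = "spring",
    trait_code = params$trait$code,
    value = y,
    replicate = 1L,
    record_id = seq_along(y),  # stable id: survives filtering, keys truth labels
    stringsAsFactors = FALSE
  )
  studies <- data.frame(
    genebank = "Synthetic genebank",
    campaign_year = 2000L + seq_len(params$n_years),
    location_name = "Synthetic station",
    latitude = 52.0, longitude = 10.0,
    seasonal_type = "spring",
    start_date = NA_character_, end_date = NA_character_,
    stringsAsFactors = FALSE
  )
  ds <- phenotype_dataset(records, traits = core_traits(), studies = studies,
                          provenance = "phenocurate simulator")
  truth <- structure(
    list(params = params,
         g = g, a = a, e = e,
         accession_index = inc$accession, year_index = inc$year,
         sigma2_G = params$sigma2_G, sigma2_A = params$sigma2_A,
         sigma2_e_by_year = stats::setNames(params$sigma_e_by_year^2,
                                            2000L + seq_len(params$n_years)),
         point_outliers = integer(0),
         outlier_campaigns = integer(0)),
    class = "synthetic_truth"
  )
  list(dataset = ds, truth = truth)
}

#' Inject point- and campaign-level contamination
#'
#' Point outliers: a random fraction of records is shifted by
#' `point_outlier_shift` local residual standard deviations, with a fair-coin
#' sign.  Campaign outliers: for the chosen campaigns the residuals of all
#' records are redrawn from a normal distribution with variance multiplied by
#' `campaign_outlier_inflation`.  Both kinds are labelled in the truth object.
#'
#' @param ds Dataset from [simulate_dataset()].
#' @param truth Matching `synthetic_truth`.
#' @param params The same [simulation_params()]; its outlier fields control
#'   the injection.
#' @return A list with the contaminated `dataset` and the updated `truth`
#'   (fields `point_outliers`: record row indices; `outlier_campaigns`:
#'   campaign-year labels).
#' @export
inject_outliers <- function(ds, truth, params) {
  stopifnot(inherits(ds, "phenotype_dataset"), inherits(truth, "synthetic_truth"),
            inherits(params, "simulation_params"))
  if (params$n_outlier_campaigns > params$n_years)
    stop("more outlier campaigns requested than campaigns simulated",
         call. = FALSE)
  set.seed(params$seed + 1L)
  n <- n_records(ds)
  rec <- ds$records

  # campaign-level: redraw residuals with inflated variance
  if (params$n_outlier_campaigns > 0) {
    bad_years <- sample.int(params$n_years, params$n_outlier_campaigns)
    for (j in bad_years) {
      idx <- which(truth$year_index == j)
      sd_new <- sqrt(params$campaign_outlier_inflation) *
        params$sigma_e_by_year[j]
      e_new <- stats::rnorm(length(idx), 0, sd_new)
      rec$value[idx] <- rec$value[idx] - truth$e[idx] + e_new
      truth$e[idx] <- e_new
    }
    truth$outlier_campaigns <- sort(2000L + bad_years)
  }

  # point-level: shift individual records by +/- shift x sigma_e,j
  n_pts <- round(params$point_outlier_rate * n)
  if (n_pts > 0) {
    pick <- sample.int(n, n_pts)
    sgn <- sample(c(-1, 1), n_pts, replace = TRUE)
    shift <- sgn * params$point_outlier_shift *
      params$sigma_e_by_year[truth$year_index[pick]]
    rec$value[pick] <- rec$value[pick] + shift
    truth$point_outliers <- sort(pick)
  }

  ds$records <- rec
  list(dataset = ds, truth = truth)
}

#' Ground-truth heritability of a simulated dataset
#'
#' Evaluates the entry-mean heritability formula
#' \eqn{h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_e / \bar N_Y)} at the
#' generating parameters, with \eqn{\sigma^2_e} the unweighted mean of the
#' per-year residual variances and \eqn{\bar N_Y} the realized mean number of
#' test years per accession in `ds` (post-curation if a curated dataset is
#' supplied).
#'
#' @param truth A `synthetic_truth`.
#' @param ds Dataset on which to realize \eqn{\bar N_Y}; typically the curated
#'   dataset whose estimate is being validated.
#' @return Heritability in `[0, 1]`.
#' @export
true_heritability <- function(truth, ds) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_bar <- mean_years_per_accession(ds)
  s2e <- mean(truth$sigma2_e_by_year)
  if (truth$sigma2_G <= 0 && s2e <= 0) return(0)
  truth$sigma2_G / (truth$sigma2_G + s2e / n_bar)
}
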