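#' Heritability recovery experiment on simulated collections
#'
#' Repeatedly simulates a clean non-orthogonal collection, runs the full
#' curation pipeline, and compares the reported entry-mean heritability with
#' the ground-truth value computed from the generating parameters and the
#' realized post-curation mean replication.  The default variance setting
#' (\eqn{\sigma^2_G = 4}, per-year residual variances averaging 1.96,
#' \eqn{\sigma^2_A = 2}) targets a true heritability of 0.85 at the expected
#' post-curation replication of the default profile
#' (\eqn{E[\bar N_Y \mid \ge 2\ \mathrm{years}] \approx 2.78}).
#'
#' @param n_seeds Number of simulation replicates.
#' @param n_accessions,n_years Size of each simulated collection.
#' @param sigma2_G,sigma2_A Generating variances.
#' @param sigma2_e_range Range of the per-year residual variances (spread
#'   linearly across years).
#' @param seed Base seed; replicate s uses `seed * 1000 + s`.
#' @return Data frame with one row per replicate: `seed`, `h2_true`,
#'   `h2_est`, `n_bar`, `kept_points`.
#' @export
heritability_recovery_experiment <- function(n_seeds = 20, n_accessions = 2000,
                                             n_years = 12, sigma2_G = 4,
                                             sigma2_A = 2,
                                             sigma2_e_range = c(1.6, 2.32),
                                             seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    p <- simulation_params(
      n_accessions, n_years,
      sigma2_G = sigma2_G, sigma2_A = sigma2_A,
      sigma_e_by_year = sqrt(seq(sigma2_e_range[1], sigma2_e_range[2],
                                 length.out = n_years)),
      seed = seed * 1000 + s)
    sim <- simulate_dataset(p)
    res <- run_pipeline(sim$dataset,
                        pipeline_config("PH", label = sprintf("sim%03d", s),
                                        compute_blues = FALSE))
    if (!identical(res$report$status, "ok"))
      return(data.frame(seed = p$seed, h2_true = NA_real_, h2_est = NA_real_,
                        n_bar = NA_real_, kept_points = NA_integer_))
    data.frame(seed = p$seed,
               h2_true = true_heritability(sim$truth, res$curated),
               h2_est = res$report$heritability,
               n_bar = res$report$n_bar_years,
               kept_points = res$report$kept_points)
  })
  do.call(rbind, rows)
}

#' Contamination recovery experiment
#'
#' Simulates collections of roughly `n_records_target` records, injects 1%
#' point outliers at `shift` local residual SDs plus one campaign with
#' `inflation`-fold residual variance, then measures how the two outlier
#' stages perform: whether the campaign stage removes the inflated campaign,
#' and the sensitivity and false-flag rate of the Holm point stage (both
#' computed over the records that survive to the point stage).
#'
#' @param n_seeds Number of simulation replicates.
#' @param n_records_target Approximate records per replicate (accession count
#'   is derived from the default replication profile's mean of 1.8
#'   records/accession).
#' @param n_years Campaigns per replicate.
#' @param rate,shift Point-outlier fraction and shift (in local residual SDs).
#' @param inflation Residual-variance multiplier of the outlier campaign.
#' @param cv_threshold,alpha Stage thresholds.
#' @param seed Base seed; replicate s uses `seed * 1000 + s`.
#' @return Data frame with one row per replicate: `seed`, `campaign_hit`
#'   (inflated campaign removed), `extra_campaigns_removed`, `sensitivity`,
#'   `false_per_1000`, `n_truth_present`, `n_clean_present`.
#' @export
outlier_recovery_experiment <- function(n_seeds = 20, n_records_target = 10000,
                                        n_years = 20, rate = 0.01, shift = 8,
                                        inflation = 25, cv_threshold = 3.5,
                                        alpha = 0.05, seed = 1) {
  profile_mean <- sum(seq_len(5) * c(0.55, 0.25, 0.10, 0.05, 0.05))
  n_acc <- round(n_records_target / profile_mean)
  rows <- lapply(seq_len(n_seeds), function(s) {
    p <- simulation_params(
      n_acc, n_years, sigma2_G = 4, sigma2_A = 2,
      sigma_e_by_year = seq(0.8, 1.5, length.out = n_years),
      point_outlier_rate = rate, point_outlier_shift = shift,
      n_outlier_campaigns = 1, campaign_outlier_inflation = inflation,
      seed = seed * 1000 + s)
    sim <- simulate_dataset(p)
    con <- inject_outliers(sim$dataset, sim$truth, p)
    ds <- apply_connectivity_filter(con$dataset)$dataset

    scores <- campaign_cv_scores(ds)
    drop <- drop_outlier_campaigns(ds, scores, cv_threshold)
    removed_years <- drop$log$years_removed
    campaign_hit <- all(con$truth$outlier_campaigns %in% removed_years)
    extra <- length(setdiff(removed_years, con$truth$outlier_campaigns))

    ds2 <- apply_connectivity_filter(drop$dataset)$dataset
    fit <- fit_reml(ds2, model_spec("fixed", "random"))
    flags <- flag_outlier_points(fit, alpha)
    ids <- fit$records$record_id
    truth_present <- ids %in% con$truth$point_outliers
    flagged <- flags$flagged
    sens <- if (any(truth_present))
      sum(flagged & truth_present) / sum(truth_present) else NA_real_
    n_clean <- sum(!truth_present)
    fp1000 <- 1000 * sum(flagged & !truth_present) / n_clean
    data.frame(seed = p$seed, campaign_hit = campaign_hit,
               extra_campaigns_removed = extra, sensitivity = sens,
               false_per_1000 = fp1000,
               n_truth_present = sum(truth_present),
               n_clean_present = n_clean)
  })
  do.call(rbind, rows)
}
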