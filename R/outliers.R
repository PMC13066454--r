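#' Score campaigns by standardized coefficient of variation
#'
#' Fits the two-way model with campaign fixed and accession random (with
#' year-specific error variances), then computes for every campaign
#' \eqn{CV_j = \hat\sigma_{e,j} / |\bar m_j|}, the estimated residual SD over
#' the absolute estimated campaign mean, and standardizes the CVs across
#' campaigns to z-scores.  A noisy campaign (e.g. a failed regeneration
#' season) stands out as a high standardized CV.
#'
#' @param ds A [phenotype_dataset()] that has passed the pre-model filters.
#' @param spec Optional [model_spec()]; defaults to genotype random / year
#'   fixed with heterogeneous errors (any supplied spec must have those roles).
#' @return A `campaign_scores` data frame with columns `campaign_year`,
#'   `campaign_mean`, `sigma2_e`, `cv`, `cv_z`, plus attribute `fit`.
#' @export
campaign_cv_scores <- function(ds, spec = NULL) {
  stopifnot(inherits(ds, "phenotype_dataset"))
  if (is.null(spec)) spec <- model_spec(genotype_role = "random",
                                        year_role = "fixed")
  if (spec$genotype_role != "random" || spec$year_role != "fixed")
    stop("campaign scoring requires genotype random and year fixed", call. = FALSE)
  fit <- fit_reml(ds, spec)
  means <- fit$year_effects  # cell means: mu + a_j
  yrs <- names(means)
  s2 <- fit$components$sigma2_e_by_year[yrs]
  if (any(means == 0))
    stop("campaign mean is zero for campaign(s) ",
         paste(yrs[means == 0], collapse = ", "),
         "; coefficient of variation undefined", call. = FALSE)
  cv <- sqrt(s2) / abs(means)
  z <- if (length(cv) >= 2L && stats::sd(cv) > 0)
    (cv - mean(cv)) / stats::sd(cv) else rep(0, length(cv))
  out <- data.frame(campaign_year = as.integer(yrs),
                    campaign_mean = as.numeric(means),
                    sigma2_e = as.numeric(s2),
                    cv = as.numeric(cv),
                    cv_z = as.numeric(z))
  attr(out, "fit") <- fit
  class(out) <- c("campaign_scores", "data.frame")
  out
}

#' Remove outlier campaigns
#'
#' Drops every record of campaigns whose standardized coefficient of
#' variation exceeds the threshold (default 3.5).  Removal is one-sided: only
#' unusually dispersed campaigns are an error signal, campaigns with low
#' dispersion are kept.  Whole campaigns are removed, never partial ones.
#'
#' @param ds A [phenotype_dataset()].
#' @param scores Output of [campaign_cv_scores()]; must cover every campaign
#'   in `ds`.
#' @param threshold Standardized-CV cutoff (default 3.5).
#' @return List with elements `dataset` and `log` (removal reason
#'   `CAMPAIGN_CV`).
#' @export
drop_outlier_campaigns <- function(ds, scores, threshold = 3.5) {
  stopifnot(inherits(ds, "phenotype_dataset"),
            inherits(scores, "campaign_scores"))
  yrs <- unique(ds$records$campaign_year)
  if (!all(yrs %in% scores$campaign_year))
    stop("scores do not cover campaign(s): ",
         paste(setdiff(yrs, scores$campaign_year), collapse = ", "),
         call. = FALSE)
  bad <- scores$campaign_year[scores$cv_z > threshold]
  keep <- !(ds$records$campaign_year %in% bad)
  .log_from_mask(ds, keep, rule = "campaign_cv",
                 reason = rep("CAMPAIGN_CV", length(keep)))
}

#' Bonferroni-Holm step-down adjustment
#'
#' Step-down adjustment controlling the familywise error rate: p-values are
#' sorted ascending, the k-th smallest is multiplied by (m - k + 1), a
#' cumulative maximum enforces monotonicity, results are capped at 1 and
#' returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order; elementwise no smaller
#'   than the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- pmin(1, cummax((m - seq_len(m) + 1L) * pvalues[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Flag outlier data points from standardized residuals
#'
#' Applies step VI of the curation procedure to a fixed-genotype fit:
#' two-sided p-values from the standard normal are computed for every
#' standardized residual \eqn{e_{ij} / \hat\sigma_{e,j}}, Holm-adjusted, and
#' records with adjusted p strictly below `alpha` are flagged.  Flagged
#' records are removed by the caller (step VII).
#'
#' @param fit A `model_fit` with `genotype_role = "fixed"`.
#' @param alpha Familywise error level, strictly inside (0, 1); default 0.05.
#' @return A `point_flags` data frame with one row per fitted record:
#'   `row` (index into `fit$records`), accession triplet columns,
#'   `campaign_year`, `std_resid`, `p_value`, `p_holm`, `flagged`.
#' @export
flag_outlier_points <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "model_fit"))
  if (fit$spec$genotype_role != "fixed")
    stop("point flagging requires a fixed-genotype fit", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  z <- fit$standardized_residuals
  p <- 2 * stats::pnorm(-abs(z))
  p_holm <- holm_adjust(p)
  out <- data.frame(
    row = seq_along(z),
    institute_code = fit$records$institute_code,
    genus = fit$records$genus,
    accession_number = fit$records$accession_number,
    campaign_year = fit$records$campaign_year,
    std_resid = z,
    p_value = p,
    p_holm = p_holm,
    flagged = p_holm < alpha,
    stringsAsFactors = FALSE
  )
  class(out) <- c("point_flags", "data.frame")
  out
}
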