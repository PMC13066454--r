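# Campaign scoring, campaign removal, Holm adjustment, point flagging.

test_that("holm_adjust reproduces the hand-executed definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)          # m = 1 identity
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holm_adjust(c(0.1, -0.01)), "\\[0, 1\\]")
})

test_that("holm_adjust equals independent references and is permutation stable", {
  set.seed(8)
  for (i in 1:200) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    a <- holm_adjust(p)
    expect_equal(a, holm_reference(p), tolerance = 1e-14)
    expect_equal(a, p.adjust(p, method = "holm"), tolerance = 1e-14)
    expect_true(all(a >= p & a <= 1))
    perm <- sample(m)
    expect_equal(holm_adjust(p[perm]), a[perm], tolerance = 1e-14)
  }
})

test_that("two campaigns give a symmetric +/- standardized CV pair", {
  grid <- expand.grid(acc = paste0("A", 1:20), yr = c(2001, 2002))
  set.seed(4)
  ds <- make_dataset(grid$acc, grid$yr,
                     100 + rnorm(40) + 3 * (grid$yr == 2002))
  sc <- campaign_cv_scores(ds)
  expect_equal(sc$cv_z[1], -sc$cv_z[2], tolerance = 1e-10)
  expect_equal(mean(sc$cv_z), 0, tolerance = 1e-10)
  expect_equal(sd(sc$cv_z), 1, tolerance = 1e-10)
})

test_that("an inflated campaign attains the maximum standardized CV and is dropped", {
  p <- simulation_params(900, 20, sigma2_G = 4, sigma2_A = 2,
                         sigma_e_by_year = 1.2, n_outlier_campaigns = 1,
                         campaign_outlier_inflation = 25, seed = 42)
  sim <- simulate_dataset(p)
  con <- inject_outliers(sim$dataset, sim$truth, p)
  ds <- apply_connectivity_filter(con$dataset)$dataset
  sc <- campaign_cv_scores(ds)
  bad <- con$truth$outlier_campaigns
  expect_equal(sc$campaign_year[which.max(sc$cv_z)], bad)
  expect_gt(max(sc$cv_z), 3.5)

  res <- drop_outlier_campaigns(ds, sc, threshold = 3.5)
  expect_false(bad %in% res$dataset$records$campaign_year)
  # whole campaigns only: removal count equals the campaign's record count
  expect_equal(res$log$records_removed,
               sum(ds$records$campaign_year == bad))
  expect_true(all(res$log$removed$reason == "CAMPAIGN_CV"))

  # identity when nothing exceeds the threshold
  sc2 <- campaign_cv_scores(res$dataset)
  res2 <- drop_outlier_campaigns(res$dataset, sc2, threshold = 3.5)
  if (max(sc2$cv_z) <= 3.5) expect_equal(res2$log$records_removed, 0L)

  # scores must cover the dataset
  expect_error(drop_outlier_campaigns(ds, sc[-1, ]), "cover")
})

test_that("null campaigns stay below the removal threshold", {
  # homogeneous campaigns: standardized CVs should never look like outliers
  hits <- sapply(1:12, function(s) {
    sim <- simulate_dataset(simulation_params(
      300, 15, sigma2_G = 4, sigma2_A = 2, sigma_e_by_year = 1.2,
      replication_profile = c(0.3, 0.4, 0.2, 0.1), seed = 500 + s))
    ds <- apply_connectivity_filter(sim$dataset)$dataset
    max(campaign_cv_scores(ds)$cv_z)
  })
  expect_true(all(hits < 3.5))
})

test_that("flag_outlier_points flags a gross outlier and nothing on clean data", {
  # noise-free data: residuals 0, no flags
  g <- seq(-3, 3, length.out = 7)
  grid <- expand.grid(acc = paste0("A", 1:7), yr = 2001:2004)
  ds0 <- make_dataset(grid$acc, grid$yr, 100 + g[as.integer(factor(grid$acc))])
  f0 <- fit_reml(ds0, model_spec("fixed", "random"))
  expect_equal(sum(flag_outlier_points(f0)$flagged), 0L)

  # an 8-SD shift on a well-replicated accession is flagged
  p <- simulation_params(120, 6, sigma2_G = 4, sigma2_A = 2,
                         sigma_e_by_year = 1,
                         replication_profile = c(0, 0, 0, 0.5, 0.3, 0.2),
                         seed = 7)
  sim <- simulate_dataset(p)
  ds <- sim$dataset
  hit <- 10L
  ds$records$value[hit] <- ds$records$value[hit] + 8
  fit <- fit_reml(apply_connectivity_filter(ds)$dataset,
                  model_spec("fixed", "random"))
  fl <- flag_outlier_points(fit)
  hit_key <- paste(ds$records$accession_number[hit], ds$records$campaign_year[hit])
  expect_true(fl$flagged[match(hit_key, paste(fl$accession_number,
                                              fl$campaign_year))])
  expect_lte(sum(fl$flagged), 2L)

  # alpha contract and monotonicity of the flag set
  expect_error(flag_outlier_points(fit, alpha = 1), "alpha")
  expect_error(flag_outlier_points(fit, alpha = 0), "alpha")
  f01 <- flag_outlier_points(fit, alpha = 0.01)
  f10 <- flag_outlier_points(fit, alpha = 0.10)
  expect_true(all(which(f01$flagged) %in% which(f10$flagged)))
  # adjusted p never below raw p
  expect_true(all(fl$p_holm >= fl$p_value - 1e-15))
  # random-genotype fits are refused
  frand <- fit_reml(apply_connectivity_filter(ds)$dataset,
                    model_spec("random", "random"))
  expect_error(flag_outlier_points(frand), "fixed")
})

test_that("familywise error on clean data is controlled at alpha", {
  # null datasets: the probability of flagging anything should not exceed
  # alpha by more than Monte Carlo noise
  n_seeds <- 60
  any_flag <- vapply(seq_len(n_seeds), function(s) {
    sim <- simulate_dataset(simulation_params(
      40, 5, sigma2_G = 4, sigma2_A = 2, sigma_e_by_year = 1,
      replication_profile = c(0.2, 0.5, 0.3), seed = 2000 + s))
    ds <- apply_connectivity_filter(sim$dataset)$dataset
    fit <- fit_reml(ds, model_spec("fixed", "random"))
    any(flag_outlier_points(fit, alpha = 0.05)$flagged)
  }, logical(1))
  expect_lte(mean(any_flag), 0.05 + 0.03 + 2 * sqrt(0.05 * 0.95 / n_seeds))
})
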