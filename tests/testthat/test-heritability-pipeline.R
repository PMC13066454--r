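# Orchestration: heritability, reports, summaries, figures.

test_that("mean_years_per_accession matches the counting oracle", {
  ds <- make_dataset(c("A", "A", "B", "B", "B", "B"),
                     c(2001, 2002, 2001, 2002, 2003, 2004),
                     rnorm(6, 100))
  expect_equal(mean_years_per_accession(ds), 3.0)

  grid <- expand.grid(acc = paste0("A", 1:5), yr = 2001:2003)
  dsk <- make_dataset(grid$acc, grid$yr, rnorm(15, 100))
  expect_equal(mean_years_per_accession(dsk), 3)

  set.seed(31)
  inc <- unique(data.frame(acc = sample(letters[1:8], 30, TRUE),
                           yr = sample(2001:2006, 30, TRUE)))
  dsr <- make_dataset(inc$acc, inc$yr, rnorm(nrow(inc), 100))
  brute <- mean(sapply(split(inc$yr, inc$acc), function(y) length(unique(y))))
  expect_equal(mean_years_per_accession(dsr), brute)

  empty <- make_dataset("A", 2001, 100)
  empty$records <- empty$records[0, , drop = FALSE]
  expect_error(mean_years_per_accession(empty), "empty")
})

test_that("heritability implements the entry-mean formula", {
  expect_equal(heritability(list(sigma2_G = 4, sigma2_e = 1), n_bar = 2),
               4 / 4.5)
  expect_equal(heritability(list(sigma2_G = 0, sigma2_e = 3), n_bar = 2), 0)
  expect_warning(
    h0 <- heritability(list(sigma2_G = 0, sigma2_e = 0), n_bar = 2), "zero")
  expect_equal(h0, 0)
  # strictly increasing in N_bar_Y when both variances positive
  grid <- seq(1, 8, by = 0.5)
  h <- sapply(grid, function(nb)
    heritability(list(sigma2_G = 2, sigma2_e = 3), nb))
  expect_true(all(diff(h) > 0))
  expect_true(all(h >= 0 & h <= 1))
  # year-specific variances are collapsed by the requested summary
  comp <- list(sigma2_G = 4,
               sigma2_e_by_year = c("2001" = 1, "2002" = 3))
  expect_equal(heritability(comp, 2), 4 / (4 + 2 / 2))
  expect_equal(heritability(comp, 2, summary = "median"), 4 / (4 + 2 / 2))
  expect_equal(heritability(comp, 2, summary = "weighted",
                            weights = c("2001" = 3, "2002" = 1)),
               4 / (4 + 1.5 / 2))
})

test_that("run_pipeline reconciles every removal and reports exact percentages", {
  p <- simulation_params(400, 12, sigma2_G = 4, sigma2_A = 2,
                         sigma_e_by_year = 1.2, point_outlier_rate = 0.01,
                         point_outlier_shift = 8, seed = 55)
  sim <- simulate_dataset(p)
  con <- inject_outliers(sim$dataset, sim$truth, p)
  # plant a few implausible raw values as recording errors
  con$dataset$records$value[1:3] <- c(-10, 0, 500)
  res <- run_pipeline(con$dataset, pipeline_config("PH", label = "contaminated"))
  rep <- res$report
  expect_equal(rep$status, "ok")
  removed_total <- sum(vapply(rep$logs, function(l) l$records_removed,
                              numeric(1)))
  expect_equal(rep$raw_points - removed_total, rep$kept_points)
  expect_equal(rep$kept_points, n_records(res$curated))
  expect_equal(rep$points_kept_pct, 100 * rep$kept_points / rep$raw_points)
  expect_equal(rep$accessions_kept_pct,
               100 * rep$kept_accessions / rep$raw_accessions)
  expect_true(rep$heritability >= 0 && rep$heritability <= 1)
  expect_equal(nrow(res$blues), n_accessions(res$curated))
})

test_that("a dataset of single-year accessions yields the explicit no-data state", {
  ds <- make_dataset(paste0("A", 1:30), rep(2001:2003, 10), rnorm(30, 100))
  res <- run_pipeline(ds, pipeline_config("PH", label = "all singletons"))
  expect_equal(res$report$status, "no_data")
  expect_true(is.na(res$report$heritability))
  expect_equal(res$report$kept_points, 0L)
  tab <- summarize_collections(list(res))
  expect_true(is.na(tab$heritability))
  expect_equal(tab$status, "no_data")
})

test_that("pipeline is deterministic and robust to the outlier stage toggle", {
  sim <- simulate_dataset(simulation_params(150, 8, seed = 66))
  cfg <- pipeline_config("PH", label = "demo")
  r1 <- run_pipeline(sim$dataset, cfg)
  r2 <- run_pipeline(sim$dataset, cfg)
  expect_identical(r1$report$heritability, r2$report$heritability)
  expect_identical(r1$blues, r2$blues)
  r3 <- run_pipeline(sim$dataset,
                     pipeline_config("PH", label = "demo",
                                     outlier_stages = FALSE))
  expect_equal(r3$report$status, "ok")
})

test_that("the outlier stage moves contaminated heritability toward the clean value", {
  # replication profile with >= 2 years so the fixed-genotype residuals
  # retain enough of each shift for the detector to see it
  diffs <- sapply(1:5, function(s) {
    p <- simulation_params(400, 10, sigma2_G = 4, sigma2_A = 2,
                           sigma_e_by_year = 1.2, point_outlier_rate = 0.01,
                           point_outlier_shift = 8,
                           replication_profile = c(0, 0.3, 0.3, 0.2, 0.2),
                           seed = 900 + s)
    sim <- simulate_dataset(p)
    con <- inject_outliers(sim$dataset, sim$truth, p)
    h_clean <- run_pipeline(sim$dataset,
                            pipeline_config("PH"))$report$heritability
    h_with <- run_pipeline(con$dataset,
                           pipeline_config("PH"))$report$heritability
    h_without <- run_pipeline(con$dataset,
                              pipeline_config("PH", outlier_stages = FALSE)
                              )$report$heritability
    abs(h_without - h_clean) - abs(h_with - h_clean)
  })
  # the stage should help (or at worst tie) in most replicates and on average
  expect_gte(sum(diffs >= -1e-12), 4)
  expect_gte(mean(diffs), 0)
})

test_that("summarize_collections renders sorted one-decimal rows", {
  expect_equal(nrow(summarize_collections(list())), 0L)
  rep1 <- structure(list(label = "B set", status = "ok", raw_points = 100L,
                         raw_accessions = 40L, kept_points = 80L,
                         kept_accessions = 30L, points_kept_pct = 80,
                         accessions_kept_pct = 75, heritability = 0.856,
                         n_bar_years = 2.5, components = NULL,
                         converged = TRUE, logs = list()),
                    class = "curation_report")
  rep2 <- rep1; rep2$label <- "A set"; rep2$points_kept_pct <- 66.666
  tab <- summarize_collections(list(rep1, rep2))
  expect_equal(tab$dataset, c("A set", "B set"))
  expect_equal(tab$points_kept_pct, c(66.7, 80.0))
  expect_equal(tab$heritability, c(85.6, 85.6))
})

test_that("plot_reports writes the three diagnostic panels", {
  sim <- simulate_dataset(simulation_params(120, 6, seed = 8))
  res <- run_pipeline(sim$dataset, pipeline_config("PH", label = "demo"))
  dir <- withr::local_tempdir()
  files <- plot_reports(list(res), dir)
  expect_length(files, 3L)
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))
  # an empty slice degrades with warnings, not errors
  empty <- run_pipeline(make_dataset(paste0("A", 1:10), rep(2001:2002, 5),
                                     rnorm(10, 100)),
                        pipeline_config("PH", label = "empty"))
  w <- capture_warnings(plot_reports(list(empty), withr::local_tempdir()))
  expect_gte(length(w), 1L)
})
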