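# The REML engine: oracle equivalences, equivariances, degenerate inputs.

test_that("balanced homogeneous REML equals the ANOVA method-of-moments oracle", {
  b <- balanced_dataset(20, 6, seed = 42)
  fit <- fit_reml(b$ds, model_spec("random", "random",
                                   heterogeneous_errors = FALSE))
  mom <- anova_mom(b$y)
  expect_true(fit$converged)
  expect_lt(abs(fit$components$sigma2_G - mom$sigma2_G) / mom$sigma2_G, 1e-6)
  expect_lt(abs(fit$components$sigma2_A - mom$sigma2_A) / mom$sigma2_A, 1e-6)
  expect_lt(abs(fit$components$sigma2_e_by_year[[1]] - mom$sigma2_e) /
              mom$sigma2_e, 1e-6)
})

test_that("homogeneous crossed fit agrees with lme4 on unbalanced data", {
  skip_if_not_installed("lme4")
  sim <- simulate_dataset(simulation_params(80, 6, sigma2_G = 9, sigma2_A = 4,
                                            sigma_e_by_year = 2, seed = 31))
  ds <- apply_connectivity_filter(sim$dataset)$dataset
  fit <- fit_reml(ds, model_spec("random", "random",
                                 heterogeneous_errors = FALSE))
  d <- data.frame(y = ds$records$value, acc = factor(accession_key(ds)),
                  yr = factor(ds$records$campaign_year))
  m <- lme4::lmer(y ~ 1 + (1 | acc) + (1 | yr), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  ref <- setNames(vc$vcov, vc$grp)
  expect_equal(fit$components$sigma2_G, unname(ref["acc"]), tolerance = 1e-4)
  expect_equal(fit$components$sigma2_A, unname(ref["yr"]), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
})

test_that("heterogeneous fixed-genotype fit agrees with nlme::lme + varIdent", {
  skip_if_not_installed("nlme")
  sim <- simulate_dataset(simulation_params(
    60, 5, sigma2_G = 9, sigma2_A = 4,
    sigma_e_by_year = c(1, 1.5, 2, 2.5, 3), seed = 5))
  ds <- apply_connectivity_filter(sim$dataset)$dataset
  fit <- fit_reml(ds, model_spec("fixed", "random"))
  d <- data.frame(y = ds$records$value, acc = factor(accession_key(ds)),
                  yr = factor(ds$records$campaign_year))
  m <- nlme::lme(y ~ 0 + acc, random = ~ 1 | yr,
                 weights = nlme::varIdent(form = ~ 1 | yr), data = d,
                 method = "REML",
                 control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                            msMaxIter = 200))
  s2A_ref <- as.numeric(nlme::VarCorr(m)[1, 1])
  w <- coef(m$modelStruct$varStruct, unconstrained = FALSE, allCoef = TRUE)
  s2e_ref <- (m$sigma * w[levels(d$yr)])^2
  expect_equal(fit$components$sigma2_A, s2A_ref, tolerance = 1e-3)
  expect_equal(unname(fit$components$sigma2_e_by_year[names(s2e_ref)]),
               unname(s2e_ref), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(sort(predict_blues(fit, se = FALSE)$blue),
               sort(unname(nlme::fixef(m))), tolerance = 1e-4)
})

test_that("BLUEs on a small design equal the dense GLS oracle", {
  # 3 accessions x 2 years, hand-chosen values
  ds <- make_dataset(rep(c("A", "B", "C"), each = 2),
                     rep(c(2001, 2002), 3),
                     c(10.2, 11.9, 14.1, 15.8, 8.7, 10.4))
  fit <- fit_reml(ds, model_spec("fixed", "random",
                                 heterogeneous_errors = FALSE))
  s2A <- fit$components$sigma2_A
  s2e <- fit$components$sigma2_e_by_year[[1]]
  acc <- factor(ds$records$accession_number)
  yr <- factor(ds$records$campaign_year)
  X <- model.matrix(~ 0 + acc)
  Zy <- model.matrix(~ 0 + yr)
  V <- s2e * diag(6) + s2A * tcrossprod(Zy)
  beta_gls <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*%
                      ds$records$value)
  blues <- predict_blues(fit)
  expect_equal(blues$blue, as.numeric(beta_gls)[order(levels(acc))],
               tolerance = 1e-6)
  # SEs match the dense covariance too
  se_gls <- sqrt(diag(solve(t(X) %*% solve(V) %*% X)))
  expect_equal(blues$se, unname(se_gls[order(levels(acc))]), tolerance = 1e-6)
})

test_that("BLUEs are translation equivariant and variances scale equivariant", {
  sim <- simulate_dataset(simulation_params(40, 5, seed = 77))
  ds <- apply_connectivity_filter(sim$dataset)$dataset
  f1 <- fit_reml(ds, model_spec("fixed", "random"))
  ds_shift <- ds; ds_shift$records$value <- ds$records$value + 11.5
  f2 <- fit_reml(ds_shift, model_spec("fixed", "random"))
  expect_equal(predict_blues(f2, se = FALSE)$blue,
               predict_blues(f1, se = FALSE)$blue + 11.5, tolerance = 1e-6)

  ds_scale <- ds; ds_scale$records$value <- ds$records$value * 3
  f3 <- fit_reml(ds_scale, model_spec("random", "random"))
  f0 <- fit_reml(ds, model_spec("random", "random"))
  expect_equal(f3$components$sigma2_G, 9 * f0$components$sigma2_G,
               tolerance = 1e-3)
  expect_equal(unname(f3$components$sigma2_e_by_year),
               9 * unname(f0$components$sigma2_e_by_year), tolerance = 1e-3)
})

test_that("noise-free data give zero residuals and boundary error variances", {
  g <- c(A = -2, B = 0, C = 5, D = 1)
  grid <- expand.grid(acc = names(g), yr = 2001:2003)
  ds <- make_dataset(grid$acc, grid$yr, 100 + g[grid$acc])
  fit <- fit_reml(ds, model_spec("fixed", "random"))
  expect_lt(max(abs(fit$residuals)), 1e-6)
  expect_true(length(fit$boundary) > 0)  # boundary reported, not hidden
  blues <- predict_blues(fit, se = FALSE)
  expect_equal(blues$blue - mean(blues$blue), unname(g - mean(g)),
               tolerance = 1e-6)
})

test_that("restricted_loglik matches a dense-matrix evaluation on a toy", {
  ds <- make_dataset(c("A", "A", "B", "B", "C"),
                     c(2001, 2002, 2001, 2002, 2001),
                     c(9.1, 10.5, 12.0, 13.2, 8.4))
  spec <- model_spec("fixed", "random")
  comp <- list(sigma2_A = 1.3,
               sigma2_e_by_year = c("2001" = 0.8, "2002" = 1.7))
  got <- restricted_loglik(ds, spec, comp)
  acc <- factor(ds$records$accession_number)
  yr <- factor(ds$records$campaign_year)
  ref <- dense_reml_loglik(
    y = ds$records$value,
    X = model.matrix(~ 0 + acc),
    Zlist = list(model.matrix(~ 0 + yr)),
    s2list = list(1.3),
    s2_rec = c(0.8, 1.7)[as.integer(yr)])
  expect_equal(got, ref, tolerance = 1e-10)

  # deterministic
  expect_identical(got, restricted_loglik(ds, spec, comp))
  # mismatched year set is an error
  expect_error(restricted_loglik(ds, spec, list(
    sigma2_A = 1, sigma2_e_by_year = c("2001" = 1))), "cover")
})

test_that("the fitted solution is a local maximum of the restricted likelihood", {
  sim <- simulate_dataset(simulation_params(50, 5, seed = 15))
  ds <- apply_connectivity_filter(sim$dataset)$dataset
  spec <- model_spec("random", "random")
  fit <- fit_reml(ds, spec)
  comp <- list(sigma2_G = fit$components$sigma2_G,
               sigma2_A = fit$components$sigma2_A,
               sigma2_e_by_year = fit$components$sigma2_e_by_year)
  ll0 <- restricted_loglik(ds, spec, comp)
  expect_equal(ll0, fit$loglik, tolerance = 1e-8)
  bump <- function(comp, what, year = NULL) {
    if (is.null(year)) comp[[what]] <- comp[[what]] * 1.1
    else comp$sigma2_e_by_year[year] <- comp$sigma2_e_by_year[year] * 1.1
    comp
  }
  expect_lte(restricted_loglik(ds, spec, bump(comp, "sigma2_G")), ll0 + 1e-8)
  expect_lte(restricted_loglik(ds, spec, bump(comp, "sigma2_A")), ll0 + 1e-8)
  for (yy in names(comp$sigma2_e_by_year))
    expect_lte(restricted_loglik(ds, spec, bump(comp, year = yy)), ll0 + 1e-8)
})

test_that("parameter recovery on sparse incidence at moderate scale", {
  # one pipeline-scale check kept cheap: 3 seeds, 600 accessions
  ests <- sapply(1:3, function(s) {
    sim <- simulate_dataset(simulation_params(
      600, 8, sigma2_G = 4, sigma2_A = 2,
      sigma_e_by_year = seq(0.9, 1.4, length.out = 8), seed = 100 + s))
    ds <- apply_connectivity_filter(sim$dataset)$dataset
    fit <- fit_reml(ds, model_spec("random", "random"))
    fit$components$sigma2_G
  })
  expect_lt(abs(mean(ests) - 4) / 4, 0.15)
})

test_that("contract errors: degenerate designs are refused with clear messages", {
  ds1 <- make_dataset(c("A", "B", "C"), c(2001, 2001, 2001), c(1, 2, 3))
  expect_error(fit_reml(ds1), "2 years")
  ds2 <- make_dataset(c("A", "A", "A"), c(2001, 2002, 2003), c(1, 2, 3))
  expect_error(fit_reml(ds2), "2 accessions")
  # a year fed only by single-year accessions is confounded in a fixed fit
  ds3 <- make_dataset(c("A", "A", "C", "C", "B"),
                      c(2001, 2002, 2001, 2002, 2003),
                      c(1, 2, 3, 4, 5))
  expect_error(fit_reml(ds3, model_spec("fixed", "random")), "2003")
  expect_error(predict_blues(fit_reml(
    apply_connectivity_filter(
      simulate_dataset(simulation_params(30, 5, seed = 2))$dataset)$dataset,
    model_spec("random", "random"))), "random")
})
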