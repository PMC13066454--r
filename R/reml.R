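#' Specify the two-way mixed model
#'
#' The curation model is the additive two-way model
#' \eqn{y_{ij} = \mu + g_i + a_j + e_{ij}} for accession \eqn{i} in campaign
#' year \eqn{j}, with the residual modelled with a year-specific variance
#' \eqn{\sigma^2_{e,j}}.  The accession term is used in two roles: random for
#' the calculation of variance components (and hence heritability), fixed for
#' outlier detection and BLUE estimation.  The campaign-scoring stage reverses
#' the roles (campaign fixed, accession random), so both factors accept either
#' role; at least one must be random.
#'
#' @param genotype_role `"random"` or `"fixed"` role of the accession effect.
#' @param year_role `"random"` or `"fixed"` role of the campaign-year effect.
#' @param heterogeneous_errors If `TRUE` (default) one residual variance per
#'   campaign year is estimated; years with fewer than 3 records share a
#'   pooled variance (flagged in the fit).
#' @param tol Relative convergence tolerance on the restricted log-likelihood.
#' @param max_iter Maximum optimizer iterations.
#' @return A `model_spec` object.
#' @export
model_spec <- function(genotype_role = c("random", "fixed"),
                       year_role = c("random", "fixed"),
                       heterogeneous_errors = TRUE,
                       tol = 1e-10, max_iter = 200L) {
  genotype_role <- match.arg(genotype_role)
  year_role <- match.arg(year_role)
  if (genotype_role == "fixed" && year_role == "fixed")
    stop("at least one of genotype and year must be random", call. = FALSE)
  stopifnot(tol > 0, max_iter >= 1)
  structure(
    list(genotype_role = genotype_role, year_role = year_role,
         heterogeneous_errors = isTRUE(heterogeneous_errors),
         tol = tol, max_iter = as.integer(max_iter)),
    class = "model_spec"
  )
}

# ---------------------------------------------------------------------------
# internal problem representation
#
# The restricted log-likelihood is evaluated through the mixed-model
# equations: with W = [X Z], R = diag(sigma2_e per record), G the random-block
# covariance and C = W' R^-1 W + diag(0, G^-1),
#   -2 l_R = (n-p) log(2 pi) + log|R| + log|G| + log|C| + y' P y ,
#   y' P y  = y' R^-1 y - rhs' C^-1 rhs,   rhs = W' R^-1 y .
# C is sparse with a pattern that does not depend on the variance parameters,
# so its Cholesky factor is symbolically analysed once and numerically
# updated per evaluation.
# ---------------------------------------------------------------------------

.reml_problem <- function(ds, spec) {
  rec <- ds$records
  n <- nrow(rec)
  if (n < 3L) stop("too few records to fit the model", call. = FALSE)
  acc <- factor(accession_key(ds))
  yr <- factor(rec$campaign_year)
  if (nlevels(yr) < 2L) stop("model requires records from at least 2 years",
                             call. = FALSE)
  if (nlevels(acc) < 2L) stop("model requires at least 2 accessions",
                              call. = FALSE)

  # identifiability: in a fixed-genotype fit a year whose records all come
  # from accessions confined to that year carries no residual information
  if (spec$genotype_role == "fixed") {
    acc_years <- tapply(rec$campaign_year, acc, function(y) length(unique(y)))
    single <- names(acc_years)[acc_years == 1L]
    if (length(single)) {
      for (j in levels(yr)) {
        in_j <- yr == j
        if (all(as.character(acc[in_j]) %in% single))
          stop(sprintf(
            "year %s is fully confounded with accession effects; apply the connectivity filter first",
            j), call. = FALSE)
      }
    }
  }

  ind <- function(f) Matrix::sparseMatrix(
    i = seq_along(f), j = as.integer(f), x = 1,
    dims = c(length(f), nlevels(f)),
    dimnames = list(NULL, levels(f)))

  Xs <- list(); Zs <- list(); blocks <- list()
  if (spec$genotype_role == "fixed") Xs$accession <- ind(acc)
  else blocks$accession <- ind(acc)
  if (spec$year_role == "fixed") Xs$year <- ind(yr)
  else blocks$year <- ind(yr)
  if (!length(Xs))
    Xs$intercept <- Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                                         dims = c(n, 1L),
                                         dimnames = list(NULL, "(Intercept)"))
  X <- do.call(cbind, Xs)
  Z <- if (length(blocks)) do.call(cbind, blocks) else NULL
  W <- if (is.null(Z)) X else cbind(X, Z)
  p <- ncol(X)
  block_sizes <- vapply(blocks, ncol, integer(1))

  # residual variance groups
  y_int <- as.integer(yr)
  if (spec$heterogeneous_errors) {
    cnt <- tabulate(y_int, nlevels(yr))
    pooled_years <- levels(yr)[cnt < 3L]
    grp_lab <- levels(yr)
    grp_lab[cnt < 3L] <- ".pooled"
    grp <- factor(grp_lab[y_int], levels = unique(grp_lab))
  } else {
    pooled_years <- character(0)
    grp <- factor(rep(".all", n))
  }
  grp_idx <- as.integer(grp)

  # centring y is exact (every X variant absorbs a constant) and avoids
  # cancellation noise in y'R^-1 y that would pollute the FD gradient
  center <- mean(rec$value)
  y <- rec$value - center
  vy <- stats::var(y)
  floor_s2 <- 1e-8 * max(vy, .Machine$double.eps)

  env <- new.env(parent = emptyenv())
  env$chol <- NULL

  # deviance at per-record residual variances and per-block variances
  deviance_at <- function(s2_rec, s2_blocks, want_solution = FALSE) {
    rinv <- 1 / s2_rec
    Ws <- W * sqrt(rinv)
    C <- Matrix::forceSymmetric(Matrix::crossprod(Ws))
    dvals <- c(rep(0, p), rep(1 / s2_blocks, times = block_sizes))
    C <- C + Matrix::Diagonal(x = dvals)
    ok <- TRUE
    if (is.null(env$chol)) {
      env$chol <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                           error = function(e) { ok <<- FALSE; NULL })
    } else {
      newch <- tryCatch(Matrix::update(env$chol, C),
                        error = function(e) { ok <<- FALSE; NULL })
      if (ok) env$chol <- newch
    }
    if (!ok) return(if (want_solution) NULL else 1e10)
    rhs <- as.vector(Matrix::crossprod(W, rinv * y))
    sol <- as.vector(Matrix::solve(env$chol, rhs, system = "A"))
    yPy <- sum(rinv * y^2) - sum(rhs * sol)
    logdetC <- 2 * as.numeric(Matrix::determinant(env$chol, sqrt = TRUE)$modulus)
    logR <- sum(log(s2_rec))
    logG <- sum(block_sizes * log(s2_blocks))
    dev <- (n - p) * log(2 * pi) + logR + logG + logdetC + yPy
    if (!is.finite(dev)) dev <- 1e10
    if (want_solution) {
      fitted <- as.vector(W %*% sol)
      list(deviance = dev, solution = sol, fitted = fitted,
           chol = env$chol, yPy = yPy)
    } else dev
  }

  list(n = n, p = p, y = y, center = center, acc = acc, yr = yr, grp = grp,
       grp_idx = grp_idx,
       X = X, W = W, blocks = blocks, block_sizes = block_sizes,
       pooled_years = pooled_years, floor_s2 = floor_s2,
       deviance_at = deviance_at, records = rec)
}

# expand (block variances, group variances) from phi and evaluate
.phi_split <- function(problem, phi) {
  nb <- length(problem$block_sizes)
  list(s2_blocks = exp(phi[seq_len(nb)]),
       s2_groups = exp(phi[nb + seq_len(nlevels(problem$grp))]))
}

#' Fit the two-way model by REML
#'
#' Maximizes the restricted log-likelihood over log-parameterized variance
#' components (one variance per random factor plus, under heterogeneous
#' errors, one residual variance per campaign year), using the sparse
#' mixed-model equations with a symbolically cached Cholesky factorization.
#' A floor of `1e-8 * var(y)` keeps the likelihood away from degenerate
#' boundaries; estimates that end on the floor are reported as boundary
#' solutions, not silently clipped.
#'
#' @param ds A [phenotype_dataset()]; it should have passed the connectivity
#'   filter (the model is otherwise unidentifiable) and must contain at least
#'   2 accessions and 2 campaign years.
#' @param spec A [model_spec()].
#' @return A `model_fit` with elements `spec`, `components` (variances `mu`,
#'   `sigma2_G`, `sigma2_A`, `sigma2_e_by_year`), `genotype_effects`
#'   (BLUEs when fixed, BLUPs when random), `year_effects`, `residuals`,
#'   `standardized_residuals` (residual divided by its year's
#'   \eqn{\hat\sigma_{e,j}}), `loglik` (restricted), `converged`,
#'   `boundary` (names of components on the variance floor), `pooled_years`.
#' @examples
#' sim <- simulate_dataset(simulation_params(50, 5, seed = 1))
#' ds <- apply_connectivity_filter(sim$dataset)$dataset
#' fit <- fit_reml(ds, model_spec("random", "random"))
#' fit$components$sigma2_G
#' @export
fit_reml <- function(ds, spec = model_spec()) {
  stopifnot(inherits(ds, "phenotype_dataset"), inherits(spec, "model_spec"))
  pr <- .reml_problem(ds, spec)
  nb <- length(pr$block_sizes)
  ng <- nlevels(pr$grp)

  vy <- max(stats::var(pr$y), pr$floor_s2)
  start <- log(c(rep(vy * 0.4 / max(nb, 1), nb), rep(vy * 0.5, ng)))
  lower <- rep(log(pr$floor_s2), nb + ng)
  upper <- rep(log(vy * 1e6 + pr$floor_s2), nb + ng)
  start <- pmin(pmax(start, lower + 1), upper - 1)

  obj <- function(phi) {
    s <- .phi_split(pr, phi)
    pr$deviance_at(s$s2_groups[pr$grp_idx], s$s2_blocks)
  }
  grad <- function(phi) {
    h <- 1e-6
    vapply(seq_along(phi), function(k) {
      up <- phi; up[k] <- up[k] + h
      dn <- phi; dn[k] <- dn[k] - h
      (obj(up) - obj(dn)) / (2 * h)
    }, numeric(1))
  }

  ctl <- list(iter.max = spec$max_iter, eval.max = 50L * spec$max_iter,
              rel.tol = max(spec$tol, 1e-14))
  res <- stats::nlminb(start, obj, gradient = grad,
                       lower = lower, upper = upper, control = ctl)
  # restart from the found point until the objective stabilizes; this both
  # clears spurious "false convergence" exits and polishes the optimum
  for (k in 1:3) {
    res2 <- stats::nlminb(res$par, obj, gradient = grad,
                          lower = lower, upper = upper, control = ctl)
    improved <- res$objective - res2$objective
    if (res2$objective <= res$objective) res <- res2
    if (improved < 1e-10 && res2$convergence == 0) break
    if (improved < 1e-12) break
  }
  # machine-tolerance polish of the optimum; worthwhile for low-dimensional
  # problems where oracle-grade precision is expected
  if (length(start) <= 8L) {
    pol <- tryCatch(
      stats::optim(res$par, obj, gr = grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1, pgtol = 0, maxit = 100L)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= res$objective) {
      res$par <- pol$par
      res$objective <- pol$value
    }
  }
  phi <- res$par
  s <- .phi_split(pr, phi)
  fin <- pr$deviance_at(s$s2_groups[pr$grp_idx], s$s2_blocks,
                        want_solution = TRUE)
  if (is.null(fin)) stop("REML system could not be factorized", call. = FALSE)

  # converged if the optimizer succeeded or the projected gradient vanishes
  # (at the lower bound only an outward-pointing gradient is required)
  g_fin <- grad(phi)
  at_lb <- phi <= lower + 1e-6
  grad_ok <- all(ifelse(at_lb, g_fin >= -0.05, abs(g_fin) <= 0.05))
  converged <- res$convergence == 0 || grad_ok
  boundary_idx <- which(phi <= lower + 1e-6)
  par_names <- c(names(pr$block_sizes), paste0("sigma2_e[", levels(pr$grp), "]"))

  sol <- fin$solution
  # undo the centring: every row of X has a single unit entry, so adding the
  # centre to each fixed-effect solution restores the observation scale
  beta <- stats::setNames(sol[seq_len(pr$p)] + pr$center, colnames(pr$X))
  u <- list()
  off <- pr$p
  for (bn in names(pr$blocks)) {
    k <- pr$block_sizes[[bn]]
    u[[bn]] <- stats::setNames(sol[off + seq_len(k)], colnames(pr$blocks[[bn]]))
    off <- off + k
  }

  residuals <- pr$y - fin$fitted
  s2_rec <- s$s2_groups[pr$grp_idx]
  std_resid <- residuals / sqrt(s2_rec)

  # per-year residual variances (pooled years share the pooled estimate)
  year_levels <- levels(pr$yr)
  grp_of_year <- vapply(year_levels, function(j) {
    as.character(pr$grp[match(j, as.character(pr$yr))])
  }, character(1))
  sigma2_e_by_year <- stats::setNames(
    s$s2_groups[match(grp_of_year, levels(pr$grp))], year_levels)

  genotype_effects <- if (spec$genotype_role == "fixed") beta[colnames(pr$X) %in% levels(pr$acc)] else u$accession
  year_effects <- if (spec$year_role == "fixed") beta[colnames(pr$X) %in% levels(pr$yr)] else u$year
  mu <- if (pr$p == 1L && colnames(pr$X)[1] == "(Intercept)") beta[[1]]
        else mean(fin$fitted) + pr$center

  components <- list(
    mu = as.numeric(mu),
    sigma2_G = if (spec$genotype_role == "random")
      as.numeric(s$s2_blocks[match("accession", names(pr$block_sizes))]) else NULL,
    sigma2_A = if (spec$year_role == "random")
      as.numeric(s$s2_blocks[match("year", names(pr$block_sizes))]) else NULL,
    sigma2_e_by_year = sigma2_e_by_year
  )

  # triplet lookup for BLUE tables
  key <- accession_key(ds)
  first <- !duplicated(key)
  triplets <- data.frame(
    key = key[first],
    institute_code = pr$records$institute_code[first],
    genus = pr$records$genus[first],
    accession_number = pr$records$accession_number[first],
    stringsAsFactors = FALSE)

  structure(
    list(spec = spec, components = components,
         genotype_effects = genotype_effects, year_effects = year_effects,
         residuals = residuals, standardized_residuals = std_resid,
         loglik = -fin$deviance / 2, converged = converged,
         boundary = par_names[boundary_idx],
         pooled_years = pr$pooled_years,
         records = pr$records, year_of_record = as.character(pr$yr),
         accession_of_record = as.character(pr$acc),
         n = pr$n, p = pr$p,
         chol = fin$chol, X_names = colnames(pr$X),
         triplets = triplets,
         optimizer = list(message = res$message, iterations = res$iterations,
                          objective = res$objective)),
    class = "model_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit: genotype %s, year %s, %s errors; n=%d, logLik=%.3f%s>\n",
              x$spec$genotype_role, x$spec$year_role,
              if (x$spec$heterogeneous_errors) "year-specific" else "pooled",
              x$n, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (!is.null(x$components$sigma2_G))
    cat(sprintf("  sigma2_G = %.5g\n", x$components$sigma2_G))
  if (!is.null(x$components$sigma2_A))
    cat(sprintf("  sigma2_A = %.5g\n", x$components$sigma2_A))
  cat(sprintf("  sigma2_e: %s\n",
              paste(sprintf("%.4g", x$components$sigma2_e_by_year), collapse = " ")))
  if (length(x$boundary))
    cat("  boundary solutions:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML objective of the model defined by `spec` on `ds` at
#' externally supplied variance components, without optimizing.  Used to
#' verify that [fit_reml()] solutions are (local) maxima and to compare
#' against dense-matrix oracles.
#'
#' @param ds A [phenotype_dataset()].
#' @param spec A [model_spec()].
#' @param components List with `sigma2_G` and/or `sigma2_A` (matching the
#'   random roles in `spec`) and `sigma2_e_by_year`, a vector named by
#'   campaign year covering exactly the years present in `ds` (a single
#'   unnamed value is accepted for homogeneous errors).
#' @return The restricted log-likelihood (a scalar).
#' @export
restricted_loglik <- function(ds, spec, components) {
  stopifnot(inherits(ds, "phenotype_dataset"), inherits(spec, "model_spec"))
  pr <- .reml_problem(ds, spec)
  s2_blocks <- numeric(length(pr$block_sizes))
  names(s2_blocks) <- names(pr$block_sizes)
  if ("accession" %in% names(s2_blocks)) {
    if (is.null(components$sigma2_G))
      stop("components$sigma2_G required for a random-genotype spec", call. = FALSE)
    s2_blocks[["accession"]] <- components$sigma2_G
  }
  if ("year" %in% names(s2_blocks)) {
    if (is.null(components$sigma2_A))
      stop("components$sigma2_A required for a random-year spec", call. = FALSE)
    s2_blocks[["year"]] <- components$sigma2_A
  }
  s2y <- components$sigma2_e_by_year
  year_levels <- levels(pr$yr)
  if (length(s2y) == 1L && is.null(names(s2y))) {
    s2_rec <- rep(as.numeric(s2y), pr$n)
  } else {
    if (!all(year_levels %in% names(s2y)))
      stop("sigma2_e_by_year does not cover years: ",
           paste(setdiff(year_levels, names(s2y)), collapse = ", "),
           call. = FALSE)
    s2_rec <- as.numeric(s2y[as.character(pr$yr)])
  }
  if (any(!is.finite(s2_rec)) || any(s2_rec <= 0) ||
      any(!is.finite(s2_blocks)) || any(s2_blocks <= 0))
    stop("variance components must be finite and positive", call. = FALSE)
  -pr$deviance_at(s2_rec, s2_blocks) / 2
}

#' Best linear unbiased estimates of accession means
#'
#' Extracts the fixed-effect accession solutions of a fixed-genotype fit.
#' Under the cell-means parameterization used by [fit_reml()] the solutions
#' are directly on the observation scale (\eqn{\mu + g_i}), so no recentring
#' is needed.  Standard errors are the square roots of the diagonal of
#' \eqn{(X' V^{-1} X)^{-1}}, taken from the inverse mixed-model-equation
#' matrix (normal approximation; no small-sample correction).
#'
#' @param fit A `model_fit` with `genotype_role = "fixed"`.
#' @param se Compute standard errors (chunked sparse solves; set `FALSE` to
#'   skip on very large fits).
#' @param chunk Number of right-hand sides per solve chunk.
#' @return Data frame with columns `institute_code`, `genus`,
#'   `accession_number`, `blue`, `se`, sorted by accession key.
#' @export
predict_blues <- function(fit, se = TRUE, chunk = 512L) {
  stopifnot(inherits(fit, "model_fit"))
  if (fit$spec$genotype_role != "fixed")
    stop("BLUEs require a fixed-genotype fit; this fit has genotype_role = 'random'",
         call. = FALSE)
  if (!fit$converged)
    warning("fit did not converge; BLUEs may be unreliable")
  blues <- fit$genotype_effects
  keys <- names(blues)
  se_vec <- rep(NA_real_, length(blues))
  if (se) {
    dim_c <- nrow(fit$chol)
    pos <- match(keys, fit$X_names)  # beta columns precede random columns
    for (start in seq(1L, length(pos), by = chunk)) {
      idx <- pos[start:min(start + chunk - 1L, length(pos))]
      E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                                dims = c(dim_c, length(idx)))
      S <- Matrix::solve(fit$chol, E, system = "A")
      se_vec[start:(start + length(idx) - 1L)] <-
        sqrt(pmax(S[cbind(idx, seq_along(idx))], 0))
    }
  }
  tri <- fit$triplets[match(keys, fit$triplets$key), , drop = FALSE]
  out <- data.frame(institute_code = tri$institute_code, genus = tri$genus,
                    accession_number = tri$accession_number,
                    blue = as.numeric(blues), se = se_vec,
                    stringsAsFactors = FALSE)
  out <- out[order(keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}
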