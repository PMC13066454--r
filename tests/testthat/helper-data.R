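# Shared fixture builders: everything is generated in code at test time.

# minimal records data frame from (accession, year, value) triples
make_records <- function(acc, year, value, trait = "PH") {
  data.frame(institute_code = "TST001", genus = "Triticum",
             accession_number = as.character(acc),
             campaign_year = as.integer(year),
             trait_code = trait, value = as.numeric(value),
             stringsAsFactors = FALSE)
}

make_dataset <- function(acc, year, value, trait = "PH") {
  phenotype_dataset(make_records(acc, year, value, trait))
}

# balanced complete a x b grid with known effects, homogeneous noise
balanced_dataset <- function(a_n = 20, b_n = 6, mu = 100, sd_g = 2,
                             sd_a = 1.4, sd_e = 1, seed = 42) {
  set.seed(seed)
  g <- rnorm(a_n, 0, sd_g); a <- rnorm(b_n, 0, sd_a)
  grid <- expand.grid(i = seq_len(a_n), j = seq_len(b_n))
  e <- rnorm(nrow(grid), 0, sd_e)
  val <- mu + g[grid$i] + a[grid$j] + e
  ds <- make_dataset(sprintf("A%03d", grid$i), 2000 + grid$j, val)
  list(ds = ds, y = matrix(val[order(grid$j, grid$i)], a_n, b_n),
       g = g, a = a)
}

# two-way ANOVA method-of-moments variance components on a balanced grid
anova_mom <- function(y) {
  a_n <- nrow(y); b_n <- ncol(y)
  MSG <- b_n * var(rowMeans(y))
  MSA <- a_n * var(colMeans(y))
  resid <- y - outer(rowMeans(y), rep(1, b_n)) -
    outer(rep(1, a_n), colMeans(y)) + mean(y)
  MSE <- sum(resid^2) / ((a_n - 1) * (b_n - 1))
  list(sigma2_G = (MSG - MSE) / b_n, sigma2_A = (MSA - MSE) / a_n,
       sigma2_e = MSE)
}

# brute-force step-down Holm from its definition, independent of the
# implementation's vectorized form
holm_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    val <- min(1, (m - k + 1) * p[o[k]])
    running <- max(running, val)
    adj[o[k]] <- running
  }
  adj
}

# repeat-until-stable connectivity oracle, removing ONE violating entity at a
# time in a randomized order (checks order-independence of the fixed point)
connectivity_oracle <- function(inc, min_years = 2, min_points = 2) {
  repeat {
    viol <- list()
    ny <- tapply(inc$year, inc$acc, function(y) length(unique(y)))
    for (a in names(ny)[ny < min_years]) viol <- c(viol, list(c("acc", a)))
    np <- table(inc$year)
    for (y in names(np)[np < min_points]) viol <- c(viol, list(c("year", y)))
    if (!length(viol)) return(inc)
    pick <- viol[[sample.int(length(viol), 1)]]
    inc <- if (pick[1] == "acc") inc[inc$acc != pick[2], , drop = FALSE]
           else inc[inc$year != as.integer(pick[2]), , drop = FALSE]
  }
}

# dense-matrix restricted log-likelihood: direct evaluation of
# -2l = (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py on small problems
dense_reml_loglik <- function(y, X, Zlist, s2list, s2_rec) {
  n <- length(y)
  V <- diag(s2_rec, n)
  for (k in seq_along(Zlist)) V <- V + s2list[[k]] * tcrossprod(Zlist[[k]])
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  dev <- (n - ncol(X)) * log(2 * pi) +
    determinant(V, logarithm = TRUE)$modulus +
    determinant(XtViX, logarithm = TRUE)$modulus +
    as.numeric(t(y) %*% P %*% y)
  -as.numeric(dev) / 2
}
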