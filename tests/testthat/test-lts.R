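test_that("c = 1 reduces to ordinary least squares", {
  set.seed(2)
  n <- 30
  X <- cbind("(Intercept)" = 1, z = rbinom(n, 1, 0.5), x = rnorm(n))
  y <- 1 + 0.5 * X[, "z"] - 0.3 * X[, "x"] + rnorm(n)
  fit <- lts_fit(y, X, c = 1)
  ols <- lm(y ~ z + x, data = data.frame(y = y, X[, -1]))
  expect_lt(max(abs(fit$coefficients - coef(ols))), 1e-8)
  inf <- lts_inference(fit, y, X)
  sm <- summary(ols)$coefficients
  expect_lt(max(abs(inf$estimate - sm[, 1])), 1e-8)
  expect_lt(max(abs(inf$std_error - sm[, 2])), 1e-8)
  expect_lt(max(abs(inf$p_value - sm[, 4])), 1e-8)
})

test_that("exact-fit recovery with 3 of 12 gross outliers at c = 0.5", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 1.5, 4.5, 7.5)
  y <- 2 + 3 * x
  y[10:12] <- y[10:12] + c(80, -120, 95)        # gross outliers
  X <- cbind(1, x)
  fit <- lts_fit(y, X, c = 0.5)
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_true(all(!(10:12 %in% fit$best_subset)))
  inf <- lts_inference(fit, y, X)
  expect_true(all(attr(inf, "outlier_flags")[10:12]))
  expect_equal(inf$estimate, c(2, 3), tolerance = 1e-10)
})

test_that("breakdown: corrupting the trimmed observations changes nothing", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 1.5, 4.5, 7.5)
  y <- 2 + 3 * x
  X <- cbind(1, x)
  h <- lts_fit(y, X, c = 0.5)$h
  bad <- seq_len(12 - h)                 # every observation LTS may trim
  y2 <- y
  y2[bad] <- 1e5 * c(1, -3, 7, -2, 5)[seq_along(bad)]
  fit <- lts_fit(y2, X, c = 0.5)
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
})

test_that("small-n optimum equals an independent exhaustive enumeration", {
  set.seed(33)
  for (rep in 1:8) {
    n <- 13
    X <- cbind(1, rnorm(n))
    y <- rnorm(n, sd = 1 + 2 * (runif(n) < 0.2))
    fit <- lts_fit(y, X, c = 0.5)
    expect_equal(fit$objective, lts_bruteforce_objective(y, X, fit$h),
                 tolerance = 1e-10)
  }
})

test_that("randomized search beats 500 random h-subsets", {
  set.seed(55)
  n <- 60
  X <- cbind(1, rbinom(n, 1, 0.5), rnorm(n))
  y <- rnorm(n) + 4 * (runif(n) < 0.15)
  fit <- lts_fit(y, X, c = 0.5, seed = 3)
  h <- fit$h
  for (draw in 1:500) {
    s <- sample.int(n, h)
    f <- lm.fit(X[s, , drop = FALSE], y[s])
    r2 <- sort((y - drop(X %*% f$coefficients))^2)
    expect_lte(fit$objective, sum(r2[seq_len(h)]) + 1e-10)
  }
})

test_that("LTS is shift and scale equivariant", {
  set.seed(9)
  n <- 40
  X <- cbind("(Intercept)" = 1, z = rbinom(n, 1, 0.5), x = rnorm(n))
  y <- rnorm(n) + 6 * (runif(n) < 0.2)
  f0 <- lts_fit(y, X, c = 0.5, seed = 4)
  i0 <- lts_inference(f0, y, X)
  f_shift <- lts_fit(y + 10, X, c = 0.5, seed = 4)
  expect_equal(unname(f_shift$coefficients - f0$coefficients), c(10, 0, 0),
               tolerance = 1e-8)
  f_scale <- lts_fit(3 * y, X, c = 0.5, seed = 4)
  i_scale <- lts_inference(f_scale, 3 * y, X)
  expect_equal(f_scale$coefficients, 3 * f0$coefficients, tolerance = 1e-8)
  expect_equal(i_scale$std_error, 3 * i0$std_error, tolerance = 1e-8)
  expect_equal(i_scale$p_value, i0$p_value, tolerance = 1e-8)
})

test_that("identical seeds give identical fits", {
  set.seed(10)
  n <- 50
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  f1 <- lts_fit(y, X, c = 0.5, seed = 77)
  f2 <- lts_fit(y, X, c = 0.5, seed = 77)
  expect_identical(f1, f2)
})

test_that("rank-deficient designs are reported with the collinear column", {
  n <- 20
  X <- cbind(a = rep(1, n), b = rnorm(n))
  X <- cbind(X, c = 2 * X[, "b"])
  expect_error(lts_fit(rnorm(n), X, c = 0.5), "collinear column.*c")
})

test_that("type-I error of the Z term is near nominal under the null", {
  set.seed(123)
  n <- 40
  X <- cbind("(Intercept)" = 1, z = rep(0:1, each = n / 2), x = rnorm(n))
  n_sim <- 1000
  # 1000 simulated taxa with zero coefficient on z, fitted with the
  # calibrated inference route shared across taxa
  pv <- matrix(rnorm(n * n_sim), n, n_sim,
               dimnames = list(NULL, paste0("t", seq_len(n_sim))))
  out <- fit_all_taxa(pv, X, c = 0.5, seed = 11, n_starts = 50)
  pz <- vapply(out$results, function(r) r$p_value[2], numeric(1))
  rate <- mean(pz < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("a large planted group effect is detected with high power", {
  set.seed(321)
  n <- 40
  n_rep <- 200
  X <- cbind("(Intercept)" = 1, z = rep(0:1, each = n / 2))
  pv <- matrix(rnorm(n * n_rep) + 2.0 * X[, "z"], n, n_rep,
               dimnames = list(NULL, paste0("t", seq_len(n_rep))))
  out <- fit_all_taxa(pv, X, c = 0.5, seed = 17, n_starts = 50)
  pz <- vapply(out$results, function(r) r$p_value[2], numeric(1))
  expect_gte(mean(pz < 0.001), 0.95)
})

test_that("taxon-wise fitting isolates failures and is deterministic", {
  set.seed(77)
  n <- 24
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     grp = rep(c("a", "b"), each = n / 2),
                     x = rnorm(n))
  X <- build_design(meta, "grp", "a", "x")
  pv <- matrix(rnorm(n * 10), n, 10,
               dimnames = list(meta$sample_id, paste0("t", 1:10)))
  pv[, 4] <- pv[, 9]                  # duplicated taxon columns
  out <- fit_all_taxa(pv, X, c = 0.5, seed = 5)
  expect_length(out$results, 10)
  expect_identical(out$results[["t4"]][, -1], out$results[["t9"]][, -1])
  out2 <- fit_all_taxa(pv, X, c = 0.5, seed = 5)
  expect_identical(out, out2)
})
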