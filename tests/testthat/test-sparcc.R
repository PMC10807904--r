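test_that("fraction estimation is posterior-mean with pseudocount", {
  ct <- count_table(matrix(1, 1, 4, dimnames = list("s1", paste0("t", 1:4))))
  expect_equal(unname(sparcc_fractions(ct, 1)[1, ]), rep(0.25, 4))
  m <- matrix(c(3, 0, 1, 2), 1, 4)
  expect_equal(unname(sparcc_fractions(m, 1)[1, ]), c(4, 1, 2, 3) / 10)
  # and the spec'd 3-taxon arithmetic on a raw matrix
  expect_equal(unname(sparcc_fractions(matrix(c(3, 0, 1), 1, 3), 1)[1, ]),
               c(4, 1, 2) / 7)
  set.seed(4)
  ct2 <- count_table(matrix(rpois(200, 30), 20, 10))
  fr <- sparcc_fractions(ct2)
  expect_true(all(fr > 0 & fr < 1))
  expect_lt(max(abs(rowSums(fr) - 1)), 1e-12)
})

test_that("log-ratio variance matches a brute-force two-pass oracle", {
  # identical columns give zero variance
  f <- matrix(c(0.3, 0.3, 0.4, 0.2, 0.2, 0.6), 2, 3, byrow = TRUE)
  T_mat <- logratio_variance(f)
  expect_equal(T_mat[1, 2], 0)
  # log-ratio values (0, 2) over 2 samples: variance 2 with n-1 denominator
  f2 <- rbind(c(0.5, 0.5), c(exp(2), 1) / (exp(2) + 1))
  expect_equal(logratio_variance(f2)[1, 2], 2, tolerance = 1e-12)
  # 200-sample log-normal fixture vs an independent two-pass variance
  set.seed(7)
  w <- matrix(rnorm(200 * 6), 200, 6)
  fr <- exp(w) / rowSums(exp(w))
  T3 <- logratio_variance(fr)
  for (k in 1:6) for (j in 1:6) {
    lr <- log(fr[, k] / fr[, j])
    mu <- sum(lr) / length(lr)
    v2 <- sum((lr - mu)^2) / (length(lr) - 1)
    expect_lt(abs(T3[k, j] - v2), 1e-10)
  }
  expect_equal(diag(T3), setNames(rep(0, 6), colnames(T3)))
  expect_error(logratio_variance(f[1, , drop = FALSE]), "at least 2 samples")
})

test_that("basis-variance solve matches an independent linear-algebra route", {
  # hand-built exact system for p = 4 with known omega
  omega_true <- c(1.5, 0.7, 2.2, 1.0)
  T_mat <- outer(omega_true, omega_true, "+")
  diag(T_mat) <- 0
  omega <- solve_basis_variances(T_mat)
  # independent route: explicit (p-2)I + 11' system solved by qr.solve
  p <- 4
  M <- matrix(1, p, p); diag(M) <- p - 1
  omega_ind <- qr.solve(M, rowSums(T_mat))
  expect_lt(max(abs(omega - omega_true)), 1e-10)
  expect_lt(max(abs(omega - omega_ind)), 1e-10)
})

test_that("basis solve recovers independent log-normal variances", {
  set.seed(21)
  n <- 2000; p <- 6
  w <- matrix(rnorm(n * p, sd = 1), n, p)     # unit basis variances
  fr <- exp(w) / rowSums(exp(w))
  omega <- solve_basis_variances(logratio_variance(fr))
  expect_lt(max(abs(omega - 1)), 0.15)
})

test_that("degenerate and singular basis systems are handled", {
  T0 <- matrix(0, 5, 5)
  omega <- solve_basis_variances(T0)
  expect_equal(as.vector(omega), rep(1e-8, 5))
  expect_true(all(attr(omega, "clamped")))
  mask <- matrix(TRUE, 5, 5); mask[2, ] <- mask[, 2] <- FALSE
  T1 <- outer(1:5 / 2, 1:5 / 2, "+"); diag(T1) <- 0
  rownames(T1) <- colnames(T1) <- paste0("t", 1:5)
  expect_error(solve_basis_variances(T1, mask), "all pairs excluded.*t2")
})

test_that("sparcc output satisfies the correlation-matrix contract", {
  ct <- tiny_counts(n = 15, p = 8)
  a <- suppressWarnings(sparcc(ct))
  v <- unclass(a)
  expect_equal(unname(diag(v)), rep(1, 8))
  expect_lt(max(abs(v - t(v))), 1e-12)
  expect_lte(max(abs(v)), 1)
  expect_equal(rownames(v), colnames(ct))
  expect_error(sparcc(unclass(ct)[, 1:3]), "at least 4 taxa")
})

test_that("sparcc is a pure function of counts and config, equivariant to ordering", {
  ct <- tiny_counts(n = 20, p = 7, seed = 31)
  a1 <- suppressWarnings(sparcc(ct))
  a2 <- suppressWarnings(sparcc(ct))
  expect_identical(unclass(a1), unclass(a2))
  # taxon permutation permutes the association matrix identically
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  ctp <- ct[, perm]; class(ctp) <- class(ct)
  ap <- suppressWarnings(sparcc(ctp))
  expect_equal(unclass(ap), unclass(a1)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
  # sample order is irrelevant
  cts <- ct[sample(seq_len(nrow(ct))), ]; class(cts) <- class(ct)
  as_ <- suppressWarnings(sparcc(cts))
  expect_equal(unclass(as_), unclass(a1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("independent taxa yield a near-diagonal estimate", {
  ct <- lognormal_counts(1000, diag(20), depth = 5e4, seed = 101)
  a <- suppressWarnings(sparcc(ct))
  off <- abs(unclass(a)); diag(off) <- 0
  expect_lt(max(off), 0.15)
})

test_that("a planted correlated pair is recovered as the top estimate", {
  R <- diag(20); R[1, 2] <- R[2, 1] <- 0.8
  ct <- lognormal_counts(500, R, depth = 5e4, seed = 202)
  a <- suppressWarnings(sparcc(ct))
  off <- abs(unclass(a)); diag(off) <- 0
  expect_equal(unname(which(off == max(off), arr.ind = TRUE)[1, ]),
               c(2, 1), ignore_attr = TRUE)
  expect_gt(unclass(a)[1, 2], 0.5)
})

test_that("estimated correlations track a structured generating matrix", {
  R <- diag(20)
  R[1:4, 1:4] <- 0.6; R[6:8, 6:8] <- -0.2
  diag(R) <- 1
  ct <- lognormal_counts(1000, R, depth = 1e5, seed = 303)
  a <- suppressWarnings(sparcc(ct))
  err <- abs(unclass(a) - R)[upper.tri(R)]
  expect_lt(mean(err), 0.1)
})

test_that("dirichlet resampling draws are seeded and reproducible", {
  ct <- tiny_counts(n = 15, p = 6, seed = 77)
  cfg <- sparcc_config(resampling_draws = 5)
  a1 <- suppressWarnings(sparcc(ct, cfg, seed = 9))
  a2 <- suppressWarnings(sparcc(ct, cfg, seed = 9))
  a3 <- suppressWarnings(sparcc(ct, cfg, seed = 10))
  expect_identical(unclass(a1), unclass(a2))
  expect_false(identical(unclass(a1), unclass(a3)))
})
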