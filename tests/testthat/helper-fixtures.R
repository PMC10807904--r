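# Shared fixture builders and independent oracles for the test suite.

extdata <- function(f) {
  p <- system.file("extdata", f, package = "dcnet")
  if (p == "") file.path("..", "..", "inst", "extdata", f) else p
}

# A tiny deterministic count table.
tiny_counts <- function(n = 8, p = 5, seed = 11) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    m <- matrix(rpois(n * p, lambda = 20) + 1, n, p)
    count_table(m, sample_ids = paste0("s", seq_len(n)),
                taxon_ids = paste0("t", seq_len(p)))
  })
}

# Log-normal compositional counts with a given basis correlation matrix.
lognormal_counts <- function(n, R, depth = 5e4, seed = 1, mu = NULL) {
  set.seed(seed)
  p <- nrow(R)
  if (is.null(mu)) mu <- rep(0, p)
  ch <- chol(R)
  w <- matrix(rnorm(n * p), n, p) %*% ch
  w <- sweep(w, 2, mu, "+")
  f <- exp(w); f <- f / rowSums(f)
  x <- t(apply(f, 1, function(fi) drop(rmultinom(1, depth, fi))))
  count_table(x, sample_ids = paste0("s", seq_len(n)),
              taxon_ids = paste0("t", seq_len(p)))
}

# Independent brute-force LTS oracle: enumerate every h-subset, fit OLS with
# lm.fit, return the minimal subset RSS. Shares no code with lts_fit().
lts_bruteforce_objective <- function(y, X, h) {
  n <- length(y)
  subs <- utils::combn(n, h)
  best <- Inf
  for (j in seq_len(ncol(subs))) {
    s <- subs[, j]
    f <- stats::lm.fit(as.matrix(X)[s, , drop = FALSE], y[s])
    if (f$rank < ncol(as.matrix(X))) next
    best <- min(best, sum(f$residuals^2))
  }
  best
}

# Independent connectivity oracle: explicit double loop.
connectivity_bruteforce <- function(a) {
  p <- nrow(a)
  th <- numeric(p)
  for (k in seq_len(p)) {
    for (j in seq_len(p)) if (j != k) th[k] <- th[k] + abs(a[k, j])
  }
  th
}

# Quiet pipeline wrapper used across tests.
run_quiet <- function(...) {
  suppressWarnings(suppressMessages(dcnet(..., verbose = FALSE)))
}
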