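#' SparCC estimation settings
#'
#' Tuning constants for the compositional correlation estimator. The defaults
#' are deliberately deterministic: fractions are posterior means under a
#' uniform prior (add-pseudocount) rather than Dirichlet resampling averages,
#' so that each leave-one-out network in the jackknife differs only because of
#' the removed sample, never because of Monte-Carlo noise.
#'
#' @param exclusion_threshold correlation magnitude above which the
#'   strongest-correlated taxon pair is excluded from the basis-variance
#'   solve, one pair per round. In (0, 1); default 0.1.
#' @param max_exclusion_rounds maximum number of exclusion rounds (default 10).
#' @param pseudocount positive count added to every cell for fraction
#'   estimation (default 1).
#' @param resampling_draws if > 0, correlation estimates are averaged over
#'   this many Dirichlet-resampled fraction draws (seeded); 0 (the default)
#'   uses the deterministic posterior-mean fractions.
#' @return list of class `sparcc_config`.
#' @export
sparcc_config <- function(exclusion_threshold = 0.1,
                          max_exclusion_rounds = 10L,
                          pseudocount = 1,
                          resampling_draws = 0L) {
  stopifnot(exclusion_threshold > 0, exclusion_threshold < 1,
            max_exclusion_rounds >= 0, pseudocount > 0,
            resampling_draws >= 0)
  structure(list(exclusion_threshold = exclusion_threshold,
                 max_exclusion_rounds = as.integer(max_exclusion_rounds),
                 pseudocount = pseudocount,
                 resampling_draws = as.integer(resampling_draws)),
            class = "sparcc_config")
}

#' Construct an association matrix object
#'
#' A symmetric taxa-by-taxa matrix of pairwise association estimates: SparCC
#' correlations (`kind = "correlation"`, unit diagonal, entries in [-1, 1]) or
#' an entrywise difference of two such matrices (`kind = "difference"`, zero
#' diagonal, entries in [-2, 2]).
#'
#' @param values symmetric numeric p x p matrix.
#' @param taxon_ids taxon identifiers; default `colnames(values)`.
#' @param kind `"correlation"` or `"difference"`.
#' @return object of class `assoc_matrix` (a matrix with a `kind` attribute).
#' @export
assoc_matrix <- function(values, taxon_ids = colnames(values),
                         kind = c("correlation", "difference")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-12)
    stop("association matrix is not symmetric")
  p <- nrow(values)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(p))
  if (kind == "correlation") {
    if (max(abs(diag(values) - 1)) > 1e-12)
      stop("correlation matrix must have unit diagonal")
    if (max(abs(values)) > 1 + 1e-12)
      stop("correlation entries must lie in [-1, 1]")
  } else {
    if (max(abs(diag(values))) > 1e-12)
      stop("difference matrix must have zero diagonal")
    if (max(abs(values)) > 2 + 1e-12)
      stop("difference entries must lie in [-2, 2]")
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(taxon_ids, taxon_ids)
  structure(values, kind = kind, class = c("assoc_matrix", "matrix", "array"))
}

#' Estimate compositional fractions from counts
#'
#' Posterior-mean fraction under a uniform Dirichlet prior:
#' `(count + pseudocount) / (depth + p * pseudocount)` per sample. All entries
#' are strictly positive, so log-ratios are always defined.
#'
#' @param counts a [count_table] (or plain count matrix, samples x taxa).
#' @param pseudocount positive pseudocount (default 1).
#' @return samples x taxa matrix of fractions; rows sum to one.
#' @export
sparcc_fractions <- function(counts, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  x <- unclass(counts) + pseudocount
  x / rowSums(x)
}

#' Log-ratio variance matrix
#'
#' `T[k, j] = var_i(log(f[i, k] / f[i, j]))` over samples, with the unbiased
#' (n - 1) denominator. Computed from the covariance matrix of log-fractions:
#' `T[k, j] = V[k, k] + V[j, j] - 2 V[k, j]`.
#'
#' @param fractions strictly positive samples x taxa fraction matrix.
#' @return symmetric p x p matrix with zero diagonal.
#' @export
logratio_variance <- function(fractions) {
  if (nrow(fractions) < 2) stop("at least 2 samples required for variances")
  if (any(fractions <= 0)) stop("fractions must be strictly positive")
  L <- log(fractions)
  V <- stats::cov(L)
  d <- diag(V)
  T_mat <- outer(d, rep(1, length(d))) + outer(rep(1, length(d)), d) - 2 * V
  T_mat <- (T_mat + t(T_mat)) / 2
  T_mat[T_mat < 0] <- 0          # numerical guard; true values are >= 0
  diag(T_mat) <- 0
  dimnames(T_mat) <- dimnames(V)
  T_mat
}

#' Solve the SparCC basis-variance linear system
#'
#' Under the sparsity assumption (included pairs are approximately
#' uncorrelated on the basis scale), `T[k, j] ~ omega_k + omega_j`, so the row
#' sums of `T` over included pairs satisfy `t = (diag(d) + A) omega` where `A`
#' is the inclusion adjacency and `d` its row degrees. Negative solutions
#' (possible on sparse data) are clamped to a floor of 1e-8 with a warning
#' flag rather than failing, since the jackknife must survive occasional
#' awkward leave-one-out subsets.
#'
#' @param T_mat log-ratio variance matrix from [logratio_variance()].
#' @param mask symmetric logical p x p inclusion mask (diagonal ignored);
#'   default all pairs included.
#' @return numeric vector of p basis variances, with attribute `clamped`
#'   (logical) marking floored entries.
#' @export
solve_basis_variances <- function(T_mat, mask = NULL) {
  p <- nrow(T_mat)
  if (p < 4) stop("at least 4 taxa required for the basis solve")
  if (is.null(mask)) mask <- matrix(TRUE, p, p)
  diag(mask) <- FALSE
  if (max(abs(mask - t(mask))) != 0) stop("mask must be symmetric")
  d <- rowSums(mask)
  if (any(d == 0)) {
    ids <- rownames(T_mat)
    if (is.null(ids)) ids <- as.character(seq_len(p))
    stop("singular basis system: all pairs excluded for taxon ",
         paste(ids[d == 0], collapse = ", "))
  }
  A <- mask * 1
  M <- diag(d) + A
  t_vec <- rowSums(T_mat * A)
  omega <- tryCatch(solve(M, t_vec), error = function(e) {
    stop("singular basis-variance system: ", conditionMessage(e))
  })
  clamped <- omega < 1e-8
  omega[clamped] <- 1e-8
  names(omega) <- rownames(T_mat)
  attr(omega, "clamped") <- clamped
  omega
}

# One deterministic SparCC pass on a fraction matrix: iterative exclusion of
# the strongest-correlated pair above threshold, one pair per round.
sparcc_from_fractions <- function(fractions, config) {
  p <- ncol(fractions)
  T_mat <- logratio_variance(fractions)
  mask <- matrix(TRUE, p, p); diag(mask) <- FALSE
  off <- upper.tri(T_mat)
  rho <- NULL
  for (round in 0:config$max_exclusion_rounds) {
    omega <- tryCatch(solve_basis_variances(T_mat, mask),
                      error = function(e) NULL)
    if (is.null(omega)) {       # exclusion made the system singular: revert
      warning("exclusion stopped early: basis system would become singular")
      break
    }
    s <- sqrt(omega)
    rho_new <- (outer(omega, omega, "+") - T_mat) / (2 * outer(s, s))
    rho_new[rho_new > 1] <- 1; rho_new[rho_new < -1] <- -1
    diag(rho_new) <- 1
    rho <- rho_new
    if (round == config$max_exclusion_rounds) break
    cand <- abs(rho)
    cand[!mask] <- 0           # never re-exclude, never look at the diagonal
    cand[!off & !lower.tri(cand)] <- 0
    m <- max(cand)
    if (m <= config$exclusion_threshold) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    # refuse an exclusion that would strand a taxon with no included pair
    if (sum(mask[ij[1], ]) <= 1 || sum(mask[ij[2], ]) <= 1) {
      warning("exclusion stopped early: taxon would lose all pairs")
      break
    }
    mask[ij[1], ij[2]] <- mask[ij[2], ij[1]] <- FALSE
  }
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- dimnames(T_mat)
  rho
}

#' SparCC compositional correlation matrix
#'
#' Estimates correlations between unobserved basis abundances from a
#' compositional count table: log-ratio variances, a linear solve for basis
#' variances under a sparsity assumption, and iterative exclusion (one pair
#' per round) of the strongest-correlated pair exceeding the threshold from
#' the basis solve. With `resampling_draws = 0` the result is a pure function
#' of the counts and configuration.
#'
#' @param counts a [count_table] (at least 4 taxa).
#' @param config a [sparcc_config()].
#' @param seed integer seed used only when `resampling_draws > 0`.
#' @return an [assoc_matrix] of kind `"correlation"`.
#' @references Friedman J, Alm EJ (2012) Inferring correlation networks from
#'   genomic survey data. PLoS Comput Biol 8:e1002687.
#' @export
sparcc <- function(counts, config = sparcc_config(), seed = 1L) {
  x <- unclass(counts)
  if (ncol(x) < 4) stop("SparCC requires at least 4 taxa; got ", ncol(x))
  if (nrow(x) < 2) stop("SparCC requires at least 2 samples")
  taxa <- colnames(x)
  if (config$resampling_draws > 0) {
    acc <- matrix(0, ncol(x), ncol(x))
    with_seed(seed, {
      for (b in seq_len(config$resampling_draws)) {
        frac <- t(apply(x + config$pseudocount, 1, function(a) {
          g <- stats::rgamma(length(a), shape = a, rate = 1)
          g / sum(g)
        }))
        acc <- acc + sparcc_from_fractions(frac, config)
      }
    })
    rho <- acc / config$resampling_draws
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    diag(rho) <- 1
  } else {
    frac <- sparcc_fractions(x, config$pseudocount)
    rho <- sparcc_from_fractions(frac, config)
  }
  assoc_matrix(rho, taxon_ids = taxa, kind = "correlation")
}

#' Write an association matrix as TSV
#'
#' @param assoc an [assoc_matrix].
#' @param path output file path.
#' @export
write_assoc_matrix <- function(assoc, path) {
  df <- data.frame(taxon = rownames(assoc), as.data.frame(unclass(assoc)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
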