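#' Least trimmed squares regression
#'
#' Minimizes the sum of the h smallest squared residuals, where
#' `h = floor(c * n) + floor((m + 1) / 2)` (clamped to `[m + 1, n]`), the
#' subset-size convention behind the usual default trimming proportion
#' c = 0.5. With `c = 1` (h = n) the estimator is ordinary least squares.
#'
#' For n <= 14 the exact optimum is found by enumerating all h-subsets
#' (the LTS objective over coefficients equals the minimum over h-subsets of
#' the subset OLS residual sum of squares). For larger n a seeded FAST-LTS
#' search is used: elemental starts refined by concentration steps (C-steps),
#' with full convergence iterations on the best candidates.
#'
#' @param y numeric response vector (length n).
#' @param X numeric design matrix (n x m, including the intercept column).
#' @param c trim proportion in [0.5, 1]; default 0.5.
#' @param seed integer seed for the randomized search.
#' @param n_starts number of elemental starts (default 500).
#' @param n_keep number of best candidates refined to convergence (default 10).
#' @param max_csteps full concentration iterations on kept candidates
#'   (default 10).
#' @return list of class `lts_fit`: `coefficients`, `best_subset` (indices of
#'   the h fitted observations), `objective` (sum of the h smallest squared
#'   residuals), `h`, `n`, `m`, `c`, `scale_raw` (consistency-corrected raw
#'   scale estimate), `residuals` (all n, at the LTS coefficients).
#' @references Rousseeuw PJ, Van Driessen K (2006) Computing LTS regression
#'   for large data sets. Data Min Knowl Discov 12:29-45.
#' @export
lts_fit <- function(y, X, c = 0.5, seed = 1L, n_starts = 500L,
                    n_keep = 10L, max_csteps = 10L) {
  X <- as.matrix(X)
  n <- length(y); m <- ncol(X)
  if (nrow(X) != n) stop("nrow(X) != length(y)")
  if (n <= m) stop("need n > m; got n = ", n, ", m = ", m)
  if (c < 0.5 || c > 1) stop("trim proportion c must lie in [0.5, 1]")
  qx <- qr(X)
  if (qx$rank < m) {
    dep <- setdiff(seq_len(m), qx$pivot[seq_len(qx$rank)])
    cn <- colnames(X); if (is.null(cn)) cn <- paste0("V", seq_len(m))
    stop("rank-deficient design; collinear column(s): ",
         paste(cn[dep], collapse = ", "))
  }
  h <- floor(c * n) + floor((m + 1) / 2)
  h <- min(n, max(m + 1, h))

  obj_of <- function(beta) {
    r2 <- (y - drop(X %*% beta))^2
    sum(sort.int(r2, partial = h)[seq_len(h)])
  }
  if (h == n) {
    beta <- qr.coef(qx, y)
    best <- list(coefficients = beta, subset = seq_len(n),
                 objective = sum(qr.resid(qx, y)^2))
  } else if (n <= 14L) {
    best <- lts_exhaustive(y, X, h)
  } else {
    best <- lts_fast(y, X, h, seed = seed, n_starts = n_starts,
                     n_keep = n_keep, max_csteps = max_csteps)
  }
  beta <- best$coefficients
  names(beta) <- colnames(X)
  res <- y - drop(X %*% beta)
  scale_raw <- sqrt(best$objective / h) * lts_consistency_factor(h / n)
  structure(list(coefficients = beta, best_subset = sort(best$subset),
                 objective = best$objective, h = h, n = n, m = m, c = c,
                 scale_raw = scale_raw, residuals = res),
            class = "lts_fit")
}

# Exact LTS by enumeration of all h-subsets; feasible for small n.
lts_exhaustive <- function(y, X, h) {
  n <- length(y)
  subsets <- utils::combn(n, h)
  best_obj <- Inf; best_beta <- NULL; best_sub <- NULL
  for (j in seq_len(ncol(subsets))) {
    s <- subsets[, j]
    f <- stats::lm.fit(X[s, , drop = FALSE], y[s])
    if (f$rank < ncol(X)) next
    obj <- sum(f$residuals^2)
    if (obj < best_obj) {
      best_obj <- obj; best_beta <- f$coefficients; best_sub <- s
    }
  }
  if (is.null(best_beta)) stop("no full-rank h-subset found")
  # The optimal coefficients are the OLS fit on the best subset, but the
  # objective must be re-evaluated on all n residuals (the h smallest may
  # differ from the enumerated subset only at ties; keep the consistent pair).
  list(coefficients = best_beta, subset = best_sub, objective = best_obj)
}

# One concentration step: from coefficients to the h smallest-residual
# observations to their OLS fit.
c_step <- function(y, X, beta, h) {
  beta[!is.finite(beta)] <- 0    # transient rank deficiency in a subset
  r2 <- (y - drop(X %*% beta))^2
  s <- sort.int(order(r2)[seq_len(h)])
  f <- stats::lm.fit(X[s, , drop = FALSE], y[s])
  co <- f$coefficients
  co[!is.finite(co)] <- 0
  list(coefficients = co, subset = s, objective = sum(f$residuals^2))
}

# FAST-LTS: seeded elemental starts, two C-steps each, then full C-step
# iteration to convergence on the best candidates.
lts_fast <- function(y, X, h, seed, n_starts, n_keep, max_csteps) {
  n <- length(y); m <- ncol(X)
  cands <- with_seed(seed, {
    out <- vector("list", n_starts)
    for (s in seq_len(n_starts)) {
      beta <- NULL
      for (try in 1:50) {
        el <- sample.int(n, m)
        f <- stats::lm.fit(X[el, , drop = FALSE], y[el])
        if (f$rank == m && all(is.finite(f$coefficients))) {
          beta <- f$coefficients; break
        }
      }
      if (is.null(beta)) next
      st <- list(coefficients = beta)
      for (k in 1:2) st <- c_step(y, X, st$coefficients, h)
      out[[s]] <- st
    }
    out[!vapply(out, is.null, logical(1))]
  })
  if (!length(cands)) stop("no full-rank elemental start found")
  objs <- vapply(cands, `[[`, numeric(1), "objective")
  keep <- order(objs)[seq_len(min(n_keep, length(cands)))]
  best <- NULL
  for (k in keep) {
    st <- cands[[k]]
    for (it in seq_len(max_csteps)) {
      nx <- c_step(y, X, st$coefficients, h)
      if (identical(nx$subset, st$subset)) { st <- nx; break }
      st <- nx
    }
    if (is.null(best) || st$objective < best$objective) best <- st
  }
  best
}

# Consistency factor making the raw LTS scale unbiased for the error sd under
# normality when the central fraction alpha = h/n is kept.
lts_consistency_factor <- function(alpha) {
  if (alpha >= 1) return(1)
  q <- stats::qnorm((1 + alpha) / 2)
  1 / sqrt(1 - 2 * q * stats::dnorm(q) / alpha)
}

#' Inference for an LTS fit via the reweighting step
#'
#' Standard errors, t-statistics and two-sided p-values come from an ordinary
#' least squares refit on the observations whose standardized raw-fit
#' residuals (raw LTS scale with its consistency factor) do not exceed 2.5 in
#' magnitude. The reweighted standard errors carry the usual truncation
#' consistency correction for the 2.5 cut. When `c = 1` nothing is trimmed
#' and the output reduces exactly to classical OLS inference.
#'
#' The asymptotic consistency factor underestimates the raw LTS scale at
#' small n, and the reweighting step selects observations using the (noisy)
#' raw fit, which overdisperses the resulting t-statistics. Both effects are
#' removed by the design-conditional Monte Carlo factors of
#' [lts_calibration()]: `scale_correction` multiplies the raw scale before
#' the 2.5 cut and `se_correction` multiplies the standard errors.
#' [fit_all_taxa()] estimates and applies them automatically; with the
#' default factors of 1 the inference is the plain reweighted-LTS recipe.
#'
#' @param fit an [lts_fit()] result.
#' @param y,X the response and design used for the fit.
#' @param scale_correction finite-sample multiplier for the raw scale
#'   (default 1; see [lts_calibration()]).
#' @param se_correction multiplier for the standard errors (default 1).
#' @return data.frame with one row per model term: `term`, `estimate`,
#'   `std_error`, `t`, `p_value`; attributes `h_used`, `n_retained`,
#'   `outlier_flags` (logical per observation, TRUE = excluded by the
#'   reweighting step), `sigma`.
#' @export
lts_inference <- function(fit, y, X, scale_correction = 1,
                          se_correction = 1) {
  X <- as.matrix(X)
  n <- fit$n; m <- fit$m
  if (fit$h == n) {          # pure OLS: no trimming, classical inference
    keep <- rep(TRUE, n)
    corr <- 1
    se_correction <- 1
  } else {
    sc <- fit$scale_raw * scale_correction
    tol <- 1e-8 * max(1, max(abs(y)))
    keep <- if (sc < tol) abs(fit$residuals) <= tol
            else abs(fit$residuals) / sc <= 2.5
    # truncation consistency for var of N(0,1) restricted to |z| <= 2.5
    a <- 2 * stats::pnorm(2.5) - 1
    corr <- 1 / sqrt((a - 2 * 2.5 * stats::dnorm(2.5)) / a)
  }
  n_keep <- sum(keep)
  if (n_keep < m + 2)
    stop("too few observations retained after reweighting (", n_keep,
         " for ", m, " terms)")
  f <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])
  if (f$rank < m) stop("rank-deficient design after reweighting")
  df_res <- n_keep - m
  rss <- sum(f$residuals^2)
  sigma <- sqrt(rss / df_res)
  XtXinv <- chol2inv(chol(crossprod(X[keep, , drop = FALSE])))
  est <- f$coefficients
  if (sigma <= 1e-12 * max(1, max(abs(y)))) {
    # degenerate exact fit: estimates are valid, sampling-based inference
    # is undefined; NA p-values exclude the taxon from FDR
    se <- rep(0, m)
    tval <- rep(NaN, m)
    pval <- rep(NA_real_, m)
  } else {
    se <- sigma * sqrt(diag(XtXinv)) * corr * se_correction
    tval <- est / se
    pval <- 2 * stats::pt(abs(tval), df = df_res, lower.tail = FALSE)
  }
  terms <- colnames(X); if (is.null(terms)) terms <- paste0("V", seq_len(m))
  out <- data.frame(term = terms, estimate = unname(est),
                    std_error = unname(se), t = unname(tval),
                    p_value = unname(pval), stringsAsFactors = FALSE)
  attr(out, "h_used") <- fit$h
  attr(out, "n_retained") <- n_keep
  attr(out, "outlier_flags") <- !keep
  attr(out, "sigma") <- sigma
  out
}

#' Design-conditional Monte Carlo calibration of reweighted-LTS inference
#'
#' Simulates standard-normal responses under the run's own design matrix,
#' fits them with the same LTS + reweighting recipe, and returns two
#' multiplicative factors: `scale_correction`, the finite-sample correction
#' for the raw LTS scale (the asymptotic consistency factor is biased low at
#' small n, which would trim good observations at the 2.5 cut), and
#' `se_correction`, the null overdispersion of the reweighted t-statistics
#' (the reweighting step keeps observations that agree with the noisy raw
#' fit, so uncorrected t-statistics are wider than Student's t). Because
#' every taxon in a run shares one design, a single calibration serves the
#' whole analysis. Deterministic given the seed. For `c = 1` (no trimming)
#' both factors are exactly 1.
#'
#' @param X design matrix of the analysis.
#' @param c trim proportion.
#' @param seed integer seed for the simulated responses and searches.
#' @param n_sims number of simulated null responses (default 200).
#' @param n_starts elemental starts per simulated fit (default 50; the raw
#'   scale is insensitive to search depth at these problem sizes).
#' @return list with `scale_correction`, `se_correction`, `n_sims`.
#' @export
lts_calibration <- function(X, c, seed = 1L, n_sims = 200L, n_starts = 50L) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  h <- min(n, max(m + 1, floor(c * n) + floor((m + 1) / 2)))
  if (h >= n)
    return(list(scale_correction = 1, se_correction = 1, n_sims = 0L))
  sims <- with_seed(seed, {
    lapply(seq_len(n_sims), function(k) {
      y <- stats::rnorm(n)
      list(y = y, fit = lts_fit(y, X, c = c, seed = child_seed(seed, k),
                                n_starts = n_starts))
    })
  })
  scale_correction <- 1 / mean(vapply(sims, function(s) s$fit$scale_raw,
                                      numeric(1)))
  tvals <- c(); dfs <- c()
  for (s in sims) {
    inf <- tryCatch(lts_inference(s$fit, s$y, X,
                                  scale_correction = scale_correction),
                    error = function(e) NULL)
    if (is.null(inf)) next
    tvals <- c(tvals, inf$t)
    dfs <- c(dfs, attr(inf, "n_retained") - m)
  }
  dbar <- mean(dfs)
  se_correction <- stats::sd(tvals) / sqrt(dbar / (dbar - 2))
  list(scale_correction = scale_correction,
       se_correction = max(se_correction, 1), n_sims = as.integer(n_sims))
}

#' Build the pseudo-value regression design matrix
#'
#' Intercept, a 0/1 indicator for the group variable (1 = `level_a`), and the
#' covariates. Categorical covariates with k levels expand to k - 1 indicator
#' terms against the first level in lexical order.
#'
#' @param meta aligned metadata data.frame.
#' @param group_var name of the binary grouping column.
#' @param level_a level coded 1 in the indicator.
#' @param covariates character vector of covariate column names.
#' @return numeric design matrix with named columns; the group term is named
#'   `group_var`.
#' @export
build_design <- function(meta, group_var, level_a, covariates = character()) {
  z <- as.integer(as.character(meta[[group_var]]) == level_a)
  X <- cbind("(Intercept)" = 1, z)
  colnames(X)[2] <- group_var
  for (v in covariates) {
    col <- meta[[v]]
    if (is.numeric(col)) {
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- v
    } else {
      f <- factor(as.character(col), levels = sort(unique(as.character(col))))
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, levels(f)[-1])
      X <- cbind(X, mm)
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    stop("design matrix rank-deficient; collinear term(s): ",
         paste(colnames(X)[dep], collapse = ", "))
  }
  X
}

#' Fit the pseudo-value regression for every taxon
#'
#' One LTS fit + reweighted inference per taxon, with a shared design matrix
#' and one shared [lts_calibration()] (computed once, applied to every
#' taxon). A taxon whose fit or inference fails is marked not-analyzable
#' (with the reason) and excluded from FDR, without aborting the run.
#'
#' @param pv pseudo-value matrix (samples x taxa), e.g. from
#'   [assemble_pseudovalues()].
#' @param X design matrix from [build_design()], row-aligned with `pv`.
#' @param c trim proportion (default 0.5).
#' @param seed seed for the randomized subset search and the calibration;
#'   the same seed is used for every taxon, so identical pseudo-value
#'   columns give identical results.
#' @param calibration optional precomputed [lts_calibration()] result;
#'   computed from `X`, `c` and `seed` when `NULL`.
#' @param ... forwarded to [lts_fit()] (e.g. `n_starts`).
#' @return list with `results` (named list of per-taxon inference tables),
#'   `failed` (named character vector of failure reasons), `terms`,
#'   `calibration`.
#' @export
fit_all_taxa <- function(pv, X, c = 0.5, seed = 1L, calibration = NULL, ...) {
  taxa <- colnames(pv)
  if (is.null(calibration))
    calibration <- lts_calibration(X, c, seed = child_seed(seed, 7919L))
  results <- vector("list", length(taxa)); names(results) <- taxa
  failed <- character(0)
  for (k in seq_along(taxa)) {
    res <- tryCatch({
      f <- lts_fit(pv[, k], X, c = c, seed = seed, ...)
      lts_inference(f, pv[, k], X,
                    scale_correction = calibration$scale_correction,
                    se_correction = calibration$se_correction)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[taxa[k]] <- conditionMessage(res)
      results[taxa[k]] <- list(NULL)
    } else {
      results[[taxa[k]]] <- res
    }
  }
  list(results = results, failed = failed, terms = colnames(X),
       calibration = calibration)
}
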