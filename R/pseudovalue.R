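#' Full-data and leave-one-out connectivities for one group
#'
#' Re-estimates the group's SparCC network once per leave-one-out subset and
#' converts each estimate to per-taxon connectivity. In the paired
#' `"difference"` mode the statistic is the connectivity of the
#' timepoint-2 minus timepoint-1 association-matrix difference, and the
#' leave-one-out unit is the subject: both of a subject's records are removed
#' together, since dropping a single timepoint record would break the pairing.
#'
#' @param counts_g [count_table] restricted to one group (rows are the
#'   group's samples; in difference mode, its timepoint-1 records, one row
#'   per subject).
#' @param config a [sparcc_config()].
#' @param counts_g_t2 optional [count_table] of the same subjects' timepoint-2
#'   records, row-aligned with `counts_g`; supplying it switches to
#'   difference mode.
#' @param normalize passed to [connectivity()].
#' @param n_cores number of worker processes for the leave-one-out loop
#'   (forked via \pkg{parallel}; results are independent of worker count).
#' @param seed seed forwarded to [sparcc()] (used only with resampling draws).
#' @return list with `theta_full` (named vector) and `theta_loo` (n_g x p
#'   matrix; row i from the data with unit i removed).
#' @export
loo_connectivities <- function(counts_g, config = sparcc_config(),
                               counts_g_t2 = NULL, normalize = FALSE,
                               n_cores = 1L, seed = 1L) {
  n_g <- nrow(counts_g)
  if (n_g < 4) stop("leave-one-out networks need at least 4 units; got ", n_g)
  if (!is.null(counts_g_t2)) {
    if (!identical(dim(counts_g), dim(counts_g_t2)))
      stop("timepoint tables must share subjects one-to-one")
    if (!identical(colnames(counts_g), colnames(counts_g_t2)))
      stop("timepoint tables must share the taxon set")
  }
  theta_of <- function(keep, stream) {
    t1 <- counts_g[keep, , drop = FALSE]
    class(t1) <- class(counts_g)
    a1 <- sparcc(t1, config, seed = child_seed(seed, 2L * stream))
    if (is.null(counts_g_t2)) return(connectivity(a1, normalize))
    t2 <- counts_g_t2[keep, , drop = FALSE]
    class(t2) <- class(counts_g_t2)
    a2 <- sparcc(t2, config, seed = child_seed(seed, 2L * stream + 1L))
    connectivity(difference_matrix(a2, a1), normalize)
  }
  theta_full <- theta_of(seq_len(n_g), 0L)
  one <- function(i) {
    tryCatch(theta_of(setdiff(seq_len(n_g), i), i),
             error = function(e)
               stop("SparCC failed with unit '", rownames(counts_g)[i],
                    "' removed: ", conditionMessage(e), call. = FALSE))
  }
  loo <- if (n_cores > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n_g), one, mc.cores = n_cores)
  } else {
    lapply(seq_len(n_g), one)
  }
  theta_loo <- do.call(rbind, loo)
  rownames(theta_loo) <- rownames(counts_g)
  list(theta_full = theta_full, theta_loo = theta_loo)
}

#' Tukey jackknife pseudo-values
#'
#' `theta_tilde[i, k] = n_g * theta_hat[k] - (n_g - 1) * theta_hat_loo[i, k]`.
#' Each pseudo-value quantifies the influence of unit i on taxon k's
#' connectivity; within a group their mean equals the jackknife estimate of
#' the connectivity, an algebraic identity used as a correctness check.
#'
#' @param theta_full named vector of full-data connectivities (length p).
#' @param theta_loo n_g x p matrix of leave-one-out connectivities.
#' @param n_g group size; must equal `nrow(theta_loo)`.
#' @return n_g x p matrix of pseudo-values.
#' @export
jackknife_pseudovalues <- function(theta_full, theta_loo, n_g) {
  if (n_g < 2) stop("jackknife needs at least 2 units")
  if (nrow(theta_loo) != n_g)
    stop("length mismatch: ", nrow(theta_loo), " leave-one-out vectors for ",
         "group size ", n_g)
  if (ncol(theta_loo) != length(theta_full))
    stop("taxon dimension mismatch between full and leave-one-out vectors")
  pv <- matrix(rep(n_g * theta_full, each = n_g), nrow = n_g) -
    (n_g - 1) * theta_loo
  dimnames(pv) <- dimnames(theta_loo)
  pv
}

#' Assemble the pseudo-value matrix for both groups
#'
#' Networks, connectivities and pseudo-values are computed per group — each
#' sample's pseudo-value comes from its own group's network and group size —
#' and the rows are stacked back into the original aligned sample order. This
#' per-group construction is what makes the regression coefficient on the
#' group indicator capture between-group connectivity differences.
#'
#' @param counts aligned [count_table] (in difference mode, the timepoint-1
#'   records, one row per subject in aligned subject order).
#' @param idx_a,idx_b integer row indices of the two groups (from
#'   [group_indices()]).
#' @param config a [sparcc_config()].
#' @param counts_t2 optional row-aligned timepoint-2 [count_table]
#'   (difference mode).
#' @param normalize passed to [connectivity()].
#' @param n_cores,seed see [loo_connectivities()].
#' @return object of class `pseudovalue_matrix`: the n x p pseudo-value
#'   matrix with attributes `group_sizes`, `theta_full` (per-group list) and
#'   `group` (per-row group label "A"/"B").
#' @export
assemble_pseudovalues <- function(counts, idx_a, idx_b,
                                  config = sparcc_config(),
                                  counts_t2 = NULL, normalize = FALSE,
                                  n_cores = 1L, seed = 1L) {
  stopifnot(length(intersect(idx_a, idx_b)) == 0)
  if (length(idx_a) < 4 || length(idx_b) < 4)
    stop("each group needs at least 4 units; got ",
         length(idx_a), " and ", length(idx_b))
  sub <- function(idx, x) {
    if (is.null(x)) return(NULL)
    y <- x[idx, , drop = FALSE]; class(y) <- class(x); y
  }
  block <- function(idx, stream) {
    lc <- loo_connectivities(sub(idx, counts), config,
                             counts_g_t2 = sub(idx, counts_t2),
                             normalize = normalize, n_cores = n_cores,
                             seed = child_seed(seed, stream))
    list(pv = jackknife_pseudovalues(lc$theta_full, lc$theta_loo,
                                     length(idx)),
         theta_full = lc$theta_full)
  }
  a <- block(idx_a, 1L)
  b <- block(idx_b, 2L)
  n <- length(idx_a) + length(idx_b)
  pv <- matrix(NA_real_, n, ncol(counts),
               dimnames = list(rep(NA_character_, n), colnames(counts)))
  pv[idx_a, ] <- a$pv
  pv[idx_b, ] <- b$pv
  rownames(pv)[idx_a] <- rownames(a$pv)
  rownames(pv)[idx_b] <- rownames(b$pv)
  grp <- character(n); grp[idx_a] <- "A"; grp[idx_b] <- "B"
  structure(pv,
            group_sizes = c(n_A = length(idx_a), n_B = length(idx_b)),
            theta_full = list(A = a$theta_full, B = b$theta_full),
            group = grp,
            class = c("pseudovalue_matrix", "matrix", "array"))
}

#' Write a pseudo-value matrix as TSV
#'
#' @param pv a `pseudovalue_matrix` (or any samples x taxa matrix).
#' @param path output file path.
#' @export
write_pseudovalues <- function(pv, path) {
  df <- data.frame(sample_id = rownames(pv), as.data.frame(unclass(pv)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
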