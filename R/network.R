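#' Per-taxon network connectivity
#'
#' The connectivity (degree centrality) of taxon k is the sum of absolute
#' off-diagonal associations in its row: `theta_hat[k] = sum_{j != k}
#' |a[k, j]|`. This is the per-taxon statistic whose jackknife pseudo-values
#' form the regression response. The unnormalized sum is the default; set
#' `normalize = TRUE` to divide by (p - 1), which only rescales the response
#' and leaves inference on the group contrast unchanged.
#'
#' @param assoc an [assoc_matrix] (correlation or difference kind).
#' @param normalize divide by (p - 1)? Default `FALSE`.
#' @return named numeric vector of non-negative connectivity scores, one per
#'   taxon.
#' @export
connectivity <- function(assoc, normalize = FALSE) {
  a <- abs(unclass(assoc))
  diag(a) <- 0
  theta <- rowSums(a)
  if (normalize) theta <- theta / (ncol(a) - 1)
  theta
}

#' Difference of two association matrices
#'
#' Entrywise `t2 - t1` over a shared taxon set, used by the paired
#' two-timepoint mode: connectivity of the difference matrix measures how
#' much a taxon's association profile changed between timepoints.
#'
#' @param assoc_t2,assoc_t1 [assoc_matrix] objects of kind `"correlation"`
#'   with identical taxon identifiers in identical order.
#' @return an [assoc_matrix] of kind `"difference"` (zero diagonal).
#' @export
difference_matrix <- function(assoc_t2, assoc_t1) {
  if (!identical(rownames(assoc_t2), rownames(assoc_t1))) {
    extra2 <- setdiff(rownames(assoc_t2), rownames(assoc_t1))
    extra1 <- setdiff(rownames(assoc_t1), rownames(assoc_t2))
    stop("taxon sets differ or are reordered; only in t2: {",
         paste(extra2, collapse = ", "), "}; only in t1: {",
         paste(extra1, collapse = ", "), "}")
  }
  if (!identical(attr(assoc_t2, "kind"), "correlation") ||
      !identical(attr(assoc_t1, "kind"), "correlation"))
    stop("difference_matrix expects two correlation-kind matrices")
  d <- unclass(assoc_t2) - unclass(assoc_t1)
  diag(d) <- 0
  assoc_matrix(d, taxon_ids = rownames(assoc_t2), kind = "difference")
}
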