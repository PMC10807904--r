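#' Storey q-values with optional fixed pi0
#'
#' Converts a vector of p-values into q-values
#' `q_i = min_{p_j >= p_i} pi0 * m * p_j / rank(p_j)`. With
#' `pi0_method = "fixed_one"` the null proportion is fixed at 1 and the
#' result is exactly the Benjamini-Hochberg adjusted p-value. With
#' `"smoother"` (the default) pi0 is estimated by fitting a cubic smoothing
#' spline to `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over the grid
#' lambda = 0.05, 0.10, ..., 0.95 and evaluating it at lambda = 0.95, clamped
#' to (0, 1]. The smoother is noisy below a few hundred tests; `fixed_one`
#' is the conservative fallback there.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param pi0_method `"smoother"` or `"fixed_one"`.
#' @return list of class `qvalue_result`: `p_value`, `q_value` (same order as
#'   input), `pi0`, `pi0_method`.
#' @references Storey JD (2002) A direct approach to false discovery rates.
#'   J R Stat Soc B 64:479-498.
#' @export
qvalues <- function(p, pi0_method = c("smoother", "fixed_one")) {
  pi0_method <- match.arg(pi0_method)
  if (length(p) < 1) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  pi0 <- if (pi0_method == "fixed_one") 1 else estimate_pi0_smoother(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / (m:1)         # descending p: rank m, m-1, ..., 1
  q <- pmin(1, cummin(q))[ro]
  structure(list(p_value = p, q_value = q, pi0 = pi0,
                 pi0_method = pi0_method),
            class = "qvalue_result")
}

# Smoother estimate of the null proportion, evaluated at lambda = 0.95.
estimate_pi0_smoother <- function(p) {
  m <- length(p)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = 0.95)$y
  min(max(pi0, 1 / m), 1)
}

#' Differentially connected taxa for one model term
#'
#' Taxa whose q-value for the given term does not exceed the threshold,
#' sorted by ascending q-value with ties broken by taxon identifier.
#'
#' @param result a `dcnet_result` (see [dcnet()]).
#' @param term model term to screen; defaults to the group indicator.
#' @param threshold q-value cut-off (default 0.05).
#' @return character vector of taxon identifiers (possibly empty), with the
#'   corresponding q-values as an attribute `q_value`.
#' @export
dc_taxa <- function(result, term = NULL, threshold = 0.05) {
  qtab <- qval(result)
  if (is.null(term)) term <- attr(result, "group_term")
  if (!term %in% colnames(qtab))
    stop("unknown term '", term, "'; available terms: ",
         paste(colnames(qtab), collapse = ", "))
  q <- qtab[, term]
  sel <- which(!is.na(q) & q <= threshold)
  ord <- sel[order(q[sel], rownames(qtab)[sel])]
  structure(rownames(qtab)[ord], q_value = unname(q[ord]))
}
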