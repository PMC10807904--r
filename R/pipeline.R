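#' Covariate-adjusted differential co-abundance network analysis
#'
#' End-to-end pseudo-value regression pipeline: (i) group-specific SparCC
#' association matrices and per-taxon connectivity; (ii) the same quantities
#' for each leave-one-out subset; (iii) jackknife pseudo-values; (iv) a
#' least trimmed squares regression of each taxon's pseudo-values on the
#' group indicator plus covariates; (v) q-values per model term and
#' differential-connectivity calls. A taxon is differentially connected (DC)
#' when the q-value of its group coefficient falls at or below the threshold:
#' the coefficient on the group indicator measures how much group membership
#' shifts a sample's influence on that taxon's connectivity, adjusting for
#' the covariates.
#'
#' In `mode = "two_timepoint"` the response is built from differences of
#' association matrices between the two timepoints within each group, so the
#' group coefficient contrasts the *change* of connectivity; metadata must be
#' in long format (one row per sample record) with subject and timepoint
#' columns, covariates taken from each subject's baseline record.
#'
#' @param counts a [count_table] (samples x taxa).
#' @param meta metadata data.frame with a `sample_id` column.
#' @param group_var name of the binary grouping column in `meta`.
#' @param covariates character vector of covariate column names (default
#'   none).
#' @param level_a group level coded 1 in the regression (default: first level
#'   in lexical order).
#' @param c LTS trim proportion in [0.5, 1]; default 0.5, the usual robust
#'   default; `c = 1` is ordinary least squares.
#' @param mode `"single"` (default) or `"two_timepoint"`.
#' @param subject_col,time_col,baseline two-timepoint mode: subject and
#'   timepoint column names and the baseline timepoint level.
#' @param config a [sparcc_config()]. The pipeline default disables the
#'   strong-pair exclusion iteration (`max_exclusion_rounds = 0`): the
#'   jackknife multiplies each leave-one-out perturbation by the group size,
#'   so the exclusion step's discrete pair-in/pair-out flips between
#'   leave-one-out subsets inject large spurious pseudo-value noise and
#'   inflate the false positive rate several-fold. For one-shot network
#'   estimation [sparcc()] keeps the classic iterative exclusion.
#' @param normalize normalize connectivity by (p - 1)? Default `FALSE`.
#' @param pi0_method q-value null-proportion method; see [qvalues()].
#'   `"auto"` (default) uses the Storey smoother when at least 100 taxa are
#'   analyzable and the conservative `"fixed_one"` (Benjamini-Hochberg)
#'   below that, where the smoother's pi0 estimate is too unstable to trust.
#' @param dc_threshold q-value cut-off for DC calls (default 0.05).
#' @param seed integer seed covering every randomized component.
#' @param n_cores workers for the leave-one-out loop.
#' @param verbose log per-stage progress to stderr.
#' @return object of class `dcnet_result`: a list with `pseudo_values`,
#'   `fits` (per-taxon inference tables), `tables` (taxa x terms matrices
#'   `estimate`, `std_error`, `t`, `p_value`, `q_value`), `failed_taxa`,
#'   `pi0` (per term), `dc` (DC taxa for the group term), `config` (full
#'   parameter snapshot sufficient to reproduce the run), `log`.
#' @seealso [pval()], [qval()], [coeff()], [stderrs()], [dc_taxa()],
#'   [dcnet_sweep()], [write_results()]
#' @export
dcnet <- function(counts, meta, group_var, covariates = character(),
                  level_a = NULL, c = 0.5,
                  mode = c("single", "two_timepoint"),
                  subject_col = NULL, time_col = NULL, baseline = NULL,
                  config = sparcc_config(max_exclusion_rounds = 0),
                  normalize = FALSE,
                  pi0_method = c("auto", "smoother", "fixed_one"),
                  dc_threshold = 0.05, seed = 1L, n_cores = 1L,
                  verbose = TRUE) {
  mode <- match.arg(mode)
  pi0_method <- match.arg(pi0_method)
  collector <- new.env(); collector$records <- list()
  t0 <- proc.time()[["elapsed"]]
  stage <- function(...) log_stage(..., collector = collector,
                                   verbose = verbose)

  if (mode == "two_timepoint") {
    if (is.null(subject_col) || is.null(time_col))
      stop("two_timepoint mode requires subject_col and time_col")
  }
  al <- align_samples(counts, meta, group_var, covariates,
                      subject_col = subject_col, time_col = time_col,
                      verbose = verbose)
  counts <- al$counts; meta <- al$meta
  stage("align", nrow(counts), " samples retained, ", al$n_dropped,
        " dropped")

  counts_t2 <- NULL
  if (mode == "two_timepoint") {
    tl <- sort(unique(as.character(meta[[time_col]])))
    if (is.null(baseline)) baseline <- tl[1]
    if (!baseline %in% tl)
      stop("baseline level '", baseline, "' not among timepoints: ",
           paste(tl, collapse = ", "))
    is_t1 <- as.character(meta[[time_col]]) == baseline
    meta_t1 <- meta[is_t1, , drop = FALSE]
    meta_t2 <- meta[!is_t1, , drop = FALSE]
    m2 <- match(meta_t1[[subject_col]], meta_t2[[subject_col]])
    c1 <- counts[is_t1, , drop = FALSE]
    c2 <- counts[!is_t1, , drop = FALSE][m2, , drop = FALSE]
    rownames(c1) <- rownames(c2) <- as.character(meta_t1[[subject_col]])
    class(c1) <- class(c2) <- class(counts)
    counts <- c1; counts_t2 <- c2
    meta <- meta_t1                     # covariates from the baseline record
    rownames(meta) <- NULL
    stage("pairing", nrow(counts), " subjects x 2 timepoints")
  }

  gi <- group_indices(meta, group_var, level_a)
  stage("groups", "n_A = ", length(gi$A), " ('", gi$level_a, "'), n_B = ",
        length(gi$B), " ('", gi$level_b, "')")

  pv <- assemble_pseudovalues(counts, gi$A, gi$B, config = config,
                              counts_t2 = counts_t2, normalize = normalize,
                              n_cores = n_cores, seed = seed)
  stage("pseudovalues", nrow(pv), " x ", ncol(pv),
        " jackknife pseudo-values (", length(gi$A) + length(gi$B) + 2,
        " SparCC network estimations per timepoint)")

  X <- build_design(meta, group_var, gi$level_a, covariates)
  fits <- fit_all_taxa(pv, X, c = c, seed = child_seed(seed, 999L))
  stage("calibration", "scale x ",
        signif(fits$calibration$scale_correction, 4), ", se x ",
        signif(fits$calibration$se_correction, 4), " (",
        fits$calibration$n_sims, " null simulations)")
  if (length(fits$failed))
    stage("regression", length(fits$failed), " taxa not analyzable: ",
          paste(names(fits$failed), collapse = ", "))
  stage("regression", sum(!vapply(fits$results, is.null, logical(1))),
        " taxa fitted by LTS (c = ", c, ", h = ",
        floor(c * nrow(pv)) + floor((ncol(X) + 1) / 2), ")")

  ok <- !vapply(fits$results, is.null, logical(1))
  taxa_ok <- names(fits$results)[ok]
  terms <- fits$terms
  make_tab <- function(field) {
    tab <- matrix(NA_real_, length(taxa_ok), length(terms),
                  dimnames = list(taxa_ok, terms))
    for (tx in taxa_ok) tab[tx, ] <- fits$results[[tx]][[field]]
    tab
  }
  tables <- list(estimate = make_tab("estimate"),
                 std_error = make_tab("std_error"),
                 t = make_tab("t"),
                 p_value = make_tab("p_value"))
  qtab <- tables$p_value * NA
  pi0 <- stats::setNames(rep(NA_real_, length(terms)), terms)
  if (pi0_method == "auto")
    pi0_method <- if (sum(ok) >= 100) "smoother" else "fixed_one"
  for (tm in terms) {
    idx <- !is.na(tables$p_value[, tm])
    if (!any(idx)) next        # degenerate: no analyzable p-values
    qr_ <- qvalues(tables$p_value[idx, tm], pi0_method = pi0_method)
    qtab[idx, tm] <- qr_$q_value
    pi0[tm] <- qr_$pi0
  }
  tables$q_value <- qtab
  stage("fdr", "pi0(", group_var, ") = ", signif(pi0[group_var], 3),
        " [", pi0_method, "]")

  cfg <- list(group_var = group_var, covariates = covariates,
              level_a = gi$level_a, level_b = gi$level_b, c = c, mode = mode,
              subject_col = subject_col, time_col = time_col,
              baseline = baseline, sparcc = unclass(config),
              normalize = normalize, pi0_method = pi0_method,
              dc_threshold = dc_threshold, seed = seed,
              n_A = length(gi$A), n_B = length(gi$B), p = ncol(pv))
  res <- structure(list(pseudo_values = pv, fits = fits$results,
                        tables = tables, failed_taxa = fits$failed,
                        pi0 = pi0, calibration = fits$calibration,
                        config = cfg, log = collector$records),
                   group_term = group_var,
                   class = "dcnet_result")
  res$dc <- dc_taxa(res, term = group_var, threshold = dc_threshold)
  stage("done", length(res$dc), " DC taxa at q <= ", dc_threshold, " (",
        round(proc.time()[["elapsed"]] - t0, 1), " s)")
  res
}

#' @export
print.dcnet_result <- function(x, ...) {
  cfg <- x$config
  cat("dcnet_result: ", cfg$n_A + cfg$n_B, " samples (",
      cfg$n_A, " '", cfg$level_a, "' vs ", cfg$n_B, " '", cfg$level_b,
      "'), ", cfg$p, " taxa, mode ", cfg$mode, "\n", sep = "")
  cat("  terms: ", paste(colnames(x$tables$estimate), collapse = ", "),
      "\n", sep = "")
  cat("  DC taxa (", cfg$group_var, ", q <= ", cfg$dc_threshold, "): ",
      if (length(x$dc)) paste(x$dc, collapse = ", ") else "none",
      "\n", sep = "")
  if (length(x$failed_taxa))
    cat("  not analyzable: ", paste(names(x$failed_taxa), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

result_table <- function(result, field, variable = NULL) {
  tab <- result$tables[[field]]
  if (is.null(variable)) return(tab)
  if (!variable %in% colnames(tab))
    stop("unknown variable '", variable, "'; available terms: ",
         paste(colnames(tab), collapse = ", "))
  stats::setNames(tab[, variable], rownames(tab))
}

#' Accessors for per-taxon regression results
#'
#' Retrieve the taxa x terms table of p-values, q-values, coefficient
#' estimates or standard errors from a [dcnet()] result — or a single named
#' vector for one variable of interest.
#'
#' @param result a `dcnet_result`.
#' @param variable optional model term name; when given, a named vector over
#'   taxa is returned instead of the full table.
#' @return numeric matrix (taxa x terms) or named vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
pval <- function(result, variable = NULL)
  result_table(result, "p_value", variable)

#' @rdname accessors
#' @export
qval <- function(result, variable = NULL)
  result_table(result, "q_value", variable)

#' @rdname accessors
#' @export
coeff <- function(result, variable = NULL)
  result_table(result, "estimate", variable)

#' @rdname accessors
#' @export
stderrs <- function(result, variable = NULL)
  result_table(result, "std_error", variable)

#' Sensitivity of DC calls to the trimming proportion
#'
#' Re-runs the full analysis for each trim proportion in `c_grid` and
#' tabulates the DC sets and their pairwise Jaccard overlap, the standard
#' check that conclusions are robust to the choice of c.
#'
#' @param counts,meta,group_var,covariates,... forwarded to [dcnet()].
#' @param c_grid numeric vector of trim proportions within [0.5, 1].
#' @return list of class `dcnet_sweep`: `runs` (named list of
#'   `dcnet_result`), `dc_table` (data.frame with columns `c`, `taxon`,
#'   `q_value`), `jaccard` (matrix of pairwise DC-set overlaps).
#' @export
dcnet_sweep <- function(counts, meta, group_var, covariates = character(),
                        c_grid = c(0.5, 0.75, 1.0), ...) {
  if (any(c_grid < 0.5 | c_grid > 1))
    stop("all c_grid values must lie in [0.5, 1]")
  runs <- lapply(c_grid, function(cc)
    dcnet(counts, meta, group_var, covariates, c = cc, ...))
  names(runs) <- paste0("c=", c_grid)
  dc_sets <- lapply(runs, function(r) as.character(r$dc))
  rows <- do.call(rbind, lapply(seq_along(c_grid), function(i) {
    dc <- runs[[i]]$dc
    if (!length(dc)) return(NULL)
    data.frame(c = c_grid[i], taxon = as.character(dc),
               q_value = attr(dc, "q_value"), stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(c = numeric(0), taxon = character(0),
                       q_value = numeric(0))
  k <- length(c_grid)
  jac <- matrix(NA_real_, k, k,
                dimnames = list(names(runs), names(runs)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    u <- union(dc_sets[[i]], dc_sets[[j]])
    jac[i, j] <- if (!length(u)) 1 else
      length(intersect(dc_sets[[i]], dc_sets[[j]])) / length(u)
  }
  structure(list(runs = runs, dc_table = rows, jaccard = jac,
                 c_grid = c_grid),
            class = "dcnet_sweep")
}

#' Write analysis outputs to a directory
#'
#' Writes `results.tsv` (one row per taxon-term pair: estimate, std_error,
#' t, p_value, q_value, dc_flag), `pseudovalues.tsv`, and `config.json`
#' (the exact parameter snapshot of the run).
#'
#' @param result a `dcnet_result`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tb <- result$tables
  dc <- as.character(result$dc)
  grp <- attr(result, "group_term")
  rows <- do.call(rbind, lapply(rownames(tb$estimate), function(tx) {
    data.frame(taxon = tx, term = colnames(tb$estimate),
               estimate = tb$estimate[tx, ],
               std_error = tb$std_error[tx, ],
               t = tb$t[tx, ], p_value = tb$p_value[tx, ],
               q_value = tb$q_value[tx, ],
               dc_flag = colnames(tb$estimate) == grp & tx %in% dc,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file.path(dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_pseudovalues(result$pseudo_values, file.path(dir, "pseudovalues.tsv"))
  jsonlite::write_json(result$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(dir)
}
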