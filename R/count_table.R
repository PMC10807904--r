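#' Construct and validate a taxa-abundance count table
#'
#' The canonical container for microbiome abundance data in dcnet is a
#' samples-by-taxa matrix of non-negative integer counts with unique sample
#' and taxon identifiers. All downstream estimation (SparCC association
#' matrices, connectivity, pseudo-values) consumes this orientation.
#'
#' @param counts numeric matrix (or data.frame coercible to one), one row per
#'   sample and one column per taxon. Values must be non-negative and
#'   integer-valued.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(counts)`.
#' @param taxon_ids character vector of unique taxon identifiers; defaults to
#'   `colnames(counts)`.
#' @return An object of class `count_table`: the validated integer matrix with
#'   dimnames set.
#' @details At least 4 taxa are required: the SparCC basis-variance linear
#'   system is degenerate below that. Samples whose total count is zero are
#'   rejected (their compositional fractions are undefined) rather than
#'   imputed.
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        taxon_ids = colnames(counts)) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix or data.frame")
  n <- nrow(counts); p <- ncol(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(p))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != n) stop("length(sample_ids) != nrow(counts)")
  if (length(taxon_ids) != p) stop("length(taxon_ids) != ncol(counts)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon identifiers: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (p < 4)
    stop("at least 4 taxa are required (SparCC basis solve is degenerate ",
         "for fewer); got ", p)
  if (anyNA(counts)) {
    idx <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop("missing count at sample '", sample_ids[idx[1]], "', taxon '",
         taxon_ids[idx[2]], "'")
  }
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count (", counts[idx[1], idx[2]], ") at sample '",
         sample_ids[idx[1]], "', taxon '", taxon_ids[idx[2]], "'")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    idx <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("non-integer count (", counts[idx[1], idx[2]], ") at sample '",
         sample_ids[idx[1]], "', taxon '", taxon_ids[idx[2]], "'")
  }
  counts <- round(counts)
  storage.mode(counts) <- "double"
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("zero-depth sample(s) rejected: ",
         paste(sample_ids[rs == 0], collapse = ", "))
  dimnames(counts) <- list(sample_ids, taxon_ids)
  class(counts) <- c("count_table", "matrix", "array")
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x), " samples x ", ncol(x), " taxa; ",
      "median depth ", stats::median(rowSums(x)), "; ",
      round(100 * mean(x == 0), 1), "% zero cells\n", sep = "")
  invisible(x)
}

#' Read a count table from delimited text
#'
#' Reads a TSV/CSV abundance table with one header row and one identifier
#' column, in either on-disk orientation, and returns the canonical
#' samples-by-taxa [count_table]. Accepting both orientations behind an
#' explicit flag removes silent transposition bugs: abundance files in the
#' wild are written both ways.
#'
#' @param path path to a delimited text file. Delimiter is inferred from the
#'   extension (`.csv` is comma; anything else tab) unless `sep` is given.
#' @param orientation `"samples_by_taxa"` if rows are samples,
#'   `"taxa_by_samples"` if rows are taxa (the table is transposed on read).
#' @param id_col column (index or name) holding row identifiers; default the
#'   first column.
#' @param sep field separator override.
#' @return A [count_table] in samples-by-taxa orientation.
#' @export
read_count_table <- function(path,
                             orientation = c("samples_by_taxa",
                                             "taxa_by_samples"),
                             id_col = 1L, sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (is.character(id_col)) {
    if (!id_col %in% names(df)) stop("identifier column '", id_col,
                                     "' not found in ", path)
    id_col <- match(id_col, names(df))
  }
  ids <- as.character(df[[id_col]])
  df <- df[, -id_col, drop = FALSE]
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn) && !anyNA(v)) {
        bad <- which(is.na(vn))[1]
        stop("non-numeric cell '", v[bad], "' at row '", ids[bad],
             "', column '", names(df)[j], "' in ", path)
      }
      df[[j]] <- vn
    }
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  if (orientation == "taxa_by_samples") m <- t(m)
  count_table(m)
}

#' Write a count table to tab-delimited text
#'
#' Writes in the canonical samples-by-taxa orientation with the identifier
#' column named `sample_id`. Integer data round-trips exactly through
#' [read_count_table()].
#'
#' @param x a [count_table].
#' @param path output file path.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path delimited text file with one header row; delimiter inferred
#'   from the extension as in [read_count_table()].
#' @param sample_col column holding sample identifiers (index or name;
#'   default first column). The column is renamed to `sample_id`.
#' @param sep field separator override.
#' @return data.frame with a `sample_id` character column first.
#' @export
read_metadata <- function(path, sample_col = 1L, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", na.strings = c("NA", ""))
  if (is.character(sample_col)) sample_col <- match(sample_col, names(df))
  if (is.na(sample_col) || sample_col > ncol(df))
    stop("sample identifier column not found in ", path)
  ids <- as.character(df[[sample_col]])
  if (anyDuplicated(ids))
    stop("duplicate sample identifiers in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[, -sample_col, drop = FALSE]
  cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE), df)
}

#' Align a count table with sample metadata
#'
#' Restricts both inputs to their common samples (complete cases on the model
#' variables), in the count table's sample order. Samples present in only one
#' input, or carrying a missing group/covariate value, are dropped with a
#' logged count.
#'
#' @param counts a [count_table].
#' @param meta data.frame with a `sample_id` column (see [read_metadata()]).
#' @param group_var name of the binary grouping column in `meta`.
#' @param covariates character vector of covariate column names (may be
#'   empty). Only these columns and `group_var` (plus `subject_col`/
#'   `time_col` if given) are screened for missingness.
#' @param subject_col,time_col optional column names for the paired
#'   two-timepoint mode; when given, every retained subject must appear
#'   exactly once per timepoint.
#' @param min_group_size smallest group size tolerated after alignment
#'   (default 4: the jackknife needs several leave-one-out networks and
#'   SparCC needs more for stability).
#' @param verbose emit a message with the number of samples dropped.
#' @return list with elements `counts` (aligned [count_table]), `meta`
#'   (aligned data.frame, same row order) and `n_dropped`.
#' @export
align_samples <- function(counts, meta, group_var, covariates = character(),
                          subject_col = NULL, time_col = NULL,
                          min_group_size = 4L, verbose = TRUE) {
  stopifnot(inherits(counts, "count_table"))
  if (!"sample_id" %in% names(meta)) stop("metadata lacks a sample_id column")
  need <- c(group_var, covariates, subject_col, time_col)
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  n_total <- nrow(counts)
  keep_ids <- intersect(rownames(counts), meta$sample_id)
  if (length(keep_ids) == 0) stop("no samples shared between counts and metadata")
  meta2 <- meta[match(keep_ids, meta$sample_id), , drop = FALSE]
  cc <- stats::complete.cases(meta2[, need, drop = FALSE])
  keep_ids <- keep_ids[cc]
  n_dropped <- n_total - length(keep_ids)
  if (length(keep_ids) == 0) stop("no samples remain after dropping missing values")
  counts2 <- counts[keep_ids, , drop = FALSE]
  class(counts2) <- class(counts)
  meta2 <- meta[match(keep_ids, meta$sample_id), , drop = FALSE]
  rownames(meta2) <- NULL
  g <- meta2[[group_var]]
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2)
    stop("grouping variable '", group_var, "' must have exactly two levels ",
         "after alignment; observed: ", paste(lev, collapse = ", "))
  if (is.null(time_col)) {
    tab <- table(as.character(g))
    if (any(tab < min_group_size))
      stop("group level(s) with fewer than ", min_group_size,
           " samples after alignment: ",
           paste(names(tab)[tab < min_group_size], collapse = ", "))
  } else {
    st <- table(as.character(meta2[[subject_col]]),
                as.character(meta2[[time_col]]))
    if (ncol(st) != 2)
      stop("timepoint column '", time_col, "' must have exactly two levels; ",
           "observed: ", paste(colnames(st), collapse = ", "))
    bad <- rownames(st)[apply(st, 1, function(r) any(r != 1))]
    if (length(bad))
      stop("subject(s) not appearing exactly once per timepoint: ",
           paste(bad, collapse = ", "))
  }
  if (verbose && n_dropped > 0)
    message("align_samples: dropped ", n_dropped,
            " sample(s) (unmatched or missing model variables)")
  list(counts = counts2, meta = meta2, n_dropped = n_dropped)
}

#' Partition aligned samples by the binary grouping variable
#'
#' @param meta aligned metadata (see [align_samples()]).
#' @param group_var name of the binary grouping column.
#' @param level_a the level defining group A; defaults to the first level in
#'   lexical order.
#' @return list with integer index vectors `A` and `B` (1-based positions in
#'   the aligned sample order), and `level_a`/`level_b`.
#' @export
group_indices <- function(meta, group_var, level_a = NULL) {
  g <- as.character(meta[[group_var]])
  lev <- sort(unique(g[!is.na(g)]))
  if (length(lev) != 2)
    stop("'", group_var, "' is not binary; observed levels: ",
         paste(lev, collapse = ", "))
  if (is.null(level_a)) level_a <- lev[1]
  if (!level_a %in% lev)
    stop("level '", level_a, "' not observed; observed levels: ",
         paste(lev, collapse = ", "))
  list(A = which(g == level_a), B = which(g != level_a),
       level_a = level_a, level_b = setdiff(lev, level_a))
}
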