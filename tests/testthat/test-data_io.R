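test_that("count table reader canonicalizes both on-disk orientations", {
  x <- matrix(1:20, nrow = 4, byrow = TRUE,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:5)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(taxon = rownames(x), x), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  ct <- read_count_table(f, orientation = "taxa_by_samples")
  expect_equal(dim(ct), c(5, 4))
  expect_equal(rownames(ct), paste0("s", 1:5))
  expect_equal(unname(unclass(ct)), unname(t(x)))
})

test_that("integer count tables round-trip through write/read exactly", {
  ct <- tiny_counts(n = 6, p = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, f)
  ct2 <- read_count_table(f)
  expect_identical(unclass(ct2), unclass(ct))
})

test_that("validation errors name the offending cell", {
  m <- matrix(5, 4, 4, dimnames = list(paste0("s", 1:4), paste0("t", 1:4)))
  m[2, 3] <- -2
  expect_error(count_table(m), "negative count.*s2.*t3")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,t1,t2,t3,t4", "s1,1,2,3,4", "s2,1,oops,3,4"), f)
  expect_error(read_count_table(f), "non-numeric cell 'oops'.*s2.*t2")
  m2 <- matrix(5, 4, 4, dimnames = list(c("a", "a", "b", "c"), paste0("t", 1:4)))
  expect_error(count_table(m2), "duplicate sample identifiers")
  expect_error(count_table(matrix(1, 5, 3)), "at least 4 taxa")
  m3 <- matrix(c(0, rep(2, 15)), 4, 4, byrow = TRUE)
  m3[1, ] <- 0
  expect_error(count_table(m3), "zero-depth")
})

test_that("packaged fixture row sums match an independent text parse", {
  f <- extdata("synthetic_counts_50x30.tsv")
  ct <- read_count_table(f)
  expect_equal(dim(ct), c(50, 30))
  # independent oracle: raw line parsing, no read.table
  lines <- readLines(f)[-1]
  vals <- lapply(strsplit(lines, "\t"), function(x) as.numeric(x[-1]))
  oracle_sums <- vapply(vals, sum, numeric(1))
  expect_equal(unname(rowSums(ct)), oracle_sums)
})

test_that("alignment intersects, preserves count order, and is idempotent", {
  ct <- tiny_counts(n = 8, p = 5)
  meta <- data.frame(sample_id = rev(rownames(ct)),
                     grp = rep(c("x", "y"), 4),
                     age = rnorm(8), stringsAsFactors = FALSE)
  al <- align_samples(ct, meta, "grp", "age", verbose = FALSE)
  expect_equal(rownames(al$counts), rownames(ct))
  expect_equal(al$meta$sample_id, rownames(ct))
  expect_equal(al$n_dropped, 0)
  al2 <- align_samples(al$counts, al$meta, "grp", "age", verbose = FALSE)
  expect_identical(unclass(al2$counts), unclass(al$counts))
  expect_identical(al2$meta, al$meta)
})

test_that("unmatched and incomplete samples are dropped with a count", {
  ct <- tiny_counts(n = 10, p = 5)
  meta <- data.frame(sample_id = rownames(ct)[1:8],
                     grp = rep(c("x", "y"), 4),
                     age = c(rnorm(7), NA), stringsAsFactors = FALSE)
  expect_message(
    al <- align_samples(ct, meta, "grp", "age", min_group_size = 2),
    "dropped 3 sample")
  expect_equal(nrow(al$counts), 7)
  expect_equal(al$n_dropped, 3)
  # without covariate screening the NA-age sample survives
  al2 <- align_samples(ct, meta, "grp", verbose = FALSE)
  expect_equal(nrow(al2$counts), 8)
})

test_that("fixture metadata with one missing covariate drops that sample", {
  ct <- read_count_table(extdata("synthetic_counts_50x30.tsv"))
  meta <- read_metadata(extdata("synthetic_meta_missing10.tsv"))
  # hand count of the 10-row fixture: one NA age -> 9 survivors
  al <- suppressMessages(align_samples(ct, meta, "pet", "age",
                                       min_group_size = 2))
  expect_equal(nrow(al$counts), 9)
  expect_false("S022" %in% rownames(al$counts))
})

test_that("alignment enforces group contracts", {
  ct <- tiny_counts(n = 8, p = 5)
  meta <- data.frame(sample_id = rownames(ct), grp = "only_one",
                     stringsAsFactors = FALSE)
  expect_error(align_samples(ct, meta, "grp", verbose = FALSE),
               "exactly two levels")
  meta$grp <- c(rep("x", 6), "y", "y")
  expect_error(align_samples(ct, meta, "grp", verbose = FALSE),
               "fewer than 4")
  meta2 <- data.frame(sample_id = paste0("zz", 1:8), grp = rep(c("x", "y"), 4))
  expect_error(align_samples(ct, meta2, "grp", verbose = FALSE),
               "no samples shared")
})

test_that("group indices partition the aligned samples", {
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     g = c("a", "a", "b", "b", "a", "b"))
  gi <- group_indices(meta, "g", level_a = "a")
  expect_equal(gi$A, c(1, 2, 5))
  expect_equal(gi$B, c(3, 4, 6))
  expect_length(intersect(gi$A, gi$B), 0)
  expect_setequal(union(gi$A, gi$B), 1:6)
  expect_error(group_indices(meta, "g", level_a = "zzz"),
               "not observed.*a, b")
  meta$g <- "a"
  expect_error(group_indices(meta, "g"), "not binary")
})

test_that("fixture group tally matches the packaged metadata", {
  meta <- read_metadata(extdata("synthetic_meta_50.tsv"))
  gi <- group_indices(meta, "pet", level_a = "dog")
  expect_length(gi$A, 23)
  expect_length(gi$B, 27)
})
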