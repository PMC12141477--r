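test_that("count table round trip is lossless and validated", {
  lib <- tiny_library(3, 1)
  meta <- tiny_meta(mice = "M1", tissues = c("primary", "lung_met"))
  counts <- matrix(c(10L, 0L, 5L, 7L, 3L, 12L), nrow = 3,
                   dimnames = list(lib$sgrna, meta$sample_id))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(counts, lib, path)
  back <- read_count_table(path, lib, meta)
  expect_identical(back, counts)
  expect_equal(dim(back), c(3L, 2L))
})

test_that("malformed count tables are rejected with informative errors", {
  lib <- tiny_library(3, 1)
  meta <- tiny_meta(mice = "M1", tissues = c("primary", "lung_met"))
  write_tsv <- function(df) {
    p <- tempfile(fileext = ".tsv")
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  base <- data.frame(sgRNA = lib$sgrna, gene = lib$gene,
                     a = c(1L, 2L, 3L), b = c(4L, 5L, 6L),
                     check.names = FALSE)
  names(base)[3:4] <- meta$sample_id

  neg <- base; neg[[3]][2] <- -1
  expect_error(read_count_table(write_tsv(neg), lib, meta), "line 3")

  frac <- base; frac[[4]][1] <- "2.5"
  expect_error(read_count_table(write_tsv(frac), lib, meta),
               "non-integer|negative")

  wrong_gene <- base; wrong_gene$gene[2] <- "OTHER"
  expect_error(read_count_table(write_tsv(wrong_gene), lib, meta),
               base$sgRNA[2], fixed = TRUE)

  unknown <- base; unknown$sgRNA[1] <- "NOT_IN_LIB"
  expect_error(read_count_table(write_tsv(unknown), lib, meta), "NOT_IN_LIB")

  bad_sample <- base; names(bad_sample)[3] <- "mystery_sample"
  expect_error(read_count_table(write_tsv(bad_sample), lib, meta),
               "mystery_sample")
})

test_that("median-of-ratios size factors match a hand computation", {
  counts <- matrix(c(10, 10, 10, 100, 20, 20, 20, 200), ncol = 2,
                   dimnames = list(paste0("sg", 1:4), c("A", "B")))
  nc <- median_ratio_normalize(counts)
  # direct median-of-ratios arithmetic: geometric means then column medians
  geo <- apply(counts, 1, function(r) exp(mean(log(r))))
  sf_oracle <- apply(counts, 2, function(col) median(col / geo))
  expect_equal(unname(nc$size_factor), unname(sf_oracle))
  expect_equal(unname(nc$size_factor[["B"]] / nc$size_factor[["A"]]), 2)
  expect_equal(nc$method, "median_ratio")

  # symmetry: identical columns get identical size factors
  same <- median_ratio_normalize(counts[, c(1, 1)] + 0)
  expect_equal(unname(same$size_factor[1]), unname(same$size_factor[2]))
})

test_that("normalization is scale-equivariant", {
  set.seed(3)
  counts <- matrix(rpois(300, 50), ncol = 3,
                   dimnames = list(paste0("sg", 1:100), c("A", "B", "C")))
  nc <- median_ratio_normalize(counts)
  scaled <- counts
  scaled[, "B"] <- scaled[, "B"] * 5L
  nc2 <- median_ratio_normalize(scaled)
  # size factors are defined up to a common constant (the geometric-mean
  # reference absorbs 5^(1/3)); the equivariance is exact on ratios, and
  # normalized values change only by that shared constant
  expect_equal(nc2$size_factor[["B"]] / nc2$size_factor[["A"]],
               5 * nc$size_factor[["B"]] / nc$size_factor[["A"]])
  expect_equal(nc2$norm, nc$norm * 5^(1 / 3))
})

test_that("normalization falls back to total counts when no sgRNA is all-positive", {
  counts <- matrix(c(0L, 5L, 8L, 0L), ncol = 2,
                   dimnames = list(c("sg1", "sg2"), c("A", "B")))
  expect_warning(nc <- median_ratio_normalize(counts), "total-count")
  expect_equal(nc$method, "total_count")
  expect_true(all(nc$size_factor > 0))
  expect_equal(unname(nc$size_factor), c(5, 8) / mean(c(5, 8)))
})

test_that("gene report has the exact dialect, is rank-sorted and round-trips", {
  genes <- c("GB", "GA")
  res <- fake_gene_result(genes, neg_p = c(0.2, 0.01), pos_p = c(0.5, 0.9))
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_report(res, path)
  header <- readLines(path, n = 1)
  expect_identical(header, paste(c("id", "num", "neg|score", "neg|p-value",
                                   "neg|fdr", "neg|rank", "pos|score",
                                   "pos|p-value", "pos|fdr", "pos|rank"),
                                 collapse = "\t"))
  back <- read_gene_report(path)
  expect_equal(nrow(back), 2)
  expect_identical(back$neg_rank, c(1L, 2L))   # sorted by neg|rank
  ord <- match(res$gene, back$gene)
  for (col in c("neg_p", "neg_fdr", "pos_p", "pos_fdr", "neg_rank",
                "pos_rank", "n_sgrna"))
    expect_equal(back[[col]][ord], res[[col]], info = col)
  expect_error(write_gene_report(res[setdiff(names(res), "pos_fdr")], path),
               "pos_fdr")
})

test_that("sample metadata YAML reads and validates", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("samples:",
               "  CL_M1_primary: {cell_line: CL, mouse: M1, tissue: primary}",
               "  CL_M1_lung_met: {cell_line: CL, mouse: M1, tissue: lung_met}"),
             path)
  meta <- read_sample_meta(path)
  expect_equal(nrow(meta), 2)
  expect_setequal(meta$tissue, c("primary", "lung_met"))

  writeLines(c("samples:",
               "  s1: {cell_line: CL, mouse: M1, tissue: spleen}"), path)
  expect_error(read_sample_meta(path), "spleen")
})

test_that("library validation enforces unique sgRNA ids", {
  lib <- tiny_library()
  expect_silent(validate_library(lib))
  dup <- rbind(lib, lib[1, ])
  expect_error(validate_library(dup), "duplicated")
})
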