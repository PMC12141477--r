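#' Read an sgRNA library annotation
#'
#' The library maps every sgRNA to exactly one gene, mirroring the layout of
#' genome-wide knockout libraries such as GeCKOv2 (several sgRNAs per gene).
#'
#' @param path Tab-separated file with header columns `sgrna`, `gene` and an
#'   optional `sequence` column. The header is matched case-insensitively and
#'   `sgRNA` is accepted for `sgrna`.
#' @return A data frame with columns `sgrna`, `gene` (and `sequence` when
#'   present), validated by [validate_library()].
#' @export
read_sgrna_library <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("sgrna", "gene") %in% names(df)))
    stop("library file must have columns 'sgrna' and 'gene': ", path)
  keep <- intersect(c("sgrna", "gene", "sequence"), names(df))
  validate_library(df[keep])
}

#' Validate an sgRNA library data frame
#'
#' @param library Data frame with columns `sgrna` and `gene`.
#' @return The library, invisibly unchanged, or an error describing the first
#'   violated invariant (duplicate sgRNA ids, missing values).
#' @export
validate_library <- function(library) {
  stopifnot(is.data.frame(library))
  if (!all(c("sgrna", "gene") %in% names(library)))
    stop("library must have columns 'sgrna' and 'gene'")
  if (anyNA(library$sgrna) || anyNA(library$gene))
    stop("library contains missing sgRNA or gene ids")
  dup <- library$sgrna[duplicated(library$sgrna)]
  if (length(dup) > 0)
    stop("duplicated sgRNA ids in library: ", paste(utils::head(dup, 5), collapse = ", "))
  library$sgrna <- as.character(library$sgrna)
  library$gene <- as.character(library$gene)
  library
}

#' Tissues recognised in sample metadata
#' @keywords internal
TISSUES <- c("primary", "lung_met", "liver_met", "plasmid")

#' Read sample metadata from YAML
#'
#' Metadata lives outside the count file: a YAML map from sample id to its
#' cell line, mouse and tissue, e.g.
#' ```yaml
#' samples:
#'   KIDNEY1_M1_primary: {cell_line: KIDNEY1, mouse: M1, tissue: primary}
#' ```
#'
#' @param path YAML file as above.
#' @return Data frame with columns `sample_id`, `cell_line`, `mouse_id`,
#'   `tissue`; tissue must be one of `primary`, `lung_met`, `liver_met`,
#'   `plasmid`.
#' @export
read_sample_meta <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$samples)) stop("metadata YAML must have a top-level 'samples' map")
  rows <- lapply(names(y$samples), function(id) {
    s <- y$samples[[id]]
    data.frame(sample_id = id,
               cell_line = as.character(s$cell_line),
               mouse_id = as.character(s$mouse),
               tissue = as.character(s$tissue),
               stringsAsFactors = FALSE)
  })
  validate_sample_meta(do.call(rbind, rows))
}

#' @rdname read_sample_meta
#' @param meta Data frame with columns `sample_id`, `cell_line`, `mouse_id`,
#'   `tissue`.
#' @export
validate_sample_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  need <- c("sample_id", "cell_line", "mouse_id", "tissue")
  if (!all(need %in% names(meta)))
    stop("sample metadata must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample ids in metadata")
  bad <- setdiff(unique(meta$tissue), TISSUES)
  if (length(bad) > 0)
    stop("unknown tissue(s) in metadata: ", paste(bad, collapse = ", "),
         " (expected ", paste(TISSUES, collapse = ", "), ")")
  key <- paste(meta$cell_line, meta$mouse_id, meta$tissue)
  if (anyDuplicated(key))
    stop("(cell_line, mouse, tissue) must identify a sample uniquely")
  meta
}

#' Read an sgRNA count table
#'
#' Reads a MAGeCK-count style TSV (`sgRNA`, `gene`, then one integer column
#' per sample) and validates it against the library and the sample metadata.
#'
#' @param path Tab-separated count file.
#' @param library sgRNA library data frame (see [read_sgrna_library()]).
#' @param meta Sample metadata data frame (see [read_sample_meta()]); every
#'   sample column of the file must appear in `meta$sample_id`.
#' @return Integer matrix (sgRNA x sample) with rownames set to sgRNA ids.
#' @export
read_count_table <- function(path, library, meta) {
  library <- validate_library(library)
  meta <- validate_sample_meta(meta)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  names(df)[1:2] <- tolower(names(df)[1:2])
  if (!identical(names(df)[1:2], c("sgrna", "gene")))
    stop("count file must start with columns 'sgRNA' and 'gene': ", path)
  samples <- names(df)[-(1:2)]
  if (length(samples) == 0) stop("count file has no sample columns: ", path)
  missing_meta <- setdiff(samples, meta$sample_id)
  if (length(missing_meta) > 0)
    stop("sample column(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  unknown <- setdiff(df$sgrna, library$sgrna)
  if (length(unknown) > 0)
    stop("count rows with sgRNA ids not in the library: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  gene_map <- stats::setNames(library$gene, library$sgrna)
  mismatch <- df$sgrna[df$gene != gene_map[df$sgrna]]
  if (length(mismatch) > 0)
    stop("gene column contradicts library mapping for sgRNA(s): ",
         paste(utils::head(mismatch, 5), collapse = ", "))
  if (anyDuplicated(df$sgrna))
    stop("duplicated sgRNA rows in count file")
  counts <- matrix(NA_integer_, nrow(df), length(samples),
                   dimnames = list(df$sgrna, samples))
  for (s in samples) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0)
      stop("non-integer or negative count in column '", s,
           "', line ", bad[1] + 1L, " of ", path)
    counts[, s] <- as.integer(v)
  }
  counts
}

#' Write an sgRNA count table
#'
#' Inverse of [read_count_table()]: writes the MAGeCK-count dialect TSV.
#'
#' @param counts Integer matrix (sgRNA x sample) with rownames.
#' @param library sgRNA library data frame used to fill the `gene` column.
#' @param path Output file.
#' @export
write_count_table <- function(counts, library, path) {
  library <- validate_library(library)
  gene_map <- stats::setNames(library$gene, library$sgrna)
  df <- data.frame(sgRNA = rownames(counts),
                   gene = unname(gene_map[rownames(counts)]),
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-of-ratios count normalization
#'
#' Size factor of a sample is the median, over sgRNAs with positive counts in
#' every sample, of that sgRNA's count divided by its geometric mean across
#' samples (the DESeq-style median-of-ratios estimator, the default used by
#' screen-analysis tools). When no sgRNA is positive everywhere the function
#' falls back to total-count size factors and emits a warning.
#'
#' @param counts Non-negative count matrix (sgRNA x sample), at least two
#'   samples.
#' @param pseudocount Non-negative value added to every count before
#'   computing ratios (default 0).
#' @return Object of class `normalized_counts`: list with elements `norm`
#'   (matrix `counts / size_factor`), `size_factor` (named, all > 0) and
#'   `method` (`"median_ratio"` or `"total_count"`).
#' @export
median_ratio_normalize <- function(counts, pseudocount = 0) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2, pseudocount >= 0)
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- counts + pseudocount
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    warning("no sgRNA with positive counts in every sample; ",
            "falling back to total-count normalization")
    tot <- colSums(m)
    if (any(tot == 0)) stop("cannot normalize: sample with zero total count")
    sf <- tot / mean(tot)
    method <- "total_count"
  } else {
    lg <- log(m[allpos, , drop = FALSE])
    geo <- exp(rowMeans(lg))
    sf <- apply(m[allpos, , drop = FALSE], 2, function(col) stats::median(col / geo))
    method <- "median_ratio"
  }
  structure(list(norm = sweep(counts, 2, sf, "/"),
                 size_factor = stats::setNames(sf, colnames(counts)),
                 method = method),
            class = "normalized_counts")
}

#' @export
print.normalized_counts <- function(x, ...) {
  cat("Normalized counts:", nrow(x$norm), "sgRNAs x", ncol(x$norm),
      "samples (", x$method, ")\n")
  print(round(x$size_factor, 4))
  invisible(x)
}

# column dialect of the gene report (MAGeCK-style)
GENE_REPORT_COLS <- c(id = "gene", num = "n_sgrna",
                      "neg|score" = "neg_score", "neg|p-value" = "neg_p",
                      "neg|fdr" = "neg_fdr", "neg|rank" = "neg_rank",
                      "pos|score" = "pos_score", "pos|p-value" = "pos_p",
                      "pos|fdr" = "pos_fdr", "pos|rank" = "pos_rank")

#' Write a gene-level screen report
#'
#' Writes the per-gene result of one comparison in the conventional screen
#' report dialect: columns `id`, `num`, `neg|score`, `neg|p-value`,
#' `neg|fdr`, `neg|rank`, `pos|score`, `pos|p-value`, `pos|fdr`, `pos|rank`,
#' sorted by ascending `neg|rank` (1 = most significant).
#'
#' @param results Gene result data frame from [gene_pvalues()].
#' @param path Output file.
#' @export
write_gene_report <- function(results, path) {
  missing <- setdiff(unname(GENE_REPORT_COLS), names(results))
  if (length(missing) > 0)
    stop("gene result is missing field(s): ", paste(missing, collapse = ", "))
  out <- results[order(results$neg_rank), unname(GENE_REPORT_COLS)]
  names(out) <- names(GENE_REPORT_COLS)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-level screen report written by [write_gene_report()]
#'
#' @param path Report TSV.
#' @return Data frame with the package's internal column names (`gene`,
#'   `n_sgrna`, `neg_score`, ...).
#' @export
read_gene_report <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  missing <- setdiff(names(GENE_REPORT_COLS), names(df))
  if (length(missing) > 0)
    stop("report is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[names(GENE_REPORT_COLS)]
  names(df) <- unname(GENE_REPORT_COLS)
  df$gene <- as.character(df$gene)
  int_cols <- c("n_sgrna", "neg_rank", "pos_rank")
  df[int_cols] <- lapply(df[int_cols], as.integer)
  df
}

#' Write a per-gene essentiality table
#'
#' @param essentiality Result of [essentiality_scores()].
#' @param path Output TSV.
#' @export
write_essentiality_table <- function(essentiality, path) {
  utils::write.table(essentiality[order(essentiality$final_rank), ],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
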