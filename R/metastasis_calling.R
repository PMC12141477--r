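#' Build the full set of per-mouse paired comparisons for one cell line
#'
#' Runs the sgRNA-to-gene pipeline for every mouse of a cell line:
#' median-of-ratios normalization over the line's samples, a mean-variance
#' model fitted on the primary-tumor samples of all mice, a paired
#' metastasis-vs-primary comparison per mouse, and gene-level alpha-RRA.
#' Liver comparisons are produced for every mouse that has a `liver_met`
#' sample.
#'
#' @param counts Integer count matrix (sgRNA x sample).
#' @param library sgRNA library data frame.
#' @param meta Sample metadata data frame.
#' @param cell_line Cell line to analyse (must appear in `meta`).
#' @param lung_preference Named numeric vector (one value per mouse):
#'   fraction of metastatic burden in the lung. The simulator provides the
#'   ground-truth value; for real screens users supply imaging-derived
#'   values.
#' @param config `rra_config` controlling the gene-level aggregation.
#' @param pseudocount Pseudocount for the paired scoring (default 1).
#' @return Object of class `mouse_comparison_set`: list with `cell_line`,
#'   `mice` (per mouse, a list with `lung` and optionally `liver`
#'   `gene_result` tables), `lung_preference`, and the fitted
#'   `variance_model`.
#' @export
screen_comparisons <- function(counts, library, meta, cell_line,
                               lung_preference, config = rra_config(),
                               pseudocount = 1) {
  meta <- validate_sample_meta(meta)
  meta <- meta[meta$cell_line == cell_line, , drop = FALSE]
  if (nrow(meta) == 0) stop("no samples for cell line ", cell_line)
  tumor_meta <- meta[meta$tissue != "plasmid", , drop = FALSE]
  counts <- counts[, tumor_meta$sample_id, drop = FALSE]
  norm <- median_ratio_normalize(counts)
  primary <- meta$sample_id[meta$tissue == "primary"]
  model <- fit_variance_model(norm, primary)
  mice <- sort(unique(tumor_meta$mouse_id))
  if (!all(mice %in% names(lung_preference)))
    stop("lung_preference missing for mouse/mice: ",
         paste(setdiff(mice, names(lung_preference)), collapse = ", "))
  per_mouse <- lapply(mice, function(m) {
    out <- list()
    lung_tab <- score_sgrnas_paired(norm, model, meta, m,
                                    treatment_tissue = "lung_met",
                                    pseudocount = pseudocount)
    out$lung <- gene_pvalues(lung_tab, library, config)
    has_liver <- any(meta$mouse_id == m & meta$tissue == "liver_met")
    if (has_liver) {
      liver_tab <- score_sgrnas_paired(norm, model, meta, m,
                                       treatment_tissue = "liver_met",
                                       pseudocount = pseudocount)
      out$liver <- gene_pvalues(liver_tab, library, config)
    }
    out
  })
  names(per_mouse) <- mice
  mouse_comparison_set(cell_line, per_mouse,
                       lung_preference[mice], model = model)
}

#' Construct a mouse comparison set from precomputed gene results
#'
#' @param cell_line Cell line label.
#' @param mice Named list (one entry per mouse) of lists with elements
#'   `lung` (required `gene_result`) and `liver` (optional `gene_result`).
#' @param lung_preference Named numeric vector in `[0, 1]`, one per mouse.
#' @param model Optional fitted `variance_model`, for the record.
#' @return Object of class `mouse_comparison_set`.
#' @export
mouse_comparison_set <- function(cell_line, mice, lung_preference,
                                 model = NULL) {
  stopifnot(is.list(mice), length(mice) >= 1, !is.null(names(mice)))
  if (!all(names(mice) %in% names(lung_preference)))
    stop("lung_preference must cover every mouse")
  universe <- NULL
  for (m in names(mice)) {
    if (is.null(mice[[m]]$lung)) stop("mouse ", m, " has no lung comparison")
    for (tab in mice[[m]]) {
      g <- sort(tab$gene)
      if (is.null(universe)) universe <- g
      else if (!identical(universe, g))
        stop("gene universes differ across comparison tables")
    }
  }
  structure(list(cell_line = cell_line, mice = mice,
                 lung_preference = lung_preference[names(mice)],
                 genes = universe, model = model),
            class = "mouse_comparison_set")
}

#' @export
print.mouse_comparison_set <- function(x, ...) {
  cat("Mouse comparison set:", x$cell_line, "-", length(x$mice), "mice,",
      length(x$genes), "genes\n")
  has_liver <- vapply(x$mice, function(m) !is.null(m$liver), TRUE)
  cat("  lung preference:",
      paste(sprintf("%s=%.2f", names(x$lung_preference), x$lung_preference),
            collapse = " "), "\n")
  cat("  liver comparisons:", sum(has_liver), "of", length(x$mice), "mice\n")
  invisible(x)
}

#' Select the mice with the highest lung-metastasis preference
#'
#' Replicate selection used before integrating p-values: of the available
#' mice, keep the `k` with the largest fraction of metastatic burden in the
#' lung (ties broken by mouse id). With fewer than `k` mice, all are used
#' with a warning.
#'
#' @param comparisons `mouse_comparison_set`.
#' @param k Number of mice to keep (default 4, out of 5).
#' @return Character vector of selected mouse ids.
#' @export
select_mice <- function(comparisons, k = 4) {
  stopifnot(inherits(comparisons, "mouse_comparison_set"), k >= 1)
  pref <- comparisons$lung_preference
  ids <- names(pref)
  if (length(ids) < k) {
    warning("only ", length(ids), " mice available; using all")
    k <- length(ids)
  }
  ids[order(-pref, ids)][seq_len(k)]
}

#' Per-gene essentiality scores across selected replicate mice
#'
#' For each gene, takes the smallest FDR-adjusted p-value across the
#' selected mice's lung-vs-primary comparisons as the representative value;
#' the essentiality score is `-log10` of it, so the highest scores mark the
#' strongest hits. Genes are ranked by ascending minimum adjusted p, ties
#' broken by the best (smallest) per-mouse rho and then gene id.
#'
#' @param comparisons `mouse_comparison_set`.
#' @param selected_mice Mouse ids to integrate (e.g. from [select_mice()]).
#' @param direction `"pos"` (metastasis-enriched sgRNAs; default — knockout
#'   of a suppressor enriches in metastases) or `"neg"` (depletion).
#' @return Data frame of class `essentiality_table`: columns `gene`, one
#'   `padj_<mouse>` column per selected mouse, `min_adj_p`,
#'   `essentiality_score`, `final_rank`. Direction and mice are stored as
#'   attributes.
#' @export
essentiality_scores <- function(comparisons, selected_mice,
                                direction = c("pos", "neg")) {
  stopifnot(inherits(comparisons, "mouse_comparison_set"))
  direction <- match.arg(direction)
  missing <- setdiff(selected_mice, names(comparisons$mice))
  if (length(missing) > 0)
    stop("unknown mouse/mice: ", paste(missing, collapse = ", "))
  genes <- comparisons$genes
  fdr_col <- paste0(direction, "_fdr")
  rho_col <- paste0(direction, "_score")
  padj <- matrix(1, length(genes), length(selected_mice),
                 dimnames = list(genes, selected_mice))
  rho <- matrix(1, length(genes), length(selected_mice))
  for (j in seq_along(selected_mice)) {
    tab <- comparisons$mice[[selected_mice[j]]]$lung
    hit <- match(genes, tab$gene)
    absent <- is.na(hit)
    if (any(absent))
      warning(sum(absent), " gene(s) missing in mouse ",
              selected_mice[j], "; treated as p = 1")
    padj[!absent, j] <- tab[[fdr_col]][hit[!absent]]
    rho[!absent, j] <- tab[[rho_col]][hit[!absent]]
  }
  min_adj_p <- apply(padj, 1, min)
  best_rho <- apply(rho, 1, min)
  res <- data.frame(gene = genes, padj, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(res)[-1] <- paste0("padj_", selected_mice)
  res$min_adj_p <- unname(min_adj_p)
  res$essentiality_score <- -log10(res$min_adj_p)
  res$final_rank <- rank_1n(res$min_adj_p, unname(best_rho), res$gene)
  attr(res, "direction") <- direction
  attr(res, "mice") <- selected_mice
  class(res) <- c("essentiality_table", "data.frame")
  res
}

#' Concordance of essentiality calls between two cell lines
#'
#' Concordant genes are significant (minimum adjusted p at or below
#' `sig_threshold`) in both cell lines. The combined rank of a gene is the
#' worse (maximum) of its two per-line final ranks, so a top combined rank
#' requires strength in both lines. The `top_k` list contains the genes that
#' independently reach the top `k` of each line, intersected, ordered by
#' combined rank (at most `k` genes).
#'
#' @param table_a,table_b `essentiality_table` objects for the two lines.
#' @param sig_threshold Significance cutoff on `min_adj_p` (default 0.05).
#' @param k Size of the per-line top lists (default 10).
#' @return Object of class `concordance_result`: list with `concordant`
#'   (character vector), `top_k` (character vector), and `table` (per shared
#'   gene: both ranks, combined rank, concordance flag).
#' @export
cross_line_concordance <- function(table_a, table_b, sig_threshold = 0.05,
                                   k = 10) {
  stopifnot(inherits(table_a, "essentiality_table"),
            inherits(table_b, "essentiality_table"))
  shared <- intersect(table_a$gene, table_b$gene)
  if (length(shared) == 0) stop("gene universes are disjoint")
  ia <- match(shared, table_a$gene)
  ib <- match(shared, table_b$gene)
  tab <- data.frame(gene = shared,
                    min_adj_p_a = table_a$min_adj_p[ia],
                    min_adj_p_b = table_b$min_adj_p[ib],
                    rank_a = table_a$final_rank[ia],
                    rank_b = table_b$final_rank[ib],
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$combined_rank <- pmax(tab$rank_a, tab$rank_b)
  tab$concordant <- tab$min_adj_p_a <= sig_threshold &
    tab$min_adj_p_b <= sig_threshold
  tab <- tab[order(tab$combined_rank, tab$gene), , drop = FALSE]
  row.names(tab) <- NULL
  in_both_top <- tab$gene[tab$rank_a <= k & tab$rank_b <= k]
  top_k <- utils::head(in_both_top, k)
  structure(list(concordant = tab$gene[tab$concordant],
                 top_k = top_k, table = tab,
                 sig_threshold = sig_threshold, k = k),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Cross-line concordance:", length(x$concordant),
      "concordant genes (min_adj_p <=", x$sig_threshold, "in both lines)\n")
  cat("Top", x$k, "in common:", paste(x$top_k, collapse = ", "), "\n")
  invisible(x)
}

#' Lung-versus-liver rank filter for organ-specific suppressors
#'
#' The alternative hit-calling route: a gene passes in a mouse when, on the
#' 1-based report ranks (1 = most significant), its depletion rank in the
#' lung comparison is strictly higher (less significant) than in the paired
#' liver comparison AND its enrichment rank in the lung is strictly lower
#' (more significant) than in the liver. A gene passes overall only when it
#' passes in every replicate mouse — the signature of a gene that regulates
#' lung but not liver metastasis. For passing genes the per-mouse p-values
#' of the chosen direction (lung comparison) are combined by Fisher's
#' method, and passing genes are ordered by the combined p.
#'
#' @param comparisons `mouse_comparison_set`; every mouse must have both a
#'   lung and a liver comparison.
#' @param direction Which lung p-value feeds the combined evidence: `"pos"`
#'   (default; enrichment of suppressor knockouts in metastases) or
#'   `"neg"`.
#' @return Data frame of class `filtered_ranking`: per gene, one
#'   `pass_<mouse>` logical column per mouse, `passes_filter`, `combined_p`
#'   (Fisher; NA for non-passing genes) and `comprehensive_rank` (1-based
#'   over passing genes only; NA otherwise).
#' @export
lung_liver_rank_filter <- function(comparisons, direction = c("pos", "neg")) {
  stopifnot(inherits(comparisons, "mouse_comparison_set"))
  direction <- match.arg(direction)
  mice <- names(comparisons$mice)
  for (m in mice)
    if (is.null(comparisons$mice[[m]]$liver))
      stop("mouse ", m, " has no liver comparison")
  genes <- comparisons$genes
  p_col <- paste0(direction, "_p")
  pass <- matrix(NA, length(genes), length(mice),
                 dimnames = list(genes, mice))
  pdir <- matrix(NA_real_, length(genes), length(mice))
  for (j in seq_along(mice)) {
    lung <- comparisons$mice[[mice[j]]]$lung
    liver <- comparisons$mice[[mice[j]]]$liver
    il <- match(genes, lung$gene)
    iv <- match(genes, liver$gene)
    pass[, j] <- lung$neg_rank[il] > liver$neg_rank[iv] &
      lung$pos_rank[il] < liver$pos_rank[iv]
    pdir[, j] <- lung[[p_col]][il]
  }
  passes <- rowSums(pass) == length(mice)
  stat <- -2 * rowSums(log(pdir))
  combined <- stats::pchisq(stat, df = 2 * length(mice), lower.tail = FALSE)
  res <- data.frame(gene = genes, pass, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(res)[-1] <- paste0("pass_", mice)
  res$n_pass <- as.integer(rowSums(pass))
  res$passes_filter <- unname(passes)
  res$combined_p <- ifelse(passes, unname(combined), NA_real_)
  res$comprehensive_rank <- NA_integer_
  if (any(passes)) {
    sub <- which(passes)
    ord <- sub[order(combined[sub], genes[sub])]
    res$comprehensive_rank[ord] <- seq_along(ord)
  }
  attr(res, "direction") <- direction
  class(res) <- c("filtered_ranking", "data.frame")
  res
}
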