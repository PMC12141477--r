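# Small fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk except files the tests write themselves.

tiny_library <- function(n_genes = 4, sgrnas_per_gene = 2) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  data.frame(sgrna = paste0(rep(genes, each = sgrnas_per_gene), "_sg",
                            seq_len(sgrnas_per_gene)),
             gene = rep(genes, each = sgrnas_per_gene),
             stringsAsFactors = FALSE)
}

tiny_meta <- function(cell_line = "CL", mice = c("M1", "M2"),
                      tissues = c("primary", "lung_met")) {
  grid <- expand.grid(mouse_id = mice, tissue = tissues,
                      stringsAsFactors = FALSE)
  data.frame(sample_id = paste(cell_line, grid$mouse_id, grid$tissue,
                               sep = "_"),
             cell_line = cell_line, mouse_id = grid$mouse_id,
             tissue = grid$tissue, stringsAsFactors = FALSE)
}

# normalized_counts wrapper around a plain matrix (size factors 1)
as_norm <- function(mat) {
  structure(list(norm = mat,
                 size_factor = stats::setNames(rep(1, ncol(mat)),
                                               colnames(mat)),
                 method = "median_ratio"),
            class = "normalized_counts")
}

# minimal per-sgRNA score table for feeding gene_pvalues directly
fake_score_table <- function(library, p_low, p_high) {
  data.frame(sgrna = library$sgrna, p_low = p_low, p_high = p_high,
             stringsAsFactors = FALSE)
}

# minimal gene_result table with prescribed one-sided p-values; ranks and
# FDR are derived the same way the pipeline derives them
fake_gene_result <- function(genes, neg_p, pos_p,
                             neg_score = neg_p, pos_score = pos_p) {
  rank_of <- function(p, s) {
    ord <- order(p, s, genes)
    r <- integer(length(p)); r[ord] <- seq_along(p); r
  }
  structure(data.frame(gene = genes, n_sgrna = 2L,
                       neg_score = neg_score, neg_p = neg_p,
                       neg_fdr = stats::p.adjust(neg_p, "BH"),
                       neg_rank = rank_of(neg_p, neg_score),
                       pos_score = pos_score, pos_p = pos_p,
                       pos_fdr = stats::p.adjust(pos_p, "BH"),
                       pos_rank = rank_of(pos_p, pos_score),
                       stringsAsFactors = FALSE),
            class = c("gene_result", "data.frame"))
}

# exhaustive alpha-RRA oracle: exact permutation p for one gene of size m,
# enumerating every size-m subset of percentile positions and applying the
# same lexicographic (rho, mean percentile) comparison as the pipeline
enum_gene_p <- function(pct, idx, alpha) {
  m <- length(idx)
  rho_obs <- alpha_rra_score(sort(pct[idx]), alpha)
  mp_obs <- mean(pct[idx])
  subsets <- utils::combn(length(pct), m)
  stats <- apply(subsets, 2, function(s)
    c(alpha_rra_score(sort(pct[s]), alpha), mean(pct[s])))
  mean(stats[1, ] < rho_obs |
         (stats[1, ] == rho_obs & stats[2, ] <= mp_obs))
}

# run the full hit-calling pipeline on a simulated screen
run_pipeline <- function(sim, config) {
  pref <- stats::setNames(sim$truth$mice$lung_preference,
                          sim$truth$mice$mouse)
  suppressWarnings(screen_comparisons(sim$counts, sim$library, sim$meta,
                                      sim$config$cell_line, pref,
                                      config = config))
}
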