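#' Configuration for gene-level robust rank aggregation
#'
#' @param alpha Top-percentile cutoff in (0, 1]: only sgRNAs whose fractional
#'   rank falls inside the top `alpha` contribute to a gene's score
#'   (default 0.05, the alpha-RRA convention).
#' @param n_perm Number of permutation draws for the null (default 10000;
#'   must be at least 100). The resolution of permutation p-values is
#'   `1 / (n_perm + 1)`.
#' @param seed Integer seed controlling the permutation stream.
#' @param fdr_method Multiple-testing correction; only Benjamini-Hochberg is
#'   supported.
#' @return Object of class `rra_config`.
#' @export
rra_config <- function(alpha = 0.05, n_perm = 10000, seed = 1L,
                       fdr_method = "benjamini_hochberg") {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha <= 1,
            is.numeric(n_perm), n_perm >= 100,
            is.numeric(seed), length(seed) == 1)
  fdr_method <- match.arg(fdr_method, "benjamini_hochberg")
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), fdr_method = fdr_method),
            class = "rra_config")
}

#' Modified robust rank aggregation score for one gene
#'
#' Given the sorted fractional ranks `r_1 <= ... <= r_m` of a gene's m sgRNAs
#' among all n sgRNAs, the score is the minimum, over positions `i` with
#' `r_i <= alpha`, of the probability that the i-th order statistic of m
#' independent uniforms falls at or below `r_i` — the regularized incomplete
#' beta `I_{r_i}(i, m - i + 1)`. If no rank falls inside the top-alpha
#' fraction the score is 1 (no evidence).
#'
#' @param r Sorted vector of fractional ranks in (0, 1].
#' @param alpha Top-percentile cutoff in (0, 1].
#' @return Score rho in (0, 1]; smaller is more significant.
#' @export
alpha_rra_score <- function(r, alpha) {
  stopifnot(is.numeric(r), length(r) >= 1, all(r > 0), all(r <= 1),
            alpha > 0, alpha <= 1)
  if (is.unsorted(r)) stop("ranks must be sorted ascending")
  m <- length(r)
  idx <- which(r <= alpha)
  if (length(idx) == 0) return(1)
  min(stats::pbeta(r[idx], idx, m - idx + 1))
}

# vectorized alpha-RRA over rows of a matrix of sorted percentiles
rho_matrix <- function(P, alpha) {
  m <- ncol(P)
  i <- matrix(seq_len(m), nrow(P), m, byrow = TRUE)
  B <- stats::pbeta(P, i, m - i + 1)
  B[P > alpha] <- 1           # excluded positions cannot set the minimum
  do.call(pmin, lapply(seq_len(m), function(j) B[, j]))
}

# null draws for genes of size m: percentiles sampled without replacement
# from the observed pool (equivalent, per gene, to permuting the
# sgRNA -> gene assignment); returns rho and the mean drawn percentile
null_rho <- function(pct, m, n_perm, alpha) {
  pct <- sort(pct)              # draws depend only on the percentile pool,
  n <- length(pct)              # not on sgRNA input order
  D <- matrix(NA_real_, n_perm, m)
  for (j in seq_len(n_perm))
    D[j, ] <- pct[sample.int(n, m)]
  mean_pct <- rowMeans(D)
  D <- matrix(D[order(row(D), D)], n_perm, m, byrow = TRUE)  # row-wise sort
  list(rho = rho_matrix(D, alpha), mean_pct = mean_pct)
}

# #{null (rho, mean_pct) <=lex observed (rho, mean_pct)} for each gene.
# rho alone is heavily discrete (every gene without an sgRNA in the top
# alpha fraction has rho = 1), so the permutation comparison is done
# lexicographically with the mean percentile as a continuous tie-break;
# this removes the atom and yields calibrated (uniform) null p-values.
count_null_le <- function(rho_obs, mp_obs, rho_null, mp_null) {
  o <- order(rho_null, mp_null)
  nr <- rho_null[o]
  nmp <- mp_null[o]
  vapply(seq_along(rho_obs), function(i) {
    lt <- findInterval(rho_obs[i], nr, left.open = TRUE)  # strictly smaller
    le <- findInterval(rho_obs[i], nr)                    # smaller or tied
    if (le > lt)  # within the tied-rho block mean percentiles are sorted
      lt + findInterval(mp_obs[i], nmp[(lt + 1):le])
    else lt
  }, numeric(1))
}

#' Gene-level alpha-RRA p-values for one comparison
#'
#' Converts per-sgRNA p-values into fractional ranks (ties averaged, divided
#' by n), aggregates each gene's ranks with [alpha_rra_score()], and
#' calibrates the score against a permutation null that preserves each
#' gene's sgRNA count: `p = (1 + #{(rho, mean pct)_perm <=
#' (rho, mean pct)_obs}) / (1 + n_perm)`, where the comparison is
#' lexicographic — rho first, the gene's mean sgRNA percentile as a
#' continuous tie-break. The tie-break matters because rho is heavily
#' discrete (all genes without an sgRNA inside the top-alpha fraction share
#' rho = 1); breaking the tie by a continuous exchangeable statistic makes
#' the null p-values exactly uniform instead of leaving an atom at 1.
#' Both selection directions are scored: `neg` (depletion, from `p_low`) and
#' `pos` (enrichment, from `p_high`). FDR is Benjamini-Hochberg; ranks are
#' 1-based, ordered by ascending p, then ascending rho, then ascending mean
#' sgRNA percentile (a continuous, direction-informative tie-break), then
#' gene id.
#'
#' @param sgrna_table `sgrna_score_table` from [score_sgrnas_paired()].
#' @param library sgRNA library mapping sgRNAs to genes.
#' @param config `rra_config` object.
#' @return Data frame of class `gene_result` with one row per gene and
#'   columns `gene`, `n_sgrna`, and `neg_score`, `neg_p`, `neg_fdr`,
#'   `neg_rank`, `neg_mean_pct` (ditto for `pos`). The comparison label of
#'   the input is propagated in `attr(, "comparison")`.
#' @export
gene_pvalues <- function(sgrna_table, library, config = rra_config()) {
  stopifnot(inherits(config, "rra_config"))
  library <- validate_library(library)
  gene_map <- stats::setNames(library$gene, library$sgrna)
  unknown <- setdiff(sgrna_table$sgrna, names(gene_map))
  if (length(unknown) > 0)
    stop("sgRNA(s) not in library: ", paste(utils::head(unknown, 5), collapse = ", "))
  gene <- unname(gene_map[sgrna_table$sgrna])
  n <- nrow(sgrna_table)

  # stable gene universe, deterministic regardless of input row order
  genes <- sort(unique(gene))
  idx_by_gene <- split(seq_len(n), gene)[genes]
  sizes <- lengths(idx_by_gene)

  one_direction <- function(p_sgrna) {
    pct <- rank(p_sgrna, ties.method = "average") / n
    rho <- numeric(length(genes))
    mean_pct <- vapply(idx_by_gene, function(ii) mean(pct[ii]), 0)
    p <- numeric(length(genes))
    for (m in sort(unique(sizes))) {
      which_g <- which(sizes == m)
      P <- t(vapply(idx_by_gene[which_g],
                    function(ii) sort(pct[ii]), numeric(m)))
      if (m == 1) P <- matrix(P, ncol = 1)
      rho_g <- rho_matrix(P, config$alpha)
      nullv <- null_rho(pct, m, config$n_perm, config$alpha)
      cnt <- count_null_le(rho_g, mean_pct[which_g], nullv$rho,
                           nullv$mean_pct)
      p[which_g] <- (1 + cnt) / (1 + config$n_perm)
      rho[which_g] <- rho_g
    }
    fdr <- stats::p.adjust(p, method = "BH")
    rnk <- rank_1n(p, rho, mean_pct, genes)
    list(score = rho, p = p, fdr = fdr, rank = rnk, mean_pct = mean_pct)
  }

  # percentile ranks come from the log-scale tails when available, so that
  # underflow of extreme p-values cannot collapse the top of the ranking
  set.seed(config$seed)
  neg <- one_direction(if (is.null(sgrna_table$log_p_low))
    sgrna_table$p_low else sgrna_table$log_p_low)
  pos <- one_direction(if (is.null(sgrna_table$log_p_high))
    sgrna_table$p_high else sgrna_table$log_p_high)

  res <- data.frame(gene = genes, n_sgrna = as.integer(sizes),
                    neg_score = neg$score, neg_p = neg$p, neg_fdr = neg$fdr,
                    neg_rank = neg$rank, neg_mean_pct = neg$mean_pct,
                    pos_score = pos$score, pos_p = pos$p, pos_fdr = pos$fdr,
                    pos_rank = pos$rank, pos_mean_pct = pos$mean_pct,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "comparison") <- attr(sgrna_table, "comparison")
  class(res) <- c("gene_result", "data.frame")
  res
}
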