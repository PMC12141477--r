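# build a comparison set from prescribed per-mouse gene-level p-values
make_set <- function(neg_lung, pos_lung, neg_liver = NULL, pos_liver = NULL,
                     pref = NULL, genes = NULL) {
  n_mice <- ncol(pos_lung)
  mice_ids <- sprintf("M%d", seq_len(n_mice))
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(pos_lung)))
  mice <- lapply(seq_len(n_mice), function(j) {
    out <- list(lung = fake_gene_result(genes, neg_lung[, j], pos_lung[, j]))
    if (!is.null(neg_liver))
      out$liver <- fake_gene_result(genes, neg_liver[, j], pos_liver[, j])
    out
  })
  names(mice) <- mice_ids
  if (is.null(pref))
    pref <- stats::setNames(rep(0.5, n_mice), mice_ids)
  mouse_comparison_set("CL", mice, pref)
}

test_that("mouse selection takes the k highest lung preferences", {
  pmat <- matrix(runif(10 * 5), 10, 5)
  set <- make_set(pmat, pmat,
                  pref = stats::setNames(c(0.9, 0.8, 0.7, 0.6, 0.2),
                                         sprintf("M%d", 1:5)))
  expect_equal(select_mice(set, 4), c("M1", "M2", "M3", "M4"))
  expect_equal(select_mice(set, 5), sprintf("M%d", 1:5))

  tied <- make_set(pmat, pmat,
                   pref = stats::setNames(rep(0.5, 5), sprintf("M%d", 1:5)))
  expect_equal(select_mice(tied, 2), c("M1", "M2"))  # lexicographic ties
  expect_warning(sel <- select_mice(tied, 7), "using all")
  expect_equal(sel, sprintf("M%d", 1:5))
})

test_that("essentiality scores take the minimum adjusted p across mice", {
  # one-gene universe: BH leaves the per-mouse p untouched, so the
  # representative value is exactly min(0.01, 0.2, 0.05, 0.5) = 0.01
  padj_target <- matrix(c(0.01, 0.2, 0.05, 0.5), 1, 4)
  set <- make_set(neg_lung = matrix(1, 1, 4), pos_lung = padj_target,
                  genes = "GA")
  ess <- essentiality_scores(set, sprintf("M%d", 1:4), "pos")
  expect_equal(ess$min_adj_p, 0.01)
  expect_equal(ess$essentiality_score, 2)
  expect_equal(ess$final_rank, 1L)
  expect_equal(ess$padj_M2, 0.2)

  # every p = 1 gives score 0
  null_set <- make_set(matrix(1, 2, 2), matrix(1, 2, 2),
                       genes = c("GA", "GB"))
  ess0 <- essentiality_scores(null_set, c("M1", "M2"), "pos")
  expect_equal(ess0$essentiality_score, c(0, 0))
  expect_setequal(ess0$final_rank, 1:2)
})

test_that("improving one mouse's p never worsens a gene's final rank", {
  set.seed(42)
  n_genes <- 40
  pos <- matrix(runif(n_genes * 3), n_genes, 3)
  neg <- matrix(runif(n_genes * 3), n_genes, 3)
  set <- make_set(neg, pos)
  ess <- essentiality_scores(set, c("M1", "M2", "M3"), "pos")
  for (g_idx in c(5, 17, 33)) {
    pos2 <- pos
    pos2[g_idx, 2] <- pos2[g_idx, 2] / 10
    ess2 <- essentiality_scores(make_set(neg, pos2), c("M1", "M2", "M3"),
                                "pos")
    g <- ess$gene[g_idx]
    expect_lte(ess2$final_rank[ess2$gene == g],
               ess$final_rank[ess$gene == g])
  }
})

test_that("cross-line concordance intersects significance and top lists", {
  genes <- sprintf("G%03d", 1:6)
  mk <- function(p) {
    set <- make_set(matrix(1, 6, 1), matrix(p, ncol = 1), genes = genes)
    essentiality_scores(set, "M1", "pos")
  }
  # line A: GA..: significant genes 1,2; line B: significant genes 1,2,3
  ta <- mk(c(0.001, 0.010, 0.30, 0.40, 0.50, 0.60))
  tb <- mk(c(0.002, 0.004, 0.006, 0.70, 0.80, 0.90))
  cc <- cross_line_concordance(ta, tb, sig_threshold = 0.05, k = 2)
  expect_setequal(cc$concordant, c("G001", "G002"))
  expect_equal(cc$top_k, c("G001", "G002"))
  expect_equal(cc$table$combined_rank[cc$table$gene == "G001"], 1L)

  # degenerate threshold: everything concordant
  cc_all <- cross_line_concordance(ta, tb, sig_threshold = 1, k = 2)
  expect_setequal(cc_all$concordant, genes)

  # top_k requires membership in BOTH per-line top lists
  tc <- mk(c(0.50, 0.010, 0.001, 0.40, 0.30, 0.60))  # top-2: G003, G002
  cc2 <- cross_line_concordance(ta, tc, sig_threshold = 0.05, k = 2)
  expect_equal(cc2$top_k, "G002")

  tb_disjoint <- tb
  tb_disjoint$gene <- paste0("X", tb_disjoint$gene)
  expect_error(cross_line_concordance(ta, tb_disjoint), "disjoint")
})

test_that("lung-liver filter applies the strict rank inequalities in all mice", {
  genes <- sprintf("G%03d", 1:8)
  n <- length(genes)
  set.seed(9)
  # gene 1: strongly lung-enriched (pos p tiny, neg p ~ 1) in every mouse;
  # liver indifferent. gene 2 fails the pos inequality in mouse 2.
  pos_lung <- matrix(runif(n * 3, 0.3, 1), n, 3)
  neg_lung <- matrix(runif(n * 3, 0.3, 1), n, 3)
  pos_liver <- matrix(runif(n * 3, 0.3, 1), n, 3)
  neg_liver <- matrix(runif(n * 3, 0.3, 1), n, 3)
  pos_lung[1, ] <- 1e-6; neg_lung[1, ] <- 1
  neg_liver[1, ] <- 1e-6                       # liver-depleted, lung-spared
  pos_lung[2, c(1, 3)] <- 1e-5; pos_liver[2, 2] <- 1e-7; pos_lung[2, 2] <- 0.99
  set <- make_set(neg_lung, pos_lung, neg_liver, pos_liver)
  fl <- lung_liver_rank_filter(set)
  expect_true(fl$passes_filter[fl$gene == "G001"])
  expect_false(fl$passes_filter[fl$gene == "G002"])
  expect_equal(fl$comprehensive_rank[fl$gene == "G001"], 1L)

  # Fisher combination oracle for the passing gene
  pvec <- pos_lung[1, ]
  fisher <- pchisq(-2 * sum(log(pvec)), df = 6, lower.tail = FALSE)
  expect_equal(fl$combined_p[fl$gene == "G001"], fisher)
  expect_true(is.na(fl$combined_p[fl$gene == "G002"]))

  set_noliver <- make_set(neg_lung, pos_lung)
  expect_error(lung_liver_rank_filter(set_noliver), "M1")
})

test_that("few genes survive the all-replicates filter under a pure null", {
  set.seed(123)
  n <- 500; R <- 3
  set <- make_set(matrix(runif(n * R), n, R), matrix(runif(n * R), n, R),
                  matrix(runif(n * R), n, R), matrix(runif(n * R), n, R))
  fl <- lung_liver_rank_filter(set)
  # expectation under independence is (1/4)^R * n ~ 7.8; allow 3x slack
  expect_lt(sum(fl$passes_filter), 3 * (1 / 4)^R * n)
})

test_that("filter is invariant to monotone relabeling of sgRNA-level evidence", {
  set.seed(31)
  n <- 60; R <- 2
  neg_l <- matrix(runif(n * R), n, R); pos_l <- matrix(runif(n * R), n, R)
  neg_v <- matrix(runif(n * R), n, R); pos_v <- matrix(runif(n * R), n, R)
  f1 <- lung_liver_rank_filter(make_set(neg_l, pos_l, neg_v, pos_v))
  squash <- function(x) x^3  # strictly monotone, rank-preserving
  f2 <- lung_liver_rank_filter(make_set(squash(neg_l), squash(pos_l),
                                        squash(neg_v), squash(pos_v)))
  expect_identical(f1$passes_filter, f2$passes_filter)
  expect_identical(f1$comprehensive_rank, f2$comprehensive_rank)
})
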