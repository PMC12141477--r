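#' Configuration of the in vivo screen simulator
#'
#' Describes a pooled knockout screen carried through transplantation and
#' organ seeding: a log-normal plasmid library, low-MOI infection, clonal
#' primary-tumor growth, per-cell organ seeding with a tight bottleneck,
#' metastatic outgrowth, and multinomial sequencing. Defaults mirror the
#' design of an in vivo genome-wide screen (MOI ~0.3, at least 200x
#' per-sgRNA founder coverage per mouse, 5 replicate mice) at desk scale.
#'
#' @param n_genes Number of genes.
#' @param sgrnas_per_gene sgRNAs per gene (default 4).
#' @param n_mice Replicate mice (default 5).
#' @param moi Multiplicity of infection in (0, 1] (default 0.3; most
#'   infected cells carry a single sgRNA).
#' @param coverage_target Founder cells per sgRNA to guarantee when
#'   `cells_per_mouse` is not given (default 200).
#' @param cells_per_mouse Cells injected per mouse; default
#'   `ceiling(coverage_target * n_sgrna / moi)` so that
#'   `cells_per_mouse * moi / n_sgrna >= coverage_target`.
#' @param suppressors Optional data frame with columns `gene`,
#'   `lung_effect`, `liver_effect` (multipliers >= 1 on the per-cell organ
#'   seeding probability). `NULL` (default) simulates a pure-null screen.
#' @param base_seed_prob Named vector `c(lung = , liver = )`: per-cell
#'   probability that a primary-tumor cell seeds the organ (defaults
#'   4e-4 / 1e-4; the ~4:1 lung:liver ratio mirrors the lung tropism of
#'   ccRCC).
#' @param bottleneck_size Named vector `c(lung = , liver = )`: maximum
#'   number of seeded cells that establish metastases (defaults 2000 /
#'   1000; metastases are founded by few clones).
#' @param growth_dispersion Dispersion of the gamma-multiplicative clonal
#'   growth noise (per-cell clone size ~ Gamma(shape = 1/dispersion,
#'   mean 1); default 0.5).
#' @param plasmid_sigma Log-normal sigma of plasmid sgRNA abundance
#'   (default 0.5).
#' @param primary_tumor_cells Primary tumor size (cells) at the time of
#'   seeding (default 5e6).
#' @param seq_depth Reads per sequenced sample (default 5e6).
#' @param seed Master seed; every random stage derives its own substream
#'   seed from it (see [simulate_screen()]).
#' @param cell_line Label used in sample ids and metadata.
#' @return Object of class `screen_sim_config`. The implied founder
#'   coverage is stored as `$coverage` and must be at least 1.
#' @export
screen_sim_config <- function(n_genes = 2000, sgrnas_per_gene = 4,
                              n_mice = 5, moi = 0.3, coverage_target = 200,
                              cells_per_mouse = NULL, suppressors = NULL,
                              base_seed_prob = c(lung = 4e-4, liver = 1e-4),
                              bottleneck_size = c(lung = 2000, liver = 1000),
                              growth_dispersion = 0.5, plasmid_sigma = 0.5,
                              primary_tumor_cells = 5e6, seq_depth = 5e6,
                              seed = 1L, cell_line = "SIM") {
  stopifnot(n_genes >= 1, sgrnas_per_gene >= 1, n_mice >= 1,
            moi > 0, moi <= 1, growth_dispersion > 0, plasmid_sigma >= 0,
            primary_tumor_cells >= 1, seq_depth >= 1,
            all(c("lung", "liver") %in% names(base_seed_prob)),
            all(c("lung", "liver") %in% names(bottleneck_size)),
            all(base_seed_prob > 0), all(base_seed_prob <= 1),
            all(bottleneck_size >= 1))
  n_sgrna <- n_genes * sgrnas_per_gene
  if (is.null(cells_per_mouse))
    cells_per_mouse <- ceiling(coverage_target * n_sgrna / moi)
  coverage <- cells_per_mouse * moi / n_sgrna
  if (coverage < 1) stop("founder coverage below 1x; increase cells_per_mouse")
  genes <- sprintf("G%05d", seq_len(n_genes))
  if (!is.null(suppressors)) {
    stopifnot(is.data.frame(suppressors),
              all(c("gene", "lung_effect", "liver_effect") %in% names(suppressors)))
    if (!all(suppressors$gene %in% genes))
      stop("suppressor gene(s) outside the simulated gene universe")
    if (any(suppressors$lung_effect < 1) || any(suppressors$liver_effect < 1))
      stop("suppressor effects must be >= 1")
  }
  structure(list(n_genes = n_genes, sgrnas_per_gene = sgrnas_per_gene,
                 n_sgrna = n_sgrna, genes = genes, n_mice = n_mice,
                 moi = moi, cells_per_mouse = cells_per_mouse,
                 coverage = coverage, suppressors = suppressors,
                 base_seed_prob = base_seed_prob,
                 bottleneck_size = bottleneck_size,
                 growth_dispersion = growth_dispersion,
                 plasmid_sigma = plasmid_sigma,
                 primary_tumor_cells = primary_tumor_cells,
                 seq_depth = seq_depth, seed = as.integer(seed),
                 cell_line = cell_line),
            class = "screen_sim_config")
}

#' @export
print.screen_sim_config <- function(x, ...) {
  cat(sprintf(paste0("Screen simulation: %d genes x %d sgRNAs, %d mice, ",
                     "MOI %.2f, %.0fx coverage, seed %d\n"),
              x$n_genes, x$sgrnas_per_gene, x$n_mice, x$moi, x$coverage,
              x$seed))
  if (!is.null(x$suppressors))
    cat("  planted suppressors:", nrow(x$suppressors), "\n")
  invisible(x)
}

# sum of n_cells iid Gamma(shape = 1/d, mean 1) clone sizes per sgRNA
clonal_growth <- function(n_cells, dispersion) {
  out <- numeric(length(n_cells))
  pos <- n_cells > 0
  out[pos] <- stats::rgamma(sum(pos), shape = n_cells[pos] / dispersion,
                            scale = dispersion)
  out
}

# multivariate hypergeometric subsample: draw k of sum(x) cells w/o replacement
mv_hypergeom <- function(x, k) {
  out <- integer(length(x))
  rem <- sum(x)
  for (i in seq_along(x)) {
    if (k <= 0 || rem <= 0) break
    draw <- stats::rhyper(1, x[i], rem - x[i], k)
    out[i] <- draw
    k <- k - draw
    rem <- rem - x[i]
  }
  out
}

#' Simulate an in vivo pooled CRISPR screen with organ-seeding bottlenecks
#'
#' Stages, per the generative model described in the package vignette:
#' (1) plasmid sgRNA abundances are log-normal; (2) each mouse's founder
#' cells are a multinomial draw of `cells_per_mouse * moi` infections;
#' (3) primary-tumor growth applies gamma-multiplicative clonal noise;
#' (4) each primary cell seeds the lung (liver) with probability
#' `base_seed_prob * effect(gene)`, truncated to the organ bottleneck by
#' sampling without replacement; (5) metastatic outgrowth applies the same
#' clonal noise to seeded cells; (6) each sample is sequenced as a
#' multinomial draw of `seq_depth` reads. Randomness is reproducible: the
#' master seed generates one substream seed per stage (plasmid, then each
#' mouse) up front, so results are byte-identical across runs.
#'
#' @param config `screen_sim_config` object.
#' @return Object of class `screen_sim`: list with `counts` (integer matrix
#'   sgRNA x sample: plasmid, then per mouse primary / lung_met /
#'   liver_met), `library`, `meta`, and `truth` (list with per-gene effect
#'   table `genes` and per-mouse burden table `mice`, including
#'   `lung_preference = lung burden / (lung + liver burden)`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  n <- config$n_sgrna
  gene_of <- rep(config$genes, each = config$sgrnas_per_gene)
  sgrna <- paste0(gene_of, "_sg", seq_len(config$sgrnas_per_gene))
  lib <- data.frame(sgrna = sgrna, gene = gene_of, stringsAsFactors = FALSE)

  lung_eff <- liver_eff <- rep(1, n)
  truth_genes <- data.frame(gene = config$genes, is_suppressor = FALSE,
                            lung_effect = 1, liver_effect = 1,
                            stringsAsFactors = FALSE)
  if (!is.null(config$suppressors)) {
    i <- match(config$suppressors$gene, truth_genes$gene)
    truth_genes$is_suppressor[i] <- TRUE
    truth_genes$lung_effect[i] <- config$suppressors$lung_effect
    truth_genes$liver_effect[i] <- config$suppressors$liver_effect
    lung_eff <- truth_genes$lung_effect[match(gene_of, truth_genes$gene)]
    liver_eff <- truth_genes$liver_effect[match(gene_of, truth_genes$gene)]
  }

  # stream splitting: master seed -> one substream seed per stage
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 1L + config$n_mice)

  set.seed(sub_seeds[1])
  ab0 <- exp(stats::rnorm(n, 0, config$plasmid_sigma))
  ab0 <- ab0 / sum(ab0)
  samples <- list()
  meta_rows <- list()
  line <- config$cell_line
  samples[[paste0(line, "_plasmid")]] <-
    as.vector(stats::rmultinom(1, config$seq_depth, ab0))
  meta_rows[[1]] <- data.frame(sample_id = paste0(line, "_plasmid"),
                               cell_line = line, mouse_id = "pool",
                               tissue = "plasmid", stringsAsFactors = FALSE)

  mouse_ids <- sprintf("M%d", seq_len(config$n_mice))
  burden <- matrix(0, config$n_mice, 2,
                   dimnames = list(mouse_ids, c("lung", "liver")))
  d <- config$growth_dispersion
  for (m in seq_len(config$n_mice)) {
    set.seed(sub_seeds[1 + m])
    mouse <- mouse_ids[m]
    founders <- as.vector(stats::rmultinom(
      1, round(config$cells_per_mouse * config$moi), ab0))
    primary_ab <- clonal_growth(founders, d)
    samples[[paste(line, mouse, "primary", sep = "_")]] <-
      as.vector(stats::rmultinom(1, config$seq_depth,
                                 primary_ab / sum(primary_ab)))
    cells <- round(primary_ab / sum(primary_ab) * config$primary_tumor_cells)
    for (organ in c("lung", "liver")) {
      eff <- if (organ == "lung") lung_eff else liver_eff
      p_seed <- pmin(1, config$base_seed_prob[[organ]] * eff)
      seeds <- stats::rbinom(n, cells, p_seed)
      cap <- config$bottleneck_size[[organ]]
      if (sum(seeds) > cap) seeds <- mv_hypergeom(seeds, cap)
      burden[mouse, organ] <- sum(seeds)
      tissue <- paste0(organ, "_met")
      sid <- paste(line, mouse, tissue, sep = "_")
      if (sum(seeds) == 0) {
        warning("mouse ", mouse, ": no cell seeded the ", organ,
                "; emitting an all-zero sample")
        samples[[sid]] <- integer(n)
      } else {
        met_ab <- clonal_growth(seeds, d)
        samples[[sid]] <-
          as.vector(stats::rmultinom(1, config$seq_depth,
                                     met_ab / sum(met_ab)))
      }
      meta_rows[[length(meta_rows) + 1]] <-
        data.frame(sample_id = sid, cell_line = line, mouse_id = mouse,
                   tissue = tissue, stringsAsFactors = FALSE)
    }
    meta_rows[[length(meta_rows) + 1]] <-
      data.frame(sample_id = paste(line, mouse, "primary", sep = "_"),
                 cell_line = line, mouse_id = mouse, tissue = "primary",
                 stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, samples)
  storage.mode(counts) <- "integer"
  rownames(counts) <- sgrna
  total <- rowSums(burden)
  truth_mice <- data.frame(mouse = mouse_ids,
                           lung_burden = burden[, "lung"],
                           liver_burden = burden[, "liver"],
                           lung_preference =
                             ifelse(total > 0, burden[, "lung"] / total, 0.5),
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(counts = counts, library = lib,
                 meta = validate_sample_meta(do.call(rbind, meta_rows)),
                 truth = list(genes = truth_genes, mice = truth_mice),
                 config = config),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Simulated screen:", nrow(x$counts), "sgRNAs x", ncol(x$counts),
      "samples (", x$config$cell_line, ")\n")
  print(x$truth$mice)
  invisible(x)
}

#' Recovery of planted suppressor genes by a ranking
#'
#' Standard precision/recall of the planted suppressor set among the
#' top-ranked genes. For an [essentiality_scores()] table the ranking is
#' `final_rank` over all genes; for a [lung_liver_rank_filter()] result it
#' is `comprehensive_rank` over passing genes, and genes excluded by the
#' filter count as ranked last.
#'
#' @param ranking `essentiality_table` or `filtered_ranking`.
#' @param truth Simulator truth (the `truth` element of a `screen_sim`).
#' @param top_fraction Fraction of the gene universe that defines the top
#'   list (default 0.01).
#' @return List with `precision`, `recall`, `mean_rank` (mean rank of the
#'   planted genes), `n_top` and `top_genes`.
#' @export
recovery_metrics <- function(ranking, truth, top_fraction = 0.01) {
  planted <- truth$genes$gene[truth$genes$is_suppressor]
  if (length(planted) == 0) stop("truth contains no planted suppressor genes")
  n_genes <- nrow(ranking)
  n_top <- max(1L, floor(top_fraction * n_genes))
  if (inherits(ranking, "filtered_ranking")) {
    rk <- ifelse(is.na(ranking$comprehensive_rank),
                 n_genes, ranking$comprehensive_rank)
  } else {
    rk <- ranking$final_rank
  }
  if (!any(planted %in% ranking$gene))
    stop("no planted gene present in the ranking's gene universe")
  top_genes <- ranking$gene[rk <= n_top]
  hit <- intersect(top_genes, planted)
  list(precision = if (length(top_genes) > 0)
         length(hit) / length(top_genes) else NA_real_,
       recall = length(hit) / length(planted),
       mean_rank = mean(rk[ranking$gene %in% planted]),
       n_top = n_top, top_genes = top_genes)
}
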