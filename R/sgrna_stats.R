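#' Fit a negative-binomial mean-variance model on control samples
#'
#' Models the variance of normalized sgRNA counts as
#' `var(mu) = mu + k * mu^b` with `k > 0`, so the predicted variance never
#' falls below the mean. `k` and `b` are estimated by regressing
#' `log(var - mean)` on `log(mean)` across sgRNAs whose empirical variance
#' exceeds their mean. With a single control sample (no replication), or
#' fewer than `min_points` overdispersed sgRNAs, the function falls back to
#' `var = mu + k0 * mu^2` with a warning.
#'
#' @param norm_counts `normalized_counts` object from
#'   [median_ratio_normalize()].
#' @param control_samples Character vector of control sample ids (columns of
#'   the normalized matrix), e.g. the primary-tumor samples of all mice.
#' @param fallback_k0 Quadratic overdispersion used by the fallback model
#'   (default 0.01).
#' @param min_points Minimum number of overdispersed sgRNAs required to fit
#'   the regression (default 10).
#' @return Object of class `variance_model`: list with `k`, `b`, `fallback`
#'   (logical) and `n_points` used in the fit.
#' @export
fit_variance_model <- function(norm_counts, control_samples,
                               fallback_k0 = 0.01, min_points = 10) {
  stopifnot(inherits(norm_counts, "normalized_counts"), fallback_k0 > 0)
  missing <- setdiff(control_samples, colnames(norm_counts$norm))
  if (length(missing) > 0)
    stop("control sample(s) not in normalized counts: ",
         paste(missing, collapse = ", "))
  x <- norm_counts$norm[, control_samples, drop = FALSE]
  fallback <- function(n_pts) {
    structure(list(k = fallback_k0, b = 2, fallback = TRUE, n_points = n_pts),
              class = "variance_model")
  }
  if (ncol(x) < 2) {
    warning("single control sample: using fallback variance model var = mu + ",
            fallback_k0, " * mu^2")
    return(fallback(0L))
  }
  mu <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  keep <- is.finite(mu) & is.finite(v) & mu > 0 & v > mu
  if (sum(keep) < min_points) {
    warning("fewer than ", min_points, " overdispersed sgRNAs; ",
            "using fallback variance model")
    return(fallback(sum(keep)))
  }
  fit <- stats::lm(log(v[keep] - mu[keep]) ~ log(mu[keep]))
  structure(list(k = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 fallback = FALSE, n_points = sum(keep)),
            class = "variance_model")
}

#' @export
print.variance_model <- function(x, ...) {
  cat(sprintf("Variance model: var(mu) = mu + %.4g * mu^%.3f%s (%d sgRNAs)\n",
              x$k, x$b, if (x$fallback) " [fallback]" else "", x$n_points))
  invisible(x)
}

#' Predicted variance at a given mean
#'
#' @param model `variance_model` object.
#' @param mu Vector of means (> 0).
#' @return `mu + k * mu^b`, always at least `mu`.
#' @export
predict_variance <- function(model, mu) {
  stopifnot(inherits(model, "variance_model"))
  mu + model$k * mu^model$b
}

#' Negative-binomial tail probabilities for observed counts
#'
#' Parameterizes the negative binomial by mean `mu` and variance `v` via
#' `size = mu^2 / (v - mu)`; when `v <= mu` the Poisson tail is used.
#' Tail convention: `p_high = P(X >= t)` (enrichment), `p_low = P(X <= t)`
#' (depletion), with `t` a non-negative integer. Both probabilities are
#' clamped away from exact 0.
#'
#' @param t Integer observed value(s).
#' @param mu Mean(s) under the null, > 0.
#' @param v Variance(s) under the null.
#' @return List with vectors `p_low` and `p_high` in (0, 1].
#' @export
nb_tail_probs <- function(t, mu, v) {
  stopifnot(length(mu) == length(t) || length(mu) == 1 || length(t) == 1)
  t <- round(t)
  if (any(t < 0)) stop("t must be non-negative")
  n <- max(length(t), length(mu), length(v))
  t <- rep_len(t, n); mu <- rep_len(mu, n); v <- rep_len(v, n)
  over <- v > mu
  log_p_low <- log_p_high <- numeric(n)
  if (any(over)) {
    r <- mu[over]^2 / (v[over] - mu[over])
    # suppressed warning: pbeta's log-space series can underflow to -Inf
    # for astronomically extreme tails; -Inf orders correctly
    log_p_low[over] <- suppressWarnings(
      stats::pnbinom(t[over], size = r, mu = mu[over], log.p = TRUE))
    log_p_high[over] <- suppressWarnings(
      stats::pnbinom(t[over] - 1, size = r, mu = mu[over],
                     lower.tail = FALSE, log.p = TRUE))
  }
  if (any(!over)) {
    log_p_low[!over] <- suppressWarnings(
      stats::ppois(t[!over], mu[!over], log.p = TRUE))
    log_p_high[!over] <- suppressWarnings(
      stats::ppois(t[!over] - 1, mu[!over], lower.tail = FALSE,
                   log.p = TRUE))
  }
  log_p_high <- pmin(log_p_high, 0)
  # tails are carried in log space as well: extreme enrichment underflows
  # the linear scale to 0, and the clamped ties would erase the ranking
  # among the strongest sgRNAs
  list(p_low = pmax(exp(log_p_low), .Machine$double.xmin),
       p_high = pmax(exp(log_p_high), .Machine$double.xmin),
       log_p_low = log_p_low, log_p_high = log_p_high)
}

#' Per-sgRNA paired enrichment statistics (metastasis vs primary, one mouse)
#'
#' For each sgRNA, the control (primary tumor) normalized count plus a
#' pseudocount defines the null mean `mu`; the variance comes from the fitted
#' mean-variance model; the treatment (metastasis) value `t` is scored with
#' negative-binomial tails. Small `p_high` marks sgRNAs enriched in the
#' metastasis (positive selection, the signature of a knocked-out metastasis
#' suppressor); small `p_low` marks depletion. The same pseudocount is added
#' to both sides so that identical counts give a score of exactly zero.
#'
#' @param norm_counts `normalized_counts` object covering both samples.
#' @param model `variance_model` from [fit_variance_model()].
#' @param meta Sample metadata data frame (see [read_sample_meta()]).
#' @param mouse_id Mouse whose paired samples are compared.
#' @param treatment_tissue Tissue of the treatment sample (default
#'   `"lung_met"`).
#' @param control_tissue Tissue of the control sample (default `"primary"`).
#' @param cell_line Optional cell line to disambiguate when `meta` spans
#'   several lines.
#' @param pseudocount Added to both control and treatment values (default 1).
#' @return Data frame of class `sgrna_score_table` with columns `sgrna`,
#'   `control_mean`, `treatment`, `score`, `p_low`, `p_high` (and their
#'   log-scale versions `log_p_low`, `log_p_high`, which preserve the
#'   ordering when the linear scale underflows), `rank_low`, `rank_high`;
#'   ranks are 1-based permutations (1 = most significant), ties broken by
#'   sgRNA id. The comparison label is stored in `attr(, "comparison")`.
#' @export
score_sgrnas_paired <- function(norm_counts, model, meta, mouse_id,
                                treatment_tissue = "lung_met",
                                control_tissue = "primary",
                                cell_line = NULL, pseudocount = 1) {
  stopifnot(inherits(norm_counts, "normalized_counts"),
            inherits(model, "variance_model"), pseudocount >= 0)
  meta <- validate_sample_meta(meta)
  if (!is.null(cell_line)) meta <- meta[meta$cell_line == cell_line, ]
  find_sample <- function(tissue) {
    id <- meta$sample_id[meta$mouse_id == mouse_id & meta$tissue == tissue]
    if (length(id) != 1 || !(id %in% colnames(norm_counts$norm)))
      stop("no ", tissue, " sample for mouse ", mouse_id)
    id
  }
  ctrl <- find_sample(control_tissue)
  trt <- find_sample(treatment_tissue)
  mu <- norm_counts$norm[, ctrl] + pseudocount
  t_obs <- round(norm_counts$norm[, trt] + pseudocount)
  v <- predict_variance(model, mu)
  tails <- nb_tail_probs(t_obs, mu, v)
  sg <- rownames(norm_counts$norm)
  res <- data.frame(sgrna = sg,
                    control_mean = unname(mu),
                    treatment = unname(t_obs),
                    score = unname((t_obs - mu) / sqrt(v)),
                    p_low = unname(tails$p_low),
                    p_high = unname(tails$p_high),
                    log_p_low = unname(tails$log_p_low),
                    log_p_high = unname(tails$log_p_high),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$rank_low <- rank_1n(res$log_p_low, res$sgrna)
  res$rank_high <- rank_1n(res$log_p_high, res$sgrna)
  attr(res, "comparison") <- list(mouse = mouse_id,
                                  treatment = treatment_tissue,
                                  control = control_tissue)
  class(res) <- c("sgrna_score_table", "data.frame")
  res
}

# deterministic 1..n ranking: ascending primary key(s), final tie-break by id
rank_1n <- function(...) {
  keys <- list(...)
  ord <- do.call(order, keys)
  r <- integer(length(keys[[1]]))
  r[ord] <- seq_along(r)
  r
}
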