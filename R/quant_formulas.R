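#' Bin per-cell RNAscope dot counts
#'
#' Bins follow the vendor's heterogeneous-expression convention: bin 0 =
#' 0 dots/cell, bin 1 = 1-3, bin 2 = 4-9, bin 3 = 10-15, bin 4 = >15.
#'
#' @param dots_per_cell Non-negative integer vector, one value per cell.
#' @return Object of class `dot_bin_counts`: named integer vector
#'   `bin0`..`bin4`.
#' @export
bin_dots <- function(dots_per_cell) {
  if (length(dots_per_cell) == 0) stop("no cells supplied")
  if (any(is.na(dots_per_cell)) || any(dots_per_cell < 0) ||
      any(dots_per_cell != floor(dots_per_cell)))
    stop("dots per cell must be non-negative integers")
  bins <- cut(dots_per_cell, breaks = c(-0.5, 0.5, 3.5, 9.5, 15.5, Inf),
              labels = paste0("bin", 0:4))
  structure(as.integer(table(bins)), names = paste0("bin", 0:4),
            class = "dot_bin_counts")
}

#' RNAscope H-score from binned dot counts
#'
#' `H = sum_k k * (% of cells in bin k)`, ranging 0-400. Percentages are
#' computed from exact counts (no pre-rounding).
#'
#' @param bins Named numeric vector `bin0`..`bin4` of cell counts (e.g. from
#'   [bin_dots()]); total must be positive.
#' @return H-score in `[0, 400]`.
#' @export
h_score <- function(bins) {
  if (length(bins) != 5 || any(bins < 0))
    stop("bins must be 5 non-negative cell counts (bin0..bin4)")
  total <- sum(bins)
  if (total == 0) stop("no cells: total bin count is zero")
  sum((0:4) * 100 * as.numeric(bins) / total)
}

#' ChIP-qPCR percent input
#'
#' `percent input = 100% x 2^(CT_input - CT_IP)`. An optional dilution
#' adjustment subtracts `log2(100 / input_percent)` from the input CT first
#' (for inputs that were a fraction of the IP material); by default no
#' adjustment is applied, matching the plain formula.
#'
#' @param ct_input CT of the input sample.
#' @param ct_ip CT of the immunoprecipitated sample.
#' @param input_percent Optional percentage of material used as input
#'   (e.g. 1 for a 1% input); `NULL` (default) applies no correction.
#' @return Percent input (strictly decreasing in `ct_ip`).
#' @export
percent_input <- function(ct_input, ct_ip, input_percent = NULL) {
  stopifnot(is.finite(ct_input), is.finite(ct_ip))
  if (!is.null(input_percent)) {
    stopifnot(input_percent > 0, input_percent <= 100)
    ct_input <- ct_input - log2(100 / input_percent)
  }
  100 * 2^(ct_input - ct_ip)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((CT_target,sample - CT_ref,sample) - (CT_target,control -
#' CT_ref,control))`.
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene CTs in
#'   the sample of interest.
#' @param ct_target_ctrl,ct_ref_ctrl Target and reference-gene CTs in the
#'   calibrator/control.
#' @return Fold change relative to the control.
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_ctrl, ct_ref_ctrl)
  stopifnot(all(is.finite(cts)))
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Caliper tumor volume
#'
#' `V = 0.5 x L x W^2` (mm^3). Warns (but still computes) when the supplied
#' width exceeds the length.
#'
#' @param length_mm Tumor length in mm.
#' @param width_mm Tumor width in mm.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0))
    stop("length and width must be non-negative")
  if (any(width_mm > length_mm))
    warning("width exceeds length; computing anyway")
  0.5 * length_mm * width_mm^2
}

#' Single-cell migration track statistics
#'
#' From an ordered track of (t, x, y) samples: accumulated path length (sum
#' of step lengths), Euclidean distance between end and start, velocity
#' (accumulated distance over elapsed time — the track-analysis convention
#' for speed), and directionality (Euclidean / accumulated; 1 for a
#' perfectly straight track, 0 when the track returns to its start or does
#' not move).
#'
#' @param track Data frame with numeric columns `t`, `x`, `y`; `t` strictly
#'   increasing; at least two samples.
#' @return List with `accumulated_distance`, `euclidean_distance`,
#'   `velocity`, `directionality`.
#' @export
track_stats <- function(track) {
  stopifnot(is.data.frame(track), all(c("t", "x", "y") %in% names(track)))
  if (nrow(track) < 2) stop("track needs at least two samples")
  if (any(diff(track$t) <= 0)) stop("track times must be strictly increasing")
  dx <- diff(track$x)
  dy <- diff(track$y)
  acc <- sum(sqrt(dx^2 + dy^2))
  euc <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
                (track$y[nrow(track)] - track$y[1])^2)
  list(accumulated_distance = acc,
       euclidean_distance = euc,
       velocity = acc / (track$t[nrow(track)] - track$t[1]),
       directionality = if (acc == 0) 0 else euc / acc)
}
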