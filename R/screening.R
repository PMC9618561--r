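# Plate-screening statistics: threshold hit calling against negative
# controls, selection-accounting percentages, the two comparison tests
# used on screening readouts, and robust Z-prime plate QC.

#' Plate table of screening signals
#'
#' @param signals named numeric vector (names are well ids).
#' @param roles character vector aligned with `signals`; each of
#'   `"sample"`, `"positive_control"`, `"negative_control"`.
#' @param plate_id plate label.
#' @return an object of class `plate_table`.
#' @export
plate_table <- function(signals, roles, plate_id = "plate1") {
  if (length(signals) != length(roles))
    bcr_error("signals and roles must be aligned", "argument_error")
  ok <- roles %in% c("sample", "positive_control", "negative_control")
  if (!all(ok))
    bcr_error("roles must be sample/positive_control/negative_control",
              "argument_error")
  if (is.null(names(signals)))
    names(signals) <- sprintf("W%03d", seq_along(signals))
  structure(list(signals = signals, roles = roles, plate_id = plate_id),
            class = "plate_table")
}

#' Read a long-format plate table (plate_id, well, role, signal)
#'
#' @param path TSV path with columns `plate_id`, `well`, `role`, `signal`.
#' @return a list of `plate_table` objects, one per plate id.
#' @export
read_plate_table <- function(path) {
  df <- read_tsv(path)
  need <- c("plate_id", "well", "role", "signal")
  if (!all(need %in% names(df)))
    bcr_error(paste("plate table needs columns:", paste(need, collapse = ", ")),
              "io_error")
  lapply(split(df, df$plate_id), function(d)
    plate_table(stats::setNames(d$signal, d$well), d$role, d$plate_id[1]))
}

#' Call hits as wells at or above a fold threshold over negative controls
#'
#' A sample well is a hit iff its signal is `>= fold_threshold` times the
#' mean of the negative-control wells (the boundary itself counts as a
#' hit). Hit calling is scale invariant.
#'
#' @param plate a [plate_table()].
#' @param fold_threshold fold over negative-control mean (default 10).
#' @return list with `labels` (named logical over sample wells), `n_hits`,
#'   and the `threshold` signal used.
#' @export
call_hits <- function(plate, fold_threshold = 10) {
  stopifnot(inherits(plate, "plate_table"))
  neg <- plate$signals[plate$roles == "negative_control"]
  if (length(neg) < 1L)
    bcr_error("at least one negative-control well required", "argument_error")
  neg_mean <- mean(neg)
  if (neg_mean <= 0)
    bcr_error("negative-control mean must be positive", "argument_error")
  thr <- fold_threshold * neg_mean
  smp <- plate$signals[plate$roles == "sample"]
  labels <- smp >= thr
  list(labels = labels, n_hits = sum(labels), threshold = thr)
}

#' Percent positive, rounded half-up to an integer
#'
#' @param n_pos,n_total positive and total counts (`0 <= n_pos <= n_total`,
#'   `n_total >= 1`).
#' @return integer percent.
#' @export
#' @examples
#' percent_positive(49, 196)  # 25
#' percent_positive(54, 75)   # 72
percent_positive <- function(n_pos, n_total) {
  if (any(n_total < 1))
    bcr_error("n_total must be >= 1", "argument_error")
  if (any(n_pos < 0) || any(n_pos > n_total))
    bcr_error("need 0 <= n_pos <= n_total", "argument_error")
  as.integer(round_half_up(100 * n_pos / n_total))
}

#' Selection-accounting percentages
#'
#' Percent of antigen-selected cells relative to total B cells and to IgG+
#' B cells, each rounded half-up to two decimals -- the two accounting
#' columns of a bulk-selection campaign table.
#'
#' @param counts list or one-row data.frame with numeric fields `selected`,
#'   `b_cells`, `igg_b_cells` (same units, e.g. 1e6 cells).
#' @return named numeric vector `c(pct_of_b_cells, pct_of_igg)`.
#' @export
#' @examples
#' selection_percentages(list(selected = 0.13, b_cells = 67, igg_b_cells = 19))
selection_percentages <- function(counts) {
  s <- as.numeric(counts$selected)
  b <- as.numeric(counts$b_cells)
  g <- as.numeric(counts$igg_b_cells)
  if (b <= 0 || g <= 0)
    bcr_error("denominators must be positive", "argument_error")
  c(pct_of_b_cells = round_half_up(100 * s / b, 2),
    pct_of_igg = round_half_up(100 * s / g, 2))
}

#' Two-tailed unpaired t test
#'
#' Student's two-sample t (pooled variance) by default, Welch variant with
#' `equal_variance = FALSE`.
#'
#' @param x,y numeric samples of size >= 2.
#' @param equal_variance pool the variances (classical Student test)?
#' @return list with `t` and two-sided `p`.
#' @export
unpaired_t_test <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    bcr_error("both samples need >= 2 observations", "argument_error")
  if (stats::var(x) + stats::var(y) == 0)
    bcr_error("degenerate (zero) variance in both samples", "argument_error")
  ht <- stats::t.test(x, y, var.equal = equal_variance,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The p value is
#' exact (full enumeration of rank arrangements) when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric samples (each >= 1 observation).
#' @return list with `U` (for the first sample) and two-sided `p`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    bcr_error("both samples need >= 1 observation", "argument_error")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= 12L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(ht$statistic), p = min(1, ht$p.value))
}

#' Z-prime plate-quality factor from control separation
#'
#' Robust form (default): `1 - 3*(rsd_pos + rsd_neg) / |median difference|`
#' with `rsd = 1.4826 * MAD`. `robust = FALSE` gives the classical
#' mean/standard-deviation Z-prime. Plates with a factor below 0.5 are
#' flagged for masking.
#'
#' @param pos,neg positive / negative control signals (>= 2 values each).
#' @param robust use median/MAD (the "R" in RZ')?
#' @param mask_below masking threshold (default 0.5).
#' @return list with `z_prime` and logical `masked`.
#' @export
robust_zprime <- function(pos, neg, robust = TRUE, mask_below = 0.5) {
  if (length(pos) < 2L || length(neg) < 2L)
    bcr_error("need >= 2 values per control group", "argument_error")
  if (robust) {
    loc_p <- stats::median(pos); loc_n <- stats::median(neg)
    sp <- stats::mad(pos); sn <- stats::mad(neg)  # 1.4826 * MAD
  } else {
    loc_p <- mean(pos); loc_n <- mean(neg)
    sp <- stats::sd(pos); sn <- stats::sd(neg)
  }
  if (loc_p == loc_n)
    bcr_error("control locations are equal; Z-prime undefined",
              "argument_error")
  z <- 1 - 3 * (sp + sn) / abs(loc_p - loc_n)
  list(z_prime = z, masked = z < mask_below)
}
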