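#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.125 -> 0.13 at 2 digits), the convention used when reporting
#' cohort percentages. Base R's `round()` rounds ties to even instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(100 * 543 / 2138, 2) # 25.40
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage table with reporting-style rounding
#'
#' Computes `100 * numerator / denominator` rounded half away from zero to
#' two decimals, the format used for cohort proportions (e.g. 543/2138 ->
#' 25.40).
#'
#' @param numerator,denominator Integer vectors (recycled); denominators
#'   must be positive.
#' @param label Optional character vector naming each row.
#' @return A tibble with columns `label`, `numerator`, `denominator`,
#'   `percent`.
#' @examples
#' proportion_table(c(543, 809), 2138)
#' @export
proportion_table <- function(numerator, denominator, label = NULL) {
  if (any(denominator <= 0)) {
    abort("`denominator` must be positive.", class = "trajsat_error")
  }
  n <- max(length(numerator), length(denominator))
  numerator <- rep_len(numerator, n)
  denominator <- rep_len(denominator, n)
  label <- if (is.null(label)) rep_len(NA_character_, n) else rep_len(label, n)
  tibble::tibble(
    label = label,
    numerator = as.integer(numerator),
    denominator = as.integer(denominator),
    percent = round_half_up(100 * numerator / denominator, 2)
  )
}

# Row-wise log(sum(exp(m))) with the usual max-shift stabilisation.
row_log_sum_exp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

# Deterministic per-stage seed stream derived from one master seed,
# kept inside the 32-bit integer range R requires.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 16807) %% 2147483647L)
}

stop_config <- function(msg) abort(msg, class = "trajsat_config_error")
stop_data <- function(msg) abort(msg, class = "trajsat_data_error")
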