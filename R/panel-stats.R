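#' Combine per-locus forensic parameters across a panel
#'
#' Across-loci combinations for independent loci:
#' `CPM = prod(PM_i)` (cumulative match probability),
#' `TDP = 1 - prod(1 - PD_i)` (total discrimination power), and
#' `CPE = 1 - prod(1 - PE_i)` (combined probability of exclusion).
#' Products are accumulated in log space so 40-plus-locus panels (CPM of
#' order 1e-18 and smaller) never underflow intermediate steps, and CPM is
#' also reported as a `"mantissaE-exponent"` string for report display.
#'
#' @param stats Per-locus tibble as returned by [locus_stats()] (columns
#'   `pm`, `pd`, `pe`, optionally `population`).
#' @return Tibble with one row per population (or a single row if no
#'   `population` column) and columns `population`, `k`, `cpm`, `cpm_str`,
#'   `tdp`, `cpe`.
#' @export
combine_panel <- function(stats) {
  stopifnot(all(c("pm", "pd", "pe") %in% names(stats)))
  if (nrow(stats) == 0L) stop("empty per-locus table", call. = FALSE)
  if (!"population" %in% names(stats)) stats$population <- "all"
  combine_one <- function(d) {
    stopifnot(
      all(d$pm >= 0 & d$pm <= 1),
      all(d$pd >= 0 & d$pd <= 1),
      all(d$pe >= 0 & d$pe <= 1)
    )
    log_cpm <- sum(log(d$pm))
    cpm <- exp(log_cpm)
    # mantissa x 10^exponent from the log-space accumulator, not from the
    # (possibly subnormal) double
    e10 <- floor(log_cpm / log(10))
    mant <- exp(log_cpm - e10 * log(10))
    tibble::tibble(
      k = nrow(d),
      cpm = cpm,
      cpm_str = sprintf("%.5fE%+d", mant, e10),
      tdp = -expm1(sum(log1p(-d$pd))),
      cpe = -expm1(sum(log1p(-d$pe)))
    )
  }
  stats |>
    dplyr::group_by(.data$population) |>
    dplyr::group_modify(~combine_one(.x)) |>
    dplyr::ungroup()
}
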