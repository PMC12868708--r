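# Discrepancy between combined genetic risk and observed diagnosis
# prevalence.  A risk/prevalence ratio well above the regional norm flags
# apparent under-diagnosis (assuming penetrance is uniform across regions,
# an assumption every report labels explicitly).

#' Ratio of genetic risk to observed prevalence
#'
#' @param risk_pct combined genetic risk, percent.
#' @param prevalence_pct observed prevalence, percent.  Vectorised.
#' @return `risk_pct / prevalence_pct` at full precision (display at 2
#'   decimals); `NA` with a warning where prevalence is zero.
#' @examples
#' risk_prevalence_ratio(0.427, 0.127)  # 3.36 (rounded for display)
#' @export
risk_prevalence_ratio <- function(risk_pct, prevalence_pct) {
  stopifnot(is.numeric(risk_pct), is.numeric(prevalence_pct),
            length(risk_pct) == length(prevalence_pct),
            all(risk_pct >= 0), all(prevalence_pct >= 0))
  zero <- prevalence_pct == 0
  if (any(zero)) {
    warning("zero prevalence: ratio undefined for ", sum(zero),
            " record(s)", call. = FALSE)
  }
  ifelse(zero, NA_real_, risk_pct / prevalence_pct)
}

#' Rank regions by apparent under-diagnosis
#'
#' @param records data frame with columns `region`, `prevalence_pct`,
#'   `risk_pct`.
#' @param top_k how many top-ratio regions to flag (default 2).
#' @return data frame with an added `ratio` column, sorted by decreasing
#'   ratio (ties broken by region name), plus a logical `flagged` column
#'   marking the `top_k` highest ratios.
#' @export
rank_discrepancies <- function(records, top_k = 2) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("region", "prevalence_pct", "risk_pct") %in%
                  names(records)),
            top_k >= 0)
  out <- records
  out$ratio <- risk_prevalence_ratio(out$risk_pct, out$prevalence_pct)
  out <- out[order(-out$ratio, out$region), , drop = FALSE]
  out$flagged <- seq_len(nrow(out)) <= top_k
  rownames(out) <- NULL
  out
}

#' Pearson correlation between prevalence and genetic risk
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero variance.
#' @return the product-moment correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}
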