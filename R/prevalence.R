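# Prevalence arithmetic on diagnosis-count tables, following the
# conventions of national EHR feasibility extracts: raw prevalence only
# (no age standardisation), disclosure-rounded counts used as-is.

#' Prevalence of a diagnosis in one stratum
#'
#' @param count diagnosed individuals (may be disclosure-rounded).
#' @param denominator stratum population; must be positive.
#' @param stratum optional stratum label.
#' @return a `prevalence_record`: list with `stratum`, `count`,
#'   `denominator`, `prevalence_pct` (exact, `100 * count / denominator`)
#'   and `one_in` (`round(denominator / count)`; `NA` when count is 0).
#' @examples
#' prevalence(1355, 225320)  # 0.6014 %, 1 in 166
#' @export
prevalence <- function(count, denominator, stratum = NA_character_) {
  stopifnot(is.numeric(count), is.numeric(denominator),
            length(count) == 1, length(denominator) == 1,
            denominator > 0, count >= 0)
  if (count > denominator) {
    stop("count exceeds denominator", call. = FALSE)
  }
  structure(
    list(stratum = stratum, count = as.integer(count),
         denominator = as.integer(denominator),
         prevalence_pct = 100 * count / denominator,
         one_in = if (count > 0) round(denominator / count) else NA_real_),
    class = "prevalence_record"
  )
}

#' @export
print.prevalence_record <- function(x, ...) {
  cat(sprintf("<prevalence_record>%s %s / %s = %.4f%% (1 in %s)\n",
              if (is.na(x$stratum)) "" else paste0(" ", x$stratum, ":"),
              format(x$count, big.mark = ","),
              format(x$denominator, big.mark = ","),
              x$prevalence_pct,
              if (is.na(x$one_in)) "-" else format(x$one_in)))
  invisible(x)
}

#' Stratified prevalence table
#'
#' @param table a `diagnosis_table` (columns `stratum`, `count`,
#'   `denominator`).
#' @return data frame `stratum`, `count`, `denominator`, `prevalence_pct`,
#'   `one_in`, sorted by decreasing raw prevalence; ties broken by stratum
#'   name so the ordering is deterministic.
#' @export
stratified_prevalence <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1,
            all(c("stratum", "count", "denominator") %in% names(table)))
  recs <- lapply(seq_len(nrow(table)), function(i) {
    p <- prevalence(table$count[i], table$denominator[i], table$stratum[i])
    data.frame(stratum = p$stratum, count = p$count,
               denominator = p$denominator,
               prevalence_pct = p$prevalence_pct, one_in = p$one_in,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(-out$prevalence_pct, out$stratum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spread of prevalence across deprivation deciles
#'
#' Percent excess of the highest over the lowest decile prevalence,
#' `(max/min - 1) * 100`, rounded to the nearest integer.
#'
#' @param prevalences numeric vector of decile prevalences (>= 2 values).
#' @return integer percent excess; `NA` when the minimum is zero.
#' @examples
#' decile_spread(c(0.154, 0.173))  # 12
#' @export
decile_spread <- function(prevalences) {
  stopifnot(is.numeric(prevalences), length(prevalences) >= 2,
            all(prevalences >= 0))
  if (min(prevalences) == 0) return(NA_integer_)
  as.integer(round((max(prevalences) / min(prevalences) - 1) * 100))
}
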