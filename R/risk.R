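# Penetrance-weighted combined genetic risk: the probability that a person
# in a region develops clinical haemochromatosis, summed over the two risk
# genotypes (C282Y homozygote, C282Y/H63D compound heterozygote) weighted by
# their penetrances.  Simple H63D genotypes carry no risk in this model.

#' Combined genetic risk of haemochromatosis
#'
#' `risk = pen_hom * p_C^2 + pen_cmpd * 2 * p_C * p_H`, the product of
#' penetrances and HWE genotype frequencies summed over the two risk
#' genotypes.
#'
#' @param freqs an [hfe_frequencies()] object.
#' @param pen a [penetrance_model()]; defaults to the male model.
#' @param region optional region label carried into the result.
#' @return a `regional_risk`: list with `region`, `risk`, `risk_pct`,
#'   `one_in` (formatted) and the penetrance label.
#' @examples
#' combined_risk(hfe_frequencies(0.0780, 0.1510))  # 0.482 %
#' @export
combined_risk <- function(freqs, pen = penetrance_model(), region = NA) {
  stopifnot(inherits(freqs, "hfe_freq"), inherits(pen, "penetrance_model"))
  g <- predict_genotypes(freqs)
  risk <- pen$pen_hom_c282y * g$hom_c282y + pen$pen_cmpd_het * g$cmpd_het
  structure(
    list(region = region, risk = risk, risk_pct = 100 * risk,
         one_in = format_one_in(risk), penetrance = pen$label),
    class = "regional_risk"
  )
}

#' @export
print.regional_risk <- function(x, ...) {
  cat(sprintf(
    "<regional_risk>%s risk %.3f%% (one in %s) [penetrance: %s]\n",
    if (is.na(x$region)) "" else paste0(" ", x$region, ":"),
    x$risk_pct, x$one_in, x$penetrance))
  invisible(x)
}

#' Regional genetic-risk table
#'
#' @param freqs data frame with columns `region`, `p_c282y`, `p_h63d`
#'   (as returned by [estimate_frequencies()]).
#' @param pen a [penetrance_model()].
#' @return data frame `region`, `p_c282y`, `p_h63d`, `risk`, `risk_pct`,
#'   `one_in`, sorted by decreasing risk, ties broken by region name.
#' @export
risk_table <- function(freqs, pen = penetrance_model()) {
  stopifnot(is.data.frame(freqs), nrow(freqs) >= 1,
            all(c("region", "p_c282y", "p_h63d") %in% names(freqs)))
  risk <- vapply(seq_len(nrow(freqs)), function(i) {
    combined_risk(hfe_frequencies(freqs$p_c282y[i], freqs$p_h63d[i]),
                  pen)$risk
  }, numeric(1))
  out <- data.frame(
    region = freqs$region,
    p_c282y = freqs$p_c282y, p_h63d = freqs$p_h63d,
    risk = risk, risk_pct = 100 * risk,
    one_in = format_one_in(risk),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$risk, out$region), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "penetrance") <- pen$label
  out
}
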