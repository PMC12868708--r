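# Shared helpers: genotype-class vocabulary, "one in N" formatting, seeding.

# The six genotype classes of the triallelic HFE locus (WT, C282Y, H63D),
# in the fixed order used by every multinomial draw and probability vector.
GENOTYPE_CLASSES <- c(
  "WT/WT", "WT/C282Y", "WT/H63D",
  "C282Y/C282Y", "C282Y/H63D", "H63D/H63D"
)

# Copies of each pathogenic allele carried by each class, same order.
C282Y_DOSE <- c(0L, 1L, 0L, 2L, 1L, 0L)
H63D_DOSE  <- c(0L, 0L, 1L, 0L, 1L, 2L)

#' Express a frequency as "one in N"
#'
#' @param f a frequency in \[0, 1\].
#' @return `round(1 / f)`; `Inf` when `f` is zero (the undefined sentinel).
#' @examples
#' one_in(0.00608)  # 164
#' @export
one_in <- function(f) {
  stopifnot(is.numeric(f), all(f >= 0 & f <= 1))
  ifelse(f > 0, round(1 / f), Inf)
}

#' Format a frequency as a compact "one in" label
#'
#' N below 1000 is printed as-is; N of 1000 and above at two significant
#' figures with a "k" suffix; N of one million and above with "M"
#' (so 1/0.0000613 prints as "16k").
#'
#' @param f a frequency in \[0, 1\] (vectorised).
#' @return character vector; `"Inf"` where `f` is zero.
#' @examples
#' format_one_in(0.0780^2)       # "164"
#' format_one_in((34 / 4342)^2)  # "16k"
#' @export
format_one_in <- function(f) {
  stopifnot(is.numeric(f), all(f >= 0 & f <= 1))
  vapply(f, function(fi) {
    if (fi <= 0) return("Inf")
    n <- 1 / fi
    if (n >= 1e6) {
      paste0(format(signif(n, 2) / 1e6, trim = TRUE), "M")
    } else if (n >= 1000) {
      paste0(format(signif(n, 2) / 1000, trim = TRUE), "k")
    } else {
      as.character(round(n))
    }
  }, character(1))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# round to the nearest multiple of 5 (DigiTrials disclosure convention)
round_nearest_5 <- function(x) as.integer(round(x / 5) * 5)
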