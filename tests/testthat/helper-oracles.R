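# Independent oracles used across the suite.  These re-derive expected
# results by brute force or direct formula, independently of the package's
# implementation paths.

# adjusted Rand index between two labellings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sij <- comb2(tab)
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  expected <- si * sj / choose(sum(tab), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Pearson chi-square of a 2x2 table by the direct O/E formula
chisq_2x2_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# HWE chi-square by the direct O/E formula
hwe_oracle <- function(obs) {
  n <- sum(obs)
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  sum((obs - e)^2 / e)
}

# Brute-force DBSCAN: core points by neighbourhood count (point included),
# clusters as connected components of the core-core eps-graph discovered in
# index order, border points assigned to the lowest-numbered adjacent
# component, everything else noise (0).  Mirrors the package's documented
# border tie-break without sharing any code with it.
dbscan_oracle <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  within <- d <= eps
  core <- rowSums(within) >= min_pts
  labels <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    comp <- comp + 1L
    frontier <- i
    labels[i] <- comp
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(v) {
        which(within[v, ] & core & labels == 0L)
      })))
      labels[nxt] <- comp
      frontier <- nxt
    }
  }
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    adjacent <- labels[within[i, ] & core]
    if (length(adjacent)) labels[i] <- min(adjacent)
  }
  labels
}

# small two-region spec set reused by several files
demo_specs <- function(n = 2000, asc = 1) {
  list(
    region_spec("North", 0.09, 0.15, n, ascertainment = asc),
    region_spec("South", 0.07, 0.15, n, ascertainment = asc)
  )
}

# the 13 printed regional (prevalence %, genetic risk %) pairs
table4 <- function() {
  data.frame(
    region = c("Cheshire & Merseyside", "London", "E-Midlands",
               "Manchester", "W-Midlands", "Southwest", "East", "Cornwall",
               "Yorkshire", "Lancashire & S Cumbria", "Southeast", "North",
               "Birmingham"),
    prevalence_pct = c(0.345, 0.195, 0.157, 0.214, 0.162, 0.131, 0.133,
                       0.159, 0.167, 0.188, 0.130, 0.160, 0.127),
    risk_pct = c(0.542, 0.376, 0.388, 0.532, 0.421, 0.356, 0.364, 0.441,
                 0.467, 0.525, 0.366, 0.519, 0.427),
    stringsAsFactors = FALSE
  )
}

# the 13 printed regional (count, denominator) pairs of the regional
# prevalence table
table3 <- function() {
  data.frame(
    stratum = c("Cheshire & Merseyside", "Manchester", "London",
                "Lancashire & S Cumbria", "Yorkshire", "W-Midlands",
                "North", "Cornwall", "E-Midlands", "East", "Southwest",
                "Southeast", "Birmingham"),
    count = c(6635, 3700, 4270, 2190, 5970, 3665, 3645, 760, 4715, 5300,
              4530, 6720, 1455),
    denominator = c(1924680, 1730190, 2184795, 1167890, 3569205, 2259905,
                    2277515, 478210, 3009140, 3993515, 3459385, 5176910,
                    1144980),
    stringsAsFactors = FALSE
  )
}
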