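# Independent brute-force oracles and tiny fixtures shared across tests.
# The oracles deliberately use the naive O(n^2) definitions, not the
# package's algorithms.

# Weighted relative Gini straight from the pairwise mean-difference formula.
gini_pairwise <- function(x, w) {
  s <- 0
  for (i in seq_along(x)) s <- s + sum(w[i] * w * abs(x[i] - x))
  mu <- sum(w * x) / sum(w)
  s / (2 * sum(w)^2 * mu)
}

# Kendall tau-b by pair enumeration with explicit tie bookkeeping.
tau_b_pairs <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
      if (a == 0) tx <- tx + 1
      if (b == 0) ty <- ty + 1
      if (a != 0 && b != 0) {
        if (a == b) C <- C + 1 else D <- D + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# A small fixed two-country, four-region registry for hand-traced cases.
toy_registry <- function() {
  data.frame(
    region_id = c("CA-ON", "CA-BC", "US-NY", "US-CA"),
    country_id = c("CA", "CA", "US", "US"),
    continent_id = rep("NAm", 4),
    group_label = rep("G1", 4),
    stringsAsFactors = FALSE
  )
}

# Affiliation records for one author from (year, region) pairs.
author_records <- function(author_id, years, regions, registry = toy_registry()) {
  lk <- setNames(registry$country_id, registry$region_id)
  data.frame(author_id = author_id, year = years, region_id = regions,
             country_id = unname(lk[regions]), stringsAsFactors = FALSE)
}

# A moderate simulated cohort reused by several suites.
default_test_cohort <- function(n_authors = 400, seed = 11, ...) {
  reg <- build_world(2, 3, 3, seed = seed)
  cfg <- cohort_config(n_authors = n_authors, seed = seed, ...)
  list(registry = reg, config = cfg, cohort = simulate_cohort(reg, cfg))
}
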