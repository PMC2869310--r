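# Shared fixtures and independent brute-force oracles.

# reference gene used across examples: X0 = 50, k = 0.01, M = 100
ref_gene <- function() gene_model(50, k = 0.01, M = 100)

# a deterministic (X0, k, M) grid of 100 calibrated models
# fractions capped at 0.8 and k at 0.05 so benefit/cost terms stay O(100):
# beyond that, catastrophic cancellation in B(1) - C(X0) exceeds the 1e-12
# absolute tolerance the calibration contract demands
param_grid <- function() {
  grid <- expand.grid(frac = seq(0.05, 0.8, length.out = 10),
                      k = c(0.001, 0.005, 0.01, 0.02, 0.05),
                      M = c(50, 100))
  grid$X0 <- grid$frac * grid$M
  grid
}

# brute-force Pearson correlation from the covariance/sd definition
oracle_pearson <- function(a, b) {
  n <- length(a)
  am <- a - sum(a) / n
  bm <- b - sum(b) / n
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# brute-force Pearson chi-square (no continuity correction) on a 2x2 table
oracle_chisq_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# records data.frame builder for retention analyses
make_records <- function(level, retained, id = sprintf("ohn_%04d", seq_along(level))) {
  data.frame(ohnologon_id = id, level = level, retained = retained,
             stringsAsFactors = FALSE)
}

# calibrated heterogeneous gene population on the generator's stated world
make_population_models <- function(n, mu = 8, sigma = 2, k = 0.01, M = 2^14,
                                   seed = 101) {
  set.seed(seed)
  X0 <- pmin(2^rnorm(n, mu, sigma), 0.9 * M)
  gene_model(X0, k = k, M = M)
}
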