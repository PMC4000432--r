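# Brute-force one-way ANOVA sums by explicit double loops, independent of
# the vectorised implementation under test.
oracle_anova <- function(y, g) {
  g <- as.character(g)
  labs <- unique(g)
  a <- length(labs)
  N <- length(y)
  gm <- 0
  for (v in y) gm <- gm + v
  gm <- gm / N
  SSB <- 0
  SSW <- 0
  n_i <- integer(a)
  for (k in seq_along(labs)) {
    yi <- y[g == labs[k]]
    n_i[k] <- length(yi)
    mi <- 0
    for (v in yi) mi <- mi + v
    mi <- mi / length(yi)
    SSB <- SSB + length(yi) * (mi - gm)^2
    for (v in yi) SSW <- SSW + (v - mi)^2
  }
  list(a = a, N = N, n_i = n_i, SSB = SSB, SSW = SSW,
       MSB = SSB / (a - 1), MSW = SSW / (N - a),
       F = (SSB / (a - 1)) / (SSW / (N - a)),
       n0 = (N - sum(n_i^2) / N) / (a - 1))
}

# textbook moment form of the ANOVA ICC, written independently of the
# package's Kish/F code paths
oracle_icc <- function(MSB, MSW, n0) (MSB - MSW) / (MSB + (n0 - 1) * MSW)

toy_dataset <- function() cluster_dataset(1:9, rep(c("g1", "g2", "g3"), each = 3))

random_balanced_dataset <- function(a, m) {
  cluster_dataset(stats::rnorm(a * m), rep(seq_len(a), each = m))
}

random_unbalanced_dataset <- function(a, m_range = c(2, 12)) {
  n_i <- sample(seq(m_range[1], m_range[2]), a, replace = TRUE)
  cluster_dataset(stats::rnorm(sum(n_i)), rep(seq_len(a), n_i))
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
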