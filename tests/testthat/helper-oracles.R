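# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately avoid the package's own code paths.

# All-pairs shortest paths by Floyd-Warshall on edge lengths 1/weight;
# efficiency = mean inverse distance over ordered pairs.
oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_density <- function(w) {
  n <- nrow(w)
  sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}

oracle_strength <- function(w) sum(w[upper.tri(w)])

oracle_degree <- function(w) as.integer(colSums(w > 0))

# Exhaustive pair-by-pair classification against a rich set of labels.
oracle_class_counts <- function(w, labels, rich) {
  counts <- c(rich_club = 0L, feeder = 0L, peripheral = 0L)
  n <- nrow(w)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] <= 0) next
    k <- (labels[i] %in% rich) + (labels[j] %in% rich)
    cl <- c("peripheral", "feeder", "rich_club")[k + 1L]
    counts[cl] <- counts[cl] + 1L
  }
  counts
}

# Symmetric random weighted graph on n nodes with edge probability p.
random_weights <- function(n, p = 0.5, wmax = 3) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  present <- runif(sum(ut)) < p
  vals <- ifelse(present, runif(sum(ut), 0.1, wmax), 0)
  w[ut] <- vals
  w + t(w)
}

# Wrap a plain weight matrix as a connectivity_matrix on letter labels.
make_cm <- function(w, rich = character(), labels = NULL) {
  n <- nrow(w)
  if (is.null(labels))
    labels <- if (n <= 26) LETTERS[seq_len(n)] else
      sprintf("R%03d", seq_len(n))
  p <- parcellation(labels, rich)
  svdnet:::new_connectivity_matrix(w, p, 0)
}

# One mediation data set whose population standardized paths are exactly
# (a, b, c') by unit-variance construction: sd(x) = sd(m) = sd(y) = 1.
simulate_mediation <- function(n, a, b, c_prime) {
  x <- rnorm(n)
  m <- a * x + sqrt(1 - a^2) * rnorm(n)
  resid_sd <- sqrt(max(1e-9, 1 - b^2 - c_prime^2 - 2 * a * b * c_prime))
  y <- b * m + c_prime * x + resid_sd * rnorm(n)
  data.frame(x = x, m = m, y = y)
}
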