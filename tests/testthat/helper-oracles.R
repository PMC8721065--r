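# Brute-force enumeration oracles, kept deliberately independent of the
# package's closed-form implementations: these operate on subject-level
# level pairs by direct counting.

oracle_pa <- function(x, y, k = 0L) 100 * mean(abs(x - y) <= k)

# RP: enumerate all n^2 ordered (X, Y) draws, X from the first
# assessment's observed levels, Y from the second's.
oracle_rp <- function(x, y) {
  n <- length(x)
  total <- 0
  for (xi in x) for (yj in y) total <- total + sign(yj - xi)
  total / n^2
}

# RC: enumerate all n^3 ordered triples (Y; X1, X2) and (X; Y1, Y2),
# counting strict betweenness (unordered extreme pair => factor 2 folded
# into the ordered enumeration).
oracle_rc <- function(x, y) {
  n <- length(x)
  between_y <- 0
  between_x <- 0
  for (yj in y) for (x1 in x) for (x2 in x)
    if (x1 < yj && yj < x2 || x2 < yj && yj < x1) between_y <- between_y + 1
  for (xi in x) for (y1 in y) for (y2 in y)
    if (y1 < xi && xi < y2 || y2 < xi && xi < y1) between_x <- between_x + 1
  (between_y - between_x) / n^3
}

# RV: rank subjects by own category with ties broken by the paired
# category; subjects with identical (x, y) share their mean rank.
oracle_augmented_ranks <- function(x, y, C) {
  r1 <- rank(x * C + y, ties.method = "average")
  r2 <- rank(y * C + x, ties.method = "average")
  list(r1 = r1, r2 = r2)
}

oracle_rv <- function(x, y, C) {
  r <- oracle_augmented_ranks(x, y, C)
  6 * sum((r$r1 - r$r2)^2) / length(x)^3
}

# Random paired sample as level vectors (uniform cell probabilities by
# default; optionally concentrated near the diagonal).
random_pairs <- function(n, C, diagonal_bias = 0) {
  x <- sample.int(C, n, replace = TRUE) - 1L
  y <- sample.int(C, n, replace = TRUE) - 1L
  if (diagonal_bias > 0) {
    keep <- stats::runif(n) < diagonal_bias
    y[keep] <- x[keep]
  }
  list(x = x, y = y, C = C)
}
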