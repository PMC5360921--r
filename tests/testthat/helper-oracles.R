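# Independent brute-force oracles used to validate the analytical code.
# Everything here is deliberately written by enumeration / first definition,
# sharing no code path with the package internals it checks.

# All non-negative integer matrices with the given row and column totals,
# returned as a list of matrices. Recursive: enumerate the first row as a
# bounded composition, recurse on the rest.
enumerate_tables <- function(k, d) {
  if (length(k) == 0L) {
    return(if (all(d == 0)) list(matrix(0L, 0, length(d))) else list())
  }
  rows <- bounded_compositions(k[1L], d)
  out <- list()
  for (r in rows) {
    for (rest in enumerate_tables(k[-1L], d - r)) {
      out[[length(out) + 1L]] <- rbind(r, rest, deparse.level = 0)
    }
  }
  out
}

# Compositions of total into length(bounds) parts with part_j <= bounds_j.
bounded_compositions <- function(total, bounds) {
  if (length(bounds) == 1L) {
    return(if (total <= bounds) list(total) else list())
  }
  out <- list()
  for (v in 0:min(total, bounds[1L])) {
    for (rest in bounded_compositions(total - v, bounds[-1L])) {
      out[[length(out) + 1L]] <- c(v, rest)
    }
  }
  out
}

oracle_entropy <- function(a) {
  p <- a[a > 0] / sum(a)
  -sum(p * log(p))
}

# Exact H2 extrema over every integer table with the given marginals.
oracle_h2_extrema <- function(k, d) {
  hs <- vapply(enumerate_tables(k, d), oracle_entropy, numeric(1))
  list(h2_min = min(hs), h2_max = max(hs))
}

# All set partitions of n elements as restricted-growth strings
# (rows of a matrix of module labels).
set_partitions <- function(n) {
  grow <- function(prefix, m) {
    if (length(prefix) == n) return(list(prefix))
    out <- list()
    for (v in seq_len(m + 1L)) {
      out <- c(out, grow(c(prefix, v), max(m, v)))
    }
    out
  }
  do.call(rbind, grow(integer(0), 0L))
}

# Exact maximum Barber modularity by exhausting every partition of the
# plant+ant species set.
oracle_best_q <- function(net) {
  a <- net$counts
  m <- sum(a)
  b <- a - outer(rowSums(a), colSums(a)) / m
  nr <- nrow(a)
  nc <- ncol(a)
  parts <- set_partitions(nr + nc)
  best <- -Inf
  for (i in seq_len(nrow(parts))) {
    lab <- parts[i, ]
    q <- sum(b * outer(lab[seq_len(nr)], lab[nr + seq_len(nc)], "==")) / m
    if (q > best) best <- q
  }
  best
}

# Hoeffding's D as the U-statistic over all ordered 5-tuples of distinct
# indices (exact for untied data; ties follow a different convention).
oracle_hoeffding_kernel <- function(x, y) {
  n <- length(x)
  cc <- function(u, v) (sign(v - u) + 1) / 2
  idx <- as.matrix(expand.grid(a = 1:n, b = 1:n, c = 1:n, d = 1:n, e = 1:n))
  distinct <- rep(TRUE, nrow(idx))
  for (i in 1:4) for (j in (i + 1):5) {
    distinct <- distinct & idx[, i] != idx[, j]
  }
  idx <- idx[distinct, , drop = FALSE]
  cae <- cc(x[idx[, 1]], x[idx[, 5]]); cpae <- cc(y[idx[, 1]], y[idx[, 5]])
  cbe <- cc(x[idx[, 2]], x[idx[, 5]]); cpbe <- cc(y[idx[, 2]], y[idx[, 5]])
  cpce <- cc(y[idx[, 3]], y[idx[, 5]]); cpde <- cc(y[idx[, 4]], y[idx[, 5]])
  term <- cae * cpae * cbe * cpbe - 2 * cae * cpae * cbe * cpce +
    cae * cbe * cpce * cpde
  30 * mean(term)
}

# Midrank-convention D computed by a structurally different route (full
# comparison matrices via outer(), diagonal corrections) - checks the
# package's loop-based computation including tied data.
oracle_hoeffding_midrank <- function(x, y) {
  n <- length(x)
  cx <- outer(x, x, function(a, b) (sign(b - a) + 1) / 2)
  cy <- outer(y, y, function(a, b) (sign(b - a) + 1) / 2)
  r <- 1 + colSums(cx) - 0.5
  s <- 1 + colSums(cy) - 0.5
  q <- 1 + colSums(cx * cy) - 0.25
  d1 <- sum((q - 1) * (q - 2))
  d2 <- sum((r - 1) * (r - 2) * (s - 1) * (s - 2))
  d3 <- sum((r - 2) * (s - 2) * (q - 1))
  30 * ((n - 2) * (n - 3) * d1 + d2 - 2 * (n - 2) * d3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

# Every distinct sorted-marginal pair for shapes up to max_dim and totals
# up to max_m (H2 extrema are invariant to marginal order).
all_marginal_pairs <- function(max_dim = 3L, max_m = 12L) {
  parts_le <- function(m, kmax) {
    # partitions of m into at most kmax parts, descending
    rec <- function(m, kmax, largest) {
      if (m == 0L) return(list(integer(0)))
      if (kmax == 0L) return(list())
      out <- list()
      for (first in seq_len(min(m, largest))) {
        for (rest in rec(m - first, kmax - 1L, first)) {
          out[[length(out) + 1L]] <- c(first, rest)
        }
      }
      out
    }
    rec(m, kmax, m)
  }
  pairs <- list()
  for (m in 1:max_m) {
    ks <- parts_le(m, max_dim)
    for (k in ks) for (d in ks) {
      pairs[[length(pairs) + 1L]] <- list(k = k, d = d, m = m)
    }
  }
  pairs
}

# A random pruned network with nr x nc species and Poisson counts.
random_network <- function(nr, nc, lambda = 2) {
  repeat {
    a <- matrix(stats::rpois(nr * nc, lambda), nr, nc)
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) {
      return(as_network(a))
    }
  }
}

# Minimal census table from (elevation, plant, ant) triples; ant = NA means
# unoccupied.
tiny_census <- function(elevation, plant, ant) {
  occupied <- !is.na(ant)
  data.frame(
    tree_id = sprintf("T%03d", seq_along(plant)),
    elevation_m = elevation,
    plant_species = plant,
    occupied = as.integer(occupied),
    ant_species = ifelse(occupied, ant, ""),
    height_m = 3, dbh_cm = 5,
    herb_cat1 = 10L, herb_cat2 = 0L, herb_cat3 = 0L, herb_cat4 = 0L
  )
}
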