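#' Network-level metrics for quantitative bipartite networks
#'
#' Five network-level indices computed from first principles on an integer
#' interaction-count matrix \eqn{a_{ij}} (plants as rows, ants as columns,
#' grand total \eqn{m}):
#'
#' * `connectance()` — realized fraction of possible links,
#'   \eqn{\#\{a_{ij}>0\}/(IJ)} (binary, the convention for count data).
#' * `generality()` — weighted mean effective number of plant partners per
#'   ant species: \eqn{\sum_j (d_j/m)\, e^{H_j}} where \eqn{d_j} is the
#'   column total and \eqn{H_j} the Shannon entropy of column \eqn{j}'s
#'   interaction proportions.
#' * `vulnerability()` — the row analogue: effective number of ant partners
#'   per plant species.
#' * `h2_prime()` — network-level specialization: the deviation of the
#'   interaction-frequency entropy \eqn{H_2=-\sum p_{ij}\ln p_{ij}} from its
#'   marginal-constrained maximum, scaled by the feasible range,
#'   \eqn{H_2' = (H_{2max}-H_2)/(H_{2max}-H_{2min})}; 0 = random partner
#'   use given marginals, 1 = maximal specialization.
#'
#' Metrics that are not defined for a network (empty network; degenerate
#' marginals for `h2_prime`) return `NA` and are propagated as missing
#' values downstream, never silently replaced by 0.
#'
#' @param net A `bipartite_network` (see [build_network()]).
#' @return A single numeric value, or `NA` when undefined.
#' @seealso [metric_set()] for all metrics at once, [h2_extrema()] for the
#'   constrained entropy bounds.
#' @examples
#' net <- as_network(matrix(c(2, 0, 0, 1), 2, 2))
#' connectance(net)   # 0.5
#' generality(net)    # 1: every ant uses a single plant
#' h2_prime(as_network(diag(3) * 2))  # 1: perfectly specialized
#' @export
connectance <- function(net) {
  if (is_empty_network(net)) return(NA_real_)
  a <- net$counts
  sum(a > 0) / (nrow(a) * ncol(a))
}

#' @rdname connectance
#' @export
generality <- function(net) {
  if (is_empty_network(net)) return(NA_real_)
  effective_partners(net$counts, margin = 2L)
}

#' @rdname connectance
#' @export
vulnerability <- function(net) {
  if (is_empty_network(net)) return(NA_real_)
  effective_partners(net$counts, margin = 1L)
}

# Abundance-weighted mean exp(Shannon entropy) over rows (margin 1) or
# columns (margin 2).
effective_partners <- function(a, margin) {
  tot <- if (margin == 1L) rowSums(a) else colSums(a)
  m <- sum(a)
  ent <- apply(a, margin, function(v) {
    p <- v[v > 0] / sum(v)
    -sum(p * log(p))
  })
  sum(tot / m * exp(ent))
}

shannon_h2 <- function(a) {
  p <- a[a > 0] / sum(a)
  -sum(p * log(p))
}

#' Constrained extrema of the interaction entropy
#'
#' For fixed row totals `k` and column totals `d`, finds the minimum and
#' maximum Shannon entropy \eqn{H_2} attainable by non-negative integer
#' matrices with those marginals, by heuristic search over deterministic
#' fill strategies (greedy descending-marginal, best-fit and subset-sum
#' completion for the minimum; proportional largest-remainder and
#' incremental unit allocation for the maximum), each polished by
#' marginal-preserving 2x2 multi-unit swaps - and, on small matrices, 3x3
#' cycle moves - until no move improves. On small matrices the result
#' matches exhaustive enumeration (checked in the test suite); should the
#' heuristic ever fall short of a true extremum the resulting H2' is still
#' clamped to [0, 1].
#'
#' @param k Integer row totals.
#' @param d Integer column totals (same sum as `k`).
#' @return List with `h2_min` and `h2_max`.
#' @export
h2_extrema <- function(k, d) {
  stopifnot(sum(k) == sum(d), all(k >= 0), all(d >= 0))
  k <- k[k > 0]
  d <- d[d > 0]
  # small-matrix regime: several starts and the full polish are affordable
  # and buy exactness; large matrices take the single cheap route
  small <- length(k) <= 4L && length(d) <= 4L && sum(k) <= 20L
  min_starts <- list(h2_fill_min(k, d))
  max_starts <- list(h2_fill_max(k, d))
  if (small) {
    min_starts <- c(min_starts, list(h2_fill_min_bestfit(k, d),
                                     h2_fill_min_subset(k, d)))
    max_starts <- c(max_starts, list(h2_fill_max_incremental(k, d)))
  }
  hmin <- min(vapply(min_starts, function(a) {
    shannon_h2(polish_extremum(a, maximize = FALSE, full = small))
  }, numeric(1)))
  hmax <- max(vapply(max_starts, function(a) {
    shannon_h2(polish_extremum(a, maximize = TRUE, full = small))
  }, numeric(1)))
  list(h2_min = hmin, h2_max = hmax)
}

# Greedy: repeatedly pour as much as possible into the cell pairing the
# largest remaining row with the largest remaining column total.
h2_fill_min <- function(k, d) {
  a <- matrix(0L, length(k), length(d))
  kr <- as.integer(k)
  dr <- as.integer(d)
  while (sum(kr) > 0L) {
    i <- which.max(kr)
    j <- which.max(dr)
    x <- min(kr[i], dr[j])
    a[i, j] <- a[i, j] + x
    kr[i] <- kr[i] - x
    dr[j] <- dr[j] - x
  }
  a
}

# Proportional allocation: floor of the marginal-product expectation, then
# unit increments at the largest remainders among rows/columns still short.
h2_fill_max <- function(k, d) {
  m <- sum(k)
  e <- outer(k, d) / m
  a <- floor(e)
  rowdef <- k - rowSums(a)
  coldef <- d - colSums(a)
  rem <- e - a
  while (sum(rowdef) > 0L) {
    cand <- outer(rowdef > 0, coldef > 0)
    scores <- ifelse(cand, rem, -Inf)
    ij <- arrayInd(which.max(scores), dim(scores))
    i <- ij[1]; j <- ij[2]
    a[i, j] <- a[i, j] + 1
    rem[i, j] <- rem[i, j] - 1
    rowdef[i] <- rowdef[i] - 1
    coldef[j] <- coldef[j] - 1
  }
  storage.mode(a) <- "integer"
  a
}

# Best-fit greedy: prefer cells whose remaining row and column totals match
# exactly (a completed block costs no extra entropy), else pour into the
# cell allowing the largest block.
h2_fill_min_bestfit <- function(k, d) {
  a <- matrix(0L, length(k), length(d))
  kr <- as.integer(k)
  dr <- as.integer(d)
  while (sum(kr) > 0L) {
    mm <- outer(kr, dr, pmin)
    feas <- outer(kr > 0, dr > 0)
    exact <- outer(kr, dr, "==") & feas
    score <- if (any(exact)) ifelse(exact, mm, -1L) else ifelse(feas, mm, -1L)
    ij <- arrayInd(which.max(score), dim(score))
    x <- min(kr[ij[1]], dr[ij[2]])
    a[ij[1], ij[2]] <- a[ij[1], ij[2]] + x
    kr[ij[1]] <- kr[ij[1]] - x
    dr[ij[2]] <- dr[ij[2]] - x
  }
  a
}

# first subset of vals summing exactly to target, smallest subsets first
subset_summing_to <- function(vals, target) {
  for (sz in seq_along(vals)) {
    combos <- utils::combn(length(vals), sz)
    for (c in seq_len(ncol(combos))) {
      if (sum(vals[combos[, c]]) == target) return(combos[, c])
    }
  }
  NULL
}

# Subset-sum greedy: complete the largest remaining marginal with an exact
# subset of the opposite side's totals when one exists (the completed
# marginal then contributes whole-block cells only).
h2_fill_min_subset <- function(k, d) {
  a <- matrix(0L, length(k), length(d))
  kr <- as.integer(k)
  dr <- as.integer(d)
  while (sum(kr) > 0L) {
    bi <- which.max(kr)
    bj <- which.max(dr)
    if (dr[bj] >= kr[bi]) {
      ss <- subset_summing_to(kr[kr > 0], dr[bj])
      if (!is.null(ss)) {
        rows <- which(kr > 0)[ss]
        a[rows, bj] <- a[rows, bj] + kr[rows]
        dr[bj] <- dr[bj] - sum(kr[rows])
        kr[rows] <- 0L
        next
      }
    } else {
      ss <- subset_summing_to(dr[dr > 0], kr[bi])
      if (!is.null(ss)) {
        cols <- which(dr > 0)[ss]
        a[bi, cols] <- a[bi, cols] + dr[cols]
        kr[bi] <- kr[bi] - sum(dr[cols])
        dr[cols] <- 0L
        next
      }
    }
    x <- min(kr[bi], dr[bj])
    a[bi, bj] <- a[bi, bj] + x
    kr[bi] <- kr[bi] - x
    dr[bj] <- dr[bj] - x
  }
  a
}

# Incremental max fill: one unit at a time into the feasible cell with the
# smallest current count (largest entropy gain), remainder-of-expectation
# as tie-break.
h2_fill_max_incremental <- function(k, d) {
  m <- sum(k)
  e <- outer(k, d) / m
  a <- matrix(0L, length(k), length(d))
  kr <- as.integer(k)
  dr <- as.integer(d)
  while (sum(kr) > 0L) {
    feas <- outer(kr > 0, dr > 0)
    score <- ifelse(feas, -a + (e - a) * 1e-6, -Inf)
    ij <- arrayInd(which.max(score), dim(score))
    a[ij[1], ij[2]] <- a[ij[1], ij[2]] + 1L
    kr[ij[1]] <- kr[ij[1]] - 1L
    dr[ij[2]] <- dr[ij[2]] - 1L
  }
  a
}

# Local search over marginal-preserving 2x2 swaps of t units
# (a[i1,j1]+t, a[i1,j2]-t, a[i2,j1]-t, a[i2,j2]+t); with full = TRUE,
# alternated with 3x3 cycle moves. First-improvement passes until a full
# pass yields none.
polish_extremum <- function(a, maximize, full = FALSE, max_rounds = 10L) {
  if (!full) return(swap_polish(a, maximize, max_t = 1L))
  for (r in seq_len(max_rounds)) {
    a1 <- swap_polish(a, maximize, max_t = NULL)
    a1 <- cycle_polish(a1, maximize)
    if (identical(a1, a)) break
    a <- a1
  }
  a
}

swap_polish <- function(a, maximize, max_t = 1L, max_passes = 200L) {
  nr <- nrow(a)
  nc <- ncol(a)
  if (nr < 2L || nc < 2L) return(a)
  m <- sum(a)
  ent <- function(x) if (x > 0) x / m * log(x / m) else 0
  sgn <- if (maximize) 1 else -1
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (i1 in seq_len(nr - 1L)) for (i2 in seq.int(i1 + 1L, nr)) {
      for (j1 in seq_len(nc - 1L)) for (j2 in seq.int(j1 + 1L, nc)) {
        tmax <- max_t %||% max(a[i1, j2] + a[i2, j1], a[i1, j1] + a[i2, j2])
        for (t in seq_len(tmax)) {
          for (delta in c(t, -t)) {
            x11 <- a[i1, j1] + delta; x12 <- a[i1, j2] - delta
            x21 <- a[i2, j1] - delta; x22 <- a[i2, j2] + delta
            if (min(x11, x12, x21, x22) < 0L) next
            dh <- -(ent(x11) + ent(x12) + ent(x21) + ent(x22)) +
              (ent(a[i1, j1]) + ent(a[i1, j2]) +
                 ent(a[i2, j1]) + ent(a[i2, j2]))
            if (sgn * dh > 1e-12) {
              a[i1, j1] <- x11; a[i1, j2] <- x12
              a[i2, j1] <- x21; a[i2, j2] <- x22
              improved <- TRUE
            }
          }
        }
      }
    }
    if (!improved) break
  }
  a
}

# Cycle move of t units: +t at (i1,j1),(i2,j2),(i3,j3), -t at
# (i1,j2),(i2,j3),(i3,j1) - reaches rearrangements no 2x2 swap can.
cycle_polish <- function(a, maximize, max_passes = 100L) {
  nr <- nrow(a)
  nc <- ncol(a)
  if (nr < 3L || nc < 3L) return(a)
  m <- sum(a)
  ent <- function(x) ifelse(x > 0, x / m * log(x / m), 0)
  sgn <- if (maximize) 1 else -1
  rows3 <- t(utils::combn(nr, 3L))
  cols3 <- t(utils::combn(nc, 3L))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (ri in seq_len(nrow(rows3))) for (ci in seq_len(nrow(cols3))) {
      for (pi in seq_len(6L)) {
        ii <- rows3[ri, ]
        jj <- cols3[ci, perms[pi, ]]
        jm <- jj[c(2L, 3L, 1L)]
        tmax <- min(a[cbind(ii, jm)])
        if (tmax < 1L) next
        for (t in seq_len(tmax)) {
          plus <- a[cbind(ii, jj)] + t
          minus <- a[cbind(ii, jm)] - t
          dh <- -(sum(ent(plus)) + sum(ent(minus))) +
            (sum(ent(a[cbind(ii, jj)])) + sum(ent(a[cbind(ii, jm)])))
          if (sgn * dh > 1e-12) {
            a[cbind(ii, jj)] <- plus
            a[cbind(ii, jm)] <- minus
            improved <- TRUE
            break
          }
        }
      }
    }
    if (!improved) break
  }
  a
}

#' @rdname connectance
#' @export
h2_prime <- function(net) {
  if (is_empty_network(net)) return(NA_real_)
  a <- net$counts
  if (net$m < 2L || (nrow(a) < 2L && ncol(a) < 2L)) return(NA_real_)
  ex <- h2_extrema(rowSums(a), colSums(a))
  if (ex$h2_max - ex$h2_min < 1e-12) return(NA_real_)
  h2 <- shannon_h2(a)
  min(max((ex$h2_max - h2) / (ex$h2_max - ex$h2_min), 0), 1)
}

#' All network-level metrics for one network
#'
#' @param net A `bipartite_network`.
#' @param metrics Which metrics to compute (default all); the rest are
#'   returned as `NA`. Restricting the set skips the associated work
#'   (useful inside resampling loops).
#' @param restarts Restarts for the modularity optimizer (which uses the
#'   current RNG stream).
#' @return A one-row data frame with columns `plant_richness`,
#'   `ant_richness`, `connectance`, `generality`, `vulnerability`,
#'   `h2_prime`, `modularity_q`. Undefined entries are `NA`.
#' @export
metric_set <- function(net, metrics = c("plant_richness", "ant_richness",
                                        "connectance", "generality",
                                        "vulnerability", "h2_prime",
                                        "modularity_q"),
                       restarts = 20L) {
  want <- function(m) m %in% metrics
  q <- NA_real_
  if (want("modularity_q") && !is_empty_network(net)) {
    q <- optimize_modularity(net, restarts = restarts)$q
  }
  data.frame(
    plant_richness = nrow(net$counts),
    ant_richness = ncol(net$counts),
    connectance = if (want("connectance")) connectance(net) else NA_real_,
    generality = if (want("generality")) generality(net) else NA_real_,
    vulnerability = if (want("vulnerability")) vulnerability(net) else NA_real_,
    h2_prime = if (want("h2_prime")) h2_prime(net) else NA_real_,
    modularity_q = q
  )
}

#' Mean percentage herbivory from ordinal damage-category leaf counts
#'
#' Leaves are scored into four ordered damage categories (0%, <5%, 5-33%,
#' >33% missing leaf area); the per-tree index is the abundance-weighted
#' average of the category midpoints.
#'
#' @param counts Length-4 non-negative leaf counts (category 1..4), or a
#'   matrix/data frame with 4 columns (one row per tree).
#' @param midpoints Category midpoints in percent; defaults to the
#'   arithmetic midpoints `c(0, 2.5, 19, 66.5)` of the category ranges.
#' @return Percentage herbivory (scalar or per-row vector); `NA` where no
#'   leaves were counted.
#' @examples
#' herbivory_index(c(10, 0, 0, 0))  # 0
#' herbivory_index(c(0, 2, 2, 0))   # 10.75
#' @export
herbivory_index <- function(counts, midpoints = c(0, 2.5, 19, 66.5)) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 4L, all(counts >= 0, na.rm = TRUE))
  tot <- rowSums(counts)
  out <- as.vector(counts %*% midpoints) / tot
  out[tot == 0] <- NA_real_
  if (length(out) == 1L) out[[1L]] else out
}

#' Occupancy rate of a host plant species
#'
#' Fraction of censused individuals occupied by an ant colony. Trees whose
#' resident ant could not be identified (`"uncertain"`) are still occupied
#' trees and count as such.
#'
#' @param records Census data frame.
#' @param plant_species Host species label (`NULL` = all species pooled).
#' @param elevation Elevation to restrict to (`NULL` = pooled).
#' @return Proportion occupied in \eqn{[0, 1]}; `NA` if no individuals in
#'   scope.
#' @export
occupancy_rate <- function(records, plant_species = NULL, elevation = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(plant_species)) keep <- keep & records$plant_species == plant_species
  if (!is.null(elevation)) keep <- keep & records$elevation_m == elevation
  n <- sum(keep)
  if (n == 0L) return(NA_real_)
  sum(as.logical(records$occupied[keep])) / n
}
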