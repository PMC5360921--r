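#' Pool interaction events across low elevations
#'
#' Turns every occupied, identified-ant census record at the pooled
#' elevations into one (plant, ant) interaction event. The pooled event list
#' is the parent community for rarefaction (the default pooling, 700 and
#' 800 m, combines the two richest transects into a single reference
#' community).
#'
#' @param records Census data frame.
#' @param elevations Elevations (m a.s.l.) to pool; default `c(700, 800)`.
#' @param exclude_uncertain Drop `"uncertain"` occupants (default `TRUE`).
#' @return Data frame of events with columns `plant_species`, `ant_species`.
#' @export
pool_community <- function(records, elevations = c(700, 800),
                           exclude_uncertain = TRUE) {
  keep <- as.logical(records$occupied) &
    records$elevation_m %in% elevations &
    !is.na(records$ant_species) & nzchar(records$ant_species)
  if (exclude_uncertain) keep <- keep & records$ant_species != "uncertain"
  out <- records[keep, c("plant_species", "ant_species"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rarefy a pooled community to a smaller abundance
#'
#' Samples `n` interaction events uniformly without replacement from the
#' pooled event list and builds the resulting network. Used to ask what a
#' low-elevation community would look like if it were only as abundant as a
#' high-elevation one.
#'
#' @param pool Event data frame from [pool_community()].
#' @param n Number of events to keep; must not exceed the pool size.
#' @return A `bipartite_network`.
#' @export
rarefy <- function(pool, n) {
  if (n < 1L || n > nrow(pool)) {
    stop(sprintf("cannot rarefy a pool of %d events to n = %s", nrow(pool), n))
  }
  idx <- sample.int(nrow(pool), n)
  sub <- pool[idx, , drop = FALSE]
  counts <- table(
    factor(sub$plant_species, levels = sort(unique(sub$plant_species))),
    factor(sub$ant_species, levels = sort(unique(sub$ant_species)))
  )
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  new_bipartite_network(counts[rowSums(counts) > 0, colSums(counts) > 0,
                               drop = FALSE])
}

#' Rarefaction-based 95% prediction bands for network metrics
#'
#' For each target elevation, repeatedly rarefies the pooled low-elevation
#' community down to that elevation's observed abundance, computes the
#' metrics on every replicate, and reports the 2.5th and 97.5th percentiles
#' (linear-interpolation percentile definition). An observed metric falling
#' outside its band changed more than the abundance decline alone can
#' explain. Replicates where a metric is undefined are dropped from the
#' percentiles and counted; a band with more than 50% undefined replicates
#' is flagged unreliable.
#'
#' @param pool Event data frame from [pool_community()].
#' @param target_sizes Named numeric vector: observed abundance (number of
#'   interaction events) per elevation; names are elevations.
#' @param n_replicates Rarefaction replicates per elevation (default 1000).
#' @param metrics Character vector of metric names to band (any of the
#'   [metric_set()] columns).
#' @param level Band coverage (default 0.95).
#' @param seed Root seed; each elevation gets an independent child stream,
#'   so adding an elevation does not perturb the others' draws.
#' @param modularity_restarts Restarts for the modularity optimizer within
#'   each replicate (kept small: it runs once per replicate).
#' @return Data frame with one row per elevation x metric: `elevation`,
#'   `metric`, `lower`, `upper`, `n_replicates`, `n_undefined`,
#'   `unreliable`.
#' @export
prediction_bands <- function(pool, target_sizes, n_replicates = 1000L,
                             metrics = c("plant_richness", "ant_richness",
                                         "connectance", "generality",
                                         "vulnerability", "h2_prime",
                                         "modularity_q"),
                             level = 0.95, seed = 1L,
                             modularity_restarts = 5L) {
  stopifnot(!is.null(names(target_sizes)))
  if (any(target_sizes > nrow(pool))) {
    stop("target size exceeds pool size; cannot rarefy upward")
  }
  alpha <- (1 - level) / 2
  out <- list()
  for (t in seq_along(target_sizes)) {
    elev <- names(target_sizes)[t]
    n <- as.integer(target_sizes[[t]])
    reps <- with_seed(child_seed(seed, t), {
      vapply(seq_len(n_replicates), function(r) {
        net <- rarefy(pool, n)
        unlist(metric_set(net, metrics = metrics,
                          restarts = modularity_restarts))[metrics]
      }, numeric(length(metrics)))
    })
    reps <- matrix(reps, nrow = length(metrics),
                   dimnames = list(metrics, NULL))
    for (met in metrics) {
      vals <- reps[met, ]
      nu <- sum(is.na(vals))
      defined <- vals[!is.na(vals)]
      qs <- if (length(defined)) {
        stats::quantile(defined, c(alpha, 1 - alpha), names = FALSE, type = 7)
      } else {
        c(NA_real_, NA_real_)
      }
      out[[length(out) + 1L]] <- data.frame(
        elevation = as.numeric(elev), metric = met,
        lower = qs[1], upper = qs[2],
        n_replicates = n_replicates, n_undefined = nu,
        unreliable = nu > n_replicates / 2
      )
    }
  }
  do.call(rbind, out)
}

#' Marginal-preserving Monte Carlo null network (Patefield draw)
#'
#' Draws a random integer interaction matrix with exactly the observed row
#' and column totals, from the multivariate hypergeometric distribution over
#' such tables (the classic two-way-table randomization: interaction events
#' shuffled independently given marginals). Uses [stats::r2dtable()], the
#' canonical Patefield algorithm; draws follow R's RNG stream.
#'
#' @param net A `bipartite_network` with `m >= 1`.
#' @return A `bipartite_network` with identical marginals.
#' @export
patefield_null <- function(net) {
  if (is_empty_network(net)) stop("cannot randomize an empty network")
  a <- net$counts
  if (nrow(a) == 1L || ncol(a) == 1L) return(net)  # marginals force the table
  r <- stats::r2dtable(1L, rowSums(a), colSums(a))[[1L]]
  dimnames(r) <- dimnames(a)
  new_bipartite_network(r, net$elevation)
}

#' Monte Carlo significance of network specialization H2'
#'
#' Tests whether the observed H2' exceeds what random partner use with the
#' same marginal totals would produce, by comparing it with H2' of
#' [patefield_null()] replicates. The p-value uses the add-one permutation
#' estimator \eqn{(1 + \#\{null \ge obs\})/(N + 1)} (one-tailed "greater" by
#' default), so `p >= 1/(N+1)` always. Because every null draw shares the
#' observed marginals, the constrained entropy extrema are computed once.
#'
#' @param net A `bipartite_network` with defined [h2_prime()].
#' @param n_null Number of null replicates (default 1000).
#' @param tail `"greater"` (specialization above random) or `"two_sided"`.
#' @return List of class `h2_significance` with `observed`, `null` (replicate
#'   values), `p_value`, `tail`, `n_null`; or `NULL` if H2' is undefined for
#'   the network.
#' @export
h2_significance <- function(net, n_null = 1000L,
                            tail = c("greater", "two_sided")) {
  tail <- match.arg(tail)
  obs <- h2_prime(net)
  if (is.na(obs)) return(NULL)
  a <- net$counts
  k <- rowSums(a)
  d <- colSums(a)
  ex <- h2_extrema(k, d)
  span <- ex$h2_max - ex$h2_min
  tabs <- stats::r2dtable(n_null, k, d)
  null_vals <- vapply(tabs, function(tab) {
    min(max((ex$h2_max - shannon_h2(tab)) / span, 0), 1)
  }, numeric(1))
  p <- if (tail == "greater") {
    (1 + sum(null_vals >= obs - 1e-12)) / (n_null + 1)
  } else {
    ctr <- abs(null_vals - stats::median(null_vals))
    (1 + sum(ctr >= abs(obs - stats::median(null_vals)) - 1e-12)) / (n_null + 1)
  }
  structure(
    list(metric = "h2_prime", observed = obs, null = null_vals,
         p_value = p, tail = tail, n_null = n_null),
    class = "h2_significance"
  )
}

#' @export
print.h2_significance <- function(x, ...) {
  cat(sprintf("H2' = %.3f vs %d marginal-preserving nulls: p = %.4g (%s)\n",
              x$observed, x$n_null, x$p_value, x$tail))
  invisible(x)
}
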