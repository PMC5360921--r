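#' Run the full elevational network analysis
#'
#' Orchestrates the whole pipeline on a census table: per-elevation
#' bipartite networks and metrics; rarefaction prediction bands from a
#' pooled low-elevation community, with a flag per metric x elevation for
#' observed values escaping their band; marginal-preserving Monte Carlo
#' significance of H2' per elevation; elevational trend tests with the
#' standard metric-to-method mapping (richness untransformed regression,
#' connectance sqrt-transformed regression, generality log-transformed
#' regression, vulnerability / H2' / modularity by Hoeffding's D); and a
#' sensitivity rerun of the trends excluding the topmost elevation with
#' data. Deterministic given `seed`: every stage draws from its own child
#' stream.
#'
#' @param census Census data frame (see [simulate_census()]), or `NULL` to
#'   simulate one from `config`.
#' @param config A [sim_config()] used when `census` is `NULL`.
#' @param pooled_elevations Elevations pooled into the rarefaction
#'   reference community (default `c(700, 800)`).
#' @param n_replicates Rarefaction replicates per elevation.
#' @param n_null Monte Carlo nulls for H2' significance.
#' @param n_perm Permutations for Hoeffding trend tests.
#' @param exclude_uncertain Exclude `"uncertain"` occupants from networks
#'   (they still count as occupied for occupancy rates).
#' @param modularity_restarts Restarts for the modularity optimizer on
#'   observed networks (band replicates use fewer; see
#'   [prediction_bands()]).
#' @param band_metrics Metrics to band (default: all).
#' @param seed Root seed for every stochastic stage.
#' @return List of class `elevnet_report`: `metrics`, `bands`,
#'   `null_tests`, `trends`, `trends_sensitivity`, `occupancy`,
#'   `herbivory`, `accounting`, `meta`.
#' @export
run_analysis <- function(census = NULL, config = sim_config(),
                         pooled_elevations = c(700, 800),
                         n_replicates = 1000L, n_null = 1000L,
                         n_perm = 10000L, exclude_uncertain = TRUE,
                         modularity_restarts = 20L,
                         band_metrics = c("plant_richness", "ant_richness",
                                          "connectance", "generality",
                                          "vulnerability", "h2_prime",
                                          "modularity_q"),
                         seed = 1L) {
  if (is.null(census)) census <- simulate_census(config)$census
  elevations <- sort(unique(census$elevation_m))
  if (!all(pooled_elevations %in% elevations)) {
    stop("pooled elevations not all present in the census: ",
         paste(setdiff(pooled_elevations, elevations), collapse = ", "))
  }

  # --- census accounting -------------------------------------------------
  occ <- as.logical(census$occupied)
  unc <- occ & census$ant_species == "uncertain"
  accounting <- data.frame(
    n_records = nrow(census),
    n_occupied = sum(occ),
    n_unoccupied = sum(!occ),
    n_uncertain = sum(unc),
    n_used_in_networks = sum(occ & (!exclude_uncertain | !unc))
  )

  # --- per-elevation networks and metrics --------------------------------
  nets <- lapply(elevations, function(e) {
    build_network(census, e, exclude_uncertain = exclude_uncertain)
  })
  names(nets) <- elevations
  metrics <- with_seed(child_seed(seed, 1L), {
    do.call(rbind, lapply(seq_along(nets), function(i) {
      ms <- metric_set(nets[[i]], restarts = modularity_restarts)
      cbind(data.frame(elevation = elevations[i], m = nets[[i]]$m), ms)
    }))
  })

  # --- rarefaction prediction bands --------------------------------------
  pool <- pool_community(census, pooled_elevations, exclude_uncertain)
  sizes <- stats::setNames(metrics$m, metrics$elevation)
  sizes <- sizes[sizes >= 1 & sizes <= nrow(pool)]
  bands <- if (nrow(pool) && length(sizes)) {
    prediction_bands(pool, sizes, n_replicates = n_replicates,
                     metrics = band_metrics, seed = child_seed(seed, 2L))
  } else {
    NULL
  }
  if (!is.null(bands)) {
    obs_long <- stats::reshape(
      metrics[, c("elevation", band_metrics)],
      direction = "long", varying = band_metrics, v.names = "observed",
      times = band_metrics, timevar = "metric", idvar = "elevation"
    )
    bands <- merge(bands, obs_long, by = c("elevation", "metric"),
                   sort = TRUE)
    bands$outside_band <- !is.na(bands$observed) & !is.na(bands$lower) &
      (bands$observed < bands$lower | bands$observed > bands$upper)
  }

  # --- H2' Monte Carlo significance --------------------------------------
  null_tests <- with_seed(child_seed(seed, 3L), {
    do.call(rbind, lapply(seq_along(nets), function(i) {
      res <- h2_significance(nets[[i]], n_null = n_null)
      if (is.null(res)) return(NULL)
      data.frame(elevation = elevations[i], metric = "h2_prime",
                 observed = res$observed, p_value = res$p_value,
                 tail = res$tail, n_null = res$n_null)
    }))
  })

  # --- elevational trends -------------------------------------------------
  trends <- with_seed(child_seed(seed, 4L),
                      trend_table(metrics, n_perm = n_perm))
  with_data <- metrics$elevation[metrics$m > 0]
  trends_sensitivity <- NULL
  if (length(with_data) > 1L) {
    top <- max(with_data)
    trends_sensitivity <- with_seed(
      child_seed(seed, 5L),
      trend_table(metrics[metrics$elevation < top, , drop = FALSE],
                  n_perm = n_perm)
    )
    trends_sensitivity$excluded_elevation <- top
  }

  # --- occupancy and herbivory summaries ---------------------------------
  occupancy <- do.call(rbind, lapply(
    sort(unique(census$plant_species)),
    function(sp) {
      data.frame(
        plant_species = sp,
        n_trees = sum(census$plant_species == sp),
        occupancy = occupancy_rate(census, sp)
      )
    }
  ))
  herb <- herbivory_index(census[, c("herb_cat1", "herb_cat2",
                                     "herb_cat3", "herb_cat4")])
  herbivory <- do.call(rbind, lapply(elevations, function(e) {
    sel <- census$elevation_m == e
    data.frame(elevation = e, n_trees = sum(sel),
               mean_herbivory_pct = mean(herb[sel], na.rm = TRUE))
  }))

  structure(
    list(
      metrics = metrics, bands = bands, null_tests = null_tests,
      trends = trends, trends_sensitivity = trends_sensitivity,
      occupancy = occupancy, herbivory = herbivory,
      accounting = accounting,
      meta = list(seed = seed, pooled_elevations = pooled_elevations,
                  n_replicates = n_replicates, n_null = n_null,
                  n_perm = n_perm, exclude_uncertain = exclude_uncertain)
    ),
    class = "elevnet_report"
  )
}

# The standard metric -> (transformation, method) mapping for trend tests.
trend_methods <- function() {
  data.frame(
    metric = c("plant_richness", "ant_richness", "connectance",
               "generality", "vulnerability", "h2_prime", "modularity_q"),
    method = c("regression", "regression", "regression", "regression",
               "hoeffding", "hoeffding", "hoeffding"),
    transformation = c("none", "none", "sqrt", "log", "none", "none", "none")
  )
}

trend_table <- function(metrics, n_perm = 10000L) {
  mm <- trend_methods()
  keep <- metrics$m > 0
  do.call(rbind, lapply(seq_len(nrow(mm)), function(i) {
    met <- mm$metric[i]
    x <- metrics$elevation[keep]
    y <- metrics[[met]][keep]
    if (mm$method[i] == "regression") {
      ok <- !is.na(y)
      if (mm$transformation[i] == "log" && any(y[ok] <= 0)) {
        # fall back rather than abort the whole table on a degenerate value
        return(fit_trend(x[ok], y[ok], "none", metric = met))
      }
      fit_trend(x, y, mm$transformation[i], metric = met)
    } else {
      hoeffding_test(x, y, n_perm = n_perm, metric = met)
    }
  }))
}

#' @export
print.elevnet_report <- function(x, ...) {
  cat("elevational network analysis report\n")
  cat(sprintf("  census: %d records, %d occupied (%d uncertain)\n",
              x$accounting$n_records, x$accounting$n_occupied,
              x$accounting$n_uncertain))
  cat(sprintf("  elevations with interactions: %d\n",
              sum(x$metrics$m > 0)))
  if (!is.null(x$bands)) {
    cat(sprintf("  metric x elevation outside rarefaction band: %d of %d\n",
                sum(x$bands$outside_band, na.rm = TRUE),
                sum(!is.na(x$bands$observed) & !is.na(x$bands$lower))))
  }
  if (!is.null(x$null_tests)) {
    cat(sprintf("  elevations with H2' above random (p < 0.05): %d of %d\n",
                sum(x$null_tests$p_value < 0.05), nrow(x$null_tests)))
  }
  invisible(x)
}

#' Write every report table as tidy CSV
#'
#' @param report An `elevnet_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("metrics", "bands", "null_tests", "trends",
              "trends_sensitivity", "occupancy", "herbivory", "accounting")
  for (tb in tables) {
    if (!is.null(report[[tb]])) {
      utils::write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                       row.names = FALSE)
    }
  }
  yaml::write_yaml(report$meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}
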