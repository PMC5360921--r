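#' Configuration for the synthetic ant-plant census generator
#'
#' Collects every tunable of the community simulator. The defaults emulate
#' an understorey ant-plant census along a tropical elevational gradient:
#' ten 100 m-spaced transects from 700 to 1600 m a.s.l., 23 myrmecophyte and
#' 10 ant species with overlapping elevational ranges, multiplicative
#' abundance decline with elevation, roughly two-thirds of host trees
#' occupied (each by exactly one ant colony), a small fraction of occupants
#' unidentifiable ("uncertain"), and ordinal herbivory damage increasing
#' with elevation.
#'
#' @param elevations Strictly increasing transect elevations (m a.s.l.).
#' @param n_plant_species,n_ant_species Species-pool sizes (>= 1).
#' @param abundance_decline_rate Multiplicative factor applied to expected
#'   abundance per 100 m of elevation gain (0.78 halves abundance about
#'   every 280 m).
#' @param specialization_gamma Non-negative concentration exponent on the
#'   plants' partner-affinity vectors: 0 gives uniform affinities (random
#'   partner use), large values concentrate each plant on one ant. A single
#'   value, or one per elevation; the default declines upslope, emulating
#'   partner use growing less selective as the partner pool thins.
#' @param occupancy_curve Probability a host tree is occupied, either a
#'   single value or one per elevation.
#' @param uncertain_fraction Fraction of occupied trees whose resident ant
#'   is recorded as `"uncertain"` (could not be collected).
#' @param herbivory_base_logits Three strictly increasing cut-points of the
#'   cumulative-logit damage model at the lowest elevation.
#' @param herbivory_elevation_slope Shift of the damage latent scale per
#'   100 m (positive = more damage upslope).
#' @param mean_leaves Mean number of leaves scored per tree.
#' @param turnover If `TRUE` (default) species have finite Gaussian
#'   elevational ranges truncated at 3 SD, so composition turns over along
#'   the gradient; if `FALSE` every species spans the whole gradient
#'   uniformly and only abundance declines (the null landscape against
#'   which rarefaction bands are calibrated).
#' @param seed RNG seed recorded with the output; all draws derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(elevations = seq(700, 1600, by = 100),
                       n_plant_species = 23L,
                       n_ant_species = 10L,
                       abundance_decline_rate = 0.78,
                       specialization_gamma = seq(3, 0.5,
                                                  length.out = length(elevations)),
                       occupancy_curve = 0.66,
                       uncertain_fraction = 0.08,
                       herbivory_base_logits = c(-0.5, 1, 3),
                       herbivory_elevation_slope = 0.15,
                       mean_leaves = 30,
                       turnover = TRUE,
                       seed = 1L) {
  if (n_plant_species < 1L || n_ant_species < 1L) {
    stop("species counts must be >= 1")
  }
  if (is.unsorted(elevations, strictly = TRUE)) {
    stop("elevations must be strictly increasing")
  }
  gamma <- rep_len(specialization_gamma, length(elevations))
  if (any(gamma < 0)) stop("specialization_gamma must be >= 0")
  occ <- rep_len(occupancy_curve, length(elevations))
  if (any(occ < 0 | occ > 1)) stop("occupancy_curve values must lie in [0,1]")
  if (is.unsorted(herbivory_base_logits, strictly = TRUE)) {
    stop("herbivory cut-points must be strictly increasing")
  }
  structure(
    list(
      elevations = as.numeric(elevations),
      n_plant_species = as.integer(n_plant_species),
      n_ant_species = as.integer(n_ant_species),
      abundance_decline_rate = abundance_decline_rate,
      specialization_gamma = gamma,
      occupancy_curve = occ,
      uncertain_fraction = uncertain_fraction,
      herbivory_base_logits = herbivory_base_logits,
      herbivory_elevation_slope = herbivory_elevation_slope,
      mean_leaves = mean_leaves,
      turnover = isTRUE(turnover),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Read / write a simulator configuration as YAML
#' @param path File path.
#' @param config A `sim_config`.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Draw the plant and ant species pools
#'
#' Plants get Gaussian elevational range kernels (truncated at 3 SD so
#' species genuinely drop out, producing turnover), lognormal peak
#' abundances, and a partner-affinity vector over the ant pool: raw
#' exponential weights raised to `specialization_gamma` and renormalized,
#' so gamma = 0 is uniform and large gamma concentrates each plant on a
#' single ant. The first ant species is a gradient-spanning generalist (a
#' dominant core species, as seen in real ant-plant communities); the rest
#' get skew-low range centers like the plants.
#'
#' @param config A [sim_config()].
#' @return List with data frames `plants` (species_id, range_center,
#'   range_width, peak_abundance) and `ants` (species_id, range_center,
#'   range_width), matrix `affinity` (plants x ants, rows sum to 1; uses
#'   the gamma of the lowest elevation), and `affinity_raw` (the weights
#'   before exponentiation, used when gamma varies along the gradient).
#' @export
sample_species_pools <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 0L), {
    np <- config$n_plant_species
    na <- config$n_ant_species
    emin <- min(config$elevations)
    span <- max(config$elevations) - emin
    if (config$turnover) {
      p_center <- emin + span * stats::rbeta(np, 1, 2.5)
      p_width <- stats::rlnorm(np, log(180), 0.35)
      a_center <- c(emin + span / 2, emin + span * stats::rbeta(na - 1, 1, 2))
      a_width <- c(span, stats::rlnorm(na - 1, log(260), 0.45))
      a_center <- a_center[seq_len(na)]
      a_width <- a_width[seq_len(na)]
    } else {
      p_center <- rep(emin + span / 2, np)
      p_width <- rep(1e6, np)
      a_center <- rep(emin + span / 2, na)
      a_width <- rep(1e6, na)
    }
    peak <- stats::rlnorm(np, log(10), 0.7)
    raw <- matrix(stats::rexp(np * na), np, na)
    aff <- t(apply(raw, 1L, power_weights,
                   gamma = config$specialization_gamma[1L]))
    if (na == 1L) aff <- matrix(1, np, 1L)
    plants <- data.frame(
      species_id = sprintf("plant_%02d", seq_len(np)),
      trophic_side = "plant",
      range_center = p_center, range_width = p_width,
      peak_abundance = peak
    )
    ants <- data.frame(
      species_id = sprintf("ant_%02d", seq_len(na)),
      trophic_side = "ant",
      range_center = a_center, range_width = a_width
    )
    dimnames(aff) <- list(plants$species_id, ants$species_id)
    dimnames(raw) <- dimnames(aff)
    list(plants = plants, ants = ants, affinity = aff, affinity_raw = raw)
  })
}

# w^gamma renormalized to sum 1, computed on the log scale so very large
# gamma concentrates cleanly instead of under/overflowing.
power_weights <- function(w, gamma) {
  lw <- gamma * log(w)
  lw[w == 0] <- -Inf
  if (all(lw == -Inf)) return(rep(0, length(w)))
  lw <- lw - max(lw)
  p <- exp(lw)
  p / sum(p)
}

# Gaussian elevational range kernel, hard-truncated at 3 SD.
range_kernel <- function(elevation, center, width) {
  z <- (elevation - center) / width
  ifelse(abs(z) <= 3, exp(-0.5 * z^2), 0)
}

#' Generate a synthetic census table
#'
#' Per elevation and plant species, tree counts are Poisson with expectation
#' peak abundance x Gaussian range kernel x multiplicative decline factor.
#' Each tree is independently occupied with the elevation's occupancy
#' probability; an occupied tree is assigned exactly one ant species by a
#' single categorical draw from its plant's affinity vector (raw partner
#' weights raised to that elevation's specialization gamma) restricted to
#' ants whose range kernel is positive at that elevation (trees with no ant
#' in range stay unoccupied). A configurable fraction of occupied trees is
#' relabelled `"uncertain"`. Heights are lognormal capped at 15 m (the
#' understorey census ceiling), DBH lognormal; per-tree leaf counts fall
#' into four ordered herbivory-damage categories via a cumulative-logit
#' model whose latent scale shifts with elevation. Each elevation consumes
#' an independent child RNG stream of `config$seed`, so the table is fully
#' reproducible and per-elevation draws are insulated from one another.
#'
#' @param config A [sim_config()].
#' @param pools Species pools from [sample_species_pools()] (drawn from the
#'   config's seed if omitted).
#' @return Data frame of census records: `tree_id`, `elevation_m`,
#'   `plant_species`, `occupied` (0/1), `ant_species` (`""`, `"uncertain"`
#'   or a label), `height_m`, `dbh_cm`, `herb_cat1`..`herb_cat4`.
#' @export
generate_census <- function(config, pools = sample_species_pools(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(pools$plants) == 0L || nrow(pools$ants) == 0L) {
    stop("species pools are empty")
  }
  e0 <- min(config$elevations)
  rows <- vector("list", length(config$elevations))
  for (t in seq_along(config$elevations)) {
    e <- config$elevations[t]
    rows[[t]] <- with_seed(child_seed(config$seed, t), {
      census_one_elevation(config, pools, e, e0, config$occupancy_curve[t],
                           config$specialization_gamma[t])
    })
  }
  out <- do.call(rbind, rows)
  if (nrow(out)) {
    out$tree_id <- sprintf("T%05d", seq_len(nrow(out)))
  }
  rownames(out) <- NULL
  out
}

census_one_elevation <- function(config, pools, e, e0, p_occ, gamma) {
  decline <- config$abundance_decline_rate^((e - e0) / 100)
  ant_avail <- range_kernel(e, pools$ants$range_center,
                            pools$ants$range_width) > 0
  affinity_raw <- pools$affinity_raw %||% pools$affinity
  lambda <- pools$plants$peak_abundance *
    range_kernel(e, pools$plants$range_center, pools$plants$range_width) *
    decline
  n_per_plant <- stats::rpois(length(lambda), lambda)
  n <- sum(n_per_plant)
  if (n == 0L) {
    return(data.frame(
      tree_id = character(0), elevation_m = numeric(0),
      plant_species = character(0), occupied = integer(0),
      ant_species = character(0), height_m = numeric(0), dbh_cm = numeric(0),
      herb_cat1 = integer(0), herb_cat2 = integer(0),
      herb_cat3 = integer(0), herb_cat4 = integer(0)
    ))
  }
  plant_idx <- rep.int(seq_along(n_per_plant), n_per_plant)
  # per-plant occupancy probability: zero when no ant is in range
  aff <- t(apply(affinity_raw, 1L, function(w) {
    power_weights(w * ant_avail, gamma)
  }))
  can_occupy <- rowSums(aff) > 0
  occupied <- stats::rbinom(n, 1L, ifelse(can_occupy[plant_idx], p_occ, 0))
  ant <- rep("", n)
  occ_pos <- which(occupied == 1L)
  for (i in unique(plant_idx[occ_pos])) {
    sel <- occ_pos[plant_idx[occ_pos] == i]
    idx <- sample.int(ncol(aff), length(sel), replace = TRUE, prob = aff[i, ])
    ant[sel] <- colnames(pools$affinity)[idx]
  }
  if (length(occ_pos)) {
    unc <- stats::rbinom(length(occ_pos), 1L, config$uncertain_fraction) == 1L
    ant[occ_pos[unc]] <- "uncertain"
  }
  herb <- draw_herbivory(config, e, e0, n)
  data.frame(
    tree_id = NA_character_, elevation_m = e,
    plant_species = pools$plants$species_id[plant_idx],
    occupied = occupied, ant_species = ant,
    height_m = round(pmin(stats::rlnorm(n, log(3.5), 0.55), 15), 2),
    dbh_cm = round(stats::rlnorm(n, log(5), 0.6), 2),
    herb_cat1 = herb[1, ], herb_cat2 = herb[2, ],
    herb_cat3 = herb[3, ], herb_cat4 = herb[4, ]
  )
}

# Leaf counts per damage category from a cumulative-logit model whose
# latent scale shifts upward with elevation.
draw_herbivory <- function(config, e, e0, n) {
  eta <- config$herbivory_elevation_slope * (e - e0) / 100
  cum <- stats::plogis(config$herbivory_base_logits - eta)
  probs <- diff(c(0, cum, 1))
  leaves <- 1L + stats::rpois(n, config$mean_leaves - 1)
  vapply(leaves, function(L) as.integer(stats::rmultinom(1L, L, probs)),
         integer(4))
}

#' Simulate a census end to end
#'
#' Draws species pools and a census table from one configuration; the
#' convenience entry point for the whole generator.
#'
#' @param config A [sim_config()].
#' @return List with `census` (data frame), `pools`, and `config`.
#' @export
simulate_census <- function(config = sim_config()) {
  pools <- sample_species_pools(config)
  list(census = generate_census(config, pools), pools = pools,
       config = config)
}

#' Write / read a census table as CSV
#'
#' The CSV schema is the generator's record schema; the seed is recorded in
#' a comment-style header line.
#'
#' @param census Census data frame.
#' @param path File path.
#' @param seed Optional seed to record.
#' @export
write_census <- function(census, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(census, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_census
#' @export
read_census <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(ant_species = "character"))
}
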