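#' Build a quantitative bipartite network for one elevation
#'
#' Aggregates occupied census records at one elevation into an integer
#' plant-by-ant interaction-count matrix. Each occupied tree contributes one
#' interaction event between its plant species and its resident ant species.
#' Records whose ant could not be identified (`"uncertain"`) are excluded by
#' default because they carry no species identity; rows and columns that end
#' up all-zero are pruned and labels are sorted so construction is
#' deterministic.
#'
#' @param records A census data frame with at least the columns
#'   `elevation_m`, `plant_species`, `occupied` (0/1 or logical) and
#'   `ant_species` (see [simulate_census()] for the full schema).
#' @param elevation Elevation (m a.s.l.) to build the network for. Use
#'   `NULL` to aggregate over all elevations present.
#' @param exclude_uncertain Drop records whose ant species is `"uncertain"`
#'   (default `TRUE`).
#' @return An object of class `bipartite_network`: a list with `counts`
#'   (integer matrix, plants as rows, ants as columns), `elevation` and `m`
#'   (grand total of interaction events). An elevation with no usable
#'   records yields an explicitly empty network (`0 x 0`, `m = 0`).
#' @examples
#' rec <- data.frame(
#'   elevation_m = 700, plant_species = c("P1", "P1", "P2"),
#'   occupied = 1L, ant_species = c("A1", "A1", "A2")
#' )
#' net <- build_network(rec, 700)
#' net$counts
#' @export
build_network <- function(records, elevation = NULL, exclude_uncertain = TRUE) {
  stopifnot(is.data.frame(records))
  needed <- c("elevation_m", "plant_species", "occupied", "ant_species")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("census table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  keep <- as.logical(records$occupied) &
    !is.na(records$ant_species) & nzchar(records$ant_species)
  if (!is.null(elevation)) keep <- keep & records$elevation_m == elevation
  if (exclude_uncertain) keep <- keep & records$ant_species != "uncertain"
  sub <- records[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(empty_network(elevation))
  }
  counts <- table(
    factor(sub$plant_species, levels = sort(unique(sub$plant_species))),
    factor(sub$ant_species, levels = sort(unique(sub$ant_species)))
  )
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  new_bipartite_network(counts, elevation)
}

new_bipartite_network <- function(counts, elevation = NULL) {
  stopifnot(is.matrix(counts))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(rownames(counts), colnames(counts))
  structure(
    list(counts = counts, elevation = elevation, m = sum(counts)),
    class = "bipartite_network"
  )
}

empty_network <- function(elevation = NULL) {
  new_bipartite_network(
    matrix(integer(0), 0, 0, dimnames = list(character(0), character(0))),
    elevation
  )
}

#' Coerce a plain count matrix to a bipartite network
#'
#' Convenience constructor for analysing matrices that did not come from a
#' census table. Empty rows/columns are pruned and dimnames invented if
#' absent.
#'
#' @param counts Non-negative integer matrix (plants as rows, ants as
#'   columns).
#' @param elevation Optional elevation label.
#' @return A `bipartite_network`.
#' @export
as_network <- function(counts, elevation = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("interaction counts must be non-negative integers")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("P%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("A%02d", seq_len(ncol(counts)))
  }
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  new_bipartite_network(counts, elevation)
}

is_empty_network <- function(net) net$m == 0L

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "bipartite network%s: %d plant x %d ant species, %d interaction events\n",
    if (is.null(x$elevation)) "" else sprintf(" @ %s m", x$elevation),
    nrow(x$counts), ncol(x$counts), x$m
  ))
  invisible(x)
}

#' @export
as.matrix.bipartite_network <- function(x, ...) x$counts

#' Write / read a network as a labelled TSV incidence matrix
#'
#' Rows are plant species, columns ant species, cells interaction counts.
#'
#' @param net A `bipartite_network`.
#' @param path File path.
#' @return `write_network` returns `path` invisibly; `read_network` a
#'   `bipartite_network`.
#' @export
write_network <- function(net, path) {
  df <- as.data.frame(net$counts)
  df <- cbind(plant_species = rownames(net$counts), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  as_network(counts)
}
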