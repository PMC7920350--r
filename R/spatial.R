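#' Build a square grid of population cells from a fine raster
#'
#' Bins fine raster pixels into square cells of side `spacing`, summing
#' populations and computing population-weighted centroids. Cells whose total
#' population is zero are dropped.
#'
#' @param raster data.frame with columns `x`, `y` (planar metre coordinates of
#'   pixel centroids) and `population` (persons, >= 0). An optional `admin_id`
#'   column is carried along for [assign_cells_to_admin()].
#' @param spacing grid cell side length in metres (> 0).
#' @param origin_offset length-2 numeric, metres added to the grid origin
#'   (which defaults to the raster's minimum corner). Shifting the origin
#'   changes how pixels are binned.
#' @return data.frame of cells with columns `id`, `x`, `y`, `population` and,
#'   if the raster carried admin labels, `admin_id` (assigned by pixel
#'   majority). Centroids are population-weighted means of member pixels.
#' @export
build_grid <- function(raster, spacing, origin_offset = c(0, 0)) {
  stopifnot(is.data.frame(raster))
  if (nrow(raster) == 0L) stop("empty raster")
  req <- c("x", "y", "population")
  if (!all(req %in% names(raster))) {
    stop("raster must have columns x, y, population")
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("spacing must be a single positive number")
  }
  if (any(raster$population < 0)) stop("negative pixel population")
  if (sum(raster$population) <= 0) stop("raster has zero total population")

  ox <- min(raster$x) + origin_offset[1]
  oy <- min(raster$y) + origin_offset[2]
  bx <- floor((raster$x - ox) / spacing)
  by <- floor((raster$y - oy) / spacing)
  key <- paste(bx, by, sep = ":")

  pop <- rowsum(raster$population, key)
  wx <- rowsum(raster$x * raster$population, key)
  wy <- rowsum(raster$y * raster$population, key)
  keep <- pop[, 1] > 0
  if (!any(keep)) stop("raster has zero total population")

  cells <- data.frame(
    id = seq_len(sum(keep)),
    x = wx[keep, 1] / pop[keep, 1],
    y = wy[keep, 1] / pop[keep, 1],
    population = pop[keep, 1],
    row.names = NULL
  )
  attr(cells, "bin_key") <- rownames(pop)[keep]
  attr(cells, "spacing") <- spacing

  if ("admin_id" %in% names(raster)) {
    cells$admin_id <- .majority_admin(key, raster$admin_id, rownames(pop)[keep])
  }
  cells
}

# majority admin label per bin; ties broken by smallest admin id
.majority_admin <- function(key, admin, bins) {
  tab <- table(key, admin)
  lab <- colnames(tab)
  # order labels so that which.max picks the smallest id on ties
  ord <- order(suppressWarnings(as.numeric(lab)), lab)
  tab <- tab[, ord, drop = FALSE]
  lab <- lab[ord]
  picked <- lab[apply(tab[bins, , drop = FALSE], 1L, which.max)]
  if (is.numeric(admin)) picked <- as.numeric(picked)
  picked
}

#' Assign grid cells to administrative units by pixel majority
#'
#' Each grid cell is assigned the administrative unit contributing the largest
#' number of its member fine-raster pixels (an area proxy). Ties are broken by
#' the smallest admin id so the assignment is deterministic.
#'
#' @param cells output of [build_grid()] (must carry the `bin_key` attribute).
#' @param raster the fine raster the grid was built from, with an `admin_id`
#'   column labelling every pixel.
#' @param spacing,origin_offset the binning used in [build_grid()].
#' @return `cells` with an `admin_id` column.
#' @export
assign_cells_to_admin <- function(cells, raster, spacing,
                                  origin_offset = c(0, 0)) {
  if (!"admin_id" %in% names(raster)) stop("raster has no admin_id labels")
  if (any(is.na(raster$admin_id))) stop("cell with no labelled pixels")
  ox <- min(raster$x) + origin_offset[1]
  oy <- min(raster$y) + origin_offset[2]
  key <- paste(floor((raster$x - ox) / spacing),
               floor((raster$y - oy) / spacing), sep = ":")
  bins <- attr(cells, "bin_key")
  if (is.null(bins)) stop("cells must come from build_grid()")
  if (!all(bins %in% key)) stop("cell with no labelled pixels")
  cells$admin_id <- .majority_admin(key, raster$admin_id, bins)
  cells
}

#' Construct a spatial system at one scale
#'
#' A spatial system holds the cells (locations the mobility model is evaluated
#' on), the administrative units they belong to (the locations the flow data
#' is observed on), and the dense matrix of pairwise centroid distances in
#' metres. At the `"admin"` scale cells and units coincide one-to-one.
#'
#' @param cells data.frame with `id`, `x`, `y`, `population`, `admin_id`.
#' @param scale_label character tag, e.g. `"admin"`, `"20km"`.
#' @return object of class `spatial_system` with elements `cells`, `units`
#'   (per-unit population and population-weighted centroid), `D` (cell-level
#'   distance matrix), `unit_D` (unit-centroid distance matrix), `unit_index`
#'   (integer unit index per cell) and `scale_label`.
#' @export
spatial_system <- function(cells, scale_label = "grid") {
  stopifnot(is.data.frame(cells))
  req <- c("id", "x", "y", "population", "admin_id")
  if (!all(req %in% names(cells))) {
    stop("cells must have columns id, x, y, population, admin_id")
  }
  if (anyDuplicated(cells$id)) stop("cell ids must be unique")
  if (any(cells$population < 0)) stop("negative cell population")
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y))) {
    stop("non-finite centroid coordinates")
  }
  units <- .units_from_cells(cells)
  if (any(units$population <= 0)) stop("unit with non-positive population")
  sys <- structure(
    list(
      cells = cells,
      units = units,
      D = distance_matrix(cells),
      unit_D = distance_matrix(data.frame(x = units$centroid_x,
                                          y = units$centroid_y)),
      unit_index = match(cells$admin_id, units$id),
      scale_label = scale_label
    ),
    class = "spatial_system"
  )
  sys
}

.units_from_cells <- function(cells) {
  ids <- sort(unique(cells$admin_id))
  f <- factor(cells$admin_id, levels = ids)
  pop <- as.numeric(tapply(cells$population, f, sum))
  cx <- as.numeric(tapply(cells$population * cells$x, f, sum)) / pop
  cy <- as.numeric(tapply(cells$population * cells$y, f, sum)) / pop
  data.frame(id = ids, population = pop, centroid_x = cx, centroid_y = cy)
}

#' @export
print.spatial_system <- function(x, ...) {
  cat(sprintf(
    "<spatial_system '%s': %d cells, %d units, total population %.0f>\n",
    x$scale_label, nrow(x$cells), nrow(x$units), sum(x$cells$population)
  ))
  invisible(x)
}

#' Collapse a system to the administrative-unit scale
#'
#' Returns a system in which each administrative unit is a single cell located
#' at its population-weighted centroid, carrying the unit's ambient
#' population. This is the scale at which models are fitted "directly".
#'
#' @param system a `spatial_system`.
#' @return a `spatial_system` with `scale_label = "admin"`.
#' @export
admin_system <- function(system) {
  u <- system$units
  cells <- data.frame(id = seq_len(nrow(u)), x = u$centroid_x,
                      y = u$centroid_y, population = u$population,
                      admin_id = u$id)
  spatial_system(cells, scale_label = "admin")
}

#' Euclidean distance matrix between centroids (metres)
#'
#' @param points data.frame with columns `x` and `y` in metres.
#' @return dense symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(points) {
  if (any(!is.finite(points$x)) || any(!is.finite(points$y))) {
    stop("non-finite coordinates")
  }
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  dimnames(D) <- NULL
  D
}

#' Merge administrative units left empty at any grid scale
#'
#' Units that own zero cells at one or more of the gridded scales are merged
#' into the unit with the nearest population-weighted centroid, consistently
#' across all scales, repeating until every unit owns at least one cell at
#' every scale. Unit centroids for the nearest-neighbour search are taken from
#' the reference (finest available) set of cells.
#'
#' @param systems named list of `spatial_system` objects, one per scale, built
#'   over the same administrative partition.
#' @return list with `systems` (rebuilt with merged admin ids) and `merge_map`
#'   (named character vector, old id -> absorbing id; empty if no merges).
#' @export
merge_small_units <- function(systems) {
  stopifnot(is.list(systems), length(systems) >= 1L)
  all_ids <- sort(unique(unlist(lapply(systems, function(s) s$units$id))))
  if (length(all_ids) < 2L) stop("need at least 2 administrative units")

  # unit centroids/populations from the union of all scales' cells (any scale
  # that knows the unit will do; prefer the first that does)
  merge_map <- character(0)
  cells_list <- lapply(systems, function(s) s$cells)

  repeat {
    # which units are empty at some scale?
    present <- lapply(cells_list, function(cl) unique(cl$admin_id))
    ids <- sort(unique(unlist(present)))
    if (length(ids) < 2L) stop("merging left a single unit")
    empty <- ids[vapply(ids, function(u) {
      any(!vapply(present, function(p) u %in% p, logical(1)))
    }, logical(1))]
    if (length(empty) == 0L) break

    # reference centroids: pooled over scales where the unit has cells
    pooled <- do.call(rbind, cells_list)
    units <- .units_from_cells(pooled)
    u <- empty[1]
    i <- match(u, units$id)
    d <- sqrt((units$centroid_x - units$centroid_x[i])^2 +
              (units$centroid_y - units$centroid_y[i])^2)
    d[i] <- Inf
    target <- units$id[which.min(d)]
    merge_map[as.character(u)] <- as.character(target)
    cells_list <- lapply(cells_list, function(cl) {
      cl$admin_id[cl$admin_id == u] <- target
      cl
    })
  }

  # resolve chains in the merge map (a -> b -> c becomes a -> c)
  if (length(merge_map) > 0L) {
    for (k in names(merge_map)) {
      while (merge_map[[k]] %in% names(merge_map)) {
        merge_map[[k]] <- merge_map[[merge_map[[k]]]]
      }
    }
  }
  out <- Map(function(s, cl) spatial_system(cl, scale_label = s$scale_label),
             systems, cells_list)
  list(systems = out, merge_map = merge_map)
}

#' Remove low-population cells from a system
#'
#' Cells with population less than or equal to `threshold` are removed and the
#' unit populations used for modelling are recomputed from the surviving
#' cells. Used at fine grid scales where very small cells dominate the cell
#' count while holding a negligible population share.
#'
#' @param system a `spatial_system`.
#' @param threshold persons; cells with population <= threshold are dropped.
#' @return the filtered `spatial_system`, with attributes `removed_cells`
#'   (count) and `removed_pop_fraction` (share of total population removed).
#' @export
filter_low_pop_cells <- function(system, threshold = 0) {
  stopifnot(threshold >= 0)
  cells <- system$cells
  drop <- cells$population <= threshold
  if (any(drop)) {
    emptied <- setdiff(unique(cells$admin_id[drop]),
                       unique(cells$admin_id[!drop]))
    if (length(emptied) > 0L) {
      stop(sprintf("filtering empties administrative unit(s): %s",
                   paste(emptied, collapse = ", ")))
    }
  }
  total <- sum(cells$population)
  out <- spatial_system(cells[!drop, , drop = FALSE],
                        scale_label = system$scale_label)
  attr(out, "removed_cells") <- sum(drop)
  attr(out, "removed_pop_fraction") <- sum(cells$population[drop]) / total
  out
}

#' Ring populations for the radiation model
#'
#' `r[i, j]` is the population of all cells k (other than i and j) whose
#' distance from i is at most the distance from i to j — the population inside
#' the circle centred at the origin with radius equal to the trip distance,
#' excluding origin and destination populations. Cells lying exactly on the
#' circle are included (right-continuous convention).
#'
#' @param system a `spatial_system`.
#' @return n x n matrix of ring populations; zero diagonal; generally
#'   asymmetric.
#' @export
ring_population <- function(system) {
  D <- system$D
  m <- system$cells$population
  n <- length(m)
  r <- matrix(0, n, n)
  if (n < 2L) return(r)
  for (i in seq_len(n)) {
    di <- D[i, ]
    o <- order(di)
    cs <- cumsum(m[o])
    # with ties, every cell at a given distance gets the cumulative total of
    # all cells at that distance or closer: point each position at the last
    # position sharing its distance value
    idx <- seq_len(n)
    same_as_next <- c(di[o][-1] == di[o][-n], FALSE)
    j <- n
    while (j > 1L) {
      if (same_as_next[j - 1L]) idx[j - 1L] <- idx[j]
      j <- j - 1L
    }
    tot <- cs[idx]
    r[i, o] <- tot - m[o] - m[i]
  }
  diag(r) <- 0
  r
}
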