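#' @title Readers and writers for the pipeline's artifact formats
#' @description
#' All artifacts are plain text: long-format CSVs plus small JSON metadata
#' sidecars. Population rasters are CSVs with columns `x`, `y`, `population`
#' and optionally `admin_id`; flow tables are CSVs with columns `origin`,
#' `destination` and a value column.
#' @name mobfit-io
NULL

#' @rdname mobfit-io
#' @param raster data.frame with `x`, `y`, `population` (and optionally
#'   `admin_id`).
#' @param path file path.
#' @export
write_raster_csv <- function(raster, path) {
  utils::write.csv(raster, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname mobfit-io
#' @export
read_raster_csv <- function(path) {
  raster <- utils::read.csv(path, fileEncoding = "UTF-8")
  req <- c("x", "y", "population")
  if (!all(req %in% names(raster))) {
    stop("raster CSV must have header columns x, y, population")
  }
  raster
}

#' @rdname mobfit-io
#' @param system a `spatial_system`.
#' @param dir directory to hold `cells.csv`, `units.csv`, `meta.json`.
#' @param merge_map optional merge map from [merge_small_units()] recorded in
#'   the metadata sidecar.
#' @export
write_spatial_system <- function(system, dir, merge_map = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(system$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(system$units, file.path(dir, "units.csv"),
                   row.names = FALSE)
  meta <- list(scale_label = system$scale_label,
               n_cells = nrow(system$cells), n_units = nrow(system$units))
  if (!is.null(merge_map)) meta$merge_map <- as.list(merge_map)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname mobfit-io
#' @export
read_spatial_system <- function(dir) {
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  spatial_system(cells, scale_label = meta$scale_label)
}

#' @rdname mobfit-io
#' @param data a [flow_dataset()].
#' @export
write_flow_dataset <- function(data, path) {
  utils::write.csv(data$counts, path, row.names = FALSE)
  jsonlite::write_json(
    list(directional = data$directional, has_diagonal = data$has_diagonal),
    .sidecar(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname mobfit-io
#' @export
read_flow_dataset <- function(path) {
  counts <- utils::read.csv(path)
  meta <- jsonlite::read_json(.sidecar(path))
  flow_dataset(counts, directional = isTRUE(meta$directional),
               has_diagonal = isTRUE(meta$has_diagonal))
}

.sidecar <- function(path) sub("\\.csv$", "", path, ignore.case = TRUE) |>
  paste0(".json")

#' @rdname mobfit-io
#' @param flows a `flow_matrix` over admin units (unit ids as dimnames).
#' @param model,params optional provenance recorded in the sidecar.
#' @export
write_flow_matrix <- function(flows, path, model = NULL, params = NULL) {
  pv <- .pair_values(flows)
  utils::write.csv(pv, path, row.names = FALSE)
  meta <- list(diagonal_policy = attr(flows, "diagonal_policy"),
               symmetrised = isTRUE(attr(flows, "symmetrised")),
               ids = rownames(flows))
  if (!is.null(model)) meta$model <- model
  if (!is.null(params)) meta$params <- as.list(params)
  jsonlite::write_json(meta, .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mobfit-io
#' @export
read_flow_matrix <- function(path) {
  pv <- utils::read.csv(path, colClasses = c(origin = "character",
                                             destination = "character"))
  meta <- jsonlite::read_json(.sidecar(path))
  ids <- unlist(meta$ids)
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  M[cbind(match(pv$origin, ids), match(pv$destination, ids))] <- pv$value
  .flow_matrix(M, meta$diagonal_policy, isTRUE(meta$symmetrised), ids)
}

#' @rdname mobfit-io
#' @param chains list of chains from [run_chain()] or a `mobility_fit`.
#' @export
write_chains_csv <- function(chains, path) {
  if (inherits(chains, "mobility_fit")) chains <- chains$chains
  tabs <- lapply(seq_along(chains), function(c) {
    ch <- chains[[c]]
    data.frame(iteration = seq_len(nrow(ch$params)), chain = c,
               ch$params, loglik = ch$loglik)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname mobfit-io
#' @export
read_chains_csv <- function(path) {
  tab <- utils::read.csv(path)
  pn <- setdiff(names(tab), c("iteration", "chain", "loglik"))
  lapply(sort(unique(tab$chain)), function(c) {
    sub <- tab[tab$chain == c, , drop = FALSE]
    list(params = as.matrix(sub[, pn, drop = FALSE]), loglik = sub$loglik)
  })
}
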